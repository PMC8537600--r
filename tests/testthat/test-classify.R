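# Cell-type classification on the four biophysical features.

test_that("perfectly separated classes are classified without error", {
  set.seed(3)
  a <- data.frame(diameter_um = rnorm(40, 6, 0.1), ri_cytosol = 1.36,
                  ri_nucleus = 1.40, nc_ratio = 0.95, label = "T")
  b <- data.frame(diameter_um = rnorm(40, 20, 0.1), ri_cytosol = 1.36,
                  ri_nucleus = 1.40, nc_ratio = 0.92, label = "CTC")
  records <- rbind(a, b)
  for (alg in c("quadratic-svm", "linear-svm", "fine-gaussian-svm",
                "medium-knn", "kernel-naive-bayes"))
    expect_equal(cv_accuracy(records, alg, cv_folds = 5, seed = 3), 1)
})

test_that("five-class synthetic populations are learned almost perfectly", {
  pop <- sample_population(c(RBC = 200, T = 200, B = 200, M = 200,
                             CTC = 200), seed = 17)
  acc <- cv_accuracy(pop, "quadratic-svm", cv_folds = 5, seed = 17)
  expect_gte(acc, 0.99)
})

test_that("accuracy approaches one as class noise vanishes", {
  pop <- sample_population(c(T = 60, B = 60, M = 60, CTC = 60),
                           params = class_parameters(ri_sd = 1e-5,
                                                     nc_sd = 1e-5),
                           seed = 2)
  pop$diameter_um <- ave(pop$diameter_um, pop$label) # collapse D spread
  expect_equal(cv_accuracy(pop, "quadratic-svm", cv_folds = 5, seed = 2), 1)
})

test_that("training and prediction are deterministic and order-invariant", {
  pop <- sample_population(c(T = 80, B = 80, M = 80, CTC = 80), seed = 4)
  test_set <- sample_population(c(T = 30, B = 30, M = 30, CTC = 30),
                                seed = 5)
  unl <- test_set[setdiff(names(test_set), "label")]
  clf1 <- train_cell_classifier(pop, seed = 9)
  clf2 <- train_cell_classifier(pop, seed = 9)
  p1 <- predict(clf1, unl)
  p2 <- predict(clf2, unl)
  expect_identical(p1$label, p2$label)
  perm <- sample(nrow(unl))
  p3 <- predict(clf1, unl[perm, ])
  expect_identical(as.character(p3$label), as.character(p1$label)[perm])
})

test_that("reference-typical cells are assigned their own class", {
  pop <- sample_population(c(RBC = 200, T = 200, B = 200, M = 200,
                             CTC = 200), seed = 17)
  clf <- train_cell_classifier(pop, seed = 17)
  centroids <- data.frame(
    diameter_um = c(18.44, 7.64, 6.60, 7.42, 9.57),
    ri_cytosol = c(1.36, 1.40, 1.36, 1.36, 1.36),
    ri_nucleus = c(1.40, NA, 1.40, 1.42, 1.38),
    nc_ratio = c(0.920, 1.00, 0.950, 0.975, 0.784))
  pred <- predict(clf, centroids)
  expect_identical(as.character(pred$label),
                   c("CTC", "RBC", "T", "B", "M"))
})

test_that("prediction on an empty table returns an empty labelled table", {
  pop <- sample_population(c(T = 50, CTC = 50), seed = 1)
  clf <- train_cell_classifier(pop, seed = 1)
  out <- predict(clf, pop[0, setdiff(names(pop), "label")])
  expect_identical(nrow(out), 0L)
  expect_true("label" %in% names(out))
})

test_that("invalid training or prediction inputs are rejected", {
  pop <- sample_population(c(T = 50, CTC = 50), seed = 1)
  expect_error(train_cell_classifier(pop, algorithm = "deep-net"),
               "quadratic-svm")
  expect_error(train_cell_classifier(pop[pop$label == "T", ]), "2 classes")
  clf <- train_cell_classifier(pop, seed = 1)
  bad <- data.frame(diameter_um = 8, ri_cytosol = 1.36, ri_nucleus = 1.40,
                    nc_ratio = 1.2)
  expect_error(predict(clf, bad), "out of range")
})

test_that("algorithm comparison uses common folds and reproducible seeds", {
  pop <- sample_population(c(RBC = 120, T = 120, B = 120, M = 120,
                             CTC = 120), seed = 23)
  tab1 <- compare_algorithms(pop, cv_folds = 5, seed = 23)
  tab2 <- compare_algorithms(pop, cv_folds = 5, seed = 23)
  expect_identical(tab1, tab2)
  expect_identical(tab1$rank, 1:5)
  expect_true(all(diff(tab1$accuracy) <= 0))
  expect_true(all(tab1$accuracy >= 0.9 & tab1$accuracy <= 1))
})
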