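# The three component classifiers and their analytic oracles.

test_that("centroid fitting averages each class and predicts the nearer mean", {
  X <- rbind(c(0, 0), c(2, 0), c(4, 4), c(6, 4))
  y <- factor(c("NORM", "NORM", "LBBB", "LBBB"), levels = c("NORM", "LBBB"))
  m <- fit_centroid(X, y)
  expect_equal(unname(m$centroids), rbind(c(1, 0), c(5, 4)))
  expect_equal(predict_centroid(m, c(1, 0)), "NORM")
  # 1-D: centroids 0 and 2, boundary at 1, tie to NORM
  m1 <- fit_centroid(matrix(c(0, 2), ncol = 1),
                     factor(c("NORM", "LBBB"), levels = c("NORM", "LBBB")))
  expect_equal(predict_centroid(m1, matrix(c(0.9, 1.1, 1.0), ncol = 1)),
               c("NORM", "LBBB", "NORM"))
  expect_error(fit_centroid(X, factor(rep("NORM", 4))), "two classes")
  expect_error(predict_centroid(m, c(1, 2, 3)), "dimension")
})

test_that("the weighted scatter matrix follows the unnormalised weighted sum", {
  X <- matrix(c(0, 2, 4, 6), ncol = 1)
  y <- factor(c("a", "a", "b", "b"))
  m <- fit_wlda(X, y, w = c(1, 1))
  expect_equal(unname(m$means), matrix(c(1, 5), ncol = 1))
  expect_equal(as.numeric(m$sigma), 4)  # (0-1)^2+(2-1)^2+(4-5)^2+(6-5)^2
  # linear in the weights
  m10 <- fit_wlda(X, y, w = c(10, 10))
  expect_equal(as.numeric(m10$sigma), 40)
  # degenerate scatter engages the logged ridge fallback
  Xd <- matrix(c(1, 1, 3, 3), ncol = 1)
  expect_warning(md <- fit_wlda(Xd, y), "ridge")
  expect_gt(md$ridge_used, 0)
  expect_error(fit_wlda(Xd, y, ridge_eps = 0), "singular")
})

test_that("posteriors follow the softmax of the linear discriminants", {
  X <- matrix(c(0, 2, 4, 6), ncol = 1)
  y <- factor(c("NORM", "NORM", "RBBB", "RBBB"))
  m <- fit_wlda(X, y, w = c(1, 1))
  # boundary at the midpoint of the means
  expect_equal(as.vector(wlda_posterior(m, 3)), c(0.5, 0.5))
  # g1 - g2 = 2 at x = 1  =>  P(NORM) = 1 / (1 + e^-2)
  expect_equal(unname(wlda_posterior(m, 1)[1, "NORM"]), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(unname(round(wlda_posterior(m, 1)[1, "NORM"], 4)), 0.8808)
  # normalization and range, including far-out x (overflow guard)
  for (x in c(-1e4, -3, 0, 3, 7, 1e4)) {
    P <- wlda_posterior(m, x)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_equal(predict_wlda(m, matrix(c(1, 3, 5), ncol = 1)),
               c("NORM", "NORM", "RBBB"))  # exact 0.5 tie resolves to NORM
  expect_error(wlda_posterior(m, NaN), "non-finite")
})

test_that("with identity scatter and equal priors the discriminant equals the centroid rule", {
  set.seed(31)
  d <- 5
  mu <- rbind(rnorm(d), rnorm(d) + 1)
  wlda <- structure(list(class_labels = c("NORM", "RBBB"), means = mu,
                         sigma = diag(d), sigma_inv = diag(d),
                         weights = c(1, 1), priors = c(0.5, 0.5),
                         ridge_eps = 0, ridge_used = 0), class = "bbb_wlda")
  cent <- structure(list(class_labels = c("NORM", "RBBB"), centroids = mu),
                    class = "bbb_centroid")
  X <- matrix(rnorm(1200 * d), ncol = d)
  expect_equal(predict_wlda(wlda, X), predict_centroid(cent, X))
})

test_that("equal-prior predictions are invariant to uniform weight scaling", {
  set.seed(32)
  X <- rbind(matrix(rnorm(80, 0), ncol = 2), matrix(rnorm(60, 2), ncol = 2))
  y <- factor(rep(c("NORM", "RBBB"), c(40, 30)))
  Xtest <- matrix(rnorm(400), ncol = 2)
  base <- predict_wlda(fit_wlda(X, y, w = c(0.03, 0.6)), Xtest)
  for (s in c(0.1, 1, 7, 120)) {
    scaled <- predict_wlda(fit_wlda(X, y, w = s * c(0.03, 0.6)), Xtest)
    expect_equal(scaled, base)
  }
})

test_that("fitting is invariant to sample order", {
  set.seed(33)
  X <- matrix(rnorm(120), ncol = 2)
  y <- factor(rep(c("NORM", "LBBB"), each = 30))
  perm <- sample(60)
  m1 <- fit_centroid(X, y); m2 <- fit_centroid(X[perm, ], y[perm])
  expect_equal(m1$centroids, m2$centroids)
  w1 <- fit_wlda(X, y); w2 <- fit_wlda(X[perm, ], y[perm])
  expect_equal(w1$sigma, w2$sigma)
  expect_equal(w1$means, w2$means)
})

test_that("the linear SVM finds the max-margin boundary and is symmetric", {
  X <- matrix(c(-1, 1), ncol = 1)
  y <- factor(c("LBBB", "RBBB"))
  m <- fit_linear_svm(X, y, C = 1000)
  # boundary at 0: decision value vanishes there
  expect_equal(as.numeric(m$weight_vector %*% 0 + m$bias), 0, tolerance = 1e-6)
  expect_equal(predict_svm(m, X), c("LBBB", "RBBB"))
  # separable 2-D blobs: perfect training accuracy
  set.seed(34)
  X2 <- rbind(matrix(rnorm(60, -3), ncol = 2), matrix(rnorm(60, 3), ncol = 2))
  y2 <- factor(rep(c("LBBB", "RBBB"), each = 30))
  m2 <- fit_linear_svm(X2, y2, C = 1)
  expect_equal(predict_svm(m2, X2), as.character(y2))
  # label swap mirrors predictions
  y2s <- factor(ifelse(y2 == "LBBB", "RBBB", "LBBB"), levels = levels(y2))
  m2s <- fit_linear_svm(X2, y2s, C = 1)
  expect_equal(predict_svm(m2s, X2), as.character(y2s))
  expect_error(fit_linear_svm(X2, y2, C = -1), "positive")
})

test_that("SVM prediction agrees with independently recomputed decision values", {
  set.seed(35)
  X <- rbind(matrix(rnorm(80, -1.5), ncol = 4), matrix(rnorm(80, 1.5), ncol = 4))
  y <- factor(rep(c("LBBB", "RBBB"), each = 20))
  m <- fit_linear_svm(X, y, C = 1)
  Xnew <- matrix(rnorm(40), ncol = 4)
  dv <- vapply(seq_len(10), function(i) sum(m$weight_vector * Xnew[i, ]) + m$bias,
               numeric(1))
  expect_equal(predict_svm(m, Xnew),
               ifelse(dv > 0, "LBBB", ifelse(dv < 0, "RBBB", "NORM")))
  # hand-built hyperplane including the zero-decision tie rule
  hm <- structure(list(class_labels = c("LBBB", "RBBB"),
                       weight_vector = c(1, 0, 0, 0), bias = -2,
                       penalty_C = 1, class_weights = c(1, 1)),
                  class = "bbb_svm")
  expect_equal(predict_svm(hm, rbind(c(3, 0, 0, 0), c(1, 0, 0, 0), c(2, 5, 5, 5))),
               c("LBBB", "RBBB", "LBBB"))  # exact zero -> first class label
})

test_that("models and bases serialize to JSON and restore identically", {
  ds <- small_dataset(seed = 8, n = c(NORM = 60, LBBB = 30, RBBB = 30))
  idx <- c(1:40, 61:80)           # 40 NORM + 20 LBBB rows
  X <- assemble_morph(ds$train[idx, ])
  y <- droplevels(ds$train$label[idx])
  dir <- withr::local_tempdir()

  cm <- fit_centroid(X, factor(ifelse(as.character(y) == "NORM", "NORM", "LBBB"),
                               levels = c("NORM", "LBBB")))
  p <- file.path(dir, "cent.json")
  write_model(cm, p)
  back <- read_model(p)
  expect_s3_class(back, "bbb_centroid")
  expect_equal(back$centroids, unname(cm$centroids), ignore_attr = TRUE)
  expect_equal(predict_centroid(back, X), predict_centroid(cm, X))

  wm <- fit_wlda(X[, c(1, 50, 401)], factor(ifelse(as.character(y) == "NORM",
                                                   "NORM", "RBBB")))
  write_model(wm, file.path(dir, "wlda.json"))
  wback <- read_model(file.path(dir, "wlda.json"))
  expect_equal(wlda_posterior(wback, X[, c(1, 50, 401)]),
               wlda_posterior(wm, X[, c(1, 50, 401)]), tolerance = 1e-12)

  sm <- fit_linear_svm(X[, 1:5], factor(ifelse(as.character(y) == "NORM",
                                               "LBBB", "RBBB")), C = 0.1)
  write_model(sm, file.path(dir, "svm.json"))
  sback <- read_model(file.path(dir, "svm.json"))
  expect_equal(sback$weight_vector, sm$weight_vector)
  expect_equal(sback$penalty_C, 0.1)

  basis <- fit_ica_basis(ds$train, "A", n_components = 5, seed = 1)
  write_model(basis, file.path(dir, "basis.json"))
  bback <- read_model(file.path(dir, "basis.json"))
  expect_s3_class(bback, "bbb_ica_basis")
  expect_equal(bback$components, basis$components)
  expect_equal(ica_project(ds$test$lead_a[[1]], bback),
               ica_project(ds$test$lead_a[[1]], basis))
})
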