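# ICA basis fitting, pseudo-inverse projection and feature assembly.

test_that("per-record basis selection takes the canonical per-class quotas", {
  # 18 records with NORM, 2 with LBBB, 3 with RBBB, ample beats each
  set.seed(10)
  mk_class <- function(cls, recs, per_rec) {
    mk_beats(rep(cls, length(recs) * per_rec),
             replicate(length(recs) * per_rec, rnorm(8), simplify = FALSE),
             replicate(length(recs) * per_rec, rnorm(8), simplify = FALSE),
             record_id = rep(recs, each = per_rec),
             r_index = rep(seq_len(per_rec) * 300L, length(recs)))
  }
  beats <- dplyr::bind_rows(
    mk_class("NORM", sprintf("n%02d", 1:18), 15),
    mk_class("LBBB", c("l01", "l02"), 120),
    mk_class("RBBB", c("r01", "r02", "r03"), 90))
  sel <- select_basis_beats(beats)
  expect_equal(nrow(sel), 620)
  expect_equal(as.vector(table(sel$label)[c("NORM", "LBBB", "RBBB")]),
               c(180L, 200L, 240L))
  # deterministic: first beats in temporal order per record
  sel2 <- select_basis_beats(beats)
  expect_identical(sel, sel2)
  first_norm <- dplyr::filter(sel, record_id == "n01")
  expect_equal(first_norm$r_index, seq_len(10) * 300L)
  # shortfall is an error naming the record
  short <- dplyr::filter(beats, !(record_id == "r02" & r_index > 300))
  expect_error(select_basis_beats(short), "r02 has only 1 RBBB")
})

test_that("projection of a component row returns a standard basis vector", {
  ds <- small_dataset(seed = 3, n = c(NORM = 60, LBBB = 30, RBBB = 30))
  basis <- fit_ica_basis(ds$train, "A", n_components = 10, seed = 1)
  for (i in c(1, 5, 10)) {
    f <- ica_project(basis$components[i, ], basis)
    e <- rep(0, 10); e[i] <- 1
    expect_equal(f, e, tolerance = 1e-8)
  }
  expect_equal(ica_project(rep(0, 200), basis), rep(0, 10))
  expect_error(ica_project(rep(0, 50), basis), "does not match")
})

test_that("the cached pseudo-inverse matches a hand-computed 2x4 case", {
  A <- rbind(c(1, 0, 0, 0), c(0, 2, 0, 0))
  pinv <- bbbensemble:::pracma_pinv(A)
  expect_equal(pinv, rbind(c(1, 0), c(0, 0.5), c(0, 0), c(0, 0)))
  basis <- structure(list(lead = "A", components = A, pinv_components = pinv,
                          n_components = 2), class = "bbb_ica_basis")
  expect_equal(ica_project(c(3, 4, 0, 0), basis), c(3, 2))
})

test_that("projection is linear", {
  ds <- small_dataset(seed = 4, n = c(NORM = 60, LBBB = 30, RBBB = 30))
  basis <- fit_ica_basis(ds$train, "B", n_components = 8, seed = 2)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(200); y <- rnorm(200)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(ica_project(a * x + b * y, basis),
                 a * ica_project(x, basis) + b * ica_project(y, basis),
                 tolerance = 1e-9)
  }
})

test_that("FastICA recovers known super-Gaussian sources", {
  set.seed(21)
  n <- 400; p <- 12
  S0 <- matrix(sign(rnorm(n * 3)) * rexp(n * 3), n, 3)      # Laplace-like
  A0 <- matrix(rnorm(3 * p), 3, p)
  X <- S0 %*% A0
  beats <- mk_beats(rep("NORM", n),
                    lapply(seq_len(n), function(i) X[i, ]),
                    lapply(seq_len(n), function(i) X[i, ]))
  basis <- fit_ica_basis(beats, "A", n_components = 3, seed = 5)
  S_est <- X %*% basis$pinv_components
  cors <- abs(stats::cor(S_est, S0))
  # each estimated component matches one distinct true source
  matched <- apply(cors, 2, max)
  expect_true(all(matched > 0.95))
  expect_equal(sort(apply(cors, 2, which.max)), 1:3)
})

test_that("basis fitting is bit-reproducible under a fixed seed", {
  ds <- small_dataset(seed = 5, n = c(NORM = 60, LBBB = 30, RBBB = 30))
  b1 <- fit_ica_basis(ds$train, "A", n_components = 6, seed = 9)
  b2 <- fit_ica_basis(ds$train, "A", n_components = 6, seed = 9)
  expect_identical(b1$components, b2$components)
  expect_identical(b1$pinv_components, b2$pinv_components)
  # the pseudo-inverse invariant
  A <- b1$components
  expect_lt(norm(A %*% b1$pinv_components %*% A - A, "F"), 1e-6 * norm(A, "F"))
})

test_that("feature assembly produces the documented layouts", {
  ds <- small_dataset(seed = 6, n = c(NORM = 60, LBBB = 30, RBBB = 30))
  beats <- ds$test[1:10, ]
  morph <- assemble_morph(beats)
  expect_equal(dim(morph), c(10, 401))
  expect_equal(morph[, 401], beats$rr_s)
  expect_equal(morph[3, 1:200], beats$lead_a[[3]])
  expect_equal(morph[3, 201:400], beats$lead_b[[3]])
  expect_equal(dim(assemble_morph(beats, leads = "A")), c(10, 201))

  bases <- list(A = fit_ica_basis(ds$train, "A", n_components = 12, seed = 1),
                B = fit_ica_basis(ds$train, "B", n_components = 12, seed = 1))
  icaf <- assemble_ica(beats, bases)
  expect_equal(dim(icaf), c(10, 25))
  expect_equal(icaf[, 25], beats$rr_s)
  # lead-A features do not depend on the lead-B basis
  bases_swapped <- list(A = bases$A, B = fit_ica_basis(ds$train, "B",
                                                       n_components = 12, seed = 99))
  icaf2 <- assemble_ica(beats, bases_swapped)
  expect_equal(icaf2[, 1:12], icaf[, 1:12])
  expect_equal(dim(assemble_ica(beats, bases, leads = "A")), c(10, 13))
  # basis/lead mismatch is an error
  expect_error(assemble_ica(beats, list(A = bases$B, B = bases$B)),
               "fitted for lead B")
})

test_that("a larger basis reconstructs training beats at least as well", {
  ds <- small_dataset(seed = 7, n = c(NORM = 80, LBBB = 30, RBBB = 30))
  X <- do.call(rbind, ds$train$lead_a)
  small <- fit_ica_basis(ds$train, "A", n_components = 10, seed = 3)
  large <- fit_ica_basis(ds$train, "A", n_components = 40, seed = 3)
  resid <- function(b) {
    R <- X - (X %*% b$pinv_components) %*% b$components
    sum(R^2)
  }
  expect_lt(resid(large), resid(small))
})
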