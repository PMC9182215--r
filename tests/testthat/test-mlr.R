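# MLR engine: scaling, OLS, LOO and k-fold Q2, subset search, raw equations.

test_that("z-scoring normalizes, is idempotent, and round-trips", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  rownames(m) <- paste0("r", 1:3)
  z <- zscore_matrix(m)
  expect_equal(z$scaled[, "a"], c(r1 = -1, r2 = 0, r3 = 1))
  expect_lt(max(abs(colMeans(z$scaled))), 1e-10)
  expect_lt(max(abs(apply(z$scaled, 2, sd) - 1)), 1e-10)
  z2 <- zscore_matrix(z$scaled)
  expect_equal(z2$scaled, z$scaled, tolerance = 1e-10)
  expect_equal(unscale_matrix(z$scaled, z$scaling), m, tolerance = 1e-10)
  expect_error(zscore_matrix(cbind(a = c(1, 1, 1))), "constant")
})

test_that("OLS recovers exact coefficients on noiseless data and matches
           the normal-equations oracle", {
  set.seed(71)
  x <- matrix(rnorm(15), ncol = 1, dimnames = list(NULL, "x"))
  y <- 3 + 2 * x[, 1]
  fit <- fit_ols(x, y)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), c(3, 2), tolerance = 1e-10)

  for (rep in 1:100) {
    X <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, paste0("x", 1:3)))
    y <- rnorm(15)
    fit <- fit_ols(X, y)
    expect_equal(unname(fit$coefficients), ols_oracle(X, y), tolerance = 1e-8)
  }
})

test_that("a flat response against orthogonal columns gives near-zero slope and R2", {
  set.seed(72)
  X <- qr.Q(qr(matrix(rnorm(30), 15)))[, 1:2]
  colnames(X) <- c("a", "b")
  y <- rep(2, 15) + rnorm(15, sd = 1e-10)
  fit <- fit_ols(X, y)
  expect_lt(abs(fit$coefficients[["a"]]), 1e-8)
  expect_lt(abs(fit$coefficients[["b"]]), 1e-8)
  expect_lt(max(abs(fit$fitted - 2)), 1e-8)  # flat prediction at the mean
})

test_that("rank-deficient designs are rejected", {
  X <- cbind(a = rnorm(10), b = 0)
  X <- cbind(X, c = X[, "a"])
  expect_error(fit_ols(X[, c("a", "c")], rnorm(10)), "rank-deficient")
})

test_that("LOO Q2: exact on noiseless data; refit equals hat identity;
           both match an independent oracle", {
  set.seed(73)
  X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  y_exact <- 1 + X %*% c(2, -1)
  expect_equal(q2_loo(X, drop(y_exact)), 1, tolerance = 1e-10)
  for (rep in 1:100) {
    Xr <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, paste0("x", 1:3)))
    yr <- rnorm(15)
    refit <- q2_loo(Xr, yr, method = "refit")
    hat <- q2_loo(Xr, yr, method = "hat")
    expect_equal(refit, hat, tolerance = 1e-8)
    expect_equal(refit, q2_loo_oracle(Xr, yr), tolerance = 1e-8)
  }
})

test_that("pure-noise responses give Q2 < R2 and usually Q2 < 0", {
  set.seed(74)
  q2s <- r2s <- numeric(200)
  for (i in 1:200) {
    X <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, paste0("x", 1:3)))
    y <- rnorm(15)
    r2s[i] <- fit_ols(X, y)$r2
    q2s[i] <- q2_loo(X, y, method = "hat")
  }
  expect_true(all(q2s <= r2s + 1e-10))
  expect_gt(mean(q2s < 0), 0.5)
})

test_that("repeated k-fold Q2: exact on noiseless data, seed-deterministic,
           and reduces to LOO at k = n", {
  set.seed(75)
  X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(2 + X %*% c(1, 3))
  cv <- q2_kfold(X, y, k = 3, iterations = 20, seed = 5)
  expect_equal(cv$mean, 1, tolerance = 1e-8)

  yn <- y + rnorm(15, sd = 0.5)
  cv1 <- q2_kfold(X, yn, k = 5, iterations = 50, seed = 9)
  cv2 <- q2_kfold(X, yn, k = 5, iterations = 50, seed = 9)
  expect_identical(cv1$values, cv2$values)
  cv3 <- q2_kfold(X, yn, k = 5, iterations = 50, seed = 10)
  expect_false(identical(cv1$values, cv3$values))

  loo <- q2_loo(X, yn, method = "refit")
  cvn <- q2_kfold(X, yn, k = 15, iterations = 3, seed = 1)
  expect_equal(cvn$mean, loo, tolerance = 1e-10)
  expect_equal(cvn$sd, 0, tolerance = 1e-12)
  expect_error(q2_kfold(X, yn, k = 16), "k must lie")
})

test_that("subset search: max_terms = 1 ranking equals the brute-force
           single-column Q2 list", {
  set.seed(76)
  sp <- synth_spec(n_descriptors = 10, seed = 20)
  m <- gen_matrix(sp)
  y <- gen_response(m, sp)$response
  sr <- subset_search(m, y, max_terms = 1, kfold_top = 0)
  brute <- vapply(colnames(m), function(cn) {
    z <- zscore_matrix(m)$scaled[, cn, drop = FALSE]
    q2_loo(z, as.numeric(y[rownames(m)]), method = "refit")
  }, numeric(1))
  expect_equal(sr$table$model, names(sort(brute, decreasing = TRUE)))
  expect_equal(sr$table$q2_loo, unname(sort(brute, decreasing = TRUE)),
               tolerance = 1e-10)
})

test_that("near-duplicate columns are never co-selected under the
           collinearity filter", {
  set.seed(77)
  m <- matrix(rnorm(150), 15, 10,
              dimnames = list(sprintf("BA%02d", 1:15), paste0("x", 1:10)))
  m[, 2] <- m[, 1] + rnorm(15, sd = 1e-4)  # |r| ~ 1
  y <- drop(m[, 1] + 0.5 * m[, 3] + rnorm(15, 0.1))
  names(y) <- rownames(m)
  sr <- subset_search(descriptor_matrix(m), y, max_terms = 3,
                      collinearity_cut = 0.99, kfold_top = 0)
  both <- vapply(sr$fits, function(f) all(c("x1", "x2") %in% f$labels),
                 logical(1))
  expect_false(any(both))
  # and every retained fit satisfies Q2 <= R2
  expect_true(all(sr$table$q2_loo <= sr$table$r2 + 1e-10))
})

test_that("search rejects degenerate inputs", {
  m <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  rownames(m) <- sprintf("BA%02d", 1:15)
  y <- setNames(rnorm(15), rownames(m))
  const <- cbind(a = rep(1, 15), b = rnorm(15))
  rownames(const) <- rownames(m)
  expect_error(subset_search(descriptor_matrix(const), y), "constant")
  expect_error(subset_search(m, setNames(rep(1, 15), rownames(m))),
               "no variance")
})

test_that("raw equations: closed form and prediction equivalence", {
  # single column, mean 10, sd 2, normalized slope 1, intercept 0
  fit <- structure(list(labels = "x",
                        coefficients = c(`(Intercept)` = 0, x = 1)),
                   class = "qssr_model_fit")
  fit <- raw_equation(fit, list(mean = c(x = 10), sd = c(x = 2)))
  expect_equal(unname(fit$coef_raw), c(-5, 0.5))
  # identity scaling leaves coefficients unchanged
  fit2 <- raw_equation(fit, list(mean = c(x = 0), sd = c(x = 1)))
  expect_equal(fit2$coef_raw, fit2$coefficients)

  set.seed(78)
  for (rep in 1:10) {
    sp <- synth_spec(seed = 300 + rep)
    m <- gen_matrix(sp)
    y <- gen_response(m, sp)$response
    sr <- subset_search(m, y, kfold_top = 0)
    f <- sr$fits[[1]]
    z <- zscore_matrix(m)
    pred_norm <- predict(f, z$scaled)
    pred_raw <- predict(f, unclass(m), raw = TRUE)
    expect_lt(max(abs(pred_norm - pred_raw)), 1e-8)
  }
  expect_error(raw_equation(fit, list(mean = c(z = 0), sd = c(z = 1))),
               "does not cover")
})

test_that("R2 and Q2 are invariant under affine rescaling of a column", {
  set.seed(79)
  sp <- synth_spec(n_descriptors = 6, true_subset = c(1, 2, 3), seed = 55)
  m <- gen_matrix(sp)
  y <- gen_response(m, sp)$response
  sr1 <- subset_search(m, y, kfold_top = 0)
  m2 <- unclass(m)
  m2[, 2] <- 7 - 3.5 * m2[, 2]
  sr2 <- subset_search(descriptor_matrix(m2), y, kfold_top = 0)
  expect_equal(sr1$table$q2_loo, sr2$table$q2_loo, tolerance = 1e-9)
  expect_equal(sr1$table$r2, sr2$table$r2, tolerance = 1e-9)
})
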