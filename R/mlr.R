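# Multivariate linear regression engine: z-score normalization, OLS with
# R2, leave-one-out and repeated k-fold Q2 (PRESS-based), exhaustive
# best-subset search ranked by Q2(LOO) -- the selection criterion, chosen
# over R2 because it also reflects predictive robustness -- and conversion
# between normalized and raw-parameter equations.

RCOND_TOL <- 1e-10  # reciprocal condition number below this = rank-deficient

#' Z-score a descriptor matrix
#'
#' Centers and scales every column to mean 0, sd 1 (sample sd, n-1
#' denominator), recording the per-column means and sds so fitted
#' normalized equations can be mapped back to raw parameters with
#' [raw_equation()].
#'
#' @param m Numeric matrix (or `qssr_descriptor_matrix`) with column names.
#' @return List with `scaled` (matrix) and `scaling` (list with named
#'   vectors `mean` and `sd`).
#' @export
zscore_matrix <- function(m) {
  m <- unclass(as.matrix(m))
  storage.mode(m) <- "double"
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  const <- which(!is.finite(sd) | sd == 0)
  if (length(const))
    stop("constant column(s) cannot be z-scored: ",
         paste(colnames(m)[const], collapse = ", "))
  scaled <- sweep(sweep(m, 2, mu), 2, sd, "/")
  list(scaled = scaled, scaling = list(mean = mu, sd = sd))
}

#' Invert a z-score transform
#'
#' @param scaled Matrix produced by [zscore_matrix()].
#' @param scaling The matching `scaling` record.
#' @return Matrix on the original scale.
#' @export
unscale_matrix <- function(scaled, scaling) {
  sweep(sweep(scaled, 2, scaling$sd[colnames(scaled)], "*"), 2,
        scaling$mean[colnames(scaled)], "+")
}

# OLS core on an explicit design matrix with intercept column prepended.
# Returns coefficients, fitted values, residuals, hat diagonal.
ols_core <- function(X, y) {
  X1 <- cbind(`(Intercept)` = 1, X)
  d <- svd(X1, nu = 0, nv = 0)$d
  if (d[length(d)] / d[1] < RCOND_TOL)
    stop(sprintf("design matrix is rank-deficient (rcond %.2e)",
                 d[length(d)] / d[1]))
  qx <- qr(X1)
  beta <- qr.coef(qx, y)
  fitted <- drop(X1 %*% beta)
  q <- qr.Q(qx)
  list(coef = beta, fitted = fitted, resid = y - fitted,
       hat = rowSums(q^2))
}

#' Ordinary least-squares fit
#'
#' Fits `y ~ X` with an intercept and computes R2 = 1 - RSS/TSS (TSS about
#' the mean of `y`). Cross-validation fields of the returned fit are `NA`
#' until filled by [q2_loo()]/[q2_kfold()] or by [subset_search()].
#'
#' @param X Numeric matrix of descriptor columns (named).
#' @param y Numeric response, length `nrow(X)`; if named, it is aligned to
#'   `rownames(X)`.
#' @return An object of class `qssr_model_fit`: selected labels,
#'   coefficients, R2, residuals, hat diagonal, `n_obs`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    if (!all(rownames(X) %in% names(y)))
      stop("response is missing values for: ",
           paste(setdiff(rownames(X), names(y)), collapse = ", "))
    y <- y[rownames(X)]
  }
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= ncol(X) + 1L)
    stop(sprintf("need n_obs > n_terms + 1 (n = %d, terms = %d)", n, ncol(X)))
  core <- ols_core(X, y)
  rss <- sum(core$resid^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(labels = colnames(X), coefficients = core$coef,
         r2 = if (tss > 0) 1 - rss / tss else NA_real_,
         rss = rss, tss = tss, fitted = core$fitted, residuals = core$resid,
         hat = core$hat, n_obs = n,
         q2_loo = NA_real_, q2_kfold3 = NA_real_, q2_kfold5 = NA_real_,
         coef_raw = NULL),
    class = "qssr_model_fit")
}

#' @export
print.qssr_model_fit <- function(x, ...) {
  cat(sprintf("<qssr_model_fit> y ~ %s\n", paste(x$labels, collapse = " + ")))
  cat(sprintf("  n = %d, R2 = %.4f, Q2_LOO = %s\n", x$n_obs, x$r2,
              ifelse(is.na(x$q2_loo), "NA", sprintf("%.4f", x$q2_loo))))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object A `qssr_model_fit`.
#' @param newdata Matrix with the fit's descriptor columns (same scale the
#'   fit was produced on; use the raw coefficients via `raw = TRUE` if the
#'   fit has been through [raw_equation()] and `newdata` is unscaled).
#' @param raw Use the raw-parameter equation (requires [raw_equation()]).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.qssr_model_fit <- function(object, newdata, raw = FALSE, ...) {
  beta <- if (raw) {
    if (is.null(object$coef_raw)) stop("fit has no raw equation; call raw_equation()")
    object$coef_raw
  } else object$coefficients
  X <- as.matrix(newdata)[, object$labels, drop = FALSE]
  drop(cbind(1, X) %*% beta)
}

#' Leave-one-out cross-validated Q2
#'
#' `Q2 = 1 - PRESS/TSS` with `PRESS = sum (y_i - yhat_(-i))^2` and TSS
#' taken about the full-sample mean. The reference path (`method =
#' "refit"`) performs the n explicit leave-one-out refits; `method = "hat"`
#' uses the algebraic identity `e_(-i) = e_i / (1 - h_ii)`, which is exact
#' for OLS and much faster.
#'
#' @param X Descriptor matrix (named columns).
#' @param y Response vector.
#' @param method `"refit"` (reference) or `"hat"`.
#' @return Q2 (numeric scalar).
#' @export
q2_loo <- function(X, y, method = c("refit", "hat")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  tss <- sum((y - mean(y))^2)
  if (method == "hat") {
    core <- ols_core(X, y)
    press <- sum((core$resid / (1 - core$hat))^2)
  } else {
    press <- 0
    for (i in seq_len(n)) {
      core <- ols_core(X[-i, , drop = FALSE], y[-i])
      pred <- drop(c(1, X[i, ]) %*% core$coef)
      press <- press + (y[i] - pred)^2
    }
  }
  1 - press / tss
}

#' Repeated k-fold cross-validated Q2
#'
#' Per iteration, the observations are randomly partitioned into k folds of
#' sizes differing by at most one; each fold is predicted from a model fit
#' on the rest; the pooled out-of-fold PRESS gives that iteration's
#' `Q2 = 1 - PRESS/TSS` (TSS about the full-sample mean). The mean and sd
#' over iterations are returned. Fully reproducible given `seed`
#' (per-iteration partitions are drawn from one seeded stream). With
#' `k = n` every partition is the singleton one and the result equals
#' [q2_loo()].
#'
#' @param X Descriptor matrix.
#' @param y Response vector.
#' @param k Number of folds, `2 <= k <= nrow(X)` (the study uses 3 and 5).
#' @param iterations Number of random partitions (default 500).
#' @param seed Integer seed for the partition stream.
#' @return List with `mean`, `sd`, `values` (per-iteration Q2), `k`,
#'   `iterations`, `seed`.
#' @export
q2_kfold <- function(X, y, k, iterations = 500L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 2L || k > n) stop(sprintf("k must lie in [2, n]; got k = %d, n = %d", k, n))
  tss <- sum((y - mean(y))^2)
  vals <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(iterations), function(it) {
      fold <- sample(rep_len(seq_len(k), n))
      press <- 0
      for (f in seq_len(k)) {
        test <- which(fold == f)
        core <- ols_core(X[-test, , drop = FALSE], y[-test])
        pred <- drop(cbind(1, X[test, , drop = FALSE]) %*% core$coef)
        press <- press + sum((y[test] - pred)^2)
      }
      1 - press / tss
    }, numeric(1))
  })
  list(mean = mean(vals), sd = stats::sd(vals), values = vals,
       k = k, iterations = as.integer(iterations), seed = as.integer(seed))
}

#' Exhaustive best-subset regression ranked by Q2(LOO)
#'
#' Fits every subset of 1..`max_terms` descriptor columns whose pairwise
#' absolute correlations all lie below `collinearity_cut`, on the z-scored
#' matrix, and ranks the fits by leave-one-out Q2 (descending). Ties are
#' broken by fewer terms, then higher R2, then lexicographic labels. Every
#' admissible fit is retained for reporting. Raw-parameter equations are
#' attached via [raw_equation()]; repeated 3-fold and 5-fold Q2 (500
#' iterations each by default) are computed for the top `kfold_top` models.
#'
#' A Q2(LOO) exceeding R2 on any fit indicates a broken PRESS computation
#' (PRESS >= RSS always holds for OLS) and aborts the search.
#'
#' @param m Descriptor matrix (`qssr_descriptor_matrix` or plain matrix
#'   with row/column names).
#' @param y Response: named vector keyed by modifier (aligned to rows of
#'   `m`) or plain vector of length `nrow(m)`.
#' @param max_terms Maximum subset size (default 3, the model size used
#'   throughout the study).
#' @param collinearity_cut Pairwise |r| at or above which two descriptors
#'   are never co-selected (default 0.8).
#' @param kfold_top Number of top-ranked models to evaluate by repeated
#'   k-fold CV (default 1; 0 to skip).
#' @param kfold_iterations Iterations per k-fold CV (default 500).
#' @param seed Seed for the k-fold partition streams.
#' @return An object of class `qssr_search`: list with `fits` (ranked list
#'   of `qssr_model_fit`), `table` (summary data frame), `scaling`,
#'   `n_subsets_considered`, `settings`.
#' @export
subset_search <- function(m, y, max_terms = 3L, collinearity_cut = 0.8,
                          kfold_top = 1L, kfold_iterations = 500L, seed = 1L) {
  z <- zscore_matrix(m)
  Z <- z$scaled
  n <- nrow(Z)
  p <- ncol(Z)
  max_terms <- as.integer(max_terms)
  if (max_terms < 1L) stop("max_terms must be >= 1")
  max_terms <- min(max_terms, p, n - 2L)
  yv <- y
  if (!is.null(names(yv)) && !is.null(rownames(Z))) {
    if (!all(rownames(Z) %in% names(yv)))
      stop("response is missing values for: ",
           paste(setdiff(rownames(Z), names(yv)), collapse = ", "))
    yv <- yv[rownames(Z)]
  }
  if (length(yv) != n) stop("length(y) must equal nrow(m)")
  yv <- as.numeric(yv)
  tss <- sum((yv - mean(yv))^2)
  if (tss <= 0) stop("response has no variance; nothing to model")

  cmat <- abs(stats::cor(Z))
  admissible_pair <- cmat < collinearity_cut
  diag(admissible_pair) <- TRUE

  fits <- list()
  considered <- 0L
  for (size in seq_len(max_terms)) {
    subs <- utils::combn(p, size, simplify = FALSE)
    for (sub in subs) {
      if (size > 1L && !all(admissible_pair[sub, sub])) next
      considered <- considered + 1L
      fit <- tryCatch({
        X <- Z[, sub, drop = FALSE]
        core <- ols_core(X, yv)
        rss <- sum(core$resid^2)
        press <- sum((core$resid / (1 - core$hat))^2)
        structure(
          list(labels = colnames(Z)[sub], coefficients = core$coef,
               r2 = 1 - rss / tss, rss = rss, tss = tss,
               fitted = core$fitted, residuals = core$resid, hat = core$hat,
               n_obs = n, q2_loo = 1 - press / tss,
               q2_kfold3 = NA_real_, q2_kfold5 = NA_real_, coef_raw = NULL),
          class = "qssr_model_fit")
      }, error = function(e) NULL)  # rank-deficient subsets are skipped
      if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
    }
  }
  if (!length(fits))
    stop("no admissible descriptor subset under the collinearity filter")

  bad <- vapply(fits, function(f) f$q2_loo > f$r2 + 1e-10, logical(1))
  if (any(bad))
    stop("internal error: Q2(LOO) exceeded R2 for some fit (PRESS < RSS is impossible for OLS)")

  q2s <- vapply(fits, `[[`, numeric(1), "q2_loo")
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  sizes <- lengths(lapply(fits, `[[`, "labels"))
  lab <- vapply(fits, function(f) paste(f$labels, collapse = " + "), character(1))
  ord <- order(-q2s, sizes, -r2s, lab)
  fits <- fits[ord]

  fits <- lapply(fits, raw_equation, scaling = z$scaling)
  for (i in seq_len(min(as.integer(kfold_top), length(fits)))) {
    X <- Z[, fits[[i]]$labels, drop = FALSE]
    cv3 <- q2_kfold(X, yv, k = 3L, iterations = kfold_iterations, seed = seed)
    cv5 <- q2_kfold(X, yv, k = 5L, iterations = kfold_iterations,
                    seed = seed + 1L)
    fits[[i]]$q2_kfold3 <- cv3$mean
    fits[[i]]$q2_kfold5 <- cv5$mean
  }

  table <- data.frame(
    rank = seq_along(fits),
    model = vapply(fits, function(f) paste(f$labels, collapse = " + "),
                   character(1)),
    n_terms = lengths(lapply(fits, `[[`, "labels")),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    q2_loo = vapply(fits, `[[`, numeric(1), "q2_loo"),
    q2_3fold = vapply(fits, `[[`, numeric(1), "q2_kfold3"),
    q2_5fold = vapply(fits, `[[`, numeric(1), "q2_kfold5"),
    stringsAsFactors = FALSE)

  structure(
    list(fits = fits, table = table, scaling = z$scaling,
         n_subsets_considered = considered,
         settings = list(max_terms = max_terms,
                         collinearity_cut = collinearity_cut,
                         kfold_iterations = as.integer(kfold_iterations),
                         seed = as.integer(seed))),
    class = "qssr_search")
}

#' @export
print.qssr_search <- function(x, ...) {
  cat(sprintf("<qssr_search> %d fits over %d admissible subsets (max %d terms)\n",
              nrow(x$table), x$n_subsets_considered, x$settings$max_terms))
  print(utils::head(x$table, 5), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Convert a normalized fit to its raw-parameter equation
#'
#' A model fit on z-scored descriptors predicts identically through
#' `b_raw_j = b_norm_j / sd_j` and `intercept_raw = intercept_norm -
#' sum_j b_norm_j mean_j / sd_j`. The raw coefficients are attached to the
#' fit as `coef_raw`.
#'
#' @param fit A `qssr_model_fit` produced on the scaled matrix matching
#'   `scaling`.
#' @param scaling A `scaling` record from [zscore_matrix()] covering every
#'   label of the fit.
#' @return The fit, with `coef_raw` filled.
#' @export
raw_equation <- function(fit, scaling) {
  if (!all(fit$labels %in% names(scaling$mean)))
    stop("scaling record does not cover fit labels: ",
         paste(setdiff(fit$labels, names(scaling$mean)), collapse = ", "))
  b <- fit$coefficients[-1]
  mu <- scaling$mean[fit$labels]
  sd <- scaling$sd[fit$labels]
  b_raw <- b / sd
  int_raw <- fit$coefficients[1] - sum(b * mu / sd)
  fit$coef_raw <- stats::setNames(c(int_raw, b_raw),
                                  c("(Intercept)", fit$labels))
  fit
}
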