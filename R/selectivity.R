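# Transforms from raw experimental outcomes (yield, dr, er) to the model
# responses log(dr) and ddG, plus per-solvent distribution summaries.
# dr is always carried as a labeled anti/syn pair -- never a bare ratio --
# so that "3:1 anti" and "1:2 syn" style reports cannot corrupt signs.

#' Gas constant in kcal/(mol K)
#' @format Length-one numeric, 1.9872e-3.
#' @export
R_KCAL <- 1.9872e-3

#' Diastereoselectivity on the log scale
#'
#' `log10(anti/syn)` (or natural log with `base = exp(1)`): positive when
#' the anti diastereomer is favored, negative when syn is favored. This is
#' the response the diastereoselectivity models predict.
#'
#' @param dr_anti,dr_syn Positive ratio terms (vectorized).
#' @param base Logarithm base, default 10.
#' @return Numeric vector of log(dr) values.
#' @export
#' @examples
#' log_dr(1, 1)    # 0
#' log_dr(1, 2)    # -0.301: 1:2 favoring syn
#' log_dr(19, 1)   # +1.279
log_dr <- function(dr_anti, dr_syn, base = 10) {
  if (any(!is.finite(dr_anti)) || any(!is.finite(dr_syn)) ||
      any(dr_anti <= 0) || any(dr_syn <= 0))
    stop("dr ratio terms must be positive and finite")
  log(dr_anti / dr_syn, base = base)
}

#' Enantioselectivity as an activation free-energy difference
#'
#' Converts an enantiomeric ratio to the difference in activation free
#' energy between the two enantiomeric pathways,
#' `ddG = -R T ln(er_major / er_minor)` in kcal/mol. Under this sign
#' convention a selective reaction (major > minor) gives a negative ddG.
#'
#' @param er_major,er_minor Positive ratio terms (vectorized).
#' @param temperature Absolute temperature in Kelvin (default 298.15).
#' @return Numeric vector, kcal/mol.
#' @export
#' @examples
#' ddg_from_er(50, 50)            # 0
#' ddg_from_er(95, 5)             # -1.745 kcal/mol at 298.15 K
ddg_from_er <- function(er_major, er_minor, temperature = 298.15) {
  if (any(!is.finite(er_major)) || any(!is.finite(er_minor)) ||
      any(er_major <= 0) || any(er_minor <= 0))
    stop("er ratio terms must be positive and finite")
  if (any(temperature <= 0)) stop("temperature must be positive (Kelvin)")
  -R_KCAL * temperature * log(er_major / er_minor)
}

#' Read an experimental outcome table
#'
#' CSV with columns `solvent, modifier, replicate, yield_pct, dr_anti,
#' dr_syn, er_major, er_minor`. Each row is one reaction run.
#'
#' @param path CSV path, or a data frame with those columns.
#' @return Data frame of class `qssr_outcomes`.
#' @export
read_outcomes <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("solvent", "modifier", "replicate", "yield_pct",
            "dr_anti", "dr_syn", "er_major", "er_minor")
  if (!all(need %in% names(df)))
    stop("outcome table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$solvent <- as.character(df$solvent)
  df$modifier <- as.character(df$modifier)
  df$replicate <- as.integer(df$replicate)
  for (col in c("dr_anti", "dr_syn", "er_major", "er_minor"))
    if (any(!is.finite(df[[col]]) | df[[col]] <= 0))
      stop(col, " must be positive and finite")
  if (any(!is.finite(df$yield_pct) | df$yield_pct < 0 | df$yield_pct > 100))
    stop("yield_pct must lie in [0, 100]")
  class(df) <- c("qssr_outcomes", "data.frame")
  df
}

#' Model responses per (solvent, modifier)
#'
#' Transforms each run to the requested response -- `"log_dr"` via
#' [log_dr()] or `"ddg"` via [ddg_from_er()] -- then averages duplicate
#' runs on the transformed scale, yielding one value per (solvent,
#' modifier).
#'
#' @param outcomes A `qssr_outcomes` (or path / data frame accepted by
#'   [read_outcomes()]).
#' @param response `"log_dr"` or `"ddg"`.
#' @param temperature Kelvin, for `"ddg"`.
#' @param base Log base, for `"log_dr"`.
#' @return Data frame with columns `solvent, modifier, value, n_replicates`.
#' @export
response_table <- function(outcomes, response = c("log_dr", "ddg"),
                           temperature = 298.15, base = 10) {
  response <- match.arg(response)
  outcomes <- read_outcomes(outcomes)
  y <- if (response == "log_dr")
    log_dr(outcomes$dr_anti, outcomes$dr_syn, base = base)
  else
    ddg_from_er(outcomes$er_major, outcomes$er_minor, temperature = temperature)
  agg <- stats::aggregate(y, by = list(solvent = outcomes$solvent,
                                       modifier = outcomes$modifier), FUN = mean)
  cnt <- stats::aggregate(y, by = list(solvent = outcomes$solvent,
                                       modifier = outcomes$modifier), FUN = length)
  out <- data.frame(solvent = agg$solvent, modifier = agg$modifier,
                    value = agg$x, n_replicates = cnt$x,
                    stringsAsFactors = FALSE)
  out[order(out$solvent, out$modifier), , drop = FALSE]
}

# Named response vector (values keyed by modifier) for one solvent.
response_vector <- function(outcomes, solvent, response = "log_dr", ...) {
  tab <- response_table(outcomes, response = response, ...)
  tab <- tab[tab$solvent == solvent, ]
  if (!nrow(tab)) stop("no outcomes for solvent ", solvent)
  stats::setNames(tab$value, tab$modifier)
}

#' Distribution summary of selectivity values
#'
#' Box-plot statistics plus a kernel density estimate, the per-solvent
#' summary used to judge whether a response has enough spread to model.
#' Quartiles use linear-interpolation quantiles; outliers are points beyond
#' the 1.5 x IQR whiskers; the density is a Gaussian KDE with Silverman's
#' bandwidth.
#'
#' @param values Numeric vector (at least one finite value).
#' @return List with `quartiles` (Q1, median, Q3), `median`, `whiskers`
#'   (lo, hi), `outliers` (values beyond the whiskers), and `density`
#'   (data frame `grid`, `height`; NULL when fewer than 2 distinct values).
#' @export
distribution_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stop("values must be a non-empty vector of finite numbers")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  outliers <- values[values < lo | values > hi]
  dens <- NULL
  if (length(unique(values)) >= 2L) {
    d <- stats::density(values, bw = "nrd0")
    dens <- data.frame(grid = d$x, height = d$y)
  }
  list(quartiles = c(Q1 = q[1], median = q[2], Q3 = q[3]),
       median = q[2], whiskers = c(lo = lo, hi = hi),
       outliers = outliers, density = dens)
}
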