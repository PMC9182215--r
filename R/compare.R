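# Per-solvent comparison of the five configuration libraries: run the
# descriptor -> response -> best-subset pipeline for every (solvent,
# response, configuration) cell, rank configurations by their best Q2(LOO),
# and flag near-ties. This is the computation behind the mechanistic
# question "which hypothesized structure best explains each solvent's
# selectivity".

#' Campaign settings
#'
#' Bundles the tunable engine parameters for [run_campaign()].
#'
#' @param max_terms Maximum model size (default 3).
#' @param collinearity_cut Pairwise |r| exclusion threshold (default 0.8).
#' @param kfold_iterations Repeated-CV iterations for top models (500).
#' @param kfold_top Top models per cell to evaluate by k-fold CV (1).
#' @param seed Master seed for all randomized steps.
#' @param temperature Kelvin, for the ddG transform (298.15).
#' @param log_base Base of log(dr) (10).
#' @param sd_floor_log_dr Minimum sd of the per-solvent log(dr) response for
#'   modeling to proceed (default 0.1 log units); narrower responses are
#'   skipped with a flag rather than fit.
#' @param sd_floor_ddg Same floor for the ddG response, kcal/mol (0.1);
#'   solvents whose er barely varies get no enantioselectivity model.
#' @return List of settings.
#' @export
campaign_settings <- function(max_terms = 3L, collinearity_cut = 0.8,
                              kfold_iterations = 500L, kfold_top = 1L,
                              seed = 1L, temperature = 298.15, log_base = 10,
                              sd_floor_log_dr = 0.1, sd_floor_ddg = 0.1) {
  list(max_terms = as.integer(max_terms), collinearity_cut = collinearity_cut,
       kfold_iterations = as.integer(kfold_iterations),
       kfold_top = as.integer(kfold_top), seed = as.integer(seed),
       temperature = temperature, log_base = log_base,
       sd_floor_log_dr = sd_floor_log_dr, sd_floor_ddg = sd_floor_ddg)
}

#' Run the full structure-selectivity campaign
#'
#' For every solvent in the outcome table and every configuration library,
#' assembles (or accepts pre-assembled) descriptor matrices, transforms the
#' outcomes to log(dr) -- and to ddG where the er response has spread --
#' and runs [subset_search()]. Configurations are ranked per (solvent,
#' response) by the best Q2(LOO). A library whose descriptor assembly fails
#' is marked failed-with-reason; the campaign continues. Responses whose
#' per-solvent spread is below the configured floor are skipped with a
#' flag, never silently dropped.
#'
#' @param libraries Named list; each element a `qssr_config_library` (to be
#'   assembled) or a ready `qssr_descriptor_matrix`.
#' @param outcomes Outcome table ([read_outcomes()] forms accepted).
#' @param design Optional `qssr_design`; when given, the outcomes must tile
#'   it exactly.
#' @param annotations,specs,ring_atoms,radii Passed to
#'   [assemble_descriptors()] for library elements that need assembly;
#'   `specs` and `ring_atoms` may be single objects or named lists keyed by
#'   library.
#' @param settings A [campaign_settings()] list.
#' @return An object of class `qssr_comparison_report`: `cells` (nested
#'   `[[solvent]][[response]][[library]]`, each with `status`, `reason`,
#'   `best` fit and `table`), `summary` (one data-frame row per cell),
#'   `rankings` (per solvent/response configuration order), `skipped`,
#'   `settings`.
#' @export
run_campaign <- function(libraries, outcomes, design = NULL,
                         annotations = NULL, specs = NULL, ring_atoms = NULL,
                         radii = bondi_radii(),
                         settings = campaign_settings()) {
  if (is.null(names(libraries)) || any(!nzchar(names(libraries))))
    stop("libraries must be a named list (configuration labels)")
  outcomes <- read_outcomes(outcomes)
  if (!is.null(design)) {
    rep <- validate_outcomes(design, outcomes)
    if (!rep$complete)
      stop(sprintf("outcomes do not tile the design: %d missing, %d extra, %d duplicated cells",
                   nrow(rep$missing), nrow(rep$extra), nrow(rep$duplicated)))
  }

  # assemble descriptor matrices where needed; failures mark the library
  per_lib <- function(x, lib) if (is.list(x) && !is.null(names(x)) &&
                                  lib %in% names(x)) x[[lib]] else x
  matrices <- list()
  lib_status <- list()
  for (lib in names(libraries)) {
    obj <- libraries[[lib]]
    if (inherits(obj, "qssr_descriptor_matrix")) {
      matrices[[lib]] <- obj
      lib_status[[lib]] <- "ok"
    } else if (inherits(obj, "qssr_config_library")) {
      res <- tryCatch(
        assemble_descriptors(obj, specs = per_lib(specs, lib),
                             annotations = annotations,
                             ring_atoms = per_lib(ring_atoms, lib),
                             radii = radii),
        error = function(e) e)
      if (inherits(res, "error")) {
        matrices[lib] <- list(NULL)
        lib_status[[lib]] <- conditionMessage(res)
      } else {
        matrices[[lib]] <- res
        lib_status[[lib]] <- "ok"
      }
    } else stop("library ", lib,
                " is neither a configuration library nor a descriptor matrix")
  }

  solvents <- unique(outcomes$solvent)
  cells <- list()
  summary_rows <- list()
  skipped <- list()
  for (solv in solvents) {
    cells[[solv]] <- list()
    for (response in c("log_dr", "ddg")) {
      y <- response_vector(outcomes, solv, response = response,
                           temperature = settings$temperature,
                           base = settings$log_base)
      floor <- if (response == "log_dr") settings$sd_floor_log_dr
               else settings$sd_floor_ddg
      if (stats::sd(y) < floor) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          solvent = solv, response = response, sd = stats::sd(y),
          floor = floor,
          reason = "response spread below modeling floor",
          stringsAsFactors = FALSE)
        next
      }
      cells[[solv]][[response]] <- list()
      for (lib in names(libraries)) {
        cell <- if (!identical(lib_status[[lib]], "ok")) {
          list(status = "failed", reason = lib_status[[lib]],
               best = NULL, table = NULL)
        } else {
          sr <- tryCatch(
            subset_search(matrices[[lib]], y,
                          max_terms = settings$max_terms,
                          collinearity_cut = settings$collinearity_cut,
                          kfold_top = settings$kfold_top,
                          kfold_iterations = settings$kfold_iterations,
                          seed = settings$seed),
            error = function(e) e)
          if (inherits(sr, "error"))
            list(status = "failed", reason = conditionMessage(sr),
                 best = NULL, table = NULL)
          else
            list(status = "ok", reason = NULL, best = sr$fits[[1]],
                 table = sr$table, search = sr)
        }
        cells[[solv]][[response]][[lib]] <- cell
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          solvent = solv, response = response, configuration = lib,
          status = cell$status,
          best_model = if (is.null(cell$best)) NA_character_
                       else paste(cell$best$labels, collapse = " + "),
          r2 = if (is.null(cell$best)) NA_real_ else cell$best$r2,
          q2_loo = if (is.null(cell$best)) NA_real_ else cell$best$q2_loo,
          q2_3fold = if (is.null(cell$best)) NA_real_ else cell$best$q2_kfold3,
          q2_5fold = if (is.null(cell$best)) NA_real_ else cell$best$q2_kfold5,
          stringsAsFactors = FALSE)
      }
    }
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame()
  rankings <- list()
  if (nrow(summary)) {
    for (key in unique(paste(summary$solvent, summary$response, sep = "|"))) {
      part <- strsplit(key, "|", fixed = TRUE)[[1]]
      sub <- summary[summary$solvent == part[1] & summary$response == part[2] &
                     summary$status == "ok", , drop = FALSE]
      sub <- sub[order(-sub$q2_loo), , drop = FALSE]
      if (nrow(sub))
        rankings[[key]] <- data.frame(solvent = part[1], response = part[2],
                                      rank = seq_len(nrow(sub)),
                                      configuration = sub$configuration,
                                      q2_loo = sub$q2_loo,
                                      stringsAsFactors = FALSE)
    }
  }
  structure(
    list(cells = cells, summary = summary,
         rankings = if (length(rankings)) do.call(rbind, c(rankings, make.row.names = FALSE)) else data.frame(),
         skipped = if (length(skipped)) do.call(rbind, skipped) else data.frame(),
         libraries = names(libraries), settings = settings),
    class = "qssr_comparison_report")
}

#' @export
print.qssr_comparison_report <- function(x, ...) {
  cat(sprintf("<qssr_comparison_report> %d libraries, %d cells (%d skipped responses)\n",
              length(x$libraries), nrow(x$summary), nrow(x$skipped)))
  if (nrow(x$rankings)) {
    top <- x$rankings[x$rankings$rank == 1L, , drop = FALSE]
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s / %s: best = %s (Q2_LOO = %.3f)\n", top$solvent[i],
                  top$response[i], top$configuration[i], top$q2_loo[i]))
  }
  invisible(x)
}

#' Best configuration per (solvent, response)
#'
#' @param report A `qssr_comparison_report`.
#' @return Data frame: one row per (solvent, response) with the top-ranked
#'   configuration and its Q2(LOO).
#' @export
best_configurations <- function(report) {
  stopifnot(inherits(report, "qssr_comparison_report"))
  report$rankings[report$rankings$rank == 1L,
                  c("solvent", "response", "configuration", "q2_loo"),
                  drop = FALSE]
}

#' Flag near-tied configurations
#'
#' Within each (solvent, response), flags every pair of configurations
#' whose best Q2(LOO) values differ by strictly less than `tolerance`.
#' Near-ties signal that several hypothesized structures explain the
#' selectivity about equally well and the ranking should not be
#' over-interpreted.
#'
#' @param report A `qssr_comparison_report`.
#' @param tolerance Q2 difference below which two configurations are
#'   considered tied (default 0.05).
#' @return Data frame with columns `solvent, response, config_a, config_b,
#'   q2_a, q2_b, delta` (empty when there are no near-ties).
#' @export
near_tie_flags <- function(report, tolerance = 0.05) {
  stopifnot(inherits(report, "qssr_comparison_report"))
  out <- list()
  r <- report$rankings
  if (nrow(r)) {
    for (key in unique(paste(r$solvent, r$response, sep = "|"))) {
      part <- strsplit(key, "|", fixed = TRUE)[[1]]
      sub <- r[r$solvent == part[1] & r$response == part[2], , drop = FALSE]
      if (nrow(sub) < 2L) next
      for (i in seq_len(nrow(sub) - 1L)) for (j in seq(i + 1L, nrow(sub))) {
        delta <- abs(sub$q2_loo[i] - sub$q2_loo[j])
        if (delta < tolerance)
          out[[length(out) + 1L]] <- data.frame(
            solvent = part[1], response = part[2],
            config_a = sub$configuration[i], config_b = sub$configuration[j],
            q2_a = sub$q2_loo[i], q2_b = sub$q2_loo[j], delta = delta,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(solvent = character(), response = character(),
               config_a = character(), config_b = character(),
               q2_a = numeric(), q2_b = numeric(), delta = numeric(),
               stringsAsFactors = FALSE)
}

#' Write a comparison-report bundle to disk
#'
#' Emits a JSON summary (`report.json`), one ranked model table CSV per
#' campaign cell (`models_<solvent>_<response>_<configuration>.csv`, seed
#' in a leading comment line), and a plain-text narrative
#' (`narrative.txt`).
#'
#' @param report A `qssr_comparison_report`.
#' @param dir Output directory (created if absent).
#' @param tie_tolerance Passed to [near_tie_flags()].
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir, tie_tolerance = 0.05) {
  stopifnot(inherits(report, "qssr_comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flags <- near_tie_flags(report, tolerance = tie_tolerance)
  jsonlite::write_json(
    list(settings = report$settings, summary = report$summary,
         rankings = report$rankings, skipped = report$skipped,
         near_ties = flags),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  for (solv in names(report$cells)) for (resp in names(report$cells[[solv]])) {
    for (lib in names(report$cells[[solv]][[resp]])) {
      cell <- report$cells[[solv]][[resp]][[lib]]
      if (!identical(cell$status, "ok")) next
      path <- file.path(dir, sprintf("models_%s_%s_%s.csv", solv, resp, lib))
      con <- file(path, "w")
      writeLines(sprintf("# seed: %d", report$settings$seed), con)
      utils::write.csv(cell$table, con, row.names = FALSE)
      close(con)
    }
  }
  lines <- c("Configuration comparison narrative", "")
  bc <- best_configurations(report)
  for (i in seq_len(nrow(bc)))
    lines <- c(lines, sprintf(
      "%s / %s: best-supported configuration is %s (Q2_LOO = %.3f).",
      bc$solvent[i], bc$response[i], bc$configuration[i], bc$q2_loo[i]))
  if (nrow(report$skipped))
    for (i in seq_len(nrow(report$skipped)))
      lines <- c(lines, sprintf(
        "%s / %s: skipped (response sd %.3f below floor %.3f).",
        report$skipped$solvent[i], report$skipped$response[i],
        report$skipped$sd[i], report$skipped$floor[i]))
  if (nrow(flags))
    for (i in seq_len(nrow(flags)))
      lines <- c(lines, sprintf(
        "%s / %s: near-tie between %s and %s (dQ2 = %.3f) -- ranking ambiguous.",
        flags$solvent[i], flags$response[i], flags$config_a[i],
        flags$config_b[i], flags$delta[i]))
  writeLines(lines, file.path(dir, "narrative.txt"))
  invisible(dir)
}
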