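# Factorial experimental design: enumeration of the (solvent x modifier x
# replicate) campaign and validation of outcome tables against it.

#' Define a factorial study design
#'
#' @param solvents Character vector of condition labels (unique).
#' @param modifiers Character vector of modifier ids (unique).
#' @param replicates Integer number of replicate runs per cell (>= 1).
#' @return An object of class `qssr_design`.
#' @export
study_design <- function(solvents, modifiers, replicates = 1L) {
  solvents <- as.character(solvents)
  modifiers <- as.character(modifiers)
  replicates <- as.integer(replicates)
  if (!length(solvents) || !length(modifiers))
    stop("solvents and modifiers must be non-empty")
  if (anyDuplicated(solvents) || anyDuplicated(modifiers))
    stop("factor labels must be unique")
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  structure(list(solvents = solvents, modifiers = modifiers,
                 replicates = replicates),
            class = "qssr_design")
}

#' @export
print.qssr_design <- function(x, ...) {
  cat(sprintf("<qssr_design> %d solvents x %d modifiers x %d replicates = %d runs\n",
              length(x$solvents), length(x$modifiers), x$replicates,
              length(x$solvents) * length(x$modifiers) * x$replicates))
  invisible(x)
}

#' The built-in aldol campaign design
#'
#' Five solvent conditions (neat ketone, hexane, chloroform, acetonitrile,
#' methanol) crossed with fifteen arylboronic-acid modifiers, every
#' reaction run in duplicate: 75 unique condition combinations, 150 runs
#' in total.
#'
#' @return A `qssr_design`.
#' @export
aldol_study_design <- function() {
  study_design(
    solvents = c("neat", "hexane", "CHCl3", "ACN", "MeOH"),
    modifiers = sprintf("BA%02d", 1:15),
    replicates = 2L
  )
}

#' Enumerate the runs of a design
#'
#' Full factorial expansion in deterministic lexicographic order: solvents
#' vary slowest, then modifiers, then the replicate index.
#'
#' @param design A `qssr_design`.
#' @return Data frame with columns `solvent, modifier, replicate`, one row
#'   per run.
#' @export
enumerate_runs <- function(design) {
  stopifnot(inherits(design, "qssr_design"))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      modifier = design$modifiers,
                      solvent = design$solvents,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid[c("solvent", "modifier", "replicate")]
}

#' Validate an outcome table against a design
#'
#' Report-based check that the records exactly tile the design: every
#' (solvent, modifier, replicate) cell present exactly once, nothing
#' outside the design.
#'
#' @param design A `qssr_design`.
#' @param outcomes A `qssr_outcomes` (or anything [read_outcomes()] takes).
#' @return List with data frames `missing`, `extra`, `duplicated` and a
#'   logical `complete` (TRUE iff all three are empty).
#' @export
validate_outcomes <- function(design, outcomes) {
  outcomes <- read_outcomes(outcomes)
  expected <- enumerate_runs(design)
  key <- function(df) paste(df$solvent, df$modifier, df$replicate, sep = "\r")
  ek <- key(expected)
  ok <- key(outcomes)
  missing <- expected[!(ek %in% ok), , drop = FALSE]
  extra <- outcomes[!(ok %in% ek), c("solvent", "modifier", "replicate"),
                    drop = FALSE]
  dup_keys <- unique(ok[duplicated(ok)])
  duplicated <- outcomes[!duplicated(ok) & ok %in% dup_keys,
                         c("solvent", "modifier", "replicate"), drop = FALSE]
  counts <- table(ok)[dup_keys]
  if (nrow(duplicated)) duplicated$times <- as.integer(counts[key(duplicated)])
  rownames(missing) <- rownames(extra) <- rownames(duplicated) <- NULL
  list(missing = missing, extra = extra, duplicated = duplicated,
       complete = !nrow(missing) && !nrow(extra) && !nrow(duplicated))
}
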