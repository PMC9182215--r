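# Per-atom electronic annotations: atomic partial charges (e.g. NBO charges
# from a DFT calculation) and selected vibrational frequencies. These are
# inputs read from CSV, never computed here.

#' Read per-atom annotation tables
#'
#' Loads atomic charges and, optionally, labeled vibrational frequencies
#' from CSV. The charge table has columns `structure,atom_index,charge`
#' (atom indices 1-based, matching XYZ/SDF line order); the frequency table
#' has columns `structure,mode,frequency_cm1`.
#'
#' @param charges Path to the charge CSV, or a data frame with those columns.
#' @param frequencies Optional path/data frame for the frequency table.
#' @param structures Optional list of `qssr_structure` (or a
#'   `qssr_config_library`); when supplied, atom indices are validated
#'   against atom counts.
#' @return An object of class `qssr_annotations` with elements `charges`
#'   and `frequencies` (data frames).
#' @export
read_annotations <- function(charges, frequencies = NULL, structures = NULL) {
  ch <- if (is.data.frame(charges)) charges else {
    if (!file.exists(charges)) stop("file not found: ", charges)
    utils::read.csv(charges, stringsAsFactors = FALSE)
  }
  need <- c("structure", "atom_index", "charge")
  if (!all(need %in% names(ch)))
    stop("charge table must have columns: ", paste(need, collapse = ", "))
  ch <- ch[need]
  ch$structure <- as.character(ch$structure)
  ch$atom_index <- as.integer(ch$atom_index)
  if (any(is.na(ch$atom_index)) || any(ch$atom_index < 1L))
    stop("atom_index must be an integer >= 1")
  if (!is.numeric(ch$charge) || any(!is.finite(ch$charge)))
    stop("charges must be finite numbers")
  dup <- duplicated(ch[c("structure", "atom_index")])
  if (any(dup))
    stop("duplicate charge rows for: ",
         paste(unique(paste0(ch$structure[dup], "[", ch$atom_index[dup], "]")),
               collapse = ", "))
  fr <- NULL
  if (!is.null(frequencies)) {
    fr <- if (is.data.frame(frequencies)) frequencies else {
      if (!file.exists(frequencies)) stop("file not found: ", frequencies)
      utils::read.csv(frequencies, stringsAsFactors = FALSE)
    }
    needf <- c("structure", "mode", "frequency_cm1")
    if (!all(needf %in% names(fr)))
      stop("frequency table must have columns: ", paste(needf, collapse = ", "))
    fr <- fr[needf]
    fr$structure <- as.character(fr$structure)
    fr$mode <- as.character(fr$mode)
    if (any(!is.finite(fr$frequency_cm1)) || any(fr$frequency_cm1 <= 0))
      stop("frequencies must be positive (cm^-1)")
    dupf <- duplicated(fr[c("structure", "mode")])
    if (any(dupf))
      stop("duplicate frequency rows for: ",
           paste(unique(paste0(fr$structure[dupf], ":", fr$mode[dupf])),
                 collapse = ", "))
  }
  out <- structure(list(charges = ch, frequencies = fr),
                   class = "qssr_annotations")
  if (!is.null(structures)) validate_annotations(out, structures)
  out
}

#' @export
print.qssr_annotations <- function(x, ...) {
  cat(sprintf("<qssr_annotations> %d charge rows (%d structures)",
              nrow(x$charges), length(unique(x$charges$structure))))
  if (!is.null(x$frequencies))
    cat(sprintf(", %d frequency rows", nrow(x$frequencies)))
  cat("\n")
  invisible(x)
}

# Validate atom indices against a structure registry.
validate_annotations <- function(annotations, structures) {
  if (inherits(structures, "qssr_config_library"))
    structures <- structures$structures
  if (inherits(structures, "qssr_structure")) structures <- list(structures)
  if (is.null(names(structures)) || any(!nzchar(names(structures))))
    names(structures) <- vapply(structures, `[[`, character(1), "name")
  ch <- annotations$charges
  for (nm in intersect(unique(ch$structure), names(structures))) {
    n <- n_atoms(structures[[nm]])
    bad <- ch$atom_index[ch$structure == nm & ch$atom_index > n]
    if (length(bad))
      stop(sprintf("atom index %d out of range for structure %s (%d atoms)",
                   bad[1], nm, n))
  }
  invisible(annotations)
}

#' Look up an atomic charge
#'
#' @param annotations A `qssr_annotations`.
#' @param structure Structure name.
#' @param atom 1-based atom index.
#' @return The charge (numeric scalar).
#' @export
lookup_charge <- function(annotations, structure, atom) {
  ch <- annotations$charges
  hit <- ch$structure == structure & ch$atom_index == as.integer(atom)
  if (!any(hit))
    stop(sprintf("no charge for atom %d of structure %s", atom, structure))
  ch$charge[hit][1]
}

#' Look up a labeled vibrational frequency
#'
#' @inheritParams lookup_charge
#' @param mode Mode label, e.g. `"B-O_stretch"`.
#' @return The frequency in cm^-1.
#' @export
lookup_frequency <- function(annotations, structure, mode) {
  fr <- annotations$frequencies
  if (is.null(fr)) stop("annotation table has no frequency data")
  hit <- fr$structure == structure & fr$mode == mode
  if (!any(hit))
    stop(sprintf("no frequency for mode %s of structure %s", mode, structure))
  fr$frequency_cm1[hit][1]
}
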