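# Descriptor specification, single-descriptor evaluation, and assembly of
# one descriptor matrix per configuration library. Descriptor kinds cover
# the stereoelectronic inventory used for structure-selectivity modeling:
# Sterimol steric parameters, distances/bond lengths/dihedrals, atomic
# charges and charge differences, point-charge dipole components in the
# aryl-ring frame, and tabulated stretching frequencies.

.descriptor_kinds <- c("sterimol_L", "sterimol_B1", "sterimol_B5",
                       "distance", "bond_length", "dihedral",
                       "charge", "charge_difference",
                       "dipole_total", "dipole_component", "frequency")

.descriptor_arity <- c(sterimol_L = 2L, sterimol_B1 = 2L, sterimol_B5 = 2L,
                       distance = 2L, bond_length = 2L, dihedral = 4L,
                       charge = 1L, charge_difference = 2L,
                       dipole_total = 0L, dipole_component = 0L,
                       frequency = 0L)

.descriptor_units <- c(sterimol_L = "Angstrom", sterimol_B1 = "Angstrom",
                       sterimol_B5 = "Angstrom", distance = "Angstrom",
                       bond_length = "Angstrom", dihedral = "degree",
                       charge = "e", charge_difference = "e",
                       dipole_total = "e.Angstrom",
                       dipole_component = "e.Angstrom",
                       frequency = "cm^-1")

#' Define a descriptor
#'
#' A descriptor specification names a kind and its arguments: atom indices
#' (1-based) for geometric, Sterimol and charge kinds; a mode label for
#' `frequency`; an axis selector for `dipole_component`. Sterimol atoms are
#' `(attach_from, attach_to)`; `charge_difference` is `q[atoms[1]] -
#' q[atoms[2]]` in the order given.
#'
#' @param kind One of `"sterimol_L"`, `"sterimol_B1"`, `"sterimol_B5"`,
#'   `"distance"`, `"bond_length"`, `"dihedral"`, `"charge"`,
#'   `"charge_difference"`, `"dipole_total"`, `"dipole_component"`,
#'   `"frequency"`.
#' @param atoms Integer vector of 1-based atom indices (arity depends on
#'   kind: distance 2, dihedral 4, charge 1, ...).
#' @param label Column label in the descriptor matrix; defaults to
#'   `kind(atoms)`.
#' @param mode Mode label, for `kind = "frequency"`.
#' @param axis Frame-axis selector for `kind = "dipole_component"`: one of
#'   `"axis1"` (centroid toward ipso), `"axis2"` (ortho/meta direction),
#'   `"normal"`.
#' @return An object of class `qssr_descriptor_spec`.
#' @export
#' @examples
#' descriptor_spec("distance", c(3, 17), label = "d_OH")
#' descriptor_spec("dipole_component", axis = "axis2", label = "mu_inplane")
descriptor_spec <- function(kind, atoms = integer(), label = NULL,
                            mode = NULL, axis = NULL) {
  kind <- match.arg(kind, .descriptor_kinds)
  atoms <- as.integer(atoms)
  arity <- .descriptor_arity[[kind]]
  if (length(atoms) != arity)
    stop(sprintf("kind %s takes %d atom argument(s), got %d",
                 kind, arity, length(atoms)))
  if (any(atoms < 1L)) stop("atom indices are 1-based (must be >= 1)")
  if (kind %in% c("distance", "bond_length", "dihedral", "charge_difference",
                  "sterimol_L", "sterimol_B1", "sterimol_B5") &&
      anyDuplicated(atoms))
    stop("repeated atom index in ", kind, " spec")
  if (kind == "frequency") {
    if (is.null(mode)) stop("frequency spec requires a mode label")
    mode <- as.character(mode)
  }
  if (kind == "dipole_component") {
    if (is.null(axis)) stop("dipole_component spec requires an axis selector")
    axis <- match.arg(axis, c("axis1", "axis2", "normal"))
  }
  if (is.null(label))
    label <- if (arity > 0) paste0(kind, "(", paste(atoms, collapse = ","), ")")
             else if (kind == "frequency") paste0("freq(", mode, ")")
             else if (kind == "dipole_component") paste0("mu_", axis)
             else "mu_tot"
  structure(list(kind = kind, atoms = atoms, label = as.character(label),
                 mode = mode, axis = axis),
            class = "qssr_descriptor_spec")
}

#' @export
print.qssr_descriptor_spec <- function(x, ...) {
  arg <- if (length(x$atoms)) paste(x$atoms, collapse = ",")
         else if (!is.null(x$mode)) x$mode else if (!is.null(x$axis)) x$axis else ""
  cat(sprintf("<descriptor> %s = %s(%s) [%s]\n", x$label, x$kind, arg,
              .descriptor_units[[x$kind]]))
  invisible(x)
}

#' Read descriptor specifications from a YAML file
#'
#' The file is a YAML sequence; each entry has `kind`, an optional `label`,
#' and `atoms` / `mode` / `axis` as the kind requires.
#'
#' @param path YAML file path.
#' @return List of `qssr_descriptor_spec`.
#' @export
read_descriptor_specs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e)
    descriptor_spec(kind = e$kind,
                    atoms = if (is.null(e$atoms)) integer() else e$atoms,
                    label = e$label, mode = e$mode, axis = e$axis))
}

#' Interatomic distance and dihedral angle
#'
#' `atom_distance()` is the Euclidean distance in Angstrom between two
#' atoms. `dihedral_angle()` is the signed torsion about the b-c bond of
#' atoms a-b-c-d, in degrees, IUPAC sign convention, range (-180, 180].
#'
#' @param s A `qssr_structure`.
#' @param i,j,a,b,c,d 1-based atom indices.
#' @return Numeric scalar.
#' @export
atom_distance <- function(s, i, j) {
  check_atom_indices(s, c(i, j))
  sqrt(sum((s$coords[i, ] - s$coords[j, ])^2))
}

#' @rdname atom_distance
#' @export
dihedral_angle <- function(s, a, b, c, d) {
  check_atom_indices(s, c(a, b, c, d))
  p <- s$coords
  b1 <- p[b, ] - p[a, ]
  b2 <- p[c, ] - p[b, ]
  b3 <- p[d, ] - p[c, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  ang <- atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
               sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(x, y) {
  c(x[2] * y[3] - x[3] * y[2],
    x[3] * y[1] - x[1] * y[3],
    x[1] * y[2] - x[2] * y[1])
}

check_atom_indices <- function(s, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > n_atoms(s)))
    stop(sprintf("atom index out of range for structure %s (%d atoms)",
                 s$name, n_atoms(s)))
  invisible(idx)
}

#' Molecular dipole from atomic point charges
#'
#' Approximates the dipole moment as the first moment of the atomic partial
#' charges about an origin: `mu = sum_i q_i (r_i - origin)`. When the total
#' charge is zero the result is origin-independent; otherwise the origin
#' matters and should be the aryl-ring centroid from [ring_frame()], the
#' reference point used throughout this package. Units are e.Angstrom;
#' multiply by [EA_TO_DEBYE] for Debye.
#'
#' @param s A `qssr_structure`.
#' @param charges Numeric vector of per-atom charges (length `n_atoms(s)`),
#'   or a `qssr_annotations` from which charges for `s$name` are pulled.
#' @param origin Reference point, length-3 (default the ring centroid is
#'   what callers pass; falls back to the origin).
#' @param axes Optional 3 x k matrix of frame axes (columns); projections of
#'   the dipole onto each are returned as `components`.
#' @return List with `mu_vec` (length-3, e.Angstrom), `mu_tot` (its norm)
#'   and `components` (named numeric, one per axis column; empty if no axes).
#' @export
dipole_from_charges <- function(s, charges, origin = c(0, 0, 0), axes = NULL) {
  if (inherits(charges, "qssr_annotations")) {
    ch <- charges$charges
    rows <- ch[ch$structure == s$name, ]
    q <- rep(NA_real_, n_atoms(s))
    q[rows$atom_index] <- rows$charge
  } else q <- as.numeric(charges)
  if (length(q) != n_atoms(s) || anyNA(q))
    stop("missing charge for atom(s) ",
         paste(which(is.na(q) | seq_along(q) > length(q)), collapse = ", "),
         " of structure ", s$name)
  rel <- sweep(s$coords, 2, origin)
  mu_vec <- drop(crossprod(rel, q))
  comps <- numeric(0)
  if (!is.null(axes)) {
    axes <- as.matrix(axes)
    comps <- drop(crossprod(axes, mu_vec))
    names(comps) <- colnames(axes)
  }
  list(mu_vec = mu_vec, mu_tot = sqrt(sum(mu_vec^2)), components = comps)
}

#' Evaluate one descriptor for one structure
#'
#' Dispatcher behind [assemble_descriptors()]; exposed for interactive use.
#' Geometric and Sterimol kinds need only the structure; charge, dipole and
#' frequency kinds need `annotations`; dipole kinds need `ring_atoms` (the
#' frame is recomputed per structure).
#'
#' @param s A `qssr_structure`.
#' @param spec A `qssr_descriptor_spec`.
#' @param annotations A `qssr_annotations`, where needed.
#' @param ring_atoms 6 ring-atom indices (ipso first), for dipole kinds.
#' @param radii van der Waals radius table for Sterimol kinds.
#' @return Numeric scalar.
#' @export
compute_descriptor <- function(s, spec, annotations = NULL, ring_atoms = NULL,
                               radii = bondi_radii()) {
  k <- spec$kind
  if (k %in% c("sterimol_L", "sterimol_B1", "sterimol_B5")) {
    st <- sterimol(s, spec$atoms[1], spec$atoms[2], radii = radii)
    return(unname(st[[sub("sterimol_", "", k)]]))
  }
  if (k %in% c("distance", "bond_length"))
    return(atom_distance(s, spec$atoms[1], spec$atoms[2]))
  if (k == "dihedral")
    return(dihedral_angle(s, spec$atoms[1], spec$atoms[2], spec$atoms[3],
                          spec$atoms[4]))
  if (k == "charge") {
    if (is.null(annotations)) stop("charge descriptor requires annotations")
    return(lookup_charge(annotations, s$name, spec$atoms[1]))
  }
  if (k == "charge_difference") {
    if (is.null(annotations)) stop("charge descriptor requires annotations")
    return(lookup_charge(annotations, s$name, spec$atoms[1]) -
           lookup_charge(annotations, s$name, spec$atoms[2]))
  }
  if (k == "frequency") {
    if (is.null(annotations)) stop("frequency descriptor requires annotations")
    return(lookup_frequency(annotations, s$name, spec$mode))
  }
  # dipole kinds
  if (is.null(annotations)) stop("dipole descriptor requires annotations")
  if (is.null(ring_atoms)) stop("dipole descriptor requires ring_atoms")
  fr <- ring_frame(s, ring_atoms)
  dip <- dipole_from_charges(s, annotations, origin = fr$centroid,
                             axes = cbind(fr$axes, normal = fr$normal))
  if (k == "dipole_total") dip$mu_tot else unname(dip$components[[spec$axis]])
}

#' Assemble a descriptor matrix for a configuration library
#'
#' Evaluates every descriptor spec for every structure in the library. The
#' result is complete or nothing: any failing (modifier, descriptor) cell
#' aborts assembly with an aggregated error naming all failures.
#'
#' @param library A `qssr_config_library`.
#' @param specs List of `qssr_descriptor_spec`.
#' @param annotations A `qssr_annotations`, where any spec needs one.
#' @param ring_atoms 6 ring-atom indices applied to every structure, or a
#'   named list (per modifier id); needed by dipole kinds.
#' @param radii van der Waals radius table for Sterimol kinds.
#' @return A `qssr_descriptor_matrix`: numeric matrix (modifiers x
#'   descriptors) with attributes `units` (named character) and
#'   `configuration` (the library label).
#' @export
assemble_descriptors <- function(library, specs, annotations = NULL,
                                 ring_atoms = NULL, radii = bondi_radii()) {
  stopifnot(inherits(library, "qssr_config_library"))
  if (inherits(specs, "qssr_descriptor_spec")) specs <- list(specs)
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate descriptor labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  mods <- names(library$structures)
  m <- matrix(NA_real_, length(mods), length(specs),
              dimnames = list(mods, labels))
  failures <- character(0)
  for (i in seq_along(mods)) {
    s <- library$structures[[i]]
    ra <- if (is.list(ring_atoms)) ring_atoms[[mods[i]]] else ring_atoms
    for (j in seq_along(specs)) {
      val <- tryCatch(
        compute_descriptor(s, specs[[j]], annotations = annotations,
                           ring_atoms = ra, radii = radii),
        error = function(e) e)
      if (inherits(val, "error")) {
        failures <- c(failures, sprintf("(%s, %s): %s", mods[i], labels[j],
                                        conditionMessage(val)))
      } else m[i, j] <- val
    }
  }
  if (length(failures))
    stop("descriptor assembly failed for ", length(failures), " cell(s):\n  ",
         paste(failures, collapse = "\n  "))
  descriptor_matrix(m, units = setNames(
    .descriptor_units[vapply(specs, `[[`, character(1), "kind")], labels),
    configuration = library$label)
}

#' Construct a descriptor matrix object
#'
#' Wraps a complete numeric matrix (modifiers x descriptors) with per-column
#' units and the provenance configuration label. [assemble_descriptors()]
#' and [gen_matrix()] build these; construct one directly to model external
#' descriptor tables.
#'
#' @param m Numeric matrix with row and column names, no missing cells.
#' @param units Named character vector of per-column units (optional).
#' @param configuration Configuration label (optional provenance tag).
#' @return A `qssr_descriptor_matrix`.
#' @export
descriptor_matrix <- function(m, units = NULL, configuration = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("descriptor matrix needs row (modifier) and column (label) names")
  if (anyDuplicated(colnames(m))) stop("duplicate descriptor column labels")
  if (anyNA(m)) stop("descriptor matrix has missing cells")
  if (is.null(units)) units <- setNames(rep("", ncol(m)), colnames(m))
  structure(m, units = units, configuration = configuration,
            class = c("qssr_descriptor_matrix", "matrix", "array"))
}

#' @export
print.qssr_descriptor_matrix <- function(x, ...) {
  cat(sprintf("<qssr_descriptor_matrix> %d modifiers x %d descriptors", nrow(x),
              ncol(x)))
  cfg <- attr(x, "configuration")
  if (!is.null(cfg)) cat(" [", cfg, "]", sep = "")
  cat("\n")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Write / read a descriptor matrix as CSV
#'
#' The CSV carries a `units` row directly under the header (first column
#' `"units"`), then one row per modifier. `configuration` is stored in a
#' leading comment line.
#'
#' @param m A `qssr_descriptor_matrix`.
#' @param path CSV path.
#' @return `write_descriptor_matrix()`: `path` invisibly;
#'   `read_descriptor_matrix()`: a `qssr_descriptor_matrix`.
#' @export
write_descriptor_matrix <- function(m, path) {
  stopifnot(inherits(m, "qssr_descriptor_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- attr(m, "configuration")
  if (!is.null(cfg)) writeLines(paste0("# configuration: ", cfg), con)
  writeLines(paste(c("modifier", colnames(m)), collapse = ","), con)
  writeLines(paste(c("units", attr(m, "units")[colnames(m)]), collapse = ","), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE)),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname write_descriptor_matrix
#' @export
read_descriptor_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  cfg <- NULL
  if (length(lines) && startsWith(lines[1], "# configuration:")) {
    cfg <- trimws(sub("# configuration:", "", lines[1], fixed = TRUE))
    lines <- lines[-1]
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df) || df[[1]][1] != "units")
    stop("descriptor CSV must carry a units row under the header")
  units <- setNames(as.character(df[1, -1]), names(df)[-1])
  body <- df[-1, , drop = FALSE]
  m <- as.matrix(body[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- body[[1]]
  descriptor_matrix(m, units = units, configuration = cfg)
}
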