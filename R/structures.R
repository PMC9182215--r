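# 3D structure container, XYZ/SDF input-output, and the aryl-ring reference
# frame used by the dipole-component descriptors. Atom indices are 1-based
# everywhere in the user-facing interface, matching XYZ/SDF line order.

#' Create a 3D structure
#'
#' The basic molecular container: element symbols plus Cartesian coordinates
#' in Angstrom. Structures are what the descriptor layer consumes; they carry
#' no bonds (connectivity is perceived from covalent radii where needed).
#'
#' @param name Identifier, typically `"<modifier id>"` or
#'   `"<modifier id>_<configuration label>"`.
#' @param elements Character vector of element symbols.
#' @param coords Numeric N x 3 matrix of coordinates in Angstrom.
#' @param charge_total Integer total formal charge (default 0).
#' @return An object of class `qssr_structure`.
#' @export
#' @examples
#' s <- structure_3d("water", c("O", "H", "H"),
#'                   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' n_atoms(s)
structure_3d <- function(name, elements, coords, charge_total = 0L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 1L)
    stop("structure must contain at least one atom")
  if (!is.matrix(coords) || ncol(coords) != 3L || nrow(coords) != length(elements))
    stop("coords must be an N x 3 matrix matching length(elements)")
  bad <- unique(elements[!is_element_symbol(elements)])
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(coords)))
    stop("coordinates must all be finite")
  dimnames(coords) <- NULL
  structure(
    list(name = as.character(name), elements = as.character(elements),
         coords = coords, charge_total = as.integer(charge_total)),
    class = "qssr_structure"
  )
}

#' @rdname structure_3d
#' @param s A `qssr_structure`.
#' @export
n_atoms <- function(s) length(s$elements)

#' @export
print.qssr_structure <- function(x, ...) {
  cat(sprintf("<qssr_structure> %s: %d atoms (%s), charge %+d\n",
              x$name, n_atoms(x),
              paste(unique(x$elements), collapse = " "), x$charge_total))
  invisible(x)
}

#' Configuration-library labels
#'
#' The five hypothesized structural configurations a modifier can be
#' parametrized in: the free boronic acid, its H-bond and pi complexes with
#' the aldehyde, and its proline and enamine adducts.
#'
#' @return Character vector of the five labels.
#' @export
configuration_labels <- function() {
  c("free_acid", "hbond_complex", "pi_complex", "proline_adduct",
    "enamine_adduct")
}

#' Create a configuration library
#'
#' A named set of structures, one per modifier, all built on the same
#' hypothesized intermediate or interaction.
#'
#' @param label One of [configuration_labels()].
#' @param structures Named list of `qssr_structure` (names = modifier ids),
#'   or an unnamed list (names are then taken from each structure's `name`).
#' @return An object of class `qssr_config_library`.
#' @export
configuration_library <- function(label, structures) {
  label <- match.arg(label, configuration_labels())
  if (!length(structures)) stop("library must contain at least one structure")
  ok <- vapply(structures, inherits, logical(1), "qssr_structure")
  if (!all(ok)) stop("all structures must be qssr_structure objects")
  if (is.null(names(structures)) || any(!nzchar(names(structures))))
    names(structures) <- vapply(structures, `[[`, character(1), "name")
  if (anyDuplicated(names(structures)))
    stop("duplicate modifier ids in library")
  structure(list(label = label, structures = structures),
            class = "qssr_config_library")
}

#' @export
print.qssr_config_library <- function(x, ...) {
  cat(sprintf("<qssr_config_library> %s: %d structures\n",
              x$label, length(x$structures)))
  invisible(x)
}

#' Read 3D structures from an XYZ or SDF file
#'
#' XYZ files may contain several concatenated records; SDF files are V2000
#' with 3D coordinates. One structure is returned per record, in file order.
#' Structure names come from the XYZ comment line (first whitespace token,
#' falling back to `record<i>`) or the SDF molecule-name line.
#'
#' @param path File path.
#' @param format `"xyz"` or `"sdf"`; default guesses from the extension.
#' @return List of `qssr_structure`.
#' @export
read_structures <- function(path, format = c("auto", "xyz", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), sdf = "sdf", mol = "sdf",
                     "xyz")
  }
  if (format == "xyz") read_xyz(path) else read_sdf(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only; blanks inside records are invalid
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    rec <- rec + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("XYZ parse error in record %d: bad atom count line %d", rec, i))
    if (i + 1L + n > length(lines))
      stop(sprintf("XYZ parse error in record %d: expected %d atom lines, file truncated", rec, n))
    title <- trimws(lines[i + 1L])
    nm <- if (nzchar(title)) strsplit(title, "\\s+")[[1]][1] else sprintf("record%d", rec)
    el <- character(n)
    xyz <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      tok <- strsplit(trimws(lines[i + 1L + k]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop(sprintf("XYZ parse error in record %d: atom line %d has %d fields",
                     rec, k, length(tok)))
      el[k] <- tok[1]
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(v)))
        stop(sprintf("XYZ parse error in record %d: non-numeric coordinate on atom line %d", rec, k))
      xyz[k, ] <- v
    }
    out[[length(out) + 1L]] <- tryCatch(
      structure_3d(nm, el, xyz),
      error = function(e) stop(sprintf("XYZ record %d: %s", rec, conditionMessage(e)),
                               call. = FALSE)
    )
    i <- i + 2L + n
  }
  if (!length(out)) stop("XYZ parse error: file contains no records")
  out
}

read_sdf <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  if (!length(sdfs)) stop("SDF parse error: file contains no records")
  lapply(seq_along(ChemmineR::sdfid(sdfs)), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    el <- sub("_[0-9]+$", "", rownames(ab))
    nm <- ChemmineR::sdfid(sdfs)[i]
    if (is.na(nm) || !nzchar(nm)) nm <- sprintf("record%d", i)
    tryCatch(structure_3d(nm, el, ab[, 1:3, drop = FALSE]),
             error = function(e) stop(sprintf("SDF record %d: %s", i,
                                              conditionMessage(e)), call. = FALSE))
  })
}

#' Write structures to an XYZ or SDF file
#'
#' Multi-record XYZ (plain) or SDF V2000. SDF output lists bonds perceived
#' from covalent radii, since the structure container itself stores none.
#'
#' @param structures A `qssr_structure` or list of them.
#' @param path Output file path.
#' @param format `"xyz"` or `"sdf"`.
#' @return `path`, invisibly.
#' @export
write_structures <- function(structures, path, format = c("xyz", "sdf")) {
  format <- match.arg(format)
  if (inherits(structures, "qssr_structure")) structures <- list(structures)
  if (format == "xyz") {
    txt <- unlist(lapply(structures, function(s) {
      c(as.character(n_atoms(s)), s$name,
        sprintf("%-3s %14.8f %14.8f %14.8f", s$elements,
                s$coords[, 1], s$coords[, 2], s$coords[, 3]))
    }))
    writeLines(txt, path)
  } else {
    sdfs <- lapply(structures, function(s) {
      bonds <- perceive_bonds(s)
      ab <- cbind(s$coords, matrix(0L, n_atoms(s), 13L))
      colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:17))
      rownames(ab) <- paste(s$elements, seq_len(n_atoms(s)), sep = "_")
      bb <- if (nrow(bonds)) cbind(bonds, 1L) else matrix(0L, 0L, 3L)
      colnames(bb) <- c("C1", "C2", "C3")
      methods::new("SDF",
        header = c(Molecule_Name = s$name, Source = "qssr", Comment = "",
                   Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                         n_atoms(s), nrow(bb))),
        atomblock = ab, bondblock = bb)
    })
    sdfset <- methods::new("SDFset", SDF = sdfs,
                           ID = vapply(structures, `[[`, character(1), "name"))
    ChemmineR::write.SDF(sdfset, path)
  }
  invisible(path)
}

# Bond list (two-column matrix of 1-based atom indices) from the covalent
# radius criterion: bonded if d < 1.3 * (r_i + r_j).
perceive_bonds <- function(s, scale = 1.3, radii = covalent_radii()) {
  r <- radii[s$elements]
  if (anyNA(r))
    stop("no covalent radius for element(s): ",
         paste(unique(s$elements[is.na(r)]), collapse = ", "))
  n <- n_atoms(s)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  d <- as.matrix(stats::dist(s$coords))
  cut <- scale * outer(r, r, `+`)
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  unname(hit[order(hit[, 1], hit[, 2]), , drop = FALSE])
}

#' Reference frame of an aromatic ring
#'
#' Computes the centroid, best-fit plane normal, and two in-plane axes of a
#' six-membered ring. The dipole-component descriptors project onto this
#' frame: axis 1 points from the centroid toward the ipso atom (the first
#' listed ring atom, by convention the ring carbon bonded to boron), axis 2
#' is the in-plane direction of the ortho/meta positions, completing a
#' right-handed frame with the normal. The normal's sign is fixed so that
#' the second listed ring atom lies on the positive axis-2 side, which makes
#' the whole frame equivariant under rigid motions.
#'
#' @param s A `qssr_structure`.
#' @param ring_atoms Integer vector of 6 atom indices (1-based); the first
#'   must be the ipso atom.
#' @param tol Coplanarity tolerance in Angstrom: maximum allowed distance of
#'   a ring atom from the best-fit plane (default 0.3).
#' @return List with `centroid` (length-3), `normal` (unit length-3), and
#'   `axes` (3 x 2 matrix, columns = in-plane axes 1 and 2).
#' @export
ring_frame <- function(s, ring_atoms, tol = 0.3) {
  ring_atoms <- as.integer(ring_atoms)
  if (length(ring_atoms) != 6L) stop("ring_atoms must list exactly 6 atoms")
  if (any(ring_atoms < 1L | ring_atoms > n_atoms(s)))
    stop("ring_atoms out of range for structure ", s$name)
  p <- s$coords[ring_atoms, , drop = FALSE]
  centroid <- colMeans(p)
  pc <- sweep(p, 2, centroid)
  sv <- svd(pc)
  normal <- sv$v[, 3]
  dev <- max(abs(pc %*% normal))
  if (dev > tol)
    stop(sprintf("ring atoms not coplanar: max deviation %.3f Angstrom exceeds %.3f",
                 dev, tol))
  a1 <- pc[1, ] - sum(pc[1, ] * normal) * normal  # centroid -> ipso, in plane
  n1 <- sqrt(sum(a1^2))
  if (n1 < 1e-8) stop("ipso atom coincides with ring centroid")
  a1 <- a1 / n1
  a2 <- c(normal[2] * a1[3] - normal[3] * a1[2],
          normal[3] * a1[1] - normal[1] * a1[3],
          normal[1] * a1[2] - normal[2] * a1[1])  # normal x a1
  # fix the normal's sign: second ring atom on the +axis2 side
  if (sum((pc[2, ]) * a2) < 0) {
    normal <- -normal
    a2 <- -a2
  }
  list(centroid = centroid, normal = normal, axes = cbind(axis1 = a1, axis2 = a2))
}
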