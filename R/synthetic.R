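# Synthetic-data generators. They replace the two inputs this pipeline
# cannot compute for itself -- DFT-derived descriptor values and the wet-lab
# outcome table -- with statistically controlled stand-ins: equicorrelated
# Gaussian descriptor matrices, planted sparse linear responses, idealized
# arylboronic-acid geometries, and outcome tables that tile a factorial
# design. Everything is deterministic given its seed and emits the same
# containers and file formats the real pipeline reads.

#' Specification for a synthetic descriptor problem
#'
#' @param n_compounds Number of modifiers (rows); default 15, the library
#'   size of the study design.
#' @param n_descriptors Number of candidate descriptors (columns); default
#'   20, a typical per-library candidate pool.
#' @param rho Equicorrelation between descriptor columns, in `[0, 1)`
#'   (default 0: independent candidates; raise it to stress the
#'   collinearity filter).
#' @param true_subset Indices (or labels) of the generating descriptors
#'   (default columns 3, 7, 9).
#' @param true_coef Their coefficients (default `c(2, -1, 0.5)`).
#' @param noise_sd Absolute sd of the Gaussian response noise; when `NULL`
#'   (default) the sd is `noise_frac_range` times the range of the
#'   noiseless response.
#' @param noise_frac_range Noise sd as a fraction of the noiseless response
#'   range (default 0.05).
#' @param seed Integer seed.
#' @return List of class `qssr_synth_spec`.
#' @export
synth_spec <- function(n_compounds = 15L, n_descriptors = 20L, rho = 0,
                       true_subset = c(3L, 7L, 9L),
                       true_coef = c(2, -1, 0.5),
                       noise_sd = NULL, noise_frac_range = 0.05, seed = 1L) {
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)")
  if (length(true_subset) != length(true_coef))
    stop("true_subset and true_coef must have equal length")
  if (is.numeric(true_subset) &&
      (any(true_subset < 1) || any(true_subset > n_descriptors)))
    stop("true_subset indices out of range")
  if (length(true_subset) > n_descriptors)
    stop("true subset larger than the descriptor pool")
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_frac_range < 0) stop("noise_frac_range must be >= 0")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors), rho = rho,
                 true_subset = true_subset, true_coef = true_coef,
                 noise_sd = noise_sd, noise_frac_range = noise_frac_range,
                 seed = as.integer(seed)),
            class = "qssr_synth_spec")
}

#' Generate an equicorrelated Gaussian descriptor matrix
#'
#' Rows (compounds) are drawn i.i.d. from a multivariate normal whose
#' columns share a single pairwise correlation `rho`
#' (`x_j = sqrt(rho) g + sqrt(1 - rho) z_j` with a per-row common factor
#' `g`). One knob is enough to stress the collinearity filter.
#'
#' @param spec A [synth_spec()].
#' @param configuration Optional provenance label for the matrix.
#' @return A `qssr_descriptor_matrix` (`n_compounds` x `n_descriptors`),
#'   rows `BA01...`, columns `x1...`.
#' @export
gen_matrix <- function(spec, configuration = NULL) {
  stopifnot(inherits(spec, "qssr_synth_spec"))
  n <- spec$n_compounds
  p <- spec$n_descriptors
  m <- withr::with_seed(spec$seed, {
    g <- stats::rnorm(n)
    z <- matrix(stats::rnorm(n * p), n, p)
    sqrt(spec$rho) * g + sqrt(1 - spec$rho) * z
  })
  dimnames(m) <- list(sprintf("BA%02d", seq_len(n)),
                      paste0("x", seq_len(p)))
  descriptor_matrix(m, units = stats::setNames(rep("z", p), colnames(m)),
                    configuration = configuration)
}

#' Generate a planted linear response
#'
#' `y = X[, subset] %*% beta + eps`, `eps ~ N(0, sd^2)`, with the noise sd
#' taken from the spec (absolute, or as a fraction of the noiseless
#' response range). The ground truth is returned alongside the response.
#'
#' @param m A descriptor matrix.
#' @param spec A [synth_spec()]; its `true_subset` may be column indices or
#'   labels of `m`.
#' @param seed Seed for the noise draw; defaults to `spec$seed + 1` so the
#'   noise stream is distinct from the matrix draw.
#' @return List with `response` (named vector keyed by row) and `truth`
#'   (list: `labels`, `coef`, `noise_sd`, `seed`).
#' @export
gen_response <- function(m, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "qssr_synth_spec"))
  m <- as.matrix(m)
  idx <- spec$true_subset
  labels <- if (is.character(idx)) idx else colnames(m)[idx]
  if (!all(labels %in% colnames(m)))
    stop("true subset not present in matrix columns")
  y0 <- drop(m[, labels, drop = FALSE] %*% spec$true_coef)
  sd <- if (!is.null(spec$noise_sd)) spec$noise_sd
        else spec$noise_frac_range * diff(range(y0))
  eps <- withr::with_seed(as.integer(seed), stats::rnorm(nrow(m), 0, sd))
  y <- stats::setNames(y0 + eps, rownames(m))
  list(response = y,
       truth = list(labels = labels, coef = spec$true_coef, noise_sd = sd,
                    seed = as.integer(seed)))
}

# ---------------------------------------------------------------------------
# Idealized arylboronic-acid geometries

.fragment_set <- c("H", "F", "Cl", "Br", "Me", "OH", "CN", "CF3", "NO2", "OMe")

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Substituent fragment atoms: positions relative to the attachment ring
# carbon, with the outward radial direction mapped to +x. Returns a list
# (elements, coords). Standard single-bond lengths (Angstrom).
fragment_atoms <- function(fragment) {
  tetra <- function(apex_bond, leaf_bond, leaf_el) {
    # apex carbon along +x; three leaves tetrahedral, tilted away from the
    # attachment (109.47 deg from the apex->attachment bond)
    ang <- 109.47 * pi / 180
    dirs <- t(vapply(c(0, 120, 240) * pi / 180, function(phi)
      c(-cos(ang), sin(ang) * cos(phi), sin(ang) * sin(phi)), numeric(3)))
    apex <- c(apex_bond, 0, 0)
    list(elements = c("C", rep(leaf_el, 3)),
         coords = rbind(apex, sweep(leaf_bond * dirs, 2, apex, `+`)))
  }
  switch(fragment,
    H  = list(elements = "H",  coords = rbind(c(1.09, 0, 0))),
    F  = list(elements = "F",  coords = rbind(c(1.35, 0, 0))),
    Cl = list(elements = "Cl", coords = rbind(c(1.73, 0, 0))),
    Br = list(elements = "Br", coords = rbind(c(1.90, 0, 0))),
    CN = list(elements = c("C", "N"),
              coords = rbind(c(1.43, 0, 0), c(1.43 + 1.16, 0, 0))),
    OH = {
      # C-O-H ~109.5 deg: the O-H bond tilts 70.5 deg off the outward axis
      o <- c(1.36, 0, 0)
      h <- o + 0.96 * c(cos(70.5 * pi / 180), sin(70.5 * pi / 180), 0)
      list(elements = c("O", "H"), coords = rbind(o, h))
    },
    Me = tetra(1.50, 1.09, "H"),
    CF3 = tetra(1.50, 1.33, "F"),
    NO2 = {
      n <- c(1.47, 0, 0)
      d <- 1.22
      # C-N-O ~120 deg: N-O bonds at 60 deg off the outward axis
      list(elements = c("N", "O", "O"),
           coords = rbind(n,
                          n + d * c(cos(60 * pi / 180),  sin(60 * pi / 180), 0),
                          n + d * c(cos(60 * pi / 180), -sin(60 * pi / 180), 0)))
    },
    OMe = {
      o <- c(1.36, 0, 0)
      cdir <- c(cos(70.5 * pi / 180), sin(70.5 * pi / 180), 0)
      cc <- o + 1.43 * cdir
      ang <- 109.47 * pi / 180
      # methyl hydrogens tetrahedral about the O-C axis, tilted away from O
      b1 <- cdir
      b2 <- c(-cdir[2], cdir[1], 0)
      b3 <- c(0, 0, 1)
      hh <- t(vapply(c(0, 120, 240) * pi / 180, function(phi)
        cc + 1.09 * (-cos(ang) * b1 + sin(ang) * (cos(phi) * b2 + sin(phi) * b3)),
        numeric(3)))
      list(elements = c("O", "C", "H", "H", "H"), coords = rbind(o, cc, hh))
    },
    stop("unknown fragment: ", fragment,
         " (available: ", paste(.fragment_set, collapse = ", "), ")")
  )
}

#' Generate idealized arylboronic-acid structures
#'
#' Builds planar phenylboronic-acid geometries from standard bond lengths
#' (C-C 1.39, C-H 1.09, C-B 1.56, B-O 1.36, O-H 0.96 Angstrom) with one
#' substituent at the para or meta position. The geometries are idealized
#' (no optimization): they exist so the geometric machinery -- ring frames,
#' Sterimol, bond perception -- can be exercised without quantum-chemistry
#' input. Atom order is fixed: ring carbons 1-6 (ipso first, so
#' `ring_atoms = 1:6` works directly), boron 7, the two B(OH)2 oxygens and
#' hydrogens 8-11, ring hydrogens, then substituent atoms.
#'
#' @param substituents Character vector of fragments, from
#'   `H, F, Cl, Br, Me, OH, CN, CF3, NO2, OMe`.
#' @param position `"para"` (default) or `"meta"`.
#' @param modifier_ids Names for the structures (default
#'   `BA_<fragment>`).
#' @param label Configuration label of the returned library (default
#'   `"free_acid"`).
#' @return A `qssr_config_library`.
#' @export
#' @examples
#' lib <- gen_toy_structures(c("H", "F", "Me"))
#' ring_frame(lib$structures[[1]], 1:6)$centroid
gen_toy_structures <- function(substituents, position = c("para", "meta"),
                               modifier_ids = NULL, label = "free_acid") {
  position <- match.arg(position)
  if (is.null(modifier_ids)) modifier_ids <- paste0("BA_", substituents)
  if (length(modifier_ids) != length(substituents))
    stop("modifier_ids must match substituents in length")
  structures <- vector("list", length(substituents))
  for (i in seq_along(substituents)) {
    frag <- substituents[i]
    if (!frag %in% .fragment_set)
      stop("unknown fragment: ", frag,
           " (available: ", paste(.fragment_set, collapse = ", "), ")")
    r_cc <- 1.39
    angles <- (0:5) * 60
    ring <- t(vapply(angles, function(a)
      r_cc * c(cos(a * pi / 180), sin(a * pi / 180), 0), numeric(3)))
    el <- rep("C", 6)
    coords <- ring
    # boron + B(OH)2, trigonal planar on the ipso carbon (+x direction)
    b <- c(r_cc + 1.56, 0, 0)
    o1 <- b + 1.36 * c(cos(60 * pi / 180),  sin(60 * pi / 180), 0)
    o2 <- b + 1.36 * c(cos(60 * pi / 180), -sin(60 * pi / 180), 0)
    h1 <- o1 + 0.96 * c(cos(0), sin(0), 0)
    h2 <- o2 + 0.96 * c(cos(0), -sin(0), 0)
    el <- c(el, "B", "O", "H", "O", "H")
    coords <- rbind(coords, b, o1, h1, o2, h2)
    # ring hydrogens on every ring carbon except ipso (1) and the
    # substituted position
    sub_pos <- if (position == "para") 4L else 3L
    for (k in setdiff(2:6, sub_pos)) {
      dir <- ring[k, ] / sqrt(sum(ring[k, ]^2))
      el <- c(el, "H")
      coords <- rbind(coords, ring[k, ] + 1.09 * dir)
    }
    # substituent fragment, outward radial direction mapped to +x
    fa <- fragment_atoms(frag)
    theta <- angles[sub_pos]
    rot <- rot_z(theta)
    placed <- t(rot %*% t(fa$coords)) +
      matrix(ring[sub_pos, ], nrow(fa$coords), 3, byrow = TRUE)
    el <- c(el, fa$elements)
    coords <- rbind(coords, placed)
    structures[[i]] <- structure_3d(modifier_ids[i], el, coords)
  }
  names(structures) <- modifier_ids
  configuration_library(label, structures)
}

#' Generate an outcome table tiling a design
#'
#' Plants per-solvent selectivity: for each solvent, the named generating
#' configuration's descriptor matrix and coefficients produce a log(dr)
#' value per modifier, back-transformed to a labeled anti/syn pair
#' (`dr_anti : dr_syn = 10^y : 1`); duplicates re-draw the replicate noise.
#' er columns are 50:50 (no enantioselection) unless the solvent's truth
#' entry carries an `er` component, in which case a planted ddG response is
#' back-transformed through `er_major/er_minor = exp(-ddG / RT)` with
#' `er_major + er_minor = 100`.
#'
#' @param design A `qssr_design`.
#' @param truth Named list keyed by solvent. Each entry:
#'   `configuration` (name into `matrices`), `subset` (labels/indices),
#'   `coef`, optional `noise_sd` (log units, default 0), optional `er` (a
#'   list with `subset`, `coef`, optional `noise_sd` in kcal/mol).
#' @param matrices Named list of descriptor matrices whose rows cover the
#'   design's modifiers.
#' @param replicate_sd Replicate noise sd on the log(dr) scale (and on ddG,
#'   kcal/mol), default 0.02.
#' @param temperature Kelvin for the er back-transform.
#' @param seed Integer seed.
#' @return A `qssr_outcomes` data frame tiling the design exactly.
#' @export
gen_outcomes <- function(design, truth, matrices, replicate_sd = 0.02,
                         temperature = 298.15, seed = 1L) {
  stopifnot(inherits(design, "qssr_design"))
  runs <- enumerate_runs(design)
  missing <- setdiff(design$solvents, names(truth))
  if (length(missing))
    stop("truth has no entry for solvent(s): ", paste(missing, collapse = ", "))
  withr::with_seed(as.integer(seed), {
    out <- runs
    out$yield_pct <- round(stats::runif(nrow(runs), 40, 99), 1)
    out$dr_anti <- NA_real_
    out$dr_syn <- 1
    out$er_major <- 50
    out$er_minor <- 50
    for (solv in design$solvents) {
      tr <- truth[[solv]]
      m <- matrices[[tr$configuration]]
      if (is.null(m)) stop("no matrix for configuration ", tr$configuration)
      m <- as.matrix(m)
      if (!all(design$modifiers %in% rownames(m)))
        stop("matrix for ", tr$configuration,
             " does not cover the design's modifiers")
      labels <- if (is.character(tr$subset)) tr$subset else colnames(m)[tr$subset]
      y0 <- drop(m[design$modifiers, labels, drop = FALSE] %*% tr$coef)
      nsd <- if (is.null(tr$noise_sd)) 0 else tr$noise_sd
      y <- y0 + stats::rnorm(length(y0), 0, nsd)
      names(y) <- design$modifiers
      rows <- which(out$solvent == solv)
      ylog <- y[out$modifier[rows]] + stats::rnorm(length(rows), 0, replicate_sd)
      out$dr_anti[rows] <- 10^ylog
      if (!is.null(tr$er)) {
        elab <- if (is.character(tr$er$subset)) tr$er$subset
                else colnames(m)[tr$er$subset]
        g0 <- drop(m[design$modifiers, elab, drop = FALSE] %*% tr$er$coef)
        esd <- if (is.null(tr$er$noise_sd)) 0 else tr$er$noise_sd
        g <- g0 + stats::rnorm(length(g0), 0, esd)
        names(g) <- design$modifiers
        grep_ <- g[out$modifier[rows]] + stats::rnorm(length(rows), 0, replicate_sd)
        ratio <- exp(-grep_ / (R_KCAL * temperature))
        out$er_major[rows] <- 100 * ratio / (1 + ratio)
        out$er_minor[rows] <- 100 / (1 + ratio)
      }
    }
    read_outcomes(out)
  })
}
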