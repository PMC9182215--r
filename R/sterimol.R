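# Sterimol substituent steric parameters (Verloop's L, B1, B5), computed
# directly from coordinates and a van der Waals radius table. The substituent
# is everything on the attach_to side of the attachment bond, found by
# cutting that bond in the covalent-radius bond graph. No +0.40 Angstrom
# correction is applied to L (classic CPK practice); L is the bare
# projection-plus-radius extent, as in modern implementations.

#' Sterimol steric parameters
#'
#' Computes Verloop's Sterimol descriptors for the substituent attached
#' through the `attach_from` -> `attach_to` bond:
#' \describe{
#'   \item{L}{length: maximum extent of the substituent along the attachment
#'     axis, measured from `attach_from`, including van der Waals radii.}
#'   \item{B5}{maximum width perpendicular to the axis.}
#'   \item{B1}{minimum width: the smallest half-width of the substituent's
#'     projection onto the plane perpendicular to the axis, over all
#'     in-plane directions.}
#' }
#' B1 is computed by an angular scan of the support function of the
#' projected atom disks (default step 0.25 degrees; the value is the minimum
#' over directions of the maximal signed extent).
#'
#' @param s A `qssr_structure`.
#' @param attach_from 1-based index of the attachment-point atom (stays on
#'   the scaffold side; L is measured from it).
#' @param attach_to 1-based index of the first substituent atom.
#' @param radii Named van der Waals radius table in Angstrom
#'   (default [bondi_radii()]).
#' @param scan_step Angular step of the B1 scan, degrees (must be <= 0.5).
#' @return Named numeric vector `c(L =, B1 =, B5 =)` in Angstrom.
#' @export
#' @examples
#' s <- structure_3d("CH", c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)))
#' sterimol(s, 1, 2)  # L = 2.29, B1 = B5 = 1.20
sterimol <- function(s, attach_from, attach_to, radii = bondi_radii(),
                     scan_step = 0.25) {
  attach_from <- as.integer(attach_from)
  attach_to <- as.integer(attach_to)
  if (attach_from == attach_to) stop("attach_from and attach_to must differ")
  n <- n_atoms(s)
  if (any(c(attach_from, attach_to) < 1L) || any(c(attach_from, attach_to) > n))
    stop("attachment atom index out of range")
  if (scan_step > 0.5) stop("scan_step must be <= 0.5 degrees")
  sub <- substituent_atoms(s, attach_from, attach_to)
  r <- radii[s$elements[sub]]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(s$elements[sub][is.na(r)]), collapse = ", "))
  axis <- s$coords[attach_to, ] - s$coords[attach_from, ]
  axis <- axis / sqrt(sum(axis^2))
  rel <- sweep(s$coords[sub, , drop = FALSE], 2, s$coords[attach_from, ])
  proj <- drop(rel %*% axis)
  perp <- rel - outer(proj, axis)
  L <- max(proj + r)
  B5 <- max(sqrt(rowSums(perp^2)) + r)
  # orthonormal in-plane basis for the projection plane
  e1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  u <- drop(perp %*% e1)
  v <- drop(perp %*% e2)
  theta <- seq(0, 2 * pi, by = scan_step * pi / 180)
  support <- vapply(theta, function(a)
    max(u * cos(a) + v * sin(a) + r), numeric(1))
  B1 <- min(support)
  c(L = L, B1 = B1, B5 = B5)
}

# Atoms on the attach_to side of the (attach_from, attach_to) bond: cut the
# bond in the covalent-radius bond graph and take attach_to's component.
# Errors if the cut does not disconnect attach_from from attach_to (the
# attachment bond is part of a ring).
substituent_atoms <- function(s, attach_from, attach_to) {
  bonds <- perceive_bonds(s)
  keep <- !((bonds[, 1] == attach_from & bonds[, 2] == attach_to) |
            (bonds[, 1] == attach_to & bonds[, 2] == attach_from))
  bonds <- bonds[keep, , drop = FALSE]
  n <- n_atoms(s)
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  queue <- attach_to
  seen[attach_to] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
  }
  if (seen[attach_from])
    stop("attachment bond is part of a ring: cutting it does not disconnect the substituent")
  which(seen)
}
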