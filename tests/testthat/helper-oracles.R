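# Shared fixtures and independent oracles. Oracles deliberately use
# different formulations than the package code paths they check.

# regular hexagon of given side length, centered at `center`, in the z = 0
# plane (vertex 1 on the +x axis)
hexagon_coords <- function(side = 1.39, center = c(0, 0, 0)) {
  ang <- (0:5) * pi / 3
  sweep(cbind(side * cos(ang), side * sin(ang), 0), 2, center, `+`)
}

# random proper rotation matrix (det +1) and translation
random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 5))
}

apply_rigid <- function(s, motion) {
  structure_3d(s$name, s$elements,
               t(motion$R %*% t(s$coords)) +
                 matrix(motion$t, nrow(s$coords), 3, byrow = TRUE),
               s$charge_total)
}

# independent dihedral: normals + acos magnitude, sign from a triple product
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                         x[3] * y[1] - x[1] * y[3],
                         x[1] * y[2] - x[2] * y[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  s <- sum(cr(n1, n2) * b2)
  if (s < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# independent B1: dense 0.01-degree support-function scan with its own
# basis construction (Gram-Schmidt against a random reference vector fixed
# by seed 0 of the caller)
b1_dense_oracle <- function(s, attach_from, attach_to, radii = bondi_radii(),
                            step_deg = 0.01) {
  axis <- s$coords[attach_to, ] - s$coords[attach_from, ]
  axis <- axis / sqrt(sum(axis^2))
  sub <- qssr:::substituent_atoms(s, attach_from, attach_to)
  r <- radii[s$elements[sub]]
  rel <- sweep(s$coords[sub, , drop = FALSE], 2, s$coords[attach_from, ])
  perp <- rel - outer(drop(rel %*% axis), axis)
  ref <- c(0.371, -0.802, 0.468)  # arbitrary fixed reference, not axis-aligned
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  u <- drop(perp %*% e1); v <- drop(perp %*% e2)
  theta <- seq(0, 2 * pi, by = step_deg * pi / 180)
  min(vapply(theta, function(a) max(u * cos(a) + v * sin(a) + r), numeric(1)))
}

# random chain-substituent toy: a one-atom scaffold with a connected random
# walk of substituent atoms, guaranteed to stay bonded along the chain and
# away from the scaffold atom
random_chain_substituent <- function(n_chain = 4,
                                     elements = c("H", "C", "N", "O", "F", "Cl")) {
  coords <- rbind(c(0, 0, 0))
  el <- "C"
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  coords <- rbind(coords, 1.5 * dir)
  el <- c(el, "C")
  for (k in seq_len(n_chain)) {
    repeat {
      step <- rnorm(3); step <- 1.4 * step / sqrt(sum(step^2))
      cand <- coords[nrow(coords), ] + step
      if (sqrt(sum(cand^2)) > 2.8) break
    }
    coords <- rbind(coords, cand)
    el <- c(el, sample(elements, 1))
  }
  structure_3d("chain", el, coords)
}

# normal-equations OLS oracle
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  unname(drop(solve(crossprod(X1), crossprod(X1, y))))
}

# explicit-refit LOO Q2 oracle built on the normal equations
q2_loo_oracle <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    beta <- ols_oracle(X[-i, , drop = FALSE], y[-i])
    press <- press + (y[i] - drop(c(1, X[i, ]) %*% beta))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# small campaign fixture: synthetic matrices for all five configurations
# with matching modifier ids
make_campaign_matrices <- function(design, seed = 1, n_descriptors = 20,
                                   rho = 0.3) {
  labels <- configuration_labels()
  out <- list()
  for (i in seq_along(labels)) {
    sp <- synth_spec(n_compounds = length(design$modifiers),
                     n_descriptors = n_descriptors, rho = rho,
                     seed = seed + 1000 * i)
    m <- gen_matrix(sp, configuration = labels[i])
    rownames(m) <- design$modifiers
    out[[labels[i]]] <- m
  }
  out
}
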