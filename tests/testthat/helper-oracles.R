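# Independent oracles and fixture builders used across the suite.  These
# deliberately avoid the code paths they check.

# --- isotopomer oracle: joint/conditional probabilities by direct
#     summation over the full enumeration --------------------------------
enum_joint <- function(aa, a1, a2, scheme) {
  iso <- enumerate_isotopomers(aa, scheme)
  sum(iso$prob[iso[[a1]] & iso[[a2]]])
}

enum_marginal <- function(aa, atom, scheme) {
  iso <- enumerate_isotopomers(aa, scheme)
  sum(iso$prob[iso[[atom]]])
}

# --- rotation-grid brute force for the Kabsch check ---------------------
# Nested grid search over ZYZ Euler angles with optimal translation
# (centroid match) at each rotation; refines around the best cell.
euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

grid_rmsd_min <- function(P, Q, levels = 4L, n0 = 18L) {
  P0 <- sweep(P, 2L, colMeans(P)); Q0 <- sweep(Q, 2L, colMeans(Q))
  rmsd_at <- function(a, b, c) {
    sqrt(mean(rowSums((P0 %*% t(euler_rot(a, b, c)) - Q0)^2)))
  }
  ctr <- c(pi, pi / 2, pi)
  hw <- c(pi, pi / 2, pi)          # half-widths of the search box
  best <- c(ctr, rmsd_at(ctr[1], ctr[2], ctr[3]))
  for (lev in seq_len(levels)) {
    as <- seq(best[1] - hw[1], best[1] + hw[1], length.out = n0)
    bs <- seq(max(best[2] - hw[2], 0), min(best[2] + hw[2], pi),
              length.out = n0)
    cs <- seq(best[3] - hw[3], best[3] + hw[3], length.out = n0)
    for (a in as) for (b in bs) for (c in cs) {
      r <- rmsd_at(a, b, c)
      if (r < best[4]) best <- c(a, b, c, r)
    }
    hw <- hw * 2.5 / n0
  }
  best[4]
}

# --- 15N spectral-density oracle for tau_c ------------------------------
# Rigid isotropic rotor, dipolar (r_NH = 1.02 A) + CSA (-160 ppm).
t1t2_ratio_spectral_density <- function(tau_c_s, field_mhz) {
  wH <- 2 * pi * field_mhz * 1e6
  wN <- wH * 0.101329
  J <- function(w) 0.4 * tau_c_s / (1 + (w * tau_c_s)^2)
  mu0_4pi <- 1e-7; hbar <- 1.054571817e-34
  gH <- 2.6752218744e8; gN <- 2.7126e7; rNH <- 1.02e-10
  d <- mu0_4pi * hbar * gH * gN / rNH^3
  c2 <- (wN * 160e-6)^2 / 3
  R1 <- d^2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- d^2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                     6 * J(wH + wN)) +
        c2 / 6 * (4 * J(0) + 3 * J(wN))
  R2 / R1     # T1/T2
}

# --- toy structures -----------------------------------------------------
toy_conformer <- function(xyz, atoms = NULL, resno = NULL) {
  n <- nrow(xyz)
  conformer(data.frame(
    resno = resno %||% seq_len(n),
    restype = "ALA",
    atom = atoms %||% rep("CA", n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

rigid_move <- function(conf, angle = pi / 3, axis = c(0, 0, 1),
                       shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(conf[, c("x", "y", "z")]) %*% t(R)
  conf$x <- xyz[, 1] + shift[1]
  conf$y <- xyz[, 2] + shift[2]
  conf$z <- xyz[, 3] + shift[3]
  conf
}

`%||%` <- function(a, b) if (is.null(a)) b else a
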