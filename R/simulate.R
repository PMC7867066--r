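# Seeded synthetic-data generators for every input type the analysis
# modules consume.  Each generator emits a machine-readable truth object
# alongside the data; identical arguments and seed give bit-identical
# output.  Intensity noise is multiplicative log-normal; shift and
# coordinate noise is additive Gaussian.

T1_DELAYS_MS <- c(10, 50, 100, 200, 300, 500, 800, 1000, 1200, 2000)
T2_DELAYS_MS <- c(16, 64, 96, 128, 156, 196, 224, 256)
TITRATION_RATIOS <- c(0, 0.25, 1, 5, 12.5, 25)

# Default residue-type composition: every standard type represented,
# weighted like a typical small soluble protein.
default_composition <- function(n_residues) {
  rep_len(AA3, n_residues)
}

#' Generate an assigned synthetic HNCACB-style peak list
#'
#' Emulates intra-residual CA/CB peak intensities of a fractionally
#' labeled sample: each residue gets a CA peak with a log-normal base
#' intensity and (except Gly) a CB peak at the model-predicted CB/CA ratio
#' for its type, times multiplicative log-normal noise.  Pro rows are
#' absent (no amide).  Peak positions are drawn in typical amide/carbon
#' shift ranges so overlap handling can be exercised.
#'
#' @param n_residues chain length before Pro removal (default 86, a small
#'   CBM-sized domain).
#' @param scheme labeling scheme (default f = 0.2 with package defaults).
#' @param attenuation per-group attenuation, see [predict_cbca_ratio()].
#' @param noise_sdlog sdlog of the multiplicative intensity noise
#'   (default 0.1, i.e. ~10% intensity scatter typical of 3D peak heights).
#' @param composition residue types along the chain (default: cycle
#'   through all 20).
#' @param seed integer seed.
#' @return list with `peaks` (a [peak_table()]) and `truth` (data.frame of
#'   generating ratios per residue).
#' @export
gen_peaklist <- function(n_residues = 86, scheme = labeling_scheme(0.2),
                         attenuation = default_attenuation(),
                         noise_sdlog = 0.1,
                         composition = default_composition(n_residues),
                         seed = 1L) {
  set.seed(seed)
  scheme <- as_labeling_scheme(scheme)
  restype <- vapply(composition, aa_three, character(1), USE.NAMES = FALSE)
  resno <- seq_along(restype)
  keep <- restype != "PRO"
  rows <- list(); truth <- list()
  for (i in which(keep)) {
    rt <- restype[i]
    base <- stats::rlnorm(1, meanlog = log(100), sdlog = 0.3)
    h_ppm <- stats::runif(1, 7, 10)
    n_ppm <- stats::runif(1, 105, 130)
    ca_ppm <- stats::runif(1, 52, 66)
    ratio <- if (rt == "GLY") NA_real_ else {
      predict_cbca_ratio(rt, scheme, attenuation)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      residue = i, restype = rt, atom = "CA", role = "intra",
      w1 = n_ppm, w2 = ca_ppm, w3 = h_ppm,
      height = base * stats::rlnorm(1, 0, noise_sdlog))
    if (rt != "GLY") {
      cb_ppm <- stats::runif(1, 18, 42)
      rows[[length(rows) + 1L]] <- data.frame(
        residue = i, restype = rt, atom = "CB", role = "intra",
        w1 = n_ppm, w2 = cb_ppm, w3 = h_ppm,
        height = base * ratio * stats::rlnorm(1, 0, noise_sdlog))
    }
    truth[[length(truth) + 1L]] <- data.frame(
      residue = i, restype = rt,
      group = classify_group(rt), true_ratio = ratio)
  }
  list(peaks = peak_table(do.call(rbind, rows), nuclei = c("N", "C", "H")),
       truth = do.call(rbind, truth))
}

#' Generate synthetic T1/T2 relaxation decay series
#'
#' Mono-exponential decays I(t) = I0 exp(-t/T) at the standard delay lists
#' (T1: 10...2000 ms; T2: 16...256 ms) with multiplicative log-normal
#' noise.  Per-residue true time constants are drawn from a narrow normal
#' around the stated mean.
#'
#' @param n_residues number of residues (default 77).
#' @param experiment `"T1"` or `"T2"` (chooses the delay list).
#' @param T_mean,T_sd mean and spread of true time constants in ms
#'   (defaults 694 and 17 for T1; pass 104 and 7 for T2).
#' @param noise relative intensity noise (sdlog; default 0.02).
#' @param I0 reference amplitude.
#' @param delays optional explicit delay list (ms).
#' @param seed integer seed.
#' @return list with `decays` (data.frame residue, delay_ms, intensity)
#'   and `truth` (residue, T_true_ms, I0).
#' @export
gen_decay <- function(n_residues = 77, experiment = c("T1", "T2"),
                      T_mean = NULL, T_sd = NULL, noise = 0.02, I0 = 1000,
                      delays = NULL, seed = 1L) {
  experiment <- match.arg(experiment)
  set.seed(seed)
  if (is.null(delays)) {
    delays <- if (experiment == "T1") T1_DELAYS_MS else T2_DELAYS_MS
  }
  if (is.null(T_mean)) T_mean <- if (experiment == "T1") 694 else 104
  if (is.null(T_sd)) T_sd <- if (experiment == "T1") 17 else 7
  T_true <- stats::rnorm(n_residues, T_mean, T_sd)
  T_true <- pmax(T_true, 1)
  rows <- lapply(seq_len(n_residues), function(r) {
    ideal <- I0 * exp(-delays / T_true[r])
    obs <- if (noise > 0) ideal * stats::rlnorm(length(delays), 0, noise)
           else ideal
    data.frame(residue = r, delay_ms = delays, intensity = obs)
  })
  list(decays = do.call(rbind, rows),
       truth = data.frame(residue = seq_len(n_residues),
                          T_true_ms = T_true, I0 = I0))
}

# Bound fraction of protein for exact two-state 1:1 binding.
bound_fraction <- function(P_mM, L_mM, kd_mM) {
  if (kd_mM == 0) return(pmin(L_mM / P_mM, 1))
  s <- P_mM + L_mM + kd_mM
  pl <- (s - sqrt(s^2 - 4 * P_mM * L_mM)) / 2
  pl / P_mM
}

#' Generate a synthetic fast-exchange HSQC titration series
#'
#' Two-state 1:1 binding in fast exchange: observed shifts move from the
#' free position toward free + Delta_max by the exact bound fraction from
#' the binding quadratic at each molar ratio.  Non-binding residues get
#' only Gaussian shift jitter.
#'
#' @param n_residues number of amide peaks (default 80).
#' @param perturbed residue ids that respond to ligand (default 4 spread
#'   through the chain).
#' @param dd_max_h,dd_max_n full perturbation at saturation, ppm (defaults
#'   0.05 and 0.2 so the weighted CSP is dominated by 1H, mirroring a
#'   weak-binding surface).
#' @param kd_mM dissociation constant (default 5 mM, weak binding).
#' @param protein_mM protein concentration (default 0.73).
#' @param ratios molar ratio series (default 0, 0.25, 1, 5, 12.5, 25).
#' @param jitter additive shift noise sd in ppm on both axes
#'   (default 0.001).
#' @param seed integer seed.
#' @return list with `series` (a [titration_series()]) and `truth`
#'   (residue, perturbed, dd_av_max, plus the saturation fraction reached
#'   at the final point as attribute `"sat_end"`).
#' @export
gen_titration <- function(n_residues = 80,
                          perturbed = round(seq(10, n_residues - 5,
                                                length.out = 4)),
                          dd_max_h = 0.05, dd_max_n = 0.2, kd_mM = 5,
                          protein_mM = 0.73, ratios = TITRATION_RATIOS,
                          jitter = 0.001, seed = 1L) {
  set.seed(seed)
  free_h <- stats::runif(n_residues, 7, 10)
  free_n <- stats::runif(n_residues, 105, 130)
  is_pert <- seq_len(n_residues) %in% perturbed
  tables <- lapply(ratios, function(r) {
    fb <- bound_fraction(protein_mM, r * protein_mM, kd_mM)
    data.frame(
      residue = seq_len(n_residues),
      h_ppm = free_h + ifelse(is_pert, fb * dd_max_h, 0) +
        stats::rnorm(n_residues, 0, jitter),
      n_ppm = free_n + ifelse(is_pert, fb * dd_max_n, 0) +
        stats::rnorm(n_residues, 0, jitter))
  })
  truth <- data.frame(
    residue = seq_len(n_residues), perturbed = is_pert,
    dd_av_max = ifelse(is_pert, csp(dd_max_h, dd_max_n), 0))
  attr(truth, "sat_end") <- bound_fraction(
    protein_mM, max(ratios) * protein_mM, kd_mM)
  list(series = titration_series(ratios, tables, protein_mM = protein_mM),
       truth = truth)
}

# Toy fold: an ideal alpha-helical backbone (N, CA, C per residue).
helix_backbone <- function(n_residues) {
  rows <- list()
  # CA helix: radius 2.3 A, rise 1.5 A, 100 degrees per residue; N and C
  # placed on slightly rotated/shifted helices so residues are chiral and
  # non-collinear.
  par <- list(N = c(r = 1.6, dz = -0.6, dphi = -28),
              CA = c(r = 2.3, dz = 0, dphi = 0),
              C = c(r = 1.7, dz = 0.6, dphi = 26))
  for (i in seq_len(n_residues)) {
    phi0 <- (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    for (at in c("N", "CA", "C")) {
      p <- par[[at]]
      phi <- phi0 + p[["dphi"]] * pi / 180
      rows[[length(rows) + 1L]] <- data.frame(
        resno = i, restype = "ALA", atom = at,
        x = p[["r"]] * cos(phi), y = p[["r"]] * sin(phi),
        z = z0 + p[["dz"]])
    }
  }
  conformer(do.call(rbind, rows))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic multi-model structure ensemble
#'
#' Builds a toy helical base fold, then creates each model as base +
#' isotropic per-atom Gaussian displacement of the given sigma followed by
#' a random rigid motion (which any correct comparison must undo).
#'
#' @param n_models number of conformers (default 20, a typical NMR bundle).
#' @param n_residues chain length (default 30).
#' @param sigma per-coordinate displacement sd in Angstrom (default 0.5).
#' @param seed integer seed.
#' @return list with `ensemble` (list of conformers), `base` (the
#'   noise-free conformer) and `truth` (list with sigma).
#' @export
gen_ensemble <- function(n_models = 20, n_residues = 30, sigma = 0.5,
                         seed = 1L) {
  set.seed(seed)
  base <- helix_backbone(n_residues)
  n_atoms <- nrow(base)
  ens <- lapply(seq_len(n_models), function(m) {
    cf <- base
    cf$x <- cf$x + stats::rnorm(n_atoms, 0, sigma)
    cf$y <- cf$y + stats::rnorm(n_atoms, 0, sigma)
    cf$z <- cf$z + stats::rnorm(n_atoms, 0, sigma)
    R <- random_rotation()
    tr <- stats::rnorm(3, 0, 10)
    xyz <- as.matrix(cf[, c("x", "y", "z")]) %*% t(R)
    cf$x <- xyz[, 1] + tr[1]; cf$y <- xyz[, 2] + tr[2]
    cf$z <- xyz[, 3] + tr[3]
    attr(cf, "model") <- m
    cf
  })
  list(ensemble = structure(ens, class = "ensemble"), base = base,
       truth = list(sigma = sigma, n_models = n_models,
                    n_residues = n_residues))
}
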