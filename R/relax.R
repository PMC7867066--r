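# 15N relaxation: mono-exponential T1/T2 fits, heteronuclear NOE, and
# rotational correlation time from the T1/T2 ratio at a single field.

# gamma(15N)/gamma(1H) magnitude used to convert the 1H carrier frequency
# to the 15N Larmor frequency; fixed constant, sign of gamma(15N) ignored.
GAMMA_RATIO_N_H <- 0.101329

#' Fit a mono-exponential decay I(t) = I0 * exp(-t/T)
#'
#' Nonlinear least squares with the initial guess taken from a log-linear
#' regression on the positive intensities.  Two points are solved exactly
#' (no error estimate); non-decaying or degenerate data yield a failure
#' flag rather than an error so that per-residue pipelines can continue.
#'
#' @param delays delay times (any time unit; the fitted T is in the same
#'   unit), strictly increasing, non-negative, length >= 2.
#' @param intensities signal intensities at those delays.
#' @param residue optional residue id carried through to the result.
#' @return object of class `relax_fit`: list with `ok`, `T`, `I0`, `sd_T`,
#'   `rss`, `n`, `residue`.
#' @examples
#' t <- c(10, 50, 100, 200, 300, 500, 800, 1000, 1200, 2000)
#' fit_monoexponential(t, 100 * exp(-t / 694))
#' @export
fit_monoexponential <- function(delays, intensities, residue = NA) {
  if (length(delays) != length(intensities) || length(delays) < 2L) {
    abort_fracnmr("need >= 2 (delay, intensity) pairs", "fracnmr_bad_input")
  }
  if (any(diff(delays) <= 0) || any(delays < 0)) {
    abort_fracnmr("delays must be non-negative and strictly increasing",
                  "fracnmr_bad_input")
  }
  fail <- function() structure(
    list(ok = FALSE, T = NA_real_, I0 = NA_real_, sd_T = NA_real_,
         rss = NA_real_, n = length(delays), residue = residue),
    class = "relax_fit")

  if (length(delays) == 2L) {
    if (any(intensities <= 0) || intensities[2] >= intensities[1]) return(fail())
    Tex <- (delays[2] - delays[1]) / log(intensities[1] / intensities[2])
    I0 <- intensities[1] * exp(delays[1] / Tex)
    return(structure(list(ok = TRUE, T = Tex, I0 = I0, sd_T = NA_real_,
                          rss = 0, n = 2L, residue = residue),
                     class = "relax_fit"))
  }

  pos <- intensities > 0
  if (sum(pos) < 2L) return(fail())
  ll <- stats::lm(log(intensities[pos]) ~ delays[pos])
  slope <- stats::coef(ll)[2]
  if (!is.finite(slope) || slope >= 0) return(fail())
  start <- list(I0 = exp(stats::coef(ll)[1]), Tc = -1 / slope)

  df <- data.frame(t = delays, y = intensities)
  # algorithm = "port": the default Gauss-Newton errors on zero-residual
  # (noiseless) data, which the recovery tests exercise
  fit <- tryCatch(
    stats::nls(y ~ I0 * exp(-t / Tc), data = df, start = start,
               algorithm = "port", lower = c(I0 = 0, Tc = 1e-12),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  co <- stats::coef(fit)
  if (!is.finite(co[["Tc"]]) || co[["Tc"]] <= 0) return(fail())
  se <- tryCatch(summary(fit)$coefficients["Tc", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(ok = TRUE, T = unname(co[["Tc"]]), I0 = unname(co[["I0"]]),
                 sd_T = unname(se), rss = sum(stats::resid(fit)^2),
                 n = nrow(df), residue = residue),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<relax_fit> T = %.4g +/- %.3g (n = %d)\n",
                x$T, x$sd_T, x$n))
  } else {
    cat("<relax_fit> FAILED (non-decaying or degenerate data)\n")
  }
  invisible(x)
}

#' Fit T1/T2 decays for every residue of a long-format table
#'
#' @param decays data.frame with columns `residue`, `delay_ms`,
#'   `intensity`.
#' @return data.frame: residue, T_ms, sd_T, ok.
#' @export
fit_decay_table <- function(decays) {
  sp <- split(decays, decays$residue)
  out <- lapply(sp, function(d) {
    d <- d[order(d$delay_ms), , drop = FALSE]
    f <- fit_monoexponential(d$delay_ms, d$intensity, residue = d$residue[1])
    data.frame(residue = d$residue[1], T_ms = f$T, sd_T = f$sd_T, ok = f$ok)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$residue), , drop = FALSE]
}

#' Heteronuclear NOE ratio
#'
#' eta = I_sat / I_ref, the 15N signal intensity with proton saturation
#' over that without.  Values near 0.8 mark rigid residues; low or negative
#' values mark flexible ones.
#'
#' @param I_sat,I_ref intensities with / without saturation (vectorized).
#' @param sd_sat,sd_ref optional per-spectrum noise estimates; when given,
#'   the propagated standard deviation of eta is attached as attribute
#'   `"sd"`.
#' @return numeric vector of NOE ratios.
#' @export
het_noe <- function(I_sat, I_ref, sd_sat = NULL, sd_ref = NULL) {
  if (any(I_ref == 0)) {
    abort_fracnmr("reference intensity is zero", "fracnmr_bad_input")
  }
  eta <- I_sat / I_ref
  if (!is.null(sd_sat) && !is.null(sd_ref)) {
    attr(eta, "sd") <- abs(eta) *
      sqrt((sd_sat / I_sat)^2 + (sd_ref / I_ref)^2)
  }
  eta
}

#' Rotational correlation time from the T1/T2 ratio
#'
#' Single-field closed form for an isotropically tumbling rigid molecule:
#' tau_c = sqrt(6 * T1/T2 - 7) / (4 * pi * nu_N), with nu_N the 15N Larmor
#' frequency.  Valid for rigid residues with tau_c above roughly a
#' nanosecond; requires T1/T2 > 7/6.
#'
#' @param ratio T1/T2 (dimensionless).
#' @param field_1H spectrometer 1H frequency in MHz.
#' @return object of class `tauc_estimate`: list with `tau_c_ns`,
#'   `t1_t2_ratio`, `field_1H`.
#' @examples
#' tauc_from_t1t2(6.7, 850)  # ~5.3 ns
#' @export
tauc_from_t1t2 <- function(ratio, field_1H) {
  if (!is.finite(ratio) || 6 * ratio - 7 <= 0) {
    abort_fracnmr(
      "T1/T2 must exceed 7/6; sub-nanosecond regime outside validity",
      "fracnmr_tauc_domain")
  }
  if (!is.finite(field_1H) || field_1H <= 0) {
    abort_fracnmr("field_1H (MHz) must be positive", "fracnmr_bad_input")
  }
  nu_N <- field_1H * 1e6 * GAMMA_RATIO_N_H   # Hz
  tau_s <- sqrt(6 * ratio - 7) / (4 * pi * nu_N)
  structure(list(tau_c_ns = tau_s * 1e9, t1_t2_ratio = ratio,
                 field_1H = field_1H),
            class = "tauc_estimate")
}

#' @export
print.tauc_estimate <- function(x, ...) {
  cat(sprintf("<tauc_estimate> tau_c = %.3g ns (T1/T2 = %.3g at %g MHz)\n",
              x$tau_c_ns, x$t1_t2_ratio, x$field_1H))
  invisible(x)
}

#' Summarize per-residue relaxation fits
#'
#' Joins T1 and T2 fits with a heteronuclear NOE table, drops failed fits
#' and residues below the NOE cutoff (flexible residues violate the rigid
#' assumption behind the tau_c closed form), and reports mean +/- sd of
#' T1, T2 and T1/T2 plus tau_c.  Because it is not obvious whether a
#' printed T1/T2 average is the mean of per-residue ratios or the ratio of
#' mean T1 to mean T2, both are reported.
#'
#' @param t1_fits,t2_fits outputs of [fit_decay_table()] (T in ms).
#' @param noe optional data.frame `residue`, `noe` (or `I_sat`, `I_ref`).
#' @param noe_cutoff minimum NOE for inclusion (default 0.65).
#' @param field_1H 1H frequency in MHz for the tau_c estimates.
#' @return list with `table` (per-residue merged data), `summary`
#'   (means/sds), `tau_c` (from mean of ratios and from ratio of means),
#'   `n_used`, `n_total`.
#' @export
summarize_relaxation <- function(t1_fits, t2_fits, noe = NULL,
                                 noe_cutoff = 0.65, field_1H = 850) {
  m <- merge(t1_fits[, c("residue", "T_ms", "ok")],
             t2_fits[, c("residue", "T_ms", "ok")],
             by = "residue", suffixes = c("_t1", "_t2"))
  if (!is.null(noe)) {
    if (!"noe" %in% names(noe)) noe$noe <- het_noe(noe$I_sat, noe$I_ref)
    m <- merge(m, noe[, c("residue", "noe")], by = "residue", all.x = TRUE)
  } else {
    m$noe <- NA_real_
  }
  m$used <- m$ok_t1 & m$ok_t2 &
    (is.na(m$noe) | m$noe >= noe_cutoff)
  keep <- m[m$used, , drop = FALSE]
  if (nrow(keep) == 0L) {
    abort_fracnmr("no residues left after trimming", "fracnmr_bad_input")
  }
  ratio <- keep$T_ms_t1 / keep$T_ms_t2
  sdv <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  summ <- data.frame(
    quantity = c("T1_ms", "T2_ms", "T1/T2"),
    mean = c(mean(keep$T_ms_t1), mean(keep$T_ms_t2), mean(ratio)),
    sd = c(sdv(keep$T_ms_t1), sdv(keep$T_ms_t2), sdv(ratio)))
  list(
    table = m,
    summary = summ,
    tau_c = list(
      from_mean_ratio = tauc_from_t1t2(mean(ratio), field_1H),
      from_ratio_of_means = tauc_from_t1t2(
        mean(keep$T_ms_t1) / mean(keep$T_ms_t2), field_1H)),
    n_used = nrow(keep), n_total = nrow(m))
}

#' Empirical rotational correlation time from molecular weight
#'
#' Stokes-Einstein-Debye estimate tau_c = 4 pi eta r^3 / (3 k T) with the
#' hydrodynamic radius r = (3 MW vbar / (4 pi N_A))^(1/3) + r_hydration.
#'
#' @param mw molecular weight in Da.
#' @param temperature in K (default 303, the measurement temperature for
#'   small-protein work at 30 C).
#' @param viscosity solvent viscosity in mPa s (default 0.797, water at
#'   303 K).
#' @param hydration_radius hydration-shell thickness added to the dry
#'   radius, in Angstrom (default 3.2).
#' @param specific_volume partial specific volume in cm^3/g (default
#'   0.73, a typical protein value).
#' @return tau_c in ns.
#' @export
empirical_tauc_from_mw <- function(mw, temperature = 303, viscosity = 0.797,
                                   hydration_radius = 3.2,
                                   specific_volume = 0.73) {
  args <- c(mw = mw, temperature = temperature, viscosity = viscosity,
            hydration_radius = hydration_radius,
            specific_volume = specific_volume)
  if (any(!is.finite(args)) || any(args <= 0)) {
    abort_fracnmr("all parameters must be positive", "fracnmr_bad_input")
  }
  NA_avog <- 6.02214076e23
  kB <- 1.380649e-23
  v_m3 <- mw * specific_volume / NA_avog * 1e-6       # cm^3 -> m^3
  r_m <- (3 * v_m3 / (4 * pi))^(1 / 3) + hydration_radius * 1e-10
  tau_s <- 4 * pi * (viscosity * 1e-3) * r_m^3 / (3 * kB * temperature)
  tau_s * 1e9
}
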