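# Chemical shift perturbation analysis of [1H,15N]-HSQC titration series.

#' Weighted average chemical shift perturbation
#'
#' Delta_av = sqrt(dH^2 + (0.154 * dN)^2), the standard amide CSP with the
#' 15N shift down-weighted for its larger ppm range.
#'
#' @param d_h,d_n 1H and 15N shift changes in ppm (vectorized).
#' @param weight 15N weight (default 0.154).
#' @return non-negative CSP in ppm.
#' @examples
#' csp(0.01, 0.10)  # 0.0184
#' @export
csp <- function(d_h, d_n, weight = 0.154) {
  if (any(!is.finite(d_h)) || any(!is.finite(d_n))) {
    abort_fracnmr("shift changes must be finite", "fracnmr_bad_input")
  }
  sqrt(d_h^2 + (weight * d_n)^2)
}

#' Build a titration series
#'
#' @param ratios molar ratios (ligand : protein), non-negative, strictly
#'   increasing, first entry 0 (the reference spectrum).
#' @param tables list of per-point peak tables, each a data.frame with
#'   columns `residue` (identifier; side-chain peaks may use suffixed
#'   pseudo-residues like `"488sc"`), `h_ppm`, `n_ppm`.  Assignment columns
#'   are optional in the later points; see [track_peaks()].
#' @param protein_mM optional protein concentration.
#' @return object of class `titration_series`.
#' @export
titration_series <- function(ratios, tables, protein_mM = NA_real_) {
  if (length(ratios) != length(tables)) {
    abort_fracnmr("one peak table per molar ratio required",
                  "fracnmr_bad_input")
  }
  if (ratios[1] != 0 || any(diff(ratios) <= 0) || any(ratios < 0)) {
    abort_fracnmr(
      "molar ratios must be non-negative, strictly increasing, starting at 0",
      "fracnmr_bad_input")
  }
  structure(list(ratios = ratios, tables = tables, protein_mM = protein_mM),
            class = "titration_series")
}

#' Track amide peaks across a titration series
#'
#' When later points carry `residue` assignments, trajectories are joined
#' on residue.  Otherwise each reference peak is matched to its nearest
#' neighbour in the scaled (1H, 0.154 * 15N) shift space within
#' `tolerance`; peaks claimed by two reference peaks, or reference peaks
#' with no match, are flagged rather than silently assigned.
#'
#' @param series a [titration_series()].
#' @param tolerance match radius in scaled ppm (default 0.05).
#' @param weight 15N scaling weight (default 0.154).
#' @return data.frame: residue, point (index), ratio, h_ppm, n_ppm,
#'   matched (logical), ambiguous (logical).
#' @export
track_peaks <- function(series, tolerance = 0.05, weight = 0.154) {
  ref <- series$tables[[1]]
  if (is.null(ref$residue)) {
    abort_fracnmr("reference point must be assigned", "fracnmr_bad_input")
  }
  out <- list()
  for (p in seq_along(series$tables)) {
    tab <- series$tables[[p]]
    if (!is.null(tab$residue)) {
      idx <- match(ref$residue, tab$residue)
      matched <- !is.na(idx)
      amb <- duplicated(idx, incomparables = NA) |
             duplicated(idx, incomparables = NA, fromLast = TRUE)
      out[[p]] <- data.frame(
        residue = ref$residue, point = p, ratio = series$ratios[p],
        h_ppm = tab$h_ppm[idx], n_ppm = tab$n_ppm[idx],
        matched = matched, ambiguous = amb & matched)
    } else {
      # nearest neighbour in scaled shift space
      nref <- nrow(ref)
      best <- rep(NA_integer_, nref)
      dist <- rep(NA_real_, nref)
      for (i in seq_len(nref)) {
        d <- sqrt((tab$h_ppm - ref$h_ppm[i])^2 +
                  (weight * (tab$n_ppm - ref$n_ppm[i]))^2)
        j <- which.min(d)
        if (length(j) && d[j] <= tolerance) { best[i] <- j; dist[i] <- d[j] }
      }
      amb <- best %in% best[duplicated(best, incomparables = NA)]
      matched <- !is.na(best) & !amb
      out[[p]] <- data.frame(
        residue = ref$residue, point = p, ratio = series$ratios[p],
        h_ppm = ifelse(matched, tab$h_ppm[best], NA_real_),
        n_ppm = ifelse(matched, tab$n_ppm[best], NA_real_),
        matched = matched, ambiguous = !is.na(best) & amb)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Endpoint-vs-reference CSP records for a titration
#'
#' Computes per-residue shift changes between the last titration point and
#' the reference (ratio 0) point and the weighted average CSP.
#'
#' @param series a [titration_series()].
#' @param threshold significance threshold in ppm; a residue is called
#'   significant when its CSP strictly exceeds it (default 0.01).
#' @param tolerance,weight passed to [track_peaks()].
#' @return data.frame: residue, dd_h, dd_n, dd_av, significant.
#' @export
csp_records <- function(series, threshold = 0.01, tolerance = 0.05,
                        weight = 0.154) {
  traj <- track_peaks(series, tolerance = tolerance, weight = weight)
  first <- traj[traj$point == 1L, , drop = FALSE]
  last <- traj[traj$point == max(traj$point), , drop = FALSE]
  m <- merge(first, last, by = "residue", suffixes = c("_0", "_end"))
  ok <- m$matched_0 & m$matched_end
  out <- data.frame(
    residue = m$residue,
    dd_h = ifelse(ok, m$h_ppm_end - m$h_ppm_0, NA_real_),
    dd_n = ifelse(ok, m$n_ppm_end - m$n_ppm_0, NA_real_))
  out$dd_av <- ifelse(ok, csp(out$dd_h[ok], out$dd_n[ok], weight), NA_real_)
  out$significant <- !is.na(out$dd_av) & out$dd_av > threshold
  out[order(match(out$residue, first$residue)), , drop = FALSE]
}

#' Select significant CSP records
#'
#' Strict inequality: a CSP exactly at the threshold is not called.
#'
#' @param records output of [csp_records()].
#' @param threshold ppm threshold (default 0.01).
#' @return subset of `records` with `dd_av > threshold`.
#' @export
call_significant <- function(records, threshold = 0.01) {
  if (!is.finite(threshold) || threshold <= 0) {
    abort_fracnmr("threshold must be positive", "fracnmr_bad_input")
  }
  records[!is.na(records$dd_av) & records$dd_av > threshold, , drop = FALSE]
}
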