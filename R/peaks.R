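# CB(i)/CA(i) peak-intensity analysis of assigned triple-resonance peak
# lists (HNCACB / intra-HNCACB style).

#' Construct a peak table
#'
#' @param df data.frame with at least columns `residue` (integer),
#'   `restype` (three-letter code), `atom` (carbon atom of the peak, `"CA"`
#'   or `"CB"` for ratio analysis), `role` (`"intra"` for the i correlation,
#'   `"seq"` for the i-1 correlation) and `height` (signal intensity, sign
#'   allowed).  Optional shift columns `w1`, `w2`, `w3` (ppm) and a logical
#'   `overlap` flag.
#' @param nuclei nuclei of the shift axes, in column order (used for
#'   per-axis overlap tolerances).
#' @return data.frame of class `peak_table`.
#' @export
peak_table <- function(df, nuclei = c("H", "N", "C")) {
  need <- c("residue", "restype", "atom", "role", "height")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_fracnmr(paste("peak table missing columns:",
                        paste(miss, collapse = ", ")), "fracnmr_bad_input")
  }
  if (any(!is.finite(df$height))) {
    abort_fracnmr("peak heights must be finite", "fracnmr_bad_input")
  }
  df$restype <- vapply(df$restype, aa_three, character(1), USE.NAMES = FALSE)
  if (is.null(df$overlap)) df$overlap <- FALSE
  structure(df, class = c("peak_table", "data.frame"),
            nuclei = nuclei)
}

#' Default per-nucleus overlap tolerances (ppm)
#' @return named numeric vector.
#' @export
default_overlap_tol <- function() c(H = 0.03, N = 0.3, C = 0.3)

#' Flag mutually overlapping peaks
#'
#' Two peaks overlap when they lie within tolerance on every shift axis;
#' both members of such a pair are flagged.  Flagged peaks are excluded
#' from the ratio analysis downstream.
#'
#' @param peaks a [peak_table()] carrying shift columns `w1..wk`.
#' @param tol per-axis tolerances (ppm), in axis order; default derived
#'   from the table's nuclei via [default_overlap_tol()].
#' @return the peak table with its `overlap` column updated.
#' @export
detect_overlap <- function(peaks, tol = NULL) {
  wcols <- grep("^w[0-9]+$", names(peaks), value = TRUE)
  if (!length(wcols)) {
    abort_fracnmr("peak table has no shift columns (w1..wk)",
                  "fracnmr_bad_input")
  }
  if (is.null(tol)) {
    nuclei <- attr(peaks, "nuclei")
    tol <- unname(default_overlap_tol()[nuclei[seq_along(wcols)]])
  }
  if (any(!is.finite(tol)) || any(tol <= 0)) {
    abort_fracnmr("overlap tolerances must be positive", "fracnmr_bad_input")
  }
  n <- nrow(peaks)
  flag <- rep(FALSE, n)
  if (n > 1L) {
    w <- as.matrix(peaks[, wcols, drop = FALSE])
    for (i in seq_len(n - 1L)) {
      d <- abs(sweep(w[(i + 1L):n, , drop = FALSE], 2L, w[i, ]))
      hit <- which(rowSums(sweep(d, 2L, tol, "<=")) == length(wcols))
      if (length(hit)) {
        flag[i] <- TRUE
        flag[i + hit] <- TRUE
      }
    }
  }
  peaks$overlap <- flag
  peaks
}

#' Compute CB(i)/CA(i) intensity ratios per residue
#'
#' Uses the intra-residual CA peak as internal reference; sequential (i-1)
#' peaks are ignored because their transfer depends on the
#' conformation-dependent 2J(N,CA) coupling.  Gly (no CB) and Pro (no
#' amide) are excluded with a reason, as are residues whose CA or CB peak
#' is overlap-flagged or missing.
#'
#' @param peaks a [peak_table()].
#' @param use_abs take absolute intensities before forming the ratio
#'   (default TRUE; CB peaks can be sign-inverted in some experiments).
#' @return data.frame of ratio records: residue, restype, ratio, excluded
#'   (one of `none`, `glycine`, `proline`, `overlap`, `missing-peak`).
#' @export
compute_cbca_ratios <- function(peaks, use_abs = TRUE) {
  stopifnot(inherits(peaks, "peak_table") || is.data.frame(peaks))
  res <- unique(peaks[, c("residue", "restype")])
  res <- res[order(res$residue), , drop = FALSE]
  recs <- lapply(seq_len(nrow(res)), function(i) {
    rn <- res$residue[i]; rt <- res$restype[i]
    rec <- list(residue = rn, restype = rt, ratio = NA_real_, excluded = "none")
    if (rt == "GLY") { rec$excluded <- "glycine"; return(rec) }
    if (rt == "PRO") { rec$excluded <- "proline"; return(rec) }
    sub <- peaks[peaks$residue == rn & peaks$role == "intra", , drop = FALSE]
    ca <- sub[sub$atom == "CA", , drop = FALSE]
    cb <- sub[sub$atom == "CB", , drop = FALSE]
    if (nrow(ca) > 1L && !all(ca$overlap)) {
      abort_fracnmr(sprintf(
        "residue %d has %d intra CA peaks without overlap flag", rn, nrow(ca)),
        "fracnmr_bad_input")
    }
    if (nrow(cb) > 1L && !all(cb$overlap)) {
      abort_fracnmr(sprintf(
        "residue %d has %d intra CB peaks without overlap flag", rn, nrow(cb)),
        "fracnmr_bad_input")
    }
    if (nrow(ca) == 0L || nrow(cb) == 0L) {
      rec$excluded <- "missing-peak"; return(rec)
    }
    if (any(ca$overlap) || any(cb$overlap)) {
      rec$excluded <- "overlap"; return(rec)
    }
    hca <- ca$height[1]; hcb <- cb$height[1]
    if (use_abs) { hca <- abs(hca); hcb <- abs(hcb) }
    if (hca == 0) { rec$excluded <- "missing-peak"; return(rec) }
    rec$ratio <- hcb / hca
    rec
  })
  out <- do.call(rbind, lapply(recs, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Aggregate ratio records by residue type
#'
#' @param records output of [compute_cbca_ratios()].
#' @return data.frame: restype, group, mean, sd, n (unexcluded records
#'   only; sd is NA for n = 1).
#' @export
aggregate_by_type <- function(records) {
  keep <- records[records$excluded == "none", , drop = FALSE]
  if (nrow(keep) == 0L) {
    abort_fracnmr("no unexcluded ratio records to aggregate",
                  "fracnmr_bad_input")
  }
  sp <- split(keep$ratio, keep$restype)
  out <- data.frame(
    restype = names(sp),
    group = classify_group(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(x) if (length(x) > 1L) stats::sd(x) else NA_real_,
                numeric(1)),
    n = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(-out$mean), , drop = FALSE]
}

#' Score amino-acid-type groups for an observed CB/CA ratio
#'
#' Deterministic likelihood-style scores against the model-predicted bands
#' of the three groups.  A band is the \[min, max\] of predicted ratios of
#' its member types at the given scheme; the score is a Gaussian kernel on
#' the distance to the band (zero inside it).  Ties (equal scores) are
#' broken by the fixed order intact-high, intermediate-TCA, broken-low.
#'
#' @param ratio observed non-negative CB/CA ratio.
#' @param scheme labeling scheme used to predict the bands
#'   (default f = 0.2 with package defaults).
#' @param attenuation per-group attenuation, see [predict_cbca_ratio()].
#' @param width Gaussian kernel width (ratio units) for distances outside
#'   a band; default 0.08, roughly the observed per-type spread.
#' @return data.frame of groups with scores, ranked best first.
#' @export
infer_type_group <- function(ratio, scheme = labeling_scheme(0.2),
                             attenuation = default_attenuation(),
                             width = 0.08) {
  if (!is.finite(ratio) || ratio < 0) {
    abort_fracnmr("'ratio' must be a non-negative number", "fracnmr_bad_input")
  }
  tab <- predict_cbca_table(scheme, attenuation)
  groups <- c("intact-high", "intermediate-TCA", "broken-low")
  score <- vapply(groups, function(g) {
    band <- range(tab$ratio[tab$group == g])
    d <- if (ratio < band[1]) band[1] - ratio
         else if (ratio > band[2]) ratio - band[2]
         else 0
    exp(-0.5 * (d / width)^2)
  }, numeric(1))
  out <- data.frame(group = groups, score = unname(score),
                    stringsAsFactors = FALSE)
  # stable tie-break: order() is stable, groups already in declared order
  out[order(-out$score), , drop = FALSE]
}

#' Stereospecific assignment of Val/Leu methyls from multiplet patterns
#'
#' In a constant-time 13C-HSQC of a fractionally labeled sample, the pro-R
#' methyl of Val and Leu keeps an intact bond to its attached carbon and
#' shows a 13C doublet, while the pro-S methyl shows a singlet.
#'
#' @param methyls data.frame with columns `residue`, `restype` (VAL or
#'   LEU), `methyl` (a label for the methyl resonance, e.g. its atom name)
#'   and `multiplet` (`"singlet"` or `"doublet"`); exactly two rows per
#'   residue.
#' @return the input with an added `stereo` column (`"pro-R"`, `"pro-S"`,
#'   or NA when the two annotations conflict, with a warning).
#' @export
stereo_assign_methyls <- function(methyls) {
  need <- c("residue", "restype", "methyl", "multiplet")
  miss <- setdiff(need, names(methyls))
  if (length(miss)) {
    abort_fracnmr(paste("methyl table missing columns:",
                        paste(miss, collapse = ", ")), "fracnmr_bad_input")
  }
  methyls$restype <- vapply(methyls$restype, aa_three, character(1),
                            USE.NAMES = FALSE)
  bad <- setdiff(unique(methyls$restype), c("VAL", "LEU"))
  if (length(bad)) {
    abort_fracnmr(paste("no diastereotopic methyl pair in residue type(s):",
                        paste(bad, collapse = ", ")),
                  "fracnmr_excluded_residue")
  }
  if (!all(methyls$multiplet %in% c("singlet", "doublet"))) {
    abort_fracnmr("multiplet annotations must be 'singlet' or 'doublet'",
                  "fracnmr_bad_input")
  }
  methyls$stereo <- NA_character_
  for (rn in unique(methyls$residue)) {
    idx <- which(methyls$residue == rn)
    if (length(idx) != 2L) {
      abort_fracnmr(sprintf(
        "residue %s must contribute exactly two methyl records", rn),
        "fracnmr_bad_input")
    }
    mm <- methyls$multiplet[idx]
    if (length(unique(mm)) != 2L) {
      warning(sprintf(
        "residue %s: two %ss - conflicting annotation, left unassigned",
        rn, mm[1]), call. = FALSE)
      next
    }
    methyls$stereo[idx] <- ifelse(mm == "doublet", "pro-R", "pro-S")
  }
  methyls
}
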