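mk_peaks <- function(rows) {
  peak_table(do.call(rbind, lapply(rows, as.data.frame)),
             nuclei = c("N", "C", "H"))
}

peak_row <- function(residue, restype, atom, height, role = "intra",
                     w1 = 120, w2 = 55, w3 = 8) {
  list(residue = residue, restype = restype, atom = atom, role = role,
       w1 = w1, w2 = w2, w3 = w3, height = height)
}

test_that("overlap detection uses the all-axes rule", {
  pk <- mk_peaks(list(
    peak_row(1, "ALA", "CA", 100, w1 = 120.0, w2 = 55.0, w3 = 8.00),
    peak_row(2, "VAL", "CA", 100, w1 = 120.0, w2 = 55.0, w3 = 8.00),
    peak_row(3, "LEU", "CA", 100, w1 = 121.0, w2 = 55.0, w3 = 8.00),
    peak_row(4, "SER", "CA", 100, w1 = 120.0, w2 = 55.0, w3 = 8.02)))
  out <- detect_overlap(pk)
  # identical positions: both flagged; 1 N-ppm apart (> 0.3 tol): clean;
  # within tolerance on every axis (0.02 ppm 1H < 0.03): flagged
  expect_equal(out$overlap, c(TRUE, TRUE, FALSE, TRUE))
  single <- detect_overlap(mk_peaks(list(peak_row(1, "ALA", "CA", 5))))
  expect_false(single$overlap)
  # separation of 2x tolerance on one axis is enough to be clean
  two <- detect_overlap(mk_peaks(list(
    peak_row(1, "ALA", "CA", 5, w3 = 8.00),
    peak_row(2, "VAL", "CA", 5, w3 = 8.06))))
  expect_equal(two$overlap, c(FALSE, FALSE))
})

test_that("CB/CA ratios, exclusions and error cases", {
  pk <- mk_peaks(list(
    peak_row(1, "ALA", "CA", 100), peak_row(1, "ALA", "CB", 85),
    peak_row(2, "GLY", "CA", 90),
    peak_row(3, "VAL", "CA", 200), peak_row(3, "VAL", "CB", 20),
    peak_row(4, "SER", "CA", 50),                       # CB missing
    peak_row(5, "THR", "CA", 80, role = "seq"),          # only sequential
    peak_row(6, "GLU", "CA", -120), peak_row(6, "GLU", "CB", 40)))
  rec <- compute_cbca_ratios(pk)
  expect_equal(nrow(rec), 6)              # exclusion completeness
  expect_equal(rec$ratio[rec$residue == 1], 0.85)
  expect_equal(rec$excluded[rec$residue == 2], "glycine")
  expect_equal(rec$ratio[rec$residue == 3], 0.10)
  expect_equal(rec$excluded[rec$residue == 4], "missing-peak")
  expect_equal(rec$excluded[rec$residue == 5], "missing-peak")
  # negative CA height handled via absolute value by default
  expect_equal(rec$ratio[rec$residue == 6], 40 / 120)

  # proline exclusion
  pkp <- mk_peaks(list(peak_row(7, "PRO", "CA", 10)))
  expect_equal(compute_cbca_ratios(pkp)$excluded, "proline")

  # duplicate unflagged intra peak is an error
  dup <- mk_peaks(list(peak_row(1, "ALA", "CA", 10),
                       peak_row(1, "ALA", "CA", 12),
                       peak_row(1, "ALA", "CB", 5)))
  expect_error(compute_cbca_ratios(dup), class = "fracnmr_bad_input")

  # overlap-flagged CA excludes the residue
  ov <- detect_overlap(mk_peaks(list(
    peak_row(1, "ALA", "CA", 10), peak_row(2, "VAL", "CA", 12),
    peak_row(1, "ALA", "CB", 5, w2 = 20))))
  expect_equal(compute_cbca_ratios(ov)$excluded, c("overlap", "missing-peak"))
})

test_that("ratios are invariant under a global intensity rescaling", {
  g <- gen_peaklist(n_residues = 40, seed = 7)
  r1 <- compute_cbca_ratios(g$peaks)
  pk2 <- g$peaks
  pk2$height <- pk2$height * 137.5
  r2 <- compute_cbca_ratios(pk2)
  expect_equal(r1$ratio, r2$ratio)
})

test_that("aggregation counts only unexcluded records", {
  rec <- data.frame(
    residue = 1:4, restype = c("ALA", "ALA", "GLY", "VAL"),
    ratio = c(0.8, 0.9, NA, NA),
    excluded = c("none", "none", "glycine", "overlap"))
  agg <- aggregate_by_type(rec)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$mean, 0.85)
  expect_equal(agg$n, 2L)
  allex <- rec[rec$excluded != "none", ]
  expect_error(aggregate_by_type(allex), class = "fracnmr_bad_input")
})

test_that("group inference ranks the expected group first", {
  expect_equal(infer_type_group(0.85)$group[1], "intact-high")
  expect_equal(infer_type_group(0.10)$group[1], "broken-low")
  expect_equal(infer_type_group(0.40)$group[1], "intermediate-TCA")
  # boundary: equidistant between two bands resolves by the declared
  # tie-break order (intact-high before intermediate-TCA)
  tab <- predict_cbca_table(labeling_scheme(0.2))
  hi_lo <- min(tab$ratio[tab$group == "intact-high"])
  mid_hi <- max(tab$ratio[tab$group == "intermediate-TCA"])
  mid_pt <- (hi_lo + mid_hi) / 2
  sc <- infer_type_group(mid_pt)
  expect_equal(sc$score[1], sc$score[2])
  expect_equal(sc$group[1], "intact-high")
})

test_that("stereospecific methyl calls from multiplet annotations", {
  mm <- data.frame(
    residue = c(10, 10, 22, 22, 31, 31),
    restype = c("VAL", "VAL", "VAL", "VAL", "LEU", "LEU"),
    methyl = c("CG1", "CG2", "CG1", "CG2", "CD1", "CD2"),
    multiplet = c("doublet", "singlet", "singlet", "doublet",
                  "doublet", "singlet"))
  out <- stereo_assign_methyls(mm)
  expect_equal(out$stereo,
               c("pro-R", "pro-S", "pro-S", "pro-R", "pro-R", "pro-S"))

  conflict <- data.frame(residue = 5, restype = "VAL",
                         methyl = c("CG1", "CG2"),
                         multiplet = c("doublet", "doublet"))
  expect_warning(res <- stereo_assign_methyls(conflict), "conflicting")
  expect_true(all(is.na(res$stereo)))

  bad <- data.frame(residue = 1, restype = "THR", methyl = c("CG2", "CG2"),
                    multiplet = c("singlet", "doublet"))
  expect_error(stereo_assign_methyls(bad),
               class = "fracnmr_excluded_residue")
})

test_that("synthetic peak lists recover the generating group structure", {
  # n = 50 residues per non-excluded type
  comp <- rep(setdiff(fracnmr:::AA3, c("GLY", "PRO")), each = 50)
  g <- gen_peaklist(n_residues = length(comp), composition = comp, seed = 11)
  rec <- compute_cbca_ratios(g$peaks)
  agg <- aggregate_by_type(rec)
  hi <- agg$mean[agg$group == "intact-high"]
  mid <- agg$mean[agg$group == "intermediate-TCA"]
  lo <- agg$mean[agg$group == "broken-low"]
  expect_gt(min(hi), max(mid))
  expect_gt(min(mid), max(lo))
  # per-type means match the generator truth within 3 sd of the mean
  tr <- unique(g$truth[!is.na(g$truth$true_ratio),
                       c("restype", "true_ratio")])
  m <- merge(agg, tr, by = "restype")
  expect_true(all(abs(m$mean - m$true_ratio) <= 3 * m$sd / sqrt(m$n)))
})
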