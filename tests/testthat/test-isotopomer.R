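sch02 <- labeling_scheme(0.2, nat_abund = 0, isotopic_purity = 1)

test_that("enumeration limits: uniform and unlabeled schemes", {
  uni <- labeling_scheme(1, nat_abund = 0, isotopic_purity = 1)
  iso <- enumerate_isotopomers("ALA", uni)
  all13 <- iso$C & iso$CA & iso$CB
  expect_equal(iso$prob[all13], 1)
  expect_equal(sum(iso$prob[!all13]), 0)

  none <- labeling_scheme(0, nat_abund = 0)
  iso0 <- enumerate_isotopomers("ALA", none)
  expect_equal(iso0$prob[!iso0$C & !iso0$CA & !iso0$CB], 1)
})

test_that("isotopomer distributions normalize for all 20 residue types", {
  schemes <- list(sch02, labeling_scheme(0.2), labeling_scheme(0.7, 0.02, 0.3, 0.95))
  for (aa in fracnmr:::AA3) {
    for (sch in schemes) {
      iso <- enumerate_isotopomers(aa, sch)
      expect_equal(sum(iso$prob), 1, tolerance = 1e-12,
                   info = paste(aa, sch$f_labeled))
      expect_true(all(iso$prob >= 0))
    }
  }
})

test_that("joint and conditional probabilities match the enumeration oracle", {
  sch <- labeling_scheme(0.2)   # defaults: nat abund, scramble, purity all on
  for (aa in fracnmr:::AA3) {
    bonds <- carbon_bonds(aa)
    for (k in seq_len(nrow(bonds))) {
      b <- c(bonds$atom1[k], bonds$atom2[k])
      pj <- p_joint_label(aa, b, sch)
      expect_equal(pj, enum_joint(aa, b[1], b[2], sch), tolerance = 1e-12,
                   info = paste(aa, b[1], b[2]))
      cond <- conditional_partner_label(aa, b[1], b[2], sch)
      expect_equal(cond, enum_joint(aa, b[1], b[2], sch) /
                           enum_marginal(aa, b[1], sch),
                   tolerance = 1e-12, info = paste(aa, b[1], b[2]))
      # joint never exceeds either marginal
      expect_lte(pj, enum_marginal(aa, b[1], sch) + 1e-12)
      expect_lte(pj, enum_marginal(aa, b[2], sch) + 1e-12)
    }
  }
})

test_that("across-precursor CA-CB bond carries f^2, intact bond carries f", {
  expect_equal(p_joint_label("VAL", c("CA", "CB"), sch02), 0.04)
  expect_equal(p_joint_label("ALA", c("CA", "CB"), sch02), 0.20)
  expect_equal(p_joint_label("LEU", c("CA", "CB"), sch02), 0.04)
  expect_equal(p_joint_label("ILE", c("CA", "CB"), sch02), 0.04)
  # conditionals
  expect_equal(conditional_partner_label("ALA", "CA", "CB", sch02), 1.0)
  expect_equal(conditional_partner_label("VAL", "CA", "CB", sch02), 0.2)
  # natural-abundance floor: independence at f = 0
  expect_equal(
    conditional_partner_label("ALA", "CA", "CB",
                              labeling_scheme(0, nat_abund = 0.011)),
    0.011)
  # uniform labeling saturates every bond
  expect_equal(
    p_joint_label("TRP", c("CZ3", "CH2"),
                  labeling_scheme(1, nat_abund = 0, isotopic_purity = 1)),
    1.0)
})

test_that("p_joint_label is monotone in f_labeled for every residue bond", {
  fs <- seq(0, 1, by = 0.25)
  for (aa in c("ALA", "VAL", "GLU", "LYS", "TRP", "HIS")) {
    bonds <- carbon_bonds(aa)
    for (k in seq_len(nrow(bonds))) {
      p <- vapply(fs, function(f) {
        p_joint_label(aa, c(bonds$atom1[k], bonds$atom2[k]),
                      labeling_scheme(f))
      }, numeric(1))
      expect_true(all(diff(p) >= -1e-12),
                  info = paste(aa, bonds$atom1[k], bonds$atom2[k]))
    }
  }
})

test_that("scramble interpolates TCA bonds between intact and independent", {
  f <- 0.2
  p0 <- p_joint_label("GLU", c("CA", "CB"),
                      labeling_scheme(f, 0, scramble = 0, isotopic_purity = 1))
  p1 <- p_joint_label("GLU", c("CA", "CB"),
                      labeling_scheme(f, 0, scramble = 1, isotopic_purity = 1))
  ph <- p_joint_label("GLU", c("CA", "CB"),
                      labeling_scheme(f, 0, scramble = 0.5, isotopic_purity = 1))
  expect_equal(p0, f)
  expect_equal(p1, f^2)
  expect_equal(ph, (p0 + p1) / 2)
  # non-TCA bonds are unaffected by scramble
  expect_equal(
    p_joint_label("ALA", c("CA", "CB"),
                  labeling_scheme(f, 0, scramble = 1, isotopic_purity = 1)),
    f)
})

test_that("bond and residue validation raise typed errors", {
  expect_error(p_joint_label("ALA", c("CA", "CG"), sch02),
               class = "fracnmr_unknown_bond")
  expect_error(enumerate_isotopomers("XYZ", sch02),
               class = "fracnmr_unknown_residue")
  expect_error(conditional_partner_label("ALA", "CA", "CB",
                                         labeling_scheme(0, nat_abund = 0)),
               class = "fracnmr_undefined_conditional")
  expect_error(labeling_scheme(1.2), class = "fracnmr_invalid_scheme")
})

test_that("pathway map invariants hold", {
  map <- pathway_map()
  # Gly has no CB
  expect_false("CB" %in% residue_sites("GLY")$atom)
  for (aa in c("ALA", "PHE", "TYR", "HIS", "SER", "CYS")) {
    expect_true(is_intact_bond(aa, "CA", "CB"), info = aa)
  }
  for (aa in c("VAL", "LEU", "ILE")) {
    expect_false(is_intact_bond(aa, "CA", "CB"), info = aa)
  }
})

test_that("predicted CB/CA ratios separate the three groups at f = 0.2", {
  tab <- predict_cbca_table(labeling_scheme(0.2))
  hi <- tab$ratio[tab$group == "intact-high"]
  mid <- tab$ratio[tab$group == "intermediate-TCA"]
  lo <- tab$ratio[tab$group == "broken-low"]
  expect_gt(min(hi), max(mid))
  expect_gt(min(mid), max(lo))
  # intact group in the observed band, broken group near 0.1
  expect_true(all(hi >= 0.75 & hi <= 0.90))
  expect_equal(mean(lo), 0.1, tolerance = 0.05)
})

test_that("predict_cbca_ratio special cases", {
  # broken/intact ratio equals f when attenuation is switched off
  r_val <- predict_cbca_ratio("VAL", sch02, attenuation = 1)
  r_ala <- predict_cbca_ratio("ALA", sch02, attenuation = 1)
  expect_equal(r_val / r_ala, 0.2)
  # natural abundance floor
  expect_equal(
    predict_cbca_ratio("ALA", labeling_scheme(0, nat_abund = 0.011),
                       attenuation = 1),
    0.011)
  expect_error(predict_cbca_ratio("GLY", sch02),
               class = "fracnmr_excluded_residue")
  expect_error(predict_cbca_ratio("PRO", sch02),
               class = "fracnmr_excluded_residue")
})

test_that("methyl multiplets follow the pro-R intact / pro-S broken rule", {
  for (aa in c("VAL", "LEU")) {
    mr <- methyl_multiplet(aa, "pro-R", sch02)
    ms <- methyl_multiplet(aa, "pro-S", sch02)
    expect_equal(unname(mr["doublet"]), 1.0, info = aa)
    expect_equal(unname(ms["doublet"]), 0.2, info = aa)
    expect_equal(sum(mr), 1)
    expect_equal(sum(ms), 1)
  }
  uni <- labeling_scheme(1, isotopic_purity = 1)
  expect_equal(unname(methyl_multiplet("LEU", "pro-R", uni)["doublet"]), 1.0)
  expect_error(methyl_multiplet("ALA", "pro-R", sch02),
               class = "fracnmr_excluded_residue")
})

test_that("classify_group covers all 20 types", {
  expect_equal(classify_group(c("PHE", "TYR", "ALA", "HIS")),
               rep("intact-high", 4))
  expect_equal(classify_group(c("VAL", "LEU", "ILE")), rep("broken-low", 3))
  expect_equal(classify_group(c("GLY", "PRO")), rep("excluded", 2))
  expect_equal(classify_group("GLU"), "intermediate-TCA")
  expect_equal(classify_group("MET"), "intermediate-TCA")
})
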