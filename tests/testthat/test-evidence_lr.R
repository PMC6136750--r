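test_that("qualitative_lr evaluates the odds-power formula", {
  expect_equal(qualitative_lr(0.99, 1), 99)
  expect_equal(qualitative_lr(0.5, 1), 1)
  expect_equal(round(qualitative_lr(0.05, 0.5), 4), 0.2294)
  expect_error(qualitative_lr(1, 1), "p_cut")
  expect_error(qualitative_lr(0.5, 0), "p_frac")
})

test_that("qualitative_lr is monotone and satisfies the odds symmetry", {
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(qualitative_lr(p, 1)) > 0))
  fr <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(qualitative_lr(0.9, fr)) > 0))
  for (pc in p)
    expect_equal(qualitative_lr(pc, 1) * qualitative_lr(1 - pc, 1), 1,
                 tolerance = 1e-12)
})

test_that("level codes map to the graded likelihood ratios", {
  expect_equal(round(level_lr(c("P-1", "P-4", "LP-1", "LP-4",
                                "LB-1", "LB-2", "B-1")), 4),
               c(99, 3.1543, 19, 2.0878, 0.0526, 0.2294, 0.0010))
  expect_error(level_lr("P-9"), "unknown evidence level")
  # four supporting-strength items equal one standalone item
  expect_equal(prod(rep(level_lr("P-4"), 4)), level_lr("P-1"),
               tolerance = 1e-9)
  expect_equal(prod(rep(level_lr("LB-2"), 2)), level_lr("LB-1"),
               tolerance = 1e-9)
})

test_that("correlated LR combination keeps the stronger same-direction item", {
  expect_equal(combine_correlated_lr(99, 19), 99)
  expect_equal(combine_correlated_lr(1, 1), 1)
  expect_equal(combine_correlated_lr(0.05, 19), 0.95)
  expect_error(combine_correlated_lr(-1, 2), "positive")
  # commutative + brute-force case analysis on random pairs
  set.seed(7)
  l1 <- exp(rnorm(10000)); l2 <- exp(rnorm(10000))
  got <- combine_correlated_lr(l1, l2)
  expect_equal(got, combine_correlated_lr(l2, l1))
  oracle <- mapply(function(a, b) {
    if (a > 1 && b > 1) max(a, b)
    else if (a < 1 && b < 1) min(a, b)
    else a * b
  }, l1, l2)
  expect_equal(got, oracle)
})

test_that("total_lr multiplies the 7 categories and flags empty profiles", {
  empty <- evidence_profile()
  expect_equal(as.numeric(total_lr(empty)), 1)
  expect_true(attr(total_lr(empty), "no_evidence"))
  one <- evidence_profile(FAA = 99)
  expect_equal(as.numeric(total_lr(one)), 99)
  expect_false(attr(total_lr(one), "no_evidence"))
  two <- evidence_profile(FAA = 19, COC = 0.0526)
  expect_equal(round(as.numeric(total_lr(two)), 4), 0.9994)
  # a single non-unit entry is returned exactly
  for (cat in evidence_categories()) {
    prof <- evidence_profile()
    prof[cat] <- 3.7
    expect_equal(as.numeric(total_lr(prof)), 3.7)
  }
  expect_error(evidence_profile(XXX = 2), "unknown evidence categories")
})

test_that("hotspot indicator requires another pathogenic variant at the residue", {
  panel <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v5"),
    gene = c("G1", "G1", "G1", "G2", "G1"),
    residue = c(175, 175, 20, 175, NA),
    consensus_class = c("VUS", "pathogenic", "benign", "benign", "VUS"),
    stringsAsFactors = FALSE)
  hs <- hotspot_indicator(panel)
  expect_true(hs[1])            # shares residue 175 with pathogenic v2
  expect_false(hs[2])           # no *other* pathogenic variant there
  expect_false(hs[3])           # no same-residue neighbour
  expect_false(hs[4])           # same residue but different gene
  expect_true(is.na(hs[5]))     # residue unknown -> indicator undefined
})

test_that("evidence profiles assemble from long tables and hotspot evidence", {
  ev <- data.frame(variant_id = c("v1", "v1", "v2", "v2"),
                   category = c("FAA", "FAA", "CSG", "COC"),
                   level_code = c("LP-1", "P-1", "LB-1", NA),
                   lr_value = c(NA, NA, NA, 4.2),
                   stringsAsFactors = FALSE)
  prof <- build_evidence_profiles(ev, c("v1", "v2", "v3"))
  expect_equal(prof$FAA, c(99, 1, 1))       # correlated fold keeps max
  expect_equal(round(prof$CSG, 4), c(1, 0.0526, 1))
  expect_equal(prof$COC, c(1, 4.2, 1))
  expect_equal(prof$STR, c(1, 1, 1))
  panel <- data.frame(variant_id = c("v1", "v2", "v3"), gene = "G",
                      residue = c(7, 7, 9),
                      consensus_class = c("pathogenic", "VUS", "VUS"),
                      stringsAsFactors = FALSE)
  prof2 <- add_hotspot_evidence(prof, panel, level = "P-4")
  expect_equal(round(prof2$FUN, 4), c(1, 3.1543, 1))
})
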