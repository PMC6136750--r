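test_that("consensus class follows the majority / tie-break / exclusion rules", {
  expect_equal(derive_consensus_class(3, 0, 1), "positive")
  expect_equal(derive_consensus_class(0, 0, 5), "excluded")
  expect_equal(derive_consensus_class(2, 2, 0), "excluded")
  expect_equal(derive_consensus_class(1, 0, 1), "positive")
  expect_equal(derive_consensus_class(0, 1, 1), "negative")
  expect_error(derive_consensus_class(0, 0, 0), "positive")
})

test_that("consensus derivation is exhaustive over all count triples <= 5", {
  grid <- expand.grid(p = 0:5, n = 0:5, v = 0:5)
  grid <- grid[rowSums(grid) > 0, ]
  got <- derive_consensus_class(grid$p, grid$n, grid$v)
  expect_true(all(got %in% c("positive", "negative", "excluded")))
  # brute-force oracle restated independently from the published hierarchy
  oracle <- apply(grid, 1, function(r) {
    p <- r["p"]; n <- r["n"]; v <- r["v"]
    if (p > max(n, v)) return("positive")
    if (n > max(p, v)) return("negative")
    if (p == v && n == 0 && p > 0) return("positive")
    if (n == v && p == 0 && n > 0) return("negative")
    "excluded"
  })
  expect_equal(got, unname(oracle))
})

test_that("unit scaling matches the published affine constants and clamps", {
  expect_equal(unname(unit_scale_scores(c(gra = 220))), 1)
  expect_equal(unname(unit_scale_scores(c(gra = 5))), 0)
  expect_equal(unname(unit_scale_scores(c(ger = -12.3))), 0)
  expect_equal(unname(unit_scale_scores(c(sif = 0))), 1)
  expect_equal(unname(unit_scale_scores(c(sif = 1))), 0)
  # pass-through predictors unchanged
  expect_equal(unname(unit_scale_scores(c(mup = 0.37))), 0.37)
  # clamping keeps the unit range for out-of-catalogue raw values
  expect_equal(unname(unit_scale_scores(c(gra = 500))), 1)
  expect_equal(unname(unit_scale_scores(c(ger = -99))), 0)
  expect_error(unit_scale_scores(c(nope = 1)), "unknown predictor")
})

test_that("scaling is affine and invertible for in-range values", {
  spec <- default_scaling_spec()
  set.seed(1)
  for (i in seq_len(nrow(spec))) {
    raw <- runif(20, spec$x_min[i], spec$x_max[i])
    v <- setNames(raw, rep(spec$predictor[i], 20))
    back <- unscale_scores(unit_scale_scores(v, spec), spec)
    expect_equal(unname(back), raw, tolerance = 1e-12)
  }
})

test_that("kNN imputation fills holes with neighbour means and is idempotent", {
  M <- matrix(c(0.1, 0.90,
                0.4, 0.21,
                0.6, 0.19,
                NA,  0.20), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  out <- impute_missing_knn(M, k = 2)
  # nearest two rows (shared column b) are rows 2 and 3 -> mean(0.4, 0.6)
  expect_equal(unname(out[4, "a"]), 0.5)
  expect_equal(out[!is.na(M)], M[!is.na(M)])
  expect_equal(impute_missing_knn(out, k = 2), out)
  # identity on complete matrices
  expect_identical(impute_missing_knn(out[1:3, ], k = 2), out[1:3, ])
  # symmetry: all rows identical except the hole
  S <- matrix(0.3, 5, 2); S[5, 1] <- NA
  expect_equal(impute_missing_knn(S, k = 3)[5, 1], 0.3)
  # a predictor missing everywhere is an error naming it
  E <- cbind(ok = c(1, 2), gone = c(NA_real_, NA_real_))
  expect_error(impute_missing_knn(E), "gone")
})

test_that("normalize_panel derives classes, scales, imputes and sets y", {
  panel <- make_toy_panel(seed = 3)
  sc <- intersect(score_names(), names(panel))
  panel[[sc[1]]][1] <- NA
  out <- normalize_panel(panel, spec = NULL, k = 5)
  expect_false(anyNA(out[, sc]))
  expect_equal(out$y, class_to_y(out$consensus_class))
  # submitter-count route
  p2 <- panel[, setdiff(names(panel), "consensus_class")]
  p2$n_positive <- 2; p2$n_negative <- 0; p2$n_vus <- 1
  out2 <- normalize_panel(p2, spec = NULL, k = 5)
  expect_true(all(out2$consensus_class == "VLP"))
})

test_that("the shipped example panel normalizes end to end", {
  f <- system.file("extdata", "example_panel.csv", package = "bayesvar")
  panel <- read_variant_table(f)
  out <- normalize_panel(panel, k = 3)
  sc <- intersect(score_names(), names(out))
  expect_false(anyNA(out[, sc]))
  expect_true(all(out[, sc] >= 0 & out[, sc] <= 1))
  # conflicting submitters excluded, tie-with-VUS kept
  expect_equal(out$consensus_class[out$variant_id == "EX0008"], "excluded")
  expect_equal(out$y[out$variant_id == "EX0006"], 1L)
  # the shipped panel has a usable hotspot pair at TP53 residue 175
  expect_false(anyNA(hotspot_indicator(out)))
})

test_that("variant tables round-trip through CSV with column mapping", {
  panel <- make_toy_panel(seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_variant_table(panel, f)
  back <- read_variant_table(f)
  expect_equal(back$variant_id, panel$variant_id)
  expect_equal(back$gra, panel$gra, tolerance = 1e-12)
  # mapped column names
  f2 <- withr::local_tempfile(fileext = ".csv")
  renamed <- panel
  names(renamed)[names(renamed) == "gene"] <- "Gene_Symbol"
  write.csv(renamed, f2, row.names = FALSE)
  back2 <- read_variant_table(f2, column_map = c(gene = "Gene_Symbol"))
  expect_equal(back2$gene, panel$gene)
  expect_error(read_variant_table(f2, column_map = c(gene = "NoSuch")),
               "NoSuch")
})
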