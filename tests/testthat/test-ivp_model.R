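score_frame <- function(m) {
  sc <- score_names()
  df <- as.data.frame(matrix(rep(m, each = 1), nrow = nrow(m)))
  names(df) <- sc[seq_len(ncol(m))]
  df
}

test_that("gene_distance is the mean pairwise Euclidean distance", {
  sc <- score_names()
  mk <- function(gene, cls, rows) {
    df <- as.data.frame(rows); names(df) <- sc[seq_len(ncol(rows))]
    for (p in setdiff(sc, names(df))) df[[p]] <- 0
    cbind(data.frame(variant_id = paste0(gene, seq_len(nrow(rows))),
                     gene = gene, residue = 1, consensus_class = cls,
                     stringsAsFactors = FALSE), df)
  }
  pA <- rbind(mk("A", "benign", matrix(0, 1, 2)),
              mk("B", "benign", matrix(0, 1, 2)))
  expect_equal(gene_distance(pA, "A", "B"), 0)
  pB <- rbind(mk("A", "benign", matrix(c(0, 0), 1, 2)),
              mk("B", "benign", matrix(c(1, 0), 1, 2)))
  expect_equal(gene_distance(pB, "A", "B"), 1)
  # 2x2 pairs vs brute force, and symmetry
  set.seed(2)
  GA <- matrix(runif(32), 2, 16); GB <- matrix(runif(32), 2, 16)
  pC <- rbind(mk("A", "benign", GA), mk("B", "benign", GB))
  brute <- mean(sapply(1:2, function(i)
    sapply(1:2, function(j) sqrt(sum((GA[i, ] - GB[j, ])^2)))))
  expect_equal(gene_distance(pC, "A", "B"), brute)
  expect_equal(gene_distance(pC, "A", "B"), gene_distance(pC, "B", "A"))
  expect_error(gene_distance(pC, "A", "Z"), "no variants")
})

test_that("training sets keep their own variants and skip expansion when full", {
  panel <- make_toy_panel(c(A = 30, B = 30, C = 30), seed = 5)
  ts <- build_training_set("A", panel)
  expect_s3_class(ts, "training_set")
  expect_equal(nrow(ts$borrow_log), 0)
  expect_setequal(ts$data$variant_id,
                  panel$variant_id[panel$gene == "A" & !is.na(class_to_y(panel$consensus_class))])
  expect_true(ts$n_negative >= 5 && ts$n_positive >= 5)
})

test_that("data expansion borrows the deficient class from the nearest donor", {
  sc <- score_names()
  mk <- function(gene, cls, base) {
    n <- length(cls)
    df <- as.data.frame(matrix(base, n, 16, byrow = TRUE) +
                          matrix(runif(n * 16, 0, 0.01), n, 16))
    names(df) <- sc
    cbind(data.frame(variant_id = paste0(gene, seq_len(n)), gene = gene,
                     residue = seq_len(n), consensus_class = cls,
                     stringsAsFactors = FALSE), df)
  }
  set.seed(11)
  # G: 6 benign + 2 pathogenic (n_pos = 2 < 5); donors: NEAR at distance
  # ~0.1 with positives, FAR at ~2 with positives
  G <- mk("G", c(rep("benign", 6), rep("pathogenic", 2)), rep(0.5, 16))
  NEAR <- mk("NEAR", rep("pathogenic", 8), rep(0.5 + 0.1 / 4, 16))
  FAR <- mk("FAR", rep("pathogenic", 8), rep(0.9, 16))
  panel <- rbind(G, NEAR, FAR)
  ts <- build_training_set("G", panel)
  expect_true(all(G$variant_id %in% ts$data$variant_id))
  expect_true(ts$n_positive >= 5 && ts$n_negative >= 5)
  expect_true(all(ts$borrow_log$donor_gene == "NEAR"))
  # pathogenic donors count 1 each: need 3 to lift n_pos from 2 to >= 5
  expect_equal(nrow(ts$borrow_log), 3)
  expect_true(all(ts$borrow_log$consensus_class == "pathogenic"))
  # VLP donors count 0.5: 6 are needed
  NEARV <- mk("NEAR", rep("VLP", 8), rep(0.5 + 0.1 / 4, 16))
  ts2 <- build_training_set("G", rbind(G, NEARV, FAR))
  expect_equal(nrow(ts2$borrow_log), 6)
  # default merge order is descending between-variant distance
  expect_true(all(diff(ts2$borrow_log$distance) <= 1e-12))
  asc <- build_training_set("G", rbind(G, NEARV, FAR), order = "ascending")
  expect_true(all(diff(asc$borrow_log$distance) >= -1e-12))
  # minima unreachable -> diagnosable error
  expect_error(build_training_set("G", rbind(G, NEARV[1:2, ])),
               "insufficient training data")
})

test_that("stepwise selection recovers the informative predictor", {
  set.seed(5)
  n <- 200
  X <- matrix(runif(n * 16), n, 16, dimnames = list(NULL, score_names()))
  y <- rbinom(n, 1, plogis(-3 + 6 * X[, "mup"]))
  df <- as.data.frame(X)
  df$consensus_class <- ifelse(y == 1, "pathogenic", "benign")
  ts <- list(gene = "g", data = df, borrow_log = data.frame())
  sel <- select_predictors(ts, seed = 2)
  expect_true("mup" %in% sel)
  expect_lte(length(sel), 4)
  # identical duplicated predictors: only one of the pair retained
  df2 <- df; df2$ger <- df2$mup
  sel2 <- select_predictors(list(gene = "g", data = df2,
                                 borrow_log = data.frame()), seed = 2)
  expect_equal(sum(c("mup", "ger") %in% sel2), 1)
})

test_that("PG fit recovers coefficients and is seed-deterministic", {
  set.seed(3)
  n <- 2000
  x <- runif(n)
  y <- rbinom(n, 1, plogis(0 + 2 * x))
  df <- data.frame(mup = x,
                   consensus_class = ifelse(y == 1, "VLP", "VLB"))
  ts <- list(gene = "g", data = df, borrow_log = data.frame())
  m <- fit_pg_logistic(ts, "mup", n_samples = 500, burn_in = 1000, seed = 9)
  expect_equal(dim(m$coefficients), c(500, 2))
  expect_lt(abs(mean(m$coefficients[, "mup"]) - 2), 0.3)
  m2 <- fit_pg_logistic(ts, "mup", n_samples = 500, burn_in = 1000, seed = 9)
  expect_identical(m$coefficients, m2$coefficients)
  # degenerate responses refuse to fit
  dfa <- df; dfa$consensus_class <- "VLP"
  expect_error(fit_pg_logistic(list(gene = "g", data = dfa), "mup"),
               "all")
})

test_that("intercept-only-like fit on balanced data centres at one half", {
  df <- data.frame(mup = rep(0, 60),
                   consensus_class = rep(c("VLB", "VLP"), 30))
  ts <- list(gene = "g", data = df, borrow_log = data.frame())
  m <- fit_pg_logistic(ts, "mup", n_samples = 500, burn_in = 500, seed = 4)
  p <- plogis(m$coefficients[, 1])
  expect_lt(abs(mean(p) - 0.5), 0.05)
})

test_that("predict_distribution is the inverse-logit of each draw", {
  m <- structure(list(gene = "g", predictors = "mup",
                      coefficients = matrix(c(0, 0, 0, 2), 2, 2,
                                            dimnames = list(NULL, c("(Intercept)", "mup")))),
                 class = "ivp_model")
  d <- predict_distribution(m, c(mup = 1))
  expect_equal(d$samples, c(0.5, plogis(2)))
  expect_equal(round(d$samples[2], 4), 0.8808)
  expect_error(predict_distribution(m, c(gra = 1)), "missing predictor")
  expect_error(predict_distribution(m, c(mup = NA)), "NA")
  # samples stay inside (0,1) for wild inputs
  set.seed(1)
  m$coefficients <- matrix(rnorm(400, sd = 20), 200, 2,
                           dimnames = list(NULL, c("(Intercept)", "mup")))
  d2 <- predict_distribution(m, c(mup = 3))
  expect_true(all(d2$samples > 0 & d2$samples < 1))
})

test_that("predictions are monotone in an all-positive coefficient", {
  set.seed(6)
  B <- cbind(rnorm(200), abs(rnorm(200)) + 0.1)
  colnames(B) <- c("(Intercept)", "mup")
  m <- structure(list(gene = "g", predictors = "mup", coefficients = B),
                 class = "ivp_model")
  lo <- predict_distribution(m, c(mup = 0.2))
  hi <- predict_distribution(m, c(mup = 0.8))
  expect_true(all(hi$samples > lo$samples))
})

test_that("posterior intervals cover true coefficients (PG sampler calibration)", {
  set.seed(12)
  cov <- replicate(50, {
    x <- rnorm(200)
    b <- c(-0.5, 1.5)
    y <- rbinom(200, 1, plogis(b[1] + b[2] * x))
    B <- bayesvar:::.pg_gibbs(cbind(1, x), y, 100, 500L, 500L)
    c(b[1] >= quantile(B[, 1], 0.025) & b[1] <= quantile(B[, 1], 0.975),
      b[2] >= quantile(B[, 2], 0.025) & b[2] <= quantile(B[, 2], 0.975))
  })
  expect_gte(mean(cov[1, ]), 0.85)
  expect_gte(mean(cov[2, ]), 0.85)
})
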