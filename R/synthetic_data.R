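#' Configuration for the synthetic multigene panel generator
#'
#' The generator emulates the structure of a hereditary-cancer multigene
#' panel: ~10 genes of very uneven size (including genes too sparse to
#' train on alone, which exercises data expansion), a benign-heavy class
#' mixture, class-shifted Beta-distributed unit-scale scores with a small
#' informative predictor subset per gene, missing-at-random score cells,
#' and sparse category-wise qualitative evidence.
#'
#' @param n_genes Number of genes.
#' @param gene_sizes Class-known variants per gene.
#' @param class_mix Proportions of benign / VLB / VLP / pathogenic
#'   (must sum to 1).
#' @param n_informative Range of informative predictors per gene.
#' @param mean_benign,mean_pathogenic Beta means of informative scores by
#'   class side.
#' @param concentration Beta concentration of informative scores.
#' @param missing_rate Probability a score cell is missing.
#' @param evidence_avail Per-category probability that a variant has an
#'   evidence item.
#' @param evidence_fidelity Probability an available item points in the
#'   variant's true direction.
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 10,
                              gene_sizes = c(120, 100, 85, 70, 55, 45, 35, 25, 12, 8),
                              class_mix = c(benign = 0.32, VLB = 0.32,
                                            VLP = 0.16, pathogenic = 0.20),
                              n_informative = c(2, 4),
                              mean_benign = 0.25, mean_pathogenic = 0.75,
                              concentration = 10,
                              missing_rate = 0.05,
                              evidence_avail = c(FAA = 0.5, COC = 0.5,
                                                 CSG = 0.4, FHX = 0.5,
                                                 FUN = 0.4, STR = 0.2,
                                                 OTH = 0.2),
                              evidence_fidelity = 0.95,
                              seed = 1) {
  if (length(gene_sizes) != n_genes)
    stop("gene_sizes must have length n_genes")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (missing_rate < 0 || missing_rate > 1 ||
      any(evidence_avail < 0) || any(evidence_avail > 1) ||
      evidence_fidelity < 0 || evidence_fidelity > 1)
    stop("rates must lie in [0, 1]")
  if (!all(names(class_mix) == c("benign", "VLB", "VLP", "pathogenic")))
    stop("class_mix must be named benign, VLB, VLP, pathogenic")
  if (!all(evidence_categories() %in% names(evidence_avail)))
    stop("evidence_avail must cover the 7 categories")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multigene variant panel
#'
#' Scores are already on the unit scale (class-conditional Beta draws),
#' so downstream use skips raw-score scaling. Ground-truth generator
#' parameters are returned in a sidecar that the pipeline never reads.
#'
#' @param config A [simulation_config()].
#' @return List with `panel` (variant table in the standard dialect, with
#'   `NA` score cells at the configured missingness) and `truth`
#'   (per-gene informative predictor sets and Beta parameters).
#' @export
simulate_panel <- function(config = simulation_config()) {
  set.seed(config$seed)
  sc <- score_names()
  genes <- sprintf("GENE%02d", seq_len(config$n_genes))
  truth <- list(genes = list(), config = config)
  rows <- list()
  vid <- 0L
  for (g in seq_len(config$n_genes)) {
    n <- config$gene_sizes[g]
    k_inf <- sample(seq(config$n_informative[1], config$n_informative[2]), 1)
    informative <- sample(sc, k_inf)
    cls <- sample(names(config$class_mix), n, replace = TRUE,
                  prob = config$class_mix)
    y <- class_to_y(cls)
    S <- matrix(NA_real_, n, length(sc), dimnames = list(NULL, sc))
    for (p in sc) {
      if (p %in% informative) {
        mu <- ifelse(y == 1, config$mean_pathogenic, config$mean_benign)
        phi <- config$concentration
      } else {
        mu <- rep(0.5, n)
        phi <- 4
      }
      S[, p] <- rbeta(n, mu * phi, (1 - mu) * phi)
    }
    rows[[g]] <- data.frame(
      variant_id = sprintf("V%05d", vid + seq_len(n)),
      gene = genes[g],
      residue = sample(1:400, n, replace = TRUE),
      consensus_class = cls,
      S, stringsAsFactors = FALSE)
    vid <- vid + n
    truth$genes[[genes[g]]] <- list(informative = informative,
                                    mean_benign = config$mean_benign,
                                    mean_pathogenic = config$mean_pathogenic)
  }
  panel <- do.call(rbind, rows)
  if (config$missing_rate > 0) {
    m <- matrix(runif(nrow(panel) * length(sc)) < config$missing_rate,
                nrow(panel), length(sc))
    for (j in seq_along(sc)) panel[[sc[j]]][m[, j]] <- NA_real_
  }
  list(panel = panel, truth = truth)
}

#' Simulate a long-format qualitative evidence table
#'
#' Each variant draws, per evidence category, an item with the configured
#' availability. Items point in the variant's true direction with
#' probability `evidence_fidelity` and in the wrong direction otherwise;
#' pathogenic-direction items sample levels `P-1`, `P-4`, `LP-1`, `LP-4`
#' and benign-direction items `LB-1`, `LB-2`, `B-1`.
#'
#' @param panel Simulated panel (needs `variant_id` and
#'   `consensus_class`).
#' @param config A [simulation_config()].
#' @param seed Seed (defaults to `config$seed + 1` so panel and evidence
#'   draws are decoupled).
#' @return Long data.frame with `variant_id`, `category`, `level_code`.
#' @export
simulate_evidence <- function(panel, config = simulation_config(),
                              seed = config$seed + 1) {
  set.seed(seed)
  y <- class_to_y(panel$consensus_class)
  path_levels <- c("P-1", "P-4", "LP-1", "LP-4")
  ben_levels <- c("LB-1", "LB-2", "B-1")
  out <- list()
  for (cat in evidence_categories()) {
    avail <- runif(nrow(panel)) < config$evidence_avail[[cat]]
    idx <- which(avail & !is.na(y))
    if (!length(idx)) next
    correct <- runif(length(idx)) < config$evidence_fidelity
    dir_path <- (y[idx] == 1) == correct
    lev <- character(length(idx))
    lev[dir_path] <- sample(path_levels, sum(dir_path), replace = TRUE)
    lev[!dir_path] <- sample(ben_levels, sum(!dir_path), replace = TRUE)
    out[[cat]] <- data.frame(variant_id = panel$variant_id[idx],
                             category = cat, level_code = lev,
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(variant_id = character(), category = character(),
                      level_code = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$variant_id, panel$variant_id), res$category), ]
}
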