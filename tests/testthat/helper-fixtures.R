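# Shared fixtures.
#
# `benchmark_counts()` is a golden fixture: confusion counts and derived
# performance statistics, as published, for 23 in silico predictor models
# (evaluated in 1,161 variants: 747 negatives, 414 positives) and 8
# multifactorial rows with their own evaluated totals. VUS splits are
# recovered from the class totals.

benchmark_insilico_counts <- function() {
  txt <- "method,TP,TN,FP,FN,VUS,sen,spe,ppv,npv,acc,p_vus
MutPred,101,496,1,17,546,0.244,0.664,0.990,0.967,0.971,0.470
phyloP_vertebrate,75,438,6,15,627,0.181,0.586,0.926,0.967,0.961,0.540
MutationAssessor,71,315,0,9,766,0.171,0.422,1.000,0.972,0.977,0.660
FATHMM,99,276,2,6,778,0.239,0.369,0.980,0.979,0.979,0.670
AGVGD,217,0,18,0,926,0.524,0.000,0.923,NA,0.923,0.798
Polyphen2_HVAR,0,414,0,21,726,0.000,0.554,NA,0.952,0.952,0.625
Siphy,0,277,0,5,879,0.000,0.371,NA,0.982,0.982,0.757
LRT,0,291,0,8,862,0.000,0.390,NA,0.973,0.973,0.742
GERP,0,329,0,12,820,0.000,0.440,NA,0.965,0.965,0.706
Polyphen2_HDIV,0,404,0,26,731,0.000,0.541,NA,0.940,0.940,0.630
SIFT,0,315,0,12,834,0.000,0.422,NA,0.963,0.963,0.718
PROVEAN,50,102,1,2,1006,0.121,0.137,0.980,0.981,0.981,0.866
phastCons_mammalian,0,361,0,14,786,0.000,0.483,NA,0.963,0.963,0.677
phastCons_vertebrate,0,455,0,10,696,0.000,0.609,NA,0.978,0.978,0.599
phyloP_mammalian,0,213,0,5,943,0.000,0.285,NA,0.977,0.977,0.812
Grantham,0,0,0,0,1161,0.000,0.000,NA,NA,NA,1.000
IVP,148,489,0,4,520,0.357,0.655,1.000,0.992,0.994,0.448
REVEL,90,475,4,20,572,0.217,0.636,0.957,0.960,0.959,0.493
MetaSVM,0,518,0,16,627,0.000,0.693,NA,0.970,0.970,0.540
Eigen,22,497,0,4,638,0.053,0.665,1.000,0.992,0.992,0.550
Eigen_PC,12,506,0,5,638,0.029,0.677,1.000,0.990,0.990,0.550
CADD,61,330,17,3,750,0.147,0.442,0.782,0.991,0.951,0.646
MutationTaster,0,517,0,13,631,0.000,0.692,NA,0.975,0.975,0.543"
  df <- read.csv(text = txt, stringsAsFactors = FALSE)
  df$n_neg <- 747
  df$n_pos <- 414
  df
}

benchmark_mvp_counts <- function() {
  txt <- "method,n_neg,n_pos,TP,TN,FP,FN,VUS,sen,spe,ppv,npv,acc,p_vus
all_any,686,330,263,519,2,0,232,0.797,0.757,0.992,1.000,0.997,0.228
all_lr10,372,226,210,358,2,0,28,0.929,0.962,0.991,1.000,0.996,0.047
all_lr100,223,74,74,223,0,0,0,1.000,1.000,1.000,1.000,1.000,0.000
all_lr1000,155,23,23,155,0,0,0,1.000,1.000,1.000,1.000,1.000,0.000
auto_any,618,255,95,287,2,0,489,0.373,0.464,0.979,1.000,0.995,0.560
auto_lr10,225,35,31,212,2,0,15,0.886,0.942,0.939,1.000,0.992,0.058
auto_lr100,174,8,8,174,0,0,0,1.000,1.000,1.000,1.000,1.000,0.000
auto_lr1000,107,0,0,107,0,0,0,NA,1.000,NA,1.000,1.000,0.000"
  read.csv(text = txt, stringsAsFactors = FALSE)
}

# confusion_summary from a benchmark row (VUS split from class totals)
row_to_confusion <- function(row) {
  confusion_summary(TP = row$TP, TN = row$TN, FP = row$FP, FN = row$FN,
                    VUS_pos = row$n_pos - row$TP - row$FN,
                    VUS_neg = row$n_neg - row$TN - row$FP)
}

# tiny deterministic panel in the standard dialect, unit-scale scores.
# Classes alternate benign/pathogenic within each gene so effective-count
# minima are predictable (a gene of size 2k holds k of each); the gene's
# informative scores are redrawn to match the reassigned classes.
make_toy_panel <- function(n_per_gene = c(A = 12, B = 10, C = 4), seed = 42) {
  cfg <- simulation_config(
    n_genes = length(n_per_gene), gene_sizes = unname(n_per_gene),
    missing_rate = 0, seed = seed)
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  panel$gene <- names(n_per_gene)[match(panel$gene, unique(panel$gene))]
  set.seed(seed + 1)
  for (g in unique(panel$gene)) {
    rows <- which(panel$gene == g)
    panel$consensus_class[rows] <- rep(c("benign", "pathogenic"),
                                       length.out = length(rows))
    y <- class_to_y(panel$consensus_class[rows])
    inf <- sim$truth$genes[[which(unique(panel$gene) == g)]]$informative
    for (p in inf) {
      mu <- ifelse(y == 1, cfg$mean_pathogenic, cfg$mean_benign)
      panel[[p]][rows] <- rbeta(length(rows), mu * cfg$concentration,
                                (1 - mu) * cfg$concentration)
    }
  }
  panel
}

# fast MCMC settings for unit tests (the sampler itself is exercised at
# full settings in the acceptance suite)
fast_config <- function(seed = 1) {
  run_config(seed = seed, burn_in = 500, n_samples = 500)
}
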