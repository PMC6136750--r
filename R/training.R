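#' Effective class counts of a set of variants
#'
#' Benign and pathogenic variants count 1, the "likely" tiers count 0.5:
#' `n_negative = n_benign + 0.5 n_VLB`, `n_positive = n_pathogenic +
#' 0.5 n_VLP`.
#'
#' @param consensus_class Character vector of five-tier class labels.
#' @return Named numeric vector `c(n_negative, n_positive)`.
#' @export
effective_counts <- function(consensus_class) {
  c(n_negative = sum(consensus_class == "benign") +
      0.5 * sum(consensus_class == "VLB"),
    n_positive = sum(consensus_class == "pathogenic") +
      0.5 * sum(consensus_class == "VLP"))
}

#' Mean between-gene variant distance
#'
#' Mean Euclidean distance, over all cross-gene variant pairs, of the
#' unit-scaled in silico score vectors. Symmetric in its gene arguments.
#'
#' @param panel Normalized panel (scaled, imputed scores).
#' @param gene_a,gene_b Gene symbols present in `panel$gene`.
#' @param scores Score column names (default the 16 standard predictors
#'   present in the panel).
#' @return Non-negative scalar.
#' @export
gene_distance <- function(panel, gene_a, gene_b,
                          scores = intersect(score_names(), names(panel))) {
  A <- as.matrix(panel[panel$gene == gene_a, scores, drop = FALSE])
  B <- as.matrix(panel[panel$gene == gene_b, scores, drop = FALSE])
  if (nrow(A) == 0 || nrow(B) == 0) stop("gene with no variants in panel")
  mean(cross_dist(A, B))
}

# pairwise Euclidean distances between rows of A and rows of B
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Build a gene-specific training set, borrowing from similar genes if sparse
#'
#' The training set for gene `G` starts as its own class-known variants.
#' If the effective counts miss the minima (`n_negative >= 5` and
#' `n_positive >= 5`), variants of the deficient side are borrowed from
#' donor genes taken in ascending order of mean between-gene distance;
#' within a donor, variants are merged one by one ordered by their mean
#' distance to `G`'s own variants (descending by default) until the
#' minima hold or the donor is exhausted.
#'
#' @param gene Gene symbol to train for.
#' @param panel Normalized panel; only rows with a defined binary `y` are
#'   used.
#' @param min_neg,min_pos Minimum effective counts (default 5 each).
#' @param order `"descending"` (most distant donor variants first, the
#'   stated procedure) or `"ascending"`.
#' @return Object of class `training_set`: list with `gene`, `data` (the
#'   member variant rows), `n_negative`, `n_positive` and `borrow_log`
#'   (data.frame of borrowed variants with their donor gene).
#' @export
build_training_set <- function(gene, panel, min_neg = 5, min_pos = 5,
                               order = c("descending", "ascending")) {
  order <- match.arg(order)
  sc <- intersect(score_names(), names(panel))
  known <- panel[!is.na(class_to_y(panel$consensus_class)), , drop = FALSE]
  own <- known[known$gene == gene, , drop = FALSE]
  if (nrow(own) == 0) stop("gene ", gene, " has no class-known variants")
  cnt <- effective_counts(own$consensus_class)
  if (sum(cnt) < min(min_neg, min_pos))
    stop("insufficient training data for gene ", gene,
         ": effective n_negative + n_positive = ", sum(cnt))
  acc <- own
  blog <- data.frame(variant_id = character(), donor_gene = character(),
                     consensus_class = character(), distance = numeric(),
                     stringsAsFactors = FALSE)
  if (cnt["n_negative"] >= min_neg && cnt["n_positive"] >= min_pos) {
    return(structure(list(gene = gene, data = acc,
                          n_negative = unname(cnt["n_negative"]),
                          n_positive = unname(cnt["n_positive"]),
                          borrow_log = blog),
                     class = "training_set"))
  }
  donors <- setdiff(unique(known$gene), gene)
  if (length(donors)) {
    dist_to_G <- vapply(donors, function(h) gene_distance(known, gene, h, sc),
                        numeric(1))
    donors <- donors[order(dist_to_G)]
  }
  own_scores <- as.matrix(own[, sc, drop = FALSE])
  for (h in donors) {
    if (cnt["n_negative"] >= min_neg && cnt["n_positive"] >= min_pos) break
    hv <- known[known$gene == h, , drop = FALSE]
    hdist <- rowMeans(cross_dist(as.matrix(hv[, sc, drop = FALSE]), own_scores))
    ord <- if (order == "descending") base::order(-hdist) else base::order(hdist)
    hv <- hv[ord, , drop = FALSE]
    hdist <- hdist[ord]
    for (r in seq_len(nrow(hv))) {
      need_neg <- cnt["n_negative"] < min_neg
      need_pos <- cnt["n_positive"] < min_pos
      if (!need_neg && !need_pos) break
      yv <- class_to_y(hv$consensus_class[r])
      if ((yv == 0 && need_neg) || (yv == 1 && need_pos)) {
        acc <- rbind(acc, hv[r, , drop = FALSE])
        blog <- rbind(blog, data.frame(variant_id = hv$variant_id[r],
                                       donor_gene = h,
                                       consensus_class = hv$consensus_class[r],
                                       distance = hdist[r],
                                       stringsAsFactors = FALSE))
        cnt <- effective_counts(acc$consensus_class)
      }
    }
  }
  if (cnt["n_negative"] < min_neg || cnt["n_positive"] < min_pos)
    stop("insufficient training data for gene ", gene,
         " even after data expansion (n_negative = ", cnt["n_negative"],
         ", n_positive = ", cnt["n_positive"], ")")
  structure(list(gene = gene, data = acc,
                 n_negative = unname(cnt["n_negative"]),
                 n_positive = unname(cnt["n_positive"]),
                 borrow_log = blog),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("Training set for gene", x$gene, "\n",
      nrow(x$data), "variants (effective n- =", x$n_negative,
      ", n+ =", x$n_positive, ");",
      nrow(x$borrow_log), "borrowed\n")
  invisible(x)
}
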