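#' Names of the 16 in silico predictor columns
#'
#' Short codes for the standalone in silico scores used by IVP models:
#' Grantham, GERP++, phastCons (vertebrate/mammalian), AGVGD, SIFT,
#' MutPred, SiPhy, LRT, phyloP (vertebrate/mammalian), PolyPhen-2
#' (HVAR/HDIV), MutationAssessor, PROVEAN and FATHMM.
#'
#' @return Character vector of length 16.
#' @export
score_names <- function() {
  c("gra", "ger", "pcv", "pcm", "agv", "sif", "mup", "sip",
    "lrt", "ppv", "ppm", "pov", "pod", "mua", "pro", "fat")
}

#' Default unit-scaling specification for the 16 in silico scores
#'
#' Each raw score is mapped affinely onto \[0, 1\] by
#' `(x_raw - x_min) / (x_max - x_min)`; predictors already on unit scale
#' pass through unchanged, and SIFT is flipped (`1 - SIFT`) so that larger
#' always means more deleterious. The constants are the published ranges
#' of each tool, e.g. Grantham on \[5, 220\] so `gra = (Grantham - 5)/215`
#' and GERP++ on \[-12.3, 6.2\] so `ger = (GERP++ + 12.3)/18.5`.
#'
#' @return A data.frame with columns `predictor`, `x_min`, `x_max`, `flip`.
#' @export
default_scaling_spec <- function() {
  data.frame(
    predictor = score_names(),
    x_min = c(5, -12.3, 0, 0, 0, 0, 0, 0, 0, -20, -13.3, 0, 0, -5.2, -14, -16.2),
    x_max = c(220, 6.2, 1, 1, 65, 1, 1, 38, 1, 10, 1.2, 1, 1, 6.5, 14, 10.7),
    flip  = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
              FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Derive a consensus class from multi-submitter counts
#'
#' Collapses per-submitter assertions into `positive`
#' (pathogenic/likely-pathogenic), `negative` (benign/likely-benign) or
#' `excluded`. A side wins outright when its count exceeds the maximum of
#' the other two; a tie with VUS is broken in favour of the asserted side
#' only when the opposite side has no submitters. Conflicting positive
#' and negative counts, or unanimous VUS, exclude the variant.
#'
#' @param n_positive,n_negative,n_vus Non-negative integer vectors of
#'   submitter counts (recycled to a common length).
#' @return Character vector in `{"positive", "negative", "excluded"}`.
#' @examples
#' derive_consensus_class(3, 0, 1)  # "positive"
#' derive_consensus_class(2, 2, 0)  # "excluded"
#' @export
derive_consensus_class <- function(n_positive, n_negative, n_vus) {
  n <- max(length(n_positive), length(n_negative), length(n_vus))
  n_positive <- rep_len(as.numeric(n_positive), n)
  n_negative <- rep_len(as.numeric(n_negative), n)
  n_vus <- rep_len(as.numeric(n_vus), n)
  counts <- cbind(n_positive, n_negative, n_vus)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("submitter counts must be non-negative integers")
  if (any(rowSums(counts) == 0))
    stop("at least one submitter count must be positive")
  out <- rep("excluded", n)
  out[n_positive > pmax(n_negative, n_vus)] <- "positive"
  out[n_negative > pmax(n_positive, n_vus)] <- "negative"
  tie_pos <- n_positive == n_vus & n_negative == 0 & n_positive > 0
  tie_neg <- n_negative == n_vus & n_positive == 0 & n_negative > 0
  out[tie_pos] <- "positive"
  out[tie_neg] <- "negative"
  out
}

#' Binary response from a five-tier consensus class
#'
#' `1` for pathogenic/VLP, `0` for benign/VLB, `NA` otherwise.
#'
#' @param consensus_class Character vector of five-tier class labels.
#' @return Integer vector with `NA` for VUS/excluded/unknown labels.
#' @export
class_to_y <- function(consensus_class) {
  y <- rep(NA_integer_, length(consensus_class))
  y[consensus_class %in% c("pathogenic", "VLP")] <- 1L
  y[consensus_class %in% c("benign", "VLB")] <- 0L
  y
}

#' Scale raw in silico scores to the unit interval
#'
#' @param raw_scores Named numeric vector, or data.frame/matrix with
#'   predictor columns. Names must appear in `spec$predictor`. Raw values
#'   outside `[x_min, x_max]` are clamped to the boundary so the unit
#'   range holds for out-of-catalogue inputs.
#' @param spec Scaling specification, see [default_scaling_spec()].
#' @return Object of the same shape with values in \[0, 1\] (`NA`
#'   preserved for missing scores).
#' @examples
#' unit_scale_scores(c(gra = 220, sif = 0))  # 1, 1
#' @export
unit_scale_scores <- function(raw_scores, spec = default_scaling_spec()) {
  if (is.data.frame(raw_scores) || is.matrix(raw_scores)) {
    out <- as.data.frame(raw_scores)
    for (nm in colnames(out)) {
      v <- setNames(as.numeric(out[[nm]]), rep(nm, nrow(out)))
      out[[nm]] <- unname(unit_scale_scores(v, spec))
    }
    return(out)
  }
  nms <- names(raw_scores)
  if (is.null(nms)) stop("raw_scores must be named by predictor")
  idx <- match(nms, spec$predictor)
  if (anyNA(idx))
    stop("unknown predictor(s) in scaling spec: ",
         paste(unique(nms[is.na(idx)]), collapse = ", "))
  lo <- spec$x_min[idx]; hi <- spec$x_max[idx]; fl <- spec$flip[idx]
  if (any(hi <= lo)) stop("scaling spec requires x_max > x_min")
  x <- pmin(pmax(as.numeric(raw_scores), lo), hi)
  s <- (x - lo) / (hi - lo)
  s[fl] <- 1 - s[fl]
  setNames(s, nms)
}

#' Invert the unit scaling
#'
#' @inheritParams unit_scale_scores
#' @param scaled_scores Named numeric vector of unit-scale values.
#' @return Raw-scale values.
#' @export
unscale_scores <- function(scaled_scores, spec = default_scaling_spec()) {
  nms <- names(scaled_scores)
  idx <- match(nms, spec$predictor)
  if (anyNA(idx)) stop("unknown predictor(s)")
  lo <- spec$x_min[idx]; hi <- spec$x_max[idx]; fl <- spec$flip[idx]
  s <- as.numeric(scaled_scores)
  s[fl] <- 1 - s[fl]
  setNames(lo + s * (hi - lo), nms)
}

#' Impute missing scores by the k-nearest-neighbour mean
#'
#' Each missing cell is replaced by the mean of that predictor over the
#' `k` nearest variants for which it is observed. Distance between two
#' variants is the Euclidean distance over the predictors observed in
#' both, divided by `sqrt(fraction shared)` so that distances computed on
#' few shared predictors are not spuriously small. If fewer than `k`
#' neighbours carry the predictor, all available ones are used.
#'
#' @param score_matrix Numeric matrix or data.frame (variants x
#'   predictors) on the unit scale, `NA` for missing.
#' @param k Neighbour count (default 40).
#' @return Completed matrix of the same dimensions; observed entries are
#'   untouched.
#' @export
impute_missing_knn <- function(score_matrix, k = 40) {
  X <- as.matrix(score_matrix)
  if (!is.numeric(X)) stop("score_matrix must be numeric")
  if (!anyNA(X)) return(X)
  p <- ncol(X)
  obs <- !is.na(X)
  all_missing <- colSums(obs) == 0
  if (any(all_missing))
    stop("predictor(s) missing for all variants: ",
         paste(colnames(X)[all_missing], collapse = ", "))
  X0 <- X; X0[!obs] <- 0
  O <- obs * 1
  shared <- O %*% t(O)
  A <- (X0 * X0) %*% t(O)
  D2 <- A + t(A) - 2 * (X0 %*% t(X0))
  D2[D2 < 0] <- 0                       # numerical noise
  D <- sqrt(D2 * p / pmax(shared, 1))
  D[shared == 0] <- Inf
  diag(D) <- Inf
  out <- X
  holes <- which(!obs, arr.ind = TRUE)
  for (r in seq_len(nrow(holes))) {
    i <- holes[r, 1]; j <- holes[r, 2]
    cand <- which(obs[, j])
    ord <- cand[order(D[i, cand])]
    finite <- ord[is.finite(D[i, ord])]
    use <- if (length(finite)) head(finite, k) else head(ord, k)
    out[i, j] <- mean(X[use, j])
  }
  out
}

#' Read a variant table from CSV/TSV
#'
#' Expects one row per variant with at least `variant_id`, `gene`,
#' `residue` and either a `consensus_class` column or submitter-count
#' columns (`n_positive`, `n_negative`, `n_vus`), plus the in silico
#' score columns. `column_map` renames non-standard headers, e.g.
#' `c(gene = "Gene_Symbol")` reads the file's `Gene_Symbol` as `gene`.
#'
#' @param path File path (delimiter sniffed by [data.table::fread()]).
#' @param column_map Optional named character vector: standard name ->
#'   file column name.
#' @return A data.frame.
#' @examples
#' f <- system.file("extdata", "example_panel.csv", package = "bayesvar")
#' panel <- read_variant_table(f)
#' normalize_panel(panel, k = 3)[, 1:8]
#' @export
read_variant_table <- function(path, column_map = NULL) {
  dt <- data.table::fread(path, data.table = FALSE, na.strings = c("NA", "", "."))
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(dt))
    if (length(missing_cols))
      stop("columns named in column_map not present in file: ",
           paste(missing_cols, collapse = ", "))
    names(dt)[match(unname(column_map), names(dt))] <- names(column_map)
  }
  dt
}

#' Normalize a variant panel
#'
#' Derives consensus classes from submitter counts when needed, unit-scales
#' the in silico score columns, and imputes missing scores by kNN. This is
#' the canonical preprocessing step before IVP model training.
#'
#' @param panel Variant data.frame (see [read_variant_table()]).
#' @param spec Scaling specification; `NULL` skips scaling (scores already
#'   on unit scale).
#' @param k Imputation neighbour count; `NA` skips imputation.
#' @return The panel with scaled, completed score columns, a
#'   `consensus_class` column, and a derived binary `y` column.
#' @export
normalize_panel <- function(panel, spec = default_scaling_spec(), k = 40) {
  panel <- as.data.frame(panel)
  sc <- intersect(score_names(), names(panel))
  if (length(sc) == 0) stop("panel contains no recognised score columns")
  if (!"consensus_class" %in% names(panel)) {
    need <- c("n_positive", "n_negative", "n_vus")
    if (!all(need %in% names(panel)))
      stop("panel needs consensus_class or submitter count columns ",
           paste(need, collapse = ", "))
    coll <- derive_consensus_class(panel$n_positive, panel$n_negative, panel$n_vus)
    # without per-tier submitter detail, collapsed sides map to the
    # conservative "likely" tier
    panel$consensus_class <- ifelse(coll == "positive", "VLP",
                             ifelse(coll == "negative", "VLB", "excluded"))
  }
  if (!is.null(spec)) {
    for (nm in sc) {
      v <- setNames(panel[[nm]], rep(nm, nrow(panel)))
      panel[[nm]] <- unname(unit_scale_scores(v, spec))
    }
  }
  if (!is.na(k)) {
    m <- as.matrix(panel[, sc, drop = FALSE])
    rownames(m) <- NULL
    panel[, sc] <- impute_missing_knn(m, k = k)
  }
  panel$y <- class_to_y(panel$consensus_class)
  panel
}

#' Write a normalized panel to CSV
#'
#' @param panel Data.frame as produced by [normalize_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
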