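#' Five-tier classification thresholds
#'
#' The target probabilities of the ACMG-style tiers: 0.001 (benign), 0.1
#' (likely benign), 0.9 (likely pathogenic) and 0.99 (pathogenic).
#'
#' @return Named numeric vector, strictly increasing.
#' @export
tier_thresholds <- function() {
  c(benign = 0.001, vlb = 0.1, vlp = 0.9, pathogenic = 0.99)
}

#' Equal-tailed credible interval of a probability distribution
#'
#' @param dist A `prob_dist` or numeric vector of at least 100 samples.
#' @param level Credible level (default 0.95 -> the 2.5th and 97.5th
#'   percentiles).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(dist, level = 0.95) {
  x <- if (inherits(dist, "prob_dist")) dist$samples else as.numeric(dist)
  if (length(x) < 100)
    stop("credible interval needs at least 100 samples (got ", length(x), ")")
  a <- (1 - level) / 2
  q <- unname(quantile(x, c(a, 1 - a)))
  c(lower = q[1], upper = q[2])
}

#' Assign a five-tier class from a credible interval
#'
#' The whole interval must clear a tier boundary: `pathogenic` when the
#' lower bound is at or above 0.99, `VLP` at or above 0.9, `benign` when
#' the upper bound is below 0.001, `VLB` below 0.1, otherwise `VUS`.
#' Requiring the full interval (not the median) to clear the boundary is
#' what controls false benign/pathogenic calls under Monte-Carlo
#' uncertainty.
#'
#' @param pci Interval from [credible_interval()] (vector `c(lower,
#'   upper)`).
#' @param thresholds Tier thresholds, see [tier_thresholds()].
#' @return One of `"benign"`, `"VLB"`, `"VUS"`, `"VLP"`, `"pathogenic"`.
#' @export
assign_class <- function(pci, thresholds = tier_thresholds()) {
  lo <- pci[[1]]; hi <- pci[[2]]
  if (!is.finite(lo) || !is.finite(hi) || lo > hi || lo < 0 || hi > 1)
    stop("invalid credible interval")
  if (lo >= thresholds[["pathogenic"]]) return("pathogenic")
  if (lo >= thresholds[["vlp"]]) return("VLP")
  if (hi < thresholds[["benign"]]) return("benign")
  if (hi < thresholds[["vlb"]]) return("VLB")
  "VUS"
}

#' Classify a probability distribution
#'
#' Convenience wrapper: credible interval plus tier assignment.
#'
#' @inheritParams credible_interval
#' @inheritParams assign_class
#' @return List with `median`, `lower`, `upper`, `class`.
#' @export
classify_distribution <- function(dist, level = 0.95,
                                  thresholds = tier_thresholds()) {
  x <- if (inherits(dist, "prob_dist")) dist$samples else as.numeric(dist)
  pci <- credible_interval(x, level)
  list(median = median(x), lower = pci[["lower"]], upper = pci[["upper"]],
       class = assign_class(pci, thresholds))
}
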