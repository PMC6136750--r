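#' Tabulate five-tier predictions against binary truth
#'
#' Predicted pathogenic/VLP counts as a positive call, benign/VLB as a
#' negative call; VUS predictions are tallied separately by truth side so
#' that indecision can be penalised downstream.
#'
#' @param predicted Character vector of five-tier predicted classes.
#' @param truth Binary vector (1 = pathogenic/VLP truth, 0 = benign/VLB).
#' @return Object of class `confusion_summary`: list of counts `TP`,
#'   `TN`, `FP`, `FN`, `VUS_pos`, `VUS_neg` plus evaluated totals.
#' @export
confusion_outcomes <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (anyNA(predicted) || anyNA(truth)) stop("unlabeled variant in input")
  ok <- c("benign", "VLB", "VUS", "VLP", "pathogenic")
  if (!all(predicted %in% ok))
    stop("unknown predicted class label(s): ",
         paste(setdiff(predicted, ok), collapse = ", "))
  pos_call <- predicted %in% c("pathogenic", "VLP")
  neg_call <- predicted %in% c("benign", "VLB")
  vus_call <- predicted == "VUS"
  truth <- as.integer(truth)
  cs <- list(TP = sum(pos_call & truth == 1), FP = sum(pos_call & truth == 0),
             TN = sum(neg_call & truth == 0), FN = sum(neg_call & truth == 1),
             VUS_pos = sum(vus_call & truth == 1),
             VUS_neg = sum(vus_call & truth == 0))
  cs$n_positive_evaluated <- cs$TP + cs$FN + cs$VUS_pos
  cs$n_negative_evaluated <- cs$TN + cs$FP + cs$VUS_neg
  structure(cs, class = "confusion_summary")
}

#' Build a confusion summary from counts
#'
#' For tabulated benchmark results where only the counts are known.
#'
#' @param TP,TN,FP,FN True/false positive/negative counts.
#' @param VUS_pos,VUS_neg VUS predictions among true positives/negatives.
#' @return A `confusion_summary`.
#' @export
confusion_summary <- function(TP, TN, FP, FN, VUS_pos = 0, VUS_neg = 0) {
  cs <- list(TP = TP, FP = FP, TN = TN, FN = FN,
             VUS_pos = VUS_pos, VUS_neg = VUS_neg)
  if (any(unlist(cs) < 0)) stop("counts must be non-negative")
  cs$n_positive_evaluated <- TP + FN + VUS_pos
  cs$n_negative_evaluated <- TN + FP + VUS_neg
  structure(cs, class = "confusion_summary")
}

#' Performance statistics under the "VUS evaluated" convention
#'
#' Sensitivity and specificity use all evaluated variants in their
#' denominators -- positives predicted VUS count against sensitivity,
#' negatives predicted VUS against specificity -- while PPV, NPV and
#' accuracy are computed over definitive calls only. Statistics with a
#' zero denominator are `NA`.
#'
#' @param cs A `confusion_summary`.
#' @param scores Optional continuous per-variant scores for the AUC.
#' @param truth Binary truth aligned with `scores`.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, `p_vus` and (when scores are given) `auc`.
#' @export
performance_stats <- function(cs, scores = NULL, truth = NULL) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    sensitivity = rat(cs$TP, cs$n_positive_evaluated),
    specificity = rat(cs$TN, cs$n_negative_evaluated),
    ppv = rat(cs$TP, cs$TP + cs$FP),
    npv = rat(cs$TN, cs$TN + cs$FN),
    accuracy = rat(cs$TP + cs$TN, cs$TP + cs$TN + cs$FP + cs$FN),
    p_vus = rat(cs$VUS_pos + cs$VUS_neg,
                cs$n_positive_evaluated + cs$n_negative_evaluated)
  )
  if (!is.null(scores)) out$auc <- auc_rank(scores, truth)
  out
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half.
#'
#' @param scores Continuous scores, larger = more pathogenic.
#' @param truth Binary truth (1 positive, 0 negative).
#' @return AUC in \[0, 1\], or `NA` when one class is absent.
#' @export
auc_rank <- function(scores, truth) {
  truth <- as.integer(truth)
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]; truth <- truth[keep]
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors measured on the
#' same variants, using the DeLong structural-component covariance
#' estimator and a two-sided normal test.
#'
#' @param scores_a,scores_b Score vectors on the same variants.
#' @param truth Binary truth.
#' @return List with `auc_a`, `auc_b`, `difference`, `se`, `z`,
#'   `p_value` (`NA` with a warning when the variance degenerates).
#' @export
delong_test <- function(scores_a, scores_b, truth) {
  truth <- as.integer(truth)
  if (length(scores_a) != length(truth) || length(scores_b) != length(truth))
    stop("scores and truth must have equal length")
  pos <- which(truth == 1); neg <- which(truth == 0)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("need both classes for a DeLong test")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  comp <- function(s) {
    M <- outer(s[pos], s[neg], psi)
    list(v10 = rowMeans(M), v01 = colMeans(M), auc = mean(M))
  }
  a <- comp(scores_a); b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- a$auc - b$auc
  if (!is.finite(var_diff) || var_diff <= 0) {
    if (diff == 0) {
      return(list(auc_a = a$auc, auc_b = b$auc, difference = 0,
                  se = 0, z = 0, p_value = 1))
    }
    warning("degenerate DeLong variance; p-value not computable")
    return(list(auc_a = a$auc, auc_b = b$auc, difference = diff,
                se = NA_real_, z = NA_real_, p_value = NA_real_))
  }
  z <- diff / sqrt(var_diff)
  list(auc_a = a$auc, auc_b = b$auc, difference = diff,
       se = sqrt(var_diff), z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Binomial confidence interval for a proportion
#'
#' Default method is Agresti-Coull (the add-z^2 adjusted Wald interval),
#' which reproduces the published panel benchmark bounds; Clopper-Pearson
#' exact and Wilson score intervals are available.
#'
#' @param successes,trials Non-negative counts, `successes <= trials`.
#' @param level Confidence level (default 0.95).
#' @param method One of `"agresti-coull"`, `"clopper-pearson"`,
#'   `"wilson"`.
#' @return Named vector `c(lower, upper)`, truncated to \[0, 1\].
#' @export
binomial_ci <- function(successes, trials, level = 0.95,
                        method = c("agresti-coull", "clopper-pearson",
                                   "wilson")) {
  method <- match.arg(method)
  x <- successes; n <- trials
  if (length(x) != 1 || length(n) != 1 || !is.finite(x) || !is.finite(n) ||
      n <= 0 || x < 0 || x > n || x != floor(x) || n != floor(n))
    stop("need integer counts with 0 <= successes <= trials, trials > 0")
  a <- 1 - level
  if (method == "clopper-pearson") {
    lo <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
    hi <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
    return(c(lower = lo, upper = hi))
  }
  z <- qnorm(1 - a / 2)
  if (method == "wilson") {
    ph <- x / n
    ctr <- (ph + z^2 / (2 * n)) / (1 + z^2 / n)
    hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    return(c(lower = max(0, ctr - hw), upper = min(1, ctr + hw)))
  }
  nt <- n + z^2
  pt <- (x + z^2 / 2) / nt
  hw <- z * sqrt(pt * (1 - pt) / nt)
  c(lower = max(0, pt - hw), upper = min(1, pt + hw))
}
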