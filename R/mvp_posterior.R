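#' Rescale an IVP distribution into a multifactorial prior
#'
#' In silico evidence alone must not push a variant beyond the likely
#' tiers, so the IVP distribution is first shifted linearly into
#' \[0.1, 0.9\] (`p.. = 0.8 p. + 0.1`) and then re-spread about its median
#' so the binomial-scale variability of the original distribution is
#' preserved: `p_n = p.._med + (p.._n - p.._med) * sd(p.._med) / sd(p._med)`
#' with `sd(p) = sqrt(p (1 - p))`. Samples are clipped to
#' `[clip[1], clip[2]]` because the spread step can overshoot when the
#' median is extreme.
#'
#' @param ivp A `prob_dist` of role `"ivp"` (any role is accepted).
#' @param clip Two-sided clipping bounds (default `c(0.001, 0.999)`, the
#'   outer tier thresholds).
#' @return A `prob_dist` of role `"prior"` with attributes `ivp_median`
#'   and `shifted_median` recording the transform.
#' @export
rescale_prior <- function(ivp, clip = c(0.001, 0.999)) {
  p_dot <- if (inherits(ivp, "prob_dist")) ivp$samples else as.numeric(ivp)
  p_dd <- 0.8 * p_dot + 0.1
  m_dot <- median(p_dot)
  m_dd <- median(p_dd)
  ratio <- sqrt(m_dd * (1 - m_dd)) / sqrt(m_dot * (1 - m_dot))
  p <- m_dd + (p_dd - m_dd) * ratio
  p <- pmin(pmax(p, clip[1]), clip[2])
  out <- new_prob_dist(p, role = "prior")
  attr(out, "ivp_median") <- m_dot
  attr(out, "shifted_median") <- m_dd
  out
}

#' Bayes-rule posterior update of a prior distribution
#'
#' Applies the total evidence likelihood ratio elementwise:
#' `q_n = p_n LR / (1 - p_n + p_n LR)`. With `LR = 1` the posterior is
#' the prior. The result carries the LR used and, when the evidence
#' profile was entirely missing, an `insufficient_evidence` flag.
#'
#' @param prior A `prob_dist` (role `"prior"`).
#' @param lr_total Positive total likelihood ratio, optionally carrying a
#'   `no_evidence` attribute from [total_lr()].
#' @return A `prob_dist` of role `"posterior"` with attributes
#'   `lr_total` and `insufficient_evidence`.
#' @export
posterior_update <- function(prior, lr_total) {
  lr <- as.numeric(lr_total)
  if (length(lr) != 1 || !is.finite(lr) || lr <= 0)
    stop("lr_total must be a single positive number")
  p <- if (inherits(prior, "prob_dist")) prior$samples else as.numeric(prior)
  q <- p * lr / (1 - p + p * lr)
  out <- new_prob_dist(q, role = "posterior")
  attr(out, "lr_total") <- lr
  attr(out, "insufficient_evidence") <- isTRUE(attr(lr_total, "no_evidence"))
  out
}
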