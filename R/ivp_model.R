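#' Ridge-stabilised logistic regression fit
#'
#' Iteratively reweighted least squares with a tiny L2 penalty (default
#' 1e-6) that keeps the subset-search fits finite under perfect
#' separation. Used only in the stepwise selection stage; the Bayesian
#' fit needs no such guard because its prior is proper.
#'
#' @param X Design matrix (no intercept column; one is added).
#' @param y Binary 0/1 response.
#' @param lambda Ridge penalty.
#' @return List with `coefficients`, `deviance`, `fitted`, `converged`.
#' @keywords internal
fit_logistic_ridge <- function(X, y, lambda = 1e-6) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  .irls_ridge(X, as.numeric(y), lambda, 50L, 1e-9)
}

# bidirectional stepwise search minimising deviance + penalty * df.
# `cache` is an environment memoising deviance by subset so the seven
# penalty sweeps share fits.
stepwise_path <- function(X, y, penalty, cache) {
  p <- ncol(X)
  dev_of <- function(subset) {
    key <- paste0("s", paste(subset, collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    d <- fit_logistic_ridge(X[, subset, drop = FALSE], y)$deviance
    cache[[key]] <- d
    d
  }
  crit <- function(subset) dev_of(subset) + penalty * (length(subset) + 1)
  current <- integer(0)
  best <- crit(current)
  repeat {
    moves <- list()
    for (j in setdiff(seq_len(p), current))
      moves[[length(moves) + 1]] <- sort(c(current, j))
    for (j in current)
      moves[[length(moves) + 1]] <- setdiff(current, j)
    if (!length(moves)) break
    vals <- vapply(moves, crit, numeric(1))
    if (min(vals) < best - 1e-8) {
      current <- moves[[which.min(vals)]]
      best <- min(vals)
    } else break
  }
  current
}

# stratified k-fold cross-validated misclassification rate of a fixed
# predictor subset at threshold 0.5
cv_error <- function(X, y, subset, nfolds = 5, seed = 1) {
  n <- length(y)
  folds <- integer(n)
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  err <- 0
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) { err <- err + sum(!tr); next }
    fit <- fit_logistic_ridge(X[tr, subset, drop = FALSE], y[tr])
    eta <- cbind(1, X[!tr, subset, drop = FALSE]) %*% fit$coefficients
    pred <- as.integer(eta > 0)
    err <- err + sum(pred != y[!tr])
  }
  err / n
}

#' Select in silico predictors by penalised stepwise logistic regression
#'
#' For each integer penalty coefficient in `penalties`, a bidirectional
#' stepwise search minimises `deviance + penalty * df` (the AIC family;
#' penalty 2 is AIC itself). The candidate subsets are then scored by
#' stratified cross-validated misclassification rate and the subset with
#' minimal CV error is returned, ties broken towards fewer predictors and
#' then towards the lower penalty. An empty winner falls back to the best
#' single predictor by CV error.
#'
#' @param training A `training_set`, or a list with elements `data`
#'   (data.frame with score columns and `consensus_class`).
#' @param penalties Integer penalty coefficients (default `2:8`).
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return Character vector of selected predictor names (length >= 1).
#' @export
select_predictors <- function(training, penalties = 2:8, nfolds = 5, seed = 1) {
  sc <- intersect(score_names(), names(training$data))
  X <- as.matrix(training$data[, sc, drop = FALSE])
  y <- class_to_y(training$data$consensus_class)
  if (length(unique(y)) < 2) stop("training responses are all identical")
  cache <- new.env(parent = emptyenv())
  subsets <- lapply(penalties, function(k) stepwise_path(X, y, k, cache))
  keys <- vapply(subsets, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  cand <- subsets[first]
  cand_pen <- penalties[first]
  nonempty <- lengths(cand) > 0
  if (!any(nonempty)) {
    errs <- vapply(seq_len(ncol(X)),
                   function(j) cv_error(X, y, j, nfolds, seed), numeric(1))
    return(sc[which.min(errs)])
  }
  cand <- cand[nonempty]; cand_pen <- cand_pen[nonempty]
  errs <- vapply(cand, function(s) cv_error(X, y, s, nfolds, seed), numeric(1))
  ord <- order(errs, lengths(cand), cand_pen)
  sc[cand[[ord[1]]]]
}

#' Fit a gene-specific Bayesian logistic IVP model
#'
#' Polya-Gamma augmented Gibbs sampling of
#' `logit Pr(y = 1) = b0 + b1 z1 + ... + bK zK` under independent
#' `N(0, prior_var)` coefficient priors. The retained draws are the
#' `n_samples` consecutive post-burn-in samples (no thinning).
#'
#' @param training A `training_set` (or list with `data`).
#' @param predictors Character vector of selected predictor columns.
#' @param n_samples Retained Gibbs samples (default 1000).
#' @param burn_in Burn-in iterations (default 20000).
#' @param prior_var Prior variance of each coefficient (default 100).
#' @param seed RNG seed; identical seeds give identical draws.
#' @return Object of class `ivp_model`: selected predictors, the
#'   `n_samples x (K+1)` coefficient draw matrix, sampler settings and
#'   the training borrow log.
#' @export
fit_pg_logistic <- function(training, predictors, n_samples = 1000,
                            burn_in = 20000, prior_var = 100, seed = 1) {
  if (length(predictors) < 1) stop("at least one predictor is required")
  df <- training$data
  y <- class_to_y(df$consensus_class)
  if (length(unique(y)) < 2)
    stop("responses are all ", unique(y), "; cannot fit")
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, predictors, drop = FALSE]))
  set.seed(seed)
  B <- .pg_gibbs(X, as.numeric(y), prior_var, as.integer(burn_in),
                 as.integer(n_samples))
  if (!all(is.finite(B))) stop("sampler returned non-finite coefficient draws")
  colnames(B) <- c("(Intercept)", predictors)
  structure(list(gene = training$gene, predictors = predictors,
                 coefficients = B,
                 settings = list(n_samples = n_samples, burn_in = burn_in,
                                 prior_var = prior_var, seed = seed),
                 borrow_log = training$borrow_log),
            class = "ivp_model")
}

#' @export
print.ivp_model <- function(x, ...) {
  cat("IVP model", if (!is.null(x$gene)) paste0("(", x$gene, ")"), "\n",
      "predictors:", paste(x$predictors, collapse = ", "), "\n",
      nrow(x$coefficients), "posterior draws; posterior means:\n")
  print(round(colMeans(x$coefficients), 3))
  invisible(x)
}

#' Predict a pathogenicity probability distribution
#'
#' Pushes each joint coefficient draw through the inverse-logit of the
#' variant's linear predictor, yielding one probability sample per draw.
#'
#' @param model An `ivp_model`.
#' @param scores Named numeric vector (or single-row data.frame) holding
#'   the model's predictors; missing values are an error (impute first).
#' @return A `prob_dist` of role `"ivp"` with `n_samples` samples.
#' @export
predict_distribution <- function(model, scores) {
  if (is.data.frame(scores)) {
    if (nrow(scores) != 1) stop("scores must describe a single variant")
    scores <- unlist(scores[1, , drop = TRUE])
  }
  need <- model$predictors
  if (!all(need %in% names(scores)))
    stop("missing predictor value(s): ",
         paste(setdiff(need, names(scores)), collapse = ", "))
  x <- as.numeric(scores[need])
  if (anyNA(x)) stop("predictor values contain NA; impute before predicting")
  eta <- model$coefficients %*% c(1, x)
  p <- plogis(drop(eta))
  # inverse-logit saturates in double precision for |eta| > ~37; nudge
  # inside the open interval so downstream transforms stay defined
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  new_prob_dist(p, role = "ivp")
}

#' Construct a probability distribution object
#'
#' @param samples Numeric vector of probability samples in (0, 1).
#' @param role One of `"ivp"`, `"prior"`, `"posterior"`.
#' @return Object of class `prob_dist`.
#' @export
new_prob_dist <- function(samples, role = c("ivp", "prior", "posterior")) {
  role <- match.arg(role)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)) || any(samples <= 0) || any(samples >= 1))
    stop("probability samples must lie strictly in (0, 1)")
  structure(list(samples = samples, role = role), class = "prob_dist")
}

#' @export
print.prob_dist <- function(x, ...) {
  q <- quantile(x$samples, c(0.025, 0.5, 0.975))
  cat("Probability distribution (", x$role, "), ", length(x$samples),
      " samples\n  median ", signif(q[2], 4), ", 95% PCI [",
      signif(q[1], 4), ", ", signif(q[3], 4), "]\n", sep = "")
  invisible(x)
}
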