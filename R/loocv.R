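#' Run configuration for model fitting and evaluation
#'
#' Collects the knobs shared across pipeline stages. The MCMC settings
#' default to 20000 burn-in iterations with 1000 retained samples; the
#' stepwise selection sweeps AIC-family penalty coefficients 2 to 8 with
#' 5-fold cross-validation.
#'
#' @param seed Global RNG seed; per-variant fits derive their own seeds
#'   from it so leave-one-out runs are reproducible.
#' @param burn_in,n_samples Gibbs sampler settings.
#' @param prior_var Coefficient prior variance.
#' @param penalties Stepwise penalty sweep.
#' @param nfolds Cross-validation folds for subset scoring.
#' @param min_neg,min_pos Training-set effective count minima.
#' @param k_impute Imputation neighbour count.
#' @param thresholds Five-tier thresholds.
#' @param borrow_order Donor merge order in data expansion.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, burn_in = 20000, n_samples = 1000,
                       prior_var = 100, penalties = 2:8, nfolds = 5,
                       min_neg = 5, min_pos = 5, k_impute = 40,
                       thresholds = tier_thresholds(),
                       borrow_order = "descending") {
  structure(list(seed = seed, burn_in = burn_in, n_samples = n_samples,
                 prior_var = prior_var, penalties = penalties,
                 nfolds = nfolds, min_neg = min_neg, min_pos = min_pos,
                 k_impute = k_impute, thresholds = thresholds,
                 borrow_order = borrow_order),
            class = "run_config")
}

# fit-and-predict for one held-out variant; returns a one-row data.frame
predict_one_loo <- function(variant, train_panel, profiles, config, fit_seed) {
  sc <- intersect(score_names(), names(train_panel))
  ts <- build_training_set(variant$gene, train_panel,
                           min_neg = config$min_neg, min_pos = config$min_pos,
                           order = config$borrow_order)
  sel <- select_predictors(ts, penalties = config$penalties,
                           nfolds = config$nfolds, seed = fit_seed)
  mdl <- fit_pg_logistic(ts, sel, n_samples = config$n_samples,
                         burn_in = config$burn_in,
                         prior_var = config$prior_var, seed = fit_seed)
  ivp <- predict_distribution(mdl, unlist(variant[1, sc]))
  prior <- rescale_prior(ivp)
  lr <- structure(1, no_evidence = TRUE)
  if (!is.null(profiles)) {
    i <- match(variant$variant_id, profiles$variant_id)
    if (!is.na(i)) {
      prof <- unlist(profiles[i, evidence_categories()])
      lr <- structure(prod(prof), no_evidence = all(prof == 1))
    }
  }
  post <- posterior_update(prior, lr)
  cls <- classify_distribution(post, thresholds = config$thresholds)
  data.frame(variant_id = variant$variant_id, gene = variant$gene,
             truth = class_to_y(variant$consensus_class),
             ivp_median = median(ivp$samples),
             prior_median = median(prior$samples),
             post_median = cls$median,
             pci_lower = cls$lower, pci_upper = cls$upper,
             class = cls$class, lr_total = as.numeric(lr),
             has_evidence = !isTRUE(attr(lr, "no_evidence")),
             n_borrowed = nrow(ts$borrow_log),
             n_predictors = length(sel),
             self_in_training = variant$variant_id %in% ts$data$variant_id,
             unevaluable = FALSE,
             stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated variant prediction
#'
#' For every class-known variant, the gene's training set is rebuilt with
#' that variant removed (so it can enter neither its own gene's data nor
#' any expansion borrow), predictor selection and the Polya-Gamma fit are
#' rerun, the held-out variant is predicted, the IVP distribution is
#' rescaled into a prior and updated with the variant's total evidence
#' LR, and the posterior is classified. Each fit is seeded
#' deterministically from `config$seed` and the variant's panel position.
#'
#' @param panel Normalized panel (scaled, imputed scores,
#'   `consensus_class`).
#' @param profiles Optional per-variant evidence profiles from
#'   [build_evidence_profiles()]; `NULL` runs IVP-only predictions.
#' @param config A [run_config()].
#' @param verbose Print one line per 50 variants.
#' @return data.frame with one row per class-known variant: medians of
#'   the IVP / prior / posterior distributions, the 95% PCI, the
#'   assigned class, `lr_total`, borrow diagnostics and an `unevaluable`
#'   flag for variants whose gene cannot reach the training minima.
#' @export
loocv_run <- function(panel, profiles = NULL, config = run_config(),
                      verbose = FALSE) {
  panel <- as.data.frame(panel)
  known_idx <- which(!is.na(class_to_y(panel$consensus_class)))
  out <- vector("list", length(known_idx))
  for (j in seq_along(known_idx)) {
    i <- known_idx[j]
    if (verbose && j %% 50 == 1)
      message("LOOCV variant ", j, "/", length(known_idx))
    fit_seed <- (config$seed + 1009L * i) %% .Machine$integer.max
    res <- tryCatch(
      predict_one_loo(panel[i, , drop = FALSE], panel[-i, , drop = FALSE],
                      profiles, config, fit_seed),
      error = function(e) {
        data.frame(variant_id = panel$variant_id[i], gene = panel$gene[i],
                   truth = class_to_y(panel$consensus_class[i]),
                   ivp_median = NA_real_, prior_median = NA_real_,
                   post_median = NA_real_, pci_lower = NA_real_,
                   pci_upper = NA_real_, class = NA_character_,
                   lr_total = NA_real_, has_evidence = NA,
                   n_borrowed = NA_integer_, n_predictors = NA_integer_,
                   self_in_training = FALSE, unevaluable = TRUE,
                   stringsAsFactors = FALSE)
      })
    out[[j]] <- res
  }
  do.call(rbind, out)
}

#' Evaluate a LOOCV prediction table
#'
#' @param predictions Output of [loocv_run()] (unevaluable rows are
#'   dropped).
#' @param score_col Column used as the continuous score for the AUC
#'   (default `"post_median"`).
#' @return List with the confusion summary and [performance_stats()].
#' @export
evaluate_predictions <- function(predictions, score_col = "post_median") {
  ok <- !predictions$unevaluable
  pred <- predictions[ok, , drop = FALSE]
  cs <- confusion_outcomes(pred$class, pred$truth)
  stats <- performance_stats(cs, scores = pred[[score_col]], truth = pred$truth)
  list(confusion = cs, stats = stats, n_evaluated = nrow(pred),
       n_unevaluable = sum(!ok))
}
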