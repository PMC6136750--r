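#' Run the full prediction pipeline on in-memory tables
#'
#' normalize -> (evidence assembly + hotspot) -> LOOCV train/predict ->
#' classify -> evaluate. Returns everything a caller needs to write
#' reports; the CLI wraps this with file I/O.
#'
#' @param panel Raw variant table (see [read_variant_table()]).
#' @param evidence Optional long evidence table.
#' @param config A [run_config()].
#' @param scale Unit-scale the score columns (set `FALSE` when scores are
#'   already scaled, e.g. simulated panels).
#' @param hotspot_level Evidence level contributed by the mutational
#'   hotspot indicator; `NA` disables the hotspot scan.
#' @return List with `panel` (normalized), `profiles`, `predictions`,
#'   `evaluation` and `config`.
#' @export
run_pipeline <- function(panel, evidence = NULL, config = run_config(),
                         scale = TRUE, hotspot_level = "P-4") {
  panel <- normalize_panel(panel,
                           spec = if (scale) default_scaling_spec() else NULL,
                           k = config$k_impute)
  profiles <- NULL
  if (!is.null(evidence) || !is.na(hotspot_level)) {
    profiles <- build_evidence_profiles(evidence, panel$variant_id)
    if (!is.na(hotspot_level) && "residue" %in% names(panel))
      profiles <- add_hotspot_evidence(profiles, panel, level = hotspot_level)
  }
  predictions <- loocv_run(panel, profiles, config)
  evaluation <- evaluate_predictions(predictions)
  list(panel = panel, profiles = profiles, predictions = predictions,
       evaluation = evaluation, config = config)
}

# serialisable run metadata embedded in every output
run_metadata <- function(config) {
  cfg <- unclass(config)
  cfg$thresholds <- as.list(cfg$thresholds)
  hash <- substr(tools::md5sum(
    {f <- tempfile(); writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), f); f}
  ), 1, 12)
  list(package = "bayesvar",
       version = as.character(utils::packageVersion("bayesvar")),
       config = cfg, config_hash = unname(hash))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `normalize`, `evaluate` and `run` (the full
#' normalize / LOOCV / classify / evaluate pipeline). Options are
#' `--key value` pairs; every JSON output embeds the run configuration
#' and its hash.
#'
#' @param args Character vector of arguments (defaults to the process
#'   command line), e.g. `c("run", "--panel", "panel.csv", "--out",
#'   "out_dir", "--seed", "7")`.
#' @return Exit status, invisibly (0 on success).
#' @export
bayesvar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: bayesvar <simulate|normalize|run|evaluate> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  seed <- as.integer(opts[["seed"]] %||% 1)
  status <- switch(cmd,
    simulate = {
      cfg <- simulation_config(seed = seed)
      sim <- simulate_panel(cfg)
      ev <- simulate_evidence(sim$panel, cfg)
      write.csv(sim$panel, req_opt(opts, "out"), row.names = FALSE)
      if (!is.null(opts[["evidence"]]))
        write.csv(ev, opts[["evidence"]], row.names = FALSE)
      if (!is.null(opts[["truth"]]))
        jsonlite::write_json(sim$truth["genes"], opts[["truth"]],
                             auto_unbox = TRUE)
      0L
    },
    normalize = {
      panel <- read_variant_table(req_opt(opts, "panel"))
      k <- as.numeric(opts[["k"]] %||% 40)
      scaled <- !identical(opts[["scaled"]], "true")
      out <- normalize_panel(panel,
                             spec = if (scaled) default_scaling_spec() else NULL,
                             k = k)
      write.csv(out, req_opt(opts, "out"), row.names = FALSE)
      0L
    },
    run = {
      panel <- read_variant_table(req_opt(opts, "panel"))
      evidence <- if (!is.null(opts[["evidence"]]))
        read_variant_table(opts[["evidence"]]) else NULL
      cfg <- run_config(seed = seed,
                        burn_in = as.integer(opts[["burn-in"]] %||% 20000),
                        n_samples = as.integer(opts[["n-samples"]] %||% 1000))
      res <- run_pipeline(panel, evidence, cfg,
                          scale = !identical(opts[["scaled"]], "true"))
      out_dir <- req_opt(opts, "out")
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(res$predictions, file.path(out_dir, "predictions.csv"),
                row.names = FALSE)
      rep <- c(run_metadata(cfg),
               list(confusion = unclass(res$evaluation$confusion),
                    stats = res$evaluation$stats))
      jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      0L
    },
    classify = {
      pred <- read_variant_table(req_opt(opts, "predictions"))
      if (!all(c("pci_lower", "pci_upper") %in% names(pred)))
        stop("predictions file must carry pci_lower and pci_upper columns")
      pred$class <- vapply(seq_len(nrow(pred)), function(i)
        assign_class(c(pred$pci_lower[i], pred$pci_upper[i])), character(1))
      write.csv(pred, req_opt(opts, "out"), row.names = FALSE)
      0L
    },
    evaluate = {
      pred <- read_variant_table(req_opt(opts, "predictions"))
      res <- evaluate_predictions(pred)
      rep <- list(confusion = unclass(res$confusion), stats = res$stats,
                  n_evaluated = res$n_evaluated)
      jsonlite::write_json(rep, req_opt(opts, "out"), auto_unbox = TRUE,
                           digits = NA, na = "null")
      0L
    },
    {
      cat("unknown subcommand: ", cmd, "\n", sep = "")
      1L
    })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]; i <- i + 2
    } else {
      opts[[key]] <- "true"; i <- i + 1
    }
  }
  opts
}

req_opt <- function(opts, key) {
  if (is.null(opts[[key]]))
    stop("missing required option --", key, call. = FALSE)
  opts[[key]]
}
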