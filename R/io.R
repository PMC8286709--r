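#' Read and write looking-time datasets
#'
#' Datasets are exchanged as UTF-8 CSV with a header row and one row per
#' trial, columns `infant_id`, `age_days`, `cohort`, `contrast`,
#' `n_hab_trials`, `trial`, `lt_seconds`. `write_dataset()` emits rows in
#' deterministic order (infant id, then trial) and, when the dataset carries
#' generator metadata, a JSON sidecar `<path>.json` with the seed and
#' configuration. `read_dataset()` validates the schema: positive looking
#' times, consecutive trial indices per infant, and a cohort column
#' consistent with `age_days` (the cohort is recomputed from age and
#' cross-checked). Habituation-trial counts outside \{1, 3, 5, 7\} are
#' accepted with a warning (non-study designs).
#'
#' @param data an `lt_dataset` (or plain data.frame with the schema above).
#' @param path CSV file path.
#' @return `read_dataset()` returns an `lt_dataset`; `write_dataset()`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(data, path) {
  need <- c("infant_id", "age_days", "cohort", "contrast", "n_hab_trials",
            "trial", "lt_seconds")
  cfg <- attr(data, "config")
  seed <- attr(data, "seed")
  if (nrow(data) > 0) {
    validate_lt_dataset(data)
    data <- data[order(data$infant_id, data$trial), need, drop = FALSE]
  } else {
    data <- data[, need, drop = FALSE]
  }
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(cfg)) {
    meta <- unclass(cfg)
    meta$cell_sizes <- NULL
    meta <- c(list(seed = seed), meta)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("infant_id", "age_days", "cohort", "contrast", "n_hab_trials",
            "trial", "lt_seconds")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("header does not match the dataset schema; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$n_hab_trials %in% hab_trial_levels()))
    warning("habituation-trial counts outside {1, 3, 5, 7}; ",
            "accepted as a non-study design")
  new_lt_dataset(df)
}

# --- command-line pipeline driver ------------------------------------------

#' Command-line pipeline driver
#'
#' A thin shell interface over the package's functions, installed as
#' `exec/lookhab`. Subcommands:
#' \describe{
#'   \item{simulate}{`--seed S --out data.csv [--preset study-like|small]`
#'     -- generate a synthetic dataset (+ JSON metadata sidecar).}
#'   \item{fit}{`--data data.csv --model GTP [--preset test|full]
#'     [--seed S] --out-dir DIR` -- fit one model; partial-pooling fits
#'     write draws (`<code>.csv`) and diagnostics (`<code>.csv.json`);
#'     no-pooling fits write per-infant median parameters
#'     (`<code>_params.csv`) and diagnostics.}
#'   \item{evaluate}{`--data data.csv --models GTP,LTP,... --out
#'     comparison.csv` -- fit each listed model and write the
#'     model-comparison table (log-likelihood at medians, predictive MAE).}
#'   \item{predict}{`--data data.csv --model GTP [--seed S] --out
#'     metrics.json` -- censored-fifth-trial prediction.}
#'   \item{analyze}{`--data data.csv --fit-dir DIR --out-dir DIR` -- ANOVA
#'     on the no-pooling parameter files found in `--fit-dir`, plus
#'     correlation table; requires a prior `fit` run.}
#'   \item{report}{`--dir DIR --out report.json` -- consolidate the JSON /
#'     CSV artifacts under a directory into one summary.}
#' }
#' Every run logs the seed and the convergence flags of the models involved;
#' non-converged models are reported, not silently dropped.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return integer exit status (0 on success), invisibly.
#' @export
lt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) {
      cat(cli_usage())
      return(invisible(2L))
    }
    cmd <- args[1]
    opts <- parse_cli_options(args[-1])
    switch(cmd,
      simulate = cli_simulate(opts),
      fit = cli_fit(opts),
      evaluate = cli_evaluate(opts),
      predict = cli_predict(opts),
      analyze = cli_analyze(opts),
      report = cli_report(opts),
      { message("unknown subcommand: ", cmd, "\n", cli_usage()); 2L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_usage <- function() {
  paste0("usage: lookhab <simulate|fit|evaluate|predict|analyze|report> ",
         "[--option value ...]\n")
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--"))
      stop("unexpected argument: ", key, call. = FALSE)
    if (i == length(args)) stop("missing value for ", key, call. = FALSE)
    opts[[substring(key, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss))
    stop("missing required option(s): ",
         paste0("--", miss, collapse = ", "), call. = FALSE)
}

cli_log <- function(...) message("[lookhab] ", ...)

cli_simulate <- function(opts) {
  cli_need(opts, c("seed", "out"))
  preset <- opts$preset %||% "study-like"
  cfg <- switch(preset,
    "study-like" = generator_config(seed = as.integer(opts$seed)),
    "small" = generator_config(
      cell_sizes = small_design(), seed = as.integer(opts$seed)),
    stop("unknown preset: ", preset, call. = FALSE))
  data <- generate_dataset(cfg)
  write_dataset(data, opts$out)
  cli_log("simulate: seed ", cfg$seed, ", ",
          length(unique(data$infant_id)), " infants -> ", opts$out)
  0L
}

small_design <- function() {
  d <- study_cell_sizes()
  d$n <- pmin(d$n, 2L)
  d
}

cli_model_config <- function(opts) {
  sampler_config(preset = opts$preset %||% "test",
                 seed = as.integer(opts$seed %||% "1"))
}

cli_fit <- function(opts) {
  cli_need(opts, c("data", "model", "out-dir"))
  data <- read_dataset(opts$data)
  spec <- parse_model_code(opts$model,
                           gamma_effects = opts[["gamma-effects"]] %||% "main")
  config <- cli_model_config(opts)
  dir.create(opts[["out-dir"]], showWarnings = FALSE, recursive = TRUE)
  code <- model_code(spec)
  if (spec$pooling == "partial") {
    fit <- fit_partial_pooling(spec, data, config)
    write_posterior(fit, file.path(opts[["out-dir"]], paste0(code, ".csv")))
    cli_log("fit ", code, ": seed ", config$seed, ", converged=",
            fit$converged, " (max R-hat ",
            format(max(fit$rhat), digits = 4), ")")
  } else {
    fit <- fit_dataset(spec, data, config)
    params <- median_infant_params(fit)
    labels <- unique(data[, c("infant_id", "contrast", "cohort",
                              "n_hab_trials")])
    params <- merge(params, labels, by = "infant_id", sort = TRUE)
    utils::write.csv(params,
                     file.path(opts[["out-dir"]], paste0(code, "_params.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(model = code, seed = config$seed,
           config = unclass(config),
           n_infants = length(fit),
           n_converged = sum(params$converged)),
      file.path(opts[["out-dir"]], paste0(code, "_params.csv.json")),
      auto_unbox = TRUE, digits = NA)
    cli_log("fit ", code, ": ", sum(params$converged), "/", nrow(params),
            " infants converged")
  }
  0L
}

cli_evaluate <- function(opts) {
  cli_need(opts, c("data", "models", "out"))
  data <- read_dataset(opts$data)
  config <- cli_model_config(opts)
  codes <- strsplit(opts$models, ",")[[1]]
  reports <- lapply(codes, function(code) {
    spec <- parse_model_code(code)
    fit <- fit_dataset(spec, data, config)
    conv <- if (inherits(fit, "lt_posterior")) fit$converged
    else mean(vapply(fit, `[[`, logical(1), "converged"))
    cli_log("evaluate ", code, ": convergence ", format(conv, digits = 3))
    fit_report(spec, fit, data, seed = config$seed)
  })
  utils::write.csv(comparison_table(reports), opts$out, row.names = FALSE)
  cli_log("evaluate: comparison -> ", opts$out)
  0L
}

cli_predict <- function(opts) {
  cli_need(opts, c("data", "model", "out"))
  data <- read_dataset(opts$data)
  config <- cli_model_config(opts)
  spec <- parse_model_code(opts$model)
  pred <- censored_prediction(spec, data, config, seed = config$seed)
  jsonlite::write_json(
    list(model = model_code(spec), seed = config$seed,
         predictive_loglik = pred$predictive_loglik,
         abs_error_mean_prediction = pred$abs_error_mean_prediction,
         abs_error_drawwise = pred$abs_error_drawwise,
         n_evaluated = pred$n_evaluated),
    opts$out, auto_unbox = TRUE, digits = NA)
  cli_log("predict ", opts$model, ": held-out loglik ",
          format(pred$predictive_loglik, digits = 6), " -> ", opts$out)
  0L
}

cli_analyze <- function(opts) {
  cli_need(opts, c("data", "fit-dir", "out-dir"))
  fit_dir <- opts[["fit-dir"]]
  param_files <- list.files(fit_dir, pattern = "_params\\.csv$",
                            full.names = TRUE)
  if (length(param_files) == 0)
    stop("no no-pooling parameter files (*_params.csv) in ", fit_dir,
         "; run `lookhab fit --model <code ending in N>` first",
         call. = FALSE)
  dir.create(opts[["out-dir"]], showWarnings = FALSE, recursive = TRUE)
  for (f in param_files) {
    params <- utils::read.csv(f, stringsAsFactors = FALSE)
    code <- sub("_params\\.csv$", "", basename(f))
    tab <- anova_table(params)
    utils::write.csv(tab, file.path(opts[["out-dir"]],
                                    paste0(code, "_anova.csv")),
                     row.names = FALSE)
    ct <- correlation_table(params)
    utils::write.csv(data.frame(model = code, t(ct)),
                     file.path(opts[["out-dir"]],
                               paste0(code, "_correlations.csv")),
                     row.names = FALSE)
    cli_log("analyze ", code, ": ANOVA and correlation tables -> ",
            opts[["out-dir"]])
  }
  0L
}

cli_report <- function(opts) {
  cli_need(opts, c("dir", "out"))
  files <- list.files(opts$dir, recursive = TRUE,
                      pattern = "\\.(csv|json)$")
  if (length(files) == 0)
    stop("no artifacts found under ", opts$dir, call. = FALSE)
  jsons <- grep("\\.json$", files, value = TRUE)
  meta <- lapply(file.path(opts$dir, jsons), function(f)
    tryCatch(jsonlite::read_json(f), error = function(e) NULL))
  names(meta) <- jsons
  jsonlite::write_json(list(artifacts = files, metadata = meta), opts$out,
                       auto_unbox = TRUE, digits = NA)
  cli_log("report: ", length(files), " artifacts -> ", opts$out)
  0L
}
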