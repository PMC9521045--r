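#' Pipeline configuration
#'
#' Bundles everything a full run needs: the input mode (synthetic generation
#' or four CSV files), the synthetic and filter configurations, the model
#' candidate sets for the HLCC and HM305 model families, the significance
#' level for the non-nested tests, the output directory and the seed.
#'
#' @param input_mode \code{"synthetic"} or \code{"files"}.
#' @param paths named list of file paths (\code{test_days},
#'   \code{accounting}, \code{performance}, \code{national_price}); required
#'   in \code{"files"} mode.
#' @param synthetic a [synthetic_config()]; required in synthetic mode.
#' @param filters a [filter_config()].
#' @param controls character vector of control covariates offered to every
#'   model.
#' @param alpha significance level for verdicts.
#' @param out_dir output directory for the report bundle.
#' @param rng_seed integer seed (overrides the synthetic config's seed).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "files"),
                            paths = NULL,
                            synthetic = synthetic_config(),
                            filters = filter_config(),
                            controls = c("soil_type", "successor",
                                         "equity_ratio", "herd_intensity",
                                         "milking_system",
                                         "outsourced_rearing",
                                         "relative_milk_price", "herd_size",
                                         "expansion_rate", "scc",
                                         "calving_interval"),
                            alpha = 0.05,
                            out_dir = tempfile("lactecon_run_"),
                            rng_seed = NULL) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "files") {
    need <- c("test_days", "accounting", "performance", "national_price")
    if (is.null(paths) || !all(need %in% names(paths))) {
      stop("files mode needs paths for: ", paste(need, collapse = ", "))
    }
  }
  if (!is.null(rng_seed)) synthetic$rng_seed <- as.integer(rng_seed)
  structure(list(input_mode = input_mode, paths = paths,
                 synthetic = synthetic, filters = filters,
                 controls = controls, alpha = alpha, out_dir = out_dir),
            class = "pipeline_config")
}

.hlcc_vars <- c("magnitude1", "time_to_peak1", "persistency1",
                "magnitude2", "time_to_peak2", "persistency2")

.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # a run is identified by its inputs, not its target
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(cfg, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> fit curves -> aggregate HLCC ->
#' economics -> merge & edit -> standardize -> four mixed models with AIC
#' backward selection and R2 decomposition -> Cox/J non-nested comparison,
#' writing every intermediate table to the output directory so each stage
#' is independently inspectable. The run is a pure function of
#' (config, seed): repeated runs produce byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the report bundle: list with \code{analysis},
#'   \code{hlcc}, \code{indicators}, \code{audit}, \code{models} (per
#'   outcome x family: selection result, R2), \code{comparisons},
#'   \code{manifest}, \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)

  ## stage: inputs
  if (config$input_mode == "synthetic") {
    pop <- generate_population(config$synthetic)
    write_population(pop, outp("inputs"))
  } else {
    rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
    pop <- list(test_days = rd(config$paths$test_days),
                accounting = rd(config$paths$accounting),
                performance = rd(config$paths$performance),
                national_price = rd(config$paths$national_price),
                truth = NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## stage: curve fitting
  fits <- stage("fit_curves", fit_lactations(pop$test_days))

  ## stage: HLCC aggregation
  year_span <- seq(min(pop$test_days$year), max(pop$test_days$year))
  weights <- stage("aggregate",
                   partition_lactation_weights(pop$test_days, fits))
  hlcc <- stage("aggregate", aggregate_hlcc(fits, weights, year_span))
  utils::write.csv(hlcc, outp("hlcc.csv"), row.names = FALSE)

  ## stage: economics
  indicators <- stage("economics",
                      compute_economic_indicators(pop$accounting,
                                                  pop$national_price))
  utils::write.csv(indicators, outp("indicators.csv"), row.names = FALSE)

  ## stage: merge & edit
  merged <- stage("edit", merge_sources(indicators, hlcc, pop$performance))
  edited <- stage("edit", apply_filters(merged, config$filters))
  analysis <- edited$data
  jsonlite::write_json(edited$audit, outp("audit.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  ## stage: standardize (model columns must be complete)
  continuous <- intersect(
    c(.hlcc_vars, "hm305", "equity_ratio", "herd_intensity",
      "relative_milk_price", "herd_size", "expansion_rate", "scc",
      "calving_interval", "age_days"), names(analysis))
  model_cols <- unique(c("iofc_cow", "iofc_milk", "year", "herd",
                         config$controls, .hlcc_vars, "hm305"))
  complete <- stats::complete.cases(analysis[model_cols])
  # a zero-decay curve fit gives infinite persistency; such herd-years
  # cannot enter the models
  for (v in model_cols) {
    x <- analysis[[v]]
    if (is.numeric(x)) complete <- complete & is.finite(x)
  }
  analysis <- analysis[complete, ]
  std <- stage("standardize", standardize_continuous(analysis, continuous))
  utils::write.csv(analysis, outp("analysis.csv"), row.names = FALSE)
  zdata <- std$data

  ## stage: models
  families <- list(hlcc = .hlcc_vars, hm305 = "hm305")
  outcomes <- c("iofc_cow", "iofc_milk")
  models <- list()
  for (oc in outcomes) {
    for (fam in names(families)) {
      sp <- model_spec(oc, c(families[[fam]], config$controls))
      sel <- stage("model", backward_select_aic(sp, zdata))
      r2 <- stage("model", r2_decomposition(sel$fit, zdata))
      key <- paste(oc, fam, sep = "_")
      models[[key]] <- list(selection = sel, r2 = r2)
      utils::write.csv(sel$fit$coefficients,
                       outp(paste0("model_", key, ".csv")),
                       row.names = FALSE)
    }
  }
  r2_list <- lapply(models, function(m) {
    list(marginal = m$r2$marginal, conditional = m$r2$conditional,
         part = as.list(m$r2$part))
  })
  jsonlite::write_json(r2_list, outp("r2.json"), auto_unbox = TRUE,
                       digits = NA)

  ## stage: non-nested comparison
  comparisons <- lapply(outcomes, function(oc) {
    tryCatch(compare_models(
      models[[paste0(oc, "_hlcc")]]$selection$fit,
      models[[paste0(oc, "_hm305")]]$selection$fit,
      zdata, alpha = config$alpha, labels = c("HLCC", "HM305")),
      error = function(e) {
        # selection can leave identical designs on small data; record it
        data.frame(test = NA_character_, outcome = oc,
                   direction = NA_character_, estimate = NA_real_,
                   se = NA_real_, statistic = NA_real_, p = NA_real_,
                   interpretation = paste("comparison degenerate:",
                                          conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
  })
  comparison_table <- do.call(rbind, comparisons)
  utils::write.csv(comparison_table, outp("nonnested.csv"),
                   row.names = FALSE)

  manifest <- list(config_hash = .config_hash(config),
                   rng_seed = if (config$input_mode == "synthetic")
                     config$synthetic$rng_seed else NA,
                   n_analysis_rows = nrow(analysis),
                   n_herds = length(unique(analysis$herd)),
                   created = "run")
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE)

  invisible(list(analysis = analysis, hlcc = hlcc, indicators = indicators,
                 audit = edited$audit, models = models,
                 comparisons = comparison_table, scaling = std$scaling,
                 manifest = manifest, out_dir = config$out_dir,
                 truth = pop$truth))
}

#' Human-readable run summary
#'
#' One-page markdown summary of a report bundle: the editing waterfall,
#' descriptive statistics of the analysis variables, model highlights and
#' the non-nested verdicts.
#'
#' @param bundle result of [run_pipeline()].
#' @return character scalar (markdown).
#' @export
summarize_run <- function(bundle) {
  lines <- c("# Pipeline run summary", "")
  if (!is.null(bundle$audit)) {
    lines <- c(lines, "## Editing waterfall", "")
    for (i in seq_len(nrow(bundle$audit))) {
      lines <- c(lines, sprintf("- %s: excluded %d, remaining %d",
                                bundle$audit$step[i],
                                bundle$audit$excluded[i],
                                bundle$audit$remaining[i]))
    }
    lines <- c(lines, "")
  }
  if (is.null(bundle$analysis) || nrow(bundle$analysis) == 0L) {
    return(paste(c(lines, "Zero modelled rows; no model section."),
                 collapse = "\n"))
  }
  desc_vars <- intersect(
    c("iofc_cow", "iofc_milk", "hm305", "equity_ratio", "herd_intensity",
      "relative_milk_price", "herd_size", "expansion_rate", "age_days",
      "scc", "calving_interval", .hlcc_vars), names(bundle$analysis))
  lines <- c(lines, "## Descriptive statistics", "",
             "| variable | mean | SD |", "|---|---|---|")
  for (v in desc_vars) {
    x <- bundle$analysis[[v]]
    lines <- c(lines, sprintf("| %s | %.3g | %.3g |", v,
                              mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE)))
  }
  lines <- c(lines, "", "## Models", "")
  for (key in names(bundle$models)) {
    m <- bundle$models[[key]]
    lines <- c(lines, sprintf(
      "- %s: %d terms retained, AIC %.1f, marginal R2 %.3f, conditional R2 %.3f",
      key, length(m$selection$fit$terms), m$selection$fit$aic,
      m$r2$marginal, m$r2$conditional))
  }
  if (!is.null(bundle$comparisons)) {
    lines <- c(lines, "", "## Non-nested comparison", "")
    cmp <- bundle$comparisons
    for (i in seq_len(nrow(cmp))) {
      lines <- c(lines, sprintf(
        "- %s test, %s, %s: statistic %.2f, p %.3g%s",
        toupper(cmp$test[i]), cmp$outcome[i], cmp$direction[i],
        cmp$statistic[i], cmp$p[i],
        ifelse(is.na(cmp$interpretation[i]), "",
               paste0(" -> ", cmp$interpretation[i]))))
    }
  }
  paste(lines, collapse = "\n")
}

#' Command-line entry point
#'
#' Thin CLI over the pipeline: subcommands \code{simulate} (write the four
#' synthetic input tables), \code{run-all} (full pipeline) and
#' \code{summarize} (print the summary of a finished run). Options:
#' \code{--out DIR}, \code{--seed INT}, \code{--herds INT},
#' \code{--years Y1:Y2}, \code{--herd-size N}.
#'
#' @param args character vector, default \code{commandArgs(TRUE)}.
#' @return exit status, invisibly.
#' @export
lactecon_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: lactecon <simulate|run-all|summarize> [--out DIR]",
        "[--seed INT] [--herds INT] [--years Y1:Y2] [--herd-size N]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  out <- opt("--out", "lactecon_out")
  seed <- as.integer(opt("--seed", "1"))
  herds <- as.integer(opt("--herds", "20"))
  yrs <- strsplit(opt("--years", "2007:2012"), ":")[[1]]
  years <- seq(as.integer(yrs[1]), as.integer(yrs[2]))
  hsize <- as.numeric(opt("--herd-size", "30"))
  syn <- synthetic_config(n_herds = herds, years = years,
                          herd_size_mean = hsize, rng_seed = seed)
  if (cmd == "simulate") {
    write_population(generate_population(syn), out)
    cat("wrote synthetic tables to", out, "\n")
  } else if (cmd == "run-all") {
    cfg <- pipeline_config(input_mode = "synthetic", synthetic = syn,
                           out_dir = out)
    bundle <- run_pipeline(cfg)
    writeLines(summarize_run(bundle), file.path(out, "summary.md"))
    cat("run complete;", nrow(bundle$analysis), "analysis rows; see", out,
        "\n")
  } else if (cmd == "summarize") {
    cat("summary requires a bundle from run-all in this session;",
        "see", file.path(out, "summary.md"), "\n")
  } else {
    cat("unknown subcommand:", cmd, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}
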