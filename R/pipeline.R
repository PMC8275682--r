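#' @title Full three-stage analysis pipeline
#'
#' @description
#' Orchestrates the evidence chain from one configuration: mean-changepoint
#' segmentations of SSB, recruitment and productivity; structural-break fits
#' of the six bivariate relationships; and the stochastic cusp fit with
#' per-year stability classification and validation.  Reports are returned
#' as one `analysis_report` and, when an output directory is given, written
#' as machine-readable JSON plus per-stage CSV tables.
#'
#' @name pipeline
NULL

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `input` (CSV path) or `fixture` (currently `"tipping"`),
#' `seed`, `min_segment_length`, `max_breaks`, `min_break_fraction`,
#' `relationships` (list of two-element response/covariate pairs),
#' `cusp` (`state`, `asym`, `bifur` variable names), `reference`
#' (`b_lim`, `msy_b_trigger`, `f_msy`, `f_pa`).  Every analysis constant is
#' a default here, never hard-coded downstream.
#'
#' @param path YAML file path.
#' @return a config list as accepted by [run_full_analysis()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

normalize_config <- function(config) {
  defaults <- list(seed = 1L, min_segment_length = 10L, max_breaks = 5L,
                   min_break_fraction = 0.15,
                   relationships = default_relationships(),
                   cusp = list(state = "ssb", asym = "scaled_pressure",
                               bifur = "sst"),
                   series = c("ssb", "recruitment", "productivity"))
  # plain name-wise overwrite (modifyList would merge nested unnamed lists)
  cfg <- defaults
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg$relationships <- lapply(cfg$relationships, unlist)
  known <- c("year", "ssb", "recruitment", "f", "sst", "productivity",
             "scaled_pressure")
  for (pair in cfg$relationships) {
    bad <- setdiff(pair, known)
    if (length(bad) > 0) {
      stop("config schema error: unknown relationship variable '",
           bad[1], "'", call. = FALSE)
    }
  }
  bad <- setdiff(unlist(cfg$cusp), known)
  if (length(bad) > 0) {
    stop("config schema error: unknown cusp variable '", bad[1], "'",
         call. = FALSE)
  }
  bad <- setdiff(cfg$series, known)
  if (length(bad) > 0) {
    stop("config schema error: unknown series '", bad[1], "'", call. = FALSE)
  }
  cfg
}

load_config_table <- function(cfg) {
  if (!is.null(cfg$input)) {
    read_stock_csv(cfg$input, cfg$column_map)
  } else if (!is.null(cfg$fixture)) {
    if (cfg$fixture != "tipping") {
      stop("config schema error: unknown fixture '", cfg$fixture, "'",
           call. = FALSE)
    }
    make_tipping_fixture(seed = cfg$seed)
  } else {
    stop("config schema error: need either 'input' or 'fixture'",
         call. = FALSE)
  }
}

#' Run the full three-stage analysis
#'
#' Validates the configuration first (no outputs are written on a schema
#' error), loads or generates the input table, then runs changepoints,
#' breakpoints and the cusp stage in order.
#'
#' @param config a config list (see [read_pipeline_config()]) or a YAML
#'   path.
#' @param out_dir optional directory; when given, `report.json` and
#'   per-stage CSVs are written there.
#' @return an `analysis_report`: `segmentations` (one per analysed series),
#'   `relationship_fits` (six `breakpoint_fit`s), `cusp`
#'   (fit, alternatives, validation), `table`, and `provenance`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- normalize_config(config)
  table <- load_config_table(cfg)
  acfg <- analysis_config(min_segment_length = cfg$min_segment_length,
                          max_breaks = cfg$max_breaks,
                          min_break_fraction = cfg$min_break_fraction,
                          seed = cfg$seed,
                          relationships = cfg$relationships)

  penalty <- aic_penalty()
  segmentations <- lapply(cfg$series, function(v) {
    pelt_mean(table[[v]], penalty = penalty,
              min_segment_length = acfg$min_segment_length,
              years = table$year)
  })
  names(segmentations) <- cfg$series

  relationship_fits <- fit_relationships(table, acfg)

  fit <- fit_cusp(table, cfg$cusp$state, cfg$cusp$asym, cfg$cusp$bifur)
  alts <- fit_alternatives(table, cfg$cusp$state, cfg$cusp$asym,
                           cfg$cusp$bifur)
  validation <- validate_cusp(fit, alts, seed = cfg$seed)

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  report <- structure(list(
    table = table,
    segmentations = segmentations,
    relationship_fits = relationship_fits,
    cusp = list(fit = fit, alternatives = alts, validation = validation),
    provenance = list(config = cfg, config_hash = unname(tools::md5sum(tf)),
                      seed = cfg$seed,
                      version = as.character(utils::packageVersion("codtip")),
                      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "analysis_report")
  unlink(tf)

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

report_json_list <- function(report) {
  seg <- lapply(report$segmentations, function(s) {
    list(penalty = s$penalty, changepoint_years = s$changepoint_years,
         segment_means = s$segment_means, cost = s$total_cost)
  })
  rel <- lapply(report$relationship_fits, function(f) {
    jsonlite::fromJSON(breakpoint_json(f), simplifyVector = FALSE)
  })
  v <- report$cusp$validation
  list(
    segmentations = seg,
    relationships = rel,
    cusp = list(
      coefficients = as.list(report$cusp$fit$coefficients),
      loglik = report$cusp$fit$loglik,
      converged = report$cusp$fit$converged,
      n_bistable = report$cusp$fit$n_bistable,
      per_year = report$cusp$fit$per_year,
      validation = list(omega1_significant = v$omega1_significant,
                        p_omega1 = v$p_omega1,
                        pct_in_cusp = v$pct_in_cusp,
                        pseudo_r2 = v$pseudo_r2,
                        aic_cusp = v$aic_cusp, aic_linear = v$aic_linear,
                        aic_logistic = v$aic_logistic,
                        verdict = v$verdict)),
    provenance = report$provenance[c("config", "config_hash", "seed",
                                     "version")]
  )
}

#' Write an analysis report to disk
#'
#' `report.json` (timestamp-free, byte-stable under a fixed config and
#' seed), `series.csv`, `per_year_states.csv` and `regime_summary.csv`.
#'
#' @param report an `analysis_report`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_json_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  utils::write.csv(as.data.frame(report$table),
                   file.path(out_dir, "series.csv"), row.names = FALSE)
  utils::write.csv(report$cusp$fit$per_year,
                   file.path(out_dir, "per_year_states.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize_regimes(report),
                   file.path(out_dir, "regime_summary.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Per-regime summary with each variable scaled to its maximum regime mean
#'
#' Regimes are the segments of the SSB changepoint segmentation.  For each
#' regime the means of SSB, recruitment, productivity, F and F/R are
#' reported, each variable divided by its largest regime mean so the
#' highest value is 1 (which preserves the within-variable ordering of
#' regimes).
#'
#' @param report an `analysis_report` with an `ssb` segmentation.
#' @return data.frame, one row per regime.
#' @export
summarize_regimes <- function(report) {
  seg <- report$segmentations$ssb
  stopifnot(!is.null(seg))
  table <- report$table
  regime_of <- findInterval(table$year, seg$segment_first_year)
  vars <- c("ssb", "recruitment", "productivity", "f", "scaled_pressure")
  means <- sapply(vars, function(v) {
    tapply(table[[v]], regime_of, mean)
  })
  scaled <- sweep(as.matrix(means), 2L, apply(means, 2L, max), "/")
  out <- data.frame(regime = seq_len(nrow(scaled)),
                    first_year = seg$segment_first_year,
                    last_year = seg$segment_last_year)
  cbind(out, as.data.frame(scaled))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Three-stage tipping-point analysis report\n")
  cat("== Changepoints ==\n")
  for (v in names(x$segmentations)) {
    s <- x$segmentations[[v]]
    cat("  ", v, ": ", s$m, " changepoint(s)",
        if (s$m > 0) paste0(" at ", paste(s$changepoint_years,
                                          collapse = ", ")),
        "\n", sep = "")
  }
  cat("== Structural breaks ==\n")
  for (nm in names(x$relationship_fits)) {
    f <- x$relationship_fits[[nm]]
    cat("  ", nm, ": ", f$m, " break(s)",
        if (f$m > 0) paste0(" after ", paste(f$break_years, collapse = ", ")),
        "\n", sep = "")
  }
  cat("== Cusp stage ==\n")
  print(x$cusp$fit)
  cat("  validation verdict:", x$cusp$validation$verdict, "\n")
  invisible(x)
}
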