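#' Annual stock-assessment series with derived pressure and productivity indices
#'
#' A `stock_series` is a validated data frame of annual stock-assessment
#' output: spawning stock biomass (SSB, tonnes), recruitment at age 1
#' (year-class strength, count in a user-chosen unit), instantaneous fishing
#' mortality F (per year) and mean sea surface temperature (SST, degrees C).
#' Two derived indices are always populated:
#'
#' * `productivity` = recruitment / SSB, recruits produced per unit spawning
#'   biomass — an index of the stock's reproductive output;
#' * `scaled_pressure` = F / recruitment, fishing mortality normalised by
#'   year-class strength — exploitation pressure relative to what the stock
#'   currently produces.
#'
#' Both indices are scale-covariant in the recruitment unit (thousands vs
#' millions): every downstream fit standardises its inputs internally, so the
#' unit choice cannot change any changepoint, breakpoint or state
#' classification.
#'
#' @param year integer vector of strictly consecutive calendar years.
#' @param ssb positive numeric, spawning stock biomass (tonnes).
#' @param recruitment positive numeric, age-1 abundance.
#' @param f non-negative numeric, fishing mortality (per year).
#' @param sst numeric, annual mean sea surface temperature (degrees C).
#' @return a data.frame of class `stock_series` with columns `year`, `ssb`,
#'   `recruitment`, `f`, `sst`, `productivity`, `scaled_pressure`, ordered by
#'   ascending year.
#' @export
stock_series <- function(year, ssb, recruitment, f, sst) {
  tab <- data.frame(year = as.integer(year), ssb = as.numeric(ssb),
                    recruitment = as.numeric(recruitment), f = as.numeric(f),
                    sst = as.numeric(sst))
  tab <- tab[order(tab$year), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("stock_series", "data.frame")
  validate_stock_series(derive_indices(tab))
}

#' Validate a stock series table
#'
#' Checks the invariants every downstream stage relies on: strictly
#' consecutive years, strictly positive SSB and recruitment, no missing
#' values, and derived columns exactly equal to the elementwise ratios of
#' their parents.
#'
#' @param table a `stock_series` (or coercible data frame with the required
#'   columns).
#' @return the table, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_stock_series <- function(table) {
  required <- c("year", "ssb", "recruitment", "f", "sst")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L) {
    stop("stock series format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(table[required])) {
    bad <- which(apply(is.na(table[required]), 1L, any))
    stop("stock series validation error: missing values in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dy <- diff(table$year)
  if (any(dy != 1L)) {
    gaps <- table$year[which(dy != 1L)] + 1L
    stop("stock series validation error: years not consecutive, gap at ",
         paste(gaps, collapse = ", "), call. = FALSE)
  }
  bad_pos <- which(table$ssb <= 0 | table$recruitment <= 0)
  if (length(bad_pos) > 0L) {
    stop("stock series validation error: nonpositive ssb or recruitment in ",
         "row(s) ", paste(bad_pos, collapse = ", "), " (year ",
         paste(table$year[bad_pos], collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(table$productivity)) {
    stopifnot(isTRUE(all.equal(table$productivity,
                               table$recruitment / table$ssb)))
  }
  if (!is.null(table$scaled_pressure)) {
    stopifnot(isTRUE(all.equal(table$scaled_pressure,
                               table$f / table$recruitment)))
  }
  invisible(table)
}

#' Populate the derived productivity and scaled-pressure columns
#'
#' `productivity` = recruitment/ssb and `scaled_pressure` = f/recruitment.
#' Idempotent: calling it twice changes nothing.
#'
#' @param table a stock series table with `ssb`, `recruitment`, `f` columns.
#' @return the table with derived columns (re)computed.
#' @export
derive_indices <- function(table) {
  if (any(table$recruitment == 0, na.rm = TRUE)) {
    stop("stock series validation error: zero recruitment, ",
         "scaled pressure F/R undefined", call. = FALSE)
  }
  table$productivity <- table$recruitment / table$ssb
  table$scaled_pressure <- table$f / table$recruitment
  if (!inherits(table, "stock_series")) {
    class(table) <- c("stock_series", "data.frame")
  }
  table
}

#' Read a stock series from CSV
#'
#' Expects an RFC-4180 CSV with a header row.  `column_map` renames input
#' headers to the canonical names, e.g.
#' `c(year = "Year", ssb = "SSB", recruitment = "R", f = "F", sst = "SST")`.
#'
#' @param path path to the CSV file.
#' @param column_map named character vector mapping canonical names
#'   (`year`, `ssb`, `recruitment`, `f`, `sst`) to the file's headers;
#'   `NULL` if the file already uses canonical names.
#' @return a validated `stock_series`.
#' @export
read_stock_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    absent <- column_map[!column_map %in% names(raw)]
    if (length(absent) > 0L) {
      stop("stock series format error: missing column(s) ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  required <- c("year", "ssb", "recruitment", "f", "sst")
  absent <- setdiff(required, names(raw))
  if (length(absent) > 0L) {
    stop("stock series format error: missing column(s) ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  yr <- suppressWarnings(as.integer(raw$year))
  if (anyNA(yr)) {
    stop("stock series format error: year column not parseable as integers",
         call. = FALSE)
  }
  stock_series(yr, raw$ssb, raw$recruitment, raw$f, raw$sst)
}

#' Write a stock series to CSV (canonical dialect)
#'
#' Writes the observed columns only; derived columns are recomputed on read
#' so a write/read round trip reproduces the table exactly.
#'
#' @param table a `stock_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stock_csv <- function(table, path) {
  utils::write.csv(table[c("year", "ssb", "recruitment", "f", "sst")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' ICES-style reference levels for report annotation
#'
#' Biomass and fishing-mortality reference points (B_lim, MSY B_trigger,
#' F_MSY, F_pa) used descriptively when annotating reports; they enter no
#' computation.
#'
#' @param b_lim limit biomass reference point (tonnes).
#' @param msy_b_trigger MSY trigger biomass (tonnes); must be >= `b_lim`.
#' @param f_msy fishing mortality target (per year).
#' @param f_pa precautionary fishing mortality (per year).
#' @return a `reference_levels` list.
#' @export
reference_levels <- function(b_lim, msy_b_trigger, f_msy, f_pa) {
  vals <- c(b_lim = b_lim, msy_b_trigger = msy_b_trigger,
            f_msy = f_msy, f_pa = f_pa)
  if (any(vals <= 0)) stop("reference levels must be strictly positive",
                           call. = FALSE)
  if (b_lim > msy_b_trigger) stop("b_lim must not exceed msy_b_trigger",
                                  call. = FALSE)
  structure(as.list(vals), class = "reference_levels")
}

#' Analysis configuration
#'
#' Bundles the tunable constants of the three-stage analysis.  Defaults are
#' the study conditions: a 10-year minimum regime length for the changepoint
#' stage, an AIC penalty, a 15%-of-n minimum breakpoint segment, and the six
#' bivariate relationships of the breakpoint stage.
#'
#' @param min_segment_length minimum changepoint segment length in years
#'   (default 10).
#' @param penalty_kind changepoint penalty rule; only `"aic"` is defined.
#' @param max_breaks maximum number of structural breaks per relationship.
#' @param min_break_fraction minimum breakpoint segment as a fraction of n
#'   (default 0.15); must lie in (0, 0.5).
#' @param seed integer seed recorded in reports.
#' @param relationships list of `c(response, covariate)` pairs; the default
#'   six are SSB~F, SSB~F/R, R~SSB, R~SST, R/SSB~SSB, R/SSB~SST.
#' @param reference optional `reference_levels` for annotation.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(min_segment_length = 10L,
                            penalty_kind = "aic",
                            max_breaks = 5L,
                            min_break_fraction = 0.15,
                            seed = 1L,
                            relationships = default_relationships(),
                            reference = NULL) {
  if (min_segment_length < 2L) stop("min_segment_length must be >= 2",
                                    call. = FALSE)
  if (min_break_fraction <= 0 || min_break_fraction >= 0.5) {
    stop("min_break_fraction must lie in (0, 0.5)", call. = FALSE)
  }
  penalty_kind <- match.arg(penalty_kind, "aic")
  structure(list(min_segment_length = as.integer(min_segment_length),
                 penalty_kind = penalty_kind,
                 max_breaks = as.integer(max_breaks),
                 min_break_fraction = min_break_fraction,
                 seed = as.integer(seed),
                 relationships = relationships,
                 reference = reference),
            class = "analysis_config")
}

#' The six default bivariate relationships of the breakpoint stage
#'
#' @return list of `c(response, covariate)` character pairs.
#' @export
default_relationships <- function() {
  list(c("ssb", "f"),
       c("ssb", "scaled_pressure"),
       c("recruitment", "ssb"),
       c("recruitment", "sst"),
       c("productivity", "ssb"),
       c("productivity", "sst"))
}
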