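# Data model for longitudinal item-level assessments plus a baseline
# covariate table. Visits are long ("tidy"): one row per recorded score,
# with an explicit medication-state column so the duplicated ON/OFF motor
# exam is first-class. Missing scores are simply absent rows, never zero.

#' Canonical baseline covariate column names
#'
#' One column per candidate baseline predictor, plus
#' `med_initiation_month` (months from enrollment to initiation of
#' symptomatic therapy; NA when never initiated during follow-up).
#'
#' @return character vector of column names.
#' @export
covariate_columns <- function() {
  c("participant_id", "age", "sex", "site", "bmi", "orth_sys_bp_change",
    "disease_duration", "updrs_total", "hy_stage", "pigd", "tremor",
    "se_adl", "moca", "scopa_aut_total", "upsit_raw", "anosmia", "ess",
    "rbdsq", "gds15", "stai_total", "sbr_striatum", "sbr_putamen", "urate",
    "csf_asyn", "csf_hb", "csf_abeta", "csf_ttau", "csf_ptau",
    "csf_ttau_abeta_ratio", "med_initiation_month")
}

new_study <- function(visits, covariates, validation = list()) {
  stopifnot(is.data.frame(visits), is.data.frame(covariates))
  missing_cov <- setdiff(unique(visits$participant_id),
                         covariates$participant_id)
  if (length(missing_cov) > 0)
    stop("participants present in visits but absent from covariates: ",
         paste(utils::head(missing_cov, 5), collapse = ", "))
  if (anyDuplicated(covariates$participant_id))
    stop("covariate table must have one row per participant")
  structure(list(visits = visits, covariates = covariates,
                 validation = validation),
            class = "pdm_study")
}

#' @export
print.pdm_study <- function(x, ...) {
  cat("pdm_study:", nrow(x$covariates), "participants,",
      nrow(unique(x$visits[c("participant_id", "scheduled_month")])),
      "visits,", nrow(x$visits), "recorded scores\n")
  if (length(x$validation$unknown_items))
    cat("  unknown item codes:",
        paste(x$validation$unknown_items, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a study dataset from in-memory tables
#'
#' Programmatic counterpart of [read_study_tables()] (no file round-trip,
#' no range validation). Visits must be long format with columns
#' `participant_id`, `scheduled_month`, `actual_month`, `item_code`,
#' `state`, `value`.
#'
#' @param visits long-format visit data.frame.
#' @param covariates baseline covariate data.frame (one row per
#'   participant; must cover every participant in `visits`).
#' @return a `pdm_study`.
#' @export
study_dataset <- function(visits, covariates) {
  if (!"actual_month" %in% names(visits))
    visits$actual_month <- as.numeric(visits$scheduled_month)
  if (!"state" %in% names(visits)) visits$state <- NA_character_
  cols <- c("participant_id", "scheduled_month", "actual_month",
            "item_code", "state", "value")
  new_study(visits[cols], covariates)
}

#' Read visit and covariate tables
#'
#' The visits file is long-format CSV with columns `participant_id`,
#' `scheduled_month`, `actual_month`, `item_code`, `state`, `value`
#' (`state` in OFF/ON or empty). The covariates file is wide, one row per
#' participant, using [covariate_columns()] names. Instrument ranges are
#' enforced at parse time (fail fast); set `enforce_ranges = FALSE` to
#' downgrade range violations to report entries.
#'
#' @param visits_path,covariates_path CSV file paths.
#' @param enforce_ranges error on out-of-range scores (default TRUE).
#' @return a `pdm_study`: list with `visits`, `covariates`, `validation`
#'   (unknown item codes, range flags).
#' @export
read_study_tables <- function(visits_path, covariates_path,
                              enforce_ranges = TRUE) {
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE,
                            colClasses = c(participant_id = "character"))
  need <- c("participant_id", "scheduled_month", "actual_month",
            "item_code", "state", "value")
  if (!all(need %in% names(visits)))
    stop("visits file lacks required columns: ",
         paste(setdiff(need, names(visits)), collapse = ", "))
  visits <- visits[need]
  visits$state[is.na(visits$state) | visits$state == ""] <- NA_character_
  bad_state <- which(!is.na(visits$state) & !visits$state %in% c("OFF", "ON"))
  if (length(bad_state))
    stop("malformed state at data row(s) ",
         paste(utils::head(bad_state, 5), collapse = ", "))
  visits$scheduled_month <- suppressWarnings(as.integer(visits$scheduled_month))
  visits$value <- suppressWarnings(as.numeric(visits$value))
  visits$actual_month <- suppressWarnings(as.numeric(visits$actual_month))
  visits$actual_month[is.na(visits$actual_month)] <-
    visits$scheduled_month[is.na(visits$actual_month)]
  bad <- which(is.na(visits$scheduled_month) | is.na(visits$value))
  if (length(bad))
    stop("malformed visit row(s) (non-numeric month or value) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  off_grid <- which(!visits$scheduled_month %in% visit_grid())
  if (length(off_grid))
    stop("scheduled_month outside the per-protocol grid at data row(s) ",
         paste(utils::head(off_grid, 5), collapse = ", "))
  if (any(visits$actual_month < 0)) stop("actual_month must be nonnegative")

  dup <- duplicated(visits[c("participant_id", "scheduled_month",
                             "item_code", "state")])
  if (any(dup))
    stop("duplicate (participant, month, item, state) at data row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "))

  codes <- item_code_table()
  unknown <- sort(setdiff(unique(visits$item_code), codes$code))
  i <- match(visits$item_code, codes$code)
  known <- !is.na(i)
  lo <- codes$min[i]; hi <- codes$max[i]; step <- codes$step[i]
  out_rng <- known & (visits$value < lo | visits$value > hi |
                        (!is.na(step) & step > 1 &
                           visits$value %% step != 0))
  state_on_nonmotor <- known & !is.na(visits$state) & !codes$motor_state[i]
  range_flags <- visits[out_rng | state_on_nonmotor, , drop = FALSE]
  if (nrow(range_flags) && enforce_ranges)
    stop("out-of-range or mis-stated scores; first offenders:\n",
         paste(utils::capture.output(utils::head(range_flags, 5)),
               collapse = "\n"))

  covariates <- utils::read.csv(covariates_path, stringsAsFactors = FALSE,
                                colClasses = c(participant_id = "character"))
  if (!"participant_id" %in% names(covariates))
    stop("covariates file lacks participant_id")
  if ("med_initiation_month" %in% names(covariates) &&
      any(covariates$med_initiation_month < 0, na.rm = TRUE))
    stop("med_initiation_month must be nonnegative when present")
  new_study(visits, covariates,
            validation = list(unknown_items = unknown,
                              range_flags = range_flags))
}

#' Write a study dataset back to the two CSV tables
#'
#' Inverse of [read_study_tables()]: `read(write(ds))` reproduces the
#' dataset, including its missingness pattern.
#'
#' @param ds a `pdm_study`.
#' @param visits_path,covariates_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_study_tables <- function(ds, visits_path, covariates_path) {
  utils::write.csv(ds$visits, visits_path, row.names = FALSE, na = "")
  utils::write.csv(ds$covariates, covariates_path, row.names = FALSE, na = "")
  invisible(c(visits_path, covariates_path))
}

#' Visit-schedule validation report
#'
#' Report-only (never fatal): per participant, scheduled grid visits missing
#' before their last observed visit, and items recorded at visits where the
#' item's schedule class says it is not assessed (e.g. the annual-only MoCA
#' at a month-3 interim visit).
#'
#' @param ds a `pdm_study`.
#' @return list of class `pdm_schedule_report` with data.frames
#'   `missing_visits` and `off_schedule_items`.
#' @export
validate_schedule <- function(ds) {
  visits <- ds$visits
  vv <- unique(visits[c("participant_id", "scheduled_month")])
  miss <- do.call(rbind, lapply(split(vv$scheduled_month, vv$participant_id),
    function(m) {
      gap <- setdiff(visit_grid()[visit_grid() <= max(m)], m)
      if (length(gap)) data.frame(scheduled_month = gap) else NULL
    }))
  missing_visits <- if (is.null(miss)) {
    data.frame(participant_id = character(), scheduled_month = integer())
  } else {
    data.frame(participant_id = sub("\\.[0-9]+$", "", rownames(miss)),
               scheduled_month = miss$scheduled_month, row.names = NULL)
  }
  codes <- item_code_table()
  sc <- codes$schedule_class[match(visits$item_code, codes$code)]
  off <- !is.na(sc) & visits$scheduled_month != 0 &
    !mapply(function(s, m) m %in% schedule_months(s), sc,
            visits$scheduled_month)
  off_schedule_items <- visits[off, c("participant_id", "scheduled_month",
                                      "item_code"), drop = FALSE]
  rownames(off_schedule_items) <- NULL
  structure(list(missing_visits = missing_visits,
                 off_schedule_items = off_schedule_items),
            class = "pdm_schedule_report")
}

#' @export
print.pdm_schedule_report <- function(x, ...) {
  cat("schedule report:", nrow(x$missing_visits), "missing visits,",
      nrow(x$off_schedule_items), "off-schedule item recordings\n")
  invisible(x)
}

#' Write a schedule report as JSON
#' @param report a `pdm_schedule_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_schedule_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}
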