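# Shared fixtures, built in code. Item shorthand: names are item codes,
# optionally suffixed "|OFF" / "|ON" for motor-state scores.

`%||%` <- function(a, b) if (is.null(a)) b else a

long_rows <- function(id, month, items, actual = month) {
  if (length(items) == 0) {
    return(data.frame(participant_id = character(), scheduled_month = integer(),
                      actual_month = numeric(), item_code = character(),
                      state = character(), value = numeric()))
  }
  parts <- strsplit(names(items), "|", fixed = TRUE)
  data.frame(participant_id = id, scheduled_month = month,
             actual_month = actual,
             item_code = vapply(parts, `[`, "", 1),
             state = vapply(parts, function(p)
               if (length(p) > 1) p[2] else NA_character_, ""),
             value = as.numeric(unlist(items)),
             stringsAsFactors = FALSE)
}

# visits: list of list(id =, month =, items = c(...), actual = )
build_study <- function(visits, covariates = NULL) {
  rows <- do.call(rbind, lapply(visits, function(v)
    long_rows(v$id, v$month, v$items,
              actual = if (is.null(v$actual)) v$month else v$actual)))
  if (is.null(covariates))
    covariates <- data.frame(participant_id = unique(rows$participant_id),
                             stringsAsFactors = FALSE)
  study_dataset(rows, covariates)
}

# A quiet baseline visit: nothing anywhere near any threshold.
normal_items <- function() {
  c(UPDRS_2_12 = 0, UPDRS_2_13 = 0, "UPDRS_3_10|OFF" = 1, "UPDRS_3_10|ON" = 0,
    MOCA_TOTAL = 28, SE_ADL = 90, SCOPA_16 = 0, UPDRS_1_1 = 0)
}

REG <- build_registry()

# one moderately sized item-level cohort shared across test files
SHARED_SIM <- simulate_cohort(sim_config(n = 180, seed = 101), REG)
SHARED_REC_ANNUAL <- derive_endpoint(SHARED_SIM$data, REG, "annual_visits")
SHARED_REC_ALL <- derive_endpoint(SHARED_SIM$data, REG, "all_visits")
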