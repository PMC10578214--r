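#' Published item code table
#'
#' Every assessment item the milestone framework consumes, addressed by a
#' namespaced string code. Scores are item-level totals as exported by the
#' study database; the package never re-scores instruments from sub-items.
#'
#' Columns:
#' \describe{
#'   \item{code}{namespaced item code, e.g. \code{UPDRS_3_10}, \code{MOCA_TOTAL}}
#'   \item{instrument}{instrument the item belongs to}
#'   \item{min,max}{documented instrument range (inclusive)}
#'   \item{step}{score granularity (5 for Schwab & England, 1 for ordinal
#'     items, NA for continuous measures)}
#'   \item{motor_state}{TRUE when the item is scored separately in the
#'     medication OFF and ON states (MDS-UPDRS Part III motor exam and
#'     Hoehn & Yahr stage)}
#'   \item{schedule_class}{most permissive visit-schedule class among the
#'     milestones referencing the item: \code{"standard"} (quarterly in year
#'     one, semiannual thereafter), \code{"six_month_then_annual"},
#'     \code{"annual_only"}}
#' }
#'
#' @return data.frame with one row per recognised item code.
#' @export
item_code_table <- function() {
  row <- function(code, instrument, min, max, step = 1, motor_state = FALSE,
                  schedule_class = "standard") {
    data.frame(code = code, instrument = instrument, min = min, max = max,
               step = step, motor_state = motor_state,
               schedule_class = schedule_class, stringsAsFactors = FALSE)
  }
  updrs <- function(code) row(code, "MDS-UPDRS", 0, 4)
  rbind(
    # Part I (non-motor experiences of daily living)
    updrs("UPDRS_1_1"), updrs("UPDRS_1_2"), updrs("UPDRS_1_5"),
    row("UPDRS_1_10", "MDS-UPDRS", 0, 4, schedule_class = "six_month_then_annual"),
    updrs("UPDRS_1_12"),
    # Part II (motor experiences of daily living)
    updrs("UPDRS_2_3"), updrs("UPDRS_2_4"), updrs("UPDRS_2_5"),
    updrs("UPDRS_2_6"), updrs("UPDRS_2_12"), updrs("UPDRS_2_13"),
    # Part III motor exam, scored per medication state
    row("UPDRS_3_1",  "MDS-UPDRS", 0, 4, motor_state = TRUE),
    row("UPDRS_3_10", "MDS-UPDRS", 0, 4, motor_state = TRUE),
    row("UPDRS_3_11", "MDS-UPDRS", 0, 4, motor_state = TRUE),
    row("UPDRS_3_12", "MDS-UPDRS", 0, 4, motor_state = TRUE),
    # Part IV (motor complications)
    updrs("UPDRS_4_1"), updrs("UPDRS_4_2"), updrs("UPDRS_4_4"),
    updrs("UPDRS_4_5"),
    row("HY", "Hoehn & Yahr", 0, 5, motor_state = TRUE),
    row("SE_ADL", "Schwab & England", 0, 100, step = 5),
    row("MOCA_TOTAL", "MoCA", 0, 30, schedule_class = "annual_only"),
    row("SCOPA_8",  "SCOPA-AUT", 0, 3, schedule_class = "six_month_then_annual"),
    row("SCOPA_9",  "SCOPA-AUT", 0, 3, schedule_class = "six_month_then_annual"),
    row("SCOPA_15", "SCOPA-AUT", 0, 3, schedule_class = "six_month_then_annual"),
    row("SCOPA_16", "SCOPA-AUT", 0, 3, schedule_class = "six_month_then_annual"),
    # Blood pressure by position (mm Hg)
    row("BP_SYS_SUPINE",   "Blood pressure", 50, 300, step = NA,
        schedule_class = "six_month_then_annual"),
    row("BP_DIA_SUPINE",   "Blood pressure", 20, 200, step = NA,
        schedule_class = "six_month_then_annual"),
    row("BP_SYS_SITTING",  "Blood pressure", 50, 300, step = NA,
        schedule_class = "six_month_then_annual"),
    row("BP_DIA_SITTING",  "Blood pressure", 20, 200, step = NA,
        schedule_class = "six_month_then_annual"),
    row("BP_SYS_STANDING", "Blood pressure", 50, 300, step = NA,
        schedule_class = "six_month_then_annual"),
    row("BP_DIA_STANDING", "Blood pressure", 20, 200, step = NA,
        schedule_class = "six_month_then_annual"),
    # Cognitive battery, standardized per published norms (z-scores)
    row("COG_MEM_HVLT_RECALL", "Cognitive battery", -10, 10, step = NA,
        schedule_class = "annual_only"),
    row("COG_MEM_HVLT_RECOG",  "Cognitive battery", -10, 10, step = NA,
        schedule_class = "annual_only"),
    row("COG_VIS_JLO",         "Cognitive battery", -10, 10, step = NA,
        schedule_class = "annual_only"),
    row("COG_SPEED_SDMT",      "Cognitive battery", -10, 10, step = NA,
        schedule_class = "annual_only"),
    row("COG_EXEC_LNS",        "Cognitive battery", -10, 10, step = NA,
        schedule_class = "annual_only"),
    row("COG_EXEC_FLUENCY",    "Cognitive battery", -10, 10, step = NA,
        schedule_class = "annual_only"),
    # Site-investigator cognitive categorization (0 = no, 1 = yes)
    row("FLAG_PDD", "Investigator assessment", 0, 1,
        schedule_class = "annual_only"),
    row("FLAG_COG_FUNC_IMPAIR", "Investigator assessment", 0, 1,
        schedule_class = "annual_only")
  )
}

#' Cognitive battery tests grouped by the four assessed domains
#' @return named list mapping domain name to item codes.
#' @export
cognitive_domains <- function() {
  list(
    memory        = c("COG_MEM_HVLT_RECALL", "COG_MEM_HVLT_RECOG"),
    visuospatial  = "COG_VIS_JLO",
    speed_attention = "COG_SPEED_SDMT",
    executive     = c("COG_EXEC_LNS", "COG_EXEC_FLUENCY")
  )
}

#' Per-protocol visit grid (months from enrollment)
#' @return integer vector: baseline, quarterly in year one, semiannual
#'   through five years.
#' @export
visit_grid <- function() c(0L, 3L, 6L, 9L, 12L, 18L, 24L, 30L, 36L, 42L, 48L, 54L, 60L)

#' Annual follow-up visits (months)
#' @return integer vector of the five annual visits.
#' @export
annual_visits <- function() c(12L, 24L, 36L, 48L, 60L)

#' Months at which a schedule class is assessed (excluding baseline)
#' @param schedule_class one of "standard", "six_month_then_annual",
#'   "annual_only".
#' @return integer vector of follow-up months.
#' @export
schedule_months <- function(schedule_class) {
  switch(schedule_class,
    standard = setdiff(visit_grid(), 0L),
    six_month_then_annual = c(6L, annual_visits()),
    annual_only = annual_visits(),
    stop("unknown schedule class: ", schedule_class)
  )
}
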