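# Independent brute-force milestone evaluator. Deliberately written as
# literal scalar re-reads of the published criteria table, one milestone at
# a time, sharing no code with the package's engine. A visit is a named
# list: items (named numeric, missing absent), off/on (named numeric for
# motor-exam scores per state), flags, and cognitive z-scores are ordinary
# items. Missing anywhere means "criterion not met".

oracle_get <- function(visit, code) {
  v <- visit$items[[code]]
  if (is.null(v)) NA_real_ else v
}
oracle_state <- function(visit, code, state) {
  v <- visit[[tolower(state)]][[code]]
  if (is.null(v)) NA_real_ else v
}
# "(ON or OFF)": satisfied if either state's score (or a stateless score)
# meets the test
oracle_oo <- function(visit, code, test) {
  vals <- c(oracle_state(visit, code, "OFF"),
            oracle_state(visit, code, "ON"), oracle_get(visit, code))
  any(!is.na(vals) & test(vals))
}
oracle_ge <- function(x, k) !is.na(x) & x >= k

oracle_evaluate <- function(visit, cutoff = -1.5) {
  g <- function(code) oracle_get(visit, code)
  hits <- character()
  add <- function(id, cond) if (isTRUE(cond)) c(hits, id) else hits

  # Domain 1: walking and balance
  hits <- add("walking_balance", oracle_ge(g("UPDRS_2_12"), 3))
  hits <- add("freezing", oracle_ge(g("UPDRS_2_13"), 3))
  hits <- add("gait", oracle_oo(visit, "UPDRS_3_10", function(x) x >= 3))
  hits <- add("freezing_of_gait",
              oracle_oo(visit, "UPDRS_3_11", function(x) x == 4))
  hits <- add("postural_instability",
              oracle_oo(visit, "UPDRS_3_12", function(x) x >= 3))
  hits <- add("hoehn_yahr", oracle_oo(visit, "HY", function(x) x >= 4))
  # Domain 2: motor complications
  hits <- add("dyskinesias",
              oracle_ge(g("UPDRS_4_1"), 3) && oracle_ge(g("UPDRS_4_2"), 3))
  hits <- add("fluctuations_impact", oracle_ge(g("UPDRS_4_4"), 3))
  hits <- add("fluctuations_complexity", oracle_ge(g("UPDRS_4_5"), 3))
  # Domain 3: cognition
  hits <- add("cognitive_impairment_moca",
              !is.na(g("MOCA_TOTAL")) && g("MOCA_TOTAL") < 21)
  hits <- add("cognitive_impairment_updrs", oracle_ge(g("UPDRS_1_1"), 3))
  hits <- add("hallucinations", oracle_ge(g("UPDRS_1_2"), 3))
  hits <- add("apathy", oracle_ge(g("UPDRS_1_5"), 3))
  hits <- add("dementia_clinical",
              !is.na(g("FLAG_PDD")) && g("FLAG_PDD") == 1)
  # dementia composite: impairment (>=1 test at/below cutoff) on >=2 of the
  # four cognitive domains AND investigator functional impairment
  imp_dom <- 0
  for (tests in list(c("COG_MEM_HVLT_RECALL", "COG_MEM_HVLT_RECOG"),
                     "COG_VIS_JLO", "COG_SPEED_SDMT",
                     c("COG_EXEC_LNS", "COG_EXEC_FLUENCY"))) {
    impaired <- FALSE
    for (code in tests) {
      z <- g(code)
      if (!is.na(z) && z <= cutoff) impaired <- TRUE
    }
    if (impaired) imp_dom <- imp_dom + 1
  }
  hits <- add("dementia_composite",
              imp_dom >= 2 && !is.na(g("FLAG_COG_FUNC_IMPAIR")) &&
                g("FLAG_COG_FUNC_IMPAIR") == 1)
  # Domain 4: autonomic dysfunction
  hits <- add("urinary_incontinence",
              oracle_ge(g("UPDRS_1_10"), 3) &&
                (oracle_ge(g("SCOPA_8"), 2) || oracle_ge(g("SCOPA_9"), 2)))
  sys_drop <- g("BP_SYS_SITTING") - g("BP_SYS_STANDING")
  dia_drop <- g("BP_DIA_SITTING") - g("BP_DIA_STANDING")
  hits <- add("orthostatic_hypotension",
              oracle_ge(g("SCOPA_15"), 2) &&
                !is.na(sys_drop) && sys_drop >= 20 &&
                !is.na(dia_drop) && dia_drop >= 10)
  hits <- add("syncope_updrs",
              !is.na(g("UPDRS_1_12")) && g("UPDRS_1_12") == 4)
  hits <- add("syncope_scopa", oracle_ge(g("SCOPA_16"), 1))
  # Domain 5: functional dependence
  hits <- add("schwab_england", !is.na(g("SE_ADL")) && g("SE_ADL") < 80)
  # Domain 6: activities of daily living
  hits <- add("choking", oracle_ge(g("UPDRS_2_3"), 3))
  hits <- add("eating", oracle_ge(g("UPDRS_2_4"), 3))
  hits <- add("dressing", oracle_ge(g("UPDRS_2_5"), 3))
  hits <- add("hygiene", oracle_ge(g("UPDRS_2_6"), 3))
  hits <- add("speech", oracle_oo(visit, "UPDRS_3_1", function(x) x >= 3))
  hits
}

# literal re-read of the schedule classes
oracle_assessable <- function(month) {
  if (month == 0) return(oracle_all_ids())
  standard <- c(3, 6, 9, 12, 18, 24, 30, 36, 42, 48, 54, 60)
  sixm <- c(6, 12, 24, 36, 48, 60)
  annual <- c(12, 24, 36, 48, 60)
  ids <- character()
  if (month %in% standard)
    ids <- c(ids, "walking_balance", "freezing", "gait", "freezing_of_gait",
             "postural_instability", "hoehn_yahr", "dyskinesias",
             "fluctuations_impact", "fluctuations_complexity",
             "cognitive_impairment_updrs", "hallucinations", "apathy",
             "syncope_updrs", "schwab_england", "choking", "eating",
             "dressing", "hygiene", "speech")
  if (month %in% sixm)
    ids <- c(ids, "urinary_incontinence", "orthostatic_hypotension",
             "syncope_scopa")
  if (month %in% annual)
    ids <- c(ids, "cognitive_impairment_moca", "dementia_clinical",
             "dementia_composite")
  ids
}
oracle_all_ids <- function() {
  c("walking_balance", "freezing", "gait", "freezing_of_gait",
    "postural_instability", "hoehn_yahr", "dyskinesias",
    "fluctuations_impact", "fluctuations_complexity",
    "cognitive_impairment_moca", "cognitive_impairment_updrs",
    "hallucinations", "apathy", "dementia_clinical", "dementia_composite",
    "urinary_incontinence", "orthostatic_hypotension", "syncope_updrs",
    "syncope_scopa", "schwab_england", "choking", "eating", "dressing",
    "hygiene", "speech")
}

# Random visit generator for the engine-vs-oracle comparison: scores drawn
# uniformly over full instrument ranges, items present independently.
random_visit_items <- function(p_present = 0.7) {
  codes <- pdmilestones::item_code_table()
  items <- list(); off <- list(); on <- list()
  for (k in seq_len(nrow(codes))) {
    code <- codes$code[k]
    draw <- function() {
      if (code %in% c("FLAG_PDD", "FLAG_COG_FUNC_IMPAIR"))
        return(sample(0:1, 1))
      if (startsWith(code, "BP_")) return(round(runif(1, 70, 200)))
      if (startsWith(code, "COG_")) return(round(runif(1, -4, 3), 2))
      if (code == "SE_ADL") return(sample(seq(0, 100, 5), 1))
      sample(codes$min[k]:codes$max[k], 1)
    }
    if (codes$motor_state[k]) {
      if (runif(1) < p_present) off[[code]] <- draw()
      if (runif(1) < p_present) on[[code]] <- draw()
    } else if (runif(1) < p_present) {
      items[[code]] <- draw()
    }
  }
  list(items = items, off = off, on = on)
}

visit_to_long <- function(visit, id, month) {
  rows <- list()
  if (length(visit$items))
    rows <- c(rows, list(long_rows(id, month, unlist(visit$items))))
  for (st in c("off", "on")) {
    v <- visit[[st]]
    if (length(v)) {
      nm <- paste0(names(v), "|", toupper(st))
      vv <- unlist(v); names(vv) <- nm
      rows <- c(rows, list(long_rows(id, month, vv)))
    }
  }
  do.call(rbind, rows)
}
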