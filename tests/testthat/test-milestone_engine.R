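test_that("registry has the documented structure", {
  expect_length(REG$milestones, 25)
  expect_setequal(unique(milestone_domains(REG)),
                  c("walking_balance", "motor_complications", "cognition",
                    "autonomic", "functional_dependence", "adl"))
  sc <- milestone_schedule_classes(REG)
  expect_setequal(names(sc)[sc == "annual_only"],
                  c("cognitive_impairment_moca", "dementia_clinical",
                    "dementia_composite"))
  expect_setequal(names(sc)[sc == "six_month_then_annual"],
                  c("urinary_incontinence", "orthostatic_hypotension",
                    "syncope_scopa"))
  expect_equal(sum(sc == "standard"), 19)
})

test_that("atoms honour the conservative missing-data and ON-or-OFF rules", {
  oo <- criterion_atom("UPDRS_3_10", ">=", 3, states = "on_or_off")
  expect_true(evaluate_atom(oo, long_rows("p", 12,
    c("UPDRS_3_10|OFF" = 3, "UPDRS_3_10|ON" = 1))))
  expect_true(evaluate_atom(oo, long_rows("p", 12, c("UPDRS_3_10|ON" = 4))))
  expect_false(evaluate_atom(oo, long_rows("p", 12, c(MOCA_TOTAL = 25))))

  moca <- criterion_atom("MOCA_TOTAL", "<", 21)
  expect_false(evaluate_atom(moca, long_rows("p", 12, c(SE_ADL = 90))))
  expect_true(evaluate_atom(moca, long_rows("p", 12, c(MOCA_TOTAL = 20))))

  drop20 <- bp_drop_atom("sys", "sitting", "standing", 20)
  expect_true(evaluate_atom(drop20, long_rows("p", 12,
    c(BP_SYS_SITTING = 130, BP_SYS_STANDING = 109))))
  expect_false(evaluate_atom(drop20, long_rows("p", 12,
    c(BP_SYS_SITTING = 130, BP_SYS_STANDING = 111))))
  expect_false(evaluate_atom(drop20, long_rows("p", 12,
    c(BP_SYS_SITTING = 130))))

  expect_error(criterion_atom("NOT_AN_ITEM", ">=", 3), "unknown item")
  expect_error(criterion_atom("MOCA_TOTAL", ">=", 35), "range")
})

test_that("conjunction milestones require every component", {
  # dyskinesias need >=3 on BOTH Part IV items
  hs <- evaluate_visit(REG, long_rows("p", 12,
    c(UPDRS_4_1 = 3, UPDRS_4_2 = 2)))
  expect_false("dyskinesias" %in% hs$hits)
  hs <- evaluate_visit(REG, long_rows("p", 12,
    c(UPDRS_4_1 = 3, UPDRS_4_2 = 3)))
  expect_true("dyskinesias" %in% hs$hits)

  # orthostatic hypotension: three-way conjunction
  hs <- evaluate_visit(REG, long_rows("p", 12,
    c(SCOPA_15 = 2, BP_SYS_SITTING = 140, BP_SYS_STANDING = 115,
      BP_DIA_SITTING = 85, BP_DIA_STANDING = 77)))
  expect_false("orthostatic_hypotension" %in% hs$hits)
  hs <- evaluate_visit(REG, long_rows("p", 12,
    c(SCOPA_15 = 2, BP_SYS_SITTING = 140, BP_SYS_STANDING = 115,
      BP_DIA_SITTING = 85, BP_DIA_STANDING = 74)))
  expect_true("orthostatic_hypotension" %in% hs$hits)

  # urinary incontinence: MDS-UPDRS 1.10 AND either SCOPA item
  hs <- evaluate_visit(REG, long_rows("p", 12, c(UPDRS_1_10 = 3)))
  expect_false("urinary_incontinence" %in% hs$hits)
  hs <- evaluate_visit(REG, long_rows("p", 12,
    c(UPDRS_1_10 = 3, SCOPA_9 = 2)))
  expect_true("urinary_incontinence" %in% hs$hits)
})

test_that("schedule restriction suppresses off-schedule milestones", {
  v <- long_rows("p", 3, c(MOCA_TOTAL = 20))
  expect_length(evaluate_visit(REG, v, restrict_to_schedule = TRUE)$hits, 0)
  expect_equal(evaluate_visit(REG, v, restrict_to_schedule = FALSE)$hits,
               "cognitive_impairment_moca")
  v12 <- long_rows("p", 12, c(MOCA_TOTAL = 20))
  expect_equal(evaluate_visit(REG, v12)$hits, "cognitive_impairment_moca")
  # baseline is always fully evaluated
  v0 <- long_rows("p", 0, c(MOCA_TOTAL = 20))
  expect_equal(evaluate_visit(REG, v0)$hits, "cognitive_impairment_moca")
})

test_that("dementia composite counts impaired domains and the flag", {
  base <- c(COG_MEM_HVLT_RECALL = -2, COG_VIS_JLO = -1.6,
            FLAG_COG_FUNC_IMPAIR = 1)
  expect_true("dementia_composite" %in%
                evaluate_visit(REG, long_rows("p", 12, base))$hits)
  # one impaired domain only
  one <- c(COG_MEM_HVLT_RECALL = -2, COG_MEM_HVLT_RECOG = -3,
           FLAG_COG_FUNC_IMPAIR = 1)
  expect_false("dementia_composite" %in%
                 evaluate_visit(REG, long_rows("p", 12, one))$hits)
  # no investigator flag -> conservative miss
  noflag <- c(COG_MEM_HVLT_RECALL = -2, COG_VIS_JLO = -1.6)
  expect_false("dementia_composite" %in%
                 evaluate_visit(REG, long_rows("p", 12, noflag))$hits)
  # configurable cutoff
  reg2 <- build_registry(cognitive_cutoff = -2.5)
  expect_false("dementia_composite" %in%
                 evaluate_visit(reg2, long_rows("p", 12, base))$hits)
})

test_that("an unremarkable visit hits nothing", {
  hs <- evaluate_visit(REG, long_rows("p", 12, normal_items()))
  expect_length(hs$hits, 0)
  expect_length(hs$domains_hit, 0)
})

test_that("engine agrees with the literal brute-force oracle", {
  set.seed(1203)
  n <- 2000
  months <- sample(visit_grid(), n, replace = TRUE)
  longs <- vector("list", n)
  expected <- vector("list", n)
  for (i in seq_len(n)) {
    v <- random_visit_items()
    longs[[i]] <- visit_to_long(v, sprintf("V%05d", i), months[i])
    expected[[i]] <- sort(intersect(oracle_evaluate(v),
                                    oracle_assessable(months[i])))
  }
  longs <- do.call(rbind, longs[!vapply(longs, is.null, NA)])
  hits <- evaluate_milestones(REG, longs, restrict_to_schedule = TRUE)
  got <- split(hits$milestone, hits$participant_id)
  for (i in seq_len(n)) {
    expect_identical(sort(unname(got[[sprintf("V%05d", i)]] %||% character())),
                     expected[[i]])
  }
})

test_that("missingness is monotone: deleting scores never adds hits", {
  set.seed(77)
  for (i in 1:60) {
    v <- random_visit_items(p_present = 0.9)
    lng <- visit_to_long(v, "p", 12)
    if (is.null(lng) || nrow(lng) < 2) next
    full <- evaluate_visit(REG, lng)$hits
    keep <- sample(nrow(lng), nrow(lng) - sample(1:3, 1))
    reduced <- evaluate_visit(REG, lng[keep, , drop = FALSE])$hits
    expect_true(all(reduced %in% full))
  }
})

test_that("registry serializes to auditable text and back", {
  path <- withr::local_tempfile(fileext = ".json")
  export_registry(REG, path)
  reg2 <- import_registry(path)
  expect_equal(milestone_domains(reg2), milestone_domains(REG))
  expect_equal(milestone_schedule_classes(reg2),
               milestone_schedule_classes(REG))
  # deserialized registry evaluates identically on random visits
  set.seed(9)
  for (i in 1:40) {
    lng <- visit_to_long(random_visit_items(), "p", sample(visit_grid(), 1))
    if (is.null(lng)) next
    expect_identical(evaluate_visit(reg2, lng)$hits,
                     evaluate_visit(REG, lng)$hits)
  }
})
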