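# Hand-built participants exercising the endpoint rules. S&E < 80 is the
# simplest single-item milestone, used as the generic "hit".

hit_items <- function() c(normal_items()[-6], SE_ADL = 75)

test_that("event time is the first scanned visit with a hit", {
  ds <- build_study(list(
    list(id = "P1", month = 0, items = normal_items()),
    list(id = "P1", month = 12, items = normal_items()),
    list(id = "P1", month = 24, items = hit_items()),
    list(id = "P1", month = 36, items = hit_items())))
  rec <- derive_endpoint(ds, REG, "annual_visits")
  expect_true(rec$included)
  expect_equal(rec$event, 1L)
  expect_equal(rec$time_months, 24)
  expect_equal(rec$first_event_milestones, "schwab_england")
  expect_equal(rec$first_event_domains, "functional_dependence")
})

test_that("annual vs all-visits modes disagree exactly on interim events", {
  ds <- build_study(list(
    list(id = "P1", month = 0, items = normal_items()),
    list(id = "P1", month = 12, items = normal_items()),
    list(id = "P1", month = 18, items = hit_items()),
    list(id = "P1", month = 24, items = hit_items())))
  rec_a <- derive_endpoint(ds, REG, "annual_visits")
  rec_all <- derive_endpoint(ds, REG, "all_visits")
  expect_equal(rec_a$time_months, 24)
  expect_equal(rec_all$time_months, 18)
  expect_equal(rec_a$event, 1L)
  expect_equal(rec_all$event, 1L)
})

test_that("baseline milestone and no-follow-up participants are excluded", {
  ds <- build_study(list(
    list(id = "PB", month = 0, items = hit_items()),
    list(id = "PB", month = 12, items = normal_items()),
    list(id = "PN", month = 0, items = normal_items()),
    list(id = "PC", month = 0, items = normal_items()),
    list(id = "PC", month = 12, items = normal_items())))
  rec <- derive_endpoint(ds, REG, "annual_visits")
  rec <- rec[order(rec$participant_id), ]
  expect_equal(rec$exclusion_reason,
               c("baseline_milestone", "none", "no_followup"))
  expect_equal(rec$included, c(FALSE, TRUE, FALSE))
  # annual mode: interim-only follow-up does not count
  ds2 <- build_study(list(
    list(id = "PI", month = 0, items = normal_items()),
    list(id = "PI", month = 3, items = normal_items())))
  rec2 <- derive_endpoint(ds2, REG, "annual_visits")
  expect_equal(rec2$exclusion_reason, "no_followup")
  # but in all-visits mode it does, censored at the interim with a flag
  rec3 <- derive_endpoint(ds2, REG, "all_visits")
  expect_true(rec3$included)
  expect_equal(rec3$event, 0L)
  expect_equal(rec3$time_months, 3)
  expect_true(rec3$deviation_interim_censor)
})

test_that("event-free participants censor at the last annual visit", {
  ds <- build_study(list(
    list(id = "P1", month = 0, items = normal_items()),
    list(id = "P1", month = 12, items = normal_items()),
    list(id = "P1", month = 30, items = normal_items()),
    list(id = "P1", month = 48, items = normal_items())))
  for (mode in c("annual_visits", "all_visits")) {
    rec <- derive_endpoint(ds, REG, mode)
    expect_equal(rec$event, 0L)
    expect_equal(rec$time_months, 48)
  }
})

test_that("missing baseline is reported or escalated", {
  ds <- build_study(list(
    list(id = "P1", month = 12, items = normal_items())))
  rec <- derive_endpoint(ds, REG, "annual_visits")
  expect_equal(rec$exclusion_reason, "missing_baseline")
  expect_error(derive_endpoint(ds, REG, "annual_visits",
                               missing_baseline = "error"), "baseline")
})

test_that("first-event tabulation counts participants, not instances", {
  ds <- build_study(list(
    # P1: S&E alone
    list(id = "P1", month = 0, items = normal_items()),
    list(id = "P1", month = 12, items = hit_items()),
    # P2: S&E and postural instability simultaneously (2 domains)
    list(id = "P2", month = 0, items = normal_items()),
    list(id = "P2", month = 12,
         items = c(hit_items(), "UPDRS_3_12|OFF" = 3)),
    # P3: MoCA alone
    list(id = "P3", month = 0, items = normal_items()),
    list(id = "P3", month = 12, items = c(normal_items()[-5], MOCA_TOTAL = 15)),
    # P4: censored
    list(id = "P4", month = 0, items = normal_items()),
    list(id = "P4", month = 12, items = normal_items())))
  tab <- tabulate_first_events(derive_endpoint(ds, REG, "annual_visits"), REG)
  expect_equal(tab$overall$n_events, 3)
  expect_equal(tab$overall$n_included, 4)
  bd <- function(d) tab$by_domain$count[tab$by_domain$domain == d]
  expect_equal(bd("functional_dependence"), 2)
  expect_equal(bd("walking_balance"), 1)
  expect_equal(bd("cognition"), 1)
  expect_equal(bd("autonomic"), 0)
  md <- tab$multi_domain
  expect_equal(md$count[md$n_domains == 1], 2)
  expect_equal(md$count[md$n_domains == 2], 1)
})

test_that("zero events tabulate to zero everywhere", {
  ds <- build_study(list(
    list(id = "P1", month = 0, items = normal_items()),
    list(id = "P1", month = 12, items = normal_items())))
  tab <- tabulate_first_events(derive_endpoint(ds, REG, "annual_visits"), REG)
  expect_equal(tab$overall$n_events, 0)
  expect_true(all(tab$by_milestone$count == 0))
})

test_that("ever-reached dominates first-event counts", {
  ds <- build_study(list(
    list(id = "P1", month = 0, items = normal_items()),
    list(id = "P1", month = 24, items = hit_items()),
    list(id = "P1", month = 48, items = c(normal_items(), UPDRS_2_3 = 3))))
  ever <- tabulate_ever_reached(ds, REG, "annual_visits")
  first <- tabulate_first_events(derive_endpoint(ds, REG, "annual_visits"),
                                 REG)
  cnt <- function(t, m) t$by_milestone$count[t$by_milestone$milestone == m]
  expect_equal(cnt(ever, "schwab_england"), 1)
  expect_equal(cnt(ever, "choking"), 1)
  expect_equal(cnt(first, "schwab_england"), 1)
  expect_equal(cnt(first, "choking"), 0)
  # property on a simulated cohort: ever >= first for every milestone
  ever_s <- tabulate_ever_reached(SHARED_SIM$data, REG, "annual_visits")
  first_s <- tabulate_first_events(SHARED_REC_ANNUAL, REG)
  expect_true(all(ever_s$by_milestone$count >= first_s$by_milestone$count))
})

test_that("generator truth drives the tabulations", {
  # every first event is Schwab & England when the mixture says so
  cfg <- sim_config(n = 120, seed = 33,
                    domain_weights = c(functional_dependence = 1),
                    baseline_milestone_prob = 0)
  sim <- simulate_cohort(cfg, REG)
  rec <- derive_endpoint(sim$data, REG, "annual_visits")
  tab <- tabulate_first_events(rec, REG)
  expect_equal(tab$by_milestone$count[
    tab$by_milestone$milestone == "schwab_england"], tab$overall$n_events)
  expect_gt(tab$overall$n_events, 0)
  # ever-reached equals the truth table restricted to annual visits
  truth_ids <- unique(sim$truth$states$participant_id[
    sim$truth$states$scheduled_month %in% annual_visits()])
  inc_ids <- rec$participant_id[rec$included]
  ever <- tabulate_ever_reached(sim$data, REG, "annual_visits")
  expect_equal(ever$by_milestone$count[
    ever$by_milestone$milestone == "schwab_england"],
    length(intersect(truth_ids, inc_ids)))
})

test_that("pipeline invariants hold on the shared simulated cohort", {
  for (rec in list(SHARED_REC_ANNUAL, SHARED_REC_ALL)) {
    n_excluded <- sum(!rec$included)
    n_event <- sum(rec$event == 1, na.rm = TRUE)
    n_censored <- sum(rec$event == 0, na.rm = TRUE)
    expect_equal(n_excluded + n_event + n_censored, nrow(rec))
    # per-protocol grid times
    expect_true(all(rec$time_months[rec$included] %in% visit_grid()))
  }
  # mode dominance
  m <- merge(SHARED_REC_ANNUAL, SHARED_REC_ALL, by = "participant_id",
             suffixes = c("_a", "_all"))
  both <- m[m$included_a & m$included_all, ]
  ev_a <- both[both$event_a == 1, ]
  expect_true(all(ev_a$event_all == 1))
  expect_true(all(ev_a$time_months_all <= ev_a$time_months_a))
})

test_that("deleting items never creates or hastens events", {
  set.seed(5)
  v <- SHARED_SIM$data$visits
  keep <- sort(sample(nrow(v), floor(0.9 * nrow(v))))
  ds2 <- study_dataset(v[keep, ], SHARED_SIM$data$covariates)
  rec2 <- derive_endpoint(ds2, REG, "annual_visits")
  m <- merge(SHARED_REC_ANNUAL, rec2, by = "participant_id",
             suffixes = c("_full", "_thin"))
  both <- m[m$included_full & m$included_thin, ]
  # no new events among participants event-free on the full data
  expect_true(all(both$event_thin[both$event_full == 0] == 0))
  # surviving events cannot move earlier
  ev_both <- both[both$event_full == 1 & both$event_thin == 1, ]
  expect_true(all(ev_both$time_months_thin >= ev_both$time_months_full))
})
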