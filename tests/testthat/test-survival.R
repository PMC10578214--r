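fake_records <- function(time, event) {
  structure(data.frame(participant_id = sprintf("P%03d", seq_along(time)),
                       included = TRUE, exclusion_reason = "none",
                       event = as.integer(event), time_months = time,
                       source_mode = "annual_visits",
                       stringsAsFactors = FALSE),
            class = c("pdm_endpoints", "data.frame"))
}

test_that("product-limit estimates match hand computation", {
  # {event@12, censor@24, event@24, censor@36}: deaths precede censorings
  rec <- fake_records(c(12, 24, 24, 36), c(1, 0, 1, 0))
  km <- km_curve(rec)
  s <- function(t) km$surv[match(t, km$time)]
  expect_equal(s(12), 0.75)
  expect_equal(s(24), 0.5)
  expect_equal(km$surv[nrow(km)], 0.5)
  expect_equal(s(0), 1)
  # all censored -> flat at 1
  km2 <- km_curve(fake_records(c(12, 24), c(0, 0)))
  expect_true(all(km2$surv == 1))
  expect_error(km_curve(fake_records(12, 1)[0, ]), "included")
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(2)
  t <- sort(sample(seq(3, 60, 3), 40, replace = TRUE))
  km <- km_curve(fake_records(t, rep(1, 40)))
  for (i in seq_len(nrow(km)))
    expect_equal(km$surv[i], mean(t > km$time[i]))
})

test_that("per-protocol rounding snaps to the 3-month grid", {
  rec <- fake_records(c(11.2, 25.4, 35.9), c(1, 1, 0))
  km <- km_curve(rec, round_to_3_months = TRUE)
  expect_true(all(km$time %% 3 == 0))
  km_raw <- km_curve(rec, round_to_3_months = FALSE)
  expect_true(11.2 %in% km_raw$time)
})

test_that("KM on a no-censoring exponential cohort matches the closed form", {
  h <- 0.012
  cfg <- sim_config(n = 5000, seed = 314,
                    hr_age_per5 = 1, hr_updrs_per5 = 1, hr_gds = 1,
                    hr_sbr_per01_dec = 1, hr_csf_decile_dec = 1,
                    base_hazard_monthly = h, annual_dropout = 0,
                    baseline_milestone_prob = 0, no_followup_prob = 0)
  se <- simulate_endpoints(cfg)
  km <- km_curve(se$records)
  s12 <- km$surv[km$time == 12]
  expected <- exp(-12 * h)
  mc_se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(s12 - expected), 2 * mc_se + 1e-9)
})

test_that("covariate transforms follow the reporting scales", {
  cov <- data.frame(participant_id = sprintf("P%03d", 1:100),
                    age = c(60, 65, runif(98, 40, 85)),
                    csf_asyn = 1:100, csf_hb = c(rep(100, 98), 300, 400),
                    stringsAsFactors = FALSE)
  specs <- default_covariate_specs()
  specs <- specs[specs$name %in% c("age", "csf_asyn"), ]
  X <- transform_covariates(cov, specs)
  # per-5-unit: ages 60 and 65 differ by exactly 1
  expect_equal(X$age[2] - X$age[1], 1)
  # deciles of 1..100 -> 1..10, ten members each, negated (decrease)
  d <- -X$csf_asyn
  expect_setequal(d, 1:10)
  expect_true(all(table(d) == 10))
  # hemoglobin filter blanks contaminated samples
  Xf <- transform_covariates(cov, specs, hb_filter = TRUE)
  expect_true(all(is.na(Xf$csf_asyn[99:100])))
  expect_equal(sum(is.na(Xf$csf_asyn)), 2)
  # all-missing covariate dropped with a warning
  cov$csf_asyn <- NA_real_
  expect_warning(transform_covariates(cov, specs), "entirely missing")
})

test_that("negating a covariate flips beta exactly", {
  se <- simulate_endpoints(sim_config(n = 300, seed = 88))
  inc <- se$records$participant_id[se$records$included]
  cov <- se$covariates[se$covariates$participant_id %in% inc, ]
  X <- transform_covariates(cov, sim_covariate_specs())
  X1 <- X[c("participant_id", "age")]
  f1 <- fit_cox_td(se$records, X1, se$med, include_med = FALSE)
  X1$age <- -X1$age
  f2 <- fit_cox_td(se$records, X1, se$med, include_med = FALSE)
  expect_equal(f2$table$beta, -f1$table$beta, tolerance = 1e-8)
})

test_that("medication switching after all event times is a no-op", {
  se <- simulate_endpoints(sim_config(n = 200, seed = 12))
  inc <- se$records$participant_id[se$records$included]
  cov <- se$covariates[se$covariates$participant_id %in% inc, ]
  X <- transform_covariates(cov, sim_covariate_specs())[
    c("participant_id", "age")]
  med_late <- stats::setNames(rep(999, length(se$med)), names(se$med))
  f_td <- fit_cox_td(se$records, X, med_late, include_med = TRUE)
  f_plain <- fit_cox_td(se$records, X, se$med, include_med = FALSE)
  expect_equal(f_td$table$beta[f_td$table$term == "age"],
               f_plain$table$beta[f_plain$table$term == "age"],
               tolerance = 1e-8)
  # med indicator never switches on: coefficient undefined (NA) or absent
  expect_true(is.na(f_td$table$beta[f_td$table$term == "med"]) ||
                !"med" %in% f_td$table$term)
})

test_that("Efron equals Breslow when there are no ties", {
  se <- simulate_endpoints(sim_config(n = 150, seed = 71))
  rec <- se$records[se$records$included, ]
  set.seed(1)
  rec$time_months <- rec$time_months + runif(nrow(rec), 0, 1)  # break ties
  X <- transform_covariates(
    se$covariates[se$covariates$participant_id %in% rec$participant_id, ],
    sim_covariate_specs())[c("participant_id", "age")]
  dat <- pdmilestones:::build_td_data(rec, X, se$med, include_med = FALSE)
  fe <- survival::coxph(survival::Surv(start, stop, status) ~ age, dat,
                        ties = "efron")
  fb <- survival::coxph(survival::Surv(start, stop, status) ~ age, dat,
                        ties = "breslow")
  expect_equal(coef(fe), coef(fb), tolerance = 1e-10)
})

test_that("screening applies the multicollinearity priority rules", {
  se <- simulate_endpoints(sim_config(n = 400, seed = 55,
                                      hr_updrs_per5 = 1.5))
  inc <- se$records$participant_id[se$records$included]
  cov <- se$covariates[se$covariates$participant_id %in% inc, ]
  # H&Y proxy strongly collinear with MDS-UPDRS total
  cov$hy_stage <- ifelse(cov$updrs_total > stats::median(cov$updrs_total),
                         2, 1)
  specs <- default_covariate_specs()
  specs <- specs[specs$name %in% c("age", "sex", "updrs_total", "hy_stage",
                                   "gds15", "sbr_striatum", "csf_asyn"), ]
  scr <- screen_predictors(se$records, cov, se$med, specs)
  st <- function(nm) scr$table$status[scr$table$name == nm]
  expect_equal(st("updrs_total"), "selected")
  expect_equal(st("hy_stage"), "excluded_by_priority")
  expect_equal(st("sex"), "forced")
  expect_equal(st("med"), "forced")
  # constant covariate is dropped with a warning
  cov$urate <- 5
  specs2 <- default_covariate_specs()
  specs2 <- specs2[specs2$name %in% c("age", "urate"), ]
  expect_warning(scr2 <- screen_predictors(se$records, cov, se$med, specs2),
                 "constant")
  expect_equal(scr2$table$status[scr2$table$name == "urate"], "degenerate")
})

test_that("backward selection keeps forced terms and prunes noise", {
  cfg <- sim_config(n = 350, seed = 61, hr_age_per5 = 1, hr_updrs_per5 = 1,
                    hr_gds = 1, hr_sbr_per01_dec = 1, hr_csf_decile_dec = 1)
  se <- simulate_endpoints(cfg)
  inc <- se$records$participant_id[se$records$included]
  cov <- se$covariates[se$covariates$participant_id %in% inc, ]
  sel <- backward_select(se$records, cov, se$med, sim_covariate_specs())
  tab <- sel$final$table
  nonforced <- setdiff(tab$term, c("sex", "med"))
  # whatever survived is significant at the retention level
  expect_true(all(tab$p[tab$term %in% nonforced] <= 0.05))
  expect_true(all(c("sex", "med") %in% tab$term))
  # removals are recorded with their p at removal
  expect_true(all(sel$trace$p_at_removal > 0.05))
  # forced-only full model is a fixed point
  scr_none <- sel$screening
  scr_none$table$status[scr_none$table$status == "selected"] <- "not_selected"
  sel2 <- backward_select(se$records, cov, se$med, sim_covariate_specs(),
                          screening = scr_none)
  expect_setequal(sel2$final$table$term, c("sex", "med"))
  expect_equal(nrow(sel2$trace), 0)
})

test_that("true effects are retained through the full workflow", {
  # moderately strong truth; both key predictors should usually survive
  kept <- c(age = 0, updrs = 0)
  R <- 10
  for (r in seq_len(R)) {
    se <- simulate_endpoints(sim_config(n = 400, seed = 700 + r))
    inc <- se$records$participant_id[se$records$included]
    cov <- se$covariates[se$covariates$participant_id %in% inc, ]
    sel <- backward_select(se$records, cov, se$med, sim_covariate_specs())
    kept["age"] <- kept["age"] + ("age" %in% sel$final$table$term)
    kept["updrs"] <- kept["updrs"] + ("updrs_total" %in% sel$final$table$term)
  }
  expect_gte(kept[["age"]], 8)
  expect_gte(kept[["updrs"]], 8)
})
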