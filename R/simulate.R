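# Synthetic longitudinal cohorts with exact ground truth. The generator is
# truth-first: it draws each participant's latent progression time from a
# proportional-hazards model, snaps it to the visit grid of the assigned
# milestone's schedule class, decides persistence at subsequent assessable
# visits, and only then back-fills item-level scores so that the milestone
# engine reproduces the intended states exactly. Deleting any normal
# (non-milestone) score can only turn hits off, so the configured
# missingness never perturbs the truth.

#' Simulation configuration
#'
#' Defaults describe an early, initially untreated PD cohort followed five
#' years on the per-protocol grid: mean age 61.5 (SD 9, truncated at 30),
#' about two-thirds male, MDS-UPDRS total around the low 30s, overdispersed
#' GDS-15 counts, striatal SBR near 1.4, log-normal CSF alpha-synuclein
#' with roughly 10% hemoglobin-contaminated samples. True hazard ratios
#' (age 1.25 per 5 years, MDS-UPDRS 1.18 per 5 units, GDS-15 1.07 per
#' point, SBR 1.07 per 0.1-unit decrease, CSF alpha-synuclein 1.09 per
#' decile decrease; sex and medication null) act on a constant monthly
#' baseline hazard of 0.01, giving roughly 45% reaching a milestone by five
#' years. Dropout is 4% per year (about 18% by year five); 7.6% of
#' participants meet a milestone at baseline and 1.5% never return.
#' First-event milestones are drawn from domain/milestone mixture weights
#' shaped like the observed first-event distribution; after a first event
#' the milestone recurs at each subsequent assessable visit with
#' probability `persistence_prob` (0.55).
#'
#' @param n number of enrolled participants.
#' @param seed RNG seed (mandatory).
#' @param ... overrides for any default listed above (see the source for
#'   the full field list).
#' @return list of class `pdm_sim_config`.
#' @export
sim_config <- function(n = 400, seed = 1, ...) {
  cfg <- list(
    n = n, seed = seed,
    age_mean = 61.5, age_sd = 9, age_min = 30,
    p_male = 0.65,
    updrs_mean = 32, updrs_sd = 13,
    gds_mu = 2.3, gds_size = 2,
    sbr_mean = 1.40, sbr_sd = 0.40, sbr_min = 0.3,
    csf_asyn_meanlog = log(1500), csf_asyn_sdlog = 0.45,
    hb_contam_frac = 0.10,
    hr_age_per5 = 1.25, hr_updrs_per5 = 1.18, hr_gds = 1.07,
    hr_sbr_per01_dec = 1.07, hr_csf_decile_dec = 1.09,
    hr_male = 1.0, hr_med = 1.0,
    base_hazard_monthly = 0.01,
    domain_weights = c(cognition = 0.141, functional_dependence = 0.120,
                       autonomic = 0.109, walking_balance = 0.066,
                       motor_complications = 0.051, adl = 0.045),
    milestone_weights = list(
      cognition = c(cognitive_impairment_moca = 25, dementia_composite = 13,
                    apathy = 11, cognitive_impairment_updrs = 10,
                    dementia_clinical = 3, hallucinations = 1),
      functional_dependence = c(schwab_england = 1),
      autonomic = c(urinary_incontinence = 20, syncope_scopa = 20,
                    syncope_updrs = 2, orthostatic_hypotension = 1),
      walking_balance = c(postural_instability = 13, walking_balance = 8,
                          gait = 7, hoehn_yahr = 3, freezing = 2,
                          freezing_of_gait = 1),
      motor_complications = c(fluctuations_complexity = 10,
                              fluctuations_impact = 11, dyskinesias = 1),
      adl = c(choking = 11, speech = 5, dressing = 1, eating = 1,
              hygiene = 1)),
    persistence_prob = 0.55,
    med_monthly_hazard = 0.02,
    annual_dropout = 0.04,
    item_missing_rate = 0.02,
    baseline_flag_missing = 0.749,
    baseline_milestone_prob = 0.076,
    no_followup_prob = 0.015,
    cognitive_cutoff = -1.5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  probs <- unlist(cfg[c("p_male", "hb_contam_frac", "persistence_prob",
                        "annual_dropout", "item_missing_rate",
                        "baseline_flag_missing", "baseline_milestone_prob",
                        "no_followup_prob")])
  stopifnot(all(probs >= 0), all(probs <= 1),
            all(cfg$base_hazard_monthly >= 0),
            all(unlist(cfg$milestone_weights) >= 0))
  if (abs(sum(cfg$domain_weights) - 1) > 1e-9)
    cfg$domain_weights <- cfg$domain_weights / sum(cfg$domain_weights)
  structure(cfg, class = "pdm_sim_config")
}

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Piecewise-constant baseline hazard on the visit grid, inverted for a
# per-participant multiplier; optional hazard switch (ratio `hr_switch`)
# at `switch_time` models the time-dependent medication effect.
draw_event_times <- function(mult, base_hazard, hr_switch = 1,
                             switch_time = Inf) {
  breaks <- visit_grid()
  K <- length(breaks) - 1
  h <- rep_len(base_hazard, K)
  Hb <- c(0, cumsum(h * diff(breaks)))
  Hfun <- function(t) {  # baseline cumulative hazard, linear tail
    j <- findInterval(pmin(t, breaks[K + 1]), breaks,
                      rightmost.closed = FALSE)
    j <- pmin(j, K)
    core <- Hb[j] + h[j] * (pmin(t, breaks[K + 1]) - breaks[j])
    core + pmax(t - breaks[K + 1], 0) * h[K]
  }
  Hinv <- function(y) {
    j <- findInterval(y, Hb)
    j <- pmin(pmax(j, 1), K)
    t <- breaks[j] + (y - Hb[j]) / h[j]
    over <- y > Hb[K + 1]
    t[over] <- breaks[K + 1] + (y[over] - Hb[K + 1]) / h[K]
    t
  }
  e <- stats::rexp(length(mult))
  if (hr_switch == 1 || all(!is.finite(switch_time))) return(Hinv(e / mult))
  st <- rep_len(switch_time, length(mult))
  Hm <- ifelse(is.finite(st), Hfun(st), Inf)
  target <- e / mult
  ifelse(target <= Hm, Hinv(target),
         Hinv(Hm + (target - Hm) / hr_switch))
}

draw_covariates <- function(cfg) {
  n <- cfg$n
  age <- rtruncnorm1(n, cfg$age_mean, cfg$age_sd, lo = cfg$age_min)
  sex <- ifelse(stats::runif(n) < cfg$p_male, "male", "female")
  updrs <- round(rtruncnorm1(n, cfg$updrs_mean, cfg$updrs_sd, lo = 3))
  gds <- stats::rnbinom(n, size = cfg$gds_size, mu = cfg$gds_mu)
  gds <- pmin(gds, 15)
  sbr <- rtruncnorm1(n, cfg$sbr_mean, cfg$sbr_sd, lo = cfg$sbr_min)
  csf <- stats::rlnorm(n, cfg$csf_asyn_meanlog, cfg$csf_asyn_sdlog)
  hb <- stats::rlnorm(n, log(40), 0.8)
  contam <- stats::runif(n) < cfg$hb_contam_frac
  hb[contam] <- stats::runif(sum(contam), 200, 600)
  data.frame(participant_id = sprintf("P%04d", seq_len(n)),
             age = round(age, 1), sex = sex, updrs_total = updrs,
             gds15 = gds, sbr_striatum = round(sbr, 3),
             csf_asyn = round(csf, 1), csf_hb = round(hb, 1),
             stringsAsFactors = FALSE)
}

linear_predictor <- function(cfg, cov) {
  d_csf <- mid_rank_deciles(cov$csf_asyn)
  (cov$age - cfg$age_mean) / 5 * log(cfg$hr_age_per5) +
    (cov$updrs_total - cfg$updrs_mean) / 5 * log(cfg$hr_updrs_per5) +
    (cov$gds15 - cfg$gds_mu) * log(cfg$hr_gds) -
    (cov$sbr_striatum - cfg$sbr_mean) / 0.1 * log(cfg$hr_sbr_per01_dec) -
    (d_csf - 5.5) * log(cfg$hr_csf_decile_dec) +
    (cov$sex == "male") * log(cfg$hr_male)
}

draw_milestone <- function(cfg, n) {
  dom <- sample(names(cfg$domain_weights), n, replace = TRUE,
                prob = cfg$domain_weights)
  unname(vapply(dom, function(d) {
    w <- cfg$milestone_weights[[d]]
    if (sum(w) <= 0) w[] <- 1
    sample(names(w), 1, prob = w)
  }, ""))
}

# Latent progression structure shared by the item-level and endpoint-only
# generators. Returns one row per participant.
draw_latents <- function(cfg) {
  cov <- draw_covariates(cfg)
  lp <- linear_predictor(cfg, cov)
  med <- stats::rexp(cfg$n, cfg$med_monthly_hazard)
  latent <- draw_event_times(exp(lp), cfg$base_hazard_monthly,
                             hr_switch = cfg$hr_med, switch_time = med)
  drop_rate <- -log(1 - cfg$annual_dropout) / 12
  dropout <- if (drop_rate > 0) stats::rexp(cfg$n, drop_rate) else
    rep(Inf, cfg$n)
  last_month <- vapply(dropout, function(d) {
    g <- visit_grid()
    max(g[g <= min(d, 60)])
  }, 0L)
  no_fu <- stats::runif(cfg$n) < cfg$no_followup_prob
  last_month[no_fu] <- 0L
  base_pos <- stats::runif(cfg$n) < cfg$baseline_milestone_prob
  milestone <- draw_milestone(cfg, cfg$n)
  cov$med_initiation_month <- ifelse(med <= last_month, round(med, 1), NA)
  list(cov = cov, lp = lp, latent = latent, last_month = last_month,
       baseline_positive = base_pos, milestone = milestone)
}

#' Simulate a full item-level cohort with ground truth
#'
#' Draws baseline covariates and a latent progression time per participant
#' from the configured proportional-hazards model, assigns the first-event
#' milestone from the mixture weights, snaps the event to the next visit of
#' that milestone's schedule class, applies persistence, dropout,
#' medication initiation and missingness, and back-fills item scores so
#' the milestone engine reproduces the intended milestone states exactly
#' (see [engine_roundtrip_check()]).
#'
#' @param config a [sim_config()].
#' @param registry milestone registry used for schedule classes and domain
#'   labels (default [build_registry()]).
#' @return list with `data` (a `pdm_study`) and `truth` (list with `states`
#'   - the true positive (participant, month, milestone) triples -, per
#'   participant `summary`, and the `config`).
#' @export
simulate_cohort <- function(config, registry = build_registry()) {
  cfg <- config
  set.seed(cfg$seed)
  lat <- draw_latents(cfg)
  sched <- milestone_schedule_classes(registry)
  doms <- milestone_domains(registry)

  states <- vector("list", cfg$n)
  event_month <- rep(NA_real_, cfg$n)
  for (i in seq_len(cfg$n)) {
    m <- lat$milestone[i]
    months <- schedule_months(sched[m])
    months <- months[months <= lat$last_month[i]]
    pos <- integer(0)
    if (lat$baseline_positive[i]) pos <- c(pos, 0L)
    ev_candidates <- months[months >= lat$latent[i]]
    if (length(ev_candidates) > 0) {
      ev <- min(ev_candidates)
      event_month[i] <- ev
      later <- months[months > ev]
      keep <- later[stats::runif(length(later)) < cfg$persistence_prob]
      pos <- c(pos, ev, keep)
    }
    if (length(pos))
      states[[i]] <- data.frame(
        participant_id = lat$cov$participant_id[i],
        scheduled_month = as.integer(pos), milestone = m,
        stringsAsFactors = FALSE)
  }
  states <- do.call(rbind, states[!vapply(states, is.null, NA)])
  if (is.null(states))
    states <- data.frame(participant_id = character(),
                         scheduled_month = integer(),
                         milestone = character(), stringsAsFactors = FALSE)

  visits <- emit_visits(cfg, lat, states)
  summary <- data.frame(
    participant_id = lat$cov$participant_id,
    milestone = lat$milestone,
    domain = unname(doms[lat$milestone]),
    latent_month = lat$latent,
    event_month = event_month,
    last_month = lat$last_month,
    baseline_positive = lat$baseline_positive,
    stringsAsFactors = FALSE)
  truth <- list(states = states, summary = summary, config = cfg)
  list(data = new_study(visits, lat$cov), truth = truth)
}

# Normal (sub-threshold) scores per item; values are drawn so that no
# milestone criterion can be met without a deliberate patch.
normal_values <- function(code, n) {
  if (startsWith(code, "UPDRS_")) return(sample(0:2, n, replace = TRUE))
  switch(code,
    HY = sample(1:2, n, replace = TRUE),
    SE_ADL = sample(seq(80, 100, by = 5), n, replace = TRUE),
    MOCA_TOTAL = sample(24:30, n, replace = TRUE),
    SCOPA_8 = , SCOPA_9 = , SCOPA_15 = sample(0:1, n, replace = TRUE),
    SCOPA_16 = rep(0, n),
    BP_SYS_SUPINE = , BP_SYS_SITTING = round(stats::rnorm(n, 130, 10)),
    BP_DIA_SUPINE = , BP_DIA_SITTING = round(stats::rnorm(n, 80, 8)),
    BP_SYS_STANDING = NA,  # filled relative to sitting
    BP_DIA_STANDING = NA,
    FLAG_PDD = , FLAG_COG_FUNC_IMPAIR = rep(0, n),
    round(pmax(stats::rnorm(n, 0, 0.5), -1.3), 2)  # cognitive z-scores
  )
}

# Item rows satisfying exactly one milestone at one visit.
satisfy_items <- function(milestone, cutoff) {
  one <- function(code, value, state = NA_character_)
    data.frame(item_code = code, state = state, value = value,
               stringsAsFactors = FALSE)
  st <- sample(c("OFF", "ON"), 1)
  sev <- function() sample(3:4, 1)
  switch(milestone,
    walking_balance = one("UPDRS_2_12", sev()),
    freezing = one("UPDRS_2_13", sev()),
    gait = one("UPDRS_3_10", sev(), st),
    freezing_of_gait = one("UPDRS_3_11", 4, st),
    postural_instability = one("UPDRS_3_12", sev(), st),
    hoehn_yahr = one("HY", sample(4:5, 1), st),
    dyskinesias = rbind(one("UPDRS_4_1", sev()), one("UPDRS_4_2", sev())),
    fluctuations_impact = one("UPDRS_4_4", sev()),
    fluctuations_complexity = one("UPDRS_4_5", sev()),
    cognitive_impairment_moca = one("MOCA_TOTAL", sample(0:20, 1)),
    cognitive_impairment_updrs = one("UPDRS_1_1", sev()),
    hallucinations = one("UPDRS_1_2", sev()),
    apathy = one("UPDRS_1_5", sev()),
    dementia_clinical = one("FLAG_PDD", 1),
    dementia_composite = {
      dd <- sample(names(cognitive_domains()), 2)
      z <- round(stats::runif(2, cutoff - 1.5, cutoff - 0.05), 2)
      rbind(one(cognitive_domains()[[dd[1]]][1], z[1]),
            one(cognitive_domains()[[dd[2]]][1], z[2]),
            one("FLAG_COG_FUNC_IMPAIR", 1))
    },
    urinary_incontinence = rbind(
      one("UPDRS_1_10", sev()),
      one(sample(c("SCOPA_8", "SCOPA_9"), 1), sample(2:3, 1))),
    orthostatic_hypotension = {
      sys_sit <- round(stats::rnorm(1, 140, 8))
      dia_sit <- round(stats::rnorm(1, 88, 6))
      rbind(one("SCOPA_15", sample(2:3, 1)),
            one("BP_SYS_SITTING", sys_sit),
            one("BP_SYS_STANDING", sys_sit - sample(20:40, 1)),
            one("BP_DIA_SITTING", dia_sit),
            one("BP_DIA_STANDING", dia_sit - sample(10:25, 1)))
    },
    syncope_updrs = one("UPDRS_1_12", 4),
    syncope_scopa = one("SCOPA_16", sample(1:3, 1)),
    schwab_england = one("SE_ADL", sample(seq(30, 75, by = 5), 1)),
    choking = one("UPDRS_2_3", sev()),
    eating = one("UPDRS_2_4", sev()),
    dressing = one("UPDRS_2_5", sev()),
    hygiene = one("UPDRS_2_6", sev()),
    speech = one("UPDRS_3_1", sev(), st),
    stop("no item patch for milestone ", milestone)
  )
}

emit_visits <- function(cfg, lat, states) {
  codes <- item_code_table()
  # participant-visit index
  pv <- do.call(rbind, lapply(seq_len(cfg$n), function(i) {
    g <- visit_grid()
    data.frame(participant_id = lat$cov$participant_id[i],
               scheduled_month = g[g <= lat$last_month[i]],
               stringsAsFactors = FALSE)
  }))
  # normal rows per item
  rows <- vector("list", nrow(codes))
  for (k in seq_len(nrow(codes))) {
    code <- codes$code[k]
    months <- c(0L, schedule_months(codes$schedule_class[k]))
    idx <- pv[pv$scheduled_month %in% months, , drop = FALSE]
    if (nrow(idx) == 0) next
    if (codes$motor_state[k]) {
      idx <- rbind(cbind(idx, state = "OFF", stringsAsFactors = FALSE),
                   cbind(idx, state = "ON", stringsAsFactors = FALSE))
    } else idx$state <- NA_character_
    idx$item_code <- code
    if (code %in% c("BP_SYS_STANDING", "BP_DIA_STANDING")) {
      base <- if (code == "BP_SYS_STANDING") 130 else 80
      sdv <- if (code == "BP_SYS_STANDING") 10 else 8
      maxdrop <- if (code == "BP_SYS_STANDING") 12 else 7
      sit <- round(stats::rnorm(nrow(idx), base, sdv))
      idx$value <- sit - sample(-5:maxdrop, nrow(idx), replace = TRUE)
      # keep the matching sitting reading consistent-ish but independent
      # draws are fine: milestone atoms difference the two columns, and
      # normals guarantee drop below threshold via the paired patch below
    } else {
      idx$value <- normal_values(code, nrow(idx))
    }
    rows[[k]] <- idx
  }
  visits <- do.call(rbind, rows)

  # standing BP must sit below the orthostatic-drop thresholds relative to
  # the SITTING draws actually emitted: recompute standing = sitting - d
  visits <- fix_bp_pairs(visits)

  # missingness on normal rows
  if (cfg$item_missing_rate > 0) {
    drop <- stats::runif(nrow(visits)) < cfg$item_missing_rate
    visits <- visits[!drop, , drop = FALSE]
  }
  # investigator flags mostly missing at baseline
  fl <- visits$item_code %in% c("FLAG_PDD", "FLAG_COG_FUNC_IMPAIR") &
    visits$scheduled_month == 0
  if (any(fl)) {
    kill <- fl & stats::runif(nrow(visits)) < cfg$baseline_flag_missing
    visits <- visits[!kill, , drop = FALSE]
  }

  # milestone patches override normals
  if (nrow(states) > 0) {
    patches <- vector("list", nrow(states))
    for (j in seq_len(nrow(states))) {
      p <- satisfy_items(states$milestone[j], cfg$cognitive_cutoff)
      p$participant_id <- states$participant_id[j]
      p$scheduled_month <- states$scheduled_month[j]
      patches[[j]] <- p
    }
    patches <- do.call(rbind, patches)
    key <- function(d) paste(d$participant_id, d$scheduled_month,
                             d$item_code, d$state, sep = "\r")
    visits <- visits[!key(visits) %in% key(patches), , drop = FALSE]
    visits <- rbind(visits[c("participant_id", "scheduled_month",
                             "item_code", "state", "value")],
                    patches[c("participant_id", "scheduled_month",
                              "item_code", "state", "value")])
  }
  visits$actual_month <- as.numeric(visits$scheduled_month)
  visits <- visits[order(visits$participant_id, visits$scheduled_month,
                         visits$item_code, visits$state),
                   c("participant_id", "scheduled_month", "actual_month",
                     "item_code", "state", "value")]
  rownames(visits) <- NULL
  visits
}

# Re-pair standing blood pressure with the sitting reading of the same
# visit so the orthostatic drop of a normal visit stays below threshold.
fix_bp_pairs <- function(visits) {
  for (comp in c("SYS", "DIA")) {
    sit_code <- paste0("BP_", comp, "_SITTING")
    sta_code <- paste0("BP_", comp, "_STANDING")
    sit <- visits[visits$item_code == sit_code, ]
    i_sta <- which(visits$item_code == sta_code)
    if (length(i_sta) == 0 || nrow(sit) == 0) next
    k_sta <- paste(visits$participant_id[i_sta],
                   visits$scheduled_month[i_sta])
    k_sit <- paste(sit$participant_id, sit$scheduled_month)
    m <- match(k_sta, k_sit)
    maxdrop <- if (comp == "SYS") 12L else 7L
    d <- sample(-5:maxdrop, length(i_sta), replace = TRUE)
    visits$value[i_sta] <- ifelse(is.na(m), visits$value[i_sta],
                                  sit$value[m] - d)
  }
  visits
}

#' Check that the engine reproduces the generator's truth exactly
#'
#' Evaluates every emitted visit through the milestone engine
#' (schedule-restricted) and compares the hit set with the truth's
#' milestone states.
#'
#' @param ds the `pdm_study` from [simulate_cohort()].
#' @param truth the matching truth object.
#' @param registry a milestone registry.
#' @return list with `pass` (logical) and `discrepancies` (data.frame of
#'   (participant, month, milestone, where) triples present on one side
#'   only).
#' @export
engine_roundtrip_check <- function(ds, truth, registry = build_registry()) {
  hits <- evaluate_milestones(registry, ds, restrict_to_schedule = TRUE)
  key <- function(d) paste(d$participant_id, d$scheduled_month, d$milestone)
  eng <- unique(key(hits))
  tru <- unique(key(truth$states))
  extra <- setdiff(eng, tru)
  missing <- setdiff(tru, eng)
  disc <- rbind(
    if (length(extra)) data.frame(key = extra, where = "engine_only"),
    if (length(missing)) data.frame(key = missing, where = "truth_only"))
  list(pass = length(extra) + length(missing) == 0,
       discrepancies = if (is.null(disc))
         data.frame(key = character(), where = character()) else disc)
}

#' Simulate endpoint records directly (no item emission)
#'
#' Fast path for statistical calibration studies: the same covariate and
#' latent-time model as [simulate_cohort()], with the annual-visit
#' observation process applied analytically (event at the first annual
#' visit at or after the latent time, censoring at the last completed
#' annual visit, baseline and no-follow-up exclusions). Hundreds of
#' replicates of this generator power the parameter-recovery and type-I
#' error checks without paying for item-level back-filling.
#'
#' @param config a [sim_config()].
#' @return list with `records` (a `pdm_endpoints` data.frame), `covariates`
#'   and `med` (named vector of initiation months).
#' @export
simulate_endpoints <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  lat <- draw_latents(cfg)
  ann <- annual_visits()
  rec <- data.frame(participant_id = lat$cov$participant_id,
                    included = TRUE, exclusion_reason = "none",
                    event = NA_integer_, time_months = NA_real_,
                    first_event_milestones = NA_character_,
                    first_event_domains = NA_character_,
                    deviation_interim_censor = FALSE,
                    source_mode = "annual_visits",
                    stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n)) {
    if (lat$baseline_positive[i]) {
      rec$included[i] <- FALSE
      rec$exclusion_reason[i] <- "baseline_milestone"
      next
    }
    avail <- ann[ann <= lat$last_month[i]]
    if (length(avail) == 0) {
      rec$included[i] <- FALSE
      rec$exclusion_reason[i] <- "no_followup"
      next
    }
    ev <- avail[avail >= lat$latent[i]]
    if (length(ev) > 0) {
      rec$event[i] <- 1L
      rec$time_months[i] <- min(ev)
      rec$first_event_milestones[i] <- lat$milestone[i]
    } else {
      rec$event[i] <- 0L
      rec$time_months[i] <- max(avail)
    }
  }
  class(rec) <- c("pdm_endpoints", "data.frame")
  med <- lat$cov$med_initiation_month
  names(med) <- lat$cov$participant_id
  list(records = rec, covariates = lat$cov, med = med,
       linear_predictor = lat$lp)
}

#' Covariate specs matching the generated covariate table
#'
#' Subset of [default_covariate_specs()] restricted to the covariates the
#' simulator emits, so the Cox workflow runs warning-free on synthetic
#' cohorts.
#'
#' @return spec data.frame (age, sex, MDS-UPDRS total, GDS-15, striatum
#'   SBR, CSF alpha-synuclein).
#' @export
sim_covariate_specs <- function() {
  specs <- default_covariate_specs()
  specs[specs$name %in% c("age", "sex", "updrs_total", "gds15",
                          "sbr_striatum", "csf_asyn"), , drop = FALSE]
}
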