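# Kaplan-Meier estimation on per-protocol time and the screening ->
# backward-selection Cox workflow. Model fitting is delegated to the
# survival package (Efron tie handling, counting-process time-dependent
# covariates); this module owns per-protocol rounding, covariate
# transforms, the univariable screening pass with multicollinearity
# priority rules, and the backward-selection loop with forced covariates.

#' Kaplan-Meier curve of progression-free survival
#'
#' Product-limit estimate over included endpoint records. With
#' `round_to_3_months = TRUE` event/censoring times are first snapped to the
#' nearest 3 months (per-protocol time). Deaths precede censorings at tied
#' times, as usual.
#'
#' @param records a `pdm_endpoints` data.frame (or any data.frame with
#'   `included`, `event`, `time_months`).
#' @param round_to_3_months snap times to the 3-month grid (default TRUE).
#' @return data.frame of class `pdm_survcurve`: `time`, `surv`, `n_risk`,
#'   `n_event`, `n_censor`, anchored at S(0) = 1.
#' @export
km_curve <- function(records, round_to_3_months = TRUE) {
  inc <- records[records$included, , drop = FALSE]
  if (nrow(inc) == 0) stop("no included records")
  t <- inc$time_months
  if (round_to_3_months) t <- 3 * round(t / 3)
  fit <- survival::survfit(survival::Surv(t, inc$event) ~ 1)
  out <- data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
                    n_risk = c(nrow(inc), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    n_censor = c(0, fit$n.censor))
  class(out) <- c("pdm_survcurve", "data.frame")
  out
}

# ---- covariate specification ------------------------------------------------

#' Default baseline-predictor specification
#'
#' One row per candidate predictor with its reporting transform, mirroring
#' the conventional scales for this cohort: age per 5-year increase,
#' MDS-UPDRS total per 5-unit increase, Schwab & England per 10-unit
#' decrease, DAT SBR per 0.1-unit decrease, CSF biomarkers as decile of
#' rank (skewed distributions), etc. `direction = "decrease"` covariates
#' are negated in the model matrix so a reported HR above 1 always means
#' faster progression as the predictor moves in the stated direction.
#'
#' Multicollinearity priority rules are encoded in `superseded_by`: when
#' both pass screening, MDS-UPDRS total supersedes Hoehn & Yahr stage and
#' the PIGD score, mean striatum SBR supersedes mean putamen SBR, and the
#' CSF t-tau/abeta ratio supersedes abeta alone. Sex and PD medication use
#' are forced into every multivariable model.
#'
#' @return data.frame with columns `name`, `source`, `transform`
#'   (`identity`, `per_k`, `decile`, `indicator_ge`), `k`, `direction`,
#'   `role` (`forced`/`candidate`), `hb_filter`, `superseded_by`.
#' @export
default_covariate_specs <- function() {
  s <- function(name, source = name, transform = "identity", k = NA_real_,
                direction = "increase", role = "candidate",
                hb_filter = FALSE, superseded_by = NA_character_) {
    data.frame(name = name, source = source, transform = transform, k = k,
               direction = direction, role = role, hb_filter = hb_filter,
               superseded_by = superseded_by, stringsAsFactors = FALSE)
  }
  rbind(
    s("age", transform = "per_k", k = 5),
    s("sex", role = "forced"),
    s("site"),
    s("bmi"),
    s("orth_sys_bp_change"),
    s("disease_duration"),
    s("updrs_total", transform = "per_k", k = 5),
    s("hy_stage", transform = "indicator_ge", k = 2,
      superseded_by = "updrs_total"),
    s("pigd", transform = "per_k", k = 0.1, direction = "decrease",
      superseded_by = "updrs_total"),
    s("tremor"),
    s("se_adl", transform = "per_k", k = 10, direction = "decrease"),
    s("moca", direction = "decrease"),
    s("scopa_aut_total"),
    s("anosmia"),
    s("upsit_raw", direction = "decrease"),
    s("ess"),
    s("rbdsq"),
    s("gds15"),
    s("stai_total"),
    s("sbr_striatum", transform = "per_k", k = 0.1, direction = "decrease"),
    s("sbr_putamen", transform = "per_k", k = 0.1, direction = "decrease",
      superseded_by = "sbr_striatum"),
    s("csf_abeta", transform = "decile", direction = "decrease",
      superseded_by = "csf_ttau_abeta_ratio"),
    s("csf_ttau", transform = "decile"),
    s("csf_ptau", transform = "decile"),
    s("csf_ttau_abeta_ratio", transform = "decile"),
    s("csf_asyn", transform = "decile", direction = "decrease",
      hb_filter = TRUE),
    s("urate")
  )
}

mid_rank_deciles <- function(x) {
  r <- rank(x, na.last = "keep", ties.method = "average")
  n <- sum(!is.na(x))
  d <- floor(10 * (r - 0.5) / n) + 1
  pmin(pmax(d, 1), 10)
}

#' Build the Cox model matrix from a covariate table
#'
#' Applies each spec's transform: `per_k` divides by `k`; `decile` maps to
#' mid-rank decile scores 1-10 among non-missing included participants;
#' `indicator_ge` is a `>= k` indicator; `direction = "decrease"` negates
#' the result. With `hb_filter = TRUE`, CSF alpha-synuclein values from
#' samples with hemoglobin above 200 ng/mL are set missing.
#'
#' @param cov covariate table (one row per participant).
#' @param specs spec rows as from [default_covariate_specs()].
#' @param hb_filter apply the hemoglobin sensitivity filter (default FALSE).
#' @return data.frame with `participant_id` plus one column per spec;
#'   all-missing covariates are dropped with a warning.
#' @export
transform_covariates <- function(cov, specs = default_covariate_specs(),
                                 hb_filter = FALSE) {
  out <- data.frame(participant_id = cov$participant_id,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    if (!sp$source %in% names(cov)) next
    x <- cov[[sp$source]]
    if (is.character(x) || is.factor(x)) {
      x <- as.character(x)
      x <- switch(sp$name,
                  sex = as.numeric(x %in% c("male", "M", "1")),
                  site = as.numeric(x %in% c("non-US", "nonUS", "1")),
                  suppressWarnings(as.numeric(x)))
    }
    if (hb_filter && isTRUE(sp$hb_filter) && "csf_hb" %in% names(cov))
      x[!is.na(cov$csf_hb) & cov$csf_hb > 200] <- NA
    v <- switch(sp$transform,
                identity = x,
                per_k = x / sp$k,
                decile = mid_rank_deciles(x),
                indicator_ge = as.numeric(x >= sp$k),
                stop("unknown transform: ", sp$transform))
    if (sp$direction == "decrease") v <- -v
    if (all(is.na(v))) {
      warning("covariate ", sp$name, " is entirely missing; dropped")
      next
    }
    out[[sp$name]] <- v
  }
  out
}

# ---- Cox fitting ------------------------------------------------------------

# Counting-process representation: one episode per participant before
# medication initiation (med = 0) and one after (med = 1); the indicator
# switches at the initiation month. Initiation at or after the event /
# censoring time leaves the indicator at 0 throughout.
build_td_data <- function(records, X, med_initiation_month,
                          include_med = TRUE) {
  inc <- records[records$included, , drop = FALSE]
  d <- merge(inc[c("participant_id", "event", "time_months")], X,
             by = "participant_id", sort = FALSE)
  med <- med_initiation_month[match(d$participant_id,
                                    names(med_initiation_month))]
  rows <- vector("list", nrow(d))
  covs <- setdiff(names(d), c("participant_id", "event", "time_months"))
  for (i in seq_len(nrow(d))) {
    ti <- d$time_months[i]
    if (ti <= 0) next
    m <- med[i]
    base <- d[i, c("participant_id", covs), drop = FALSE]
    if (include_med && !is.na(m) && m < ti) {
      if (m > 0)
        rows[[i]] <- rbind(
          cbind(base, start = 0, stop = m, status = 0L, med = 0),
          cbind(base, start = m, stop = ti, status = d$event[i], med = 1))
      else
        rows[[i]] <- cbind(base, start = 0, stop = ti, status = d$event[i],
                           med = 1)
    } else {
      row <- cbind(base, start = 0, stop = ti, status = d$event[i])
      if (include_med) row$med <- 0
      rows[[i]] <- row
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, NA)])
}

#' Fit a Cox model with the time-dependent medication covariate
#'
#' Partial likelihood with Efron's tie approximation on counting-process
#' data; the PD-medication indicator is 0 before symptomatic-treatment
#' initiation and 1 after.
#'
#' @param records included endpoint records (`pdm_endpoints`).
#' @param X model matrix from [transform_covariates()] (may be just
#'   `participant_id` for a medication-only model).
#' @param med_initiation_month named numeric vector (participant id ->
#'   months to initiation; NA for never).
#' @param conf_level CI level for reported hazard ratios (default 0.95).
#' @param include_med include the time-dependent medication indicator.
#' @return object of class `pdm_cox`: coefficient `table` (term, beta, se,
#'   hr, lo, hi, z, p), tie method, `n`/`n_event`, and the underlying
#'   `survival::coxph` fit (for e.g. Schoenfeld-residual diagnostics via
#'   `survival::cox.zph`).
#' @export
fit_cox_td <- function(records, X, med_initiation_month,
                       conf_level = 0.95, include_med = TRUE) {
  dat <- build_td_data(records, X, med_initiation_month, include_med)
  covs <- setdiff(names(dat), c("participant_id", "start", "stop", "status"))
  if (length(covs) == 0) stop("no covariates to fit")
  if (sum(dat$status) < 1) stop("no events among included records")
  f <- stats::as.formula(paste("survival::Surv(start, stop, status) ~",
                               paste(covs, collapse = " + ")))
  fit <- survival::coxph(f, data = dat, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  if (!is.null(fit$info) && any(grepl("converge", fit$info)))
    stop("Cox fit failed to converge: ", fit$info)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(term = names(beta), beta = unname(beta),
                    se = unname(se), hr = exp(unname(beta)),
                    lo = exp(unname(beta - q * se)),
                    hi = exp(unname(beta + q * se)),
                    z = unname(z),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, ties = "efron", conf_level = conf_level,
                 n = fit$n, n_event = fit$nevent, fit = fit),
            class = "pdm_cox")
}

#' @export
print.pdm_cox <- function(x, ...) {
  cat("Cox model (Efron ties), ", x$n_event, " events / ", x$n,
      " records, ", round(100 * x$conf_level), "% CI\n", sep = "")
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f, %.2f)", tab$hr, tab$lo, tab$hi)
  print(tab[c("term", "hr", "p")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Univariable screening of candidate predictors
#'
#' Fits one Cox model per candidate (the candidate alone; PD medication use
#' is screened as its own time-dependent model) and reports the hazard
#' ratio with a 90% CI. A candidate passes at `p <= alpha`; the
#' multicollinearity priority rules then mark candidates superseded by a
#' passing rival as `excluded_by_priority`. Forced covariates (sex,
#' medication) are always carried into the full model.
#'
#' @inheritParams fit_cox_td
#' @param cov covariate table.
#' @param specs covariate specification (default [default_covariate_specs()]).
#' @param alpha screening significance level (default 0.10).
#' @param hb_filter apply the CSF hemoglobin filter.
#' @return object of class `pdm_screening`: `table` with per-candidate HR,
#'   90% CI, p, and `status` in selected / not_selected /
#'   excluded_by_priority / forced / degenerate.
#' @export
screen_predictors <- function(records, cov, med_initiation_month,
                              specs = default_covariate_specs(),
                              alpha = 0.10, hb_filter = FALSE) {
  X <- transform_covariates(cov, specs, hb_filter = hb_filter)
  fitted <- names(X)[-1]
  res <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    row <- data.frame(name = sp$name, hr = NA_real_, lo = NA_real_,
                      hi = NA_real_, p = NA_real_, status = "degenerate",
                      stringsAsFactors = FALSE)
    if (!sp$name %in% fitted) return(row)
    x <- X[[sp$name]]
    if (stats::var(x, na.rm = TRUE) == 0) {
      warning("covariate ", sp$name, " is constant; dropped from screening")
      return(row)
    }
    f <- tryCatch(
      fit_cox_td(records, X[c("participant_id", sp$name)],
                 med_initiation_month, conf_level = 0.90,
                 include_med = FALSE),
      error = function(e) NULL)
    if (is.null(f)) return(row)
    tr <- f$table[f$table$term == sp$name, ]
    row[c("hr", "lo", "hi", "p")] <- tr[c("hr", "lo", "hi", "p")]
    row$status <- if (sp$role == "forced") "forced"
      else if (tr$p <= alpha) "selected" else "not_selected"
    row
  })
  tab <- do.call(rbind, res)
  # medication screened in its own time-dependent model
  fmed <- fit_cox_td(records, X["participant_id"], med_initiation_month,
                     conf_level = 0.90, include_med = TRUE)
  trm <- fmed$table[fmed$table$term == "med", ]
  tab <- rbind(tab, data.frame(name = "med", hr = trm$hr, lo = trm$lo,
                               hi = trm$hi, p = trm$p, status = "forced",
                               stringsAsFactors = FALSE))
  passed <- tab$name[tab$status == "selected"]
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    if (!is.na(sp$superseded_by) && sp$name %in% passed &&
        sp$superseded_by %in% passed)
      tab$status[tab$name == sp$name] <- "excluded_by_priority"
  }
  structure(list(table = tab, alpha = alpha, hb_filter = hb_filter,
                 specs = specs),
            class = "pdm_screening")
}

#' @export
print.pdm_screening <- function(x, ...) {
  tab <- x$table
  tab$hr <- ifelse(is.na(tab$hr), "-",
                   sprintf("%.2f (%.2f, %.2f)", tab$hr, tab$lo, tab$hi))
  print(tab[c("name", "hr", "p", "status")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Backward selection from the screened full model
#'
#' Starts from forced covariates plus every screening-selected candidate
#' and removes, one at a time, the non-forced covariate with the largest
#' p-value above `retain_alpha` (ties broken by smaller absolute
#' coefficient), refitting after each removal. Sex and medication are never
#' removed.
#'
#' @inheritParams screen_predictors
#' @param screening result of [screen_predictors()]; computed if NULL.
#' @param retain_alpha retention significance level (default 0.05).
#' @return list of class `pdm_selection`: `final` (`pdm_cox` with 95% CIs),
#'   `screening`, and `trace` (data.frame of removals with p at removal).
#' @export
backward_select <- function(records, cov, med_initiation_month,
                            specs = default_covariate_specs(),
                            screening = NULL, retain_alpha = 0.05,
                            hb_filter = FALSE) {
  if (is.null(screening))
    screening <- screen_predictors(records, cov, med_initiation_month,
                                   specs = specs, hb_filter = hb_filter)
  forced <- setdiff(specs$name[specs$role == "forced"], "med")
  current <- union(forced, screening$table$name[
    screening$table$status == "selected"])
  X <- transform_covariates(cov, specs, hb_filter = hb_filter)
  current <- intersect(current, names(X))
  trace <- data.frame(step = integer(), removed = character(),
                      p_at_removal = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- fit_cox_td(records, X[c("participant_id", current)],
                      med_initiation_month, conf_level = 0.95)
    tab <- fit$table
    cand <- tab[!tab$term %in% c(forced, "med"), , drop = FALSE]
    worst <- cand[cand$p > retain_alpha, , drop = FALSE]
    if (nrow(worst) == 0) break
    worst <- worst[order(-worst$p, abs(worst$beta)), , drop = FALSE]
    drop_term <- worst$term[1L]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = drop_term,
                                     p_at_removal = worst$p[1L]))
    current <- setdiff(current, drop_term)
  }
  structure(list(final = fit, screening = screening, trace = trace,
                 forced = c(forced, "med"), retain_alpha = retain_alpha),
            class = "pdm_selection")
}

#' @export
print.pdm_selection <- function(x, ...) {
  cat("backward selection: removed",
      nrow(x$trace), "covariate(s); final model:\n")
  print(x$final)
  invisible(x)
}
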