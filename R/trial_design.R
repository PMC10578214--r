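# Sample size for a two-arm log-rank design whose control arm follows a
# piecewise-linear survival curve (knots on the 3-month per-protocol grid,
# e.g. from a Kaplan-Meier estimate). Required events come from the
# Schoenfeld identity; the full sample size from a Lakatos-style Markov
# evaluation over monthly intervals, cross-checked by simulation.

#' Design specification for a two-arm log-rank trial
#'
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @param hr hazard ratio of the experimental relative to the comparison
#'   arm (must be positive and not 1).
#' @param length_months study length in months (24 or 36 in the motivating
#'   designs; any positive value accepted).
#' @param allocation_ratio experimental:control allocation (default 1).
#' @param accrual_months uniform accrual period; 0 = instantaneous entry
#'   (default).
#' @param dropout_hazard monthly exponential dropout hazard (default 0).
#' @return list of class `pdm_design`.
#' @export
design_spec <- function(alpha = 0.05, power = 0.80, hr, length_months = 36,
                        allocation_ratio = 1, accrual_months = 0,
                        dropout_hazard = 0) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, hr > 0,
            length_months > 0, allocation_ratio > 0, accrual_months >= 0,
            dropout_hazard >= 0)
  if (hr == 1) stop("hazard ratio of 1 gives an infinite sample size")
  structure(list(alpha = alpha, power = power, hr = hr,
                 length_months = length_months,
                 allocation_ratio = allocation_ratio,
                 accrual_months = accrual_months,
                 dropout_hazard = dropout_hazard),
            class = "pdm_design")
}

#' Required events for a log-rank test (Schoenfeld identity)
#'
#' `d = ceil((z[1-alpha/2] + z[power])^2 (1+r)^2 / (r (log hr)^2))`, which
#' for a balanced design (r = 1) is the familiar factor of 4.
#'
#' @param spec a [design_spec()].
#' @return integer number of required events.
#' @export
schoenfeld_events <- function(spec) {
  r <- spec$allocation_ratio
  z <- stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
  ceiling(z^2 * (1 + r)^2 / r / log(spec$hr)^2)
}

# ---- piecewise-linear survival ---------------------------------------------

#' Piecewise-linear survival curve
#'
#' Linear interpolation of S(t) between knots; flat extrapolation beyond
#' the last knot. A knot at t = 0 with S = 1 is added when absent.
#'
#' @param times knot times (months, nondecreasing).
#' @param surv survival values at the knots (nonincreasing, within [0, 1]).
#' @return object of class `pdm_pwsurv`.
#' @export
piecewise_survival <- function(times, surv) {
  stopifnot(length(times) == length(surv), length(times) >= 1,
            !is.unsorted(times), all(surv >= 0), all(surv <= 1),
            all(diff(surv) <= 1e-12))
  if (times[1] > 0) {
    times <- c(0, times)
    surv <- c(1, surv)
  }
  if (abs(surv[1] - 1) > 1e-12) stop("S(0) must equal 1")
  structure(list(times = times, surv = surv), class = "pdm_pwsurv")
}

#' Convert a Kaplan-Meier curve to its piecewise-linear approximation
#'
#' Knots at the (per-protocol) grid times of the estimate, with linear
#' interpolation between them and flat extrapolation beyond the last.
#'
#' @param curve a `pdm_survcurve` from [km_curve()] (or a data.frame with
#'   `time` and `surv`).
#' @return a `pdm_pwsurv`.
#' @export
piecewise_from_km <- function(curve) {
  if (nrow(curve) == 0) stop("empty survival curve")
  piecewise_survival(curve$time, curve$surv)
}

#' Evaluate a piecewise-linear survival curve
#' @param pw a `pdm_pwsurv`.
#' @param t times (months).
#' @return S(t), linearly interpolated, flat beyond the last knot.
#' @export
pw_surv <- function(pw, t) {
  if (length(pw$times) == 1) return(rep(pw$surv, length(t)))
  stats::approx(pw$times, pw$surv, xout = t, method = "linear",
                rule = 2)$y
}

# Inverse: smallest t with S(t) = u. Inf when u below the curve's minimum
# (the event never happens within the observed span).
pw_inverse <- function(pw, u) {
  smin <- min(pw$surv)
  out <- rep(Inf, length(u))
  if (length(pw$times) == 1) return(out)
  ok <- u >= smin
  if (any(ok)) {
    s <- rev(pw$surv)
    tt <- rev(pw$times)
    keep <- !duplicated(s, fromLast = TRUE)  # flat segments: earliest time
    out[ok] <- stats::approx(s[keep], tt[keep], xout = u[ok],
                             method = "linear", rule = 2)$y
  }
  out
}

# ---- Lakatos Markov sample size --------------------------------------------

#' Log-rank sample size against a piecewise-linear control curve
#'
#' Markov (Lakatos-style) evaluation on monthly intervals: the experimental
#' curve is `S_c(t)^hr` (proportional hazards); at-risk proportions in each
#' arm are depleted by events, dropout, and (with a finite accrual period)
#' administrative censoring; interval-wise contributions to the expected
#' log-rank numerator and its variance give the total N meeting the target
#' power. The simpler Schoenfeld normal-approximation N
#' (`events / mean event probability`) is reported as a cross-check.
#'
#' @param control a `pdm_pwsurv` control-arm survival curve covering
#'   `[0, length_months]` (flat extrapolation applies beyond its last knot).
#' @param spec a [design_spec()].
#' @param step_months discretization step (default 1 month).
#' @return list of class `pdm_samplesize`: `n_total` (rounded up to an even
#'   total under 1:1 allocation), `n_per_arm`, `d_events`
#'   ([schoenfeld_events()]), `event_prob_control`, `event_prob_experimental`,
#'   `n_schoenfeld`, `method = "lakatos"`.
#' @export
lakatos_sample_size <- function(control, spec, step_months = 1) {
  L <- spec$length_months
  hr <- spec$hr
  if (pw_surv(control, L) >= 1 - 1e-12)
    stop("control curve predicts no events over the study; sample size undefined")
  r <- spec$allocation_ratio
  qc <- 1 / (1 + r)   # control fraction
  qe <- r / (1 + r)
  grid <- seq(0, L, by = step_months)
  if (grid[length(grid)] < L) grid <- c(grid, L)
  Sc <- pw_surv(control, grid)
  Se <- Sc^hr
  # conditional event probabilities per interval
  pc <- -diff(Sc) / Sc[-length(Sc)]
  pe <- -diff(Se) / Se[-length(Se)]
  # monthly dropout / administrative-censoring probabilities
  pd <- 1 - exp(-spec$dropout_hazard * diff(grid))
  # with uniform accrual over A months, a patient entering at time a is
  # administratively censored at L - a; in reverse time the at-risk
  # fraction from accrual alone at time t is min(1, (L - t)/A)
  acc_frac <- function(t) {
    A <- spec$accrual_months
    if (A <= 0) rep(1, length(t)) else pmin(1, pmax(0, (L - t) / A))
  }
  rho_c <- qc; rho_e <- qe
  num <- 0; var <- 0
  d_total_c <- 0; d_total_e <- 0
  t0 <- grid[-length(grid)]
  a0 <- acc_frac(t0); a1 <- acc_frac(grid[-1])
  for (i in seq_along(pc)) {
    # administrative censoring from staggered entry shrinks both arms
    adm <- if (a0[i] > 0) a1[i] / a0[i] else 0
    d_c <- rho_c * pc[i]
    d_e <- rho_e * pe[i]
    d_i <- d_c + d_e
    if (d_i > 0 && rho_c > 0 && rho_e > 0) {
      phi <- rho_e / rho_c
      theta <- hr
      num <- num + d_i * (phi * theta / (1 + phi * theta) -
                            phi / (1 + phi))
      var <- var + d_i * phi / (1 + phi)^2
    }
    d_total_c <- d_total_c + d_c
    d_total_e <- d_total_e + d_e
    rho_c <- (rho_c - d_c) * (1 - pd[i]) * adm
    rho_e <- (rho_e - d_e) * (1 - pd[i]) * adm
  }
  z <- stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
  n_raw <- z^2 * var / num^2
  n_total <- ceiling(n_raw)
  if (r == 1 && n_total %% 2 == 1) n_total <- n_total + 1
  d <- schoenfeld_events(spec)
  p_ev_c <- 1 - pw_surv(control, L)
  p_ev_e <- 1 - pw_surv(control, L)^hr
  n_sch <- ceiling(d / (qc * p_ev_c + qe * p_ev_e))
  if (r == 1 && n_sch %% 2 == 1) n_sch <- n_sch + 1
  structure(list(n_total = n_total, n_per_arm = n_total * c(qc, qe),
                 d_events = d, event_prob_control = p_ev_c,
                 event_prob_experimental = p_ev_e, n_schoenfeld = n_sch,
                 method = "lakatos", spec = spec),
            class = "pdm_samplesize")
}

#' @export
print.pdm_samplesize <- function(x, ...) {
  cat(sprintf(
    "log-rank sample size (HR %.2f, %g-month study): N = %d total (%d events; Schoenfeld cross-check N = %d)\n",
    x$spec$hr, x$spec$length_months, x$n_total, x$d_events, x$n_schoenfeld))
  invisible(x)
}

#' Table of total sample sizes over study lengths and hazard ratios
#'
#' Convenience grid (rows = control curves, columns = length x HR), shaped
#' like a design table for a hypothetical two-arm milestone trial.
#'
#' @param controls named list of `pdm_pwsurv` control curves (e.g. annual
#'   vs all-visit estimates).
#' @param lengths_months study lengths (default c(24, 36)).
#' @param hrs hazard ratios (default c(0.50, 0.75)).
#' @param ... passed to [design_spec()].
#' @return data.frame: one row per control curve, one column per
#'   (length, hr) combination.
#' @export
sample_size_grid <- function(controls, lengths_months = c(24, 36),
                             hrs = c(0.50, 0.75), ...) {
  rows <- lapply(names(controls), function(nm) {
    vals <- unlist(lapply(lengths_months, function(L)
      vapply(hrs, function(h)
        lakatos_sample_size(controls[[nm]],
                            design_spec(hr = h, length_months = L, ...))$n_total,
        0)))
    labs <- as.vector(t(outer(lengths_months, hrs, function(L, h)
      sprintf("len%d_hr%.2f", L, h))))
    out <- as.data.frame(as.list(vals))
    names(out) <- labs
    cbind(data.frame(source = nm, stringsAsFactors = FALSE), out)
  })
  do.call(rbind, rows)
}

#' Empirical power by trial simulation
#'
#' Draws event times by inverting the piecewise-linear control curve
#' (experimental arm via `S_c^hr`), applies administrative censoring at the
#' study end (plus optional dropout and uniform accrual), and runs the
#' two-sided log-rank test per replicate.
#'
#' @param control a `pdm_pwsurv` control curve.
#' @param spec a [design_spec()].
#' @param n_total total sample size (split by the allocation ratio).
#' @param n_sims number of simulated trials (default 2000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class `pdm_power`: `power` (rejection proportion),
#'   `se` (binomial standard error), `n_sims`, `n_total`.
#' @export
simulate_power <- function(control, spec, n_total, n_sims = 2000, seed) {
  stopifnot(n_total >= 4)
  set.seed(seed)
  r <- spec$allocation_ratio
  n_c <- round(n_total / (1 + r))
  n_e <- n_total - n_c
  L <- spec$length_months
  rej <- logical(n_sims)
  arm <- c(rep(0L, n_c), rep(1L, n_e))
  for (s in seq_len(n_sims)) {
    u <- stats::runif(n_c + n_e)
    t_ev <- numeric(n_c + n_e)
    t_ev[arm == 0] <- pw_inverse(control, u[arm == 0])
    t_ev[arm == 1] <- pw_inverse(control, u[arm == 1]^(1 / spec$hr))
    cens <- rep(L, n_c + n_e)
    if (spec$accrual_months > 0)
      cens <- cens - stats::runif(n_c + n_e, 0, spec$accrual_months)
    if (spec$dropout_hazard > 0)
      cens <- pmin(cens, stats::rexp(n_c + n_e, spec$dropout_hazard))
    time <- pmin(t_ev, cens)
    status <- as.integer(t_ev <= cens)
    if (sum(status) == 0 || length(unique(arm[status == 1])) == 0) {
      rej[s] <- FALSE
      next
    }
    sd <- survival::survdiff(survival::Surv(time, status) ~ arm)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    rej[s] <- p < spec$alpha
  }
  pow <- mean(rej)
  structure(list(power = pow, se = sqrt(pow * (1 - pow) / n_sims),
                 n_sims = n_sims, n_total = n_total, spec = spec),
            class = "pdm_power")
}

#' @export
print.pdm_power <- function(x, ...) {
  cat(sprintf("empirical power: %.1f%% (SE %.1f%%) at N = %d over %d trials\n",
              100 * x$power, 100 * x$se, x$n_total, x$n_sims))
  invisible(x)
}
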