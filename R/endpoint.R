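# Composite time-to-first-milestone endpoint. A participant's clock runs
# from enrollment to the first scanned visit at which any milestone
# criterion is met; milestone-free participants are right-censored at their
# last completed annual visit. Participants meeting any milestone at
# baseline, or with no follow-up of the scanned kind, are excluded.

scan_months <- function(source_mode) {
  switch(source_mode,
         annual_visits = annual_visits(),
         all_visits = setdiff(visit_grid(), 0L),
         stop("source_mode must be 'annual_visits' or 'all_visits'"))
}

#' Derive the composite endpoint per participant
#'
#' Baseline (month 0) is evaluated over all 25 milestones for the exclusion
#' rule. Under `"annual_visits"` only the five annual follow-ups are
#' scanned; under `"all_visits"` the seven interim visits (3, 6, 9, 18, 30,
#' 42, 54 months) are scanned too, each milestone restricted to its
#' schedule class. Event time is the actual month of the first visit with a
#' hit; censoring time is the last completed annual visit in both modes. A
#' participant observed only at interim visits and event-free is censored at
#' their last interim visit and flagged (`deviation_interim_censor`).
#'
#' @param ds a `pdm_study`.
#' @param registry a milestone registry.
#' @param source_mode `"annual_visits"` or `"all_visits"`.
#' @param missing_baseline `"exclude"` (default) or `"error"` for
#'   participants with no baseline visit.
#' @return data.frame of class `pdm_endpoints`, one row per enrolled
#'   participant: `included`, `exclusion_reason`, `event`, `time_months`,
#'   `first_event_milestones` / `first_event_domains` (semicolon lists),
#'   `deviation_interim_censor`, `source_mode`.
#' @export
derive_endpoint <- function(ds, registry,
                            source_mode = c("annual_visits", "all_visits"),
                            missing_baseline = c("exclude", "error")) {
  source_mode <- match.arg(source_mode)
  missing_baseline <- match.arg(missing_baseline)
  months <- scan_months(source_mode)

  hits <- evaluate_milestones(registry, ds, restrict_to_schedule = TRUE)
  completed <- unique(ds$visits[c("participant_id", "scheduled_month",
                                  "actual_month")])
  ids <- ds$covariates$participant_id

  base_hit_ids <- unique(hits$participant_id[hits$scheduled_month == 0])
  no_baseline <- setdiff(ids, completed$participant_id[
    completed$scheduled_month == 0])
  if (length(no_baseline) && missing_baseline == "error")
    stop("participants without a baseline visit: ",
         paste(utils::head(no_baseline, 5), collapse = ", "))

  fu_hits <- hits[hits$scheduled_month %in% months, , drop = FALSE]
  rec <- lapply(ids, function(id) {
    out <- data.frame(participant_id = id, included = FALSE,
                      exclusion_reason = "none", event = NA_integer_,
                      time_months = NA_real_,
                      first_event_milestones = NA_character_,
                      first_event_domains = NA_character_,
                      deviation_interim_censor = FALSE,
                      stringsAsFactors = FALSE)
    if (id %in% no_baseline) {
      out$exclusion_reason <- "missing_baseline"
      return(out)
    }
    if (id %in% base_hit_ids) {
      out$exclusion_reason <- "baseline_milestone"
      return(out)
    }
    comp <- completed[completed$participant_id == id &
                        completed$scheduled_month > 0, , drop = FALSE]
    if (!any(comp$scheduled_month %in% months)) {
      out$exclusion_reason <- "no_followup"
      return(out)
    }
    out$included <- TRUE
    h <- fu_hits[fu_hits$participant_id == id, , drop = FALSE]
    if (nrow(h) > 0) {
      first_m <- min(h$scheduled_month)
      h1 <- h[h$scheduled_month == first_m, , drop = FALSE]
      out$event <- 1L
      out$time_months <- h1$actual_month[1L]
      out$first_event_milestones <- paste(sort(h1$milestone), collapse = ";")
      out$first_event_domains <- paste(sort(unique(h1$domain)), collapse = ";")
    } else {
      annual <- comp[comp$scheduled_month %in% annual_visits(), , drop = FALSE]
      out$event <- 0L
      if (nrow(annual) > 0) {
        out$time_months <- annual$actual_month[which.max(annual$scheduled_month)]
      } else {
        out$time_months <- comp$actual_month[which.max(comp$scheduled_month)]
        out$deviation_interim_censor <- TRUE
      }
    }
    out
  })
  res <- do.call(rbind, rec)
  res$source_mode <- source_mode
  class(res) <- c("pdm_endpoints", "data.frame")
  res
}

split_semicolon <- function(x) strsplit(x, ";", fixed = TRUE)

#' Tabulate first events by milestone and domain
#'
#' Counts participants (not milestone instances) whose first event included
#' each milestone / domain, as a count and percent of included
#' participants, plus the breakdown of how many first events spanned 1-4
#' domains concurrently.
#'
#' @param records a `pdm_endpoints` data.frame (one source mode).
#' @param registry a milestone registry (for the milestone -> domain map and
#'   zero-count rows).
#' @return list of class `pdm_first_event_table`: `overall`, `by_domain`,
#'   `by_milestone`, `multi_domain`.
#' @export
tabulate_first_events <- function(records, registry) {
  if (length(unique(records$source_mode)) > 1)
    stop("records mix source modes")
  inc <- records[records$included, , drop = FALSE]
  ev <- inc[inc$event == 1, , drop = FALSE]
  n_inc <- nrow(inc)
  doms <- milestone_domains(registry)

  mls <- split_semicolon(ev$first_event_milestones)
  m_count <- vapply(names(doms), function(m)
    sum(vapply(mls, function(s) m %in% s, NA)), 0L)
  dms <- split_semicolon(ev$first_event_domains)
  d_count <- vapply(unique(doms), function(d)
    sum(vapply(dms, function(s) d %in% s, NA)), 0L)
  n_dom <- vapply(dms, length, 0L)
  multi <- as.data.frame(table(n_domains = factor(n_dom, levels = 1:4)),
                         responseName = "count")
  pct <- function(k) if (n_inc > 0) 100 * k / n_inc else 0 * k
  structure(list(
    overall = data.frame(n_included = n_inc, n_events = nrow(ev),
                         percent = pct(nrow(ev))),
    by_domain = data.frame(domain = names(d_count), count = unname(d_count),
                           percent = unname(pct(d_count))),
    by_milestone = data.frame(milestone = names(m_count),
                              domain = unname(doms[names(m_count)]),
                              count = unname(m_count),
                              percent = unname(pct(m_count))),
    multi_domain = multi,
    source_mode = unique(records$source_mode)),
    class = "pdm_first_event_table")
}

#' @export
print.pdm_first_event_table <- function(x, ...) {
  cat("first-event table (", x$source_mode, "): ", x$overall$n_events,
      "/", x$overall$n_included, " (",
      sprintf("%.1f%%", x$overall$percent), ") reached any milestone\n",
      sep = "")
  print(x$by_domain[order(-x$by_domain$count), ], row.names = FALSE)
  invisible(x)
}

#' Tabulate how often each milestone was ever reached
#'
#' Counts included participants with at least one hit of each milestone at
#' any scanned visit, regardless of whether another milestone occurred
#' first. Always at least the first-event count for every milestone.
#'
#' @inheritParams derive_endpoint
#' @return list with `by_domain` and `by_milestone` data.frames
#'   (count and percent of included participants).
#' @export
tabulate_ever_reached <- function(ds, registry,
                                  source_mode = c("annual_visits",
                                                  "all_visits")) {
  source_mode <- match.arg(source_mode)
  records <- derive_endpoint(ds, registry, source_mode)
  inc_ids <- records$participant_id[records$included]
  months <- scan_months(source_mode)
  hits <- evaluate_milestones(registry, ds, restrict_to_schedule = TRUE)
  hits <- hits[hits$participant_id %in% inc_ids &
                 hits$scheduled_month %in% months, , drop = FALSE]
  doms <- milestone_domains(registry)
  m_count <- vapply(names(doms), function(m)
    length(unique(hits$participant_id[hits$milestone == m])), 0L)
  d_count <- vapply(unique(doms), function(d)
    length(unique(hits$participant_id[hits$domain == d])), 0L)
  n_inc <- length(inc_ids)
  pct <- function(k) if (n_inc > 0) 100 * k / n_inc else 0 * k
  list(by_domain = data.frame(domain = names(d_count),
                              count = unname(d_count),
                              percent = unname(pct(d_count))),
       by_milestone = data.frame(milestone = names(m_count),
                                 domain = unname(doms[names(m_count)]),
                                 count = unname(m_count),
                                 percent = unname(pct(m_count))),
       n_included = n_inc, source_mode = source_mode)
}

#' Write endpoint records to CSV
#' @param records a `pdm_endpoints` data.frame.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_endpoint_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}
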