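# Stability of the composite endpoint: once a participant reaches a first
# milestone at an annual visit, do they still meet criteria for ANY
# milestone at subsequent annual visits? Reachers split into persistent
# (hit at the next annual visit), temporary reverters (clean at the next
# but hit at a later one), and permanent reverters (never hit again);
# participants with no subsequent annual visit are set aside.

#' Classify milestone reachers by persistence
#'
#' @param ds a `pdm_study`.
#' @param registry a milestone registry.
#' @param records endpoint records derived in `"annual_visits"` mode.
#' @param restrict_to_schedule restrict subsequent-status evaluation to each
#'   milestone's schedule class (default TRUE; all annual visits assess all
#'   milestones, so this only matters for irregular data).
#' @return data.frame of class `pdm_reverters`, one row per event
#'   participant: `category` (persistent / temporary_reverter /
#'   permanent_reverter / no_subsequent_annual_visit),
#'   `reversion_gap_years` (temporary reverters only),
#'   `n_subsequent_annual_visits`, `le2_additional_followups`.
#' @export
classify_reverters <- function(ds, registry, records,
                               restrict_to_schedule = TRUE) {
  if (!all(records$source_mode == "annual_visits"))
    stop("stability analysis requires annual_visits endpoint records")
  ev <- records[records$included & records$event == 1, , drop = FALSE]
  hits <- evaluate_milestones(registry, ds, restrict_to_schedule)
  completed <- unique(ds$visits[c("participant_id", "scheduled_month")])
  out <- lapply(seq_len(nrow(ev)), function(i) {
    id <- ev$participant_id[i]
    ev_month <- ev$time_months[i]
    subs <- sort(completed$scheduled_month[
      completed$participant_id == id &
        completed$scheduled_month %in% annual_visits() &
        completed$scheduled_month > ev_month])
    hit_months <- unique(hits$scheduled_month[
      hits$participant_id == id & hits$scheduled_month %in% subs])
    rec <- data.frame(participant_id = id, event_month = ev_month,
                      category = NA_character_,
                      reversion_gap_years = NA_real_,
                      n_subsequent_annual_visits = length(subs),
                      le2_additional_followups = length(subs) <= 2,
                      stringsAsFactors = FALSE)
    if (length(subs) == 0) {
      rec$category <- "no_subsequent_annual_visit"
    } else if (subs[1L] %in% hit_months) {
      rec$category <- "persistent"
    } else if (length(hit_months) > 0) {
      rec$category <- "temporary_reverter"
      rec$reversion_gap_years <- (min(hit_months) - ev_month) / 12
    } else {
      rec$category <- "permanent_reverter"
    }
    rec
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(participant_id = character(), event_month = numeric(),
                      category = character(), reversion_gap_years = numeric(),
                      n_subsequent_annual_visits = integer(),
                      le2_additional_followups = logical())
  class(res) <- c("pdm_reverters", "data.frame")
  res
}

#' Domain-level persistence summary
#'
#' For participants whose first event included each domain (and who
#' completed at least one subsequent annual visit), the proportion who met
#' milestone criteria (a) within the same domain at the next annual visit,
#' (b) within any domain at the next annual visit, and (c) within any
#' domain at any subsequent annual visit.
#'
#' @inheritParams classify_reverters
#' @return data.frame, one row per domain: `n`, `same_domain_next`,
#'   `any_domain_next`, `any_domain_any_subsequent` (proportions).
#' @export
domain_persistence <- function(ds, registry, records,
                               restrict_to_schedule = TRUE) {
  ev <- records[records$included & records$event == 1, , drop = FALSE]
  hits <- evaluate_milestones(registry, ds, restrict_to_schedule)
  completed <- unique(ds$visits[c("participant_id", "scheduled_month")])
  doms <- unique(milestone_domains(registry))
  per <- lapply(seq_len(nrow(ev)), function(i) {
    id <- ev$participant_id[i]
    ev_month <- ev$time_months[i]
    subs <- sort(completed$scheduled_month[
      completed$participant_id == id &
        completed$scheduled_month %in% annual_visits() &
        completed$scheduled_month > ev_month])
    if (length(subs) == 0) return(NULL)
    h <- hits[hits$participant_id == id & hits$scheduled_month %in% subs, ,
              drop = FALSE]
    next_m <- subs[1L]
    data.frame(
      participant_id = id,
      first_domains = ev$first_event_domains[i],
      any_next = next_m %in% h$scheduled_month,
      any_any = nrow(h) > 0,
      same_next_domains = paste(unique(
        h$domain[h$scheduled_month == next_m]), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rows <- lapply(doms, function(d) {
    if (is.null(per)) {
      return(data.frame(domain = d, n = 0L, same_domain_next = NA_real_,
                        any_domain_next = NA_real_,
                        any_domain_any_subsequent = NA_real_))
    }
    in_d <- vapply(split_semicolon(per$first_domains),
                   function(s) d %in% s, NA)
    sub <- per[in_d, , drop = FALSE]
    n <- nrow(sub)
    same <- vapply(split_semicolon(sub$same_next_domains),
                   function(s) d %in% s, NA)
    data.frame(domain = d, n = n,
               same_domain_next = if (n) mean(same) else NA_real_,
               any_domain_next = if (n) mean(sub$any_next) else NA_real_,
               any_domain_any_subsequent = if (n) mean(sub$any_any)
                                           else NA_real_)
  })
  do.call(rbind, rows)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Plain Pearson chi-square with 1 degree of freedom,
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`. The continuity (Yates) correction is
#' OFF by default, matching the convention used for the reverter
#' comparison.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param correction apply the continuity correction (default FALSE).
#' @return list of class `pdm_chi2`: `counts`, `statistic`, `df` (1),
#'   `p_value`, `correction`.
#' @export
pearson_chi2_2x2 <- function(counts, correction = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all margins of the 2x2 table must be positive")
  n <- sum(counts)
  num <- abs(counts[1, 1] * counts[2, 2] - counts[1, 2] * counts[2, 1])
  if (correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(rowSums(counts)) / prod(colSums(counts))
  structure(list(counts = counts, statistic = unname(stat), df = 1L,
                 p_value = stats::pchisq(unname(stat), df = 1,
                                         lower.tail = FALSE),
                 correction = correction),
            class = "pdm_chi2")
}

#' @export
print.pdm_chi2 <- function(x, ...) {
  cat(sprintf("Pearson chi-square(1)%s = %.4g, p = %.4g\n",
              if (x$correction) " [continuity-corrected]" else "",
              x$statistic, x$p_value))
  invisible(x)
}

#' Compare permanent vs temporary reverters on short follow-up
#'
#' Builds the 2x2 table of reverter group (permanent vs temporary) against
#' completing two or fewer additional annual follow-ups, and runs
#' [pearson_chi2_2x2()].
#'
#' @param reverters a `pdm_reverters` data.frame.
#' @param correction continuity correction (default FALSE).
#' @return a `pdm_chi2` result; the table rows are (permanent, temporary)
#'   and columns (<=2 follow-ups, >2 follow-ups).
#' @export
reverter_followup_test <- function(reverters, correction = FALSE) {
  perm <- reverters[reverters$category == "permanent_reverter", ]
  temp <- reverters[reverters$category == "temporary_reverter", ]
  counts <- rbind(
    permanent = c(sum(perm$le2_additional_followups),
                  sum(!perm$le2_additional_followups)),
    temporary = c(sum(temp$le2_additional_followups),
                  sum(!temp$le2_additional_followups)))
  colnames(counts) <- c("le2_followups", "gt2_followups")
  pearson_chi2_2x2(counts, correction = correction)
}
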