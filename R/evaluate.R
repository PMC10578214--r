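# Vectorized milestone evaluation over a wide visit table. One row per
# (participant, scheduled visit); one column per item, motor-exam items
# duplicated as "ITEM|OFF" / "ITEM|ON". Missing is NA and, under the
# conservative rule, never satisfies a criterion.

visits_wide <- function(visits) {
  if (nrow(visits) == 0) {
    return(data.frame(participant_id = character(), scheduled_month = integer(),
                      actual_month = numeric()))
  }
  dt <- data.table::as.data.table(visits)
  dt[, key := ifelse(!is.na(state) & state %in% c("OFF", "ON"),
                     paste(item_code, state, sep = "|"), item_code)]
  w <- data.table::dcast(dt, participant_id + scheduled_month + actual_month ~ key,
                         value.var = "value",
                         fun.aggregate = function(x) x[1L])
  as.data.frame(w)
}

col_or_na <- function(w, nm) {
  if (nm %in% names(w)) w[[nm]] else rep(NA_real_, nrow(w))
}

eval_node <- function(node, w, cutoff) {
  n <- nrow(w)
  switch(node$kind,
    all = Reduce(`&`, lapply(node$children, eval_node, w = w, cutoff = cutoff)),
    any = Reduce(`|`, lapply(node$children, eval_node, w = w, cutoff = cutoff)),
    atom = {
      op <- switch(node$cmp, ">=" = `>=`, "==" = `==`, "<" = `<`)
      test <- function(v) !is.na(v) & op(v, node$threshold)
      if (node$states == "on_or_off") {
        test(col_or_na(w, paste0(node$item, "|OFF"))) |
          test(col_or_na(w, paste0(node$item, "|ON"))) |
          test(col_or_na(w, node$item))
      } else {
        test(col_or_na(w, node$item))
      }
    },
    bp_drop = {
      pref <- if (node$which == "sys") "BP_SYS_" else "BP_DIA_"
      from <- col_or_na(w, paste0(pref, toupper(node$from)))
      to <- col_or_na(w, paste0(pref, toupper(node$to)))
      !is.na(from) & !is.na(to) & (from - to) >= node$min_drop
    },
    cog_impairment = {
      doms <- cognitive_domains()
      n_imp <- rep(0L, n)
      for (tests in doms) {
        imp <- rep(FALSE, n)
        for (code in tests) {
          v <- col_or_na(w, code)
          imp <- imp | (!is.na(v) & v <= cutoff)
        }
        n_imp <- n_imp + imp
      }
      n_imp >= node$min_domains
    },
    flag = {
      v <- col_or_na(w, node$item)
      !is.na(v) & v == 1
    },
    stop("unknown criterion node kind: ", node$kind)
  )
}

#' Evaluate all milestones on every visit of a dataset
#'
#' Applies each milestone's criterion tree to every visit. With
#' `restrict_to_schedule = TRUE`, a milestone is only evaluated at visits
#' where its schedule class says it is assessed (baseline is always fully
#' evaluated, as required for the baseline-exclusion rule).
#'
#' @param registry a [build_registry()] registry.
#' @param visits long-format visit data (the `visits` element of a
#'   [read_study_tables()] dataset, or the dataset itself).
#' @param restrict_to_schedule logical; restrict milestones to their
#'   schedule class.
#' @return data.frame of hits with columns `participant_id`,
#'   `scheduled_month`, `actual_month`, `milestone`, `domain` (zero rows if
#'   nothing is hit).
#' @export
evaluate_milestones <- function(registry, visits, restrict_to_schedule = TRUE) {
  if (inherits(visits, "pdm_study")) visits <- visits$visits
  w <- visits_wide(visits)
  doms <- milestone_domains(registry)
  out <- vector("list", length(registry$milestones))
  for (i in seq_along(registry$milestones)) {
    m <- registry$milestones[[i]]
    hit <- eval_node(m$criterion, w, registry$cognitive_cutoff)
    if (restrict_to_schedule) {
      ok <- w$scheduled_month == 0 |
        w$scheduled_month %in% schedule_months(m$schedule_class)
      hit <- hit & ok
    }
    if (any(hit)) {
      out[[i]] <- data.frame(
        participant_id = w$participant_id[hit],
        scheduled_month = w$scheduled_month[hit],
        actual_month = w$actual_month[hit],
        milestone = m$id, domain = m$domain, stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, NA)]
  if (length(out) == 0) {
    return(data.frame(participant_id = character(), scheduled_month = integer(),
                      actual_month = numeric(), milestone = character(),
                      domain = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$participant_id, res$scheduled_month, res$milestone), ,
      drop = FALSE]
}

#' Evaluate one visit
#'
#' @param registry a milestone registry.
#' @param visit long-format rows for a single (participant, scheduled_month).
#' @param restrict_to_schedule see [evaluate_milestones()].
#' @return a `milestone_hit_set`: list with `participant_id`,
#'   `scheduled_month`, `hits` (milestone ids) and `domains_hit`.
#' @export
evaluate_visit <- function(registry, visit, restrict_to_schedule = TRUE) {
  stopifnot(length(unique(visit$participant_id)) <= 1,
            length(unique(visit$scheduled_month)) <= 1)
  h <- evaluate_milestones(registry, visit, restrict_to_schedule)
  structure(list(participant_id = unique(visit$participant_id),
                 scheduled_month = unique(visit$scheduled_month),
                 hits = h$milestone,
                 domains_hit = unique(h$domain)),
            class = "milestone_hit_set")
}

#' Evaluate a single criterion atom on one visit
#'
#' Mostly useful for auditing a registry entry; `evaluate_milestones()` is
#' the workhorse.
#'
#' @param atom a criterion node built with the [criterion] constructors.
#' @param visit long-format rows for a single visit.
#' @param cognitive_cutoff impairment cutoff used by cognitive-domain atoms.
#' @return logical scalar; FALSE whenever a required value is missing.
#' @export
evaluate_atom <- function(atom, visit, cognitive_cutoff = -1.5) {
  w <- visits_wide(visit)
  if (nrow(w) == 0) return(FALSE)
  as.logical(eval_node(atom, w, cognitive_cutoff))[1L]
}
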