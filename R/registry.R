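# ---- criterion tree constructors -------------------------------------------

#' Criterion atoms and boolean nodes
#'
#' A milestone criterion is a small boolean tree over atoms. Atoms compare a
#' single item score against a threshold (`criterion_atom`), test a postural
#' blood-pressure drop (`bp_drop_atom`), count impaired cognitive domains
#' (`cog_impairment_atom`), or test an investigator yes/no flag
#' (`flag_atom`). `all_of`/`any_of` combine children.
#'
#' Under the conservative missing-data rule, an atom whose required value is
#' absent evaluates to FALSE: a milestone can never be met through missing
#' data. Atoms with `states = "on_or_off"` are satisfied when EITHER the
#' medication-OFF or the medication-ON score meets the threshold, so a single
#' recorded state suffices.
#'
#' @param item item code from [item_code_table()].
#' @param cmp comparator, one of `">="`, `"=="`, `"<"`.
#' @param threshold numeric threshold within the item's instrument range.
#' @param states `"none"` for items without a medication state, or
#'   `"on_or_off"` for motor-exam items.
#' @param which `"sys"` or `"dia"` blood-pressure component.
#' @param from,to postural positions (`"supine"`, `"sitting"`, `"standing"`).
#' @param min_drop minimum positional drop in mm Hg.
#' @param min_domains minimum number of impaired cognitive domains.
#' @param ... child nodes for `all_of`/`any_of`.
#' @return a criterion node (list with class `"pdm_criterion"`).
#' @name criterion
NULL

new_criterion <- function(x) structure(x, class = "pdm_criterion")

#' @rdname criterion
#' @export
criterion_atom <- function(item, cmp, threshold, states = c("none", "on_or_off")) {
  states <- match.arg(states)
  stopifnot(cmp %in% c(">=", "==", "<"))
  codes <- item_code_table()
  i <- match(item, codes$code)
  if (is.na(i)) stop("unknown item code: ", item)
  if (threshold < codes$min[i] || threshold > codes$max[i])
    stop("threshold ", threshold, " outside instrument range for ", item)
  new_criterion(list(kind = "atom", item = item, cmp = cmp,
                     threshold = threshold, states = states))
}

#' @rdname criterion
#' @export
bp_drop_atom <- function(which = c("sys", "dia"), from = "sitting",
                         to = "standing", min_drop) {
  which <- match.arg(which)
  stopifnot(from %in% c("supine", "sitting"), to == "standing", min_drop > 0)
  new_criterion(list(kind = "bp_drop", which = which, from = from, to = to,
                     min_drop = min_drop))
}

#' @rdname criterion
#' @export
cog_impairment_atom <- function(min_domains = 2) {
  new_criterion(list(kind = "cog_impairment", min_domains = min_domains))
}

#' @rdname criterion
#' @export
flag_atom <- function(item) {
  stopifnot(item %in% c("FLAG_PDD", "FLAG_COG_FUNC_IMPAIR"))
  new_criterion(list(kind = "flag", item = item))
}

#' @rdname criterion
#' @export
all_of <- function(...) new_criterion(list(kind = "all", children = list(...)))

#' @rdname criterion
#' @export
any_of <- function(...) new_criterion(list(kind = "any", children = list(...)))

# ---- registry ---------------------------------------------------------------

#' Build the registry of the 25 progression milestones
#'
#' The registry is the declarative core of the framework: 25 milestone
#' definitions across six clinical domains, each with a criterion tree and a
#' visit-schedule class. Thresholds mark unequivocal, at least moderately
#' severe dysfunction (e.g. MDS-UPDRS item responses of 3 "severe" or 4,
#' MoCA below 21, loss of independent function on Schwab & England).
#'
#' Schedule classes: most milestones are assessed quarterly in year one and
#' semiannually thereafter (`"standard"`); the three SCOPA-AUT-based
#' autonomic milestones only at six months and then annually
#' (`"six_month_then_annual"`); the three cognitive-battery/MoCA/investigator
#' milestones only annually (`"annual_only"`).
#'
#' @param cognitive_cutoff z-score at or below which a cognitive test counts
#'   as impaired for the dementia (composite) milestone; a domain is
#'   impaired when at least one of its tests is at or below the cutoff.
#'   Default -1.5 standard deviations.
#' @return object of class `"milestone_registry"`: a named list of milestone
#'   definitions plus the cognitive cutoff.
#' @export
build_registry <- function(cognitive_cutoff = -1.5) {
  ms <- function(id, label, domain, criterion, schedule_class = "standard") {
    structure(list(id = id, label = label, domain = domain,
                   criterion = criterion, schedule_class = schedule_class),
              class = "milestone_definition")
  }
  u <- function(item, thr = 3, cmp = ">=", states = "none")
    criterion_atom(item, cmp, thr, states)

  defs <- list(
    # Domain 1: walking and balance
    ms("walking_balance", "Walking and balance", "walking_balance",
       u("UPDRS_2_12")),
    ms("freezing", "Freezing", "walking_balance", u("UPDRS_2_13")),
    ms("gait", "Gait", "walking_balance",
       u("UPDRS_3_10", states = "on_or_off")),
    ms("freezing_of_gait", "Freezing of gait", "walking_balance",
       u("UPDRS_3_11", 4, "==", states = "on_or_off")),
    ms("postural_instability", "Postural instability", "walking_balance",
       u("UPDRS_3_12", states = "on_or_off")),
    ms("hoehn_yahr", "Hoehn and Yahr stage", "walking_balance",
       u("HY", 4, states = "on_or_off")),
    # Domain 2: motor complications
    ms("dyskinesias", "Dyskinesias", "motor_complications",
       all_of(u("UPDRS_4_1"), u("UPDRS_4_2"))),
    ms("fluctuations_impact", "Fluctuations (functional impact)",
       "motor_complications", u("UPDRS_4_4")),
    ms("fluctuations_complexity", "Fluctuations (complexity)",
       "motor_complications", u("UPDRS_4_5")),
    # Domain 3: cognition
    ms("cognitive_impairment_moca", "Cognitive impairment (MoCA)",
       "cognition", criterion_atom("MOCA_TOTAL", "<", 21),
       schedule_class = "annual_only"),
    ms("cognitive_impairment_updrs", "Cognitive impairment (MDS-UPDRS)",
       "cognition", u("UPDRS_1_1")),
    ms("hallucinations", "Hallucinations", "cognition", u("UPDRS_1_2")),
    ms("apathy", "Apathy", "cognition", u("UPDRS_1_5")),
    ms("dementia_clinical", "Dementia (clinical diagnosis)", "cognition",
       flag_atom("FLAG_PDD"), schedule_class = "annual_only"),
    ms("dementia_composite", "Dementia (composite)", "cognition",
       all_of(cog_impairment_atom(2), flag_atom("FLAG_COG_FUNC_IMPAIR")),
       schedule_class = "annual_only"),
    # Domain 4: autonomic dysfunction
    ms("urinary_incontinence", "Urinary incontinence", "autonomic",
       all_of(u("UPDRS_1_10"),
              any_of(u("SCOPA_8", 2), u("SCOPA_9", 2))),
       schedule_class = "six_month_then_annual"),
    ms("orthostatic_hypotension", "Orthostatic hypotension", "autonomic",
       all_of(u("SCOPA_15", 2),
              bp_drop_atom("sys", "sitting", "standing", 20),
              bp_drop_atom("dia", "sitting", "standing", 10)),
       schedule_class = "six_month_then_annual"),
    ms("syncope_updrs", "Syncope (MDS-UPDRS)", "autonomic",
       u("UPDRS_1_12", 4, "==")),
    ms("syncope_scopa", "Syncope (SCOPA-AUT)", "autonomic",
       u("SCOPA_16", 1), schedule_class = "six_month_then_annual"),
    # Domain 5: functional dependence
    ms("schwab_england", "Schwab & England", "functional_dependence",
       criterion_atom("SE_ADL", "<", 80)),
    # Domain 6: activities of daily living
    ms("choking", "Choking", "adl", u("UPDRS_2_3")),
    ms("eating", "Eating", "adl", u("UPDRS_2_4")),
    ms("dressing", "Dressing", "adl", u("UPDRS_2_5")),
    ms("hygiene", "Hygiene", "adl", u("UPDRS_2_6")),
    ms("speech", "Speech", "adl", u("UPDRS_3_1", states = "on_or_off"))
  )
  names(defs) <- vapply(defs, `[[`, "", "id")
  structure(list(milestones = defs, cognitive_cutoff = cognitive_cutoff),
            class = "milestone_registry")
}

#' @export
print.milestone_registry <- function(x, ...) {
  doms <- milestone_domains(x)
  cat("milestone_registry:", length(x$milestones), "milestones in",
      length(unique(doms)), "domains\n")
  for (d in unique(doms))
    cat("  ", d, ": ", paste(names(doms)[doms == d], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Milestone id -> domain map
#' @param registry a milestone registry.
#' @return named character vector (names are milestone ids).
#' @export
milestone_domains <- function(registry) {
  vapply(registry$milestones, `[[`, "", "domain")
}

#' Milestone id -> schedule class map
#' @param registry a milestone registry.
#' @return named character vector.
#' @export
milestone_schedule_classes <- function(registry) {
  vapply(registry$milestones, `[[`, "", "schedule_class")
}

#' Milestones assessable at a given follow-up month
#' @param registry a milestone registry.
#' @param month scheduled month (0 = baseline).
#' @return character vector of milestone ids whose schedule class includes
#'   the month; at baseline (month 0) all milestones are returned, since the
#'   baseline evaluation used for exclusions considers every milestone.
#' @export
assessable_milestones <- function(registry, month) {
  if (month == 0) return(names(registry$milestones))
  sc <- milestone_schedule_classes(registry)
  keep <- vapply(sc, function(s) month %in% schedule_months(s), NA)
  names(sc)[keep]
}

# ---- registry serialization -------------------------------------------------

criterion_to_list <- function(node) {
  if (node$kind %in% c("all", "any"))
    list(kind = node$kind, children = lapply(node$children, criterion_to_list))
  else unclass(node)
}

criterion_from_list <- function(x) {
  if (x$kind %in% c("all", "any"))
    new_criterion(list(kind = x$kind,
                       children = lapply(x$children, criterion_from_list)))
  else new_criterion(x)
}

#' Export / import a registry as auditable structured text (JSON)
#'
#' The export is plain JSON so that clinicians can audit thresholds; an
#' imported registry evaluates identically to the original.
#'
#' @param registry a milestone registry.
#' @param path file path.
#' @return `export_registry` invisibly returns `path`; `import_registry`
#'   returns a `milestone_registry`.
#' @export
export_registry <- function(registry, path) {
  out <- list(
    cognitive_cutoff = registry$cognitive_cutoff,
    milestones = lapply(unname(registry$milestones), function(m)
      list(id = m$id, label = m$label, domain = m$domain,
           schedule_class = m$schedule_class,
           criterion = criterion_to_list(m$criterion)))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_registry
#' @export
import_registry <- function(path) {
  x <- jsonlite::read_json(path)
  defs <- lapply(x$milestones, function(m)
    structure(list(id = m$id, label = m$label, domain = m$domain,
                   criterion = criterion_from_list(m$criterion),
                   schedule_class = m$schedule_class),
              class = "milestone_definition"))
  names(defs) <- vapply(defs, `[[`, "", "id")
  structure(list(milestones = defs, cognitive_cutoff = x$cognitive_cutoff),
            class = "milestone_registry")
}
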