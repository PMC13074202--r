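#' Intervention-level taxonomies of the six domains
#'
#' Fixed label sets with strictly ordered urgency ranks (higher = more
#' urgent): physical_activity (initiate/increase/maintain), stress
#' (urgent/reduce/maintain), nutrition (reduce/maintain/increase), sleep
#' (urgent/general), adherence (urgent/general/maintain), general_behaviors
#' (urgent/reduce).
#'
#' @return Named list: domain -> named integer vector (level -> urgency rank).
#' @export
domain_taxonomies <- function() {
  list(
    physical_activity = c(initiate = 3L, increase = 2L, maintain = 1L),
    stress = c(urgent = 3L, reduce = 2L, maintain = 1L),
    nutrition = c(reduce = 3L, increase = 2L, maintain = 1L),
    sleep = c(urgent = 2L, general = 1L),
    adherence = c(urgent = 3L, general = 2L, maintain = 1L),
    general_behaviors = c(urgent = 2L, reduce = 1L)
  )
}

rule_ops <- c("lt", "le", "gt", "ge", "eq", "in")

new_rule <- function(id, domain, when, then, weight = 1, note = NULL) {
  stopifnot(is.character(id), nzchar(id))
  for (cond in when) {
    if (length(cond) < 3) stop("rule ", id, ": condition needs [variable, op, value]")
    if (!cond[[2]] %in% rule_ops)
      stop("rule ", id, ": unknown comparator ", cond[[2]])
  }
  if (weight <= 0) stop("rule ", id, ": weight must be positive")
  structure(list(id = id, domain = domain, when = when, then = then,
                 weight = weight, note = note), class = "kb_rule")
}

#' Load a rule knowledge base from YAML
#'
#' The file carries `fallbacks` (domain -> level fired when no rule matches)
#' and `rules`, each with fields `id`, `domain`, `when` (list of
#' `[variable, comparator, value]` conjuncts; comparators `lt`, `le`, `gt`,
#' `ge`, `eq`, `in`), `then` (target level), `weight`, and an optional
#' provenance `note`. Loading validates against the fixed domain taxonomies
#' and, when a schema is supplied, against the variable names; violations
#' raise an error listing rule id and reason.
#'
#' @param path YAML rule file.
#' @param schema Optional `cohort_schema` for variable-existence checks.
#' @return A `knowledge_base`: `domains` (taxonomies), `fallbacks`, `rules`
#'   grouped by domain.
#' @export
load_rules <- function(path, schema = NULL) {
  raw <- yaml::read_yaml(path)
  tax <- domain_taxonomies()
  rules <- lapply(raw$rules, function(r)
    new_rule(r$id, r$domain, r$when, r$then,
             weight = if (is.null(r$weight)) 1 else r$weight, note = r$note))
  kb <- structure(list(domains = tax,
                       fallbacks = raw$fallbacks,
                       rules = rules), class = "knowledge_base")
  rep <- validate_kb(kb, schema)
  if (nrow(rep$violations))
    stop("invalid knowledge base:\n",
         paste(sprintf("  [%s] %s", rep$violations$rule, rep$violations$reason),
               collapse = "\n"))
  kb
}

#' Validate a knowledge base
#'
#' Checks that all six domains are present with a fallback level inside the
#' taxonomy (so any input is guaranteed a decision), that every rule
#' targets a level of its domain taxonomy, that rule ids are unique, and --
#' when a schema is given -- that every referenced variable exists.
#' Domains with no rules are valid (the fallback covers them) and emit a
#' coverage note.
#'
#' @param kb A `knowledge_base`.
#' @param schema Optional `cohort_schema`.
#' @return List: `violations` (data frame rule/reason) and `notes`.
#' @export
validate_kb <- function(kb, schema = NULL) {
  tax <- domain_taxonomies()
  v <- list(); notes <- character()
  add <- function(rule, reason) v[[length(v) + 1L]] <<- data.frame(rule = rule, reason = reason)
  for (d in names(tax)) {
    fb <- kb$fallbacks[[d]]
    if (is.null(fb)) add("<fallback>", paste0("domain ", d, " has no fallback level"))
    else if (!fb %in% names(tax[[d]]))
      add("<fallback>", paste0("fallback ", fb, " not in ", d, " taxonomy"))
  }
  extra <- setdiff(names(kb$fallbacks), names(tax))
  for (d in extra) add("<fallback>", paste0("unknown domain ", d))
  ids <- vapply(kb$rules, `[[`, character(1), "id")
  for (dup in unique(ids[duplicated(ids)])) add(dup, "duplicate rule id")
  for (r in kb$rules) {
    if (!r$domain %in% names(tax)) { add(r$id, paste0("unknown domain ", r$domain)); next }
    if (!r$then %in% names(tax[[r$domain]]))
      add(r$id, paste0("level ", r$then, " not in ", r$domain,
                       " taxonomy {", paste(names(tax[[r$domain]]), collapse = ", "), "}"))
    if (!is.null(schema)) {
      for (cond in r$when) {
        if (!cond[[1]] %in% schema_names(schema))
          add(r$id, paste0("undefined variable ", cond[[1]]))
      }
    }
  }
  counts <- table(factor(vapply(kb$rules, `[[`, character(1), "domain"),
                         levels = names(tax)))
  for (d in names(counts)[counts == 0])
    notes <- c(notes, paste0("domain ", d, " has no rules; fallback ",
                             kb$fallbacks[[d]] %||% "?", " covers all inputs"))
  list(violations = if (length(v)) do.call(rbind, v)
       else data.frame(rule = character(), reason = character()),
       notes = notes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default shipped knowledge base
#'
#' Loads the rule file shipped with the package: a structural
#' reconstruction of the six-domain rule base with implementation-chosen
#' guideline-anchored thresholds (BP control target <130/80 mmHg,
#' prediabetes glucose >= 100 mg/dL, cholesterol >= 200 mg/dL,
#' triglycerides >= 150 mg/dL, overweight BMI >= 25, adult sleep window
#' 7-9 h). All thresholds live in the YAML file, never in code, so they can
#' be re-parameterized for local calibration.
#'
#' @return A `knowledge_base`.
#' @export
default_kb <- function() {
  load_rules(system.file("extdata", "default_rules.yaml", package = "htncds"),
             schema = default_schema())
}

#' Is blood pressure controlled?
#'
#' Control target: systolic < 130 and diastolic < 80 mmHg.
#'
#' @param sbp Systolic pressure (mmHg).
#' @param dbp Diastolic pressure (mmHg).
#' @return Logical.
#' @export
bp_controlled <- function(sbp, dbp) sbp < 130 & dbp < 80

condition_holds <- function(cond, values) {
  var <- cond[[1]]; op <- cond[[2]]; ref <- cond[[3]]
  if (!var %in% names(values))
    stop("rule references variable absent from patient values: ", var)
  v <- values[[var]]
  if (is.null(v) || (length(v) == 1L && is.na(v)))
    stop("rule input ", var, " is missing; run imputation first")
  switch(op,
    lt = as.numeric(v) < as.numeric(ref),
    le = as.numeric(v) <= as.numeric(ref),
    gt = as.numeric(v) > as.numeric(ref),
    ge = as.numeric(v) >= as.numeric(ref),
    eq = as.character(v) == as.character(ref),
    `in` = {
      sel <- unlist(strsplit(as.character(v), ";", fixed = TRUE))
      any(sel %in% unlist(ref))
    },
    stop("unknown comparator ", op))
}

rule_fires <- function(rule, values) {
  all(vapply(rule$when, condition_holds, logical(1), values = values))
}
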