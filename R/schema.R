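#' Declare a cohort variable
#'
#' A variable schema entry describes one column of a patient table: its kind
#' (numeric, categorical, multi-select), measurement units, a clinically
#' plausible range for numeric kinds, the allowed category labels otherwise,
#' and role flags that mark which stages consume it.
#'
#' @param name Variable name (must match the CSV header).
#' @param kind One of `"numeric"`, `"categorical"`, `"multihot"`.
#' @param units Free-text units, e.g. `"mmHg"`, `"mg/dL"`; `NA` if unitless.
#' @param plausible_range Optional numeric `c(low, high)` with `low < high`;
#'   numeric kinds only.
#' @param categories Character vector of allowed labels; required (non-empty)
#'   for categorical and multihot kinds. For categorical variables category
#'   order also serves as the deterministic tie-break in mode imputation.
#' @param roles Character vector drawn from
#'   `c("identifier", "clustering_feature", "rule_input")`.
#' @return A `variable_schema` list.
#' @export
variable_schema <- function(name, kind = c("numeric", "categorical", "multihot"),
                            units = NA_character_, plausible_range = NULL,
                            categories = NULL, roles = character()) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  bad <- setdiff(roles, c("identifier", "clustering_feature", "rule_input"))
  if (length(bad)) stop("unknown role flag(s): ", paste(bad, collapse = ", "))
  if (!is.null(plausible_range)) {
    if (kind != "numeric") stop("plausible_range only applies to numeric variables: ", name)
    stopifnot(length(plausible_range) == 2L)
    if (!(plausible_range[1] < plausible_range[2]))
      stop("plausible_range low must be < high for variable ", name)
  }
  if (kind %in% c("categorical", "multihot") && (is.null(categories) || !length(categories)))
    stop(kind, " variable ", name, " must declare a non-empty category list")
  structure(
    list(name = name, kind = kind, units = units,
         plausible_range = plausible_range,
         categories = as.character(categories), roles = roles),
    class = "variable_schema"
  )
}

#' Assemble a cohort schema
#'
#' @param ... `variable_schema` entries (or a single list of them).
#' @return A `cohort_schema` object (ordered list of variables). Exactly one
#'   entry must carry the `identifier` role.
#' @export
cohort_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && !inherits(vars[[1]], "variable_schema")) vars <- vars[[1]]
  if (!all(vapply(vars, inherits, logical(1), "variable_schema")))
    stop("all entries must be variable_schema objects")
  nm <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate variable names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  n_id <- sum(vapply(vars, function(v) "identifier" %in% v$roles, logical(1)))
  if (n_id != 1L) stop("schema must contain exactly one identifier variable, found ", n_id)
  names(vars) <- nm
  structure(vars, class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("<cohort_schema> ", length(x), " variables (",
      sum(schema_kinds(x) == "numeric"), " numeric, ",
      sum(schema_kinds(x) == "categorical"), " categorical, ",
      sum(schema_kinds(x) == "multihot"), " multihot)\n", sep = "")
  invisible(x)
}

#' Variable kinds of a schema
#' @param schema A `cohort_schema`.
#' @return Named character vector of kinds.
#' @export
schema_kinds <- function(schema) {
  stats::setNames(vapply(schema, `[[`, character(1), "kind"),
                  vapply(schema, `[[`, character(1), "name"))
}

#' Variable names of a schema
#' @param schema A `cohort_schema`.
#' @return Character vector.
#' @export
schema_names <- function(schema) unname(vapply(schema, `[[`, character(1), "name"))

#' Name of the identifier variable in a schema
#' @param schema A `cohort_schema`.
#' @return Character scalar.
#' @export
identifier_variable <- function(schema) {
  nm <- schema_names(schema)
  nm[vapply(schema, function(v) "identifier" %in% v$roles, logical(1))]
}

#' Variables carrying a given role flag
#' @param schema A `cohort_schema`.
#' @param role One of `"identifier"`, `"clustering_feature"`, `"rule_input"`.
#' @return Character vector of variable names.
#' @export
schema_role <- function(schema, role) {
  nm <- schema_names(schema)
  nm[vapply(schema, function(v) role %in% v$roles, logical(1))]
}

#' Read a schema from a YAML file
#'
#' The file holds a list of variable entries with fields `name`, `kind`,
#' `units`, `plausible_range`, `categories`, `roles`.
#'
#' @param path Path to a YAML schema file.
#' @return A `cohort_schema`.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  vars <- lapply(raw, function(v) {
    variable_schema(
      name = v$name, kind = v$kind,
      units = if (is.null(v$units)) NA_character_ else v$units,
      plausible_range = if (is.null(v$plausible_range)) NULL else as.numeric(v$plausible_range),
      categories = v$categories,
      roles = if (is.null(v$roles)) character() else unlist(v$roles)
    )
  })
  cohort_schema(vars)
}

#' Write a schema to a YAML file
#' @param schema A `cohort_schema`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_schema <- function(schema, path) {
  raw <- lapply(unclass(schema), function(v) {
    v[!vapply(v, is.null, logical(1))]
  })
  yaml::write_yaml(unname(raw), path)
  invisible(path)
}

#' Default 52-variable hypertension cohort schema
#'
#' One identifier plus 52 data variables: 16 numeric measurements (the 15
#' clustering features -- age, weight, height, systolic/diastolic blood
#' pressure, sleep duration, weekly physical activity, cigarettes per day,
#' screen time, hemoglobin, glucose, cholesterol, triglycerides, creatinine,
#' eGFR -- plus derived BMI), 34 categorical items covering sociodemographic,
#' clinical, behavioral and symptom domains, and 2 multi-select checklists
#' (comorbidities, avoided foods). Plausible ranges are broad clinical
#' screening bounds, used for flagging only, never for deletion.
#'
#' @return A `cohort_schema` with 53 entries.
#' @export
default_schema <- function() {
  num <- function(name, units, lo, hi, roles = c("clustering_feature", "rule_input"))
    variable_schema(name, "numeric", units, c(lo, hi), roles = roles)
  cat2 <- function(name, categories, roles = character())
    variable_schema(name, "categorical", categories = categories, roles = roles)

  yn <- c("no", "yes")
  freq3 <- c("never", "occasional", "frequent")

  cohort_schema(
    variable_schema("patient_id", "categorical", categories = "any",
                    roles = "identifier"),
    # -- numeric clinical measurements ------------------------------------
    num("age", "years", 18, 100),
    num("weight", "kg", 30, 200),
    num("height", "cm", 120, 220),
    num("sbp", "mmHg", 70, 250),
    num("dbp", "mmHg", 40, 150),
    num("sleep_hours", "h/night", 2, 14),
    num("activity_days", "days/week", 0, 7),
    num("cigarettes_per_day", "cigarettes/day", 0, 60),
    num("screen_hours", "h/day", 0, 18),
    num("hemoglobin", "g/dL", 5, 22),
    num("glucose", "mg/dL", 40, 600),
    num("cholesterol", "mg/dL", 80, 500),
    num("triglycerides", "mg/dL", 30, 1000),
    num("creatinine", "mg/dL", 0.2, 15),
    num("egfr", "mL/min/1.73m2", 5, 150),
    variable_schema("bmi", "numeric", "kg/m2", c(10, 70), roles = "rule_input"),
    # -- categorical: sociodemographic ------------------------------------
    cat2("gender", c("female", "male")),
    cat2("marital_status", c("single", "married", "widowed", "divorced")),
    cat2("education_level", c("1", "2", "3")),
    cat2("employment_status", c("1", "2", "3")),
    cat2("socioeconomic_status", c("low", "middle", "high")),
    cat2("residence_area", c("urban", "rural")),
    cat2("health_insurance", yn),
    # -- categorical: clinical --------------------------------------------
    cat2("hypertension_confirmed", yn),
    cat2("antihypertensive_medication", yn, roles = "rule_input"),
    cat2("medication_adherence", c("adherent", "partial", "non_adherent"),
         roles = "rule_input"),
    cat2("medication_side_effects", yn),
    cat2("glycemic_status", c("none", "prediabetes", "diabetes")),
    cat2("family_history_htn", yn),
    cat2("family_history_diabetes", yn),
    cat2("prior_cardiovascular_event", yn),
    # -- categorical: behavioral ------------------------------------------
    cat2("smoking_status", c("never", "former", "current"), roles = "rule_input"),
    cat2("alcohol_consumption", c("does_not_drink", "occasional", "frequent"),
         roles = "rule_input"),
    cat2("stress_level", c("low", "moderate", "high"), roles = "rule_input"),
    cat2("physical_activity_type", c("none", "walking", "sports", "gym")),
    cat2("salt_intake", c("low", "moderate", "high")),
    cat2("fried_food_frequency", freq3),
    cat2("fruit_vegetable_intake", c("daily", "weekly", "rarely")),
    cat2("red_meat_frequency", freq3),
    cat2("sugary_drink_frequency", freq3),
    cat2("coffee_consumption", freq3),
    cat2("sleep_quality", c("good", "fair", "poor")),
    cat2("daytime_sleepiness", yn),
    cat2("work_schedule", c("day", "night", "rotating")),
    cat2("transport_mode", c("walking", "public", "private")),
    # -- categorical: symptoms & engagement -------------------------------
    cat2("dizziness_symptoms", yn),
    cat2("headache_frequency", freq3),
    cat2("vision_problems", yn),
    cat2("bp_self_monitoring", yn),
    cat2("attends_checkups", yn),
    # -- multi-select checklists ------------------------------------------
    variable_schema("comorbidities", "multihot",
                    categories = c("diabetes", "dyslipidemia", "obesity",
                                   "ckd", "prostatitis", "arthritis")),
    variable_schema("avoided_foods", "multihot",
                    categories = c("salt", "fat", "sugar", "caffeine", "alcohol"))
  )
}
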