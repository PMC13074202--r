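# Small schema/cohort fixtures built in code.

tiny_schema <- function() {
  cohort_schema(
    variable_schema("id", "categorical", categories = "any", roles = "identifier"),
    variable_schema("glucose", "numeric", "mg/dL", c(40, 600),
                    roles = c("clustering_feature", "rule_input")),
    variable_schema("height", "numeric", "cm", c(120, 220),
                    roles = "clustering_feature"),
    variable_schema("gender", "categorical", categories = c("female", "male")),
    variable_schema("avoided_foods", "multihot",
                    categories = c("salt", "fat", "sugar"))
  )
}

tiny_cohort <- function() {
  df <- data.frame(
    id = c("a", "b", "c"),
    glucose = c(90, NA, 110),
    height = c(1.65, 170, NA),
    gender = c("female", "male", "male"),
    avoided_foods = c("salt;fat", "", NA),
    stringsAsFactors = FALSE
  )
  cohort_table(tiny_schema(), df)
}

# id + two numeric columns, for hand-checkable imputation cases
xy_schema <- function() {
  cohort_schema(
    variable_schema("id", "categorical", categories = "any", roles = "identifier"),
    variable_schema("x", "numeric"),
    variable_schema("y", "numeric")
  )
}

xy_cohort <- function(x, y) {
  cohort_table(xy_schema(),
               data.frame(id = sprintf("r%03d", seq_along(x)), x = x, y = y,
                          stringsAsFactors = FALSE))
}

# a neutral patient covering every rule input of the shipped knowledge base
default_patient <- function() {
  list(patient_id = "px", age = 50, weight = 70, height = 165, sbp = 125,
       dbp = 78, sleep_hours = 8, activity_days = 4, cigarettes_per_day = 0,
       screen_hours = 2, hemoglobin = 14, glucose = 90, cholesterol = 180,
       triglycerides = 120, creatinine = 0.9, egfr = 90, bmi = 23,
       gender = "female", antihypertensive_medication = "no",
       medication_adherence = "adherent", smoking_status = "never",
       alcohol_consumption = "does_not_drink", stress_level = "low")
}

# cached default synthetic cohort + preprocessed version (shared by several
# test files; generation is seeded and cheap but preprocessing is the slow
# part, so build once per test run)
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_cohort(default_study_config(seed = 314159L))
      pp <- preprocess_cohort(gen$cohort)
      keep <- match(pp$cohort$data$patient_id, gen$cohort$data$patient_id)
      cache <<- list(gen = gen, clean = pp$cohort, report = pp$report,
                     labels = gen$truth$labels[keep])
    }
    cache
  }
})
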