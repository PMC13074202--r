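test_that("record filter drops strictly above the threshold", {
  # 52 data variables, rows missing 27 (0.519) and 26 (0.500) cells
  sc <- default_schema()
  gen <- generate_cohort(default_study_config(seed = 5))
  tab <- gen$cohort
  vars <- setdiff(schema_names(sc), "patient_id")
  # clear all masks, then plant exact per-row missingness
  tab$mask[] <- FALSE
  for (v in vars) tab$data[[v]][is.na(tab$data[[v]])] <- tab$data[[v]][!is.na(tab$data[[v]])][1]
  plant <- function(row, k) {
    for (v in vars[seq_len(k)]) {
      tab$data[[v]][row] <<- NA
      tab$mask[row, v] <<- TRUE
    }
  }
  plant(1, 27); plant(2, 26)
  out <- filter_incomplete_records(tab)
  expect_equal(out$report$rows_dropped, 1L)
  expect_equal(out$report$dropped_ids, tab$data$patient_id[1])
  expect_true(tab$data$patient_id[2] %in% out$cohort$data$patient_id)
})

test_that("a fixture with exactly 8 over-threshold rows keeps 615 of 623", {
  cfg <- default_study_config(seed = 8)
  cfg$missing_rate <- 0.15 # low enough that no row crosses 50% by chance
  gen <- generate_cohort(cfg)
  tab <- gen$cohort
  vars <- setdiff(schema_names(tab$schema), "patient_id")
  for (row in 1:8) {
    for (v in vars[1:27]) {
      tab$data[[v]][row] <- NA
      tab$mask[row, v] <- TRUE
    }
  }
  stopifnot(sum(missingness_summary(tab)$per_row$fraction > 0.5) == 8)
  out <- filter_incomplete_records(tab)
  expect_equal(nrow(out$cohort$data), 615L)
  expect_equal(out$report$rows_dropped, 8L)
})

test_that("meter-recorded heights are multiplied by 100", {
  tab <- tiny_cohort() # heights 1.65, 170, NA
  out <- correct_height_units(tab)
  expect_equal(out$cohort$data$height[1:2], c(165, 170))
  expect_equal(out$report$unit_corrections, 1L)
  expect_equal(out$report$corrected_ids, "a")
})

test_that("all planted meter heights are corrected", {
  gen <- default_bundle()$gen
  planted <- sum(gen$cohort$data$height < 3, na.rm = TRUE)
  out <- correct_height_units(gen$cohort)
  expect_equal(out$report$unit_corrections, planted)
  expect_equal(out$report$unit_corrections, 314L)
  expect_true(all(out$cohort$data$height >= 100, na.rm = TRUE))
})

test_that("implausible values are flagged with addresses, never deleted", {
  tab <- tiny_cohort()
  tab$data$glucose[3] <- 5000
  flags <- flag_implausible(tab)
  expect_equal(nrow(flags), 2L) # glucose 5000 + the 1.65 m height
  g <- flags[flags$variable == "glucose", ]
  expect_equal(g$id, "c")
  expect_equal(g$value, 5000)
  expect_equal(g$low, 40)
  expect_equal(g$high, 600)
  # all in range -> empty report
  expect_equal(nrow(flag_implausible(xy_cohort(1:3, 1:3))), 0L)
})

test_that("KNN imputation matches the hand oracle", {
  tab <- xy_cohort(c(1, 1, 10), c(2, NA, 20))
  out <- impute_numeric_knn(tab, preprocess_config(knn_k = 1))
  expect_equal(out$cohort$data$y[2], 2)
  expect_equal(out$report$numeric_cells_imputed, 1L)
  expect_equal(sum(out$cohort$mask), 0L)

  # k = 2: mean of the two nearest donors
  tab2 <- xy_cohort(c(1, 1.1, 1.2, 50), c(4, 6, NA, 100))
  out2 <- impute_numeric_knn(tab2, preprocess_config(knn_k = 2))
  expect_equal(out2$cohort$data$y[3], 5)
})

test_that("no missing cells leaves the table unchanged", {
  tab <- xy_cohort(1:5, 6:10)
  out <- impute_numeric_knn(tab, preprocess_config())
  expect_identical(out$cohort$data, tab$data)
  expect_equal(out$report$numeric_cells_imputed, 0L)
})

test_that("square-root heuristic gives k = 25 at n = 615", {
  x <- c(NA, rnorm(614))
  tab <- xy_cohort(x, rnorm(615))
  out <- impute_numeric_knn(tab, preprocess_config(knn_k = "sqrt"))
  expect_equal(out$report$k, 25)
})

test_that("a variable missing everywhere is unimputable", {
  tab <- xy_cohort(c(NA, NA, NA), 1:3)
  expect_error(impute_numeric_knn(tab, preprocess_config(knn_k = 1)), "x")
})

test_that("mode imputation uses the modal category and logs ties", {
  sc <- tiny_schema()
  df <- data.frame(id = letters[1:4], glucose = 1:4, height = rep(170, 4),
                   gender = c("female", "female", "male", NA),
                   avoided_foods = rep("", 4))
  out <- impute_categorical_mode(cohort_table(sc, df))
  rep <- out$report$categorical_cells_imputed
  expect_equal(out$cohort$data$gender[4], "female")
  expect_equal(rep$imputed_value[rep$variable == "gender"], "female")
  expect_false(rep$tie[rep$variable == "gender"])

  # female-majority cohort with 4 missing -> "female" imputed 4 times
  df2 <- data.frame(id = sprintf("p%02d", 1:10), glucose = 1:10,
                    height = rep(170, 10),
                    gender = c(rep("female", 4), rep("male", 2), rep(NA, 4)),
                    avoided_foods = rep("", 10))
  out2 <- impute_categorical_mode(cohort_table(sc, df2))
  rep2 <- out2$report$categorical_cells_imputed
  expect_equal(rep2$n_imputed[rep2$variable == "gender"], 4L)
  expect_equal(rep2$imputed_value[rep2$variable == "gender"], "female")

  # exact tie breaks by schema category order and is logged
  df3 <- data.frame(id = letters[1:3], glucose = 1:3, height = rep(170, 3),
                    gender = c("female", "male", NA),
                    avoided_foods = rep("", 3))
  out3 <- impute_categorical_mode(cohort_table(sc, df3))
  rep3 <- out3$report$categorical_cells_imputed
  expect_equal(out3$cohort$data$gender[3], "female")
  expect_true(rep3$tie[rep3$variable == "gender"])
})

test_that("blank multihot entries become explicit zeros", {
  tab <- tiny_cohort() # avoided_foods: "salt;fat", "", NA
  before <- sum(tab$mask[, "avoided_foods"])
  out <- multihot_fill_zero(tab)
  expect_equal(before, 1L)
  expect_equal(sum(out$mask[, "avoided_foods"]), 0L)
  expect_identical(out$data$avoided_foods, c("salt;fat", "", ""))
})

test_that("z-score standardization uses the population sd", {
  tab <- xy_cohort(c(1, 2, 3), c(0, 0, 0))
  expect_warning(sm <- zscore_standardize(tab, c("x", "y")), "constant")
  expect_equal(sm$values[, "x"],
               c(-1.224744871391589, 0, 1.224744871391589),
               ignore_attr = TRUE)
  expect_equal(sm$values[, "y"], c(0, 0, 0), ignore_attr = TRUE)
  # idempotence on an already standardized column
  tab2 <- xy_cohort(sm$values[, "x"], c(1, 2, 4))
  sm2 <- zscore_standardize(tab2, "x")
  expect_equal(sm2$values[, "x"], sm$values[, "x"], tolerance = 1e-12,
               ignore_attr = TRUE)
  # type errors
  expect_error(zscore_standardize(tiny_cohort(), "gender"), "non-numeric")
})

test_that("one-hot encoding has the analytic column count", {
  gen <- default_bundle()
  enc <- one_hot_encode(gen$clean)
  sc <- gen$clean$schema
  expected <- 0L
  for (v in setdiff(schema_names(sc), "patient_id")) {
    expected <- expected +
      if (schema_kinds(sc)[[v]] == "numeric") 1L else length(sc[[v]]$categories)
  }
  expect_equal(ncol(enc$matrix), expected)
  expect_equal(nrow(enc$registry), expected)

  # one-hot property: categorical indicator rows sum to 1
  gcols <- enc$registry$column[enc$registry$variable == "gender"]
  expect_true(all(rowSums(enc$matrix[, gcols]) == 1))
  # multihot rows are unconstrained but binary
  mcols <- enc$registry$column[enc$registry$variable == "avoided_foods"]
  expect_true(all(enc$matrix[, mcols] %in% c(0, 1)))
})

test_that("correlations are symmetric, bounded, and recover rho = 0.4", {
  set.seed(99)
  n <- 5000
  x <- rnorm(n)
  y <- 0.4 * x + sqrt(1 - 0.16) * rnorm(n)
  tab <- xy_cohort(x, y)
  r <- pearson_correlations(zscore_standardize(tab, c("x", "y")))
  expect_equal(diag(r), c(x = 1, y = 1))
  expect_equal(r, t(r), tolerance = 1e-12)
  expect_lt(abs(r["x", "y"] - 0.4), 0.05)
  # exact limits
  tab2 <- xy_cohort(1:4, -(1:4))
  r2 <- pearson_correlations(zscore_standardize(tab2, c("x", "y")))
  expect_equal(r2["x", "y"], -1)
})

test_that("the full pipeline empties the mask and never touches observed cells", {
  b <- default_bundle()
  gen <- b$gen
  expect_equal(sum(b$clean$mask), 0L)
  keep <- match(b$clean$data$patient_id, gen$cohort$data$patient_id)
  for (v in setdiff(schema_names(gen$cohort$schema), c("patient_id", "height", "bmi"))) {
    obs <- !gen$cohort$mask[keep, v]
    expect_identical(b$clean$data[[v]][obs], gen$cohort$data[[v]][keep][obs])
  }
})

test_that("median imputation barely moves the dominant cluster structure", {
  # two dominant profiles only; at k = 2 the optimal partition is unique so
  # label changes reflect imputation, not optimizer degeneracy
  cfg <- default_study_config(seed = 21)
  cfg$profiles <- cfg$profiles[1:2]
  gen <- generate_cohort(cfg)
  lab_for <- function(method) {
    pp <- preprocess_cohort(gen$cohort, preprocess_config(numeric_method = method))
    sm <- zscore_standardize(pp$cohort, schema_role(pp$cohort$schema, "clustering_feature"))
    list(ids = pp$cohort$data$patient_id,
         labels = run_clustering(pca_scores(fit_pca(sm)), "kmeans", 2,
                                 seed = 1)$labels)
  }
  a <- lab_for("knn"); b <- lab_for("median")
  common <- intersect(a$ids, b$ids)
  la <- a$labels[match(common, a$ids)]
  lb <- b$labels[match(common, b$ids)]
  flip <- min(mean(la != lb), mean(la != (3 - lb))) # best label permutation
  expect_lt(flip, 0.10)
})
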