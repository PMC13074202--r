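#' Dual-weighting configuration
#'
#' @param alpha Individual-evidence weight (default 0.85).
#' @param beta Cluster-evidence weight (default 0.15). `alpha + beta` must
#'   equal 1 within 1e-12.
#' @return A `weight_config`.
#' @export
weight_config <- function(alpha = 0.85, beta = 0.15) {
  stopifnot(alpha >= 0, beta >= 0)
  if (abs(alpha + beta - 1) > 1e-12) stop("alpha + beta must equal 1")
  structure(list(alpha = alpha, beta = beta), class = "weight_config")
}

empty_scores <- function(taxonomy) stats::setNames(rep(0, length(taxonomy)),
                                                   names(taxonomy))

#' Evaluate the rule base on one patient
#'
#' Every satisfied rule adds its weight to its target level. Per-domain
#' scores are normalized to sum to 1 when any rule fired; otherwise the
#' domain's fallback level receives score 1 and the fallback flag is set.
#' Evaluation is pure: identical values and knowledge base give an
#' identical fired set.
#'
#' @param values Named list (or single-row data frame) of patient values
#'   covering every variable the knowledge base references.
#' @param kb A `knowledge_base`.
#' @param normalize Normalize fired scores to sum 1 (default TRUE).
#' @return Named list per domain: `scores` (full taxonomy vector), `fired`
#'   (rule ids), `fallback` (logical).
#' @export
evaluate_individual <- function(values, kb, normalize = TRUE) {
  if (is.data.frame(values)) values <- as.list(values[1, , drop = FALSE])
  out <- list()
  for (d in names(kb$domains)) {
    tax <- kb$domains[[d]]
    scores <- empty_scores(tax)
    fired <- character()
    for (r in kb$rules) {
      if (r$domain != d) next
      if (rule_fires(r, values)) {
        scores[r$then] <- scores[r$then] + r$weight
        fired <- c(fired, r$id)
      }
    }
    fallback <- length(fired) == 0L
    if (fallback) {
      scores[kb$fallbacks[[d]]] <- 1
    } else if (normalize) {
      scores <- scores / sum(scores)
    }
    out[[d]] <- list(scores = scores, fired = fired, fallback = fallback)
  }
  out
}

#' Evaluate the rule base on a cluster's centroid profile
#'
#' Builds a virtual patient from the cluster's numeric centroid means,
#' modal categories and majority-selected multihot options, then evaluates
#' it exactly like an individual.
#'
#' @param profile One entry of a `cluster_profile_set` (`$profiles[[j]]`).
#' @param kb A `knowledge_base`.
#' @inheritParams evaluate_individual
#' @return As [evaluate_individual()].
#' @export
cluster_context <- function(profile, kb, normalize = TRUE) {
  evaluate_individual(profile$virtual_patient, kb, normalize = normalize)
}

#' Combine individual and cluster domain scores
#'
#' `combined[level] = alpha * individual[level] + beta * cluster[level]`;
#' the result sums to 1 whenever both inputs do.
#'
#' @param individual,cluster Per-domain score lists from
#'   [evaluate_individual()] / [cluster_context()].
#' @param weights A `weight_config`.
#' @return Named list per domain of combined score vectors.
#' @export
combine_scores <- function(individual, cluster, weights = weight_config()) {
  stopifnot(identical(names(individual), names(cluster)))
  out <- list()
  for (d in names(individual)) {
    si <- individual[[d]]$scores; sc <- cluster[[d]]$scores
    if (!identical(names(si), names(sc)))
      stop("taxonomy mismatch in domain ", d)
    out[[d]] <- weights$alpha * si + weights$beta * sc
  }
  out
}

choose_level <- function(scores, taxonomy) {
  top <- names(scores)[scores == max(scores)]
  if (length(top) == 1L) return(top)
  top <- top[taxonomy[top] == max(taxonomy[top])] # higher urgency first
  sort(top)[1]                                    # then alphabetical
}

#' Recommend intervention levels for one patient
#'
#' Runs individual evaluation, cluster-context evaluation and dual-weighted
#' combination per domain; the chosen level is the combined-score argmax,
#' ties broken by higher urgency rank then alphabetically. The full trace
#' (fired rule ids, all three score vectors, fallback flags) is attached.
#'
#' @param values Patient values (named list or single-row data frame).
#' @param cluster_id The patient's cluster.
#' @param profiles A `cluster_profile_set`.
#' @param kb A `knowledge_base`.
#' @param weights A `weight_config`.
#' @return A `recommendation_set`: patient id, cluster, and per-domain
#'   `level`, `combined`, `individual`, `cluster`, `fired`, `fallback`.
#' @export
recommend_patient <- function(values, cluster_id, profiles, kb,
                              weights = weight_config()) {
  if (is.data.frame(values)) values <- as.list(values[1, , drop = FALSE])
  pkey <- paste0("cluster_", cluster_id)
  if (!pkey %in% names(profiles$profiles)) stop("unknown cluster id ", cluster_id)
  ind <- evaluate_individual(values, kb)
  ctx <- cluster_context(profiles$profiles[[pkey]], kb)
  comb <- combine_scores(ind, ctx, weights)
  domains <- lapply(names(comb), function(d) {
    list(level = choose_level(comb[[d]], kb$domains[[d]]),
         combined = comb[[d]], individual = ind[[d]]$scores,
         cluster = ctx[[d]]$scores, fired = ind[[d]]$fired,
         fallback = ind[[d]]$fallback)
  })
  names(domains) <- names(comb)
  structure(list(patient = values[[1]], cluster = cluster_id,
                 domains = domains), class = "recommendation_set")
}

#' Recommend across a cohort and tabulate level distributions
#'
#' @param cohort A preprocessed `cohort_table`.
#' @param labels Cluster assignment aligned to cohort rows.
#' @param profiles A `cluster_profile_set` for those labels.
#' @param kb A `knowledge_base`.
#' @param weights A `weight_config`.
#' @return A `cohort_recommendations`: `levels` (data frame: id, cluster,
#'   one column per domain) and `matrix` (data frame: domain, level,
#'   overall percentage, one percentage column per cluster; percentages per
#'   domain sum to 100).
#' @export
recommend_cohort <- function(cohort, labels, profiles, kb,
                             weights = weight_config()) {
  stopifnot(nrow(cohort$data) == length(labels))
  id_var <- identifier_variable(cohort$schema)
  n <- nrow(cohort$data)
  doms <- names(kb$domains)
  ctx_cache <- lapply(profiles$profiles, cluster_context, kb = kb)
  lev_df <- data.frame(id = cohort$data[[id_var]], cluster = labels,
                       stringsAsFactors = FALSE)
  for (d in doms) lev_df[[d]] <- NA_character_
  for (i in seq_len(n)) {
    values <- as.list(cohort$data[i, , drop = FALSE])
    ind <- evaluate_individual(values, kb)
    ctx <- ctx_cache[[paste0("cluster_", labels[i])]]
    comb <- combine_scores(ind, ctx, weights)
    for (d in doms)
      lev_df[[d]][i] <- choose_level(comb[[d]], kb$domains[[d]])
  }
  clusters <- sort(unique(labels))
  rows <- list()
  for (d in doms) {
    tax <- names(kb$domains[[d]])
    overall <- 100 * prop.table(table(factor(lev_df[[d]], levels = tax)))
    row <- data.frame(domain = d, level = tax,
                      overall_pct = as.numeric(overall))
    for (cl in clusters) {
      sub <- lev_df[[d]][labels == cl]
      row[[paste0("cluster_", cl, "_pct")]] <-
        as.numeric(100 * prop.table(table(factor(sub, levels = tax))))
    }
    rows[[d]] <- row
  }
  structure(list(levels = lev_df, matrix = do.call(rbind, unname(rows)),
                 weights = weights), class = "cohort_recommendations")
}

#' Mean within-cluster recommendation homogeneity
#'
#' Mean pairwise agreement of per-domain levels inside each cluster,
#' averaged over domains and clusters (weighted by cluster size).
#'
#' @param recs A `cohort_recommendations`.
#' @return Numeric in `[0, 1]`.
#' @export
recommendation_homogeneity <- function(recs) {
  lev_df <- recs$levels
  doms <- setdiff(names(lev_df), c("id", "cluster"))
  vals <- c(); wts <- c()
  for (cl in unique(lev_df$cluster)) {
    sub <- lev_df[lev_df$cluster == cl, doms, drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    for (d in doms) {
      counts <- table(sub[[d]])
      agree <- (sum(counts^2) - n) / (n * (n - 1))
      vals <- c(vals, agree); wts <- c(wts, n)
    }
  }
  sum(vals * wts) / sum(wts)
}

#' Sweep the cluster weight and count decision flips
#'
#' Recomputes cohort recommendations for each beta in `betas`
#' (`alpha = 1 - beta`) and counts per-(patient, domain) level changes
#' between consecutive beta values.
#'
#' @inheritParams recommend_cohort
#' @param betas Numeric vector of cluster weights in `[0, 1]`.
#' @return A `beta_sweep` list: `betas`, `recommendations` (one
#'   `cohort_recommendations` per beta), `flips` (data frame: from, to,
#'   flipped pairs, total pairs, fraction), `homogeneity` per beta.
#' @export
beta_sweep <- function(cohort, labels, profiles, kb, betas) {
  stopifnot(all(betas >= 0 & betas <= 1))
  recs <- lapply(betas, function(b)
    recommend_cohort(cohort, labels, profiles, kb,
                     weight_config(alpha = 1 - b, beta = b)))
  names(recs) <- paste0("beta_", betas)
  doms <- setdiff(names(recs[[1]]$levels), c("id", "cluster"))
  flips <- NULL
  if (length(betas) > 1) {
    flips <- do.call(rbind, lapply(seq_len(length(betas) - 1L), function(i) {
      a <- recs[[i]]$levels[doms]; b <- recs[[i + 1L]]$levels[doms]
      changed <- sum(as.matrix(a) != as.matrix(b))
      total <- nrow(a) * length(doms)
      data.frame(from = betas[i], to = betas[i + 1L], flipped = changed,
                 total = total, fraction = changed / total)
    }))
  }
  structure(list(betas = betas, recommendations = recs, flips = flips,
                 homogeneity = vapply(recs, recommendation_homogeneity,
                                      numeric(1))),
            class = "beta_sweep")
}
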