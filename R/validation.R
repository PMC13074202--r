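#' Stratified case sampling proportional to cluster sizes
#'
#' Per-cluster allocations follow largest-remainder rounding of
#' `n * size / total`; within each cluster, cases are drawn uniformly
#' without replacement. A stratum smaller than its allocation is capped and
#' the excess redistributed (with a warning).
#'
#' @param labels Cluster assignment (one entry per case).
#' @param n Number of cases to draw (`n <= length(labels)`).
#' @param seed Integer seed; identical seeds give identical selections.
#' @return Sorted integer vector of selected row indices; attribute
#'   `allocation` holds the per-cluster counts.
#' @export
stratified_sample <- function(labels, n, seed = 1L) {
  stopifnot(n <= length(labels))
  sizes <- table(labels)
  quota <- n * as.numeric(sizes) / length(labels)
  alloc <- floor(quota)
  rem <- n - sum(alloc)
  if (rem > 0) {
    extra <- order(quota - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  over <- alloc > as.numeric(sizes)
  if (any(over)) {
    warning("stratum smaller than its allocation; capped and redistributed")
    excess <- sum(alloc[over] - as.numeric(sizes)[over])
    alloc[over] <- as.numeric(sizes)[over]
    while (excess > 0) {
      room <- which(alloc < as.numeric(sizes))
      take <- room[order(quota[room] - alloc[room], decreasing = TRUE)[1]]
      alloc[take] <- alloc[take] + 1
      excess <- excess - 1
    }
  }
  set.seed(seed)
  picked <- unlist(lapply(seq_along(sizes), function(j) {
    idx <- which(labels == names(sizes)[j])
    if (alloc[j] == 0) integer() else idx[sample.int(length(idx), alloc[j])]
  }))
  structure(sort(picked), allocation = stats::setNames(as.integer(alloc),
                                                       names(sizes)))
}

#' Simulate an expert rater panel
#'
#' Each rater independently emits the true label with probability `echo`,
#' otherwise a uniformly drawn *other* level of the domain taxonomy.
#'
#' @param truth Data frame with a case identifier column `id` and one
#'   column per domain holding the true level.
#' @param echo Echo probability in `[0, 1]`.
#' @param raters Number of raters (default 5).
#' @param seed Integer seed.
#' @param taxonomies Domain taxonomies (level universe per domain).
#' @return A `ratings_panel`: long data frame `ratings` (case_id, rater_id,
#'   domain, level) plus `cases`, `raters`, `domains`.
#' @export
simulate_rater_panel <- function(truth, echo, raters = 5L, seed = 1L,
                                 taxonomies = domain_taxonomies()) {
  stopifnot(echo >= 0, echo <= 1, "id" %in% names(truth))
  domains <- setdiff(names(truth), c("id", "cluster"))
  set.seed(seed)
  out <- list()
  for (d in domains) {
    levels <- names(taxonomies[[d]])
    if (is.null(levels)) levels <- sort(unique(truth[[d]]))
    for (r in seq_len(raters)) {
      keep <- stats::runif(nrow(truth)) < echo
      lab <- truth[[d]]
      if (any(!keep)) {
        lab[!keep] <- vapply(truth[[d]][!keep], function(tl) {
          others <- setdiff(levels, tl)
          if (!length(others)) tl else sample(others, 1)
        }, character(1))
      }
      out[[paste(d, r)]] <- data.frame(case_id = truth$id,
                                       rater_id = paste0("rater_", r),
                                       domain = d, level = lab)
    }
  }
  structure(list(ratings = do.call(rbind, unname(out)),
                 cases = truth$id, raters = paste0("rater_", seq_len(raters)),
                 domains = domains),
            class = "ratings_panel")
}

#' Majority consensus of a rater panel
#'
#' A level supported by a simple majority of raters (>= 3 of 5) wins; when
#' no level reaches a majority, the plurality wins; a full plurality tie is
#' broken by the higher urgency rank and the case is flagged.
#'
#' @param panel A `ratings_panel` (complete: every rater rated every case
#'   and domain).
#' @param taxonomies Domain taxonomies providing urgency ranks.
#' @return Data frame: case_id, domain, level, strength (agreeing raters),
#'   majority (reached >= majority count), tie_broken.
#' @export
majority_consensus <- function(panel, taxonomies = domain_taxonomies()) {
  ratings <- panel$ratings
  n_raters <- length(panel$raters)
  need <- floor(n_raters / 2) + 1L
  keys <- unique(ratings[c("case_id", "domain")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- ratings[ratings$case_id == keys$case_id[i] &
                     ratings$domain == keys$domain[i], ]
    if (nrow(sub) != n_raters)
      stop("incomplete panel for case ", keys$case_id[i], ", domain ",
           keys$domain[i])
    counts <- sort(table(sub$level), decreasing = TRUE)
    top <- max(counts)
    winners <- names(counts)[counts == top]
    tie <- length(winners) > 1
    level <- if (tie) {
      ranks <- taxonomies[[keys$domain[i]]][winners]
      ranks[is.na(ranks)] <- 0
      winners[order(-ranks, winners)][1]
    } else winners[1]
    data.frame(case_id = keys$case_id[i], domain = keys$domain[i],
               level = level, strength = as.integer(top),
               majority = top >= need, tie_broken = tie)
  })
  do.call(rbind, rows)
}

#' Percent agreement between system and consensus labels
#'
#' Overall agreement is matches / cases. Per-level agreement divides the
#' matches among cases where the *system* chose that level by the system's
#' count for that level.
#'
#' @param system Character vector of system levels.
#' @param consensus Character vector of consensus levels (same length).
#' @return List: `overall` fraction, `per_level` data frame (level,
#'   system_n, matches, agreement), `n`.
#' @export
percent_agreement <- function(system, consensus) {
  stopifnot(length(system) == length(consensus))
  match_v <- system == consensus
  levels <- sort(unique(system))
  per <- do.call(rbind, lapply(levels, function(l) {
    idx <- system == l
    data.frame(level = l, system_n = sum(idx), matches = sum(match_v[idx]),
               agreement = sum(match_v[idx]) / sum(idx))
  }))
  list(overall = if (length(system)) mean(match_v) else NA_real_,
       per_level = per, n = length(system))
}

#' Build a confusion table (system x consensus)
#'
#' @param system,consensus Character vectors of equal length.
#' @param levels Level universe (default: union of observed labels).
#' @return Integer matrix with system levels as rows.
#' @export
confusion_table <- function(system, consensus,
                            levels = sort(union(system, consensus))) {
  table(factor(system, levels = levels), factor(consensus, levels = levels))
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace/total` and chance agreement `p_e` from the marginal
#' products. The 95% CI is `kappa +/- 1.96 * SE` with the standard
#' asymptotic standard error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`,
#' clipped to `[-1, 1]`.
#'
#' @param table Square confusion matrix (system x consensus counts).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `kappa`, `p_o`, `p_e`, `se`, `ci` (length-2), `n`,
#'   `undefined` flag (TRUE when `p_e = 1`).
#' @export
cohens_kappa <- function(table, conf_level = 0.95) {
  m <- as.matrix(table)
  stopifnot(nrow(m) == ncol(m), sum(m) >= 1)
  n <- sum(m)
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - p_e < 1e-12)
    return(list(kappa = NA_real_, p_o = p_o, p_e = p_e, se = NA_real_,
                ci = c(NA_real_, NA_real_), n = n, undefined = TRUE))
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(-1, kappa + c(-1, 1) * z * se))
  list(kappa = kappa, p_o = p_o, p_e = p_e, se = se, ci = ci, n = n,
       undefined = FALSE)
}

#' Chi-square homogeneity test of two level distributions
#'
#' Builds the 2 x L table (source x level) and applies Pearson's chi-square
#' without continuity correction; df = L - 1.
#'
#' @param system_counts,consensus_counts Named count vectors over the same
#'   levels with equal totals.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_homogeneity <- function(system_counts, consensus_counts) {
  levels <- union(names(system_counts), names(consensus_counts))
  if (length(levels) < 2) stop("at least 2 levels required")
  o1 <- stats::setNames(rep(0, length(levels)), levels)
  o1[names(system_counts)] <- system_counts
  o2 <- stats::setNames(rep(0, length(levels)), levels)
  o2[names(consensus_counts)] <- consensus_counts
  if (sum(o1) != sum(o2)) stop("system and consensus totals must be equal")
  O <- rbind(system = o1, consensus = o2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  zero <- colnames(E)[colSums(E == 0) > 0]
  if (length(zero)) stop("expected count of 0 for level(s): ",
                         paste(zero, collapse = ", "))
  stat <- sum((O - E)^2 / E)
  df <- length(levels) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Expert-agreement report
#'
#' Compares system recommendations with the panel's majority consensus:
#' per-domain and pooled-overall percent agreement, Cohen's kappa with 95%
#' CI, and chi-square homogeneity of the level distributions. Cases whose
#' consensus required a tie-break are excluded from the comparisons and
#' counted. The overall chi-square sums the per-domain statistics and
#' degrees of freedom; the overall kappa pools all (case, domain) pairs
#' into one confusion table.
#'
#' @param system Data frame with `id` plus one column per domain (e.g. the
#'   `levels` element of a `cohort_recommendations`, subset to the rated
#'   cases).
#' @param panel A `ratings_panel` covering the same cases and domains.
#' @param taxonomies Domain taxonomies.
#' @return An `agreement_report`: `per_domain` (data frame), `overall`
#'   (list), `by_level` (Table-6-style data frame), `excluded_ties` count.
#' @export
agreement_report <- function(system, panel, taxonomies = domain_taxonomies()) {
  consensus <- majority_consensus(panel, taxonomies)
  domains <- intersect(setdiff(names(system), c("id", "cluster")),
                       unique(consensus$domain))
  per_rows <- list(); lvl_rows <- list()
  pooled_sys <- character(); pooled_con <- character()
  excluded <- 0L
  chi_sum <- 0; df_sum <- 0L
  for (d in domains) {
    con <- consensus[consensus$domain == d, ]
    mrow <- match(con$case_id, system$id)
    sys_lab <- system[[d]][mrow]
    keep <- !con$tie_broken
    excluded <- excluded + sum(!keep)
    sys_lab <- sys_lab[keep]; con_lab <- con$level[keep]
    pooled_sys <- c(pooled_sys, sys_lab); pooled_con <- c(pooled_con, con_lab)
    levels <- names(taxonomies[[d]])
    ct <- confusion_table(sys_lab, con_lab, levels = levels)
    kap <- cohens_kappa(ct)
    pa <- percent_agreement(sys_lab, con_lab)
    chi <- tryCatch(
      chi_square_homogeneity(
        table(factor(sys_lab, levels = levels)),
        table(factor(con_lab, levels = levels))),
      error = function(e) list(statistic = NA_real_, df = NA_integer_,
                               p_value = NA_real_))
    if (is.finite(chi$statistic)) {
      chi_sum <- chi_sum + chi$statistic; df_sum <- df_sum + chi$df
    }
    per_rows[[d]] <- data.frame(
      domain = d, n = length(sys_lab), agreement = pa$overall,
      kappa = kap$kappa, kappa_lo = kap$ci[1], kappa_hi = kap$ci[2],
      chi_square = chi$statistic, df = chi$df, p_value = chi$p_value)
    for (l in levels) {
      sys_n <- sum(sys_lab == l); con_n <- sum(con_lab == l)
      lvl_rows[[paste(d, l)]] <- data.frame(
        domain = d, level = l, system_n = sys_n,
        system_pct = 100 * sys_n / max(1, length(sys_lab)),
        consensus_n = con_n,
        consensus_pct = 100 * con_n / max(1, length(con_lab)),
        agreement = if (sys_n > 0) sum(sys_lab == l & con_lab == l) / sys_n
                    else NA_real_)
    }
  }
  pooled_ct <- confusion_table(pooled_sys, pooled_con)
  pooled_kap <- cohens_kappa(pooled_ct)
  overall <- list(
    n_pairs = length(pooled_sys),
    agreement = mean(pooled_sys == pooled_con),
    kappa = pooled_kap$kappa, kappa_ci = pooled_kap$ci,
    chi_square = chi_sum, df = df_sum,
    p_value = stats::pchisq(chi_sum, df_sum, lower.tail = FALSE))
  structure(list(per_domain = do.call(rbind, unname(per_rows)),
                 overall = overall,
                 by_level = do.call(rbind, unname(lvl_rows)),
                 excluded_ties = excluded,
                 consensus = consensus),
            class = "agreement_report")
}
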