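#' Principal component analysis with variance-threshold retention
#'
#' Components are ordered by descending eigenvalue with a deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#' The retained count is the smallest m whose cumulative explained-variance
#' ratio reaches `tau` (inclusive).
#'
#' @param matrix A `standardized_matrix` or plain numeric matrix whose
#'   columns are already standardized.
#' @param tau Variance retention threshold in (0, 1]; default 0.90.
#' @return A `pca_model`: loadings, eigenvalues, explained-variance ratios,
#'   `retained_m`, `tau`, and the score matrix.
#' @export
fit_pca <- function(matrix, tau = 0.90) {
  X <- if (inherits(matrix, "standardized_matrix")) matrix$values else as.matrix(matrix)
  p <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rotation <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  ev <- p$sdev^2
  ratios <- ev / sum(ev)
  m <- which(cumsum(ratios) >= tau - 1e-12)[1]
  structure(list(loadings = rotation, eigenvalues = ev,
                 explained_variance_ratios = ratios,
                 retained_m = m, tau = tau, scores = scores),
            class = "pca_model")
}

#' Retained-component scores of a PCA model
#' @param model A `pca_model`.
#' @return Numeric matrix (rows x retained_m).
#' @export
pca_scores <- function(model) {
  model$scores[, seq_len(model$retained_m), drop = FALSE]
}

check_labels <- function(points, labels, min_clusters = 2L) {
  stopifnot(nrow(points) == length(labels))
  tab <- table(labels)
  if (length(tab) < min_clusters)
    stop("at least ", min_clusters, " non-empty clusters required, found ",
         length(tab))
  invisible(tab)
}

#' Mean silhouette coefficient
#'
#' For point i with mean same-cluster distance a(i) (excluding i) and
#' lowest mean distance to another cluster b(i),
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Singletons receive s = 0; when
#' a = 0 and b > 0, s = 1.
#'
#' @param points Numeric matrix.
#' @param labels Cluster assignment (length nrow(points)).
#' @return List: `mean` and per-point `s`.
#' @export
silhouette_index <- function(points, labels) {
  points <- as.matrix(points)
  check_labels(points, labels)
  D <- as.matrix(stats::dist(points))
  lev <- sort(unique(labels))
  n <- nrow(points)
  sizes <- table(factor(labels, levels = lev))
  # mean distance from each point to each cluster
  agg <- vapply(lev, function(g) rowSums(D[, labels == g, drop = FALSE]),
                numeric(n))
  own <- match(labels, lev)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ni <- sizes[[own[i]]]
    if (ni == 1L) { s[i] <- 0; next }
    a <- agg[i, own[i]] / (ni - 1)
    b <- min(agg[i, -own[i], drop = TRUE] / sizes[-own[i]])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(mean = mean(s), s = s)
}

#' Davies-Bouldin index
#'
#' `DB = (1/c) sum_i max_{j != i} (d(X_i) + d(X_j)) / d(c_i, c_j)` with
#' d(X_i) the mean Euclidean distance of members to their centroid. Lower is
#' better. Coincident centroids yield `Inf` with a warning.
#'
#' @inheritParams silhouette_index
#' @return Numeric scalar.
#' @export
davies_bouldin_index <- function(points, labels) {
  points <- as.matrix(points)
  check_labels(points, labels)
  lev <- sort(unique(labels))
  cen <- do.call(rbind, lapply(lev, function(g)
    colMeans(points[labels == g, , drop = FALSE])))
  disp <- vapply(seq_along(lev), function(j) {
    mem <- points[labels == lev[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(mem, 2, cen[j, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cen))
  c_n <- length(lev)
  worst <- vapply(seq_len(c_n), function(i) {
    r <- (disp[i] + disp[-i]) / M[i, -i]
    max(r)
  }, numeric(1))
  if (any(!is.finite(worst)))
    warning("coincident centroids: Davies-Bouldin index is infinite")
  mean(worst)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster scatter traces with the standard
#' (k - 1, n - k) degree-of-freedom normalization:
#' `CH = (trace(S_B)/(k-1)) / (trace(S_W)/(n-k))`. Higher is better. Zero
#' within-cluster scatter yields `Inf` with a warning.
#'
#' @inheritParams silhouette_index
#' @return Numeric scalar.
#' @export
calinski_harabasz_index <- function(points, labels) {
  points <- as.matrix(points)
  check_labels(points, labels)
  n <- nrow(points)
  lev <- sort(unique(labels))
  k <- length(lev)
  stopifnot(n > k)
  grand <- colMeans(points)
  sb <- 0; sw <- 0
  for (g in lev) {
    mem <- points[labels == g, , drop = FALSE]
    cen <- colMeans(mem)
    sb <- sb + nrow(mem) * sum((cen - grand)^2)
    sw <- sw + sum(sweep(mem, 2, cen)^2)
  }
  if (sw == 0) {
    warning("zero within-cluster scatter: Calinski-Harabasz index is infinite")
    return(Inf)
  }
  (sb / (k - 1)) / (sw / (n - k))
}

#' All three internal validity indices
#' @inheritParams silhouette_index
#' @return A `validity_indices` list: `silhouette_mean`, `davies_bouldin`,
#'   `calinski_harabasz`.
#' @export
validity_indices <- function(points, labels) {
  structure(list(silhouette_mean = silhouette_index(points, labels)$mean,
                 davies_bouldin = davies_bouldin_index(points, labels),
                 calinski_harabasz = calinski_harabasz_index(points, labels)),
            class = "validity_indices")
}

kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1, ] <- points[sample.int(n, 1), ]
  d2 <- rowSums(sweep(points, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- points[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(points, 2, centers[j, ])^2))
  }
  centers
}

#' Fit a clustering model
#'
#' K-means uses k-means++ initialization with Lloyd iterations, 10 restarts,
#' best inertia kept. HAC uses Ward linkage (`ward.D2`) on Euclidean
#' distance. GMM uses full covariances with labels by maximum
#' responsibility. Identical seeds give identical labels. An empty cluster
#' triggers a re-seeded retry, then an error.
#'
#' @param points Numeric matrix (typically retained PCA scores).
#' @param algorithm One of `"kmeans"`, `"hac"`, `"gmm"`.
#' @param k Cluster count (>= 2).
#' @param seed Integer seed.
#' @param restarts K-means restarts (default 10).
#' @return A `cluster_model`: algorithm, k, labels (1..k), per-cluster
#'   centroids in the clustered space, sizes, seed and (for k-means) the
#'   best total within-cluster sum of squares.
#' @export
run_clustering <- function(points, algorithm = c("kmeans", "hac", "gmm"),
                           k, seed = 1L, restarts = 10L) {
  algorithm <- match.arg(algorithm)
  points <- as.matrix(points)
  stopifnot(k >= 2, all(is.finite(points)))
  n <- nrow(points)
  labels <- NULL; inertia <- NA_real_
  if (algorithm == "kmeans") {
    set.seed(seed)
    best <- NULL
    attempt <- 0L
    while (is.null(best) && attempt < 2L) {
      for (r in seq_len(restarts)) {
        fit <- tryCatch(
          stats::kmeans(points, centers = kmeanspp_init(points, k),
                        iter.max = 100L, algorithm = "Lloyd"),
          error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit) || length(unique(fit$cluster)) < k) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      attempt <- attempt + 1L
    }
    if (is.null(best)) stop("k-means produced an empty cluster in every restart")
    labels <- best$cluster
    inertia <- best$tot.withinss
  } else if (algorithm == "hac") {
    labels <- stats::cutree(stats::hclust(stats::dist(points), method = "ward.D2"), k)
  } else {
    set.seed(seed)
    fit <- Mclust(points, G = k, modelNames = "VVV", verbose = FALSE)
    if (is.null(fit))
      fit <- Mclust(points, G = k, verbose = FALSE)
    if (is.null(fit)) stop("GMM fit failed for k = ", k)
    labels <- as.integer(fit$classification)
  }
  if (length(unique(labels)) < k) stop("empty cluster after fit (", algorithm, ")")
  lev <- sort(unique(labels))
  labels <- match(labels, lev)
  cen <- do.call(rbind, lapply(seq_len(k), function(j)
    colMeans(points[labels == j, , drop = FALSE])))
  structure(list(algorithm = algorithm, k = as.integer(k),
                 labels = labels, centroids_reduced = cen,
                 sizes = as.integer(table(labels)), seed = as.integer(seed),
                 tot_withinss = inertia),
            class = "cluster_model")
}

#' Per-cluster means of cohort variables in original units
#'
#' @param cohort A preprocessed `cohort_table`.
#' @param labels Cluster assignment aligned to cohort rows.
#' @param variables Numeric variable names (default: clustering features).
#' @return k x variables matrix of per-cluster means.
#' @export
cluster_centroids_original <- function(cohort, labels,
                                       variables = schema_role(cohort$schema, "clustering_feature")) {
  X <- as.matrix(cohort$data[variables])
  lev <- sort(unique(labels))
  cen <- do.call(rbind, lapply(lev, function(g)
    colMeans(X[labels == g, , drop = FALSE], na.rm = TRUE)))
  rownames(cen) <- lev
  cen
}

#' Select a clustering model over an algorithm x k grid
#'
#' Every grid cell is scored with the three validity indices; the chosen
#' cell maximizes mean silhouette, breaking ties by higher
#' Calinski-Harabasz, then lower Davies-Bouldin (a deterministic total
#' order).
#'
#' @param points Numeric matrix.
#' @param algorithms Algorithms to try.
#' @param k_range Integer vector of cluster counts.
#' @param seed Integer seed shared across cells.
#' @return A `selection_report`: `grid` data frame, `chosen` row, fitted
#'   `models` (named `algorithm_k`), and a `rationale` string.
#' @export
select_model <- function(points, algorithms = c("kmeans", "hac", "gmm"),
                         k_range = 3:6, seed = 1L) {
  stopifnot(length(algorithms) >= 1, length(k_range) >= 1)
  rows <- list(); models <- list()
  for (alg in algorithms) for (k in k_range) {
    model <- run_clustering(points, alg, k, seed = seed)
    vi <- suppressWarnings(validity_indices(points, model$labels))
    key <- paste0(alg, "_", k)
    models[[key]] <- model
    rows[[key]] <- data.frame(algorithm = alg, k = k,
                              silhouette = vi$silhouette_mean,
                              calinski_harabasz = vi$calinski_harabasz,
                              davies_bouldin = vi$davies_bouldin)
  }
  grid <- do.call(rbind, unname(rows))
  ord <- order(-grid$silhouette, -grid$calinski_harabasz, grid$davies_bouldin)
  chosen <- grid[ord[1], ]
  structure(list(
    grid = grid, chosen = chosen,
    models = models,
    chosen_model = models[[paste0(chosen$algorithm, "_", chosen$k)]],
    rationale = paste0("lexicographic: max silhouette (", round(chosen$silhouette, 4),
                       "), then max Calinski-Harabasz, then min Davies-Bouldin")),
    class = "selection_report")
}

#' Assess clustering stability across seeds
#'
#' Refits the model under each seed and reports pairwise adjusted Rand
#' indices between runs.
#'
#' @param points Numeric matrix.
#' @param algorithm Clustering algorithm.
#' @param k Cluster count.
#' @param seeds Integer vector (>= 2 seeds).
#' @return A `stability_report`: `seeds`, `pairwise_ari`, `mean_ari`.
#' @export
assess_stability <- function(points, algorithm, k, seeds) {
  stopifnot(length(seeds) >= 2)
  runs <- lapply(seeds, function(s) run_clustering(points, algorithm, k, seed = s)$labels)
  pairs <- utils::combn(length(runs), 2)
  ari <- apply(pairs, 2, function(ij)
    adjustedRandIndex(runs[[ij[1]]], runs[[ij[2]]]))
  structure(list(seeds = seeds, pairwise_ari = ari, mean_ari = mean(ari)),
            class = "stability_report")
}

#' Default cluster-naming rules
#'
#' Each rule maps a dominant-deviation signature (variable and direction of
#' the centroid's departure from the cohort mean) to a phenotype label. The
#' defaults reproduce the study's three profile names.
#'
#' @return List of rules (`name`, `variable`, `direction`).
#' @export
default_naming_rules <- function() {
  list(
    list(name = "metabolic_hypertensive", variable = "glucose", direction = "high"),
    list(name = "dyslipidemic_anemic", variable = "cholesterol", direction = "high"),
    list(name = "constitutional_atypical", variable = "height", direction = "high")
  )
}

#' Profile clusters: descriptive statistics, importance, names
#'
#' Numeric variables are summarized as per-cluster mean/sd, categorical and
#' multihot variables as frequency tables. Variable importance is the
#' one-way F statistic of each clustering feature across clusters, ranked
#' descending. Names are assigned by greedily matching naming-rule
#' signatures to the cluster with the strongest corresponding deviation.
#' Each cluster also carries a "virtual patient" (numeric means, modal
#' categories, majority-selected multihot options) used as the group-level
#' descriptor by the inference engine.
#'
#' @param cohort A preprocessed `cohort_table`.
#' @param labels Cluster assignment aligned to cohort rows.
#' @param naming_rules See [default_naming_rules()].
#' @return A `cluster_profile_set`.
#' @export
profile_clusters <- function(cohort, labels, naming_rules = default_naming_rules()) {
  stopifnot(nrow(cohort$data) == length(labels))
  lev <- sort(unique(labels))
  feats <- schema_role(cohort$schema, "clustering_feature")
  num_vars <- Filter(function(v) cohort$schema[[v]]$kind == "numeric",
                     data_variables(cohort$schema))

  g <- factor(labels, levels = lev)
  fstat <- vapply(feats, function(v) {
    x <- cohort$data[[v]]
    if (anyNA(x) || stats::sd(x) == 0) return(0)
    f <- stats::anova(stats::lm(x ~ g))[["F value"]][1]
    if (is.finite(f)) f else 0
  }, numeric(1))
  importance <- data.frame(variable = feats, f_statistic = fstat)
  importance <- importance[order(-importance$f_statistic), ]
  rownames(importance) <- NULL

  overall_mu <- vapply(num_vars, function(v) mean(cohort$data[[v]]), numeric(1))
  overall_sd <- vapply(num_vars, function(v) stats::sd(cohort$data[[v]]), numeric(1))

  profiles <- lapply(lev, function(cl) {
    rows <- labels == cl
    numeric_summary <- data.frame(
      variable = num_vars,
      mean = vapply(num_vars, function(v) mean(cohort$data[[v]][rows]), numeric(1)),
      sd = vapply(num_vars, function(v) stats::sd(cohort$data[[v]][rows]), numeric(1)))
    cat_freq <- list(); virtual <- as.list(numeric_summary$mean)
    names(virtual) <- num_vars
    for (v in data_variables(cohort$schema)) {
      spec <- cohort$schema[[v]]
      if (spec$kind == "categorical") {
        tab <- table(factor(cohort$data[[v]][rows], levels = spec$categories))
        cat_freq[[v]] <- prop.table(tab)
        virtual[[v]] <- names(tab)[which.max(tab)]
      } else if (spec$kind == "multihot") {
        sel <- lapply(cohort$data[[v]][rows], split_multihot)
        prev <- vapply(spec$categories, function(cc)
          mean(vapply(sel, function(s) cc %in% s, logical(1))), numeric(1))
        cat_freq[[v]] <- prev
        virtual[[v]] <- paste(spec$categories[prev >= 0.5], collapse = ";")
      }
    }
    list(cluster = cl, n = sum(rows), numeric = numeric_summary,
         categorical = cat_freq, virtual_patient = virtual)
  })
  names(profiles) <- paste0("cluster_", lev)

  # greedy signature matching for names
  dev <- do.call(cbind, lapply(profiles, function(p) {
    z <- (p$numeric$mean - overall_mu[p$numeric$variable]) /
      ifelse(overall_sd[p$numeric$variable] > 0, overall_sd[p$numeric$variable], 1)
    stats::setNames(z, p$numeric$variable)
  }))
  cluster_names <- rep(NA_character_, length(lev))
  free_rules <- naming_rules; free_clusters <- seq_along(lev)
  while (length(free_rules) && length(free_clusters)) {
    score <- vapply(free_rules, function(r) {
      if (!r$variable %in% rownames(dev)) return(-Inf)
      s <- dev[r$variable, free_clusters]
      if (r$direction == "low") s <- -s
      max(s)
    }, numeric(1))
    if (all(!is.finite(score))) break
    ri <- which.max(score)
    r <- free_rules[[ri]]
    s <- dev[r$variable, free_clusters]
    if (r$direction == "low") s <- -s
    ci <- free_clusters[which.max(s)]
    cluster_names[ci] <- r$name
    free_rules <- free_rules[-ri]
    free_clusters <- setdiff(free_clusters, ci)
  }
  cluster_names[is.na(cluster_names)] <-
    paste0("cluster_", lev[is.na(cluster_names)])
  for (i in seq_along(profiles)) profiles[[i]]$name <- cluster_names[i]

  structure(list(profiles = profiles, variable_importance = importance,
                 names = cluster_names, clusters = lev),
            class = "cluster_profile_set")
}
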