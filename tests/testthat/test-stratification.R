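test_that("PCA handles rank-1, boundary, and isotropic structure", {
  # two perfectly correlated columns -> one component carries everything
  z <- scale(rnorm(50))[, 1]
  p1 <- fit_pca(cbind(a = z, b = z), tau = 0.9)
  expect_equal(p1$explained_variance_ratios[1], 1)
  expect_equal(p1$retained_m, 1L)
  expect_equal(sum(p1$explained_variance_ratios), 1, tolerance = 1e-9)

  # sample covariance eigenvalues exactly 12 and 4/3 (ratio 9:1): the 90%
  # boundary is inclusive, so one component suffices
  X <- cbind(a = c(3, 3, -3, -3), b = c(1, -1, 1, -1))
  p2 <- fit_pca(X, tau = 0.90)
  expect_equal(p2$explained_variance_ratios, c(0.9, 0.1))
  expect_equal(p2$retained_m, 1L)
  expect_equal(fit_pca(X, tau = 0.91)$retained_m, 2L)

  # isotropic 3-D Gaussian: ratios ~ 1/3 each, all three needed
  set.seed(11)
  G <- matrix(rnorm(12000), ncol = 3)
  p3 <- fit_pca(scale(G), tau = 0.9)
  expect_true(all(abs(p3$explained_variance_ratios - 1 / 3) < 0.03))
  expect_equal(p3$retained_m, 3L)

  # ratios are non-increasing; sign convention is deterministic
  expect_true(all(diff(p3$explained_variance_ratios) <= 1e-12))
  for (j in 1:3) {
    l <- p3$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("silhouette reproduces the 1-D hand oracle", {
  X <- matrix(c(0, 1, 5, 6), ncol = 1)
  lab <- c(1, 1, 2, 2)
  res <- silhouette_index(X, lab)
  expect_equal(res$s, c(9 / 11, 7 / 9, 7 / 9, 9 / 11), tolerance = 1e-12)
  expect_equal(res$mean, (9 / 11 + 7 / 9) / 2, tolerance = 1e-12)
  expect_equal(round(res$mean, 4), 0.798)
})

test_that("silhouette limit and baseline behavior", {
  # coincident points per cluster, far apart: a = 0 convention gives s = 1
  X <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(silhouette_index(X, c(1, 1, 2, 2))$mean, 1)
  # single cluster is undefined
  expect_error(silhouette_index(X, rep(1, 4)), "clusters")
  # random labels on isotropic noise hover near zero
  set.seed(2)
  Xn <- matrix(rnorm(400), ncol = 2)
  labn <- sample(1:3, 200, replace = TRUE)
  expect_lt(abs(silhouette_index(Xn, labn)$mean), 0.1)
})

test_that("Davies-Bouldin reproduces the hand oracle and scales", {
  X <- matrix(c(0, 1, 5, 6), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(davies_bouldin_index(X, lab), 0.2, tolerance = 1e-12)
  # moving duplicated clusters apart x10 shrinks DB x10
  X_far <- matrix(c(0, 1, 50, 51), ncol = 1)
  expect_equal(davies_bouldin_index(X_far, lab), 0.02, tolerance = 1e-12)
  expect_error(davies_bouldin_index(X, rep(1, 4)), "clusters")
  expect_warning(davies_bouldin_index(matrix(c(0, 0, 1, 1), ncol = 1),
                                      c(1, 2, 1, 2)), "coincident")
})

test_that("Calinski-Harabasz reproduces the hand oracle", {
  X <- matrix(c(0, 1, 5, 6), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(calinski_harabasz_index(X, lab), 50, tolerance = 1e-12)
  expect_warning(
    ch <- calinski_harabasz_index(matrix(c(0, 0, 5, 5), ncol = 1), lab),
    "infinite")
  expect_identical(ch, Inf)
  # random labels sit inside a permutation baseline band
  set.seed(3)
  Xn <- matrix(rnorm(400), ncol = 2)
  labn <- sample(1:3, 200, replace = TRUE)
  perm <- replicate(50, calinski_harabasz_index(Xn, sample(labn)))
  obs <- calinski_harabasz_index(Xn, labn)
  expect_gte(obs, quantile(perm, 0.005) * 0.5)
  expect_lte(obs, quantile(perm, 0.995) * 2)
})

test_that("indices match brute-force double-loop oracles on random instances", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(6:30, 1)
    d <- sample(1:4, 1)
    k <- sample(2:4, 1)
    inst <- random_instance(n, d, k)
    expect_equal(silhouette_index(inst$X, inst$lab)$mean,
                 oracle_silhouette(inst$X, inst$lab), tolerance = 1e-9)
    expect_equal(davies_bouldin_index(inst$X, inst$lab),
                 oracle_davies_bouldin(inst$X, inst$lab), tolerance = 1e-9)
    expect_equal(calinski_harabasz_index(inst$X, inst$lab),
                 oracle_calinski_harabasz(inst$X, inst$lab), tolerance = 1e-9)
  }
})

test_that("silhouette is rigid-motion invariant; CH and DB shift invariant", {
  set.seed(7)
  inst <- random_instance(25, 3, 3)
  theta <- 0.7
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  Xr <- inst$X %*% R
  Xt <- sweep(inst$X, 2, c(5, -3, 100), `+`)
  expect_equal(silhouette_index(Xr, inst$lab)$mean,
               silhouette_index(inst$X, inst$lab)$mean, tolerance = 1e-9)
  expect_equal(silhouette_index(Xt, inst$lab)$mean,
               silhouette_index(inst$X, inst$lab)$mean, tolerance = 1e-9)
  expect_equal(davies_bouldin_index(Xt, inst$lab),
               davies_bouldin_index(inst$X, inst$lab), tolerance = 1e-9)
  expect_equal(calinski_harabasz_index(Xt, inst$lab),
               calinski_harabasz_index(inst$X, inst$lab), tolerance = 1e-9)
})

planted_gaussians <- function(seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(j)
    cbind(rnorm(30, centers[j, 1], 0.5), rnorm(30, centers[j, 2], 0.5))))
  list(X = X, lab = rep(1:3, each = 30))
}

test_that("all three algorithms recover well-separated planted clusters", {
  g <- planted_gaussians()
  for (alg in c("kmeans", "hac", "gmm")) {
    m <- run_clustering(g$X, alg, 3, seed = 5)
    expect_equal(mclust::adjustedRandIndex(m$labels, g$lab), 1.0,
                 info = alg)
    expect_true(all(m$sizes > 0))
    # centroids equal the mean of their members
    for (j in 1:3)
      expect_equal(m$centroids_reduced[j, ],
                   colMeans(g$X[m$labels == j, , drop = FALSE]),
                   tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("k-means is deterministic per seed and hac handles k = n", {
  g <- planted_gaussians(2)
  a <- run_clustering(g$X, "kmeans", 3, seed = 9)
  b <- run_clustering(g$X, "kmeans", 3, seed = 9)
  expect_identical(a$labels, b$labels)
  sub <- g$X[1:6, ]
  m <- run_clustering(sub, "hac", 6, seed = 1)
  expect_equal(sort(m$labels), 1:6)
})

test_that("model selection honors the documented lexicographic rule", {
  g <- planted_gaussians(3)
  sel <- select_model(g$X, algorithms = "kmeans", k_range = 3, seed = 1)
  expect_equal(nrow(sel$grid), 1L)
  expect_equal(sel$chosen$k, 3)

  sel2 <- select_model(g$X, algorithms = c("kmeans", "hac"), k_range = 2:4,
                       seed = 1)
  ord <- order(-sel2$grid$silhouette, -sel2$grid$calinski_harabasz,
               sel2$grid$davies_bouldin)
  expect_equal(sel2$chosen, sel2$grid[ord[1], ], ignore_attr = TRUE)
  expect_equal(sel2$chosen$k, 3) # planted structure wins
})

test_that("stability: deterministic hac gives ARI 1, k-means recovers planting", {
  g <- planted_gaussians(4)
  st_hac <- assess_stability(g$X, "hac", 3, seeds = 1:4)
  expect_true(all(st_hac$pairwise_ari == 1))
  expect_equal(st_hac$mean_ari, 1)
  st_km <- assess_stability(g$X, "kmeans", 3, seeds = 1:10)
  expect_gte(st_km$mean_ari, 0.99)
  # pure noise: contract only, value unconstrained but finite
  set.seed(6)
  noise <- matrix(rnorm(200), ncol = 2)
  st_noise <- assess_stability(noise, "kmeans", 3, seeds = 1:5)
  expect_true(all(st_noise$pairwise_ari >= -1 & st_noise$pairwise_ari <= 1))
  expect_equal(st_noise$mean_ari, mean(st_noise$pairwise_ari))
})

test_that("profiling ranks discriminators and names phenotypes", {
  b <- default_bundle()
  pr <- profile_clusters(b$clean, b$labels)
  top5 <- pr$variable_importance$variable[1:5]
  expect_true(all(c("glucose", "cholesterol") %in% top5))
  expect_setequal(pr$variable_importance$variable,
                  schema_role(b$clean$schema, "clustering_feature"))
  expect_setequal(pr$names, c("metabolic_hypertensive", "dyslipidemic_anemic",
                              "constitutional_atypical"))
  # the 7-patient tall profile gets the constitutional label
  atyp <- which(pr$names == "constitutional_atypical")
  expect_equal(pr$profiles[[atyp]]$n, sum(b$labels == 3))
  # cluster means in original units match direct computation
  cen <- cluster_centroids_original(b$clean, b$labels)
  expect_equal(cen[1, "glucose"],
               mean(b$clean$data$glucose[b$labels == 1]), ignore_attr = TRUE)
})

test_that("constant variables rank last; a single shifted variable ranks first", {
  sc <- cohort_schema(
    variable_schema("id", "categorical", categories = "any", roles = "identifier"),
    variable_schema("shifted", "numeric", roles = "clustering_feature"),
    variable_schema("flat", "numeric", roles = "clustering_feature"),
    variable_schema("noise", "numeric", roles = "clustering_feature")
  )
  set.seed(8)
  n <- 40
  df <- data.frame(id = sprintf("p%02d", 1:n),
                   shifted = c(rnorm(n / 2), rnorm(n / 2, 8)),
                   flat = rep(5, n), noise = rnorm(n))
  tab <- cohort_table(sc, df)
  pr <- profile_clusters(tab, rep(1:2, each = n / 2))
  expect_equal(pr$variable_importance$variable[1], "shifted")
  expect_equal(pr$variable_importance$variable[3], "flat")
  expect_equal(pr$variable_importance$f_statistic[3], 0)
})
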