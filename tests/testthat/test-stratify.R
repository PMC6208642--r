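test_that("sqrt-JSD matches closed forms and is a metric", {
  rel <- make_rel(cbind(c(0.5, 0.5), c(0.25, 0.75)))
  expect_equal(jsd_distance(rel)$d[1, 2], 0.1839078, tolerance = 1e-6)

  same <- make_rel(cbind(c(0.3, 0.7), c(0.3, 0.7)))
  expect_equal(jsd_distance(same)$d[1, 2], 0)

  disj <- make_rel(cbind(c(1, 0), c(0, 1)))
  expect_equal(jsd_distance(disj)$d[1, 2], sqrt(log(2)), tolerance = 1e-12)

  expect_error(jsd_distance(make_rel(cbind(c(0.5, 0.6)))), "sum to 1")

  ## identity, symmetry, triangle inequality on random triples
  set.seed(7)
  for (i in 1:1000) {
    d <- jsd_distance(random_rel(5, 3))$d
    expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
  }
})

test_that("PAM recovers separated structure and degenerate k", {
  ## two tight, far-apart pairs
  rel <- make_rel(cbind(c(0.98, 0.01, 0.01), c(0.97, 0.02, 0.01),
                        c(0.01, 0.01, 0.98), c(0.02, 0.01, 0.97)))
  fit <- pam_cluster(jsd_distance(rel), 2)
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])

  d <- jsd_distance(random_rel(4, 6))
  all_self <- pam_cluster(d, 6)
  expect_equal(all_self$cost, 0)
  expect_equal(sort(all_self$medoids), 1:6)
  expect_error(pam_cluster(d, 7), "out of range")
})

test_that("PAM attains the brute-force optimal medoid cost on small instances", {
  set.seed(11)
  for (trial in 1:30) {
    n <- sample(5:8, 1); k <- sample(2:3, 1)
    d <- jsd_distance(random_rel(6, n))$d
    fit <- pam_cluster(d, k)
    expect_equal(fit$cost, brute_force_pam_cost(d, k), tolerance = 1e-9)
  }
})

test_that("PAM agrees with the cluster package on separated data", {
  skip_if_not_installed("cluster")
  com <- generate_community(community_config(seed = 13))
  d <- jsd_distance(to_relative(com$table))
  mine <- pam_cluster(d, 3)
  ref <- cluster::pam(stats::as.dist(d$d), 3)
  expect_equal(adjusted_rand_index(mine$labels, ref$clustering), 1)
})

test_that("Calinski-Harabasz matches a hand evaluation and is label-invariant", {
  set.seed(2)
  d <- jsd_distance(random_rel(5, 6))$d
  labels <- c(1, 1, 2, 2, 3, 3)
  ## independent evaluation of the medoid-based formula
  gm <- which.min(colSums(d))
  bt <- 0; wt <- 0
  for (c_ in 1:3) {
    idx <- which(labels == c_)
    mc <- idx[which.min(colSums(d[idx, idx, drop = FALSE]))]
    bt <- bt + length(idx) * d[mc, gm]^2
    wt <- wt + sum(d[mc, idx]^2)
  }
  expect_equal(calinski_harabasz(d, labels), (bt / 2) / (wt / 3), tolerance = 1e-12)

  perm <- c(2, 2, 3, 3, 1, 1)  # relabeled clusters
  expect_equal(calinski_harabasz(d, perm), calinski_harabasz(d, labels))

  ## zero within-cluster spread with separation: +inf sentinel
  tight <- matrix(0.7, 4, 4); tight[1, 2] <- tight[2, 1] <- 0
  tight[3, 4] <- tight[4, 3] <- 0; diag(tight) <- 0
  expect_equal(calinski_harabasz(tight, c(1, 1, 2, 2)), .Machine$double.xmax)
  expect_error(calinski_harabasz(d, rep(1, 6)), "CH requires")
})

test_that("CH-guided k selection finds planted component counts", {
  com3 <- generate_community(community_config(seed = 21))
  sel3 <- select_k_pam(jsd_distance(to_relative(com3$table)))
  expect_equal(sel3$k, 3)

  com2 <- generate_community(community_config(K = 2, mixing = c(0.6, 0.4),
                                              seed = 22))
  sel2 <- select_k_pam(jsd_distance(to_relative(com2$table)))
  expect_equal(sel2$k, 2)

  ## single homogeneous component: selection runs, downstream validation
  ## is expected to withhold support (checked in the validation tests)
  null <- generate_community(community_config(K = 1, mixing = 1,
                                              alpha = list(rep(2, 30)), seed = 23))
  expect_error(select_k_pam(jsd_distance(to_relative(null$table))), NA)
})

test_that("method agreement counts mismatches after optimal matching", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(method_agreement(a, c(3, 3, 1, 1, 2, 2))$mismatches, 0)
  expect_equal(method_agreement(a, c(3, 3, 1, 1, 2, 2))$ari, 1)
  flip <- c(3, 3, 1, 2, 2, 2)  # one sample moved after relabeling
  expect_equal(method_agreement(a, flip)$mismatches, 1)
  expect_error(method_agreement(a, c(1, 2)), "differ")

  ## random labels vs planted: ARI near zero
  set.seed(31)
  com <- generate_community(community_config(seed = 31))
  rand <- sample(1:3, 40, replace = TRUE)
  expect_lt(abs(method_agreement(com$labels, rand)$ari), 0.15)
})

test_that("adjusted Rand index matches the mclust oracle", {
  skip_if_not_installed("mclust")
  set.seed(5)
  for (i in 1:25) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("core microbes are the dominant taxa with the expected correlation signs", {
  com <- generate_community(community_config(seed = 41))
  rel <- to_relative(com$table)
  cores <- core_microbes(rel, com$labels)
  ## planted cores: taxa 1-2 (component 1), 3-4 (component 2), 5 (component 3)
  expect_setequal(cores$cores[[1]], c("taxon_1", "taxon_2"))
  expect_setequal(cores$cores[[2]], c("taxon_3", "taxon_4"))
  expect_equal(cores$cores[[3]], "taxon_5")

  within <- cores$pairs[cores$pairs$kind == "within", ]
  between <- cores$pairs[cores$pairs$kind == "between", ]
  expect_true(all(within$rho > 0))
  expect_true(all(within$p < 0.01))   # co-dominant block rises and falls together
  expect_true(all(between$rho < 0))   # compositional closure across subgroups
  expect_lt(min(between$p), 0.01)     # strongest opposition clearly significant

  ## one homogeneous component: no between-set pairs to report
  uni <- make_rel(matrix(rep(1 / 4, 16), 4, dimnames = list(paste0("t", 1:4), NULL)))
  expect_warning(c1 <- core_microbes(uni, rep(1, 4), min_mean = 0.5), "no qualifying")
  expect_equal(sum(c1$pairs$kind == "between"), 0)
})
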