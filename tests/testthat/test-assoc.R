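test_that("Fisher exact r x c matches enumeration oracles", {
  expect_equal(fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2))$p, 0.4857143,
               tolerance = 1e-6)
  expect_equal(fisher_exact_rxc(matrix(c(5, 0, 0, 5), 2))$p, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(matrix(c(4, 4, 2, 2), 2, byrow = TRUE))$p, 1)
  expect_equal(fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2))$p, 1)  # zero margin

  ## 2x2 dhyper enumeration oracle, exact to 1e-12
  set.seed(2)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    support <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(support, r1, n - r1, c1)
    oracle <- sum(probs[probs <= dhyper(a, r1, n - r1, c1) * (1 + 1e-7)])
    expect_equal(fisher_exact_rxc(tab)$p, oracle, tolerance = 1e-12)
  }

  ## r x c against the independent base-R enumeration
  set.seed(3)
  for (i in 1:20) {
    tab <- matrix(rpois(sample(c(4, 6), 1), 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }

  ## large totals fall back to seeded Monte-Carlo near the exact value
  big <- matrix(c(200, 100, 120, 180), 2)
  mc <- fisher_exact_rxc(big, mc_draws = 2e4, seed = 5)
  expect_equal(mc$method, "monte_carlo")
  expect_lt(abs(mc$p - fisher.test(big)$p.value), 0.01)
})

test_that("event chi-square reproduces closed-form cases", {
  r <- chisq_events(c(5, 10, 14), c(12, 5, 4))
  expect_equal(r$p, 1.3e-5, tolerance = 0.05)  # 2 significant figures
  expect_equal(chisq_events(c(10, 20), c(1, 2))$statistic, 0)
  expect_equal(chisq_events(c(10, 20), c(1, 2))$p, 1)
  r2 <- chisq_events(c(10, 0), c(1, 1))
  expect_equal(r2$statistic, 10)
  expect_equal(r2$p, pchisq(10, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r2$p, 0.001565, tolerance = 1e-3)
})

test_that("Kruskal-Wallis matches hand ranks and the base-R oracle", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p, 1)

  ## rank invariance under monotone transform
  g <- list(rexp(5), rexp(4), rexp(6))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, function(x) x^3))$statistic,
               tolerance = 1e-12)

  set.seed(4)
  for (i in 1:40) {
    g <- lapply(1:3, function(j) sample(1:9, sample(3:6, 1), replace = TRUE))
    mine <- kruskal_wallis(g)
    ref <- kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  expect_equal(mann_whitney(1:3, 11:13)$p, 0.1, tolerance = 1e-12)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  x <- rnorm(8); y <- rnorm(9)
  expect_equal(mann_whitney(x, y)$p, mann_whitney(y, x)$p, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:60, nx); y <- sample(setdiff(1:60, x), ny)
    expect_equal(mann_whitney(x, y)$p, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  ## tied / large path against the normal approximation oracle
  for (i in 1:20) {
    x <- sample(1:6, 10, replace = TRUE); y <- sample(1:6, 12, replace = TRUE)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mann_whitney(x, y)$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Spearman matches enumeration and the t-approximation", {
  expect_equal(spearman_cor(1:5, c(1, 3, 2, 5, 4))$rho, 0.8, tolerance = 1e-12)
  expect_equal(spearman_cor(1:6, 6:1)$rho, -1)
  expect_equal(spearman_cor(1:6, (1:6)^2)$rho, 1)
  expect_true(is.na(spearman_cor(1:5, rep(2, 5))$rho))

  set.seed(6)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    x <- sample(1:40, n); y <- sample(1:40, n)
    expect_equal(spearman_cor(x, y)$p, brute_force_spearman_p(x, y),
                 tolerance = 1e-9)
  }
  ## larger n: t-approximation formula check
  x <- rnorm(30); y <- x + rnorm(30)
  r <- spearman_cor(x, y)
  tt <- r$rho * sqrt(28 / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tt), 28), tolerance = 1e-12)
})

test_that("multiple-testing adjustment follows BH and Storey conventions", {
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_p(rep(0.2, 5)), rep(0.2, 5))
  p <- runif(60)
  expect_equal(adjust_p(p, "bh"), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(adjust_p(p, "bh") >= p))
  expect_true(all(adjust_p(p, "qvalue") <= adjust_p(p, "bh") + 1e-12))
  ## pi0 caps at 1 when all p exceed lambda
  hi <- c(0.6, 0.7, 0.8, 0.9)
  expect_equal(adjust_p(hi, "qvalue"), adjust_p(hi, "bh"))
  expect_length(adjust_p(numeric(0)), 0)
  expect_error(adjust_p(c(0.5, 0)), "in \\(0,1\\]")
})

test_that("rank tests keep nominal type-I error on null Gaussian data", {
  set.seed(8)
  reps <- 5000
  kw_rej <- mw_rej <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(10); y <- rnorm(10); z <- rnorm(10)
    kw_rej[i] <- kruskal_wallis(list(x, y, z))$p < 0.05
    mw_rej[i] <- mann_whitney(x, y)$p < 0.05
  }
  expect_gt(mean(kw_rej), 0.035); expect_lt(mean(kw_rej), 0.065)
  expect_gt(mean(mw_rej), 0.035); expect_lt(mean(mw_rej), 0.065)
})

test_that("the feature screen routes by declared type", {
  ## event-count routing reproduces the exacerbation fixture
  fx <- cohort_fixtures()$exacerbations
  labels <- rep(1:3, fx$patients)
  events <- unlist(lapply(1:3, function(k) {  # per-patient events with exact totals
    n <- fx$patients[k]; e <- fx$events[k]
    base <- rep(e %/% n, n); base[seq_len(e %% n)] <- base[seq_len(e %% n)] + 1
    base
  }))
  clin <- clinical_table(data.frame(exac = events),
                         types = c(exac = "event_count"))
  rep_ <- run_feature_screen(clin, labels)
  expect_equal(rep_$test, "chisq_events")
  expect_equal(rep_$p, 1.3e-5, tolerance = 0.05)

  ## planted smear association is detected; continuous feature routed to KW
  set.seed(9)
  com <- generate_community(community_config(seed = 9))
  clin2 <- generate_clinical(com$labels,
                             clinical_config(smear_prob = c(0.8, 0.0, 0.8),
                                             seed = 9))
  scr <- run_feature_screen(clin2, com$labels)
  expect_lt(scr$p[scr$feature == "smear"], 0.05)
  expect_equal(scr$test[scr$feature == "lymphocyte_pct"], "kruskal_wallis")
  expect_true(all(c("padj", "q") %in% colnames(scr)))
  expect_error(run_feature_screen(clin2, com$labels[-1]), "align")
})

test_that("the feature screen keeps its false-positive rate on null features", {
  set.seed(10)
  hits <- 0; n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    labels <- rep(1:3, times = c(12, 10, 8))
    clin <- clinical_table(data.frame(v = rnorm(30)), c(v = "continuous"))
    if (run_feature_screen(clin, labels)$p[1] < 0.05) hits <- hits + 1
  }
  expect_lt(abs(hits / n_seeds - 0.05), 3 * sqrt(0.05 * 0.95 / n_seeds) + 0.01)
})

test_that("co-detection permutation test behaves at the extremes", {
  set.seed(11)
  pres <- matrix(FALSE, 5, 30, dimnames = list(paste0("t", 1:5),
                                               paste0("s", 1:30)))
  group <- paste0("s", 1:15)
  expect_equal(codetection_test(pres, c("t1", "t2"), group, B = 99)$p, 1)

  pres2 <- pres
  pres2[c("t1", "t2"), 1:15] <- TRUE  # co-detected only inside the group
  r <- codetection_test(pres2, c("t1", "t2"), group, B = 999, seed = 2)
  expect_lte(r$p, 0.01)
  expect_equal(r$statistic, 15)

  pres3 <- pres2
  pres3["t5", ] <- TRUE  # non-set taxon changes nothing
  expect_equal(codetection_test(pres3, c("t1", "t2"), group, B = 999, seed = 2)$p,
               r$p)
  expect_error(codetection_test(pres2, "t1", paste0("s", 1:40), B = 99), "larger")
})
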