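## Clustering-quality assessment: average silhouette width, prediction
## strength, and a simulation-based significance test against a
## single-component Dirichlet-multinomial null.

#' Silhouette widths and their average
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)), with a(i) the mean distance of
#' sample i to its own cluster (excluding itself) and b(i) the smallest
#' mean distance to any other cluster. Members of singleton clusters score
#' 0 by convention.
#'
#' @param dist a `distance_matrix` or matrix.
#' @param labels cluster labels with >= 2 clusters.
#' @return list(widths = per-sample s(i), asw = average silhouette width).
#' @export
silhouette_widths <- function(dist, labels) {
  d <- as_dist_matrix(dist)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette requires at least 2 clusters")
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (length(own) - 1)
    b <- min(vapply(setdiff(seq_len(k), labels[i]), function(c_)
      mean(d[i, labels == c_]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(widths = s, asw = mean(s))
}

#' Prediction strength of a clustering at a given k
#'
#' Cross-validation co-assignment stability: per repeat the samples are
#' split in half at random, PAM is run on each half, test samples are
#' classified to the nearest training medoid, and for each test-side
#' cluster (of size >= 2) the fraction of its member pairs that the
#' training classifier co-assigns is computed. The repeat statistic is the
#' minimum over test clusters; PS(k) is the mean over repeats. k = 1
#' returns 1 by convention. A test cluster of size < 2 contributes 1.
#'
#' @param dist a `distance_matrix` (n >= 2k + 2 samples).
#' @param k number of clusters.
#' @param repeats number of random half-splits.
#' @param seed integer seed; results are deterministic given the seed.
#' @return list(ps = mean over repeats, per_repeat, sd).
#' @export
prediction_strength <- function(dist, k, repeats = 50, seed = 1) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (k == 1) return(list(ps = 1, per_repeat = rep(1, repeats), sd = 0))
  if (n < 2 * k + 2) stop("need n >= 2k + 2")
  set.seed(child_seed(seed, "prediction_strength"))
  per <- numeric(repeats)
  for (r in seq_len(repeats)) {
    train <- sort(sample(n, floor(n / 2)))
    test <- setdiff(seq_len(n), train)
    fit_tr <- pam_cluster(d[train, train, drop = FALSE], k)
    fit_te <- pam_cluster(d[test, test, drop = FALSE], k)
    ## classify test points to nearest training medoid
    med_tr <- train[fit_tr$medoids]
    assign_tr <- apply(d[med_tr, test, drop = FALSE], 2, which.min)
    stats_c <- vapply(seq_len(k), function(c_) {
      members <- which(fit_te$labels == c_)
      m <- length(members)
      if (m < 2) return(1)
      same <- outer(assign_tr[members], assign_tr[members], "==")
      (sum(same) - m) / (m * (m - 1))
    }, 0)
    per[r] <- min(stats_c)
  }
  list(ps = mean(per), per_repeat = per, sd = stats::sd(per))
}

#' Simulation test of clustering significance
#'
#' Tests whether the observed cluster structure exceeds what a homogeneous
#' community would produce: a single-component Dirichlet multinomial is
#' fitted to all samples, B tables are simulated from it with the observed
#' per-sample library sizes, and the Calinski-Harabasz index at `chosen_k`
#' (PAM on square-root JSD) is computed for each. The p-value is the
#' add-one upper tail (1 + #\{CH_sim >= CH_obs\}) / (B + 1), so it is never
#' exactly 0.
#'
#' @param table an [abundance_table].
#' @param chosen_k the cluster number under test.
#' @param B number of null simulations (>= 19).
#' @param seed integer seed.
#' @return list(p, ch_observed, ch_null, B).
#' @export
simulation_test <- function(table, chosen_k, B = 199, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  if (B < 19) stop("B must be at least 19 for usable resolution")
  null_fit <- dmm_fit(table, K = 1, n_restarts = 1, seed = child_seed(seed, "null_fit"))
  alpha <- null_fit$alpha[1, ]
  totals <- colSums(table$counts)
  ch_of <- function(counts) {
    rel <- counts / rep(pmax(colSums(counts), 1), each = nrow(counts))
    rel_obj <- structure(list(rel = rel, rank = table$rank, sample_meta = NULL),
                         class = "relative_abundance")
    rownames(rel_obj$rel) <- rownames(table$counts) %||% paste0("t", seq_len(nrow(counts)))
    colnames(rel_obj$rel) <- paste0("s", seq_len(ncol(counts)))
    dd <- jsd_distance(rel_obj)
    calinski_harabasz(dd, pam_cluster(dd, chosen_k)$labels)
  }
  ch_obs <- ch_of(table$counts)
  set.seed(child_seed(seed, "simulation_test"))
  ch_null <- numeric(B)
  for (b in seq_len(B)) {
    sim <- dmm_simulate(alpha, totals)
    ch_null[b] <- ch_of(sim)
  }
  list(p = (1 + sum(ch_null >= ch_obs)) / (B + 1),
       ch_observed = ch_obs, ch_null = ch_null, B = B)
}

#' Full clustering validation report
#'
#' Combines per-k average silhouette width, prediction strength at the
#' chosen k, and the simulation p-value, and applies the decision rule:
#' a clustering is "supported" iff PS > `ps_threshold` (default 0.8) and
#' simulation p < `p_threshold` (default 0.05).
#'
#' @param table an [abundance_table].
#' @param dist its square-root JSD `distance_matrix`.
#' @param result a `clustering_result` from [select_k_pam].
#' @param repeats,B,seed validation parameters.
#' @param ps_threshold,p_threshold decision thresholds.
#' @return A `validation_report` list: asw (per k in the index table), ps,
#'   simulation_p, thresholds, supported.
#' @export
validate_clustering <- function(table, dist, result, repeats = 50, B = 199,
                                seed = 1, ps_threshold = 0.8,
                                p_threshold = 0.05) {
  ks <- result$index_table$k %||% result$k
  asw <- vapply(ks, function(k)
    silhouette_widths(dist, pam_cluster(dist, k)$labels)$asw, 0)
  ps <- prediction_strength(dist, result$k, repeats = repeats, seed = seed)
  sim <- simulation_test(table, result$k, B = B, seed = seed)
  structure(list(k = result$k, asw = data.frame(k = ks, asw = asw),
                 ps = ps$ps, ps_sd = ps$sd, simulation_p = sim$p,
                 thresholds = c(ps = ps_threshold, p = p_threshold),
                 supported = ps$ps > ps_threshold && sim$p < p_threshold),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: k = %d, PS = %.3f, simulation p = %.4f -> %s\n",
              x$k, x$ps, x$simulation_p,
              if (x$supported) "supported" else "not supported"))
  invisible(x)
}
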