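## Pneumotype discovery: Jensen-Shannon distance, k-medoids (PAM) with
## Calinski-Harabasz model selection, cross-method agreement, core microbes.

#' Square-root Jensen-Shannon divergence between samples
#'
#' d(i,j) = sqrt( H(m) - (H(p_i)+H(p_j))/2 ) with m the midpoint
#' distribution and H the natural-log Shannon entropy (0 log 0 = 0). The
#' square root makes JSD a metric; values lie in \[0, sqrt(log 2)\]. No
#' pseudocounts are needed: the midpoint form is finite for zeros.
#'
#' @param rel a `relative_abundance` object whose columns sum to 1.
#' @return A `distance_matrix` object: symmetric matrix with zero diagonal
#'   plus sample ids and a metric tag.
#' @export
jsd_distance <- function(rel) {
  stopifnot(inherits(rel, "relative_abundance"))
  p <- rel$rel
  tot <- colSums(p)
  if (any(abs(tot - 1) > 1e-8)) stop("columns must sum to 1 (non-normalized column)")
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hs <- apply(p, 2, H)
  n <- ncol(p)
  d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- (p[, i] + p[, j]) / 2
    jsd <- H(m) - (hs[i] + hs[j]) / 2
    d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
  }
  structure(list(d = d, metric = "sqrt_jsd"), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples, metric '%s'\n",
              nrow(x$d), x$metric))
  invisible(x)
}

as_dist_matrix <- function(x) {
  if (inherits(x, "distance_matrix")) return(x$d)
  if (inherits(x, "dist")) return(as.matrix(x))
  as.matrix(x)
}

## Total cost of a medoid set: sum over points of distance to nearest medoid.
medoid_cost <- function(d, medoids) {
  sum(do.call(pmin, lapply(medoids, function(m) d[m, ])))
}

#' Partitioning around medoids (deterministic BUILD + SWAP)
#'
#' k-medoids clustering on a precomputed distance matrix, minimising the
#' total distance of points to their nearest medoid. Small instances
#' (at most 2000 candidate medoid subsets) are solved exactly by
#' exhaustive enumeration, because the BUILD+SWAP local search — like any
#' k-medoids swap heuristic — can stall in a local optimum even at n = 5.
#' Larger instances use BUILD (greedy seeding) followed by SWAP
#' (best-improving medoid/non-medoid exchange until none improves). All
#' ties are broken toward the lowest sample index, so the result is
#' deterministic.
#'
#' @param dist a `distance_matrix`, `dist` or square matrix.
#' @param k number of clusters, 2 <= k <= n (k = n allowed: each point its
#'   own medoid at zero cost).
#' @return A `clustering_result`: method, labels (1..k), medoid ids,
#'   cost, k.
#' @export
pam_cluster <- function(dist, k) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k out of range")
  if (choose(n, k) <= 2000) {
    subsets <- utils::combn(n, k)
    costs <- apply(subsets, 2, function(m) medoid_cost(d, m))
    medoids <- subsets[, which.min(costs)]  # combn order: lowest indices win ties
    return(pam_finalize(d, medoids, k))
  }
  ## BUILD
  medoids <- which.min(colSums(d))  # ties: which.min takes lowest index
  while (length(medoids) < k) {
    near <- do.call(pmin, lapply(medoids, function(m) d[m, ]))
    gains <- vapply(seq_len(n), function(h) {
      if (h %in% medoids) return(-Inf)
      sum(pmax(near - d[h, ], 0))
    }, 0)
    medoids <- c(medoids, which.max(gains))
  }
  ## SWAP
  repeat {
    cur <- medoid_cost(d, medoids)
    best <- cur; best_swap <- NULL
    for (mi in seq_along(medoids)) {
      others <- medoids[-mi]
      for (h in seq_len(n)) {
        if (h %in% medoids) next
        cost <- medoid_cost(d, c(others, h))
        if (cost < best - 1e-12) { best <- cost; best_swap <- c(mi, h) }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
  }
  pam_finalize(d, medoids, k)
}

pam_finalize <- function(d, medoids, k) {
  medoids <- sort(medoids)
  labels <- apply(d[medoids, , drop = FALSE], 2, which.min)
  structure(list(method = "pam", labels = as.integer(labels),
                 medoids = medoids, medoid_ids = rownames(d)[medoids],
                 cost = medoid_cost(d, medoids), k = k,
                 sample_ids = rownames(d)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result (%s): k = %d, sizes %s\n", x$method, x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

## Global medoid: index minimizing total distance to all points.
global_medoid <- function(d) which.min(colSums(d))

#' Calinski-Harabasz index on a distance matrix
#'
#' Pseudo-F ratio of between- to within-cluster dispersion computed with
#' medoids as centers: CH = \[sum_c n_c d(m_c, m)^2 / (k-1)\] /
#' \[sum_i d(i, m_c(i))^2 / (n-k)\], where m_c is cluster c's medoid and m
#' the global medoid. Zero within-cluster dispersion with positive
#' between-cluster dispersion returns the largest representable value.
#'
#' @param dist a `distance_matrix` or matrix.
#' @param labels cluster labels, >= 2 non-empty clusters, k < n.
#' @return Numeric CH score.
#' @export
calinski_harabasz <- function(dist, labels) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2 || k >= n) stop("CH requires 2 <= k < n")
  gm <- global_medoid(d)
  between <- 0; within <- 0
  for (c_ in seq_len(k)) {
    idx <- which(labels == c_)
    mc <- idx[which.min(colSums(d[idx, idx, drop = FALSE]))]
    between <- between + length(idx) * d[mc, gm]^2
    within <- within + sum(d[mc, idx]^2)
  }
  if (within == 0) {
    if (between == 0) return(0)
    return(.Machine$double.xmax)
  }
  (between / (k - 1)) / (within / (n - k))
}

#' Choose the number of pneumotypes by PAM + Calinski-Harabasz
#'
#' Runs [pam_cluster] for each k in `k_range` and picks the k with the
#' highest CH index (ties toward the smaller k).
#'
#' @param dist a `distance_matrix`.
#' @param k_range candidate cluster numbers (default 2:6).
#' @return A `clustering_result` for the chosen k with an `index_table`
#'   data.frame (k, CH, cost) attached.
#' @export
select_k_pam <- function(dist, k_range = 2:6) {
  d <- as_dist_matrix(dist)
  if (min(k_range) < 2 || max(k_range) >= nrow(d))
    stop("k_range must lie within (1, n)")
  fits <- lapply(k_range, function(k) pam_cluster(dist, k))
  ch <- vapply(seq_along(k_range), function(i)
    calinski_harabasz(d, fits[[i]]$labels), 0)
  tab <- data.frame(k = k_range, CH = ch,
                    cost = vapply(fits, function(f) f$cost, 0))
  best <- which.max(ch)
  out <- fits[[best]]
  out$index_table <- tab
  out$chosen_k <- k_range[best]
  out
}

#' Agreement between two clusterings of the same samples
#'
#' Matches labels optimally (best permutation of the smaller label set on
#' the confusion matrix, exhaustive over <= k! permutations) and reports
#' the number of mismatched samples together with the adjusted Rand index.
#'
#' @param a,b `clustering_result`s or label vectors over identical samples.
#' @return list(mismatches, ari, matching).
#' @export
method_agreement <- function(a, b) {
  la <- if (inherits(a, "clustering_result")) a$labels else a
  lb <- if (inherits(b, "clustering_result")) b$labels else b
  if (inherits(a, "clustering_result") && inherits(b, "clustering_result") &&
      !identical(a$sample_ids, b$sample_ids))
    stop("sample sets differ")
  if (length(la) != length(lb)) stop("sample sets differ")
  la <- as.integer(factor(la)); lb <- as.integer(factor(lb))
  ka <- max(la); kb <- max(lb)
  swap <- ka > kb
  if (swap) { tmp <- la; la <- lb; lb <- tmp; tmp <- ka; ka <- kb; kb <- tmp }
  tab <- matrix(0L, ka, kb)
  for (i in seq_along(la)) tab[la[i], lb[i]] <- tab[la[i], lb[i]] + 1L
  perms <- perm_matrix(kb)
  agree <- apply(perms, 1, function(p) {
    sum(vapply(seq_len(ka), function(r) tab[r, p[r]], 0L))
  })
  best <- which.max(agree)
  list(mismatches = length(la) - agree[best],
       ari = adjusted_rand_index(la, lb),
       matching = perms[best, seq_len(ka)])
}

#' Core microbes of each pneumotype and their correlation structure
#'
#' The core set of a subgroup comprises up to `top_m` taxa with the highest
#' within-subgroup mean relative abundance, each required to (a) reach mean
#' abundance >= `min_mean` in that subgroup and (b) achieve its
#' across-subgroup maximum mean there. For every pair of core taxa the
#' Spearman correlation of their abundances over all samples is reported,
#' split into within-set and between-set pairs; compositional closure makes
#' cores of different subgroups compete for the same read fraction, so
#' between-set correlations are expected negative.
#'
#' @param rel a `relative_abundance` object.
#' @param labels subgroup labels per sample.
#' @param top_m maximum core size per subgroup.
#' @param min_mean minimum within-subgroup mean relative abundance.
#' @return list(cores = per-subgroup taxon id lists, pairs = data.frame of
#'   taxon pairs with kind ("within"/"between"), rho and p).
#' @export
core_microbes <- function(rel, labels, top_m = 2, min_mean = 0.05) {
  stopifnot(inherits(rel, "relative_abundance"))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  means <- sapply(seq_len(k), function(c_)
    rowMeans(rel$rel[, labels == c_, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, ncol = k)
  rownames(means) <- rownames(rel$rel)
  argmax_grp <- apply(means, 1, which.max)
  cores <- lapply(seq_len(k), function(c_) {
    elig <- which(means[, c_] >= min_mean & argmax_grp == c_)
    if (length(elig) == 0) {
      warning(sprintf("subgroup %d has no qualifying core taxon", c_))
      return(character(0))
    }
    elig <- elig[order(means[elig, c_], decreasing = TRUE)]
    rownames(rel$rel)[utils::head(elig, top_m)]
  })
  core_taxa <- unlist(cores)
  grp_of <- rep(seq_len(k), lengths(cores))
  pairs <- list()
  if (length(core_taxa) >= 2) {
    cmb <- utils::combn(length(core_taxa), 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(j) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      r <- spearman_cor(rel$rel[core_taxa[i1], ], rel$rel[core_taxa[i2], ])
      data.frame(taxon1 = core_taxa[i1], taxon2 = core_taxa[i2],
                 kind = if (grp_of[i1] == grp_of[i2]) "within" else "between",
                 rho = r$rho, p = r$p)
    })
  }
  list(cores = cores,
       pairs = if (length(pairs)) do.call(rbind, pairs)
               else data.frame(taxon1 = character(0), taxon2 = character(0),
                               kind = character(0), rho = numeric(0),
                               p = numeric(0)))
}

#' Classical MDS coordinates of a distance matrix
#'
#' Plain 2-D principal-coordinate dump for plotting; not an inference step.
#'
#' @param dist a `distance_matrix`.
#' @param ndim number of coordinates.
#' @return Matrix of sample coordinates.
#' @export
ordination_coords <- function(dist, ndim = 2) {
  stats::cmdscale(stats::as.dist(as_dist_matrix(dist)), k = ndim)
}
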