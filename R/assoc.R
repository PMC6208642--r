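## Association tests between pneumotype labels and clinical features.
## The tests themselves are implemented from first principles (exact
## enumeration where feasible); only tail probabilities of the reference
## chi-square / normal / t distributions come from base R.

## log-probability of an r x c table under the multivariate hypergeometric
## (fixed margins) null.
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

## Enumerate all tables with the given margins, calling f(tab) on each.
enumerate_tables <- function(row_margins, col_margins, f) {
  r <- length(row_margins); c <- length(col_margins)
  tab <- matrix(0L, r, c)
  rec <- function(i, col_left) {
    if (i == r) {
      tab[r, ] <<- col_left
      f(tab)
      return(invisible())
    }
    fill_row <- function(j, row_left, col_left) {
      if (j == c) {
        if (row_left <= col_left[c]) {
          tab[i, c] <<- row_left
          cl <- col_left; cl[c] <- cl[c] - row_left
          rec(i + 1L, cl)
        }
        return(invisible())
      }
      for (v in 0:min(row_left, col_left[j])) {
        tab[i, j] <<- v
        cl <- col_left; cl[j] <- cl[j] - v
        fill_row(j + 1L, row_left - v, cl)
      }
    }
    fill_row(1L, row_margins[i], col_left)
  }
  rec(1L, as.integer(col_margins))
  invisible()
}

#' Fisher exact test for an r x c contingency table
#'
#' Two-sided exact test of independence: the p-value is the total null
#' (fixed-margin multivariate hypergeometric) probability of all tables no
#' more probable than the observed one. Tables with total count <= 300 are
#' enumerated exactly; larger tables use a seeded Monte-Carlo estimate
#' (100,000 margin-preserving draws, add-one estimator).
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2.
#' @param mc_draws Monte-Carlo sample size for large tables.
#' @param seed seed for the Monte-Carlo path.
#' @return list(test, p, n, method); a zero row/column margin gives p = 1
#'   with a note.
#' @export
fisher_exact_rxc <- function(tab, mc_draws = 1e5, seed = 1) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  n <- sum(tab)
  rm_ <- rowSums(tab); cm <- colSums(tab)
  if (any(rm_ == 0) || any(cm == 0))
    return(list(test = "fisher_exact", p = 1, n = n, method = "degenerate margin"))
  lp_obs <- log_table_prob(tab) + 1e-7  # tolerance for ties
  if (n <= 300) {
    p <- 0
    enumerate_tables(rm_, cm, function(t2) {
      lp <- log_table_prob(t2)
      if (lp <= lp_obs) p <<- p + exp(lp)
    })
    list(test = "fisher_exact", p = min(p, 1), n = n, method = "enumeration")
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(mc_draws)) {
      t2 <- stats::r2dtable(1, rm_, cm)[[1]]
      if (log_table_prob(t2) <= lp_obs) hits <- hits + 1L
    }
    list(test = "fisher_exact", p = (hits + 1) / (mc_draws + 1), n = n,
         method = "monte_carlo")
  }
}

#' Chi-square test for event counts against exposure
#'
#' Goodness-of-fit test of whether events (e.g. COPD exacerbations) are
#' distributed across groups proportionally to exposure (e.g. patients per
#' group): expected events E_g = total * exposure_g / sum(exposure),
#' X^2 = sum (O-E)^2/E, p from the chi-square upper tail on groups-1 df.
#'
#' @param events per-group event counts.
#' @param exposure per-group exposures (> 0), e.g. patient counts.
#' @return list(test, statistic, df, p, expected, n, low_expected_warning).
#' @export
chisq_events <- function(events, exposure) {
  if (length(events) != length(exposure)) stop("events/exposure length mismatch")
  if (sum(events) <= 0) stop("no events")
  if (any(exposure <= 0)) stop("exposures must be positive")
  expected <- sum(events) * exposure / sum(exposure)
  stat <- sum((events - expected)^2 / expected)
  df <- length(events) - 1L
  list(test = "chisq_events", statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected, n = sum(events),
       low_expected_warning = any(expected < 1))
}

## Average ranks with tie information; returns list(ranks, tie_sizes).
avg_ranks <- function(x) {
  r <- rank(x, ties.method = "average")
  list(ranks = r, ties = as.integer(table(x)))
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with average ranks and the standard tie correction; p-value
#' from the chi-square approximation on (groups - 1) df.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list(test, statistic, df, p, n, medians).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  r <- rank(x, ties.method = "average")
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- as.integer(table(x))
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  df <- length(groups) - 1L
  if (correction == 0) {  # all values identical
    return(list(test = "kruskal_wallis", statistic = 0, df = df, p = 1,
                n = n, medians = vapply(groups, stats::median, 0)))
  }
  h <- h / correction
  list(test = "kruskal_wallis", statistic = h, df = df,
       p = stats::pchisq(h, df, lower.tail = FALSE), n = n,
       medians = vapply(groups, stats::median, 0))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p by enumeration of all rank assignments when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param x,y numeric vectors.
#' @return list(test, statistic (U for x), p, n, method, medians).
#' @export
mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y), ties.method = "average")
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (nx + ny <= 12 && !has_ties) {
    ## enumerate all C(nx+ny, nx) placements of x's ranks
    combs <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(seq_len(nx + ny)[combs], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    ties <- as.integer(table(c(x, y)))
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) return(list(test = "mann_whitney", statistic = u, p = 1,
                                 n = n, method = "degenerate",
                                 medians = c(stats::median(x), stats::median(y))))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(test = "mann_whitney", statistic = u, p = min(p, 1), n = nx + ny,
       method = method, medians = c(stats::median(x), stats::median(y)))
}

#' Spearman rank correlation
#'
#' rho on average ranks. The two-sided p-value is exact (full permutation
#' enumeration) for n <= 7 without ties, and otherwise uses the
#' t-approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(rho, p, n, method); zero variance in either vector yields
#'   rho = NA with a flag.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 7 && !has_ties) {
    perms <- perm_matrix(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    }
    method <- "t_approx"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Multiple-testing adjustment: Benjamini-Hochberg or Storey q-values
#'
#' BH: step-up adjusted p-values with monotonicity enforcement. qvalue:
#' single-lambda Storey estimate pi0 = min(1, #\{p > lambda\} /
#' ((1-lambda) m)) multiplied into the BH-adjusted values.
#'
#' @param p vector of p-values in (0, 1].
#' @param method "bh" or "qvalue".
#' @param lambda tuning parameter for the pi0 estimate.
#' @return Numeric vector of adjusted values, same order as `p`.
#' @export
adjust_p <- function(p, method = c("bh", "qvalue"), lambda = 0.5) {
  method <- match.arg(method)
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must be in (0,1]")
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  bh <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  if (method == "bh") return(bh)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  pmin(1, pi0 * bh)
}

#' Clinical feature table with declared types
#'
#' @param data data.frame with one row per sample; row names or a
#'   `sample_id` column identify samples.
#' @param types named character vector mapping feature columns to one of
#'   "categorical", "continuous", "event_count".
#' @param exposure for event-count features: name of the exposure quantity
#'   ("patients" by default, meaning per-subgroup patient counts).
#' @return A `clinical_table` object.
#' @export
clinical_table <- function(data, types, exposure = "patients") {
  if (!all(names(types) %in% colnames(data)))
    stop("type declared for unknown column: ",
         paste(setdiff(names(types), colnames(data)), collapse = ", "))
  bad <- setdiff(unique(types), c("categorical", "continuous", "event_count"))
  if (length(bad)) stop("unknown feature type: ", paste(bad, collapse = ", "))
  structure(list(data = data, types = types, exposure = exposure),
            class = "clinical_table")
}

#' Feature-vs-subgroup association screen
#'
#' Dispatches each declared clinical feature to the appropriate test:
#' categorical features to [fisher_exact_rxc] on the feature-by-subgroup
#' contingency table, continuous features to [kruskal_wallis] across
#' subgroups, and event-count features to [chisq_events] with per-subgroup
#' patient counts as exposure. Missing values are dropped per feature with
#' the n used reported. BH-adjusted p and Storey q-values are attached
#' across the screen.
#'
#' @param clinical a [clinical_table]; rows aligned with `labels`.
#' @param labels integer subgroup labels (one per sample/patient).
#' @param q_threshold,padj_threshold significance thresholds recorded in
#'   the report (defaults 0.1 and 0.05).
#' @return A data.frame (class `association_report`) with one row per
#'   feature: feature, test, statistic, p, padj, q, n.
#' @export
run_feature_screen <- function(clinical, labels, q_threshold = 0.1,
                               padj_threshold = 0.05) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (nrow(clinical$data) != length(labels))
    stop("labels must align with clinical rows")
  labels <- as.integer(factor(labels))
  rows <- lapply(names(clinical$types), function(f) {
    type <- clinical$types[[f]]
    v <- clinical$data[[f]]
    ok <- !is.na(v)
    res <- switch(type,
      categorical = {
        tab <- table(v[ok], labels[ok])
        r <- fisher_exact_rxc(as.matrix(tab))
        data.frame(feature = f, test = r$test, statistic = NA_real_,
                   p = r$p, n = r$n)
      },
      continuous = {
        g <- split(as.numeric(v[ok]), labels[ok])
        g <- g[lengths(g) > 0]
        r <- kruskal_wallis(g)
        data.frame(feature = f, test = r$test, statistic = r$statistic,
                   p = r$p, n = r$n)
      },
      event_count = {
        ev <- tapply(as.numeric(v[ok]), labels[ok], sum)
        expo <- tapply(rep(1, sum(ok)), labels[ok], sum)  # patients per subgroup
        r <- chisq_events(as.numeric(ev), as.numeric(expo))
        data.frame(feature = f, test = r$test, statistic = r$statistic,
                   p = r$p, n = r$n)
      },
      stop("unknown feature type for column ", f))
    res
  })
  rep_ <- do.call(rbind, rows)
  rep_$padj <- adjust_p(rep_$p, "bh")
  rep_$q <- adjust_p(rep_$p, "qvalue")
  attr(rep_, "thresholds") <- c(q = q_threshold, padj = padj_threshold)
  class(rep_) <- c("association_report", "data.frame")
  rep_
}

#' Co-detection permutation test
#'
#' Tests whether samples in a group (e.g. COPD) carry at least two taxa
#' from a designated set (e.g. upper-airway/oral microbes) more often than
#' expected: the statistic is the number of group samples with >= 2 of the
#' set's taxa present, and the null is B random permutations of group
#' membership (add-one p-value).
#'
#' @param presence logical taxa x samples matrix.
#' @param uo_taxa taxon ids forming the set of interest.
#' @param group sample ids forming the group of interest.
#' @param B number of permutations.
#' @param seed integer seed.
#' @return list(test, statistic, p, n).
#' @export
codetection_test <- function(presence, uo_taxa, group, B = 9999, seed = 1) {
  if (length(uo_taxa) == 0 || length(group) == 0) stop("empty set")
  if (length(group) > ncol(presence)) stop("group larger than sample count")
  codet <- colSums(presence[uo_taxa, , drop = FALSE]) >= 2
  obs <- sum(codet[group])
  if (obs == 0) return(list(test = "codetection", statistic = 0, p = 1,
                            n = ncol(presence)))
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(B)) {
    g <- sample(colnames(presence), length(group))
    if (sum(codet[g]) >= obs) ge <- ge + 1L
  }
  list(test = "codetection", statistic = obs, p = (ge + 1) / (B + 1),
       n = ncol(presence))
}
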