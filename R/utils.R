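## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples.
#' Computed from the confusion matrix via the pair-counting formula.
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return A single numeric value in \[-1, 1\]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # degenerate: both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

## All permutations of 1..n as a matrix (n! rows). Only used for small n.
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

## Deterministic child seed derived from a base seed and a stream tag,
## kept inside 32-bit integer range.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483587) + 1L
}

## Dirichlet draws via normalized gammas; rows are draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  zero <- rowSums(x) == 0  # possible for tiny alphas; fall back to uniform
  if (any(zero)) x[zero, ] <- 1
  x / rowSums(x)
}

stopifnot_named <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
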