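## Dirichlet multinomial mixture (DMM) clustering of count compositions,
## fitted by EM with a digamma fixed-point M-step for the Dirichlet
## parameters. The multinomial coefficient is omitted from all component
## log-densities; it is constant per sample and cancels in responsibilities
## and in model comparison.

## Component log-density matrix: n x K, entry = log P(x_i | alpha_k)
## (without the multinomial coefficient):
##   lgamma(A_k) - lgamma(N_i + A_k) + sum_t [lgamma(x_it + a_kt) - lgamma(a_kt)]
dmm_logp <- function(X, alpha) {
  N <- rowSums(X)
  K <- nrow(alpha)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    a <- alpha[k, ]
    A <- sum(a)
    out[, k] <- lgamma(A) - lgamma(N + A) +
      rowSums(lgamma(sweep(X, 2, a, "+"))) - sum(lgamma(a))
  }
  out
}

## Observed-data log-likelihood given logp (n x K) and mixing weights.
dmm_loglik <- function(logp, pi_) {
  lw <- sweep(logp, 2, log(pi_), "+")
  mx <- apply(lw, 1, max)
  sum(mx + log(rowSums(exp(lw - mx))))
}

## One Minka fixed-point sweep of alpha for component k under weights w.
dmm_alpha_update <- function(X, a, w) {
  N <- rowSums(X)
  A <- sum(a)
  denom <- sum(w * (digamma(N + A) - digamma(A)))
  if (denom <= 0) return(a)
  num <- colSums(w * (digamma(sweep(X, 2, a, "+")) - rep(digamma(a), each = nrow(X))))
  pmax(a * num / denom, 1e-10)  # positivity floor
}

## Moment-style initial alpha for a component from weighted mean composition.
init_alpha <- function(X, w, scale = 10) {
  rel <- X / pmax(rowSums(X), 1)
  m <- colSums(w * rel) / sum(w)
  pmax(m * scale, 1e-3)
}

#' Fit a Dirichlet multinomial mixture by EM
#'
#' Models each sample's counts as multinomial with a Dirichlet-distributed
#' composition, mixed over K components. The E-step computes
#' responsibilities from the component Dirichlet-multinomial log-densities
#' via log-sum-exp; the M-step updates mixing weights to mean
#' responsibilities and the Dirichlet parameters by the digamma fixed-point
#' iteration, which monotonically increases the likelihood. The best of
#' `n_restarts` runs by final log-likelihood is returned. The first restart
#' is seeded from PAM labels on square-root JSD (hardened responsibilities);
#' the remainder use random soft assignments.
#'
#' @param table an [abundance_table] (or a counts matrix, taxa x samples).
#' @param K number of mixture components, 1 <= K <= n samples.
#' @param n_restarts number of EM restarts.
#' @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @return A `dmm_model`: K, pi (mixing weights), alpha (K x taxa),
#'   responsibilities (samples x K), labels (argmax responsibilities),
#'   loglik, loglik_trace, iterations, seed.
#' @export
dmm_fit <- function(table, K, n_restarts = 3, seed = 1, tol = 1e-6,
                    max_iter = 500) {
  X <- if (inherits(table, "abundance_table")) t(table$counts) else t(as.matrix(table))
  n <- nrow(X); T_ <- ncol(X)
  if (K > n) stop("K exceeds number of samples")
  if (any(X < 0)) stop("counts must be non-negative")

  run_em <- function(resp) {
    pi_ <- pmax(colMeans(resp), 1e-12); pi_ <- pi_ / sum(pi_)
    alpha <- t(sapply(seq_len(K), function(k) init_alpha(X, resp[, k])))
    if (K == 1) alpha <- matrix(alpha, 1, T_)
    trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      ## M-step (alpha): a few fixed-point sweeps per EM iteration
      for (k in seq_len(K)) {
        for (s in seq_len(3)) alpha[k, ] <- dmm_alpha_update(X, alpha[k, ], resp[, k])
      }
      pi_ <- pmax(colMeans(resp), 1e-12); pi_ <- pi_ / sum(pi_)
      ## E-step
      logp <- dmm_logp(X, alpha)
      ll <- dmm_loglik(logp, pi_)
      lw <- sweep(logp, 2, log(pi_), "+")
      mx <- apply(lw, 1, max)
      resp <- exp(lw - mx)
      resp <- resp / rowSums(resp)
      trace <- c(trace, ll)
      if (!is.finite(ll)) return(NULL)
      if (it > 1 && abs(ll - prev) <= tol * (abs(prev) + 1)) break
      prev <- ll
    }
    list(pi = pi_, alpha = alpha, resp = resp, loglik = ll, trace = trace,
         iterations = length(trace))
  }

  soften <- function(hard) {  # hard labels -> 0.9/0.1-smoothed responsibilities
    r <- matrix(0.1 / max(K - 1, 1), n, K)
    r[cbind(seq_len(n), hard)] <- if (K > 1) 0.9 else 1
    r / rowSums(r)
  }

  best <- NULL
  for (r_ in seq_len(n_restarts)) {
    set.seed(child_seed(seed, paste0("dmm_restart", r_)))
    resp0 <- if (r_ == 1 && K > 1) {
      rel <- structure(list(rel = t(X / pmax(rowSums(X), 1)),
                            rank = "init", sample_meta = NULL),
                       class = "relative_abundance")
      colnames(rel$rel) <- paste0("s", seq_len(n))
      rownames(rel$rel) <- paste0("t", seq_len(T_))
      soften(pam_cluster(jsd_distance(rel), K)$labels)
    } else if (K == 1) {
      matrix(1, n, 1)
    } else {
      r0 <- matrix(stats::rgamma(n * K, 1), n, K)
      r0 / rowSums(r0)
    }
    fit <- run_em(resp0)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop("EM failed to produce a finite likelihood in all restarts")
  structure(list(K = K, pi = best$pi, alpha = best$alpha,
                 responsibilities = best$resp,
                 labels = apply(best$resp, 1, which.max),
                 loglik = best$loglik, loglik_trace = best$trace,
                 iterations = best$iterations, seed = seed),
            class = "dmm_model")
}

#' @export
print.dmm_model <- function(x, ...) {
  cat(sprintf("dmm_model: K = %d, loglik = %.3f (%d EM iterations)\n",
              x$K, x$loglik, x$iterations))
  invisible(x)
}

#' Choose the number of DMM components by BIC
#'
#' Fits [dmm_fit] for each K in `K_range` and selects the K minimising
#' BIC = -2 loglik + p log(n) with p = K * T + (K - 1) free parameters
#' (T Dirichlet parameters per component plus K-1 mixing weights). BIC is
#' used in place of a Laplace evidence approximation and the choice is
#' recorded in the returned table.
#'
#' @param table an [abundance_table] or counts matrix.
#' @param K_range candidate component counts (default 1:6).
#' @param ... passed to [dmm_fit].
#' @return list(model = best `dmm_model`, chosen_K, score_table =
#'   data.frame(K, loglik, bic), criterion = "bic").
#' @export
dmm_select_K <- function(table, K_range = 1:6, ...) {
  X <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  n <- ncol(X); T_ <- nrow(X)
  fits <- lapply(K_range, function(K) dmm_fit(table, K, ...))
  ll <- vapply(fits, function(f) f$loglik, 0)
  p <- K_range * T_ + (K_range - 1)
  bic <- -2 * ll + p * log(n)
  best <- which.min(bic)
  list(model = fits[[best]], chosen_K = K_range[best],
       score_table = data.frame(K = K_range, loglik = ll, bic = bic),
       criterion = "bic")
}

#' Simulate count tables from a fitted single-component DMM
#'
#' Draws a composition from Dirichlet(alpha) per sample and counts from a
#' multinomial at the given library sizes. Used as the null model of the
#' clustering simulation test.
#'
#' @param alpha Dirichlet parameter vector (length = taxa).
#' @param totals per-sample library sizes.
#' @return Counts matrix, taxa x samples.
#' @keywords internal
dmm_simulate <- function(alpha, totals) {
  n <- length(totals)
  p <- rdirichlet(n, alpha)
  X <- vapply(seq_len(n), function(i) stats::rmultinom(1, totals[i], p[i, ])[, 1],
              numeric(length(alpha)))
  X
}
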