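## Shared builders for the test suite. All fixtures are constructed in code.

## A relative_abundance object from a taxa x samples matrix of proportions.
make_rel <- function(m, rank = "genus") {
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  structure(list(rel = m, rank = rank, sample_meta = NULL),
            class = "relative_abundance")
}

## Random composition matrix (columns on the simplex).
random_rel <- function(n_taxa, n_samples) {
  m <- matrix(stats::rexp(n_taxa * n_samples), n_taxa, n_samples)
  make_rel(sweep(m, 2, colSums(m), "/"))
}

## Brute-force optimal k-medoid cost by exhaustive subset search.
brute_force_pam_cost <- function(d, k) {
  n <- nrow(d)
  subsets <- utils::combn(n, k)
  min(apply(subsets, 2, function(m)
    sum(apply(d[m, , drop = FALSE], 2, min))))
}

## Independent Spearman exact two-sided p by full permutation enumeration,
## written without package internals.
brute_force_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  vals <- vapply(perms(ry), function(p) abs(stats::cor(rx, p)), 0)
  mean(vals >= obs - 1e-9)
}

## A small taxonomy: root -> 2 kingdoms -> phyla -> ... -> species.
toy_tree <- function() {
  nodes <- data.frame(
    id     = c("root", "K1", "K2", "P1", "P2", "F1", "G1", "G2", "G3",
               "S1", "S2", "S3", "S4"),
    parent = c("root", "root", "root", "K1", "K2", "P1", "F1", "F1", "P2",
               "G1", "G1", "G2", "G3"),
    rank   = c("root", "kingdom", "kingdom", "phylum", "phylum", "family",
               "genus", "genus", "genus",
               "species", "species", "species", "species"))
  taxonomy_tree(nodes)
}

## One alignment-hit row.
hit <- function(read, taxon, score, evalue = 1e-20, qcov = 90) {
  data.frame(read_id = read, taxon_id = taxon, bitscore = score,
             evalue = evalue, qcov = qcov, stringsAsFactors = FALSE)
}
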