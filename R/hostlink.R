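## Host-microbe interaction screens: rank correlations between taxa and
## gene expression, nonparametric differential expression across
## pneumotypes, targeted gene-set and cytokine comparisons.

#' Construct an expression matrix container
#'
#' @param tpm genes x samples matrix of TPM values (>= 0).
#' @return An `expression_matrix` with an untransformed tag.
#' @export
expression_matrix <- function(tpm) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm))) rownames(tpm) <- paste0("gene_", seq_len(nrow(tpm)))
  if (anyDuplicated(rownames(tpm))) stop("duplicate gene ids")
  if (!is.null(colnames(tpm)) && anyDuplicated(colnames(tpm)))
    stop("duplicate sample ids")
  if (any(tpm < 0)) stop("TPM values must be >= 0")
  structure(list(tpm = tpm, transform = "none"), class = "expression_matrix")
}

#' Log-transform TPM values
#'
#' x -> log2(x + 1e-5); the small offset keeps zeros finite while leaving
#' expressed genes essentially unchanged. Applying the transform twice is
#' an error.
#'
#' @param expr an [expression_matrix].
#' @return The transformed `expression_matrix` (tag set to "log2").
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$transform != "none") stop("matrix is already transformed")
  expr$tpm <- log2(expr$tpm + 1e-5)
  expr$transform <- "log2"
  expr
}

## Vectorized Spearman rho and t-approximation p for all row pairs of two
## matrices sharing columns. Rows with zero variance get NA.
spearman_screen_matrix <- function(A, B) {
  ra <- t(apply(A, 1, rank))
  rb <- t(apply(B, 1, rank))
  n <- ncol(A)
  const_a <- apply(A, 1, function(x) length(unique(x)) == 1)
  const_b <- apply(B, 1, function(x) length(unique(x)) == 1)
  rho <- stats::cor(t(ra), t(rb))
  rho[const_a, ] <- NA; rho[, const_b] <- NA
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- rho * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  list(rho = rho, p = p)
}

#' Screen for taxon-gene expression correlations
#'
#' Computes Spearman correlation between every (taxon relative abundance,
#' gene expression) pair over shared samples (t-approximation p-values)
#' and reports pairs passing both the per-pair p threshold and the Storey
#' q threshold computed across all tested pairs. Constant taxa or genes
#' are skipped and listed.
#'
#' @param rel a `relative_abundance` (ideally restricted to taxa passing
#'   the detection filter, the analysis universe of the screens).
#' @param expr an [expression_matrix] (log-transformed or not; Spearman is
#'   rank-invariant).
#' @param p_thresh,q_thresh significance thresholds (defaults 0.01, 0.01).
#' @return list(pairs = data.frame(taxon, gene, rho, p, q), n_tested,
#'   skipped).
#' @export
taxa_gene_screen <- function(rel, expr, p_thresh = 0.01, q_thresh = 0.01) {
  stopifnot(inherits(rel, "relative_abundance"),
            inherits(expr, "expression_matrix"))
  samples <- intersect(colnames(rel$rel), colnames(expr$tpm))
  if (length(samples) < 6) stop("need at least 6 shared samples")
  A <- rel$rel[, samples, drop = FALSE]
  B <- expr$tpm[, samples, drop = FALSE]
  res <- spearman_screen_matrix(A, B)
  ok <- is.finite(res$p)
  skipped <- list(taxa = rownames(A)[apply(A, 1, stats::sd) == 0],
                  genes = rownames(B)[apply(B, 1, stats::sd) == 0])
  p <- res$p[ok]
  q_all <- rep(NA_real_, length(res$p))
  q_all[ok] <- adjust_p(pmax(p, .Machine$double.xmin), "qvalue")
  q <- matrix(q_all, nrow(A), nrow(B))
  idx <- which(res$p < p_thresh & q < q_thresh, arr.ind = TRUE)
  pairs <- data.frame(taxon = rownames(A)[idx[, 1]],
                      gene = rownames(B)[idx[, 2]],
                      rho = res$rho[idx], p = res$p[idx], q = q[idx],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$p), , drop = FALSE]
  list(pairs = pairs, n_tested = sum(ok), skipped = skipped)
}

#' Differential-expression screen across pneumotypes
#'
#' Per gene, a Kruskal-Wallis test across the subgroups (Mann-Whitney when
#' only two), BH-adjusted over genes. A nonparametric screen is used
#' deliberately: with ~10-20 samples per subgroup it makes no
#' distributional assumptions (noted in the report attribute). Subgroups
#' with fewer than 3 samples are excluded with a warning; constant genes
#' are never reported.
#'
#' @param expr an [expression_matrix].
#' @param labels subgroup labels per sample (aligned with columns).
#' @param padj_thresh BH threshold (default 0.01).
#' @return list(table = per-gene data.frame(gene, statistic, p, padj,
#'   per-subgroup medians), significant = gene ids with padj < threshold).
#' @export
subgroup_de_screen <- function(expr, labels, padj_thresh = 0.01) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$tpm) != length(labels)) stop("labels must align with samples")
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  keep_groups <- which(sizes >= 3)
  if (length(keep_groups) < 2) stop("need >= 2 subgroups with >= 3 samples")
  if (length(keep_groups) < max(labels))
    warning("excluding subgroup(s) with < 3 samples: ",
            paste(setdiff(seq_len(max(labels)), keep_groups), collapse = ", "))
  keep <- labels %in% keep_groups
  x <- expr$tpm[, keep, drop = FALSE]
  g <- as.integer(factor(labels[keep]))
  rows <- lapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    if (length(unique(v)) == 1)
      return(data.frame(gene = rownames(x)[i], statistic = NA_real_,
                        p = NA_real_))
    grp <- split(v, g)
    r <- if (length(grp) == 2) mann_whitney(grp[[1]], grp[[2]])
         else kruskal_wallis(grp)
    data.frame(gene = rownames(x)[i], statistic = r$statistic, p = r$p)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$p)
  tab$padj <- NA_real_
  tab$padj[ok] <- adjust_p(tab$p[ok], "bh")
  meds <- t(apply(x, 1, function(v) tapply(v, g, stats::median)))
  colnames(meds) <- paste0("median_grp", seq_len(ncol(meds)))
  tab <- cbind(tab, meds)
  attr(tab, "method") <- "nonparametric rank tests (KW/MWU) with BH adjustment"
  list(table = tab,
       significant = tab$gene[!is.na(tab$padj) & tab$padj < padj_thresh])
}

#' Compare a gene set between two pneumotypes
#'
#' Per gene in the set, a Mann-Whitney test between the two subgroups;
#' the summary counts genes with p < 0.05 and reports how consistently the
#' first subgroup is the higher one (direction consistency fraction, by
#' median difference, ties excluded). Gene ids missing from the matrix are
#' listed, not fatal.
#'
#' @param expr an [expression_matrix].
#' @param labels subgroup labels per sample.
#' @param geneset a [gene_set].
#' @param pair length-2 vector of subgroup labels to compare (first vs
#'   second).
#' @return list(table, n_significant, direction_consistency, missing).
#' @export
geneset_compare <- function(expr, labels, geneset, pair) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(geneset, "gene_set"))
  if (length(pair) != 2) stop("pair must name two subgroups")
  in1 <- labels == pair[1]; in2 <- labels == pair[2]
  if (!any(in1) || !any(in2)) stop("both subgroups must be present")
  present <- intersect(geneset$genes, rownames(expr$tpm))
  missing <- setdiff(geneset$genes, present)
  rows <- lapply(present, function(gn) {
    r <- mann_whitney(expr$tpm[gn, in1], expr$tpm[gn, in2])
    data.frame(gene = gn, U = r$statistic, p = r$p,
               median1 = r$medians[1], median2 = r$medians[2],
               higher_in_first = r$medians[1] > r$medians[2])
  })
  tab <- do.call(rbind, rows)
  nonties <- tab$median1 != tab$median2
  list(table = tab,
       n_significant = sum(tab$p < 0.05),
       direction_consistency = if (any(nonties)) mean(tab$higher_in_first[nonties])
                               else NA_real_,
       missing = missing)
}

#' Compare cytokine concentrations across pneumotypes
#'
#' Kruskal-Wallis per analyte; analytes with p < `p_thresh` are flagged
#' with their per-subgroup medians. Output order follows sorted analyte
#' names so it is stable under input reordering.
#'
#' @param cytokines analyte x sample numeric matrix or data.frame.
#' @param labels subgroup labels per sample.
#' @param p_thresh reporting threshold (default 0.05).
#' @return list(table, significant).
#' @export
cytokine_compare <- function(cytokines, labels, p_thresh = 0.05) {
  m <- as.matrix(cytokines)
  if (!is.numeric(m)) stop("non-numeric cytokine values (check input cells)")
  if (ncol(m) != length(labels)) stop("labels must align with samples")
  m <- m[order(rownames(m)), , drop = FALSE]
  g <- as.integer(factor(labels))
  rows <- lapply(seq_len(nrow(m)), function(i) {
    r <- kruskal_wallis(split(m[i, ], g))
    meds <- t(r$medians); colnames(meds) <- paste0("median_grp", seq_along(r$medians))
    cbind(data.frame(analyte = rownames(m)[i], statistic = r$statistic,
                     p = r$p), meds)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, significant = tab$analyte[tab$p < p_thresh])
}

#' Named gene set
#'
#' @param name set name.
#' @param genes non-empty character vector of gene ids.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, genes) {
  if (length(genes) == 0) stop("gene set must be non-empty")
  structure(list(name = name, genes = unique(as.character(genes))),
            class = "gene_set")
}

#' Th17-differentiation key genes
#'
#' The 13 genes central to Th17 cell differentiation used by the targeted
#' pathway comparison (IL-6/TGF-beta signalling through STAT3 and RORC to
#' the IL-17 effectors). Shipped as a plain-text file and user-overridable.
#'
#' @param path optional path to a custom one-gene-per-line file.
#' @return A [gene_set].
#' @export
th17_geneset <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "th17_key_genes.txt", package = "pneumotyper")
  genes <- readLines(path)
  genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
  gene_set("Th17_differentiation_key", genes)
}
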