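#' Construct a taxa-by-sample abundance table
#'
#' The basic container for read-count profiles: an integer matrix with taxa
#' as rows and samples as columns, carrying the taxonomic rank the counts
#' were aggregated at. Counts are typically reads assigned to archaea,
#' bacteria, fungi or viruses (ABFV) in a metatranscriptome, so that a
#' taxon's share of the column total reflects its transcriptional activity.
#'
#' @param counts numeric matrix of non-negative integers, taxa x samples.
#'   Row names are taxon ids, column names sample ids (generated if absent).
#' @param rank taxonomic rank label, e.g. "phylum", "genus" or "species".
#' @param sample_meta optional data.frame of per-sample metadata with one
#'   row per column of `counts`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(counts, rank = "genus", sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (all(colSums(counts) == 0)) stop("all columns are empty")
  if (!is.null(sample_meta) && nrow(sample_meta) != ncol(counts))
    stop("sample_meta rows must match number of samples")
  structure(list(counts = counts, rank = rank, sample_meta = sample_meta),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples at rank '%s'\n",
              nrow(x$counts), ncol(x$counts), x$rank))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Convert counts to per-sample relative abundances
#'
#' Each cell becomes count / column total ("read abundance": the taxon's
#' proportion of all ABFV reads in that sample). Empty columns are returned
#' as all-zero with a warning rather than NaN.
#'
#' @param table an [abundance_table].
#' @return A `relative_abundance` object: same axes, columns summing to 1
#'   (or 0 for empty samples).
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  counts <- table$counts
  tot <- colSums(counts)
  if (any(tot == 0))
    warning("empty sample column(s): ",
            paste(colnames(counts)[tot == 0], collapse = ", "))
  rel <- sweep(counts, 2, ifelse(tot == 0, 1, tot), "/")
  structure(list(rel = rel, rank = table$rank, sample_meta = table$sample_meta),
            class = "relative_abundance")
}

#' @export
print.relative_abundance <- function(x, ...) {
  cat(sprintf("relative_abundance: %d taxa x %d samples at rank '%s'\n",
              nrow(x$rel), ncol(x$rel), x$rank))
  invisible(x)
}

#' Detection filter: keep taxa reaching a minimum abundance in any sample
#'
#' Implements the inclusive prevalence rule used to call transcriptionally
#' active taxa: a taxon is kept iff its relative abundance is at least
#' `threshold` (default 1%) in at least one sample. Row order is preserved.
#'
#' @param rel a `relative_abundance` object.
#' @param threshold detection threshold as a fraction in (0, 1).
#' @return list with `rel` (filtered `relative_abundance`, possibly with
#'   zero rows) and `kept` (character vector of retained taxon ids).
#' @export
detection_filter <- function(rel, threshold = 0.01) {
  stopifnot(inherits(rel, "relative_abundance"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0,1)")
  keep <- apply(rel$rel, 1, max) >= threshold
  out <- rel
  out$rel <- rel$rel[keep, , drop = FALSE]
  list(rel = out, kept = rownames(rel$rel)[keep])
}

#' Per-sample alpha diversity
#'
#' @param rel a `relative_abundance` object.
#' @param index one of "shannon" (-sum p log p, natural log), "simpson"
#'   (1 - sum p^2) or "richness" (number of taxa with p > 0).
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(rel, index = c("shannon", "simpson", "richness")) {
  stopifnot(inherits(rel, "relative_abundance"))
  index <- match.arg(index)
  apply(rel$rel, 2, function(p) {
    switch(index,
      shannon  = { q <- p[p > 0]; -sum(q * log(q)) },
      simpson  = 1 - sum(p^2),
      richness = sum(p > 0))
  })
}

#' Rarefaction of detectable taxa
#'
#' Subsamples each sample's reads without replacement to the requested
#' depths and counts taxa whose subsampled relative abundance reaches
#' `threshold`, averaged over `reps` replicates. Used to judge whether the
#' sequencing depth suffices to detect taxa above a given activity level.
#'
#' @param table an [abundance_table].
#' @param depths integer vector of subsampling depths.
#' @param threshold detection threshold on the subsampled relative
#'   abundance; 0 counts any taxon with at least one subsampled read.
#' @param reps number of random subsamples per (sample, depth).
#' @param seed integer seed; the curve is deterministic given the seed.
#' @return A data.frame with columns sample, depth, mean_detected.
#'   Depths exceeding a sample's total are skipped with a warning.
#' @export
rarefaction <- function(table, depths, threshold = 0, reps = 10, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  counts <- table$counts
  set.seed(seed)
  rows <- list()
  for (s in colnames(counts)) {
    x <- counts[, s]
    total <- sum(x)
    for (d in depths) {
      if (d > total) {
        warning(sprintf("depth %d exceeds total %d in sample %s; skipped",
                        d, total, s))
        next
      }
      det <- numeric(reps)
      pool <- rep.int(seq_along(x), x)
      for (r in seq_len(reps)) {
        sub <- tabulate(sample(pool, d), nbins = length(x))  # without replacement
        det[r] <- if (threshold == 0) sum(sub > 0)
                  else sum(sub / d >= threshold)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(sample = s, depth = d, mean_detected = mean(det))
    }
  }
  do.call(rbind, rows)
}

#' Concordance between two abundance tables of the same samples
#'
#' Compares taxon profiles measured by two assays (e.g. metatranscriptome
#' vs 16S rRNA amplicon) with Spearman correlation: pooled over all
#' (shared-sample, union-taxon) pairs with absent taxa as 0, and per sample
#' on the taxon union. A zero-to-1e-6 substitution is a log-display
#' convention only and is never applied before correlating.
#'
#' @param relA,relB `relative_abundance` objects sharing >=1 sample and
#'   >=3 taxa.
#' @return list with `pooled` (rho, p, n), `per_sample` (data.frame),
#'   `shared_taxa`, `onlyA`, `onlyB`.
#' @export
compare_tables <- function(relA, relB) {
  stopifnot(inherits(relA, "relative_abundance"),
            inherits(relB, "relative_abundance"))
  samples <- intersect(colnames(relA$rel), colnames(relB$rel))
  if (length(samples) < 1) stop("no shared samples")
  shared <- intersect(rownames(relA$rel), rownames(relB$rel))
  if (length(shared) < 3) stop("fewer than 3 shared taxa")
  union_taxa <- union(rownames(relA$rel), rownames(relB$rel))
  expand <- function(rel) {
    m <- matrix(0, length(union_taxa), length(samples),
                dimnames = list(union_taxa, samples))
    common <- intersect(rownames(rel$rel), union_taxa)
    m[common, ] <- rel$rel[common, samples, drop = FALSE]
    m
  }
  a <- expand(relA); b <- expand(relB)
  pooled <- spearman_cor(as.vector(a), as.vector(b))
  per <- do.call(rbind, lapply(samples, function(s) {
    r <- spearman_cor(a[, s], b[, s])
    data.frame(sample = s, rho = r$rho, p = r$p, n = r$n)
  }))
  list(pooled = list(rho = pooled$rho, p = pooled$p, n = pooled$n),
       per_sample = per, shared_taxa = shared,
       onlyA = setdiff(rownames(relA$rel), shared),
       onlyB = setdiff(rownames(relB$rel), shared))
}

#' Read a counts TSV (taxa rows, first column taxon id, header sample ids)
#' @param path file path.
#' @param rank rank label to attach.
#' @return An [abundance_table].
#' @export
read_counts_tsv <- function(path, rank = "genus") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  abundance_table(m, rank = rank)
}

#' Write a counts TSV
#' @param table an [abundance_table].
#' @param path output file path.
#' @export
write_counts_tsv <- function(table, path) {
  df <- data.frame(taxon = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
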