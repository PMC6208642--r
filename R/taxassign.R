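## MEGAN-style lowest-common-ancestor read assignment from tabular
## alignment hits, with per-rank count tables.

RANK_ORDER <- c("root", "superkingdom", "kingdom", "phylum", "class",
                "order", "family", "genus", "species")

#' Build a taxonomy tree
#'
#' @param nodes data.frame with columns id, parent, rank. Exactly one root
#'   must have parent == id. Ranks are drawn from the fixed ordered set
#'   root > superkingdom > kingdom > phylum > class > order > family >
#'   genus > species (plus "no rank").
#' @param names optional data.frame with columns id, name.
#' @return A `taxonomy_tree` with parent/rank/name lookups.
#' @export
taxonomy_tree <- function(nodes, names = NULL) {
  id <- as.character(nodes$id)
  parent <- as.character(nodes$parent)
  rank <- as.character(nodes$rank)
  if (anyDuplicated(id)) stop("duplicate node ids")
  root <- id[id == parent]
  if (length(root) != 1) stop("tree must have exactly one root")
  bad <- setdiff(unique(rank), c(RANK_ORDER, "no rank"))
  if (length(bad)) stop("unknown rank label: ", paste(bad, collapse = ", "))
  parent_of <- stats::setNames(parent, id)
  ## verify every node reaches the root (also detects cycles)
  for (x in id) {
    seen <- character(0); cur <- x
    while (cur != root) {
      if (cur %in% seen) stop("cycle detected at node ", x)
      seen <- c(seen, cur)
      if (!cur %in% id) stop("node ", x, " does not reach root")
      cur <- unname(parent_of[cur])
      if (length(seen) > length(id)) stop("node ", x, " does not reach root")
    }
  }
  name_of <- if (!is.null(names))
    stats::setNames(as.character(names$name), as.character(names$id))
  else stats::setNames(id, id)
  structure(list(parent = parent_of, rank = stats::setNames(rank, id),
                 name = name_of, root = root),
            class = "taxonomy_tree")
}

## Path from a node up to (and including) the root, node first.
path_to_root <- function(tree, id) {
  path <- id
  while (id != tree$root) {
    id <- tree$parent[[id]]
    path <- c(path, id)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node ancestral to (or equal to) every input taxon;
#' lca of a single taxon is itself. Commutative and associative in its
#' input set.
#'
#' @param tree a [taxonomy_tree].
#' @param taxon_ids character vector of node ids.
#' @return A single node id.
#' @export
lca <- function(tree, taxon_ids) {
  taxon_ids <- unique(as.character(taxon_ids))
  unknown <- setdiff(taxon_ids, names(tree$parent))
  if (length(unknown)) stop("unknown taxon id: ", paste(unknown, collapse = ", "))
  if (length(taxon_ids) == 1) return(taxon_ids)
  common <- rev(path_to_root(tree, taxon_ids[1]))  # root first
  for (t in taxon_ids[-1]) {
    p <- rev(path_to_root(tree, t))
    m <- min(length(common), length(p))
    eq <- common[seq_len(m)] == p[seq_len(m)]
    common <- common[seq_len(if (all(eq)) m else which(!eq)[1] - 1)]
  }
  common[length(common)]
}

#' Read BLAST tabular hits (outfmt 6)
#'
#' Default column order: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore, plus an optional qcovhsp
#' column. `columns` can remap nonstandard layouts. The subject id is used
#' as the taxon id.
#'
#' @param path TSV file of alignment hits (no header).
#' @param columns character vector naming the columns in file order.
#' @return data.frame with read_id, taxon_id, bitscore, evalue, qcov.
#' @export
read_blast_hits <- function(path,
                            columns = c("qseqid", "sseqid", "pident", "length",
                                        "mismatch", "gapopen", "qstart", "qend",
                                        "sstart", "send", "evalue", "bitscore",
                                        "qcovhsp")) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  columns <- columns[seq_len(min(length(columns), ncol(df)))]
  colnames(df)[seq_along(columns)] <- columns
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$bitscore) | !is.finite(df$evalue) |
                 df$bitscore < 0 | df$evalue < 0)
  if (length(bad)) stop("malformed row at line ", bad[1])
  data.frame(read_id = as.character(df$qseqid),
             taxon_id = as.character(df$sseqid),
             bitscore = df$bitscore, evalue = df$evalue,
             qcov = if ("qcovhsp" %in% colnames(df)) df$qcovhsp else NA_real_,
             stringsAsFactors = FALSE)
}

#' Filter alignment hits by score thresholds and top-percent band
#'
#' Drops hits with bitscore < `min_score`, e-value > `max_evalue`, or query
#' coverage < `min_qcov` (coverage checked only when present), then keeps,
#' per read, hits whose bitscore is within `top_percent`% of the read's
#' best retained bitscore (inclusive band, so ties at the best score are
#' all kept).
#'
#' @param hits data.frame as from [read_blast_hits].
#' @param min_score minimum bitscore (MEGAN "Min Score", default 100).
#' @param max_evalue maximum e-value (default 1e-10).
#' @param min_qcov minimum query coverage percent (default 60).
#' @param top_percent retention band below the best bitscore (default 10).
#' @return Filtered data.frame of retained hits.
#' @export
filter_hits <- function(hits, min_score = 100, max_evalue = 1e-10,
                        min_qcov = 60, top_percent = 10) {
  keep <- hits$bitscore >= min_score & hits$evalue <= max_evalue
  if (!all(is.na(hits$qcov))) keep <- keep & (is.na(hits$qcov) | hits$qcov >= min_qcov)
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  best <- tapply(hits$bitscore, hits$read_id, max)
  hits[hits$bitscore >= (1 - top_percent / 100) * best[hits$read_id], ,
       drop = FALSE]
}

## Ancestor of `id` at exactly `rank`, or NA if the path skips/ends above it.
ancestor_at_rank <- function(tree, id, rank) {
  for (node in path_to_root(tree, id)) {
    if (tree$rank[[node]] == rank) return(node)
  }
  NA_character_
}

#' Assign reads to taxa by LCA and summarise per rank
#'
#' Each read is assigned to the lowest common ancestor of its retained
#' hits' taxa (duplicate taxa from multiple HSPs are collapsed first —
#' alignment multiplicity is not evidence). Per-rank count tables aggregate
#' reads whose assignment lies at or below that rank; a read assigned above
#' a rank is "unassigned" at it, and reads with no retained hits are
#' "unaligned".
#'
#' @param tree a [taxonomy_tree].
#' @param hits data.frame of alignment hits (pre- or unfiltered).
#' @param min_score,max_evalue,min_qcov,top_percent passed to [filter_hits].
#' @param ranks ranks at which to tabulate (default genus and species).
#' @return list(assignments = data.frame(read_id, taxon_id),
#'   tables = per-rank [abundance_table] (single "all_reads" sample),
#'   summary = data.frame(rank, assigned, unassigned, unaligned,
#'   assigned_fraction)).
#' @export
assign_reads <- function(tree, hits, min_score = 100, max_evalue = 1e-10,
                         min_qcov = 60, top_percent = 10,
                         ranks = c("genus", "species")) {
  all_reads <- unique(hits$read_id)
  kept <- filter_hits(hits, min_score, max_evalue, min_qcov, top_percent)
  by_read <- split(kept$taxon_id, kept$read_id)
  assigned <- vapply(by_read, function(tx) lca(tree, tx), "")
  unaligned <- setdiff(all_reads, names(assigned))
  assignments <- data.frame(read_id = names(assigned),
                            taxon_id = unname(assigned),
                            stringsAsFactors = FALSE)
  n_reads <- length(all_reads)
  tables <- list(); summary <- list()
  for (rk in ranks) {
    at_rank <- vapply(assignments$taxon_id, function(id)
      ancestor_at_rank(tree, id, rk), "")
    ok <- !is.na(at_rank)
    counts <- table(at_rank[ok])
    m <- matrix(as.integer(counts), ncol = 1,
                dimnames = list(names(counts), "all_reads"))
    tables[[rk]] <- if (nrow(m) > 0) abundance_table(m, rank = rk) else NULL
    summary[[rk]] <- data.frame(
      rank = rk, assigned = sum(ok),
      unassigned = nrow(assignments) - sum(ok),
      unaligned = length(unaligned),
      assigned_fraction = sum(ok) / n_reads)
  }
  list(assignments = assignments, unaligned = unaligned, tables = tables,
       summary = do.call(rbind, summary))
}
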