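# Leaf placement: nearest-leaf-by-identity assignment of recruited PR
# reads on the reference alignment, and aggregation to taxonomic clusters.

leaf_residue_matrix <- function(aln) {
  mat <- aln_as_matrix(aln)
  mc <- match_columns(mat)
  m <- mat[, mc, drop = FALSE]
  rownames(m) <- names(aln$rows)
  m
}

#' Assign recruited reads to reference-tree leaves
#'
#' For each read, identity against every leaf is the fraction of matching
#' residues over the profile match columns inside the read's aligned span,
#' skipping columns where both read and leaf are gapped (a gap against a
#' residue counts as a mismatch). The best leaf wins only if the number of
#' compared columns reaches `min_cols` and the identity margin to the
#' second-best leaf reaches `min_margin`; otherwise the read is UNPLACED —
#' the analogue of discarding reads placed on internal nodes rather than
#' leaves.
#'
#' @param recruited data.frame of recruited reads for one marker (from
#'   [recruit_sample()]), with `read_id`, `col_first`, `col_last`,
#'   `aligned`.
#' @param aln The marker's `reference_alignment` (leaf ids = row ids).
#' @param min_cols Minimum compared columns (default 20).
#' @param min_margin Minimum identity margin best vs second best
#'   (default 0.01).
#' @return data.frame `read_id`, `leaf_id` (`NA` when unplaced), `identity`,
#'   `margin`, `compared`, `placed`.
#' @export
assign_leaves <- function(recruited, aln, min_cols = 20, min_margin = 0.01) {
  stopifnot(inherits(aln, "reference_alignment"))
  lm <- leaf_residue_matrix(aln)
  n_leaf <- nrow(lm)
  n <- nrow(recruited)
  leaf_id <- rep(NA_character_, n)
  identity <- margin <- rep(NA_real_, n)
  compared <- integer(n)
  for (i in seq_len(n)) {
    cf <- recruited$col_first[i]
    cl <- recruited$col_last[i]
    if (is.na(cf) || cl > ncol(lm) || cf < 1) next
    rchars <- strsplit(recruited$aligned[i], "", fixed = TRUE)[[1]]
    span <- lm[, cf:cl, drop = FALSE]
    read_gap <- rchars == .GAP
    leaf_gap <- span == .GAP
    both_gap <- sweep(leaf_gap, 2, read_gap, `&`)
    eq <- sweep(span, 2, rchars, `==`) & !leaf_gap &
      matrix(!read_gap, n_leaf, length(rchars), byrow = TRUE)
    cmp <- rowSums(!both_gap)
    idv <- ifelse(cmp > 0, rowSums(eq) / cmp, 0)
    best <- which.max(idv)
    second <- if (n_leaf >= 2) max(idv[-best]) else 0
    compared[i] <- cmp[best]
    identity[i] <- idv[best]
    margin[i] <- idv[best] - second
    if (cmp[best] >= min_cols && margin[i] >= min_margin)
      leaf_id[i] <- rownames(lm)[best]
  }
  data.frame(read_id = recruited$read_id, leaf_id = leaf_id,
             identity = identity, margin = margin, compared = compared,
             placed = !is.na(leaf_id), stringsAsFactors = FALSE)
}

#' Assign a single recruited read to a leaf
#'
#' Convenience wrapper around [assign_leaves()] for one read.
#'
#' @inheritParams assign_leaves
#' @param read One-row data.frame (a recruited read).
#' @return One-row assignment data.frame; `leaf_id` is `NA` when the read
#'   is UNPLACED.
#' @export
assign_leaf <- function(read, aln, min_cols = 20, min_margin = 0.01) {
  assign_leaves(read[1, , drop = FALSE], aln, min_cols, min_margin)
}

#' Aggregate leaf assignments to clusters
#'
#' Counts placed reads per cluster label; UNPLACED reads are excluded and
#' fractions are computed out of all placed reads. Leaves absent from the
#' cluster map are counted as `"other"` with a warning.
#'
#' @param assignments data.frame from [assign_leaves()].
#' @param tree A `clade_tree` carrying the leaf-to-cluster map.
#' @return data.frame `cluster`, `count`, `fraction`, with attribute
#'   `all_unplaced` set to `TRUE` (and zero rows) when nothing placed.
#' @export
aggregate_clusters <- function(assignments, tree) {
  stopifnot(inherits(tree, "clade_tree"))
  placed <- assignments[assignments$placed, , drop = FALSE]
  if (!nrow(placed)) {
    out <- data.frame(cluster = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE)
    attr(out, "all_unplaced") <- TRUE
    return(out)
  }
  cl <- tree$cluster_map[placed$leaf_id]
  if (anyNA(cl)) {
    warning(sum(is.na(cl)), " read(s) on leaves absent from the cluster map",
            " counted as 'other'")
    cl[is.na(cl)] <- "other"
  }
  tab <- table(cl)
  out <- data.frame(cluster = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  attr(out, "all_unplaced") <- FALSE
  out
}
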