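# Reference data: curated marker alignments, position-specific scoring
# profiles, the PR frequency-tuning site, and the PR clade tree.

.GAP <- "-"

# Alignment columns retained as profile match columns: gap fraction < 0.5
# and at least one residue observed.
match_columns <- function(aln_matrix) {
  gap_frac <- colMeans(aln_matrix == .GAP)
  which(gap_frac < 0.5 & colSums(aln_matrix != .GAP) > 0)
}

aln_as_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
}

new_reference_alignment <- function(rows, marker) {
  structure(list(marker = marker, rows = rows,
                 n_columns = if (length(rows)) nchar(rows[[1]]) else 0L),
            class = "reference_alignment")
}

validate_reference_alignment <- function(aln) {
  rows <- aln$rows
  if (length(rows) < 2L) stop("reference alignment needs at least 2 rows")
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("reference alignment row ids must be unique and non-empty")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    modal <- as.integer(names(sort(table(widths), decreasing = TRUE))[1])
    bad <- names(rows)[widths != modal]
    stop("ragged alignment: row(s) ", paste(bad, collapse = ", "),
         " differ in length from the majority (", modal, " columns)")
  }
  ok <- c(aa_alphabet(), .GAP)
  chars <- unique(unlist(strsplit(rows, "", fixed = TRUE)))
  extra <- setdiff(chars, ok)
  if (length(extra))
    stop("alignment contains non amino-acid characters: ",
         paste(extra, collapse = ", "))
  aln
}

#' Residue background distributions
#'
#' `"uniform"` is 1/20 per residue. `"codon"` is the residue composition of
#' translating uniform random nucleotides — synonymous-codon multiplicities
#' over the 61 sense codons — which is the correct null for score
#' calibration when candidate peptides come from six-frame translation of
#' non-coding sequence.
#'
#' @param type `"uniform"` or `"codon"`.
#' @return Named numeric vector over `aa_alphabet()`, summing to 1.
#' @export
aa_background <- function(type = c("uniform", "codon")) {
  type <- match.arg(type)
  aa <- aa_alphabet()
  if (type == "uniform") return(setNames(rep(1 / 20, 20), aa))
  gc <- Biostrings::GENETIC_CODE
  cnt <- table(factor(gc[gc != "*"], levels = aa))
  setNames(as.numeric(cnt) / sum(cnt), aa)
}

#' Load a curated reference alignment from aligned FASTA
#'
#' Reads one marker's aligned amino-acid reference set (gap character `-`).
#' Rows whose ungapped length falls below `min_ungapped` are dropped with a
#' warning; the default of 200 residues mirrors the curation rule that
#' reference ORFs must be long enough not to distort the alignment.
#'
#' @param path Path to an aligned FASTA file.
#' @param marker One of `marker_genes()`.
#' @param min_ungapped Minimum ungapped row length retained (residues).
#' @return A `reference_alignment` object with fields `marker`, `rows`
#'   (named aligned sequences) and `n_columns`.
#' @export
load_reference_alignment <- function(path, marker = marker_genes(),
                                     min_ungapped = 200) {
  marker <- match.arg(marker)
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  rows <- toupper(as.character(seqs))
  names(rows) <- sub("\\s.*$", "", names(rows))
  ungapped <- nchar(gsub(.GAP, "", rows, fixed = TRUE))
  short <- ungapped < min_ungapped
  if (any(short)) {
    warning("dropping ", sum(short), " row(s) with ungapped length < ",
            min_ungapped, ": ", paste(names(rows)[short], collapse = ", "))
    rows <- rows[!short]
  }
  validate_reference_alignment(new_reference_alignment(rows, marker))
}

#' @export
print.reference_alignment <- function(x, ...) {
  cat("Reference alignment [", x$marker, "]: ", length(x$rows), " rows x ",
      x$n_columns, " columns\n", sep = "")
  invisible(x)
}

#' Build a position-specific scoring profile from a reference alignment
#'
#' Match columns are alignment columns with gap fraction below 0.5; the
#' number of match columns is the profile length used as `funcLen` (or
#' `RecALen`) in abundance normalization. Scores are per-column log-odds in
#' bits against a background residue distribution, with Laplace-style
#' pseudocounts:
#' `score = log2(((count + pc * bg_r) / (n + pc)) / bg_r)`.
#'
#' @param aln A `reference_alignment`.
#' @param pseudocount Positive pseudocount mass (default 1).
#' @param background Residue background distribution over `aa_alphabet()`
#'   (default uniform 1/20); must sum to 1.
#' @param gap_open,gap_extend Affine gap penalties in bits; a gap of length
#'   g costs `gap_open + (g - 1) * gap_extend`.
#' @return A `marker_profile` with the score matrix (`L_func` x 20), the
#'   match-column indices into the source alignment, the background, the
#'   gap penalties, and the ungapped reference peptides used by the k-mer
#'   screen. `fts_column` and `score_cutoff` start unset.
#' @export
build_profile <- function(aln, pseudocount = 1,
                          background = rep(1 / 20, 20),
                          gap_open = 4, gap_extend = 1) {
  stopifnot(inherits(aln, "reference_alignment"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a positive number")
  if (length(background) != 20 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be 20 positive frequencies summing to 1")
  aa <- aa_alphabet()
  names(background) <- aa
  mat <- aln_as_matrix(aln)
  mc <- match_columns(mat)
  if (length(mc) == 0L) stop("no match columns: alignment is gap-dominated")
  scores <- matrix(NA_real_, nrow = length(mc), ncol = 20,
                   dimnames = list(NULL, aa))
  for (i in seq_along(mc)) {
    col <- mat[, mc[i]]
    col <- col[col != .GAP]
    cnt <- tabulate(match(col, aa), nbins = 20)
    n <- length(col)
    scores[i, ] <- log2(((cnt + pseudocount * background) /
                           (n + pseudocount)) / background)
  }
  structure(list(marker = aln$marker, L_func = length(mc),
                 match_scores = scores, background = background,
                 gap_open = gap_open, gap_extend = gap_extend,
                 score_cutoff = NA_real_, fts_column = NA_integer_,
                 match_cols = mc,
                 ref_peptides = gsub(.GAP, "", aln$rows, fixed = TRUE)),
            class = "marker_profile")
}

#' @export
print.marker_profile <- function(x, ...) {
  cat("Marker profile [", x$marker, "]: ", x$L_func, " match columns",
      if (!is.na(x$score_cutoff)) paste0("; cutoff ",
                                         signif(x$score_cutoff, 4), " bits"),
      if (!is.na(x$fts_column)) paste0("; FTS at match column ", x$fts_column),
      "\n", sep = "")
  invisible(x)
}

#' Locate the frequency-tuning site on the profile
#'
#' The spectral tuning site (FTS) of proteorhodopsin is supplied as an
#' anchor: a reference row id and a 1-based position on that row's
#' *ungapped* sequence. The function maps the anchor residue to its
#' alignment column and returns that column's rank among the profile match
#' columns.
#'
#' @param aln A `reference_alignment` (typically the PR reference).
#' @param anchor_seq_id Row id of the anchor sequence.
#' @param anchor_residue_index 1-based position on the ungapped anchor row.
#' @param profile Optional `marker_profile` built from `aln`; if omitted the
#'   match-column rule is re-applied to `aln`.
#' @return Integer match-column index in `[1, L_func]`.
#' @export
locate_fts <- function(aln, anchor_seq_id, anchor_residue_index,
                       profile = NULL) {
  stopifnot(inherits(aln, "reference_alignment"))
  if (!anchor_seq_id %in% names(aln$rows))
    stop("anchor sequence '", anchor_seq_id, "' not in alignment")
  chars <- strsplit(aln$rows[[anchor_seq_id]], "", fixed = TRUE)[[1]]
  residue_cols <- which(chars != .GAP)
  if (anchor_residue_index < 1 || anchor_residue_index > length(residue_cols))
    stop("anchor position ", anchor_residue_index,
         " beyond ungapped length ", length(residue_cols))
  col <- residue_cols[anchor_residue_index]
  mc <- if (is.null(profile)) match_columns(aln_as_matrix(aln))
        else profile$match_cols
  rank <- match(col, mc)
  if (is.na(rank))
    stop("anchor falls on alignment column ", col,
         ", which is not a profile match column; re-curate the anchor")
  rank
}

#' Load the PR clade tree and its leaf-to-cluster map
#'
#' @param tree_path Rooted newick file; leaf names must be unique.
#' @param map_path Two-column TSV with header `leaf_id<TAB>cluster`.
#' @return A `clade_tree`: the `ape::phylo` tree plus a named character
#'   vector `cluster_map` over all leaves. Leaves missing from the map are
#'   assigned cluster `"other"` with a warning; map rows that reference
#'   absent leaves produce a warning.
#' @export
load_clade_tree <- function(tree_path, map_path) {
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stop("could not parse newick: ", tree_path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  map <- read.delim(map_path, header = TRUE, sep = "\t",
                    colClasses = "character")
  if (!all(c("leaf_id", "cluster") %in% names(map)))
    stop("cluster map must have columns leaf_id and cluster")
  clade_tree(tree, setNames(map$cluster, map$leaf_id))
}

#' Construct a clade tree from in-memory objects
#'
#' @param tree An `ape::phylo` tree.
#' @param cluster_map Named character vector, leaf id to cluster label.
#' @return A `clade_tree` object.
#' @export
clade_tree <- function(tree, cluster_map) {
  leaves <- tree$tip.label
  absent <- setdiff(names(cluster_map), leaves)
  if (length(absent))
    warning("cluster map references absent leaves: ",
            paste(absent, collapse = ", "))
  unmapped <- setdiff(leaves, names(cluster_map))
  if (length(unmapped)) {
    warning("leaves without cluster label assigned to 'other': ",
            paste(unmapped, collapse = ", "))
    cluster_map[unmapped] <- "other"
  }
  structure(list(tree = tree, cluster_map = cluster_map[leaves]),
            class = "clade_tree")
}

#' @export
print.clade_tree <- function(x, ...) {
  cat("Clade tree: ", length(x$tree$tip.label), " leaves, ",
      length(unique(x$cluster_map)), " clusters\n", sep = "")
  invisible(x)
}

#' Serialize a marker profile to TSV
#'
#' Writes one row per match column with the 20 residue scores, preceded by
#' `#`-prefixed header lines recording marker, `L_func`, FTS column, gap
#' penalties, score cutoff and background. Reference peptides are not
#' serialized; [read_profile()] therefore returns a profile suitable for
#' scoring but not for the k-mer screen unless peptides are reattached.
#'
#' @param profile A `marker_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(paste0("# marker=", profile$marker),
           paste0("# L_func=", profile$L_func),
           paste0("# fts_column=", profile$fts_column),
           paste0("# gap_open=", profile$gap_open),
           paste0("# gap_extend=", profile$gap_extend),
           paste0("# score_cutoff=", profile$score_cutoff),
           paste0("# background=",
                  paste(format(profile$background, digits = 17),
                        collapse = ",")))
  writeLines(hdr, con)
  df <- data.frame(match_col = seq_len(profile$L_func),
                   profile$match_scores, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker profile written by [write_profile()]
#'
#' @param path Path to a profile TSV.
#' @return A `marker_profile` (without reference peptides).
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(p) paste(p[-1], collapse = "="), ""),
                   vapply(kv, `[[`, "", 1))
  tab <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                    check.names = FALSE)
  scores <- as.matrix(tab[, aa_alphabet(), drop = FALSE])
  dimnames(scores) <- list(NULL, aa_alphabet())
  structure(list(marker = vals[["marker"]],
                 L_func = as.integer(vals[["L_func"]]),
                 match_scores = scores,
                 background = setNames(
                   as.numeric(strsplit(vals[["background"]], ",")[[1]]),
                   aa_alphabet()),
                 gap_open = as.numeric(vals[["gap_open"]]),
                 gap_extend = as.numeric(vals[["gap_extend"]]),
                 score_cutoff = suppressWarnings(
                   as.numeric(vals[["score_cutoff"]])),
                 fts_column = suppressWarnings(
                   as.integer(vals[["fts_column"]])),
                 match_cols = seq_len(as.integer(vals[["L_func"]])),
                 ref_peptides = NULL),
            class = "marker_profile")
}
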