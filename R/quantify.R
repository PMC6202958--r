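# Headline quantities: recA-normalized abundance, RNA:DNA expression
# ratios, Shannon cluster evenness, and spectral-tuning classification.

#' recA-normalized marker gene abundance
#'
#' Computes `(func_count / func_len) / (recA_count / recA_len)`: the
#' length-corrected marker read count relative to the length-corrected
#' count of the single-copy housekeeping gene recA, interpretable as the
#' fraction of genomes carrying the marker. Lengths are the profile
#' match-column counts (`funcLen`, `RecALen`). Values above 1 are
#' legitimate (multi-copy genes or co-occurring variants) and are not
#' clipped.
#'
#' @param func_count,recA_count Recruited read counts (vectorized).
#' @param func_len,recA_len Profile lengths in match columns (> 0).
#' @param percent If TRUE, report as a percentage (x 100).
#' @return Numeric; `NA` with a warning where `recA_count` is 0 (undefined,
#'   not an error).
#' @export
normalized_abundance <- function(func_count, func_len, recA_count, recA_len,
                                 percent = FALSE) {
  if (any(func_len <= 0) || any(recA_len <= 0))
    stop("profile lengths must be positive")
  out <- (func_count / func_len) / (recA_count / recA_len)
  undef <- recA_count == 0
  if (any(undef)) {
    warning("recA count is 0: normalized abundance undefined")
    out[undef] <- NA_real_
  }
  if (percent) out * 100 else out
}

#' RNA:DNA expression ratio of a marker
#'
#' The marker's relative abundance in the RNA library divided by its
#' relative abundance in the DNA library; a depth-independent proxy for
#' per-gene-copy expression.
#'
#' @param rna_count,dna_count Recruited counts in each library.
#' @param rna_total,dna_total Library read totals (> 0).
#' @return An `expression_ratio` list: `rna_rel`, `dna_rel`, `ratio`, and
#'   `undefined` (TRUE when `dna_count` is 0, in which case `ratio` is
#'   `NA`).
#' @export
rna_dna_ratio <- function(rna_count, rna_total, dna_count, dna_total) {
  if (rna_total <= 0 || dna_total <= 0) stop("library totals must be positive")
  rna_rel <- rna_count / rna_total
  dna_rel <- dna_count / dna_total
  undefined <- dna_count == 0
  structure(list(rna_rel = rna_rel, dna_rel = dna_rel,
                 ratio = if (undefined) NA_real_ else rna_rel / dna_rel,
                 undefined = undefined),
            class = "expression_ratio")
}

#' Shannon evenness of a cluster composition
#'
#' Shannon entropy `H` (natural log) over the positive cluster counts and
#' Pielou's evenness `J = H / ln(S)` with `S` the number of occupied
#' clusters. `J` is undefined for `S <= 1`.
#'
#' @param counts Non-negative counts per cluster.
#' @return An `evenness_result` list: `H` (nats), `S`, `J` (`NA` when
#'   undefined).
#' @export
shannon_evenness <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- counts[counts > 0]
  S <- length(pos)
  if (S == 0)
    return(structure(list(H = NA_real_, S = 0L, J = NA_real_),
                     class = "evenness_result"))
  H <- as.numeric(vegan::diversity(pos, index = "shannon"))
  J <- if (S >= 2) H / log(S) else NA_real_
  structure(list(H = H, S = as.integer(S), J = J), class = "evenness_result")
}

#' Classify recruited PR reads at the frequency-tuning site
#'
#' Only reads whose aligned span covers the FTS match column with a residue
#' (not a gap) are counted. Glutamine (Q) is blue-absorbing; leucine (L)
#' and methionine (M) are green-absorbing; any other residue is tallied as
#' "other" and excluded from the blue fraction, such residues being too
#' rare to interpret.
#'
#' @param reads data.frame of recruited PR reads (from [recruit_sample()]).
#' @param fts_column FTS match-column index on the PR profile.
#' @return A `tuning_counts` list: `n_blue`, `n_green`, `n_other`,
#'   `n_covering`, and `blue_fraction = n_blue / (n_blue + n_green)`
#'   (`NA` when no blue or green residues observed).
#' @export
classify_fts <- function(reads, fts_column) {
  if (is.na(fts_column) || fts_column < 1)
    stop("fts_column must be a defined match-column index")
  res <- character(0)
  if (nrow(reads)) {
    cover <- !is.na(reads$col_first) & reads$col_first <= fts_column &
      reads$col_last >= fts_column
    res <- substr(reads$aligned[cover],
                  fts_column - reads$col_first[cover] + 1,
                  fts_column - reads$col_first[cover] + 1)
    res <- res[res != .GAP & res != ""]
  }
  n_blue <- sum(res == "Q")
  n_green <- sum(res %in% c("L", "M"))
  n_other <- length(res) - n_blue - n_green
  structure(list(n_blue = n_blue, n_green = n_green, n_other = n_other,
                 n_covering = length(res),
                 blue_fraction = if (n_blue + n_green > 0)
                   n_blue / (n_blue + n_green) else NA_real_),
            class = "tuning_counts")
}

#' @export
print.tuning_counts <- function(x, ...) {
  cat("Tuning counts: blue", x$n_blue, "green", x$n_green, "other",
      x$n_other, "| blue fraction",
      if (is.na(x$blue_fraction)) "undefined" else
        signif(x$blue_fraction, 4), "\n")
  invisible(x)
}

#' @export
print.evenness_result <- function(x, ...) {
  cat("Shannon evenness: H =", signif(x$H, 4), "nats, S =", x$S, ", J =",
      if (is.na(x$J)) "undefined" else signif(x$J, 4), "\n")
  invisible(x)
}

#' @export
print.expression_ratio <- function(x, ...) {
  cat("RNA:DNA ratio:",
      if (x$undefined) "undefined (no DNA reads)" else signif(x$ratio, 4),
      "\n")
  invisible(x)
}
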