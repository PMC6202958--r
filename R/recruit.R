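# Read recruitment: six-frame translation, exact k-mer candidate screen,
# profile alignment with affine gaps, decoy-calibrated score cutoffs, and
# per-sample recruitment with best-marker assignment.

#' Six-frame translation of short reads
#'
#' Translates each read in all six frames under the standard genetic code,
#' splits each frame at stop codons, and returns the stop-free peptide
#' fragments of at least `min_len` residues. Codons containing `N`
#' translate to `X`. Reads shorter than `3 * min_len` simply produce no
#' fragments.
#'
#' @param reads Character vector or `Biostrings::DNAStringSet` (alphabet
#'   `ACGTN`); names are used as read ids (defaults `read1`, `read2`, ...).
#' @param min_len Minimum fragment length in residues (default 15).
#' @return data.frame with `read_id`, `frame` (+1..+3 forward, -1..-3 on
#'   the reverse complement), `peptide` and `offset`, the 0-based start of
#'   the fragment on the original read (leftmost base for either strand).
#' @export
six_frame_translate <- function(reads, min_len = 15) {
  if (inherits(reads, "DNAStringSet")) {
    x <- reads
  } else {
    reads <- toupper(as.character(reads))
    bad <- grepl("[^ACGTN]", reads)
    if (any(bad))
      stop("non-nucleotide characters in read(s): ",
           paste(head(which(bad), 5), collapse = ", "))
    x <- Biostrings::DNAStringSet(reads)
  }
  if (is.null(names(x))) names(x) <- paste0("read", seq_along(x))
  widths <- Biostrings::width(x)
  out <- vector("list", 6)
  oi <- 0
  for (strand in c(1L, -1L)) {
    y <- if (strand == 1L) x else Biostrings::reverseComplement(x)
    for (f in 1:3) {
      oi <- oi + 1
      ncod <- pmax((widths - f + 1L) %/% 3L, 0L)
      keep <- which(ncod >= 1L)
      if (!length(keep)) next
      sub <- Biostrings::subseq(y[keep], start = f,
                                width = 3L * ncod[keep])
      pep <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X")))
      segs <- gregexpr("[^*]+", pep)
      n_seg <- vapply(segs, function(s) if (s[1] == -1L) 0L else length(s),
                      0L)
      if (sum(n_seg) == 0L) next
      rid <- rep(names(y)[keep], n_seg)
      wid <- rep(widths[keep], n_seg)
      s_aa <- unlist(lapply(segs, function(s) if (s[1] == -1L) integer() else
        as.integer(s)))
      l_aa <- unlist(lapply(segs, function(s) if (s[1] == -1L) integer() else
        attr(s, "match.length")))
      frag <- substring(rep(pep, n_seg), s_aa, s_aa + l_aa - 1L)
      off_strand <- (f - 1L) + 3L * (s_aa - 1L)     # 0-based, reading strand
      off <- if (strand == 1L) off_strand else
        wid - (off_strand + 3L * l_aa)               # leftmost base, original
      keep2 <- l_aa >= min_len
      out[[oi]] <- list(read_id = rid[keep2], frame = rep(strand * f,
                                                          sum(keep2)),
                        peptide = frag[keep2], offset = off[keep2])
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(read_id = character(), frame = integer(),
                      peptide = character(), offset = integer(),
                      stringsAsFactors = FALSE))
  res <- data.frame(
    read_id = unlist(lapply(out, `[[`, "read_id"), use.names = FALSE),
    frame = unlist(lapply(out, `[[`, "frame"), use.names = FALSE),
    peptide = unlist(lapply(out, `[[`, "peptide"), use.names = FALSE),
    offset = unlist(lapply(out, `[[`, "offset"), use.names = FALSE),
    stringsAsFactors = FALSE)
  res
}

#' Screen translated fragments by exact k-mer sharing
#'
#' A fragment survives iff it shares at least one exact k-mer with any
#' ungapped reference peptide of the marker; the fast stand-in for a
#' translated similarity pre-search before profile alignment.
#'
#' @param fragments data.frame from [six_frame_translate()] (or a character
#'   vector of peptides).
#' @param references Character vector of ungapped reference peptides.
#' @param k Word size (default 4, minimum 3).
#' @return The surviving subset of `fragments`. Fragments shorter than `k`
#'   are dropped with a warning.
#' @export
screen_candidates <- function(fragments, references, k = 4) {
  if (k < 3) stop("k must be at least 3")
  if (length(references) == 0) stop("empty reference set")
  peps <- if (is.data.frame(fragments)) fragments$peptide else fragments
  if (length(peps) == 0) return(fragments[0, , drop = FALSE])
  if (any(nchar(peps) < k))
    warning(sum(nchar(peps) < k), " fragment(s) shorter than k = ", k,
            " dropped")
  keep <- cpp_kmer_screen(peps, references, as.integer(k))
  if (is.data.frame(fragments)) fragments[keep, , drop = FALSE]
  else fragments[keep]
}

#' Align a peptide fragment to a marker profile
#'
#' Best local alignment of the peptide against the profile's match columns
#' by dynamic programming over the log-odds scores with affine gap
#' penalties (a gap of length g costs `gap_open + (g - 1) * gap_extend`
#' bits); alignments cannot start or end in a gap. Unknown residues (`X`)
#' score 0 bits at every column.
#'
#' @param fragment Peptide string (or a one-row data.frame from
#'   [six_frame_translate()]).
#' @param profile A `marker_profile`.
#' @return A list with `bit_score`, `profile_span` (`c(first, last)` match
#'   columns), `pep_span`, and `column_residues`: a string over the spanned
#'   columns with `-` where a column is skipped (inserted peptide residues
#'   map to no column). When the best local score is <= 0 the fragment is
#'   unaligned: `profile_span` and `column_residues` are `NA`.
#' @export
align_to_profile <- function(fragment, profile) {
  stopifnot(inherits(profile, "marker_profile"))
  pep <- if (is.data.frame(fragment)) fragment$peptide[[1]] else fragment
  r <- cpp_profile_align(profile$match_scores, pep,
                         profile$gap_open, profile$gap_extend)
  list(bit_score = r$score,
       profile_span = c(r$col_first, r$col_last),
       pep_span = c(r$pep_first, r$pep_last),
       column_residues = r$aligned)
}

#' Calibrate a recruitment score cutoff from background decoys
#'
#' Draws `decoy_count` random peptides of length `fragment_len` from the
#' profile's background residue distribution, scores them against the
#' profile, and returns the empirical `1 - target_fpr` score quantile,
#' floored at 10 bits. This decoy-calibrated cutoff is the package's
#' self-contained stand-in for tool-specific e-value thresholds.
#'
#' @param profile A `marker_profile`.
#' @param decoy_count Number of decoys (>= 1000).
#' @param fragment_len Decoy length in residues. Calibrating at the full
#'   translated read length (the longest fragment a read can yield) keeps
#'   the per-read false recruitment rate controlled even though each read
#'   offers several frames and markers as chances.
#' @param target_fpr Target per-fragment false positive rate, in (0, 0.1].
#' @param seed Integer seed; the cutoff is bit-reproducible.
#' @param floor_bits Minimum cutoff (default 10 bits).
#' @return Cutoff in bits.
#' @export
calibrate_cutoff <- function(profile, decoy_count = 10000, fragment_len = 50,
                             target_fpr = 1e-3, seed = 1, floor_bits = 10) {
  stopifnot(inherits(profile, "marker_profile"))
  if (decoy_count < 1000) stop("decoy_count must be at least 1000")
  if (target_fpr <= 0 || target_fpr > 0.1)
    stop("target_fpr must be in (0, 0.1]")
  scores <- with_seed(seed, {
    draw <- matrix(sample(aa_alphabet(), decoy_count * fragment_len,
                          replace = TRUE, prob = profile$background),
                   nrow = decoy_count)
    decoys <- do.call(paste0, as.data.frame(draw, stringsAsFactors = FALSE))
    cpp_profile_scores(profile$match_scores, decoys,
                       profile$gap_open, profile$gap_extend)
  })
  max(quantile(scores, 1 - target_fpr, type = 1, names = FALSE), floor_bits)
}

#' Calibrate per-read recruitment cutoffs for a profile set
#'
#' Every read offers several recruitment chances: up to six translated
#' frames, each screened against every marker profile. To keep the
#' per-*read* false recruitment rate at `target_fpr`, each profile's
#' cutoff is calibrated by [calibrate_cutoff()] at the Bonferroni-corrected
#' per-comparison rate `target_fpr / (n_frames * n_profiles)`, with decoys
#' of the full translated read length (the hardest-case fragment).
#'
#' @param profiles Named list of `marker_profile` objects.
#' @param target_fpr Target per-read false recruitment rate (default 1e-3).
#' @param read_length Read length in bp; decoy length is `read_length / 3`.
#' @param decoy_count Decoys per profile (default 20000; the corrected
#'   quantile sits in the extreme tail, so use generous decoy sets).
#' @param seed Integer seed.
#' @param n_frames Number of translated frames per read (default 6).
#' @return Named numeric vector of cutoffs in bits.
#' @export
calibrate_cutoffs <- function(profiles, target_fpr = 1e-3, read_length = 150,
                              decoy_count = 20000, seed = 1, n_frames = 6) {
  per_comparison <- target_fpr / (n_frames * length(profiles))
  frag_len <- max(15L, as.integer(read_length) %/% 3L)
  cuts <- vapply(seq_along(profiles), function(i)
    calibrate_cutoff(profiles[[i]], decoy_count = decoy_count,
                     fragment_len = frag_len, target_fpr = per_comparison,
                     seed = derive_seed(seed, i)), 0)
  setNames(cuts, names(profiles))
}

#' Recruit a read set against the marker profiles
#'
#' Runs six-frame translation, the per-marker k-mer screen, and profile
#' alignment; each read is assigned to at most one marker — the
#' best-scoring (marker, frame) combination, with ties broken by marker
#' order PR < psaA < pufM < recA and then by lower frame (order
#' +1, +2, +3, -1, -2, -3) — and counted iff its bit score reaches the
#' marker's cutoff.
#'
#' @param reads Character vector or `DNAStringSet` of reads.
#' @param profiles Named list of `marker_profile` objects (names from
#'   `marker_genes()`); each must carry its `ref_peptides` for the screen.
#' @param cutoffs Named numeric vector of score cutoffs in bits; defaults
#'   to each profile's `score_cutoff` field.
#' @param k Screen word size (default 4).
#' @param min_len Minimum translated fragment length (default 15).
#' @return A `recruitment` list: `recruited`, a per-marker data.frame
#'   (`read_id`, `marker`, `frame`, `bit_score`, `col_first`, `col_last`,
#'   `aligned` — the column-residue string); `counts`, the per-marker
#'   recruited read counts (`funcAbun` / `RecAAbun` numerators); and
#'   `n_reads`, the library size used as the relative-abundance denominator.
#' @export
recruit_sample <- function(reads, profiles, cutoffs = NULL, k = 4,
                           min_len = 15) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  markers <- intersect(marker_genes(), names(profiles))
  if (!length(markers)) stop("profiles must be named by marker gene")
  if (is.null(cutoffs))
    cutoffs <- vapply(profiles[markers], `[[`, 0, "score_cutoff")
  if (any(is.na(cutoffs[markers])))
    stop("missing score cutoff for: ",
         paste(markers[is.na(cutoffs[markers])], collapse = ", "))
  n_reads <- length(reads)
  frags <- six_frame_translate(reads, min_len = min_len)
  frame_rank <- c(`1` = 1, `2` = 2, `3` = 3, `-1` = 4, `-2` = 5, `-3` = 6)
  for (m in markers)
    if (is.null(profiles[[m]]$ref_peptides))
      stop("profile for ", m, " carries no reference peptides for the screen")
  empty <- data.frame(read_id = character(), marker = character(),
                      frame = integer(), bit_score = numeric(),
                      col_first = integer(), col_last = integer(),
                      aligned = character(), stringsAsFactors = FALSE)
  scores <- if (nrow(frags))
    cpp_score_markers(frags$peptide,
                      lapply(profiles[markers], `[[`, "ref_peptides"),
                      lapply(profiles[markers], `[[`, "match_scores"),
                      vapply(profiles[markers], `[[`, 0, "gap_open"),
                      vapply(profiles[markers], `[[`, 0, "gap_extend"),
                      as.integer(k))
  else matrix(NA_real_, 0, length(markers))
  hit <- which(!is.na(scores), arr.ind = TRUE)
  if (!nrow(hit)) {
    rec <- setNames(rep(list(empty), length(markers)), markers)
    return(structure(list(recruited = rec,
                          counts = setNames(integer(length(markers)), markers),
                          n_reads = n_reads), class = "recruitment"))
  }
  best <- data.frame(read_id = frags$read_id[hit[, 1]],
                     frame = frags$frame[hit[, 1]],
                     peptide = frags$peptide[hit[, 1]],
                     marker = markers[hit[, 2]],
                     bit_score = scores[hit],
                     stringsAsFactors = FALSE)
  best$marker_rank <- match(best$marker, marker_genes())
  # best (marker, frame, fragment) per read wins; counted iff it reaches
  # the winning marker's cutoff
  ord <- order(best$read_id, -best$bit_score, best$marker_rank,
               frame_rank[as.character(best$frame)])
  best <- best[ord, , drop = FALSE]
  best <- best[!duplicated(best$read_id), , drop = FALSE]
  best <- best[best$bit_score >= cutoffs[best$marker], , drop = FALSE]
  if (!nrow(best)) {
    rec <- setNames(rep(list(empty), length(markers)), markers)
    return(structure(list(recruited = rec,
                          counts = setNames(integer(length(markers)), markers),
                          n_reads = n_reads), class = "recruitment"))
  }
  # full alignment (with traceback) only for the winning fragments
  aln <- lapply(seq_len(nrow(best)), function(i)
    align_to_profile(best$peptide[i], profiles[[best$marker[i]]]))
  best$col_first <- vapply(aln, function(a) a$profile_span[1], 0L)
  best$col_last <- vapply(aln, function(a) a$profile_span[2], 0L)
  best$aligned <- vapply(aln, function(a) as.character(a$column_residues), "")
  recruited <- lapply(markers, function(m) {
    d <- best[best$marker == m,
              c("read_id", "marker", "frame", "bit_score",
                "col_first", "col_last", "aligned"), drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(recruited) <- markers
  structure(list(recruited = recruited,
                 counts = vapply(recruited, nrow, 0L),
                 n_reads = n_reads),
            class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  cat("Recruitment over", x$n_reads, "reads:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
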