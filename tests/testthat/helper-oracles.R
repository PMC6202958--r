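# Independent oracles and shared fixtures. The alignment oracle enumerates
# chains of matched (column, residue) pairs directly, with no shared code
# with the package's dynamic-programming kernel.

# Best local alignment score by exhaustive chain enumeration: a local
# alignment is a strictly increasing chain of matched pairs; between
# consecutive pairs exactly one side may jump (affine gap, cost
# open + (g - 1) * extend); alignments start and end on a match.
bf_best_local <- function(S, pep, gap_open = 4, gap_extend = 1) {
  aa <- aa_alphabet()
  L <- nrow(S)
  r <- match(strsplit(pep, "", fixed = TRUE)[[1]], aa)
  m <- length(r)
  sc <- function(i, j) if (is.na(r[j])) 0 else S[i, r[j]]
  memo <- matrix(NA_real_, L, m)
  best_from <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    ext <- 0
    for (i2 in seq_len(L)) for (j2 in seq_len(m)) {
      di <- i2 - i; dj <- j2 - j
      if (di < 1 || dj < 1 || min(di, dj) != 1) next
      g <- max(di, dj) - 1
      cost <- if (g == 0) 0 else gap_open + (g - 1) * gap_extend
      cand <- best_from(i2, j2) - cost
      if (cand > ext) ext <- cand
    }
    memo[i, j] <<- sc(i, j) + ext
    memo[i, j]
  }
  best <- 0
  for (i in seq_len(L)) for (j in seq_len(m))
    best <- max(best, best_from(i, j))
  best
}

# Wrap a raw score matrix as a marker_profile for align_to_profile().
raw_profile <- function(S, gap_open = 4, gap_extend = 1, marker = "PR") {
  colnames(S) <- aa_alphabet()
  structure(list(marker = marker, L_func = nrow(S), match_scores = S,
                 background = stats::setNames(rep(1 / 20, 20), aa_alphabet()),
                 gap_open = gap_open, gap_extend = gap_extend,
                 score_cutoff = NA_real_, fts_column = NA_integer_,
                 match_cols = seq_len(nrow(S)), ref_peptides = NULL),
            class = "marker_profile")
}

# Textbook one-sided paired t-test, coded from the definition.
oracle_paired_t <- function(x, y, direction = "greater") {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- stats::pt(t, df = n - 1, lower.tail = (direction == "less"))
  list(statistic = t, p_value = p)
}

# Exact one-sided signed-rank p-value by enumeration of all sign patterns
# (requires untied absolute differences, zeros already excluded).
oracle_signed_rank_exact <- function(x, y, direction = "greater") {
  d <- (x - y)[x != y]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% rk
  if (direction == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

# Shannon entropy / Pielou evenness from the definition.
oracle_evenness <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  H <- -sum(p * log(p))
  list(H = H, J = H / log(length(p)))
}

# -- small community builders ------------------------------------------------

# Minimal n-taxon community carrying PR and recA only.
pr_only_community <- function(abundance, fts, clusters = NULL,
                              error_rate = 0, background_fraction = 0,
                              mult_PR = 1) {
  n <- length(abundance)
  taxa <- data.frame(
    taxon_id = sprintf("tx%02d", seq_len(n)),
    cluster = clusters %||% rep("SAR11", n),
    abundance = abundance,
    has_PR = TRUE, has_psaA = FALSE, has_pufM = FALSE, has_recA = TRUE,
    len_PR = 750, len_psaA = 750, len_pufM = 750, len_recA = 1062,
    mult_PR = mult_PR, mult_psaA = 0, mult_pufM = 0, mult_recA = 1,
    fts_residue = fts, stringsAsFactors = FALSE)
  community_spec(taxa, error_rate = error_rate,
                 background_fraction = background_fraction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- memoized acceptance fixture --------------------------------------------
# The survey-scale community, its reference set, codon-background profiles
# and calibrated cutoffs are shared across acceptance tests; recruitments
# are memoized by (library, seed) so the abundance and expression-ratio
# tests reuse the same simulated libraries.

.acc <- new.env(parent = emptyenv())

acc_fixture <- function() {
  if (is.null(.acc$fx)) {
    spec <- example_community()
    refset <- generate_reference_set(spec, divergence = 0.1, seed = 7)
    profiles <- lapply(refset$alignments, build_profile,
                       background = aa_background("codon"))
    profiles$PR$fts_column <- refset$fts_position
    cutoffs <- calibrate_cutoffs(profiles, target_fpr = 1e-3,
                                 read_length = 150, seed = 3)
    truth <- truth_summary(spec)
    .acc$fx <- list(spec = spec, refset = refset, profiles = profiles,
                    cutoffs = cutoffs, truth = truth,
                    lens = vapply(profiles, `[[`, 0L, "L_func"))
    .acc$rec <- list()
  }
  .acc$fx
}

acc_recruit <- function(library, seed, n_reads = 50000) {
  key <- paste(library, seed, n_reads)
  if (is.null(.acc$rec[[key]])) {
    fx <- acc_fixture()
    rd <- simulate_reads(fx$spec, fx$refset, n_reads, library = library,
                         seed = seed)
    .acc$rec[[key]] <- recruit_sample(rd$reads, fx$profiles, fx$cutoffs)
  }
  .acc$rec[[key]]
}
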