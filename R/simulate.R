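# Synthetic picoplankton community generator: reference sets, paired
# DNA/RNA read libraries, and ground-truth tables for every estimator.

#' Define a synthetic community
#'
#' A community is a table of taxa with relative genome abundances, marker
#' gene complements, per-gene nucleotide lengths, per-gene expression
#' multipliers (expected RNA copies per gene copy, relative to recA = 1),
#' a PR clade label and a PR frequency-tuning-site residue.
#'
#' @param taxa data.frame with columns `taxon_id`, `cluster`, `abundance`
#'   and, per marker `m` in `marker_genes()`, `has_<m>` (logical; `has_recA`
#'   defaults to TRUE if absent), `len_<m>` (nt, multiple of 3) and
#'   `mult_<m>` (expression multiplier, >= 0); plus `fts_residue` (one
#'   amino-acid letter, used for PR carriers).
#' @param read_length Simulated read length in bp (default 150, single-end;
#'   only forward reads enter placement, so no pairing is modelled).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param background_fraction Fraction of reads drawn from random
#'   non-marker sequence (default 0.8), so recruitment specificity is
#'   genuinely exercised.
#' @return A validated `community_spec`.
#' @export
community_spec <- function(taxa, read_length = 150, error_rate = 0.005,
                           background_fraction = 0.8) {
  stopifnot(is.data.frame(taxa), nrow(taxa) >= 1)
  need <- c("taxon_id", "cluster", "abundance", "fts_residue")
  miss <- setdiff(need, names(taxa))
  if (length(miss)) stop("taxa is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(taxa$taxon_id)) stop("duplicate taxon_id")
  if (!("has_recA" %in% names(taxa))) taxa$has_recA <- TRUE
  for (m in marker_genes()) {
    for (pre in c("has_", "len_", "mult_")) {
      col <- paste0(pre, m)
      if (!(col %in% names(taxa))) stop("taxa is missing column ", col)
    }
  }
  if (abs(sum(taxa$abundance) - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", sum(taxa$abundance), ")")
  if (any(taxa$abundance < 0)) stop("abundances must be non-negative")
  if (!any(taxa$has_recA)) stop("at least one taxon must carry recA")
  for (m in marker_genes()) {
    has <- taxa[[paste0("has_", m)]]
    len <- taxa[[paste0("len_", m)]][has]
    mult <- taxa[[paste0("mult_", m)]][has]
    if (!any(has)) next
    if (any(len %% 3 != 0)) stop(m, " gene lengths must be multiples of 3")
    if (length(unique(len)) != 1L)
      stop(m, " gene length must be identical across carrier taxa ",
           "(references are gapless equal-length alignments)")
    if (any(len < read_length))
      stop(m, " gene length must be at least the read length")
    if (any(!is.finite(mult)) || any(mult < 0))
      stop(m, " expression multipliers must be finite and >= 0")
  }
  bad_fts <- taxa$has_PR & !(taxa$fts_residue %in% aa_alphabet())
  if (any(bad_fts))
    stop("PR carriers need a valid fts_residue: ",
         paste(taxa$taxon_id[bad_fts], collapse = ", "))
  if (read_length < 30) stop("read_length must be at least 30 bp")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must be in [0, 1)")
  structure(list(taxa = taxa, read_length = read_length,
                 error_rate = error_rate,
                 background_fraction = background_fraction),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat("Community: ", nrow(x$taxa), " taxa; read length ", x$read_length,
      " bp; error rate ", x$error_rate, "; background fraction ",
      x$background_fraction, "\n", sep = "")
  invisible(x)
}

# uniform synonymous codon table, stop codons excluded
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

mutate_protein <- function(protein, rate) {
  aa <- aa_alphabet()
  hit <- which(runif(length(protein)) < rate)
  for (i in hit) protein[i] <- sample(setdiff(aa, protein[i]), 1)
  protein
}

back_translate <- function(protein, codons) {
  paste(vapply(protein, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1)]
  }, ""), collapse = "")
}

#' Generate a synthetic reference set for a community
#'
#' For each marker an ancestor protein is drawn from the uniform residue
#' background and independently mutated per carrier taxon at the given
#' divergence; PR carriers have their tuning-site residue forced to the
#' community table. Nucleotide genes are obtained by uniform synonymous
#' back-translation. The per-marker reference "alignment" is the gapless
#' stack of the equal-length variants; the PR clade tree is built by
#' single-linkage clustering on pairwise protein identity.
#'
#' @param spec A `community_spec`.
#' @param divergence Per-residue substitution probability from the ancestor,
#'   in `[0, 0.5)`; at 0.5 or above leaf placement would be meaningless.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param fts_position 1-based residue index of the PR tuning site on the
#'   (ungapped) PR protein; default 105, the canonical tuning-site numbering.
#' @return A `reference_set`: `alignments` (per marker present in the
#'   community), `genes` (per marker, named nucleotide sequences), `tree`
#'   (a `clade_tree` over PR carriers, `NULL` if fewer than 2), and
#'   `fts_position` (equals the PR FTS match column, the alignments being
#'   gapless).
#' @export
generate_reference_set <- function(spec, divergence = 0.1, seed = 1,
                                   fts_position = 105) {
  stopifnot(inherits(spec, "community_spec"))
  if (divergence >= 0.5) stop("divergence must be < 0.5")
  if (divergence < 0) stop("divergence must be non-negative")
  taxa <- spec$taxa
  codons <- .codon_table()
  with_seed(seed, {
    alignments <- list()
    genes <- list()
    proteins <- list()
    for (m in marker_genes()) {
      carriers <- taxa$taxon_id[taxa[[paste0("has_", m)]]]
      if (!length(carriers)) next
      plen <- taxa[[paste0("len_", m)]][taxa[[paste0("has_", m)]]][1] / 3
      if (m == "PR" && fts_position > plen)
        stop("fts_position beyond PR protein length ", plen)
      ancestor <- sample(aa_alphabet(), plen, replace = TRUE)
      vars <- lapply(carriers, function(t) mutate_protein(ancestor, divergence))
      names(vars) <- carriers
      if (m == "PR") {
        for (t in carriers)
          vars[[t]][fts_position] <- taxa$fts_residue[taxa$taxon_id == t]
      }
      proteins[[m]] <- vars
      rows <- vapply(vars, paste, "", collapse = "")
      alignments[[m]] <- new_reference_alignment(rows, m)
      if (length(rows) >= 2) validate_reference_alignment(alignments[[m]])
      genes[[m]] <- vapply(vars, back_translate, "", codons = codons)
    }
    tree <- NULL
    pr <- proteins[["PR"]]
    if (!is.null(pr) && length(pr) >= 2) {
      ids <- names(pr)
      n <- length(ids)
      d <- matrix(0, n, n, dimnames = list(ids, ids))
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        d[i, j] <- d[j, i] <- mean(pr[[i]] != pr[[j]])
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      phy <- ape::as.phylo(hc)
      cm <- setNames(taxa$cluster, taxa$taxon_id)[ids]
      tree <- clade_tree(phy, cm)
    }
    structure(list(alignments = alignments, genes = genes, tree = tree,
                   fts_position = as.integer(fts_position),
                   divergence = divergence, seed = seed),
              class = "reference_set")
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set: markers ", paste(names(x$alignments), collapse = ", "),
      "; divergence ", x$divergence, "\n", sep = "")
  invisible(x)
}

#' Simulate a sequencing library from a community
#'
#' Reads are background (random uniform nucleotides) with probability
#' `background_fraction`; otherwise the source gene is drawn from all
#' (taxon, gene) pairs with probability proportional to
#' `abundance * gene_length` for DNA libraries and
#' `abundance * gene_length * expression_multiplier` for RNA libraries —
#' the read-sampling law of uniform shotgun sequencing over equal-size
#' genomes. Start positions are uniform within the gene, strands random,
#' and substitutions occur independently at `error_rate` per base.
#'
#' @param spec A `community_spec`.
#' @param refset Matching `reference_set`.
#' @param n_reads Number of reads (> 0).
#' @param library `"DNA"` or `"RNA"`.
#' @param seed Integer seed.
#' @return List with `reads` (named `Biostrings::DNAStringSet`) and `truth`
#'   (data.frame `read_id`, `taxon`, `gene` — a marker or `"background"` —,
#'   `strand`, `start` on the gene forward strand).
#' @export
simulate_reads <- function(spec, refset, n_reads, library = c("DNA", "RNA"),
                           seed = 1) {
  stopifnot(inherits(spec, "community_spec"), inherits(refset, "reference_set"))
  library <- match.arg(library)
  if (n_reads <= 0) stop("n_reads must be positive")
  n_reads <- as.integer(n_reads)
  taxa <- spec$taxa
  rl <- spec$read_length
  # source table over (taxon, marker)
  src <- do.call(rbind, lapply(marker_genes(), function(m) {
    has <- taxa[[paste0("has_", m)]]
    if (!any(has)) return(NULL)
    data.frame(taxon = taxa$taxon_id[has], gene = m,
               len = taxa[[paste0("len_", m)]][has],
               w = taxa$abundance[has] * taxa[[paste0("len_", m)]][has] *
                 (if (library == "RNA") taxa[[paste0("mult_", m)]][has] else 1))
  }))
  if (sum(src$w) <= 0) stop("no positive-weight read source for ", library)
  with_seed(seed, {
    is_bg <- runif(n_reads) < spec$background_fraction
    idx <- rep(NA_integer_, n_reads)
    n_gene <- sum(!is_bg)
    if (n_gene > 0)
      idx[!is_bg] <- sample.int(nrow(src), n_gene, replace = TRUE,
                                prob = src$w / sum(src$w))
    reads <- character(n_reads)
    start <- integer(n_reads)
    bases <- c("A", "C", "G", "T")
    if (any(is_bg)) {
      nb <- sum(is_bg)
      reads[is_bg] <- vapply(seq_len(nb), function(i)
        paste(sample(bases, rl, replace = TRUE), collapse = ""), "")
      start[is_bg] <- NA_integer_
    }
    if (n_gene > 0) {
      gi <- which(!is_bg)
      len <- src$len[idx[gi]]
      st <- as.integer(floor(runif(n_gene) * (len - rl + 1)) + 1)
      start[gi] <- st
      key <- paste(src$gene[idx[gi]], src$taxon[idx[gi]])
      seqs <- vapply(seq_len(n_gene), function(k) {
        g <- refset$genes[[src$gene[idx[gi[k]]]]][[src$taxon[idx[gi[k]]]]]
        substr(g, st[k], st[k] + rl - 1)
      }, "")
      # sequencing errors: independent per-base substitutions
      if (spec$error_rate > 0) {
        hits <- which(runif(n_gene * rl) < spec$error_rate)
        for (h in hits) {
          k <- (h - 1) %/% rl + 1
          p <- (h - 1) %% rl + 1
          cur <- substr(seqs[k], p, p)
          substr(seqs[k], p, p) <- sample(setdiff(bases, cur), 1)
        }
      }
      reads[gi] <- seqs
    }
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
    ids <- sprintf("read_%07d", seq_len(n_reads))
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- ids
    flip <- strand == "-"
    if (any(flip))
      dna[flip] <- Biostrings::reverseComplement(dna[flip])
    truth <- data.frame(read_id = ids,
                        taxon = ifelse(is_bg, NA_character_, src$taxon[idx]),
                        gene = ifelse(is_bg, "background", src$gene[idx]),
                        strand = strand, start = start,
                        stringsAsFactors = FALSE)
    list(reads = dna, truth = truth)
  })
}

#' Ground-truth expectations for a community
#'
#' Expresses the community parameters in the currencies the pipeline
#' estimates: recA-normalized marker abundance
#' (`sum(a_t * has_g) / sum(a_t * has_recA)`), recA-adjusted RNA:DNA
#' expression ratios (abundance-weighted mean multiplier among carriers,
#' divided by the same quantity for recA), PR cluster gene and transcript
#' fractions, and the expected blue fraction among blue plus green
#' tuning-site residues.
#'
#' @param spec A `community_spec`.
#' @return A `truth_table` list: `norm_abundance`, `rna_dna_ratio` (named by
#'   marker), `cluster_gene_fraction`, `cluster_transcript_fraction` (named
#'   by cluster, PR carriers only), and `blue_fraction`.
#' @export
truth_summary <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  t <- spec$taxa
  a_recA <- sum(t$abundance * t$has_recA)
  if (a_recA <= 0) stop("no taxon with recA")
  norm <- vapply(marker_genes(), function(m)
    sum(t$abundance * t[[paste0("has_", m)]]) / a_recA, 0)
  wmean_mult <- function(m) {
    has <- t[[paste0("has_", m)]]
    if (!any(has)) return(NA_real_)
    sum(t$abundance[has] * t[[paste0("mult_", m)]][has]) / sum(t$abundance[has])
  }
  r_recA <- wmean_mult("recA")
  ratio <- vapply(marker_genes(), function(m) wmean_mult(m) / r_recA, 0)
  pr <- t[t$has_PR, , drop = FALSE]
  cg <- ct <- NULL
  blue <- NA_real_
  if (nrow(pr)) {
    cg <- tapply(pr$abundance, pr$cluster, sum) / sum(pr$abundance)
    w <- pr$abundance * pr$mult_PR
    ct <- if (sum(w) > 0) tapply(w, pr$cluster, sum) / sum(w) else NULL
    bg_mask <- pr$fts_residue %in% c("Q", "L", "M")
    if (any(bg_mask))
      blue <- sum(pr$abundance[pr$fts_residue == "Q"]) /
        sum(pr$abundance[bg_mask])
  }
  structure(list(norm_abundance = norm, rna_dna_ratio = ratio,
                 cluster_gene_fraction = cg,
                 cluster_transcript_fraction = ct,
                 blue_fraction = blue),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Truth table\n  normalized abundance: ",
      paste(names(x$norm_abundance), signif(x$norm_abundance, 3),
            sep = "=", collapse = ", "),
      "\n  RNA:DNA ratio (recA-adjusted): ",
      paste(names(x$rna_dna_ratio), signif(x$rna_dna_ratio, 3),
            sep = "=", collapse = ", "),
      "\n  blue fraction: ", signif(x$blue_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' A survey-scale example community
#'
#' Ten taxa emulating a coastal picoplankton community: PR in 90% of
#' genomes split over SAR11, Gammaproteobacteria, other Alphaproteobacteria,
#' an environmental clade and an "other" cluster; psaA in 20%; pufM in 10%
#' (carried by the single taxon lacking PR); recA in all. Expression
#' multipliers are tuned so the expected recA-adjusted RNA:DNA ratios are
#' 26.2 (PR), 11 (psaA) and 0.013 (pufM), SAR11 contributes 52% of PR
#' transcripts, and the expected blue fraction at the tuning site is 0.633.
#'
#' @param read_length,error_rate,background_fraction Passed to
#'   [community_spec()].
#' @return A `community_spec`.
#' @export
example_community <- function(read_length = 150, error_rate = 0.005,
                              background_fraction = 0.8) {
  R <- 26.2            # target mean PR RNA:DNA ratio
  ab <- c(0.15, 0.12, 0.08, 0.09, 0.07, 0.08, 0.06, 0.07, 0.18, 0.10)
  cl <- c("SAR11", "SAR11", "SAR11", "Gammaproteobacteria",
          "Gammaproteobacteria", "other_Alphaproteobacteria",
          "other_Alphaproteobacteria", "environmental", "other", "AAnP")
  share <- c(SAR11 = 0.52, Gammaproteobacteria = 0.15,
             other_Alphaproteobacteria = 0.12, environmental = 0.08,
             other = 0.13)
  cl_ab <- tapply(ab[1:9], cl[1:9], sum)
  mult_PR <- c(R * 0.9 * share[cl[1:9]] / cl_ab[cl[1:9]], 0)
  taxa <- data.frame(
    taxon_id = sprintf("taxon_%02d", 1:10),
    cluster = cl, abundance = ab,
    has_PR = c(rep(TRUE, 9), FALSE),
    has_psaA = c(FALSE, TRUE, TRUE, rep(FALSE, 7)),
    has_pufM = c(rep(FALSE, 9), TRUE),
    has_recA = TRUE,
    len_PR = 750, len_psaA = 2202, len_pufM = 921, len_recA = 1062,
    mult_PR = as.numeric(mult_PR),
    mult_psaA = ifelse(c(FALSE, TRUE, TRUE, rep(FALSE, 7)), 11, 0),
    mult_pufM = ifelse(c(rep(FALSE, 9), TRUE), 0.013, 0),
    mult_recA = 1,
    # blue (Q) carriers sum to 0.57 of the 0.90 PR abundance: 63.3% blue
    fts_residue = c("Q", "L", "Q", "Q", "Q", "L", "M", "L", "Q", "L"),
    stringsAsFactors = FALSE)
  community_spec(taxa, read_length = read_length, error_rate = error_rate,
                 background_fraction = background_fraction)
}
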