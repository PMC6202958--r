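# Six-frame translation, k-mer screen, profile alignment, calibration,
# per-sample recruitment.

test_that("six-frame translation splits at stops and handles N and strand", {
  # "ATGGCATAAATGGCA" frame +1: MA * MA
  fr <- six_frame_translate("ATGGCATAAATGGCA", min_len = 2)
  f1 <- fr[fr$frame == 1, ]
  expect_equal(f1$peptide, c("MA", "MA"))
  expect_equal(f1$offset, c(0L, 9L))

  # reverse strand recovers the peptide in a negative frame
  pep <- "MKVLDEWQ"
  codons <- photomarker:::.codon_table()
  set.seed(1)
  nt <- paste(vapply(strsplit(pep, "")[[1]],
                     function(a) sample(codons[[a]], 1), ""), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  fr_rc <- six_frame_translate(rc, min_len = 8)
  expect_true(pep %in% fr_rc$peptide)
  expect_true(all(fr_rc$frame[fr_rc$peptide == pep] < 0))

  # all-N read yields X runs, never spurious fragments of real residues
  frN <- six_frame_translate(paste(rep("N", 60), collapse = ""), min_len = 15)
  expect_true(all(grepl("^X+$", frN$peptide)) || nrow(frN) == 0)

  expect_error(six_frame_translate("ACGTZZ"), "non-nucleotide")
  # short reads yield nothing rather than erroring
  expect_equal(nrow(six_frame_translate("ACGTAC", min_len = 15)), 0)
})

test_that("translation offsets address the encoding bases on both strands", {
  set.seed(11)
  read <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  fr <- six_frame_translate(read, min_len = 5)
  for (i in seq_len(nrow(fr))) {
    seg <- substr(read, fr$offset[i] + 1,
                  fr$offset[i] + 3 * nchar(fr$peptide[i]))
    if (fr$frame[i] < 0)
      seg <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seg)))
    expect_equal(as.character(Biostrings::translate(
      Biostrings::DNAString(seg))), fr$peptide[i])
  }
})

test_that("the k-mer screen keeps sharers and drops strangers", {
  refs <- c("MKVLDEWQRTS", "ACDEFGHIKLMNP")
  expect_equal(screen_candidates("XXMKVLXX", refs, k = 4), "XXMKVLXX")
  expect_equal(length(screen_candidates("WWWWWWWW", refs, k = 4)), 0)
  expect_warning(out <- screen_candidates(c("MKV"), refs, k = 4), "shorter")
  expect_equal(length(out), 0)
  expect_error(screen_candidates("MKVL", character(0)), "empty reference")
  expect_error(screen_candidates("MKVL", refs, k = 2), "k must be")
})

test_that("profile alignment scores the consensus and rejects noise", {
  aln <- photomarker:::new_reference_alignment(
    c(s1 = "ACDE", s2 = "ACDE", s3 = "ACDE", s4 = "ACDE"), "PR")
  prof <- build_profile(aln, pseudocount = 1)
  hit <- align_to_profile("ACDE", prof)
  expect_equal(hit$bit_score, 4 * log2(16.2), tolerance = 1e-10)
  expect_equal(hit$bit_score, 16.07, tolerance = 1e-2)
  expect_equal(hit$profile_span, c(1, 4))
  expect_equal(hit$column_residues, "ACDE")
  # all cell scores negative: no local alignment
  miss <- align_to_profile("WWWW", prof)
  expect_lte(miss$bit_score, 0)
  expect_true(is.na(miss$column_residues))
})

test_that("alignment equals exhaustive enumeration on a dense grid", {
  set.seed(1234)
  cases <- 0
  for (rep in 1:60) {
    L <- sample(2:8, 1)
    m <- sample(2:12, 1)
    go <- sample(c(2, 4, 6), 1)
    ge <- sample(c(0.5, 1), 1)
    for (variant in 1:4) {
      S <- matrix(rnorm(L * 20, mean = c(-1, 0)[1 + variant %% 2], sd = 2),
                  L, 20)
      pep <- paste(sample(c(aa_alphabet(), "X"), m, replace = TRUE),
                   collapse = "")
      prof <- raw_profile(S, gap_open = go, gap_extend = ge)
      got <- align_to_profile(pep, prof)$bit_score
      want <- bf_best_local(S, pep, go, ge)
      expect_equal(got, want, tolerance = 1e-10)
      cases <- cases + 1
    }
  }
  expect_gte(cases, 200)
})

test_that("score-only and traceback kernels agree", {
  set.seed(77)
  S <- matrix(rnorm(40 * 20, 0, 2), 40, 20)
  prof <- raw_profile(S)
  peps <- vapply(1:50, function(i)
    paste(sample(aa_alphabet(), sample(5:30, 1), replace = TRUE),
          collapse = ""), "")
  fast <- photomarker:::cpp_profile_scores(S, peps, 4, 1)
  full <- vapply(peps, function(p) align_to_profile(p, prof)$bit_score, 0)
  expect_equal(unname(full[fast > 0]), fast[fast > 0], tolerance = 1e-10)
})

test_that("decoy calibration is reproducible and controls its own FPR", {
  aln <- photomarker:::new_reference_alignment(
    stats::setNames(rep(list(paste(rep(c("M", "K", "V", "D", "E"), 20),
                                   collapse = "")), 3) |> unlist(),
                    c("a", "b", "c")), "PR")
  prof <- build_profile(aln, background = aa_background("codon"))
  c1 <- calibrate_cutoff(prof, decoy_count = 5000, fragment_len = 40,
                         target_fpr = 1e-2, seed = 1)
  c2 <- calibrate_cutoff(prof, decoy_count = 5000, fragment_len = 40,
                         target_fpr = 1e-2, seed = 1)
  expect_identical(c1, c2)
  expect_gte(c1, 10)

  # fresh decoys from the same background exceed the cutoff at most at the
  # target rate (within 3 binomial SE); the 10-bit floor only lowers FPR
  fresh <- photomarker:::with_seed(99, {
    draw <- matrix(sample(aa_alphabet(), 5000 * 40, replace = TRUE,
                          prob = prof$background), nrow = 5000)
    apply(draw, 1, paste, collapse = "")
  })
  scores <- photomarker:::cpp_profile_scores(prof$match_scores, fresh,
                                             prof$gap_open, prof$gap_extend)
  fpr <- mean(scores >= c1)
  expect_lte(fpr, 1e-2 + 3 * sqrt(1e-2 * 0.99 / 5000))

  expect_error(calibrate_cutoff(prof, decoy_count = 10), "at least 1000")
  expect_error(calibrate_cutoff(prof, target_fpr = 0.5), "target_fpr")
})

test_that("reads go to the best-scoring marker; chimeras are not split", {
  spec <- example_community(error_rate = 0, background_fraction = 0)
  rs <- generate_reference_set(spec, divergence = 0.1, seed = 17)
  profiles <- lapply(rs$alignments, build_profile,
                     background = aa_background("codon"))
  cutoffs <- calibrate_cutoffs(profiles, seed = 5)
  # a read made of half PR, half recA codons aligns to both profiles but
  # is assigned only once, to the higher-scoring marker
  pr_gene <- rs$genes$PR[[1]]
  recA_gene <- rs$genes$recA[[1]]
  chimera <- paste0(substr(pr_gene, 1, 90), substr(recA_gene, 1, 60))
  rec <- recruit_sample(c(chi = chimera), profiles, cutoffs)
  expect_equal(sum(rec$counts), 1)
  expect_equal(unname(rec$counts[["PR"]]), 1)  # 30 vs 20 aligned residues
})

test_that("recruitment is sensitive, strand-symmetric and cutoff-monotone", {
  spec <- example_community(error_rate = 0, background_fraction = 0)
  rs <- generate_reference_set(spec, divergence = 0.1, seed = 17)
  profiles <- lapply(rs$alignments, build_profile,
                     background = aa_background("codon"))
  cutoffs <- calibrate_cutoffs(profiles, seed = 5)
  rd <- simulate_reads(spec, rs, 4000, "DNA", seed = 23)
  rec <- recruit_sample(rd$reads, profiles, cutoffs)
  # error-free reads overlap their profile by 50 residues: near-total
  # sensitivity, and no marker confusion
  allrec <- do.call(rbind, unname(rec$recruited))
  m <- merge(allrec[, c("read_id", "marker")],
             rd$truth[, c("read_id", "gene")], by = "read_id")
  expect_true(all(m$marker == m$gene))
  expect_gte(nrow(m) / 4000, 0.95)

  # reverse-complementing every read changes no count
  rc <- Biostrings::reverseComplement(rd$reads)
  rec_rc <- recruit_sample(rc, profiles, cutoffs)
  expect_identical(rec$counts, rec_rc$counts)

  # counts never increase as cutoffs rise
  for (extra in c(5, 20, 60)) {
    rec_hi <- recruit_sample(rd$reads, profiles, cutoffs + extra)
    expect_true(all(rec_hi$counts <= rec$counts))
  }
})

test_that("a pure-background library is recruited at most at 3x target", {
  fx <- acc_fixture()
  bg <- photomarker:::with_seed(1299, {
    draw <- matrix(sample(c("A", "C", "G", "T"), 20000 * 150,
                          replace = TRUE), nrow = 20000)
    do.call(paste0, as.data.frame(draw, stringsAsFactors = FALSE))
  })
  rec <- recruit_sample(bg, fx$profiles, fx$cutoffs)
  expect_lte(sum(rec$counts) / 20000, 3e-3)
})
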