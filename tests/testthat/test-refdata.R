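# Reference alignments, profiles, FTS location, clade trees.

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

test_that("aligned FASTA loads, with the short-row curation filter", {
  p <- write_fasta(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "ACDEF-HIKL"))
  aln <- load_reference_alignment(p, "PR", min_ungapped = 0)
  expect_s3_class(aln, "reference_alignment")
  expect_equal(aln$n_columns, 10)
  expect_equal(length(aln$rows), 3)

  # a 150-residue row among 250-residue rows is rejected at the default
  # 200-residue curation threshold
  long <- paste(rep("A", 250), collapse = "")
  short <- paste(c(rep("A", 150), rep("-", 100)), collapse = "")
  p2 <- write_fasta(c(r1 = long, r2 = long, r3 = short))
  expect_warning(aln2 <- load_reference_alignment(p2, "recA"), "r3")
  expect_equal(length(aln2$rows), 2)
})

test_that("ragged and empty alignments are hard errors naming the row", {
  p <- write_fasta(c(a = "ACDE", b = "ACD", c = "ACDE"))
  expect_error(load_reference_alignment(p, "PR", min_ungapped = 0), "b")
  p_empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), p_empty)
  expect_error(load_reference_alignment(p_empty, "PR"), "empty|parse")
  expect_error(load_reference_alignment(tempfile(), "PR"), "no such file")
})

test_that("profile scores follow the log-odds formula with pseudocounts", {
  aln <- photomarker:::new_reference_alignment(
    c(s1 = "ACDE", s2 = "ACDE", s3 = "ACDE", s4 = "ACDE"), "PR")
  prof <- build_profile(aln, pseudocount = 1)
  expect_equal(prof$L_func, 4)
  # consensus: log2(((4 + 0.05) / 5) / 0.05)
  expect_equal(unname(prof$match_scores[1, "A"]), log2(16.2), tolerance = 1e-12)
  expect_equal(unname(prof$match_scores[1, "A"]), 4.018, tolerance = 1e-3)
  # absent residue: log2(((0 + 0.05) / 5) / 0.05) = log2(0.2)
  expect_equal(unname(prof$match_scores[1, "W"]), log2(0.2), tolerance = 1e-12)
  expect_equal(unname(prof$match_scores[1, "W"]), -2.322, tolerance = 1e-3)
  expect_true(all(is.finite(prof$match_scores)))
})

test_that("gap-dominated columns are not match columns", {
  aln <- photomarker:::new_reference_alignment(
    c(s1 = "A-CD", s2 = "A-CD", s3 = "A-CD", s4 = "AWCD"), "PR")
  prof <- build_profile(aln)
  expect_equal(prof$L_func, 3)
  expect_equal(prof$match_cols, c(1L, 3L, 4L))
  all_gap <- photomarker:::new_reference_alignment(
    c(s1 = "--", s2 = "--"), "PR")
  expect_error(build_profile(all_gap), "match column")
})

test_that("profiles are deterministic and consensus scores grow with depth", {
  aln <- photomarker:::new_reference_alignment(
    c(s1 = "MKV", s2 = "MKV", s3 = "MRV"), "recA")
  expect_identical(build_profile(aln), build_profile(aln))
  for (N in c(2, 5, 20)) {
    rows <- stats::setNames(rep("MKV", N), paste0("s", seq_len(N)))
    prof <- build_profile(photomarker:::new_reference_alignment(rows, "PR"))
    expect_true(all(diag(prof$match_scores[, c("M", "K", "V")]) > 0))
  }
  score_at <- function(N) {
    rows <- stats::setNames(rep("MKV", N), paste0("s", seq_len(N)))
    build_profile(photomarker:::new_reference_alignment(rows, "PR")
                  )$match_scores[1, "M"]
  }
  expect_true(score_at(4) < score_at(8) && score_at(8) < score_at(50))
})

test_that("locate_fts maps anchor residues through gaps to match columns", {
  aln <- photomarker:::new_reference_alignment(
    c(anchor = "A-CDE", other = "AWCDE", third = "AWCDE"), "PR")
  # column 2 has 1 gap in 3 rows (fraction < 0.5): all 5 columns are match
  expect_equal(locate_fts(aln, "anchor", 2), 3)
  expect_equal(locate_fts(aln, "anchor", 1), 1)
  expect_error(locate_fts(aln, "anchor", 99), "beyond")
  expect_error(locate_fts(aln, "missing", 1), "not in alignment")
  # anchor residue on a non-match column fails with re-curation advice
  aln2 <- photomarker:::new_reference_alignment(
    c(anchor = "AW", b = "A-", c = "A-", d = "A-"), "PR")
  expect_error(locate_fts(aln2, "anchor", 2), "re-curate")
})

test_that("locate_fts inverts the column-to-ungapped back-map", {
  set.seed(42)
  chars <- sample(c(aa_alphabet(), "-", "-"), 40, replace = TRUE)
  anchor <- paste(chars, collapse = "")
  full <- paste(sample(aa_alphabet(), 40, replace = TRUE), collapse = "")
  aln <- photomarker:::new_reference_alignment(
    c(anchor = anchor, f1 = full, f2 = full), "PR")
  mc <- photomarker:::match_columns(photomarker:::aln_as_matrix(aln))
  residue_cols <- which(chars != "-")
  for (i in seq_along(residue_cols)) {
    if (!(residue_cols[i] %in% mc)) next
    expect_equal(mc[locate_fts(aln, "anchor", i)], residue_cols[i])
  }
})

test_that("clade trees load with cluster-map fallbacks and hard errors", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((l1:1,l2:1):1,(l3:1,(l4:1,l5:1):1):1);", tf)
  mf <- tempfile(fileext = ".tsv")
  writeLines(c("leaf_id\tcluster", "l1\tSAR11", "l2\tSAR11",
               "l3\tviral", "l4\tarchaeal", "l5\tenvironmental"), mf)
  ct <- load_clade_tree(tf, mf)
  expect_s3_class(ct, "clade_tree")
  expect_equal(length(ct$cluster_map), 5)
  expect_equal(unname(ct$cluster_map["l3"]), "viral")

  # partial map: missing leaf goes to "other" with a warning
  mf2 <- tempfile(fileext = ".tsv")
  writeLines(c("leaf_id\tcluster", "l1\tSAR11", "l2\tSAR11",
               "l3\tviral", "l4\tarchaeal"), mf2)
  expect_warning(ct2 <- load_clade_tree(tf, mf2), "l5")
  expect_equal(unname(ct2$cluster_map["l5"]), "other")

  # duplicate leaves are fatal
  tf2 <- tempfile(fileext = ".nwk")
  writeLines("((l1:1,l1:1):1,l3:1);", tf2)
  expect_error(load_clade_tree(tf2, mf), "duplicate")

  # map rows for absent leaves warn
  mf3 <- tempfile(fileext = ".tsv")
  writeLines(c("leaf_id\tcluster", "l1\tSAR11", "l2\tSAR11", "l3\tviral",
               "l4\tarchaeal", "l5\tviral", "ghost\tviral"), mf3)
  expect_warning(load_clade_tree(tf, mf3), "ghost")
})

test_that("profile TSV serialization round-trips", {
  aln <- photomarker:::new_reference_alignment(
    c(s1 = "MKVA", s2 = "MKVA", s3 = "MRVC"), "pufM")
  prof <- build_profile(aln, background = aa_background("codon"))
  prof$fts_column <- 2L
  prof$score_cutoff <- 12.5
  path <- tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$marker, "pufM")
  expect_equal(back$L_func, prof$L_func)
  expect_equal(back$match_scores, prof$match_scores, tolerance = 1e-12)
  expect_equal(back$background, prof$background, tolerance = 1e-12)
  expect_equal(back$fts_column, 2L)
  expect_equal(back$score_cutoff, 12.5)
})

test_that("codon background matches sense-codon multiplicities", {
  bg <- aa_background("codon")
  expect_equal(sum(bg), 1)
  expect_equal(unname(bg["L"]), 6 / 61)
  expect_equal(unname(bg["M"]), 1 / 61)
  expect_equal(unname(aa_background("uniform")), rep(0.05, 20))
})
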