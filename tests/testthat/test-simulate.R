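# Synthetic community generator: reference sets, read libraries, truth.

test_that("community_spec validates its invariants", {
  spec <- pr_only_community(c(0.6, 0.4), c("Q", "L"))
  expect_s3_class(spec, "community_spec")
  bad <- spec$taxa
  bad$abundance <- c(0.6, 0.5)
  expect_error(community_spec(bad), "sum to 1")
  bad2 <- spec$taxa
  bad2$len_PR <- c(750, 753)
  expect_error(community_spec(bad2), "identical across carrier")
  bad3 <- spec$taxa
  bad3$mult_PR <- c(-1, 1)
  expect_error(community_spec(bad3), "multipliers")
  bad4 <- spec$taxa
  bad4$has_recA <- FALSE
  expect_error(community_spec(bad4), "recA")
})

test_that("reference sets are seeded, forced at the FTS, and leaf-complete", {
  spec <- pr_only_community(c(0.5, 0.3, 0.2), c("Q", "L", "M"))
  rs1 <- generate_reference_set(spec, divergence = 0.05, seed = 7)
  rs2 <- generate_reference_set(spec, divergence = 0.05, seed = 7)
  expect_identical(rs1$alignments, rs2$alignments)
  expect_identical(rs1$genes, rs2$genes)
  expect_equal(sort(rs1$tree$tree$tip.label), sort(spec$taxa$taxon_id))
  # FTS residues forced per taxon
  for (i in 1:3) {
    prot <- strsplit(rs1$alignments$PR$rows[[spec$taxa$taxon_id[i]]], "")[[1]]
    expect_equal(prot[rs1$fts_position], spec$taxa$fts_residue[i])
  }
  # genes back-translate their proteins
  gene <- rs1$genes$PR[[1]]
  prot <- Biostrings::translate(Biostrings::DNAString(gene))
  expect_equal(as.character(prot), rs1$alignments$PR$rows[[1]])
  expect_error(generate_reference_set(spec, divergence = 0.6, seed = 1),
               "divergence")
})

test_that("error-free reads from a one-gene community are exact substrings", {
  taxa <- pr_only_community(1, "Q")$taxa
  taxa$has_PR <- FALSE
  spec <- community_spec(taxa, error_rate = 0, background_fraction = 0)
  rs <- generate_reference_set(spec, divergence = 0, seed = 2)
  rd <- simulate_reads(spec, rs, 200, "DNA", seed = 5)
  gene <- rs$genes$recA[[1]]
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(gene)))
  for (i in seq_len(200)) {
    read <- as.character(rd$reads[[i]])
    expect_true(grepl(read, gene, fixed = TRUE) ||
                  grepl(read, rc, fixed = TRUE))
  }
  expect_true(all(rd$truth$gene == "recA"))
  # recorded start matches the forward-strand substring
  fwd <- rd$truth$strand == "+"
  starts <- rd$truth$start[fwd]
  expect_true(all(substring(gene, starts, starts + 149) ==
                    as.character(rd$reads[fwd])))
})

test_that("identical seeds give identical libraries", {
  spec <- pr_only_community(c(0.7, 0.3), c("Q", "L"),
                            background_fraction = 0.5, error_rate = 0.01)
  rs <- generate_reference_set(spec, seed = 3)
  a <- simulate_reads(spec, rs, 500, "RNA", seed = 9)
  b <- simulate_reads(spec, rs, 500, "RNA", seed = 9)
  expect_identical(as.character(a$reads), as.character(b$reads))
  expect_identical(a$truth, b$truth)
})

test_that("RNA read counts follow length x expression weighting", {
  # single taxon, PR multiplier 26 vs recA 1: expected PR:recA read ratio
  # is 26 * (len_PR / len_recA)
  spec <- pr_only_community(1, "Q", mult_PR = 26)
  rs <- generate_reference_set(spec, seed = 4)
  rd <- simulate_reads(spec, rs, 50000, "RNA", seed = 21)
  tab <- table(rd$truth$gene)
  p_pr <- (26 * 750) / (26 * 750 + 1 * 1062)
  se <- sqrt(p_pr * (1 - p_pr) / 50000)
  expect_lt(abs(tab[["PR"]] / 50000 - p_pr), 3 * se)
})

test_that("library composition matches the multinomial across seeds", {
  spec <- pr_only_community(c(0.5, 0.5), c("Q", "L"),
                            background_fraction = 0.2)
  rs <- generate_reference_set(spec, seed = 6)
  w_gene <- 0.8 * c(0.5 * 750, 0.5 * 750, 0.5 * 1062, 0.5 * 1062) /
    (0.5 * 750 + 0.5 * 750 + 0.5 * 1062 + 0.5 * 1062)
  probs <- c(w_gene, 0.2)
  failures <- 0
  for (s in 1:20) {
    rd <- simulate_reads(spec, rs, 50000, "DNA", seed = 400 + s)
    key <- ifelse(rd$truth$gene == "background", "bg",
                  paste(rd$truth$gene, rd$truth$taxon))
    obs <- table(factor(key, levels = c("PR tx01", "PR tx02",
                                        "recA tx01", "recA tx02", "bg")))
    pval <- suppressWarnings(
      stats::chisq.test(as.integer(obs), p = probs)$p.value)
    if (pval < 0.001) failures <- failures + 1
  }
  expect_lte(failures, 1)
})

test_that("truth_summary expresses community parameters as estimands", {
  # all taxa carry PR -> normalized abundance 1
  spec <- pr_only_community(c(0.5, 0.5), c("Q", "L"))
  expect_equal(unname(truth_summary(spec)$norm_abundance["PR"]), 1)
  # 10 equal taxa, 9 with PR -> 0.9
  taxa <- pr_only_community(rep(0.1, 10), rep("Q", 10))$taxa
  taxa$has_PR[10] <- FALSE
  tr <- truth_summary(community_spec(taxa))
  expect_equal(unname(tr$norm_abundance["PR"]), 0.9)
  # two equal taxa, Q and L -> blue fraction 0.5
  spec3 <- pr_only_community(c(0.5, 0.5), c("Q", "L"))
  expect_equal(truth_summary(spec3)$blue_fraction, 0.5)
  # rare non-blue-green residues excluded from the fraction
  spec4 <- pr_only_community(c(0.4, 0.4, 0.2), c("Q", "L", "V"))
  expect_equal(truth_summary(spec4)$blue_fraction, 0.5)
})

test_that("the survey-scale example community encodes its targets", {
  spec <- example_community()
  tr <- truth_summary(spec)
  expect_equal(unname(tr$norm_abundance[c("PR", "psaA", "pufM")]),
               c(0.9, 0.2, 0.1))
  expect_equal(unname(tr$rna_dna_ratio[c("PR", "psaA", "pufM")]),
               c(26.2, 11, 0.013), tolerance = 1e-9)
  expect_equal(unname(tr$cluster_transcript_fraction["SAR11"]), 0.52,
               tolerance = 1e-9)
  expect_equal(tr$blue_fraction, 0.57 / 0.9, tolerance = 1e-9)
})
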