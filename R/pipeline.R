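# Pipeline orchestration: validated YAML configuration and the end-to-end
# simulate -> recruit -> place -> quantify -> stats driver with TSV outputs.

.default_config <- function() {
  list(seed = 1L, outdir = "photomarker_out", tau = 0.25,
       profile = list(pseudocount = 1, gap_open = 4, gap_extend = 1,
                      background = "codon"),
       recruit = list(k = 4, target_fpr = 1e-3, min_fragment_len = 15,
                      decoy_count = 20000),
       place = list(min_cols = 20, min_margin = 0.01),
       stats = list(spearman_pairs = list(
         list(var1 = "chl_a_ug_per_L", var2 = "blue_fraction"))))
}

.merge_defaults <- function(x, d) {
  for (k in names(d)) {
    if (is.null(x[[k]])) x[[k]] <- d[[k]]
    else if (is.list(d[[k]]) && is.list(x[[k]]))
      x[[k]] <- .merge_defaults(x[[k]], d[[k]])
  }
  x
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent list), fills defaults
#' (`k = 4`, `target_fpr = 1e-3`, `tau = 0.25`, placement and profile
#' parameters), range-checks values and reports *all* violations in one
#' error. Unknown top-level keys yield a warning. The configuration drives
#' either a simulation run (`simulation:` with a `taxa:` table or
#' `community: example`) plus a `samples:` metadata list (columns mirroring
#' sample_id / station / season / chl_a_ug_per_L), with optional per-sample
#' `abundance:` overrides and `dna:`/`rna:` switches.
#'
#' @param x Path to a YAML file, or a configuration list.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  known <- c("seed", "outdir", "tau", "profile", "recruit", "place",
             "stats", "simulation", "samples")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("unknown configuration keys ignored: ",
            paste(unknown, collapse = ", "))
  cfg <- .merge_defaults(cfg[intersect(names(cfg), known)], .default_config())
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be one integer")
  chk(cfg$recruit$target_fpr > 0 && cfg$recruit$target_fpr <= 0.1,
      "recruit$target_fpr must be in (0, 0.1]")
  chk(cfg$recruit$k >= 3, "recruit$k must be >= 3")
  chk(cfg$tau > 0, "tau must be positive")
  chk(cfg$profile$pseudocount > 0, "profile$pseudocount must be positive")
  chk(cfg$profile$background %in% c("uniform", "codon"),
      "profile$background must be 'uniform' or 'codon'")
  chk(cfg$place$min_cols >= 1, "place$min_cols must be >= 1")
  chk(!is.null(cfg$simulation), "a simulation section is required")
  if (!is.null(cfg$simulation)) {
    sim <- .merge_defaults(cfg$simulation,
                           list(read_length = 150, error_rate = 0.005,
                                background_fraction = 0.8, divergence = 0.1,
                                fts_position = 105, n_reads_dna = 20000,
                                n_reads_rna = 20000))
    chk(!is.null(sim$taxa) || identical(sim$community, "example"),
        "simulation needs a taxa table or community: example")
    chk(sim$divergence < 0.5, "simulation$divergence must be < 0.5")
    cfg$simulation <- sim
  }
  chk(!is.null(cfg$samples) && length(cfg$samples) >= 1,
      "at least one sample is required")
  if (!is.null(cfg$samples)) {
    ids <- vapply(cfg$samples, function(s) as.character(s$sample_id %||% NA),
                  "")
    chk(!anyNA(ids), "every sample needs a sample_id")
    chk(!anyDuplicated(ids), "duplicated sample_id")
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.community_from_config <- function(sim) {
  if (identical(sim$community, "example"))
    return(example_community(read_length = sim$read_length,
                             error_rate = sim$error_rate,
                             background_fraction = sim$background_fraction))
  taxa <- do.call(rbind, lapply(sim$taxa, function(t)
    as.data.frame(t, stringsAsFactors = FALSE)))
  community_spec(taxa, read_length = sim$read_length,
                 error_rate = sim$error_rate,
                 background_fraction = sim$background_fraction)
}

.apply_abundance_override <- function(spec, override) {
  if (is.null(override)) return(spec)
  ab <- unlist(override)
  taxa <- spec$taxa
  idx <- match(names(ab), taxa$taxon_id)
  if (anyNA(idx)) stop("abundance override names unknown taxa: ",
                       paste(names(ab)[is.na(idx)], collapse = ", "))
  taxa$abundance[idx] <- as.numeric(ab)
  taxa$abundance <- taxa$abundance / sum(taxa$abundance)
  community_spec(taxa, spec$read_length, spec$error_rate,
                 spec$background_fraction)
}

.quantify_library <- function(rec, profiles, refset, place_cfg) {
  markers <- names(rec$counts)
  lens <- vapply(profiles[markers], `[[`, 0L, "L_func")
  norm <- if (!is.na(rec$counts["recA"]) && "recA" %in% markers)
    normalized_abundance(rec$counts, lens,
                         rec$counts[["recA"]], lens[["recA"]])
  else rep(NA_real_, length(markers))
  clusters <- NULL
  assignments <- NULL
  if ("PR" %in% markers && !is.null(refset$tree) &&
      nrow(rec$recruited$PR) > 0) {
    assignments <- assign_leaves(rec$recruited$PR, refset$alignments$PR,
                                 min_cols = place_cfg$min_cols,
                                 min_margin = place_cfg$min_margin)
    clusters <- aggregate_clusters(assignments, refset$tree)
  }
  even <- if (!is.null(clusters) && nrow(clusters))
    shannon_evenness(clusters$count) else shannon_evenness(integer(0))
  list(counts = rec$counts, lens = lens, n_reads = rec$n_reads,
       norm_abundance = norm, clusters = clusters,
       assignments = assignments, evenness = even, recruited = rec$recruited)
}

#' Run the full pipeline from a configuration
#'
#' Builds the community and reference set, constructs and calibrates the
#' four marker profiles, then for every sample and library simulates reads,
#' recruits them, places PR reads on the clade tree, and computes
#' normalized abundances, RNA:DNA ratios, cluster fractions, evenness and
#' tuning counts; finally runs the cross-sample statistics (paired
#' one-sided evenness tests, the chlorophyll tuning trend, and the declared
#' Spearman/FDR family). All tables are written as TSV under `outdir`
#' together with a machine-readable `run_info.yaml`; a rerun with the same
#' seed is bit-identical.
#'
#' @param config A `run_config` from [validate_config()] (or a path/list
#'   accepted by it).
#' @param outdir Output directory override; `NULL` suppresses file output.
#' @return Invisibly, a list of the result tables (`abundance`, `ratios`,
#'   `clusters`, `evenness`, `tuning`, `tests`, `trend`, `spearman`,
#'   `samples`, plus the `profiles`, `cutoffs` and `refset` used).
#' @export
run_pipeline <- function(config, outdir = config$outdir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  seed <- as.integer(config$seed)
  sim <- config$simulation
  base_spec <- .community_from_config(sim)
  refset <- generate_reference_set(base_spec, divergence = sim$divergence,
                                   seed = derive_seed(seed, 1),
                                   fts_position = sim$fts_position)
  pc <- config$profile
  profiles <- lapply(refset$alignments, build_profile,
                     pseudocount = pc$pseudocount, gap_open = pc$gap_open,
                     gap_extend = pc$gap_extend,
                     background = aa_background(pc$background))
  if ("PR" %in% names(profiles))
    profiles$PR$fts_column <- refset$fts_position
  rc <- config$recruit
  cutoffs <- calibrate_cutoffs(profiles, target_fpr = rc$target_fpr,
                               read_length = base_spec$read_length,
                               decoy_count = rc$decoy_count,
                               seed = derive_seed(seed, 10))
  for (m in names(profiles)) profiles[[m]]$score_cutoff <- cutoffs[[m]]

  samples <- do.call(rbind, lapply(config$samples, function(s)
    data.frame(sample_id = s$sample_id, station = s$station %||% NA,
               season = s$season %||% NA,
               chl_a_ug_per_L = as.numeric(s$chl_a_ug_per_L %||% NA),
               stringsAsFactors = FALSE)))
  abundance <- ratios <- clusters <- evenness <- tuning <- NULL
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    spec_s <- .apply_abundance_override(base_spec, s$abundance)
    libs <- list()
    for (lib in c("DNA", "RNA")) {
      want <- if (lib == "DNA") s$dna %||% TRUE else s$rna %||% TRUE
      if (!isTRUE(want)) next
      n_reads <- if (lib == "DNA") sim$n_reads_dna else sim$n_reads_rna
      rd <- simulate_reads(spec_s, refset, n_reads, library = lib,
                           seed = derive_seed(seed,
                                              100 + 10 * i +
                                                (lib == "RNA")))
      rec <- recruit_sample(rd$reads, profiles, cutoffs, k = rc$k,
                            min_len = rc$min_fragment_len)
      libs[[lib]] <- .quantify_library(rec, profiles, refset, config$place)
      q <- libs[[lib]]
      abundance <- rbind(abundance, data.frame(
        sample_id = s$sample_id, library = lib, total_reads = q$n_reads,
        marker = names(q$counts), count = as.integer(q$counts),
        profile_len = as.integer(q$lens),
        norm_abundance = as.numeric(q$norm_abundance),
        stringsAsFactors = FALSE, row.names = NULL))
      if (!is.null(q$clusters) && nrow(q$clusters))
        clusters <- rbind(clusters, cbind(sample_id = s$sample_id,
                                          library = lib, q$clusters))
      evenness <- rbind(evenness, data.frame(
        sample_id = s$sample_id, library = lib, H = q$evenness$H,
        S = q$evenness$S, J = q$evenness$J, stringsAsFactors = FALSE))
      if (lib == "DNA" && "PR" %in% names(q$recruited)) {
        tc <- classify_fts(q$recruited$PR, refset$fts_position)
        tuning <- rbind(tuning, data.frame(
          sample_id = s$sample_id, n_blue = tc$n_blue, n_green = tc$n_green,
          n_other = tc$n_other, n_covering = tc$n_covering,
          blue_fraction = tc$blue_fraction, stringsAsFactors = FALSE))
      }
    }
    for (m in names(profiles)) {
      have_both <- !is.null(libs$DNA) && !is.null(libs$RNA)
      rr <- if (have_both)
        rna_dna_ratio(libs$RNA$counts[[m]], libs$RNA$n_reads,
                      libs$DNA$counts[[m]], libs$DNA$n_reads)
      else list(rna_rel = NA_real_, dna_rel = NA_real_, ratio = NA_real_,
                undefined = TRUE)
      ratios <- rbind(ratios, data.frame(
        sample_id = s$sample_id, marker = m,
        rna_rel = rr$rna_rel, dna_rel = rr$dna_rel, ratio = rr$ratio,
        undefined = rr$undefined, stringsAsFactors = FALSE))
    }
  }
  # cross-sample statistics
  tests <- NULL
  wide_j <- merge(evenness[evenness$library == "DNA", c("sample_id", "J")],
                  evenness[evenness$library == "RNA", c("sample_id", "J")],
                  by = "sample_id", suffixes = c("_dna", "_rna"))
  wide_j <- wide_j[complete.cases(wide_j), , drop = FALSE]
  if (nrow(wide_j) >= 2) {
    tt <- paired_t_one_sided(wide_j$J_dna, wide_j$J_rna, "greater")
    wt <- wilcoxon_signed_rank_paired(wide_j$J_dna, wide_j$J_rna, "greater")
    tests <- data.frame(
      test = c("evenness_paired_t", "evenness_wilcoxon"),
      statistic = c(tt$statistic, wt$statistic),
      p_value = c(tt$p_value, wt$p_value),
      n = c(tt$n_pairs, wt$n_pairs),
      direction = "greater",
      degenerate = c(tt$degenerate, wt$degenerate),
      stringsAsFactors = FALSE)
  }
  tuning_cols <- if (!is.null(tuning))
    tuning[, c("sample_id", "blue_fraction")]
  else data.frame(sample_id = character(), blue_fraction = numeric())
  summary_tab <- merge(samples, tuning_cols, by = "sample_id", all.x = TRUE)
  pr_ratio <- ratios[ratios$marker == "PR", c("sample_id", "ratio")]
  names(pr_ratio)[2] <- "ratio_PR"
  summary_tab <- merge(summary_tab, pr_ratio, by = "sample_id", all.x = TRUE)
  trend <- fit_tuning_trend(
    data.frame(chl = summary_tab$chl_a_ug_per_L,
               blue_fraction = summary_tab$blue_fraction),
    tau = config$tau)
  sp_pairs <- do.call(rbind, lapply(config$stats$spearman_pairs, function(p)
    data.frame(var1 = p$var1, var2 = p$var2, stringsAsFactors = FALSE)))
  spearman <- if (!is.null(sp_pairs) &&
                  all(unlist(sp_pairs) %in% names(summary_tab)))
    spearman_fdr(summary_tab, sp_pairs) else NULL
  out <- list(abundance = abundance, ratios = ratios, clusters = clusters,
              evenness = evenness, tuning = tuning, tests = tests,
              trend = trend, spearman = spearman, samples = summary_tab,
              profiles = profiles, cutoffs = cutoffs, refset = refset)
  if (!is.null(outdir)) write_pipeline_outputs(out, config, outdir)
  invisible(out)
}

write_tsv <- function(df, path) {
  if (is.null(df)) return(invisible(NULL))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(res, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$abundance, file.path(outdir, "abundance.tsv"))
  write_tsv(res$ratios, file.path(outdir, "ratios.tsv"))
  write_tsv(res$clusters, file.path(outdir, "clusters.tsv"))
  write_tsv(res$evenness, file.path(outdir, "evenness.tsv"))
  write_tsv(res$tuning, file.path(outdir, "tuning.tsv"))
  write_tsv(res$tests, file.path(outdir, "stats_tests.tsv"))
  write_tsv(res$spearman, file.path(outdir, "spearman.tsv"))
  tr <- res$trend
  write_tsv(data.frame(fitted = tr$fitted, slope = tr$slope,
                       intercept = tr$intercept, r_squared = tr$r_squared,
                       n_points = tr$n_points, tau = tr$tau,
                       above_mean_blue = tr$above_mean_blue,
                       n_above = tr$n_above),
            file.path(outdir, "trend.tsv"))
  info <- list(package = "photomarker",
               version = as.character(utils::packageVersion("photomarker")),
               seed = config$seed, tau = config$tau,
               profile = config$profile, recruit = config$recruit,
               place = config$place,
               cutoffs = as.list(res$cutoffs))
  yaml::write_yaml(info, file.path(outdir, "run_info.yaml"))
  invisible(outdir)
}
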