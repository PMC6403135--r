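# End-to-end synthetic-study driver: simulate, summarise, call DMCs/DMRs,
# annotate, profile, correlate, detect rhythms, integrate, and score
# everything against the planted truth. The analysis/ scripts and the
# acceptance script are thin wrappers around this.

#' Run the full daily-methylome analysis on a simulated study
#'
#' Simulates a genome, per-sample methylomes with planted differential
#' regions, and an expression matrix with planted rhythms and gene-body
#' coupling; then runs every pipeline stage and scores the calls against
#' the truth ledger. All randomness derives from `seed`; rerunning with
#' the same seed and parameters reproduces every output byte for byte.
#'
#' @param seed Integer seed.
#' @param out_dir Optional directory: primary TSV/BED outputs are written
#'   there.
#' @param n_chrom,chrom_length,n_genes,n_tes Genome scale.
#' @param coverage_mean Mean per-site read coverage.
#' @param n_planted_dmrs,planted_delta,planted_width Planted-region layout.
#' @param rhythmic_fraction,amplitude_range,noise_sd Expression simulation.
#' @param coupling_rho Target Spearman correlation between gene-body
#'   methylation and expression.
#' @param alpha,min_diff_dmc,min_diff_dmr,min_dmcs,max_gap DMC/DMR
#'   thresholds (defaults 0.05, 0.2, 0.1, 3, 300).
#' @return List with every intermediate and result table (see the analysis
#'   scripts for the catalogue).
#' @export
run_daily_methylome_analysis <- function(seed = 1, out_dir = NULL,
                                         n_chrom = 2, chrom_length = 2e5,
                                         n_genes = 100, n_tes = 40,
                                         coverage_mean = 30,
                                         n_planted_dmrs = 12,
                                         planted_delta = 0.4,
                                         planted_width = 800,
                                         rhythmic_fraction = 0.12,
                                         amplitude_range = c(1, 3),
                                         noise_sd = 0.5,
                                         coupling_rho = 0.5,
                                         alpha = 0.05, min_diff_dmc = 0.2,
                                         min_diff_dmr = 0.1, min_dmcs = 3,
                                         max_gap = 300) {
  set.seed(seed)
  design <- sample_design()
  sim <- simulate_genome(n_chrom = n_chrom, chrom_length = chrom_length,
                         n_genes = n_genes, n_tes = n_tes)
  planted <- if (n_planted_dmrs > 0) {
    plant_default_dmrs(sim, design, n = n_planted_dmrs,
                       width = planted_width, delta = planted_delta)
  } else NULL
  simmeth <- simulate_methylome(sim, design, planted_dmrs = planted,
                                coverage_mean = coverage_mean)
  r_hat <- estimate_nonconversion(simmeth$controls$n_converted,
                                  simmeth$controls$n_unconverted)
  # genome-wide summary on the pooled study (all samples)
  pooled <- simmeth$mset$sites
  pooled$n_meth <- as.integer(rowSums(simmeth$mset$n_meth))
  pooled$n_unmeth <- as.integer(rowSums(simmeth$mset$n_total) -
                                  rowSums(simmeth$mset$n_meth))
  mc_flags <- call_methylated_sites(pooled, r_hat)
  summary_tab <- genome_summary(pooled, mc_flags, r = r_hat)
  windows <- sliding_windows(pooled, sim$chrom_lengths)
  # differential methylation per comparison
  dmcs <- do.call(rbind, lapply(design$comparisons$id, function(cmp) {
    call_dmcs(simmeth$mset, design, cmp, r = r_hat, alpha = alpha,
              min_diff = min_diff_dmc)
  }))
  dmrs <- do.call(rbind, lapply(design$comparisons$id, function(cmp) {
    call_dmrs(dmcs[dmcs$comparison == cmp, , drop = FALSE], simmeth$mset,
              design, r = r_hat, min_diff = min_diff_dmr,
              min_dmcs = min_dmcs, max_gap = max_gap)
  }))
  dmr_stats <- dmr_summary(dmrs, dmcs)
  dmr_recovery <- if (!is.null(planted)) {
    evaluate_dmr_recovery(dmrs, simmeth$truth)
  } else NULL
  # annotation
  index <- build_feature_index(sim$genes, sim$tes, sim$chrom_lengths)
  dmr_features <- if (nrow(dmrs)) assign_features(dmrs, index) else NULL
  dmc_features <- if (nrow(dmcs)) assign_features(dmcs, index) else NULL
  dmgs <- differentially_methylated_genes(dmrs, sim$genes, sim$chrom_lengths)
  feature_levels <- feature_methylation_profile(pooled, index, r = r_hat)
  dmc_metagene <- if (nrow(dmcs)) metagene_profile(dmcs, sim$genes) else NULL
  # expression, rhythm, integration; genes near planted regions respond
  # anti-phase (methylation up -> expression down), which is itself a
  # daily signal the rhythm detector can find
  response <- plant_expression_response(sim, design, planted)
  simexpr <- simulate_expression(
    sim$genes, design, rhythmic_fraction = rhythmic_fraction,
    amplitude_range = amplitude_range, noise_sd = noise_sd,
    coupling = list(scores = simmeth$truth$gene_body_factor,
                    rho = coupling_rho, sign = 1),
    group_shifts = response$group_shifts)
  rhythm_fits <- detect_rhythmic_genes(simexpr$expr, design$timepoints)
  rhythm_recovery <- evaluate_rhythm_recovery(rhythm_fits, simexpr$truth)
  body_levels <- gene_region_methylation(simmeth$mset, design, sim$genes,
                                         region = "gene_body", r = r_hat)
  correlation <- methylation_expression_correlation(body_levels,
                                                    simexpr$expr, design)
  integration <- integrate_dmr_rhythm(rhythm_fits, dmgs$links, simexpr$expr,
                                      design)
  params <- list(alpha = alpha, min_diff_dmc = min_diff_dmc,
                 min_diff_dmr = min_diff_dmr, min_dmcs = min_dmcs,
                 max_gap = max_gap, coverage_mean = coverage_mean,
                 n_planted_dmrs = n_planted_dmrs,
                 planted_delta = planted_delta)
  res <- list(seed = seed, params = params, design = design, sim = sim,
              simmeth = simmeth,
              r_hat = r_hat, pooled = pooled, summary = summary_tab,
              windows = windows, dmcs = dmcs, dmrs = dmrs,
              dmr_stats = dmr_stats, dmr_recovery = dmr_recovery,
              dmr_features = dmr_features, dmc_features = dmc_features,
              dmgs = dmgs, feature_levels = feature_levels,
              dmc_metagene = dmc_metagene, expr = simexpr$expr,
              expr_truth = simexpr$truth, rhythm_fits = rhythm_fits,
              rhythm_recovery = rhythm_recovery, body_levels = body_levels,
              correlation = correlation, integration = integration)
  if (!is.null(out_dir)) write_analysis_outputs(res, out_dir)
  res
}

#' Write the primary tabular outputs of a pipeline run
#'
#' Deterministic TSV/BED files: genome summary, per-window levels, DMCs,
#' DMRs (BED6+), DMR statistics, feature levels, metagene profile, rhythm
#' fits, correlation table, quadrant counts, and the run manifest.
#'
#' @param res Result list from [run_daily_methylome_analysis()].
#' @param out_dir Output directory (created if needed).
#' @export
write_analysis_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) {
    if (!is.null(x)) {
      utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  tsv(res$summary, "genome_summary.tsv")
  tsv(res$windows, "window_levels.tsv")
  tsv(res$dmcs, "dmcs.tsv")
  write_dmr_bed(res$dmrs, file.path(out_dir, "dmrs.bed"))
  tsv(res$dmr_stats, "dmr_summary.tsv")
  tsv(res$feature_levels, "feature_levels.tsv")
  tsv(res$dmc_metagene, "dmc_metagene.tsv")
  tsv(res$rhythm_fits, "rhythm_fits.tsv")
  tsv(res$correlation$correlations, "methylation_expression_correlation.tsv")
  tsv(res$integration$per_comparison, "rhythm_dmr_quadrants.tsv")
  write_expression_matrix(res$expr, file.path(out_dir, "expression.tsv"))
  manifest <- c(list(seed = res$seed, nonconversion_rate_hat = res$r_hat),
                res$params)
  write_config(manifest, file.path(out_dir, "run_manifest.txt"))
  invisible(out_dir)
}
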