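test_that("genome simulation is seed-deterministic down to the files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- simulate_genome(n_chrom = 1, chrom_length = 30000, n_genes = 6,
                        n_tes = 3, seed = 5, out_dir = d1)
  g2 <- simulate_genome(n_chrom = 1, chrom_length = 30000, n_genes = 6,
                        n_tes = 3, seed = 5, out_dir = d2)
  for (f in c("genome.fa", "genes.gff3", "tes.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # annotations are internally consistent and within bounds
  g <- g1$genes$genes
  expect_true(all(g$start >= 1 & g$end <= 30000))
  expect_true(all(g1$genes$exons$start >= g$start[match(g1$genes$exons$gene_id,
                                                        g$gene_id)]))
  # genes never overlap each other
  if (nrow(g) > 1) {
    o <- order(g$start)
    expect_true(all(g$start[o][-1] > g$end[o][-nrow(g)]))
  }
})

test_that("simulated annotations survive the round trip through their files", {
  d <- withr::local_tempdir()
  sim <- simulate_genome(n_chrom = 1, chrom_length = 40000, n_genes = 8,
                         n_tes = 4, seed = 9, out_dir = d)
  gm <- read_gene_models(file.path(d, "genes.gff3"))
  expect_equal(gm$genes[, c("gene_id", "chrom", "start", "end", "strand",
                            "tss", "tes")],
               sim$genes$genes[, c("gene_id", "chrom", "start", "end",
                                   "strand", "tss", "tes")],
               ignore_attr = TRUE)
  te <- read_te_bed(file.path(d, "tes.bed"))
  expect_equal(te, sim$tes, ignore_attr = TRUE)
  fa <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_equal(as.character(fa), as.character(sim$genome))
})

test_that("degenerate genome requests behave as specified", {
  g0 <- simulate_genome(n_chrom = 1, chrom_length = 5000, n_genes = 0,
                        n_tes = 0, seed = 1)
  expect_equal(nrow(g0$genes$genes), 0)
  expect_equal(Biostrings::width(g0$genome), 5000)
  expect_error(simulate_genome(n_chrom = 1, chrom_length = 10000,
                               n_genes = 50, seed = 1),
               "too densely packed")
})

test_that("planted regions shift group levels by the planted effect", {
  design <- sample_design()
  sim <- simulate_genome(n_chrom = 1, chrom_length = 30000, n_genes = 5,
                         n_tes = 2, seed = 2)
  planted <- data.frame(comparison = "G2vG1", chrom = "Chr01", start = 5000L,
                        end = 5800L, delta = 0.4, direction = "hyper",
                        contexts = "CHH", stringsAsFactors = FALSE)
  sm <- simulate_methylome(sim, design, planted_dmrs = planted,
                           coverage_mean = 200, sample_jitter_sd = 0,
                           nonconversion_rate = 0, seed = 3)
  in_region <- sm$mset$sites$pos >= 5000 & sm$mset$sites$pos <= 5800 &
    sm$mset$sites$context == "CHH"
  lvl <- function(grp) {
    m <- rowSums(sm$mset$n_meth[in_region, design$groups[[grp]]])
    t <- rowSums(sm$mset$n_total[in_region, design$groups[[grp]]])
    sum(m) / sum(t)
  }
  expect_equal(lvl("G2") - lvl("G1"), 0.4, tolerance = 0.03)
  # truth ledger carries the induced hypo effect in the next comparison too
  eff <- sm$truth$expected_effects
  expect_setequal(eff$comparison, c("G2vG1", "G3vG2"))
  expect_setequal(eff$direction, c("hyper", "hypo"))
  # planting outside the genome is rejected
  bad <- planted; bad$end <- 99999L
  expect_error(simulate_methylome(sim, design, planted_dmrs = bad),
               "outside the simulated genome")
})

test_that("lambda spike-in counts follow the non-conversion rate", {
  design <- sample_design()
  sim <- simulate_genome(n_chrom = 1, chrom_length = 2000, n_genes = 0,
                         n_tes = 0, seed = 4)
  sm <- simulate_methylome(sim, design, nonconversion_rate = 0.01,
                           lambda_total = 10000, seed = 5)
  # binomial mean 100, sd ~ 10: all samples within 4 sigma
  expect_true(all(abs(sm$controls$n_unconverted - 100) < 40))
  r_hat <- estimate_nonconversion(sm$controls$n_converted,
                                  sm$controls$n_unconverted)
  expect_lt(abs(r_hat - 0.01), 0.002)
})

test_that("methylome simulation is seed-deterministic", {
  design <- sample_design()
  sim <- simulate_genome(n_chrom = 1, chrom_length = 20000, n_genes = 3,
                         n_tes = 1, seed = 6)
  sm1 <- simulate_methylome(sim, design, seed = 7)
  sm2 <- simulate_methylome(sim, design, seed = 7)
  expect_identical(sm1$mset$n_meth, sm2$mset$n_meth)
  expect_identical(sm1$mset$n_total, sm2$mset$n_total)
  expect_identical(sm1$controls, sm2$controls)
})

test_that("truth ledger round-trips through its TSV + manifest form", {
  design <- sample_design()
  sim <- simulate_genome(n_chrom = 1, chrom_length = 30000, n_genes = 5,
                         n_tes = 2, seed = 2)
  planted <- plant_default_dmrs(sim, design, n = 3)
  sm <- simulate_methylome(sim, design, planted_dmrs = planted, seed = 3)
  se <- simulate_expression(sim$genes, design, seed = 4,
                            coupling = list(scores = sm$truth$gene_body_factor))
  truth <- sm$truth
  truth$rhythmic_genes <- se$truth$rhythmic_genes
  truth$couplings <- se$truth$couplings
  d <- withr::local_tempdir()
  write_simulation_truth(truth, d)
  back <- read_simulation_truth(d)
  expect_equal(back$planted_dmrs, truth$planted_dmrs, ignore_attr = TRUE)
  expect_equal(back$expected_effects, truth$expected_effects,
               ignore_attr = TRUE)
  expect_equal(back$baseline_levels, truth$baseline_levels,
               tolerance = 1e-12)
  expect_equal(back$nonconversion_rate, truth$nonconversion_rate)
  expect_equal(back$rhythmic_genes, truth$rhythmic_genes, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("expression simulation: null amplitudes stay null, seeds reproduce", {
  design <- sample_design()
  ids <- sprintf("g%03d", 1:300)
  se0 <- simulate_expression(ids, design, rhythmic_fraction = 0, seed = 8)
  rf <- detect_rhythmic_genes(se0$expr, design$timepoints)
  expect_lte(sum(rf$rhythmic), 3)      # flat genes: essentially no calls
  se0b <- simulate_expression(ids, design, rhythmic_fraction = 0, seed = 8)
  expect_identical(se0$expr, se0b$expr)
  expect_error(simulate_expression(ids, design, rhythmic_fraction = 1.4),
               "rhythmic_fraction")
})

test_that("pooled context means converge to the configured baselines", {
  design <- sample_design(groups = list(G1 = c("s1", "s2")),
                          comparisons = data.frame(group_a = character(),
                                                   group_b = character()),
                          timepoints = c(s1 = 0, s2 = 4))
  sim <- simulate_genome(n_chrom = 1, chrom_length = 1.2e5, n_genes = 25,
                         n_tes = 10, seed = 10)
  sm <- simulate_methylome(sim, design, coverage_mean = 30, seed = 11)
  pooled <- sm$mset$sites
  pooled$n_meth <- as.integer(rowSums(sm$mset$n_meth))
  pooled$n_unmeth <- as.integer(rowSums(sm$mset$n_total)) - pooled$n_meth
  tab <- genome_summary(pooled, r = sm$r)
  gen <- tab[tab$chrom == "genome", ]
  got <- gen$level[match(c("CG", "CHG", "CHH"), gen$context)]
  expect_lt(max(abs(got - c(0.4399, 0.2984, 0.1157))), 0.01)
})
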