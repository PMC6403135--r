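#!/usr/bin/env Rscript
# Step 1: generate the synthetic study.
#
# Two 200 kb chromosomes, 100 genes, 40 TEs; nine leaf samples over 48 h
# (LD day then CL free-run) grouped G1..G5 with four consecutive-group
# comparisons; planted CHH differential regions (delta = 0.4) on groups
# G2/G3/G4; planted 24 h rhythms (12% of genes) and positive gene-body
# methylation/expression coupling (Spearman 0.5). Writes the raw study
# inputs exactly as a sequencing provider would deliver them, plus the
# truth ledger used later for scoring.

library(methylrhythm)

seed <- 1
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

set.seed(seed)
design <- sample_design()
print(design)

sim <- simulate_genome(seed = seed, out_dir = out)
cat("genome:", length(sim$genome), "chromosomes,",
    sum(Biostrings::width(sim$genome)), "bp;",
    nrow(sim$genes$genes), "genes,", nrow(sim$tes), "TEs\n")

planted <- plant_default_dmrs(sim, design, n = 12, width = 800, delta = 0.4)
simmeth <- simulate_methylome(sim, design, planted_dmrs = planted,
                              coverage_mean = 30, seed = seed + 1L)
report_paths <- write_sim_methylome(simmeth, out)
cat("methylome:", nrow(simmeth$mset$sites), "cytosines x",
    length(simmeth$mset$samples), "samples;",
    nrow(simmeth$truth$expected_effects), "expected differential effects\n")

# genes near planted regions respond anti-phase in expression; the shift
# is itself a daily signal, so these genes are rhythmic in their own right
response <- plant_expression_response(sim, design, planted)
se <- simulate_expression(sim$genes, design, rhythmic_fraction = 0.12,
                          coupling = list(scores = simmeth$truth$gene_body_factor,
                                          rho = 0.5),
                          group_shifts = response$group_shifts,
                          seed = seed + 2L)
write_expression_matrix(se$expr, file.path(out, "expression.tsv"))
cat("expression:", nrow(se$expr), "genes;",
    nrow(se$truth$rhythmic_genes), "planted rhythmic genes\n")

truth <- simmeth$truth
truth$rhythmic_genes <- se$truth$rhythmic_genes
truth$couplings <- se$truth$couplings
truth$expression_shifts <- se$truth$expression_shifts
write_simulation_truth(truth, file.path(out, "truth"))
write_config(c(seed = seed, coverage_mean = 30, planted_delta = 0.4,
               rhythmic_fraction = 0.12, coupling_rho = 0.5),
             file.path(out, "sim_config.txt"))
cat("wrote study inputs and truth ledger under", out, "\n")
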