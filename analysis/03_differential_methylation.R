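#!/usr/bin/env Rscript
# Step 3: DMC and DMR calling.
#
# Per comparison: pool counts within groups, Fisher exact test per
# covered position, BH over all tested positions, keep q < 0.05 and
# |corrected level difference| > 0.2 as DMCs; cluster same-direction DMCs
# (gap < 300 bp, >= 3 members) and keep regions whose pooled level
# difference exceeds 0.1 as DMRs. Scores the calls against the truth
# ledger.

library(methylrhythm)

simdir <- "results/sim"
out <- "results/differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- sample_design()
reports <- lapply(setNames(nm = design$samples), function(s) {
  read_cytosine_report(file.path(simdir, paste0(s, ".cytosine_report.tsv")))
})
mset <- methylome_set(reports)
controls <- read.delim(file.path(simdir, "lambda_controls.tsv"))
r_hat <- estimate_nonconversion(controls$n_converted, controls$n_unconverted)

dmcs <- do.call(rbind, lapply(design$comparisons$id, function(cmp) {
  d <- call_dmcs(mset, design, cmp, r = r_hat, alpha = 0.05, min_diff = 0.2)
  cat(sprintf("%s: %d positions tested, %d skipped, %d DMCs\n", cmp,
              attr(d, "n_tested"), attr(d, "n_skipped"), nrow(d)))
  d
}))
write.table(dmcs, file.path(out, "dmcs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

dmrs <- do.call(rbind, lapply(design$comparisons$id, function(cmp) {
  call_dmrs(dmcs[dmcs$comparison == cmp, , drop = FALSE], mset, design,
            r = r_hat, min_diff = 0.1, min_dmcs = 3, max_gap = 300)
}))
write_dmr_bed(dmrs, file.path(out, "dmrs.bed"))

stats <- dmr_summary(dmrs, dmcs)
write.table(stats, file.path(out, "dmr_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ov <- stats[stats$comparison == "overall", ]
cat(sprintf("DMRs: %d (%d hypo / %d hyper, ratio %.2f); DMC contexts: CG %.1f%%, CHG %.1f%%, CHH %.1f%%\n",
            ov$n_dmr, ov$n_hypo, ov$n_hyper, ov$hypo_hyper_ratio,
            ov$pct_cg, ov$pct_chg, ov$pct_chh))

truth <- read_simulation_truth(file.path(simdir, "truth"))
rec <- evaluate_dmr_recovery(dmrs, truth)
cat(sprintf("recovery vs truth: sensitivity %.2f, precision %.2f (%d/%d expected effects)\n",
            rec$sensitivity, rec$precision, rec$n_recovered, rec$n_truth))
write_config(c(alpha = 0.05, min_diff_dmc = 0.2, min_diff_dmr = 0.1,
               min_dmcs = 3, max_gap = 300, r_hat = r_hat,
               sensitivity = rec$sensitivity, precision = rec$precision),
             file.path(out, "manifest.txt"))
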