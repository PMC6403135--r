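#!/usr/bin/env Rscript
# Step 2: genome-wide methylome description.
#
# Reads the per-sample cytosine reports back from disk, estimates the
# bisulfite non-conversion rate from the lambda spike-in, corrects all
# levels with it, and reports per-context/per-chromosome levels, the
# fraction of positions called methylated, 3 kb / 600 bp sliding-window
# levels, and per-feature (promoter/UTR/exon/intron/TE family) levels.

library(methylrhythm)

simdir <- "results/sim"
out <- "results/methylome"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- sample_design()
reports <- lapply(setNames(nm = design$samples), function(s) {
  read_cytosine_report(file.path(simdir, paste0(s, ".cytosine_report.tsv")))
})
mset <- methylome_set(reports)
print(mset)

controls <- read.delim(file.path(simdir, "lambda_controls.tsv"))
r_hat <- estimate_nonconversion(controls$n_converted, controls$n_unconverted)
cat(sprintf("lambda non-conversion rate: %.4f%%\n", 100 * r_hat))

pooled <- mset$sites
pooled$n_meth <- as.integer(rowSums(mset$n_meth))
pooled$n_unmeth <- as.integer(rowSums(mset$n_total)) - pooled$n_meth

flags <- call_methylated_sites(pooled, r_hat, alpha = 0.05, min_coverage = 5)
summary_tab <- genome_summary(pooled, flags, r = r_hat)
write.table(summary_tab, file.path(out, "genome_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
gen <- summary_tab[summary_tab$chrom == "genome", ]
cat(sprintf("mean corrected levels: CG %.2f%%, CHG %.2f%%, CHH %.2f%%\n",
            100 * gen$level[gen$context == "CG"],
            100 * gen$level[gen$context == "CHG"],
            100 * gen$level[gen$context == "CHH"]))

genome <- Biostrings::readDNAStringSet(file.path(simdir, "genome.fa"))
chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
win <- sliding_windows(pooled, chrom_lengths, window = 3000, step = 600)
write.table(win, file.path(out, "window_levels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("windows:", length(unique(paste(win$chrom, win$start))), "\n")

genes <- read_gene_models(file.path(simdir, "genes.gff3"))
tes <- read_te_bed(file.path(simdir, "tes.bed"))
idx <- build_feature_index(genes, tes, chrom_lengths)
feat <- feature_methylation_profile(pooled, idx, r = r_hat)
write.table(feat, file.path(out, "feature_levels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("feature classes profiled:", length(unique(feat$feature)), "\n")
write_config(c(r_hat = r_hat, alpha = 0.05, min_coverage = 5,
               window = 3000, step = 600),
             file.path(out, "manifest.txt"))
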