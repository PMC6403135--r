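#!/usr/bin/env Rscript
# Step 4: genomic context of the differential calls.
#
# Assigns DMRs and DMCs to feature classes (promoter > UTR > exon >
# intron > flank > TE > intergenic precedence for the exclusive label),
# identifies differentially methylated genes (DMR overlapping the gene
# body or the 2 kb promoter), and computes the TSS/TES-anchored metagene
# density profile of the DMCs (2 kb flanks in 20 x 100 bp bins, body in
# 20 proportional bins).

library(methylrhythm)

simdir <- "results/sim"
diffdir <- "results/differential"
out <- "results/annotation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- Biostrings::readDNAStringSet(file.path(simdir, "genome.fa"))
chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
genes <- read_gene_models(file.path(simdir, "genes.gff3"))
tes <- read_te_bed(file.path(simdir, "tes.bed"))
idx <- build_feature_index(genes, tes, chrom_lengths)

dmrs <- read_dmr_bed(file.path(diffdir, "dmrs.bed"))
dmcs <- read.delim(file.path(diffdir, "dmcs.tsv"))

report_assignment <- function(items, label) {
  a <- assign_features(items, idx)
  tab <- as.data.frame(table(primary = a$primary))
  tab$fraction_pct <- 100 * tab$Freq / sum(tab$Freq)
  write.table(tab, file.path(out, paste0(label, "_features.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  genic <- paste(sprintf("%s %.1f%%", names(a$genic_fractions),
                         a$genic_fractions), collapse = ", ")
  cat(label, "genic composition:", genic, "\n")
  invisible(a)
}
if (nrow(dmrs)) report_assignment(dmrs, "dmr")
if (nrow(dmcs)) report_assignment(dmcs, "dmc")

dmgs <- differentially_methylated_genes(dmrs, genes, chrom_lengths)
write.table(dmgs$links, file.path(out, "dmg_links.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("differentially methylated genes per comparison:",
    paste(names(dmgs$per_comparison), dmgs$per_comparison, sep = "=",
          collapse = ", "),
    "| union:", length(dmgs$union_genes), "\n")

prof <- metagene_profile(dmcs, genes, flank = 2000, n_bins = 20,
                         body_bins = 20)
write.table(prof, file.path(out, "dmc_metagene.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
tss_bin <- prof$density[21]
flank_max <- max(prof$density[c(1:20, 41:60)])
cat(sprintf("DMC metagene: density %.2g at the TSS-adjacent bin vs flank max %.2g\n",
            tss_bin, flank_max))
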