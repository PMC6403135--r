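# Synthetic study generator: random genomes with gene/TE annotations,
# per-sample cytosine reports with planted differential methylation,
# lambda spike-in controls, and expression matrices with planted 24 h
# rhythms and methylation-expression coupling. Every planted effect is
# recorded in a truth ledger so downstream stages can be scored.

.DEFAULT_BASELINES <- c(CG = 0.4399, CHG = 0.2984, CHH = 0.1157)
.DEFAULT_TE_FAMILIES <- c("hAT", "CMC-EnSpm", "Gypsy", "Copia", "LINE")

#' Simulate a genome with gene and TE annotations
#'
#' Uniform-composition random sequence; non-overlapping genes with 1-6
#' exons and terminal UTRs on both strands; TEs placed in the remaining
#' intergenic space with family labels. Rerunning with the same seed
#' reproduces the output exactly.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes,n_tes Number of genes / TEs to place genome-wide.
#' @param te_families Family labels sampled for TEs.
#' @param gene_span_range,te_span_range Span ranges (bp) sampled uniformly.
#' @param seed Optional integer seed.
#' @param out_dir If given, writes `genome.fa`, `genes.gff3`, `tes.bed`
#'   there.
#' @return List of class `sim_genome`: `genome` (`DNAStringSet`), `genes`
#'   (`gene_models`), `tes` (data frame), `chrom_lengths`, and `paths`
#'   when written.
#' @export
simulate_genome <- function(n_chrom = 2, chrom_length = 2e5, n_genes = 100,
                            n_tes = 40, te_families = .DEFAULT_TE_FAMILIES,
                            gene_span_range = c(900, 3000),
                            te_span_range = c(300, 2000),
                            seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- sprintf("Chr%02d", seq_len(n_chrom))
  chrom_lengths <- stats::setNames(rep(as.integer(chrom_length), n_chrom), chroms)
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  placed <- stats::setNames(vector("list", n_chrom), chroms)  # occupied intervals
  place_interval <- function(span, margin, what) {
    for (attempt in 1:200) {
      ch <- sample(chroms, 1)
      if (span + 2 > chrom_lengths[[ch]]) next
      start <- sample.int(chrom_lengths[[ch]] - span, 1)
      end <- start + span - 1L
      occ <- placed[[ch]]
      clash <- FALSE
      if (length(occ)) {
        for (iv in occ) {
          if (start <= iv[2] + margin && end >= iv[1] - margin) {
            clash <- TRUE
            break
          }
        }
      }
      if (!clash) {
        placed[[ch]][[length(placed[[ch]]) + 1]] <<- c(start, end)
        return(list(chrom = ch, start = start, end = end))
      }
    }
    stop("cannot place ", what, ": genome too densely packed")
  }
  gene_rows <- list(); exon_rows <- list(); utr5_rows <- list(); utr3_rows <- list()
  for (i in seq_len(n_genes)) {
    span <- sample(gene_span_range[1]:gene_span_range[2], 1)
    loc <- place_interval(span, margin = 200, what = "genes")
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("gene%04d", i)
    n_ex <- sample(1:6, 1)
    n_seg <- 2L * n_ex - 1L
    u <- stats::runif(n_seg, 0.5, 1.5)
    seg <- pmax(50L, as.integer(round(u / sum(u) * span)))
    seg[1] <- seg[1] + (span - sum(seg))
    if (seg[1] < 50L) { # rebalance if the correction undercut the first exon
      seg <- rep(span %/% n_seg, n_seg)
      seg[1] <- seg[1] + span - sum(seg)
    }
    bounds <- loc$start + cumsum(c(0L, seg))
    ex_idx <- seq(1, n_seg, by = 2)
    ex <- data.frame(gene_id = gid, start = bounds[ex_idx],
                     end = bounds[ex_idx + 1] - 1L, stringsAsFactors = FALSE)
    # terminal UTRs in transcript orientation
    first_ex <- if (strand == "+") 1L else nrow(ex)
    last_ex <- if (strand == "+") nrow(ex) else 1L
    w5 <- min(150L, (ex$end[first_ex] - ex$start[first_ex] + 1L) %/% 3L)
    w3 <- min(150L, (ex$end[last_ex] - ex$start[last_ex] + 1L) %/% 3L)
    if (w5 >= 20L) {
      utr5_rows[[gid]] <- if (strand == "+") {
        data.frame(gene_id = gid, start = ex$start[1], end = ex$start[1] + w5 - 1L)
      } else {
        data.frame(gene_id = gid, start = ex$end[nrow(ex)] - w5 + 1L,
                   end = ex$end[nrow(ex)])
      }
    }
    if (w3 >= 20L) {
      utr3_rows[[gid]] <- if (strand == "+") {
        data.frame(gene_id = gid, start = ex$end[nrow(ex)] - w3 + 1L,
                   end = ex$end[nrow(ex)])
      } else {
        data.frame(gene_id = gid, start = ex$start[1], end = ex$start[1] + w3 - 1L)
      }
    }
    gene_rows[[gid]] <- data.frame(
      gene_id = gid, chrom = loc$chrom, start = loc$start, end = loc$end,
      strand = strand, stringsAsFactors = FALSE)
    exon_rows[[gid]] <- ex
  }
  te_rows <- list()
  for (i in seq_len(n_tes)) {
    span <- sample(te_span_range[1]:te_span_range[2], 1)
    loc <- place_interval(span, margin = 50, what = "TEs")
    te_rows[[i]] <- data.frame(chrom = loc$chrom, start = loc$start,
                               end = loc$end,
                               family = sample(te_families, 1),
                               stringsAsFactors = FALSE)
  }
  bind <- function(x, cols) {
    if (length(x)) {
      out <- do.call(rbind, x); rownames(out) <- NULL; out
    } else {
      as.data.frame(stats::setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols))
    }
  }
  genes_df <- bind(gene_rows, c("gene_id", "chrom", "start", "end", "strand"))
  if (nrow(genes_df)) {
    ord <- order(genes_df$chrom, genes_df$start)
    genes_df <- genes_df[ord, , drop = FALSE]
    rownames(genes_df) <- NULL
    genes_df$tss <- ifelse(genes_df$strand == "+", genes_df$start, genes_df$end)
    genes_df$tes <- ifelse(genes_df$strand == "+", genes_df$end, genes_df$start)
  } else {
    genes_df <- data.frame(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character(), tss = integer(),
                           tes = integer(), stringsAsFactors = FALSE)
  }
  exons_df <- bind(exon_rows, c("gene_id", "start", "end"))
  introns <- do.call(rbind, lapply(split(exons_df, exons_df$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1], start = e$end[-nrow(e)] + 1L,
               end = e$start[-1] - 1L, stringsAsFactors = FALSE)
  }))
  if (is.null(introns)) introns <- data.frame(gene_id = character(),
                                              start = integer(), end = integer())
  rownames(introns) <- NULL
  genes <- structure(list(genes = genes_df, exons = exons_df, introns = introns,
                          utr5 = bind(utr5_rows, c("gene_id", "start", "end")),
                          utr3 = bind(utr3_rows, c("gene_id", "start", "end"))),
                     class = "gene_models")
  tes <- bind(te_rows, c("chrom", "start", "end", "family"))
  if (nrow(tes)) {
    tes <- tes[order(tes$chrom, tes$start), , drop = FALSE]
    rownames(tes) <- NULL
  } else {
    tes <- data.frame(chrom = character(), start = integer(), end = integer(),
                      family = character(), stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  out <- structure(list(genome = genome, genes = genes, tes = tes,
                        chrom_lengths = chrom_lengths),
                   class = "sim_genome")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(out_dir, "genome.fa"),
                  gff3 = file.path(out_dir, "genes.gff3"),
                  bed = file.path(out_dir, "tes.bed"))
    Biostrings::writeXStringSet(genome, paths$fasta)
    write_gene_models_gff3(genes, paths$gff3)
    if (nrow(tes)) {
      bed <- data.frame(tes$chrom, tes$start - 1L, tes$end, tes$family)
      utils::write.table(bed, paths$bed, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      file.create(paths$bed)
    }
    out$paths <- paths
  }
  out
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and UTR features with ID/Parent attributes in
#' the layout [read_gene_models()] expects.
#'
#' @param genes A `gene_models` object.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  g <- genes$genes
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start, end,
            strand, attrs)
  }
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    mid <- paste0(gid, ".1")
    lines <- c(lines,
               fmt(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
                   paste0("ID=", gid)),
               fmt(g$chrom[i], "mRNA", g$start[i], g$end[i], g$strand[i],
                   paste0("ID=", mid, ";Parent=", gid)))
    sub <- function(tab, type) {
      t <- tab[tab$gene_id == gid, , drop = FALSE]
      if (!nrow(t)) return(character(0))
      fmt(g$chrom[i], type, t$start, t$end, g$strand[i],
          paste0("Parent=", mid))
    }
    lines <- c(lines, sub(genes$exons, "exon"),
               sub(genes$utr5, "five_prime_UTR"),
               sub(genes$utr3, "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}

.validate_planted <- function(planted, design, chrom_lengths) {
  if (is.null(planted) || nrow(planted) == 0) return(invisible(NULL))
  needed <- c("comparison", "chrom", "start", "end", "delta", "direction")
  if (!all(needed %in% names(planted))) {
    stop("planted_dmrs needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(!planted$comparison %in% design$comparisons$id)) {
    stop("planted DMR references unknown comparison")
  }
  if (any(!planted$chrom %in% names(chrom_lengths)) ||
      any(planted$start < 1) ||
      any(planted$end > chrom_lengths[planted$chrom])) {
    stop("planted DMR outside the simulated genome")
  }
  if (any(planted$delta <= 0 | planted$delta > 1)) {
    stop("planted effect sizes must be in (0, 1]")
  }
  if (any(!planted$direction %in% c("hyper", "hypo"))) {
    stop("planted direction must be 'hyper' or 'hypo'")
  }
  invisible(NULL)
}

#' Simulate per-sample methylomes with planted differential regions
#'
#' For every genomic cytosine on both strands, per-sample coverage is
#' drawn from an overdispersed negative-binomial distribution and the
#' methylated count from a binomial whose success probability is the true
#' level plus non-conversion noise on unmethylated molecules
#' (`p = level + (1 - level) * r`). True levels are context baselines
#' modulated by feature class (TEs elevated, UTRs depressed, flanks mildly
#' elevated) and a per-gene body factor, renormalised per context so the
#' genome-wide mean matches the baselines; samples add a small level
#' jitter. Planted regions shift the level of one group's samples by
#' `delta` (restricted to `contexts`, default CHH). The truth ledger
#' records all per-comparison effects the group offsets induce, including
#' effects induced in neighbouring comparisons that reuse an offset group.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param design A [sample_design()].
#' @param baseline_levels Named per-context mean levels.
#' @param planted_dmrs Data frame (`comparison`, `chrom`, `start`, `end`,
#'   `delta`, `direction`, optional `contexts` comma-separated, default
#'   `"CHH"`). `hyper` raises group b of the comparison, `hypo` raises
#'   group a.
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and size.
#' @param nonconversion_rate False-methylation rate on unmethylated
#'   molecules (lambda-control chemistry).
#' @param sample_jitter_sd Between-sample level jitter (absolute).
#' @param lambda_total Total lambda-control cytosine reads per sample.
#' @param feature_multipliers Level multipliers by feature class.
#' @param gene_body_sd SD of the per-gene lognormal body-level factor
#'   (drives gene-to-gene body methylation variation).
#' @param seed Optional integer seed.
#' @return List of class `sim_methylome`: `mset` (a [methylome_set()]),
#'   `controls` (per-sample lambda counts), `truth` (class `sim_truth`),
#'   `r` (the true non-conversion rate).
#' @export
simulate_methylome <- function(sim, design,
                               baseline_levels = .DEFAULT_BASELINES,
                               planted_dmrs = NULL,
                               coverage_mean = 30, coverage_dispersion = 5,
                               nonconversion_rate = 0.005,
                               sample_jitter_sd = 0.02,
                               lambda_total = 1e5,
                               feature_multipliers = c(TE = 1.5, utr = 0.5,
                                                       exon = 0.9, intron = 0.9,
                                                       flank = 1.2,
                                                       intergenic = 1),
                               gene_body_sd = 0.3,
                               seed = NULL) {
  stopifnot(all(baseline_levels >= 0 & baseline_levels <= 1),
            coverage_mean > 0,
            nonconversion_rate >= 0, nonconversion_rate < 1)
  .validate_planted(planted_dmrs, design, sim$chrom_lengths)
  if (!is.null(seed)) set.seed(seed)
  sites <- enumerate_cytosines(sim$genome)
  n <- nrow(sites)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  g <- sim$genes$genes
  mk_gr <- function(tab, chrom = NULL) {
    if (is.null(tab) || nrow(tab) == 0) {
      return(GenomicRanges::GRanges())
    }
    if (is.null(chrom)) chrom <- tab$chrom
    GenomicRanges::GRanges(chrom, IRanges::IRanges(tab$start, tab$end))
  }
  gene_chrom <- function(tab) g$chrom[match(tab$gene_id, g$gene_id)]
  # feature class per site, priority TE > UTR > exon > intron > flank
  class_of <- rep("intergenic", n)
  if (nrow(g)) {
    plus <- g$strand == "+"
    flank_up <- data.frame(chrom = g$chrom,
                           start = ifelse(plus, g$start - 2000, g$end + 1),
                           end = ifelse(plus, g$start - 1, g$end + 2000))
    flank_dn <- data.frame(chrom = g$chrom,
                           start = ifelse(plus, g$end + 1, g$start - 2000),
                           end = ifelse(plus, g$end + 2000, g$start - 1))
    flanks <- rbind(flank_up, flank_dn)
    flanks$start <- pmax(1, flanks$start)
    flanks$end <- pmin(unname(sim$chrom_lengths[flanks$chrom]), flanks$end)
    flanks <- flanks[flanks$end >= flanks$start, ]
    assign_cls <- function(gr, label) {
      class_of[IRanges::overlapsAny(site_gr, gr)] <<- label
    }
    assign_cls(mk_gr(flanks), "flank")
    assign_cls(mk_gr(sim$genes$introns, gene_chrom(sim$genes$introns)), "intron")
    assign_cls(mk_gr(sim$genes$exons, gene_chrom(sim$genes$exons)), "exon")
    assign_cls(mk_gr(rbind(sim$genes$utr5, sim$genes$utr3),
                     gene_chrom(rbind(sim$genes$utr5, sim$genes$utr3))), "utr")
  }
  class_of[IRanges::overlapsAny(site_gr, mk_gr(sim$tes))] <- "TE"
  level <- unname(baseline_levels[sites$context]) *
    unname(feature_multipliers[class_of])
  # per-gene body factor: gene-to-gene variation in body methylation
  gene_body_factor <- stats::setNames(exp(stats::rnorm(nrow(g), 0, gene_body_sd)),
                                      g$gene_id)
  if (nrow(g)) {
    hits <- GenomicRanges::findOverlaps(site_gr, mk_gr(g))
    level[S4Vectors::queryHits(hits)] <- level[S4Vectors::queryHits(hits)] *
      gene_body_factor[S4Vectors::subjectHits(hits)]
  }
  # renormalise per context so genome means equal the requested baselines
  for (pass in 1:3) {
    for (cx in unique(sites$context)) {
      i <- sites$context == cx
      level[i] <- level[i] * baseline_levels[[cx]] / mean(level[i])
    }
    level <- pmin(0.99, pmax(0.001, level))
  }
  # per-group planted offsets
  offsets <- matrix(0, n, length(design$groups),
                    dimnames = list(NULL, names(design$groups)))
  truth_regions <- NULL
  if (!is.null(planted_dmrs) && nrow(planted_dmrs) > 0) {
    planted <- planted_dmrs
    if (is.null(planted$contexts)) planted$contexts <- "CHH"
    cmp <- design$comparisons[match(planted$comparison, design$comparisons$id), ]
    planted$offset_group <- ifelse(planted$direction == "hyper",
                                   cmp$group_b, cmp$group_a)
    for (i in seq_len(nrow(planted))) {
      ctxs <- strsplit(planted$contexts[i], ",")[[1]]
      in_region <- sites$chrom == planted$chrom[i] &
        sites$pos >= planted$start[i] & sites$pos <= planted$end[i] &
        sites$context %in% ctxs
      offsets[in_region, planted$offset_group[i]] <-
        offsets[in_region, planted$offset_group[i]] + planted$delta[i]
    }
    # expand to the per-comparison effects these group offsets induce
    truth_regions <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
      do.call(rbind, lapply(seq_len(nrow(design$comparisons)), function(j) {
        cj <- design$comparisons[j, ]
        net <- (planted$offset_group[i] == cj$group_b) * planted$delta[i] -
          (planted$offset_group[i] == cj$group_a) * planted$delta[i]
        if (net == 0) return(NULL)
        data.frame(comparison = cj$id, chrom = planted$chrom[i],
                   start = planted$start[i], end = planted$end[i],
                   contexts = planted$contexts[i], effect = net,
                   direction = if (net > 0) "hyper" else "hypo",
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  # draw counts
  samples <- design$samples
  r <- nonconversion_rate
  n_meth <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  n_total <- n_meth
  sample_offsets <- sapply(samples, function(s) {
    in_groups <- names(design$groups)[vapply(design$groups, function(m) s %in% m,
                                             logical(1))]
    rowSums(offsets[, in_groups, drop = FALSE])
  })
  for (s in samples) {
    p_true <- pmin(1, pmax(0, level + sample_offsets[, s] +
                             stats::rnorm(n, 0, sample_jitter_sd)))
    cov <- stats::rnbinom(n, mu = coverage_mean, size = coverage_dispersion)
    p_obs <- p_true + (1 - p_true) * r
    n_total[, s] <- cov
    n_meth[, s] <- stats::rbinom(n, cov, p_obs)
  }
  controls <- data.frame(
    sample = samples,
    n_unconverted = stats::rbinom(length(samples), lambda_total, r),
    stringsAsFactors = FALSE)
  controls$n_converted <- lambda_total - controls$n_unconverted
  truth <- structure(list(planted_dmrs = planted_dmrs,
                          expected_effects = truth_regions,
                          baseline_levels = baseline_levels,
                          nonconversion_rate = r,
                          gene_body_factor = gene_body_factor,
                          rhythmic_genes = NULL, couplings = NULL),
                     class = "sim_truth")
  mset <- structure(list(sites = sites, n_meth = n_meth, n_total = n_total,
                         samples = samples),
                    class = "methylome_set")
  structure(list(mset = mset, controls = controls, truth = truth, r = r),
            class = "sim_methylome")
}

#' Write per-sample cytosine reports and lambda controls to disk
#'
#' Emits one 7-column report per sample (the format
#' [read_cytosine_report()] parses) plus `lambda_controls.tsv`.
#'
#' @param simmeth A `sim_methylome`.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of report paths.
#' @export
write_sim_methylome <- function(simmeth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- stats::setNames(character(length(simmeth$mset$samples)),
                           simmeth$mset$samples)
  for (s in simmeth$mset$samples) {
    d <- simmeth$mset$sites
    d$n_meth <- simmeth$mset$n_meth[, s]
    d$n_unmeth <- simmeth$mset$n_total[, s] - simmeth$mset$n_meth[, s]
    paths[s] <- file.path(out_dir, paste0(s, ".cytosine_report.tsv"))
    write_cytosine_report(d, paths[s])
  }
  utils::write.table(simmeth$controls,
                     file.path(out_dir, "lambda_controls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

#' Simulate an expression matrix over the daily time course
#'
#' Rhythmic genes follow `mesor + A cos(2 pi (t - phase) / 24)` on the
#' log2 scale with additive Gaussian noise (multiplicative lognormal on the
#' FPKM scale); other genes are flat plus noise. When a `coupling` is
#' given, gene mesors are tied to the supplied per-gene scores (typically
#' the simulated gene-body methylation factors) at a target Spearman
#' correlation, so expression is monotone-coupled to body methylation.
#'
#' @param gene_ids Character vector of gene ids (or a `gene_models`).
#' @param design A [sample_design()] carrying sample time stamps.
#' @param rhythmic_fraction Fraction of genes given a 24 h rhythm
#'   (default 0.12).
#' @param amplitude_range Range of rhythm amplitudes (log2 units).
#' @param noise_sd Per-sample log2 noise SD.
#' @param mesor_mean,mesor_sd Baseline log2 abundance distribution.
#' @param coupling Optional list: `scores` (named numeric, one per gene),
#'   `rho` (target Spearman, default 0.5), `sign` (+1/-1, default +1).
#' @param group_shifts Optional data frame (`gene_id`, `group_id`,
#'   `shift`): additive log2 expression shifts applied to a group's
#'   samples, used to plant methylation-responsive expression changes.
#' @param period Rhythm period in hours (default 24).
#' @param seed Optional integer seed.
#' @return List: `expr` (genes x samples FPKM-scale matrix) and `truth`
#'   (data frames `rhythmic_genes`, `couplings`, `expression_shifts`).
#' @export
simulate_expression <- function(gene_ids, design, rhythmic_fraction = 0.12,
                                amplitude_range = c(1, 3), noise_sd = 0.5,
                                mesor_mean = 4, mesor_sd = 1.5,
                                coupling = NULL, group_shifts = NULL,
                                period = 24, seed = NULL) {
  if (rhythmic_fraction < 0 || rhythmic_fraction > 1) {
    stop("rhythmic_fraction must be in [0,1]")
  }
  if (inherits(gene_ids, "gene_models")) gene_ids <- gene_ids$genes$gene_id
  if (!is.null(seed)) set.seed(seed)
  n <- length(gene_ids)
  samples <- design$samples
  t <- unname(design$timepoints[samples])
  # mesor: optionally coupled to the supplied methylation scores through a
  # Gaussian copula (Spearman rho -> latent Pearson r = 2 sin(pi rho / 6))
  latent <- stats::rnorm(n)
  couplings <- NULL
  if (!is.null(coupling)) {
    scores <- coupling$scores[gene_ids]
    if (any(is.na(scores))) stop("coupling scores missing for some genes")
    rho <- if (is.null(coupling$rho)) 0.5 else coupling$rho
    sgn <- if (is.null(coupling$sign)) 1 else coupling$sign
    z <- stats::qnorm((rank(scores, ties.method = "first") - 0.5) / n)
    r_lat <- 2 * sin(pi * rho / 6)
    latent <- sgn * (r_lat * z + sqrt(1 - r_lat^2) * latent)
    couplings <- data.frame(gene_id = gene_ids, score = unname(scores),
                            rho = rho, sign = sgn, stringsAsFactors = FALSE)
  }
  mesor <- mesor_mean + mesor_sd * latent
  n_rhythmic <- round(rhythmic_fraction * n)
  rhythmic_idx <- sort(sample.int(n, n_rhythmic))
  amplitude <- numeric(n)
  amplitude[rhythmic_idx] <- stats::runif(n_rhythmic, amplitude_range[1],
                                          amplitude_range[2])
  phase <- numeric(n)
  phase[rhythmic_idx] <- stats::runif(n_rhythmic, 0, period)
  w <- 2 * pi / period
  signal <- outer(amplitude, rep(1, length(t))) *
    cos(w * (matrix(t, n, length(t), byrow = TRUE) - phase))
  y <- mesor + signal + matrix(stats::rnorm(n * length(t), 0, noise_sd),
                               n, length(t))
  if (!is.null(group_shifts) && nrow(group_shifts)) {
    for (i in seq_len(nrow(group_shifts))) {
      gi <- match(group_shifts$gene_id[i], gene_ids)
      if (is.na(gi)) next
      members <- design$groups[[group_shifts$group_id[i]]]
      si <- match(members, samples)
      y[gi, si] <- y[gi, si] + group_shifts$shift[i]
    }
  }
  expr <- matrix(pmax(0, 2^y - 1), n, length(t),
                 dimnames = list(gene_ids, samples))
  truth <- list(
    rhythmic_genes = data.frame(gene_id = gene_ids[rhythmic_idx],
                                amplitude = amplitude[rhythmic_idx],
                                phase = phase[rhythmic_idx],
                                stringsAsFactors = FALSE),
    couplings = couplings,
    expression_shifts = group_shifts)
  list(expr = expr, truth = truth)
}

#' Write and read a simulation truth ledger
#'
#' TSV tables (planted regions, expected per-comparison effects, rhythmic
#' genes, couplings, gene body factors) plus a flat key-value manifest;
#' [read_simulation_truth()] restores the same `sim_truth` object.
#'
#' @param truth A `sim_truth` object.
#' @param dir Ledger directory.
#' @export
write_simulation_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    if (!is.null(x) && nrow(x)) {
      utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  wt(truth$planted_dmrs, "planted_dmrs.tsv")
  wt(truth$expected_effects, "expected_effects.tsv")
  wt(truth$rhythmic_genes, "rhythmic_genes.tsv")
  wt(truth$couplings, "couplings.tsv")
  wt(truth$expression_shifts, "expression_shifts.tsv")
  if (!is.null(truth$gene_body_factor)) {
    wt(data.frame(gene_id = names(truth$gene_body_factor),
                  factor = unname(truth$gene_body_factor)),
       "gene_body_factors.tsv")
  }
  manifest <- c(nonconversion_rate = truth$nonconversion_rate,
                stats::setNames(truth$baseline_levels,
                                paste0("baseline_", names(truth$baseline_levels))))
  write_config(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_simulation_truth
#' @export
read_simulation_truth <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.table(p, sep = "\t", header = TRUE,
                                          stringsAsFactors = FALSE) else NULL
  }
  manifest <- read_config(file.path(dir, "manifest.txt"))
  base <- manifest[startsWith(names(manifest), "baseline_")]
  gbf <- rd("gene_body_factors.tsv")
  structure(list(
    planted_dmrs = rd("planted_dmrs.tsv"),
    expected_effects = rd("expected_effects.tsv"),
    baseline_levels = stats::setNames(as.numeric(base),
                                      sub("^baseline_", "", names(base))),
    nonconversion_rate = as.numeric(manifest[["nonconversion_rate"]]),
    gene_body_factor = if (!is.null(gbf)) stats::setNames(gbf$factor, gbf$gene_id) else NULL,
    rhythmic_genes = rd("rhythmic_genes.tsv"),
    couplings = rd("couplings.tsv"),
    expression_shifts = rd("expression_shifts.tsv")), class = "sim_truth")
}

#' Default planted-region layout for a simulated study
#'
#' Places `n` well-separated regions on the simulated genome and raises
#' the methylation of one group per region, cycling through the
#' comparisons whose raised group (G2, G3, G4 under the standard design)
#' is not shared with any other group, so a planted offset touches exactly
#' the intended samples. Each plant induces a hyper effect in the
#' comparison where the raised group is the later one and a hypo effect in
#' the next comparison (the raised group becomes the baseline there); both
#' land in the truth ledger, so hyper and hypo calls are exercised in
#' balance.
#'
#' @param sim A `sim_genome`.
#' @param design A [sample_design()].
#' @param n Number of regions.
#' @param width Region width (bp).
#' @param delta Planted level offset.
#' @param contexts Context set (comma-separated string), default `"CHH"`.
#' @param comparisons Comparison ids cycled through; each plant is a
#'   `hyper` on that comparison's later group.
#' @return `planted_dmrs` data frame for [simulate_methylome()].
#' @export
plant_default_dmrs <- function(sim, design, n = 12, width = 800, delta = 0.4,
                               contexts = "CHH",
                               comparisons = c("G2vG1", "G3vG2", "G4vG3")) {
  chroms <- names(sim$chrom_lengths)
  # evenly spaced anchors per chromosome, away from the ends
  per_chrom <- ceiling(n / length(chroms))
  rows <- list()
  k <- 0
  for (ci in seq_along(chroms)) {
    len <- sim$chrom_lengths[[ci]]
    anchors <- round(seq(0.08, 0.92, length.out = per_chrom) * len)
    for (a in anchors) {
      if (k >= n) break
      k <- k + 1
      rows[[k]] <- data.frame(
        comparison = comparisons[(k - 1) %% length(comparisons) + 1],
        chrom = chroms[ci], start = a, end = min(a + width - 1, len),
        delta = delta, direction = "hyper",
        contexts = contexts, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plant anti-phase expression responses to the planted methylation
#'
#' For every gene lying within `flank` bp of a planted region, schedules
#' an additive log2 expression shift of `-shift_per_delta * delta` on the
#' samples of the group whose methylation the region raises -- methylation
#' up, expression down, the anti-phase pattern the integration stage is
#' designed to detect. A group-constant shift is itself a daily signal
#' (each group is a fixed clock time), so responding genes are genuinely
#' rhythmic and can be picked up by the detector on their own merits; they
#' are recorded in the truth under `expression_shifts`, not among the
#' planted cosine genes.
#'
#' @param sim A `sim_genome`.
#' @param design A [sample_design()].
#' @param planted_dmrs Planted regions (see [simulate_methylome()]).
#' @param shift_per_delta Log2 shift per unit of planted level offset
#'   (default 3).
#' @param flank Gene-to-region association distance in bp (default 2000,
#'   the promoter width).
#' @return List: `group_shifts` (data frame for [simulate_expression()])
#'   and `gene_ids`.
#' @export
plant_expression_response <- function(sim, design, planted_dmrs,
                                      shift_per_delta = 3, flank = 2000) {
  g <- sim$genes$genes
  if (is.null(planted_dmrs) || nrow(planted_dmrs) == 0 || nrow(g) == 0) {
    return(list(group_shifts = NULL, gene_ids = character(0)))
  }
  cmp <- design$comparisons
  rows <- lapply(seq_len(nrow(planted_dmrs)), function(i) {
    p <- planted_dmrs[i, ]
    grp <- if (p$direction == "hyper") cmp$group_b[cmp$id == p$comparison]
           else cmp$group_a[cmp$id == p$comparison]
    hit <- g$chrom == p$chrom & g$start <= p$end + flank &
      g$end >= p$start - flank
    if (!any(hit)) return(NULL)
    data.frame(gene_id = g$gene_id[hit], group_id = grp,
               shift = -shift_per_delta * p$delta, stringsAsFactors = FALSE)
  })
  group_shifts <- do.call(rbind, rows)
  list(group_shifts = group_shifts,
       gene_ids = unique(group_shifts$gene_id))
}

#' Score called DMRs against the simulation truth
#'
#' A truth effect counts as recovered when a called DMR of the same
#' comparison and direction overlaps its region; a called DMR is a true
#' positive when it matches some truth effect the same way.
#'
#' @param dmrs Called DMRs (all comparisons stacked).
#' @param truth A `sim_truth` with `expected_effects`.
#' @return List `sensitivity`, `precision`, `n_truth`, `n_called`,
#'   `n_recovered`.
#' @export
evaluate_dmr_recovery <- function(dmrs, truth) {
  eff <- truth$expected_effects
  if (is.null(eff) || nrow(eff) == 0) stop("truth ledger has no expected effects")
  match_one <- function(t_row, d) {
    any(d$comparison == t_row$comparison & d$direction == t_row$direction &
          d$chrom == t_row$chrom & d$start <= t_row$end & d$end >= t_row$start)
  }
  recovered <- vapply(seq_len(nrow(eff)), function(i) {
    match_one(eff[i, ], dmrs)
  }, logical(1))
  tp_called <- vapply(seq_len(nrow(dmrs)), function(i) {
    d <- dmrs[i, ]
    any(eff$comparison == d$comparison & eff$direction == d$direction &
          eff$chrom == d$chrom & eff$start <= d$end & eff$end >= d$start)
  }, logical(1))
  list(sensitivity = mean(recovered),
       precision = if (nrow(dmrs)) mean(tp_called) else NA_real_,
       n_truth = nrow(eff), n_called = nrow(dmrs),
       n_recovered = sum(recovered))
}

#' Score rhythmic-gene detection against the simulation truth
#'
#' Sensitivity is measured on the planted cosine genes. Genes carrying a
#' planted methylation-driven group shift are daily signals in their own
#' right, so detecting one is not a false positive: the FDR is computed
#' against the union of both planted sets.
#'
#' @param rhythm_fits Output of [detect_rhythmic_genes()].
#' @param truth A `sim_truth` (or the `truth` element of
#'   [simulate_expression()]) with `rhythmic_genes` and optionally
#'   `expression_shifts`.
#' @return List `sensitivity`, `fdr`, `n_true`, `n_detected`.
#' @export
evaluate_rhythm_recovery <- function(rhythm_fits, truth) {
  planted <- truth$rhythmic_genes$gene_id
  genuine <- planted
  if (!is.null(truth$expression_shifts)) {
    genuine <- union(genuine, truth$expression_shifts$gene_id)
  }
  detected <- rhythm_fits$gene_id[rhythm_fits$rhythmic]
  list(sensitivity = if (length(planted)) mean(planted %in% detected) else NA_real_,
       fdr = if (length(detected)) mean(!detected %in% genuine) else 0,
       n_true = length(planted), n_detected = length(detected))
}
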