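# Strand-aware feature decomposition of the genome: promoter/UTR/exon/
# intron/flank/TE interval index, feature assignment of sites and regions,
# differentially methylated genes, per-feature methylation levels, and
# metagene (TSS/TES-anchored) profiles.

.GENIC_CLASSES <- c("promoter", "five_prime_utr", "three_prime_utr", "exon",
                    "intron")
# primary-label precedence when an item overlaps several classes
.PRECEDENCE <- c("promoter", "five_prime_utr", "three_prime_utr", "exon",
                 "intron", "upstream2k", "downstream2k", "TE", "intergenic")

.gr <- function(chrom, start, end, chrom_lengths) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         seqlengths = chrom_lengths)
}

#' Build a queryable feature index from gene and TE annotations
#'
#' Feature classes: `promoter` (the `promoter_width` bp immediately
#' upstream of the TSS, strand-aware), `five_prime_utr`, `three_prime_utr`,
#' `exon`, `intron`, `upstream2k`/`downstream2k` flanks (for the level
#' profile; the upstream flank coincides with the promoter at default
#' widths), `TE:<family>` for each TE family, and `intergenic` (the
#' complement of everything else). Intervals are clipped at chromosome
#' bounds. A position may carry several labels.
#'
#' @param genes A `gene_models` object.
#' @param tes TE data frame from [read_te_bed()] (may be empty or `NULL`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param promoter_width Promoter span upstream of the TSS (default 2000).
#' @param flank Profile flank width (default 2000).
#' @return Object of class `feature_index`: named list of `GRanges` plus
#'   the gene table.
#' @export
build_feature_index <- function(genes, tes, chrom_lengths,
                                promoter_width = 2000, flank = 2000) {
  g <- genes$genes
  if (any(!g$chrom %in% names(chrom_lengths)) ||
      any(g$end > chrom_lengths[g$chrom]) || any(g$start < 1)) {
    stop("gene outside chromosome bounds")
  }
  plus <- g$strand == "+"
  clip <- function(chrom, start, end) {
    keep <- end >= 1 & start <= chrom_lengths[chrom]
    .gr(chrom[keep], pmax(1, start[keep]),
        pmin(unname(chrom_lengths[chrom[keep]]), end[keep]), chrom_lengths)
  }
  upstream <- function(width) {
    clip(g$chrom,
         ifelse(plus, g$tss - width, g$tss + 1),
         ifelse(plus, g$tss - 1, g$tss + width))
  }
  downstream <- function(width) {
    clip(g$chrom,
         ifelse(plus, g$tes + 1, g$tes - width),
         ifelse(plus, g$tes + width, g$tes - 1))
  }
  sub_gr <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(.gr(character(), integer(), integer(), chrom_lengths))
    chrom <- g$chrom[match(tab$gene_id, g$gene_id)]
    .gr(chrom, tab$start, tab$end, chrom_lengths)
  }
  idx <- list(
    promoter = upstream(promoter_width),
    five_prime_utr = sub_gr(genes$utr5),
    three_prime_utr = sub_gr(genes$utr3),
    exon = sub_gr(genes$exons),
    intron = sub_gr(genes$introns),
    gene_body = .gr(g$chrom, g$start, g$end, chrom_lengths),
    upstream2k = upstream(flank),
    downstream2k = downstream(flank)
  )
  if (!is.null(tes) && nrow(tes) > 0) {
    for (fam in unique(tes$family)) {
      t <- tes[tes$family == fam, ]
      idx[[paste0("TE:", fam)]] <- .gr(t$chrom, t$start, t$end, chrom_lengths)
    }
  }
  covered <- GenomicRanges::reduce(do.call(c, unname(idx)))
  genome_gr <- .gr(names(chrom_lengths), 1, unname(chrom_lengths), chrom_lengths)
  idx$intergenic <- GenomicRanges::setdiff(genome_gr, covered)
  structure(list(classes = idx, genes = g, chrom_lengths = chrom_lengths),
            class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat("feature_index:", length(x$classes), "classes over",
      length(x$chrom_lengths), "chromosomes\n")
  invisible(x)
}

.items_gr <- function(items, chrom_lengths) {
  if (!"start" %in% names(items)) {
    items$start <- items$pos
    items$end <- items$pos
  }
  if (any(!items$chrom %in% names(chrom_lengths))) {
    stop("item on unknown chromosome")
  }
  .gr(items$chrom, items$start, items$end, chrom_lengths)
}

#' Assign positions or intervals to genomic feature classes
#'
#' Each item is matched against every feature class (an item may overlap
#' several); the exclusive "primary" label uses the precedence
#' promoter > UTR > exon > intron > upstream/downstream flank > TE >
#' intergenic. TE families are collapsed to `TE` for the primary label but
#' reported per family in the overlap counts.
#'
#' @param items Data frame with `chrom` and either `pos` or `start`/`end`.
#' @param index A [build_feature_index()] object.
#' @return List: `primary` (character vector per item), `overlap` (logical
#'   item x class matrix), `counts` (per class, any-overlap),
#'   `genic_fractions` (percentages of primary labels over genic items:
#'   promoter/UTR/exon/intron, summing to 100).
#' @export
assign_features <- function(items, index) {
  gr <- .items_gr(items, index$chrom_lengths)
  classes <- names(index$classes)
  overlap <- sapply(classes, function(cl) {
    IRanges::overlapsAny(gr, index$classes[[cl]])
  })
  overlap <- matrix(overlap, nrow = length(gr),
                    dimnames = list(NULL, classes))
  te_any <- if (any(startsWith(classes, "TE:"))) {
    rowSums(overlap[, startsWith(classes, "TE:"), drop = FALSE]) > 0
  } else rep(FALSE, length(gr))
  primary <- rep("intergenic", length(gr))
  for (cl in rev(setdiff(.PRECEDENCE, c("TE", "intergenic")))) {
    if (cl %in% classes) primary[overlap[, cl]] <- cl
  }
  # TE sits between flank and intergenic in precedence
  primary[te_any & primary == "intergenic"] <- "TE"
  counts <- colSums(overlap)
  genic <- primary %in% c("promoter", "five_prime_utr", "three_prime_utr",
                          "exon", "intron")
  gf <- table(factor(primary[genic],
                     levels = c("promoter", "five_prime_utr",
                                "three_prime_utr", "exon", "intron")))
  genic_fractions <- if (sum(gf) > 0) 100 * as.numeric(gf) / sum(gf) else
    rep(0, length(gf))
  names(genic_fractions) <- names(gf)
  list(primary = primary, overlap = overlap, counts = counts,
       genic_fractions = genic_fractions)
}

#' Identify differentially methylated genes
#'
#' A gene is differentially methylated when at least one DMR overlaps its
#' body (the full span, introns and UTRs included) or its promoter
#' (`promoter_width` bp upstream of the TSS, strand-aware). Genes are
#' counted once per comparison and once in the union; the individual
#' gene-DMR links are retained for downstream integration.
#'
#' @param dmrs DMR data frame (any number of comparisons).
#' @param genes A `gene_models` object.
#' @param chrom_lengths Named chromosome lengths.
#' @param promoter_width Default 2000.
#' @return List: `links` (data frame `gene_id`, `comparison`, `dmr_index`,
#'   `region` in body/promoter, `direction`, `diff`), `per_comparison`
#'   (named counts), `union_genes` (character vector).
#' @export
differentially_methylated_genes <- function(dmrs, genes, chrom_lengths,
                                            promoter_width = 2000) {
  g <- genes$genes
  empty <- list(links = data.frame(gene_id = character(),
                                   comparison = character(),
                                   dmr_index = integer(), region = character(),
                                   direction = character(), diff = numeric(),
                                   stringsAsFactors = FALSE),
                per_comparison = integer(0), union_genes = character(0))
  if (is.null(dmrs) || nrow(dmrs) == 0 || nrow(g) == 0) return(empty)
  dmr_gr <- .gr(dmrs$chrom, dmrs$start, dmrs$end, chrom_lengths)
  plus <- g$strand == "+"
  body_gr <- .gr(g$chrom, g$start, g$end, chrom_lengths)
  prom_start <- ifelse(plus, g$tss - promoter_width, g$tss + 1)
  prom_end <- ifelse(plus, g$tss - 1, g$tss + promoter_width)
  keep <- prom_end >= 1 & prom_start <= chrom_lengths[g$chrom]
  prom_gr <- .gr(g$chrom[keep], pmax(1, prom_start[keep]),
                 pmin(unname(chrom_lengths[g$chrom[keep]]), prom_end[keep]),
                 chrom_lengths)
  link <- function(target_gr, ids, region) {
    h <- GenomicRanges::findOverlaps(dmr_gr, target_gr)
    data.frame(gene_id = ids[S4Vectors::subjectHits(h)],
               comparison = dmrs$comparison[S4Vectors::queryHits(h)],
               dmr_index = S4Vectors::queryHits(h),
               region = rep(region, length(h)),
               direction = dmrs$direction[S4Vectors::queryHits(h)],
               diff = dmrs$diff[S4Vectors::queryHits(h)],
               stringsAsFactors = FALSE)
  }
  links <- rbind(link(body_gr, g$gene_id, "gene_body"),
                 link(prom_gr, g$gene_id[keep], "promoter"))
  links <- links[order(links$comparison, links$gene_id), , drop = FALSE]
  rownames(links) <- NULL
  per_comparison <- vapply(split(links$gene_id, links$comparison),
                           function(x) length(unique(x)), integer(1))
  list(links = links, per_comparison = per_comparison,
       union_genes = sort(unique(links$gene_id)))
}

#' Mean methylation level per feature class and context
#'
#' Coverage-weighted (pooled) corrected levels by feature class and
#' sequence context. Classes containing no covered cytosines are absent
#' from the table rather than reported as zero.
#'
#' @param sites Site data frame with counts (`chrom`, `pos`, `context`,
#'   `n_meth`, `n_unmeth`).
#' @param index A [build_feature_index()] object.
#' @param r Non-conversion rate.
#' @return Data frame `feature`, `context`, `n_sites`, `level`.
#' @export
feature_methylation_profile <- function(sites, index, r = 0) {
  gr <- .items_gr(sites, index$chrom_lengths)
  rows <- lapply(names(index$classes), function(cl) {
    hit <- IRanges::overlapsAny(gr, index$classes[[cl]])
    if (!any(hit)) return(NULL)
    d <- data.table::as.data.table(sites[hit, c("context", "n_meth", "n_unmeth")])
    agg <- d[, .(n_sites = .N, n_meth = sum(n_meth), n_total = sum(n_meth + n_unmeth)),
             by = context]
    agg <- agg[n_total > 0]
    if (nrow(agg) == 0) return(NULL)
    data.frame(feature = cl, context = agg$context, n_sites = agg$n_sites,
               level = correct_level(agg$n_meth / agg$n_total, r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metagene profile around gene bodies
#'
#' Genes are aligned at the TSS and TES: each `flank` bp flank is cut into
#' `n_bins` fixed-width bins (100 bp at defaults) and the gene body into
#' `body_bins` proportional bins. Minus-strand genes are orientation
#' flipped so bin 1 is always the most 5' upstream bin. Items (DMC
#' positions, DMR intervals via their midpoint, or per-site levels via
#' `values`) falling in a bin are counted; the reported density is items
#' per bp per gene, or the mean of `values` when given.
#'
#' @param items Data frame with `chrom` and `pos` (or `start`/`end`, in
#'   which case midpoints are profiled).
#' @param genes A `gene_models` object.
#' @param flank Flank width in bp; must be divisible by `n_bins`.
#' @param n_bins Bins per flank (default 20).
#' @param body_bins Bins across the gene body (default 20).
#' @param values Optional numeric vector (one per item) to average per bin
#'   instead of counting.
#' @return Data frame: `bin` (1..`2*n_bins+body_bins`), `region`
#'   (`upstream`, `body`, `downstream`), `count`, `bp` (total bp of the bin
#'   over all genes), `density` (count/bp), and `mean_value` when `values`
#'   was supplied.
#' @export
metagene_profile <- function(items, genes, flank = 2000, n_bins = 20,
                             body_bins = 20, values = NULL) {
  if (flank %% n_bins != 0) stop("flank must be divisible by n_bins")
  bin_bp <- flank / n_bins
  g <- genes$genes
  total_bins <- 2L * n_bins + body_bins
  if (!"pos" %in% names(items)) {
    items <- data.frame(chrom = items$chrom,
                        pos = floor((items$start + items$end) / 2))
  }
  counts <- numeric(total_bins)
  vsums <- numeric(total_bins)
  it <- data.table::as.data.table(items)
  it[, val := if (is.null(values)) NA_real_ else values]
  for (i in seq_len(nrow(g))) {
    plus <- g$strand[i] == "+"
    tss <- g$tss[i]; tes <- g$tes[i]
    len <- abs(tes - tss) + 1L
    sel <- it$chrom == g$chrom[i] &
      it$pos >= min(tss, tes) - flank & it$pos <= max(tss, tes) + flank
    if (!any(sel)) next
    p <- it$pos[sel]
    v <- it$val[sel]
    # signed distance along the gene's own orientation, 0 at the TSS
    s <- if (plus) p - tss else tss - p
    bin <- integer(length(s))
    up <- s < 0
    dn <- s >= len
    body <- !up & !dn
    bin[up] <- n_bins + ceiling((s[up] + 1) / bin_bp)            # 1..n_bins
    bin[body] <- n_bins + pmin(body_bins, floor(s[body] / len * body_bins) + 1L)
    bin[dn] <- n_bins + body_bins + pmin(n_bins, floor((s[dn] - len) / bin_bp) + 1L)
    ok <- bin >= 1L & bin <= total_bins
    tb <- tabulate(bin[ok], nbins = total_bins)
    counts <- counts + tb
    if (!is.null(values)) {
      vs <- rowsum(v[ok], bin[ok])
      vsums[as.integer(rownames(vs))] <- vsums[as.integer(rownames(vs))] + vs[, 1]
    }
  }
  body_bp_per_gene <- (abs(g$tes - g$tss) + 1) / body_bins
  bp <- c(rep(bin_bp * nrow(g), n_bins),
          rep(sum(body_bp_per_gene), body_bins),
          rep(bin_bp * nrow(g), n_bins))
  out <- data.frame(
    bin = seq_len(total_bins),
    region = rep(c("upstream", "body", "downstream"),
                 c(n_bins, body_bins, n_bins)),
    count = counts, bp = bp, density = counts / bp)
  if (!is.null(values)) out$mean_value <- ifelse(counts > 0, vsums / counts, NA_real_)
  out
}
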