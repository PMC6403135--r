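# Methylation-expression integration over the daily time course:
# gene-region methylation levels, rank correlation with expression,
# fixed-period harmonic regression for rhythmic-gene detection, the
# DMR x rhythm quadrant accounting, and the qPCR fold-change utility.

.REGION_SPECS <- c("promoter_500", "promoter_1000", "promoter_1500",
                   "promoter_2000", "gene_body", "downstream_500")

.region_window <- function(gene, region) {
  # gene: one row of the gene table; returns c(start, end), strand-aware
  plus <- gene$strand == "+"
  if (region == "gene_body") return(c(gene$start, gene$end))
  width <- as.integer(sub(".*_", "", region))
  if (startsWith(region, "promoter")) {
    if (plus) c(gene$tss - width, gene$tss - 1) else c(gene$tss + 1, gene$tss + width)
  } else { # downstream
    if (plus) c(gene$tes + 1, gene$tes + width) else c(gene$tes - width, gene$tes - 1)
  }
}

#' Pooled methylation level of a gene region per sample group
#'
#' Coverage-weighted corrected level over a strand-aware gene region
#' (promoter windows of 0.5/1/1.5/2 kb upstream of the TSS, the gene body,
#' or 0.5 kb downstream of the TES), pooled over a group's samples. Genes
#' with no covered cytosine in the region get `NA`.
#'
#' @param mset A [methylome_set()].
#' @param design A [sample_design()].
#' @param genes A `gene_models` object.
#' @param region One of `"promoter_500"`, `"promoter_1000"`,
#'   `"promoter_1500"`, `"promoter_2000"`, `"gene_body"`,
#'   `"downstream_500"`.
#' @param r Non-conversion rate.
#' @return Data frame `gene_id`, `region`, `group_id`, `level`, `n_sites`.
#' @export
gene_region_methylation <- function(mset, design, genes, region = "gene_body",
                                    r = 0) {
  if (!region %in% .REGION_SPECS) {
    stop("unknown region spec '", region, "'; use one of: ",
         paste(.REGION_SPECS, collapse = ", "))
  }
  g <- genes$genes
  windows <- t(vapply(seq_len(nrow(g)),
                      function(i) .region_window(g[i, ], region), numeric(2)))
  site_gr <- GenomicRanges::GRanges(mset$sites$chrom,
                                    IRanges::IRanges(mset$sites$pos, mset$sites$pos))
  ws <- pmax(1, windows[, 1])
  we <- windows[, 2]
  bad <- we < ws       # window entirely off the chromosome start
  ws[bad] <- 1; we[bad] <- 0
  win_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(ws, we))
  hits <- GenomicRanges::findOverlaps(site_gr, win_gr)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  rows <- lapply(names(design$groups), function(grp) {
    members <- design$groups[[grp]]
    nm <- rowSums(mset$n_meth[, members, drop = FALSE])
    nt <- rowSums(mset$n_total[, members, drop = FALSE])
    dt <- data.table::data.table(gene = gi, nm = nm[si], nt = nt[si])
    agg <- dt[, .(n_meth = sum(nm), n_total = sum(nt), n_sites = sum(nt > 0)),
              by = gene]
    level <- rep(NA_real_, nrow(g))
    nsite <- rep(0L, nrow(g))
    covered <- agg[n_total > 0]
    level[covered$gene] <- correct_level(covered$n_meth / covered$n_total, r)
    nsite[agg$gene] <- agg$n_sites
    data.frame(gene_id = g$gene_id, region = region, group_id = grp,
               level = level, n_sites = nsite, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate region methylation with gene expression
#'
#' Rank (Spearman) correlation between the per-gene, per-group region
#' methylation level and the group-mean log-scale expression, across all
#' gene x group points, per region. Expression is `log2(x + 1)` averaged
#' over a group's member samples; rank correlation makes the result
#' invariant to any monotone expression transform.
#'
#' @param levels Output of [gene_region_methylation()] (one or more
#'   regions stacked).
#' @param expr Genes x samples expression matrix (FPKM scale).
#' @param design A [sample_design()].
#' @param method Correlation method (default `"spearman"`).
#' @return List: `correlations` (data frame `region`, `rho`, `p`, `n`;
#'   `NA` when fewer than 3 complete pairs) and `pairs` (scatter-ready
#'   `gene_id`, `region`, `group_id`, `level`, `log_expr`).
#' @export
methylation_expression_correlation <- function(levels, expr, design,
                                               method = "spearman") {
  log_expr <- log2(expr + 1)
  group_expr <- sapply(names(design$groups), function(grp) {
    rowMeans(log_expr[, design$groups[[grp]], drop = FALSE])
  })
  pairs <- levels
  pairs$log_expr <- NA_real_
  gi <- match(pairs$gene_id, rownames(expr))
  ok <- !is.na(gi)
  pairs$log_expr[ok] <- group_expr[cbind(gi[ok], match(pairs$group_id[ok],
                                                       colnames(group_expr)))]
  cors <- lapply(unique(pairs$region), function(rg) {
    d <- pairs[pairs$region == rg & !is.na(pairs$level) & !is.na(pairs$log_expr), ]
    if (nrow(d) < 3) {
      return(data.frame(region = rg, rho = NA_real_, p = NA_real_,
                        n = nrow(d), stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(d$level, d$log_expr,
                                           method = method, exact = FALSE))
    data.frame(region = rg, rho = unname(ct$estimate), p = ct$p.value,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  list(correlations = do.call(rbind, cors), pairs = pairs)
}

#' Detect rhythmic genes by fixed-period harmonic regression
#'
#' Fits `log2(x+1) = mesor + a cos(2 pi t / period) + b sin(2 pi t /
#' period)` per gene by least squares and tests the two harmonic terms
#' against the intercept-only model with an F test; BH correction over all
#' genes. With `moderate = TRUE` (the default when at least 10 genes are
#' supplied) the residual variances are shrunk across genes by limma's
#' empirical-Bayes machinery before the F test -- with a handful of
#' residual degrees of freedom per gene, borrowing strength across the
#' transcriptome is what makes the test usable. Amplitude is
#' `sqrt(a^2 + b^2)` and phase the peak time `atan2(b, a) * period /
#' (2 pi)` mapped to `[0, period)`. Constant genes get p = 1 by
#' convention.
#'
#' @param expr Genes x samples expression matrix (FPKM scale).
#' @param timepoints Hours per sample (named by sample id, or in column
#'   order of `expr`).
#' @param period Fixed period in hours (default 24).
#' @param q_threshold BH q-value threshold for the `rhythmic` flag
#'   (default 0.05).
#' @param moderate Shrink residual variances across genes (limma
#'   `eBayes`); `NULL` (default) enables it when 10 or more genes are
#'   present.
#' @return Data frame (`rhythm_fits`): `gene_id`, `mesor`, `amplitude`,
#'   `phase`, `p`, `q`, `rhythmic`.
#' @export
detect_rhythmic_genes <- function(expr, timepoints, period = 24,
                                  q_threshold = 0.05, moderate = NULL) {
  if (!is.null(names(timepoints))) {
    if (!all(colnames(expr) %in% names(timepoints))) {
      stop("missing timepoints for some samples")
    }
    timepoints <- timepoints[colnames(expr)]
  }
  n <- ncol(expr)
  if (n < 5) stop("at least 5 time points required")
  if (is.null(moderate)) moderate <- nrow(expr) >= 10
  y <- log2(t(expr) + 1)           # samples x genes
  w <- 2 * pi / period
  X <- cbind(1, cos(w * timepoints), sin(w * timepoints))
  if (qr(X)$rank < 3) stop("time points do not identify the harmonic terms")
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, y)           # 3 x genes
  fit <- X %*% beta
  rss <- colSums((y - fit)^2)
  tss <- colSums(scale(y, scale = FALSE)^2)
  df2 <- n - 3
  constant <- tss < .Machine$double.eps^0.5
  if (moderate) {
    colnames(X) <- c("intercept", "c1", "s1")
    p <- rep(NA_real_, ncol(y))
    if (any(!constant)) {
      lfit <- limma::eBayes(limma::lmFit(t(y[, !constant, drop = FALSE]), X))
      tab <- limma::topTable(lfit, coef = c("c1", "s1"), number = Inf,
                             sort.by = "none")
      p[!constant] <- tab$P.Value
    }
  } else {
    Fstat <- ((tss - rss) / 2) / (rss / df2)
    p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
    p[!is.finite(Fstat) & !constant] <- 0    # exact fit
  }
  p[constant] <- 1                           # constant series
  amplitude <- sqrt(beta[2, ]^2 + beta[3, ]^2)
  phase <- (atan2(beta[3, ], beta[2, ]) * period / (2 * pi)) %% period
  q <- adjust_fdr(p)
  data.frame(gene_id = rownames(expr), mesor = beta[1, ],
             amplitude = amplitude, phase = phase, p = p, q = q,
             rhythmic = q < q_threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cross rhythmic genes with DMR direction and expression change
#'
#' For every rhythmic gene linked to at least one DMR in a comparison,
#' classifies the gene into a (methylation direction, expression change)
#' quadrant: hyper/hypo from the linked DMR (the largest-|diff| DMR wins
#' if a gene has links of both directions in one comparison) and up/down
#' from the sign of the change in group-mean `log2(x+1)` expression across
#' the same comparison. Genes with zero expression in both groups are
#' excluded and tallied.
#'
#' @param rhythm_fits Output of [detect_rhythmic_genes()].
#' @param dmg_links `links` element from
#'   [differentially_methylated_genes()].
#' @param expr Genes x samples expression matrix.
#' @param design A [sample_design()].
#' @return List: `per_comparison` (data frame `comparison`, quadrant
#'   counts `hyper_down`, `hyper_up`, `hypo_down`, `hypo_up`,
#'   `n_excluded`), `union` (the same counting distinct genes across
#'   comparisons), `genes` (per-gene classification rows),
#'   `n_rhythmic_dmg` and `frac_rhythmic_with_dmr`.
#' @export
integrate_dmr_rhythm <- function(rhythm_fits, dmg_links, expr, design) {
  rhythmic <- rhythm_fits$gene_id[rhythm_fits$rhythmic]
  links <- dmg_links[dmg_links$gene_id %in% rhythmic, , drop = FALSE]
  log_expr <- log2(expr + 1)
  group_mean <- sapply(names(design$groups), function(grp) {
    rowMeans(log_expr[, design$groups[[grp]], drop = FALSE])
  })
  rows <- list()
  n_excluded <- stats::setNames(integer(nrow(design$comparisons)),
                                design$comparisons$id)
  for (i in seq_len(nrow(design$comparisons))) {
    cmp <- design$comparisons[i, ]
    l <- links[links$comparison == cmp$id, , drop = FALSE]
    if (nrow(l) == 0) next
    for (gid in unique(l$gene_id)) {
      gl <- l[l$gene_id == gid, , drop = FALSE]
      direction <- gl$direction[which.max(abs(gl$diff))]
      if (!gid %in% rownames(expr)) next
      ea <- mean(expr[gid, design$groups[[cmp$group_a]]])
      eb <- mean(expr[gid, design$groups[[cmp$group_b]]])
      if (ea == 0 && eb == 0) {
        n_excluded[cmp$id] <- n_excluded[cmp$id] + 1L
        next
      }
      d_expr <- group_mean[gid, cmp$group_b] - group_mean[gid, cmp$group_a]
      if (d_expr == 0) {
        n_excluded[cmp$id] <- n_excluded[cmp$id] + 1L
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, comparison = cmp$id, direction = direction,
        expression = if (d_expr > 0) "up" else "down",
        log2fc = d_expr, stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), comparison = character(),
               direction = character(), expression = character(),
               log2fc = numeric(), stringsAsFactors = FALSE)
  quad_counts <- function(d, label) {
    data.frame(
      comparison = label,
      hyper_down = length(unique(d$gene_id[d$direction == "hyper" & d$expression == "down"])),
      hyper_up = length(unique(d$gene_id[d$direction == "hyper" & d$expression == "up"])),
      hypo_down = length(unique(d$gene_id[d$direction == "hypo" & d$expression == "down"])),
      hypo_up = length(unique(d$gene_id[d$direction == "hypo" & d$expression == "up"])),
      stringsAsFactors = FALSE)
  }
  per_comparison <- do.call(rbind, lapply(design$comparisons$id, function(id) {
    out <- quad_counts(genes[genes$comparison == id, , drop = FALSE], id)
    out$n_excluded <- n_excluded[[id]]
    out
  }))
  union <- quad_counts(genes, "union")
  union$n_excluded <- sum(n_excluded)
  n_rhythmic_dmg <- length(unique(links$gene_id))
  list(per_comparison = per_comparison, union = union, genes = genes,
       n_rhythmic_dmg = n_rhythmic_dmg,
       frac_rhythmic_with_dmr = if (length(rhythmic)) n_rhythmic_dmg / length(rhythmic) else NA_real_)
}

#' Relative qPCR fold change by the 2^-ddCt method
#'
#' `2 ^ -((ct_target_test - ct_ref_test) - (ct_target_control -
#' ct_ref_control))`.
#'
#' @param ct_target_test,ct_ref_test Ct of target and reference gene in the
#'   test condition.
#' @param ct_target_control,ct_ref_control The same in the control
#'   condition.
#' @return Fold change (1 = no change).
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_test), is.finite(ct_ref_test),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_control - ct_ref_control)
  2^(-ddct)
}
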