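# DMC and DMR calling between sample groups: pooled 2x2 Fisher exact
# tests with BH correction, effect-size gating, single-linkage DMC
# clustering into regions, and summary statistics.

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment; `NA` p-values stay `NA` and do not count toward
#' the number of tests.
#'
#' @param p Numeric vector of p-values in `[0,1]` (NA allowed).
#' @return q-values, monotone in `p`.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0,1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Vectorised two-sided Fisher exact test for 2x2 count tables
#'
#' For each table `[[a, b], [c, d]]` the two-sided p-value is the sum of
#' hypergeometric point probabilities not exceeding the observed one (with
#' the conventional `1 + 1e-7` relative tie tolerance). Computed in bulk
#' over the concatenated hypergeometric supports, so genome-scale position
#' streams are feasible.
#'
#' @param a,b,c,d Integer vectors: `a`,`b` = methylated/unmethylated in
#'   group A; `c`,`d` = the same in group B.
#' @return Numeric vector of p-values.
#' @export
fisher_test_2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (n == 0) return(numeric(0))
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("counts must be non-negative")
  m <- a + c          # methylated margin (white balls)
  nn <- b + d         # unmethylated margin (black balls)
  k <- a + b          # group A coverage (draws)
  lo <- pmax(0L, k - nn)
  hi <- pmin(k, m)
  out <- numeric(n)
  chunk <- 5e4L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    lens <- hi[idx] - lo[idx] + 1L
    tab <- rep(seq_along(idx), lens)
    xs <- rep(lo[idx], lens) + (sequence(lens) - 1L)
    dp <- stats::dhyper(xs, rep(m[idx], lens), rep(nn[idx], lens),
                        rep(k[idx], lens))
    d_obs <- stats::dhyper(a[idx], m[idx], nn[idx], k[idx])
    keep <- dp <= rep(d_obs, lens) * (1 + 1e-7)
    p <- rowsum(dp * keep, tab)[, 1]
    out[idx] <- pmin(1, p)
  }
  out
}

#' Pool methylation counts across the members of a group
#'
#' Sums methylated and total counts over a group's samples at every
#' position of the shared site universe; samples missing a position
#' contribute zero counts (they were aligned that way on import).
#'
#' @param mset A [methylome_set()].
#' @param design A [sample_design()].
#' @param group_id Group to pool.
#' @return Data frame: the site columns plus pooled `n_meth`, `n_unmeth`.
#' @export
pool_group_counts <- function(mset, design, group_id) {
  members <- design$groups[[group_id]]
  if (is.null(members)) stop("unknown group ", group_id)
  missing <- setdiff(members, colnames(mset$n_meth))
  if (length(missing)) stop("samples not in methylome set: ",
                            paste(missing, collapse = ", "))
  nm <- rowSums(mset$n_meth[, members, drop = FALSE])
  nt <- rowSums(mset$n_total[, members, drop = FALSE])
  sites <- mset$sites[, setdiff(names(mset$sites), c("n_meth", "n_unmeth")),
                      drop = FALSE]
  cbind(sites,
        data.frame(n_meth = as.integer(nm), n_unmeth = as.integer(nt - nm)))
}

#' Per-position differential methylation test between two pooled groups
#'
#' Two-sided Fisher exact p-value of the 2x2 methylated/unmethylated table
#' plus the corrected level difference (group B minus group A). Positions
#' with zero coverage in either group get `NA` (skipped, not an error).
#'
#' @param counts_a,counts_b Data frames (or lists) with `n_meth` and
#'   `n_unmeth` for the same positions.
#' @param r Non-conversion rate used to correct the pooled levels.
#' @return Data frame `level_a`, `level_b`, `diff`, `p`.
#' @export
dmc_test <- function(counts_a, counts_b, r = 0) {
  ta <- counts_a$n_meth + counts_a$n_unmeth
  tb <- counts_b$n_meth + counts_b$n_unmeth
  covered <- ta > 0 & tb > 0
  level_a <- correct_level(methylation_level(counts_a$n_meth, counts_a$n_unmeth), r)
  level_b <- correct_level(methylation_level(counts_b$n_meth, counts_b$n_unmeth), r)
  p <- rep(NA_real_, length(ta))
  p[covered] <- fisher_test_2x2(counts_a$n_meth[covered], counts_a$n_unmeth[covered],
                                counts_b$n_meth[covered], counts_b$n_unmeth[covered])
  data.frame(level_a = level_a, level_b = level_b, diff = level_b - level_a, p = p)
}

#' Call differentially methylated cytosines for one comparison
#'
#' Pools counts within each group, runs the Fisher exact test at every
#' position covered in both groups, applies BH over all tested positions
#' genome-wide, and retains positions with q < `alpha` and a corrected
#' level difference exceeding `min_diff` in absolute value.
#'
#' @param mset A [methylome_set()].
#' @param design A [sample_design()].
#' @param comparison Comparison id (e.g. `"G2vG1"`) from the design.
#' @param r Non-conversion rate.
#' @param alpha BH q-value threshold (default 0.05).
#' @param min_diff Minimum |level difference| (default 0.2).
#' @return Data frame of DMCs (site columns, `level_a`, `level_b`, `diff`,
#'   `p`, `q`, `direction`, `comparison`), sorted by chromosome and
#'   position, with attributes `n_tested` and `n_skipped`.
#' @export
call_dmcs <- function(mset, design, comparison, r = 0, alpha = 0.05,
                      min_diff = 0.2) {
  cmp <- design$comparisons[design$comparisons$id == comparison, ]
  if (nrow(cmp) != 1) stop("unknown comparison ", comparison)
  pa <- pool_group_counts(mset, design, cmp$group_a)
  pb <- pool_group_counts(mset, design, cmp$group_b)
  res <- dmc_test(pa, pb, r)
  res$q <- adjust_fdr(res$p)
  keep <- !is.na(res$q) & res$q < alpha & abs(res$diff) > min_diff
  out <- cbind(mset$sites[keep, , drop = FALSE], res[keep, , drop = FALSE])
  out$direction <- ifelse(out$diff > 0, "hyper", "hypo")
  out$comparison <- rep(comparison, nrow(out))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- sum(!is.na(res$p))
  attr(out, "n_skipped") <- sum(is.na(res$p))
  out
}

#' Cluster DMCs into differentially methylated regions
#'
#' Single-linkage clustering of same-direction DMCs whose adjacent gaps are
#' below `max_gap`; a DMC of the opposite direction breaks a chain.
#' Clusters with at least `min_dmcs` members become candidate regions
#' spanning the first to last member DMC; the region level difference is
#' the pooled corrected difference over ALL cytosines in the span (not just
#' the DMCs), and candidates with |diff| > `min_diff` are emitted.
#'
#' @param dmcs DMCs from [call_dmcs()] (one comparison), sorted by
#'   chromosome and position.
#' @param mset The [methylome_set()] the DMCs came from.
#' @param design A [sample_design()].
#' @param r Non-conversion rate.
#' @param min_diff Minimum |region level difference| (default 0.1).
#' @param min_dmcs Minimum member DMCs (default 3).
#' @param max_gap Adjacent member DMCs must be closer than this (default
#'   300 bp).
#' @param call_alpha,call_min_coverage Parameters for flagging methylated
#'   cytosines inside each region (the `n_mc` field).
#' @return Data frame of DMRs: `chrom`, `start`, `end`, `length`,
#'   `comparison`, `n_dmc`, `diff`, `direction`, `n_mc`, `n_cg`, `n_chg`,
#'   `n_chh`.
#' @export
call_dmrs <- function(dmcs, mset, design, r = 0, min_diff = 0.1, min_dmcs = 3,
                      max_gap = 300, call_alpha = 0.05, call_min_coverage = 5) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), comparison = character(),
                      n_dmc = integer(), diff = numeric(),
                      direction = character(), n_mc = integer(),
                      n_cg = integer(), n_chg = integer(), n_chh = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(dmcs) == 0) return(empty)
  if (length(unique(dmcs$comparison)) != 1) {
    stop("DMCs must come from a single comparison")
  }
  ord <- order(dmcs$chrom, dmcs$pos)
  if (!identical(ord, seq_len(nrow(dmcs)))) stop("DMCs must be sorted by (chrom, pos)")
  comparison <- dmcs$comparison[1]
  cmp <- design$comparisons[design$comparisons$id == comparison, ]
  pa <- pool_group_counts(mset, design, cmp$group_a)
  pb <- pool_group_counts(mset, design, cmp$group_b)
  pooled_all <- pa
  pooled_all$n_meth <- pa$n_meth + pb$n_meth
  pooled_all$n_unmeth <- pa$n_unmeth + pb$n_unmeth
  mc_flags <- call_methylated_sites(pooled_all, r, alpha = call_alpha,
                                    min_coverage = call_min_coverage)
  new_cluster <- c(TRUE, dmcs$chrom[-1] != dmcs$chrom[-nrow(dmcs)] |
                     diff(dmcs$pos) >= max_gap |
                     dmcs$direction[-1] != dmcs$direction[-nrow(dmcs)])
  cl <- cumsum(new_cluster)
  out <- lapply(split(seq_len(nrow(dmcs)), cl), function(ii) {
    if (length(ii) < min_dmcs) return(NULL)
    d <- dmcs[ii, , drop = FALSE]
    chrom <- d$chrom[1]
    start <- min(d$pos); end <- max(d$pos)
    in_span <- pa$chrom == chrom & pa$pos >= start & pa$pos <= end
    la <- correct_level(methylation_level(sum(pa$n_meth[in_span]),
                                          sum(pa$n_unmeth[in_span])), r)
    lb <- correct_level(methylation_level(sum(pb$n_meth[in_span]),
                                          sum(pb$n_unmeth[in_span])), r)
    region_diff <- lb - la
    if (is.na(region_diff) || abs(region_diff) <= min_diff) return(NULL)
    data.frame(chrom = chrom, start = start, end = end,
               length = end - start + 1L, comparison = comparison,
               n_dmc = length(ii), diff = region_diff,
               direction = d$direction[1], n_mc = sum(mc_flags[in_span]),
               n_cg = sum(d$context == "CG"), n_chg = sum(d$context == "CHG"),
               n_chh = sum(d$context == "CHH"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise DMR and DMC calls
#'
#' Per comparison and overall: DMR count, hypo/hyper counts and their
#' ratio, maximum region length, maximum methylated-cytosine content, and
#' the context composition of the member DMCs as percentages.
#'
#' @param dmrs Data frame of DMRs (possibly several comparisons).
#' @param dmcs Data frame of DMCs (used for the context composition of all
#'   DMC calls; pass `NULL` to use the DMRs' member-DMC context counts).
#' @return Data frame with one row per comparison plus an `overall` row.
#' @export
dmr_summary <- function(dmrs, dmcs = NULL) {
  one <- function(d, dc, label) {
    n_hypo <- sum(d$direction == "hypo")
    n_hyper <- sum(d$direction == "hyper")
    if (is.null(dc)) {
      ctx <- c(CG = sum(d$n_cg), CHG = sum(d$n_chg), CHH = sum(d$n_chh))
    } else {
      ctx <- c(CG = sum(dc$context == "CG"), CHG = sum(dc$context == "CHG"),
               CHH = sum(dc$context == "CHH"))
    }
    pct <- if (sum(ctx) > 0) 100 * ctx / sum(ctx) else c(CG = 0, CHG = 0, CHH = 0)
    data.frame(comparison = label, n_dmr = nrow(d), n_hypo = n_hypo,
               n_hyper = n_hyper,
               hypo_hyper_ratio = if (n_hyper > 0) n_hypo / n_hyper else NA_real_,
               max_length = if (nrow(d)) max(d$length) else 0L,
               max_n_mc = if (nrow(d)) max(d$n_mc) else 0L,
               pct_cg = unname(pct["CG"]), pct_chg = unname(pct["CHG"]),
               pct_chh = unname(pct["CHH"]), stringsAsFactors = FALSE)
  }
  comps <- unique(dmrs$comparison)
  rows <- lapply(comps, function(cp) {
    one(dmrs[dmrs$comparison == cp, , drop = FALSE],
        if (is.null(dmcs)) NULL else dmcs[dmcs$comparison == cp, , drop = FALSE],
        cp)
  })
  rows <- c(rows, list(one(dmrs, dmcs, "overall")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
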