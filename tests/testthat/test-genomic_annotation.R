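chrlen <- c(Chr01 = 20000L)

two_gene_index <- function() {
  genes <- make_gene_models(
    data.frame(gene_id = c("gP", "gM"), chrom = "Chr01",
               start = c(5001L, 12001L), end = c(8000L, 14000L),
               strand = c("+", "-"), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("gP", "gP", "gM"),
                       start = c(5001L, 6501L, 12001L),
                       end = c(6000L, 8000L, 14000L), stringsAsFactors = FALSE),
    utr5 = data.frame(gene_id = c("gP", "gM"), start = c(5001L, 13901L),
                      end = c(5150L, 14000L), stringsAsFactors = FALSE))
  tes <- data.frame(chrom = "Chr01", start = 1000L, end = 2500L,
                    family = "hAT", stringsAsFactors = FALSE)
  build_feature_index(genes, tes, chrlen)
}

test_that("promoters are strand-aware and clipped at chromosome bounds", {
  idx <- two_gene_index()
  prom <- as.data.frame(idx$classes$promoter)
  # + strand gene at 5001: promoter [3001, 5000]
  expect_true(any(prom$start == 3001 & prom$end == 5000))
  # - strand gene ending at 14000: promoter [14001, 16000]
  expect_true(any(prom$start == 14001 & prom$end == 16000))
  # gene starting near the chromosome edge: promoter clipped to [1, 99]
  g_edge <- make_gene_models(data.frame(
    gene_id = "gE", chrom = "Chr01", start = 100L, end = 600L, strand = "+",
    stringsAsFactors = FALSE))
  idx2 <- build_feature_index(g_edge, NULL, chrlen)
  prom2 <- as.data.frame(idx2$classes$promoter)
  expect_equal(c(prom2$start, prom2$end), c(1, 99))
  g_off <- make_gene_models(data.frame(
    gene_id = "gO", chrom = "Chr01", start = 100L, end = 99999L,
    strand = "+", stringsAsFactors = FALSE))
  expect_error(build_feature_index(g_off, NULL, chrlen), "bounds")
})

test_that("feature assignment honours multi-labels and the precedence rule", {
  idx <- two_gene_index()
  items <- data.frame(
    chrom = "Chr01",
    start = c(6101L, 4901L, 1500L, 18000L),
    end = c(6200L, 5100L, 1600L, 18100L))
  # item 1 wholly inside the gP intron; item 2 spans promoter and 5'UTR;
  # item 3 inside the TE; item 4 in open intergenic space
  res <- assign_features(items, idx)
  expect_equal(res$primary[1], "intron")
  expect_true(res$overlap[2, "promoter"] && res$overlap[2, "five_prime_utr"])
  expect_equal(res$primary[2], "promoter")
  expect_equal(res$primary[3], "TE")
  expect_true(res$overlap[3, "TE:hAT"])
  expect_equal(res$primary[4], "intergenic")
  expect_equal(sum(res$genic_fractions), 100)
  expect_error(assign_features(data.frame(chrom = "ChrX", start = 1, end = 2),
                               idx), "unknown chromosome")
})

test_that("every position gets a label and assignment matches a position scan", {
  idx <- two_gene_index()
  pos <- seq(1L, 20000L, by = 7L)
  items <- data.frame(chrom = "Chr01", pos = pos)
  res <- assign_features(items, idx)
  # partition-cover: intergenic is exactly the complement of the rest
  other <- res$overlap[, colnames(res$overlap) != "intergenic", drop = FALSE]
  expect_identical(res$overlap[, "intergenic"], rowSums(other) == 0)
  # brute-force interval scan per class
  for (cl in colnames(res$overlap)) {
    ivs <- as.data.frame(idx$classes[[cl]])
    hit <- vapply(pos, function(p) any(p >= ivs$start & p <= ivs$end),
                  logical(1))
    expect_identical(unname(res$overlap[, cl]), hit, info = cl)
  }
})

test_that("differentially methylated genes use body-or-promoter overlap, once per gene", {
  idx <- two_gene_index()
  genes <- make_gene_models(
    data.frame(gene_id = "g1", chrom = "Chr01", start = 5001L, end = 8000L,
               strand = "+", stringsAsFactors = FALSE))
  dmr <- function(s, e, cmp = "G2vG1") {
    data.frame(chrom = "Chr01", start = s, end = e, length = e - s + 1L,
               comparison = cmp, n_dmc = 3L, diff = 0.3, direction = "hyper",
               n_mc = 5L, n_cg = 0L, n_chg = 0L, n_chh = 3L,
               stringsAsFactors = FALSE)
  }
  # promoter overlap only
  res <- differentially_methylated_genes(dmr(4000, 4500), genes, chrlen)
  expect_equal(res$union_genes, "g1")
  expect_equal(res$links$region, "promoter")
  # far away: nothing
  res2 <- differentially_methylated_genes(dmr(1, 100), genes, chrlen)
  expect_length(res2$union_genes, 0)
  # two DMRs on one gene: counted once
  res3 <- differentially_methylated_genes(rbind(dmr(4000, 4500), dmr(6000, 6200)),
                                          genes, chrlen)
  expect_equal(unname(res3$per_comparison["G2vG1"]), 1L)
  expect_equal(res3$union_genes, "g1")
})

test_that("per-feature levels recover the planted ordering, uniform input is flat", {
  idx <- two_gene_index()
  set.seed(71)
  pos <- sort(sample.int(20000L, 4000))
  # uniform methylome: all features should agree within sampling error
  s_unif <- make_sites("Chr01", pos, rbinom(4000, 30, 0.3),
                       30 - rbinom(4000, 30, 0.3), context = "CG")
  s_unif$n_unmeth <- 30L - s_unif$n_meth
  prof_u <- feature_methylation_profile(s_unif, idx)
  expect_lt(diff(range(prof_u$level[prof_u$n_sites > 100])), 0.08)
  # planted ordering: TE > exon > UTR
  lvl <- rep(0.3, length(pos))
  te_hit <- pos >= 1000 & pos <= 2500
  utr_hit <- (pos >= 5001 & pos <= 5150) | (pos >= 13901 & pos <= 14000)
  lvl[te_hit] <- 0.8
  lvl[utr_hit] <- 0.05
  nm <- rbinom(length(pos), 30, lvl)
  s_ord <- make_sites("Chr01", pos, nm, 30L - nm, context = "CG")
  prof <- feature_methylation_profile(s_ord, idx)
  get <- function(f) prof$level[prof$feature == f]
  expect_gt(get("TE:hAT"), get("exon"))
  expect_gt(get("exon"), get("five_prime_utr"))
})

test_that("metagene bins have the documented geometry and flag planted patterns", {
  genes <- make_gene_models(data.frame(
    gene_id = c("gA", "gB"), chrom = "Chr01", start = c(5001L, 12001L),
    end = c(7000L, 14000L), strand = c("+", "-"), stringsAsFactors = FALSE))
  prof0 <- metagene_profile(data.frame(chrom = "Chr01", pos = 6000L), genes)
  expect_equal(nrow(prof0), 60)
  expect_equal(unique(prof0$bp[prof0$region == "upstream"]), 100 * 2)
  expect_error(metagene_profile(data.frame(chrom = "Chr01", pos = 1L), genes,
                                flank = 2000, n_bins = 30), "divisible")
  # flank-only placement: body bins (including the TSS/TES-adjacent ones) dip
  set.seed(81)
  flank_pos <- c(sample(3001:5000, 400, TRUE), sample(7001:9000, 400, TRUE),
                 sample(10001:12000, 400, TRUE), sample(14001:16000, 400, TRUE))
  prof1 <- metagene_profile(data.frame(chrom = "Chr01", pos = flank_pos), genes)
  body <- prof1$density[prof1$region == "body"]
  flank <- prof1$density[prof1$region != "body"]
  expect_equal(sum(body), 0)
  expect_gt(min(flank), 0)
})

test_that("orientation flip is an involution: mirrored genes give mirrored profiles", {
  # one plus gene and its mirror-image minus gene with mirrored items
  gp <- make_gene_models(data.frame(
    gene_id = "gp", chrom = "Chr01", start = 5001L, end = 7000L,
    strand = "+", stringsAsFactors = FALSE))
  gm <- make_gene_models(data.frame(
    gene_id = "gm", chrom = "Chr01", start = 5001L, end = 7000L,
    strand = "-", stringsAsFactors = FALSE))
  set.seed(91)
  pos <- sample(3001:9000, 500, TRUE)
  mirror <- 12001L - pos  # reflection about the gene centre
  p1 <- metagene_profile(data.frame(chrom = "Chr01", pos = pos), gp)
  p2 <- metagene_profile(data.frame(chrom = "Chr01", pos = mirror), gm)
  expect_equal(p2$count, p1$count)
})
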