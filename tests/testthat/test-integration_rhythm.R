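design9 <- sample_design()

test_that("gene region levels pool counts over strand-aware windows", {
  genes <- make_gene_models(data.frame(
    gene_id = c("gp", "gm"), chrom = "Chr01", start = c(5001L, 9001L),
    end = c(6000L, 10000L), strand = c("+", "-"), stringsAsFactors = FALSE))
  d <- mini_design()
  # two covered sites in gp's body: (3,1) and (1,3) pool to 0.5
  sites <- make_sites("Chr01", c(5100L, 5200L, 4800L, 10300L),
                      0, 0, context = "CG")
  nm <- cbind(a1 = c(3L, 1L, 2L, 4L), a2 = c(0L, 0L, 2L, 0L),
              b1 = c(0L, 0L, 0L, 0L), b2 = c(0L, 0L, 0L, 0L))
  nt <- cbind(a1 = c(4L, 4L, 4L, 4L), a2 = c(0L, 0L, 4L, 4L),
              b1 = c(0L, 0L, 0L, 0L), b2 = c(0L, 0L, 0L, 0L))
  ms <- make_mset(sites, nm, nt)
  body <- gene_region_methylation(ms, d, genes, "gene_body")
  expect_equal(body$level[body$gene_id == "gp" & body$group_id == "A"], 0.5)
  expect_true(is.na(body$level[body$gene_id == "gp" & body$group_id == "B"]))
  # promoter_500 of the + gene (TSS 5001) is [4501, 5000]: site at 4800
  prom <- gene_region_methylation(ms, d, genes, "promoter_500")
  expect_equal(prom$level[prom$gene_id == "gp" & prom$group_id == "A"], 0.5)
  expect_equal(prom$n_sites[prom$gene_id == "gp" & prom$group_id == "A"], 1L)
  # downstream_500 is strand-aware: for gm (minus strand) TES = 9001 and
  # downstream runs leftwards over [8501, 9000], which holds no sites
  dn <- gene_region_methylation(ms, d, genes, "downstream_500")
  expect_equal(dn$n_sites[dn$gene_id == "gm" & dn$group_id == "A"], 0L)
  expect_error(gene_region_methylation(ms, d, genes, "enhancer"),
               "unknown region spec")
})

test_that("rank correlation is exact in the monotone limit and NA when degenerate", {
  d <- mini_design()
  genes <- sprintf("g%02d", 1:20)
  lv <- data.frame(gene_id = rep(genes, 2), region = "gene_body",
                   group_id = rep(c("A", "B"), each = 20),
                   level = rep(seq(0.05, 0.9, length.out = 20), 2),
                   n_sites = 10L, stringsAsFactors = FALSE)
  expr <- matrix(rep(2^(seq(1, 8, length.out = 20)), 4), nrow = 20,
                 dimnames = list(genes, d$samples))
  res <- methylation_expression_correlation(lv, expr, d)
  expect_equal(res$correlations$rho, 1)
  # monotone transform of expression leaves the rank correlation unchanged
  res2 <- methylation_expression_correlation(lv, expr^3, d)
  expect_equal(res2$correlations$rho, 1)
  # fewer than 3 complete pairs: undefined
  lv3 <- lv[1:2, ]
  lv3$level <- c(0.2, 0.4)
  res3 <- methylation_expression_correlation(lv3, expr, d)
  expect_true(is.na(res3$correlations$rho))
})

test_that("harmonic regression recovers noiseless cosines exactly", {
  t <- unname(design9$timepoints)
  ids <- c("gcos", "gflat")
  y <- rbind(5 + 2 * cos(2 * pi * (t - 8) / 24), rep(3, 9))
  expr <- matrix(pmax(0, 2^y - 1), 2, 9,
                 dimnames = list(ids, names(design9$timepoints)))
  rf <- detect_rhythmic_genes(expr, design9$timepoints, moderate = FALSE)
  g <- rf[rf$gene_id == "gcos", ]
  expect_equal(g$amplitude, 2, tolerance = 1e-9)
  expect_equal(g$phase, 8, tolerance = 1e-9)
  expect_equal(g$mesor, 5, tolerance = 1e-9)
  expect_lt(g$p, 1e-12)
  expect_equal(rf$p[rf$gene_id == "gflat"], 1)   # constant: not rhythmic
  expect_false(rf$rhythmic[rf$gene_id == "gflat"])
  # closed-form recovery over random noiseless inputs
  set.seed(101)
  for (i in 1:10) {
    A <- runif(1, 0.5, 3); ph <- runif(1, 0, 24); m <- runif(1, 3, 6)
    yy <- m + A * cos(2 * pi * (t - ph) / 24)
    e1 <- matrix(pmax(0, 2^rbind(yy, yy) - 1), 2, 9,
                 dimnames = list(c("a", "b"), names(design9$timepoints)))
    r1 <- detect_rhythmic_genes(e1, design9$timepoints, moderate = FALSE)
    expect_equal(r1$amplitude[1], A, tolerance = 1e-9)
    expect_equal(r1$phase[1], ph, tolerance = 1e-9)
  }
  expect_error(detect_rhythmic_genes(expr[, 1:4], design9$timepoints[1:4]),
               "5 time points")
})

test_that("false-positive control of rhythm detection respects the BH level", {
  set.seed(111)
  ids <- sprintf("g%04d", 1:1000)
  se <- simulate_expression(ids, design9, rhythmic_fraction = 0, seed = 112)
  rf <- detect_rhythmic_genes(se$expr, design9$timepoints)
  expect_lte(sum(rf$rhythmic) / 1000, 0.01)
})

test_that("quadrant integration classifies by DMR direction and expression change", {
  rf <- data.frame(gene_id = c("g1", "g2", "g3"), mesor = 1, amplitude = 1,
                   phase = 0, p = 0.001, q = 0.001,
                   rhythmic = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  links <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3"),
    comparison = c("G2vG1", "G2vG1", "G3vG2", "G2vG1"),
    dmr_index = 1:4, region = "promoter",
    direction = c("hyper", "hypo", "hyper", "hyper"),
    diff = c(0.5, -0.4, 0.3, 0.2), stringsAsFactors = FALSE)
  expr <- matrix(1, 3, 9, dimnames = list(c("g1", "g2", "g3"),
                                          design9$samples))
  # g1 down in G2 vs G1; g2 up in G2 vs G1 and down in G3 vs G2
  expr["g1", design9$groups$G2] <- 0.4
  expr["g2", design9$groups$G2] <- 3
  res <- integrate_dmr_rhythm(rf, links, expr, design9)
  pc <- res$per_comparison
  expect_equal(pc$hyper_down[pc$comparison == "G2vG1"], 1)  # g1
  expect_equal(pc$hypo_up[pc$comparison == "G2vG1"], 1)     # g2
  expect_equal(pc$hyper_down[pc$comparison == "G3vG2"], 1)  # g2 again
  # g3 is not rhythmic: contributes nowhere
  expect_false("g3" %in% res$genes$gene_id)
  # per-comparison quadrant counts sum to classified genes
  for (cmp in unique(res$genes$comparison)) {
    row <- pc[pc$comparison == cmp, ]
    expect_equal(row$hyper_down + row$hyper_up + row$hypo_down + row$hypo_up,
                 length(unique(res$genes$gene_id[res$genes$comparison == cmp])))
  }
  expect_equal(res$n_rhythmic_dmg, 2)
})

test_that("anti-phase planted coupling dominates the quadrant table", {
  # genes whose methylation rises while expression falls and vice versa
  set.seed(121)
  n <- 60
  ids <- sprintf("g%03d", seq_len(n))
  rf <- data.frame(gene_id = ids, mesor = 1, amplitude = 1, phase = 0,
                   p = 0.001, q = 0.001, rhythmic = TRUE,
                   stringsAsFactors = FALSE)
  dirs <- rep(c("hyper", "hypo"), n / 2)
  links <- data.frame(gene_id = ids, comparison = "G2vG1", dmr_index = seq_len(n),
                      region = "gene_body", direction = dirs,
                      diff = ifelse(dirs == "hyper", 0.4, -0.4),
                      stringsAsFactors = FALSE)
  expr <- matrix(2, n, 9, dimnames = list(ids, design9$samples))
  expr[dirs == "hyper", design9$groups$G2] <- 0.5   # hyper genes go down
  expr[dirs == "hypo", design9$groups$G2] <- 8      # hypo genes go up
  res <- integrate_dmr_rhythm(rf, links, expr, design9)
  u <- res$union
  expect_equal(u$hyper_down + u$hypo_up, n)
  expect_equal(u$hyper_up + u$hypo_down, 0)
})

test_that("ddCt fold change follows the exponent rule", {
  expect_equal(ddct_fold_change(20, 18, 22, 20), 1)
  expect_equal(ddct_fold_change(19, 18, 22, 20), 2)
  expect_equal(ddct_fold_change(20, 19, 18, 16), 2)
  expect_equal(ddct_fold_change(24, 18, 20, 16), 0.25)
  expect_error(ddct_fold_change(NA, 1, 1, 1))
})
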