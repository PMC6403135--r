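test_that("Fisher test matches worked examples and the enumeration oracle", {
  # identical margins -> p = 1, no difference
  res <- dmc_test(list(n_meth = 10, n_unmeth = 10),
                  list(n_meth = 10, n_unmeth = 10))
  expect_equal(res$p, 1)
  expect_equal(res$diff, 0)
  # complete separation
  res2 <- dmc_test(list(n_meth = 20, n_unmeth = 0),
                   list(n_meth = 0, n_unmeth = 20))
  expect_equal(res2$diff, -1)
  expect_equal(res2$p, oracle_fisher_p(20, 0, 0, 20), tolerance = 1e-12)
  res3 <- dmc_test(list(n_meth = 15, n_unmeth = 5),
                   list(n_meth = 5, n_unmeth = 15))
  expect_equal(res3$diff, -0.5)
  expect_equal(res3$p, oracle_fisher_p(15, 5, 5, 15), tolerance = 1e-12)
})

test_that("Fisher test agrees with stats::fisher.test on random tables", {
  set.seed(21)
  a <- rpois(200, 8); b <- rpois(200, 8); c <- rpois(200, 8); d <- rpois(200, 8)
  mine <- fisher_test_2x2(a, b, c, d)
  ref <- vapply(seq_along(a), function(i) {
    stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2))$p.value
  }, numeric(1))
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("zero-coverage positions are skipped with a tally, not errors", {
  a <- list(n_meth = c(5, 0), n_unmeth = c(5, 0))
  b <- list(n_meth = c(1, 3), n_unmeth = c(9, 3))
  res <- dmc_test(a, b)
  expect_false(is.na(res$p[1]))
  expect_true(is.na(res$p[2]))
})

test_that("BH adjustment matches the hand computation and the step-up oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:500, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr(p), oracle_bh(p))
  }
  # q is monotone in p
  p <- runif(100)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("group pooling sums member counts and conserves totals", {
  s1 <- make_sites("Chr01", 10, 3, 1)
  s2 <- make_sites("Chr01", 10, 2, 4)
  s3 <- make_sites("Chr01", c(10, 50), c(1, 7), c(1, 3))
  s4 <- make_sites("Chr01", 10, 0, 2)
  ms <- methylome_set(list(a1 = s1, a2 = s2, b1 = s3, b2 = s4))
  d <- mini_design()
  pa <- pool_group_counts(ms, d, "A")
  expect_equal(pa$n_meth[pa$pos == 10], 5L)
  expect_equal(pa$n_unmeth[pa$pos == 10], 5L)
  expect_equal(pa$n_meth[pa$pos == 50], 0L)   # absent member contributes zero
  pb <- pool_group_counts(ms, d, "B")
  expect_equal(sum(pa$n_meth) + sum(pb$n_meth),
               sum(ms$n_meth))                # conservation
  expect_error(pool_group_counts(ms, d, "Z"), "unknown group")
})

test_that("DMC calling enforces both the q-value and effect-size gates", {
  set.seed(41)
  n <- 300
  pos <- seq_len(n) * 10L
  # null background plus one strongly different position and one position
  # with a large but weakly supported difference
  nm_a <- rbinom(n, 50, 0.3); nm_b <- rbinom(n, 50, 0.3)
  nt <- rep(50L, n)
  nm_a[1] <- 5L; nm_b[1] <- 45L       # diff 0.8, overwhelming
  nm_a[2] <- 0L; nm_b[2] <- 2L        # large diff, 3 reads only
  nt_small <- nt; nt_small[2] <- 3L
  sites <- make_sites("Chr01", pos, 0, 0)
  half <- function(x) as.integer(round(x / 2))
  ms <- make_mset(sites,
                  n_meth = cbind(a1 = half(nm_a), a2 = nm_a - half(nm_a),
                                 b1 = half(nm_b), b2 = nm_b - half(nm_b)),
                  n_total = cbind(a1 = half(nt_small), a2 = nt_small - half(nt_small),
                                  b1 = half(nt_small), b2 = nt_small - half(nt_small)))
  dmcs <- call_dmcs(ms, mini_design(), "BvA")
  expect_true(10 %in% dmcs$pos)                 # strong position retained
  expect_false(20 %in% dmcs$pos)                # underpowered position dropped
  expect_true(all(dmcs$q < 0.05 & abs(dmcs$diff) > 0.2))
  expect_equal(attr(dmcs, "n_tested"), n)
})

test_that("DMR clustering follows the gap, size and direction rules", {
  d <- mini_design()
  # counts: group A level 0.1, group B level 0.5 inside [1000,1400]
  pos <- c(1000L, 1150L, 1400L, 5000L)
  sites <- make_sites("Chr01", pos, 0, 0, context = c("CHH", "CHH", "CG", "CHH"))
  ms <- make_mset(sites,
                  n_meth = cbind(a1 = c(3, 3, 3, 3), a2 = c(3, 3, 3, 3),
                                 b1 = c(15, 15, 15, 3), b2 = c(15, 15, 15, 3)),
                  n_total = matrix(30L, 4, 4,
                                   dimnames = list(NULL, c("a1", "a2", "b1", "b2"))))
  dmcs <- call_dmcs(ms, d, "BvA")
  expect_equal(nrow(dmcs), 3)
  dmrs <- call_dmrs(dmcs, ms, d)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 1000L)
  expect_equal(dmrs$end, 1400L)
  expect_equal(dmrs$length, 401L)
  expect_equal(dmrs$n_dmc, 3L)
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$n_chh, 2L)
  expect_equal(dmrs$n_cg, 1L)
  expect_equal(dmrs$diff, 0.4, tolerance = 1e-9)

  # two DMCs only: below min_dmcs
  expect_equal(nrow(call_dmrs(dmcs[1:2, ], ms, d)), 0)
  # a gap of exactly max_gap splits the cluster
  dmcs_gap <- dmcs
  dmcs_gap$pos <- c(1000L, 1150L, 1450L)
  expect_equal(nrow(call_dmrs(dmcs_gap, ms, d, max_gap = 300)), 0)
  expect_error(call_dmrs(dmcs[c(2, 1, 3), ], ms, d), "sorted")
})

test_that("clusters agree with the brute-force oracle and break on direction", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    pos <- sort(sample.int(20000, n))
    dir <- sample(c("hyper", "hypo"), n, replace = TRUE)
    new_cluster <- c(TRUE, pos[-1] - pos[-n] >= 300 | dir[-1] != dir[-n])
    mine <- split(seq_len(n), cumsum(new_cluster))
    oracle <- oracle_dmc_clusters(pos, dir, 300)
    expect_equal(unname(mine), oracle)
  }
})

test_that("raising the region difference threshold never increases DMR count", {
  d <- mini_design()
  set.seed(61)
  n <- 400
  pos <- sort(sample.int(60000, n))
  la <- runif(n, 0.05, 0.3)
  lb <- pmin(0.95, la + sample(c(0, 0.45), n, replace = TRUE, prob = c(0.6, 0.4)))
  draw <- function(lv) rbinom(n, 30, lv)
  ms <- make_mset(make_sites("Chr01", pos, 0, 0, context = "CHH"),
                  n_meth = cbind(a1 = draw(la), a2 = draw(la),
                                 b1 = draw(lb), b2 = draw(lb)),
                  n_total = matrix(30L, n, 4,
                                   dimnames = list(NULL, c("a1", "a2", "b1", "b2"))))
  dmcs <- call_dmcs(ms, d, "BvA")
  counts <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5),
                   function(md) nrow(call_dmrs(dmcs, ms, d, min_diff = md)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # every emitted DMR satisfies the three construction constraints
  dmrs <- call_dmrs(dmcs, ms, d)
  if (nrow(dmrs)) {
    expect_true(all(dmrs$n_dmc >= 3))
    expect_true(all(abs(dmrs$diff) > 0.1))
    for (i in seq_len(nrow(dmrs))) {
      member <- dmcs$pos >= dmrs$start[i] & dmcs$pos <= dmrs$end[i] &
        dmcs$direction == dmrs$direction[i]
      expect_true(all(diff(dmcs$pos[member]) < 300))
    }
  }
})

test_that("DMR summary computes ratios and context percentages", {
  dmrs <- data.frame(chrom = "c", start = 1:43 * 1000L, end = 1:43 * 1000L + 400L,
                     length = 401L, comparison = "G2vG1", n_dmc = 3L,
                     diff = c(rep(-0.3, 23), rep(0.3, 20)),
                     direction = rep(c("hypo", "hyper"), c(23, 20)),
                     n_mc = 5L, n_cg = 1L, n_chg = 3L, n_chh = 8L,
                     stringsAsFactors = FALSE)
  s <- dmr_summary(dmrs)
  overall <- s[s$comparison == "overall", ]
  expect_equal(overall$hypo_hyper_ratio, 1.15)
  expect_equal(overall$pct_cg + overall$pct_chg + overall$pct_chh, 100)
  empty <- dmr_summary(dmrs[0, ])
  expect_equal(empty$n_dmr, 0)
  expect_equal(empty$max_length, 0)
})
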