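# Independent oracles used across the suite. Each is written from the
# definition, not from the implementation it checks.

# Two-sided Fisher exact p for one 2x2 table by literal enumeration of all
# tables with the observed margins, summing point probabilities (computed
# from binomial coefficients) not exceeding the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  xs <- max(0, k - nn):min(k, m)
  probs <- choose(m, xs) * choose(nn, k - xs) / choose(m + nn, k)
  obs <- choose(m, a) * choose(nn, k - a) / choose(m + nn, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up from the definition: q_(i) = min over j >= i
# of m * p_(j) / j, capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- min(1, running)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Context of a cytosine from its own-strand trinucleotide, straight from
# the definition (CG / CHG / CHH with H in {A, C, T}).
oracle_context <- function(tri) {
  b <- strsplit(tri, "")[[1]]
  if (b[1] != "C") return(NA_character_)
  if (b[2] == "G") "CG" else if (b[3] == "G") "CHG" else "CHH"
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Maximal single-linkage clusters of same-direction DMCs with gaps below
# max_gap, by an O(n^2) scan over every candidate window.
oracle_dmc_clusters <- function(pos, direction, max_gap) {
  n <- length(pos)
  clusters <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && pos[j + 1] - pos[j] < max_gap &&
           direction[j + 1] == direction[i]) {
      j <- j + 1
    }
    clusters[[length(clusters) + 1]] <- i:j
    i <- j + 1
  }
  clusters
}

# Small helpers for fixtures built in code --------------------------------

make_gene_models <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end, stringsAsFactors = FALSE)
  }
  introns <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1], start = e$end[-nrow(e)] + 1L,
               end = e$start[-1] - 1L, stringsAsFactors = FALSE)
  }))
  if (is.null(introns)) {
    introns <- data.frame(gene_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  }
  empty <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons, introns = introns,
                 utr5 = if (is.null(utr5)) empty else utr5,
                 utr3 = if (is.null(utr3)) empty else utr3),
            class = "gene_models")
}

make_sites <- function(chrom, pos, n_meth, n_unmeth, context = "CG",
                       strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, n_meth = as.integer(n_meth),
             n_unmeth = as.integer(n_unmeth),
             trinucleotide = "CNN", stringsAsFactors = FALSE)
}

# Two-group, four-sample design used by small differential tests
mini_design <- function() {
  sample_design(groups = list(A = c("a1", "a2"), B = c("b1", "b2")),
                comparisons = data.frame(group_a = "A", group_b = "B",
                                         stringsAsFactors = FALSE),
                timepoints = c(a1 = 0, a2 = 24, b1 = 4, b2 = 28))
}

# Build a methylome_set directly from aligned per-sample count matrices
make_mset <- function(sites, n_meth, n_total) {
  structure(list(sites = sites, n_meth = n_meth, n_total = n_total,
                 samples = colnames(n_meth)),
            class = "methylome_set")
}
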