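# Readers and writers for every on-disk format the pipeline touches, the
# sample/group design, and the aligned multi-sample methylome container.
# Internal coordinates are 1-based inclusive throughout (the convention of
# the cytosine report and GFF3); BED I/O converts at the boundary.

#' Read a per-cytosine methylation count report
#'
#' Parses the 7-column cytosine-report dialect (chrom, 1-based position,
#' strand, methylated count, unmethylated count, context, trinucleotide),
#' keeping sites whose coverage reaches `min_coverage`.
#'
#' @param path Path to a tab-separated report without header.
#' @param min_coverage Minimum `n_meth + n_unmeth` for a site to be kept
#'   (default 0: keep everything, including uncovered reference cytosines).
#' @return Data frame of sites (`chrom`, `pos`, `strand`, `context`,
#'   `n_meth`, `n_unmeth`, `trinucleotide`) in file order.
#' @export
read_cytosine_report <- function(path, min_coverage = 0) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = "character", showProgress = FALSE)
  if (nrow(dt) == 0) {
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      context = character(), n_meth = integer(),
                      n_unmeth = integer(), trinucleotide = character()))
  }
  if (ncol(dt) != 7) {
    bad <- which(rowSums(!is.na(dt)) != 7)[1]
    stop("malformed cytosine report (expected 7 columns) at line ",
         if (is.na(bad)) 1 else bad)
  }
  data.table::setnames(dt, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                             "context", "trinucleotide"))
  pos <- suppressWarnings(as.integer(dt$pos))
  n_meth <- suppressWarnings(as.integer(dt$n_meth))
  n_unmeth <- suppressWarnings(as.integer(dt$n_unmeth))
  bad <- which(is.na(pos) | is.na(n_meth) | is.na(n_unmeth) |
                 pos < 1L | n_meth < 0L | n_unmeth < 0L |
                 !dt$strand %in% c("+", "-"))
  if (length(bad)) stop("malformed cytosine report line ", bad[1])
  bad_ctx <- which(!dt$context %in% .CONTEXTS)
  if (length(bad_ctx)) {
    stop("unknown context token '", dt$context[bad_ctx[1]], "' at line ", bad_ctx[1])
  }
  out <- data.frame(chrom = dt$chrom, pos = pos, strand = dt$strand,
                    context = dt$context, n_meth = n_meth, n_unmeth = n_unmeth,
                    trinucleotide = dt$trinucleotide, stringsAsFactors = FALSE)
  unsorted <- vapply(split(out$pos, out$chrom), is.unsorted, logical(1))
  if (any(unsorted)) {
    stop("positions not sorted within chromosome ",
         names(unsorted)[unsorted][1])
  }
  out[out$n_meth + out$n_unmeth >= min_coverage, , drop = FALSE]
}

#' Write a per-cytosine methylation count report
#'
#' Emits the exact 7-column dialect [read_cytosine_report()] reads.
#'
#' @param sites Data frame of sites with the report columns.
#' @param path Output path.
#' @export
write_cytosine_report <- function(sites, path) {
  data.table::fwrite(
    sites[, c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context",
              "trinucleotide")],
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Builds one strand-aware gene model per `gene` feature: TSS/TES are the
#' start/end on the plus strand and flipped on the minus strand; introns are
#' the gaps between exons within the gene span.
#'
#' @param path GFF3 file with gene/mRNA/exon (and optionally UTR) features;
#'   coordinates 1-based inclusive.
#' @return An object of class `gene_models`: a list with data frames
#'   `genes` (`gene_id`, `chrom`, `start`, `end`, `strand`, `tss`, `tes`),
#'   `exons`, `introns`, `utr5`, `utr3` (each `gene_id`, `start`, `end`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  strand_chr <- as.character(GenomicRanges::strand(gr))
  if (any(type == "gene" & strand_chr == "*")) stop("gene feature missing strand")
  get_id <- function(x) if (!is.null(x$ID)) as.character(x$ID) else NA_character_
  genes_gr <- gr[type == "gene"]
  gene_ids <- get_id(genes_gr)
  # map every feature to its gene via Parent chains (exon -> mRNA -> gene)
  parent1 <- vapply(as.list(gr$Parent), function(p) {
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  id2gene <- stats::setNames(gene_ids, gene_ids)
  mrna <- gr[type == "mRNA"]
  if (length(mrna)) {
    id2gene <- c(id2gene, stats::setNames(
      unname(id2gene[parent1[type == "mRNA"]]), get_id(mrna)))
  }
  owner <- id2gene[parent1]
  feat_df <- function(what) {
    sel <- type == what & !is.na(owner)
    data.frame(gene_id = unname(owner[sel]),
               start = GenomicRanges::start(gr[sel]),
               end = GenomicRanges::end(gr[sel]),
               stringsAsFactors = FALSE)
  }
  exons <- feat_df("exon")
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    start = GenomicRanges::start(genes_gr),
    end = GenomicRanges::end(genes_gr),
    strand = strand_chr[type == "gene"],
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  # validate exons and derive introns
  span <- genes[match(exons$gene_id, genes$gene_id), ]
  if (any(exons$start < span$start | exons$end > span$end)) {
    stop("exon outside gene bounds for gene ",
         exons$gene_id[which(exons$start < span$start | exons$end > span$end)[1]])
  }
  introns <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1],
               start = e$end[-nrow(e)] + 1L,
               end = e$start[-1] - 1L, stringsAsFactors = FALSE)
  }))
  if (is.null(introns)) {
    introns <- data.frame(gene_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  }
  introns <- introns[introns$end >= introns$start, , drop = FALSE]
  rownames(introns) <- NULL
  structure(list(genes = genes, exons = exons, introns = introns,
                 utr5 = feat_df("five_prime_UTR"),
                 utr3 = feat_df("three_prime_UTR")),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$introns), "introns\n")
  invisible(x)
}

#' Read transposable-element annotations from BED
#'
#' BED intervals (0-based half-open) are converted to the internal 1-based
#' inclusive convention; the BED name field is the TE family label.
#'
#' @param path BED3+name file.
#' @return Data frame `chrom`, `start`, `end`, `family`.
#' @export
read_te_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      family = character(), stringsAsFactors = FALSE))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4) stop("TE BED needs at least 4 columns (chrom,start,end,name)")
  if (any(raw[[2]] >= raw[[3]])) {
    stop("degenerate BED interval (start >= end) at line ",
         which(raw[[2]] >= raw[[3]])[1])
  }
  data.frame(chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]) + 1L,
             end = as.integer(raw[[3]]), family = as.character(raw[[4]]),
             stringsAsFactors = FALSE)
}

#' Write DMRs as BED6+ with call metadata
#'
#' Columns: chrom, 0-based start, half-open end, name = comparison id,
#' score = round(1000 * |diff|), strand ".", then `n_dmc`, `diff`,
#' `direction`, `n_mc`, and member-DMC context counts `n_cg`, `n_chg`,
#' `n_chh`. [read_dmr_bed()] restores these fields losslessly.
#'
#' @param dmrs Data frame of DMRs from [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  cols <- data.frame(
    chrom = dmrs$chrom, start = dmrs$start - 1L, end = dmrs$end,
    name = dmrs$comparison, score = round(1000 * abs(dmrs$diff)),
    strand = rep(".", nrow(dmrs)), n_dmc = dmrs$n_dmc, diff = dmrs$diff,
    direction = dmrs$direction, n_mc = dmrs$n_mc, n_cg = dmrs$n_cg,
    n_chg = dmrs$n_chg, n_chh = dmrs$n_chh, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(cols, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write DMR BED to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read DMRs written by [write_dmr_bed()]
#'
#' @param path BED6+ file produced by [write_dmr_bed()].
#' @return Data frame with the documented DMR fields (1-based inclusive
#'   coordinates).
#' @export
read_dmr_bed <- function(path) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      comparison = character(), n_dmc = integer(),
                      diff = numeric(), direction = character(),
                      n_mc = integer(), n_cg = integer(), n_chg = integer(),
                      n_chh = integer(), stringsAsFactors = FALSE)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]) + 1L,
             end = as.integer(raw[[3]]), comparison = as.character(raw[[4]]),
             n_dmc = as.integer(raw[[7]]), diff = as.numeric(raw[[8]]),
             direction = as.character(raw[[9]]), n_mc = as.integer(raw[[10]]),
             n_cg = as.integer(raw[[11]]), n_chg = as.integer(raw[[12]]),
             n_chh = as.integer(raw[[13]]), stringsAsFactors = FALSE)
}

#' Expression matrix I/O
#'
#' Tab-separated with a header row of sample ids and a leading `gene_id`
#' column; abundances are FPKM-scale non-negative reals.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  m
}

#' @rdname read_expression_matrix
#' @param expr Genes x samples numeric matrix with dimnames.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flat key-value config I/O
#'
#' One `key = value` pair per line; values are kept as strings (callers
#' coerce). Used for run manifests and the sample-to-group mapping.
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)\\s*$", lines))
  if (any(lengths(kv) != 3)) stop("malformed config line: ", lines[lengths(kv) != 3][1])
  stats::setNames(vapply(kv, `[`, character(1), 3),
                  vapply(kv, `[`, character(1), 2))
}

#' @rdname read_config
#' @param config Named vector (coerced to character).
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

#' Sample/group design for the daily time course
#'
#' The default design follows the two-day sampling scheme: nine leaf
#' samples over 48 h, the first day under a light/dark (LD) cycle and the
#' second under continuous light (CL, free-running). Samples are paired
#' into five groups by clock time -- G1 (LD0, CL0), G2 (LD4, CL4),
#' G3 (LD8, CL8), G4 (LD16, CL16), G5 (CL0, CL24) -- so each group captures
#' one time of day on both days; note CL0 serves in both G1 and G5. The
#' ordered comparisons are consecutive-group contrasts.
#'
#' @param groups Named list mapping group id to member sample ids.
#' @param comparisons Data frame with columns `group_a`, `group_b` (the
#'   second group is the "later" one; hyper/hypo direction is b vs a).
#' @param timepoints Named numeric vector of sampling times (hours from the
#'   LD0 origin) for every sample.
#' @return Object of class `sample_design`.
#' @export
sample_design <- function(groups = NULL, comparisons = NULL, timepoints = NULL) {
  if (is.null(groups)) {
    groups <- list(G1 = c("LD0", "CL0"), G2 = c("LD4", "CL4"),
                   G3 = c("LD8", "CL8"), G4 = c("LD16", "CL16"),
                   G5 = c("CL0", "CL24"))
  }
  if (is.null(comparisons)) {
    comparisons <- data.frame(group_a = c("G1", "G2", "G3", "G4"),
                              group_b = c("G2", "G3", "G4", "G5"),
                              stringsAsFactors = FALSE)
  }
  if (is.null(timepoints)) {
    timepoints <- c(LD0 = 0, LD4 = 4, LD8 = 8, LD16 = 16,
                    CL0 = 24, CL4 = 28, CL8 = 32, CL16 = 40, CL24 = 48)
  }
  samples <- unique(unlist(groups, use.names = FALSE))
  if (!all(samples %in% names(timepoints))) {
    stop("missing timepoints for: ",
         paste(setdiff(samples, names(timepoints)), collapse = ", "))
  }
  bad <- !comparisons$group_a %in% names(groups) |
    !comparisons$group_b %in% names(groups)
  if (any(bad)) stop("comparison references undefined group")
  for (i in seq_len(nrow(comparisons))) {
    a <- groups[[comparisons$group_a[i]]]
    b <- groups[[comparisons$group_b[i]]]
    if (length(intersect(a, b))) {
      stop("groups ", comparisons$group_a[i], " and ", comparisons$group_b[i],
           " share samples; a comparison's groups must be disjoint")
    }
  }
  comparisons$id <- if (nrow(comparisons)) {
    paste0(comparisons$group_b, "v", comparisons$group_a)
  } else character(0)
  structure(list(groups = groups, comparisons = comparisons,
                 timepoints = timepoints[samples], samples = samples),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design:", length(x$samples), "samples,", length(x$groups),
      "groups,", nrow(x$comparisons), "comparisons\n")
  for (g in names(x$groups)) {
    cat(" ", g, "=", paste(x$groups[[g]], collapse = ", "), "\n")
  }
  cat("  comparisons:", paste(x$comparisons$id, collapse = ", "), "\n")
  invisible(x)
}

#' Align per-sample cytosine reports into one multi-sample container
#'
#' All samples are aligned on the union of their positions; a sample
#' missing a position contributes zero counts there.
#'
#' @param reports Named list of per-sample site data frames (as returned by
#'   [read_cytosine_report()]); names are sample ids.
#' @return Object of class `methylome_set`: `sites` (the shared site table)
#'   plus integer matrices `n_meth` and `n_total` (sites x samples).
#' @export
methylome_set <- function(reports) {
  stopifnot(is.list(reports), length(reports) > 0, !is.null(names(reports)))
  key_of <- function(d) paste(d$chrom, d$pos, d$strand, sep = ":")
  all_sites <- data.table::rbindlist(
    lapply(reports, function(d) d[, c("chrom", "pos", "strand", "context",
                                      "trinucleotide")]))
  sites <- unique(as.data.frame(all_sites))
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  key <- key_of(sites)
  n <- nrow(sites)
  n_meth <- matrix(0L, n, length(reports),
                   dimnames = list(NULL, names(reports)))
  n_total <- n_meth
  for (s in names(reports)) {
    d <- reports[[s]]
    idx <- match(key_of(d), key)
    n_meth[idx, s] <- d$n_meth
    n_total[idx, s] <- d$n_meth + d$n_unmeth
  }
  structure(list(sites = sites, n_meth = n_meth, n_total = n_total,
                 samples = names(reports)),
            class = "methylome_set")
}

#' @export
print.methylome_set <- function(x, ...) {
  cat("methylome_set:", nrow(x$sites), "cytosines x", length(x$samples),
      "samples\n  contexts:",
      paste(names(table(x$sites$context)), table(x$sites$context),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
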