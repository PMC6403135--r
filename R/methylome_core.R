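# Per-site and regional methylation arithmetic: context classification,
# level estimation with non-conversion correction, methylated-position
# calling, sliding windows, genome summaries, and the amplicon (BS-PCR
# clone) estimator.

.CONTEXTS <- c("CG", "CHG", "CHH")

.revcomp_chars <- function(x) {
  # x: character vector of single bases
  chartr("ACGTN", "TGCAN", x)
}

.context_from_tri <- function(tri) {
  # tri: uppercase trinucleotide read 5'->3' on the cytosine's own strand.
  # Positions with N in the two downstream bases get NA.
  second <- substr(tri, 2L, 2L)
  third <- substr(tri, 3L, 3L)
  ctx <- rep(NA_character_, length(tri))
  known <- second %in% c("A", "C", "G", "T") & third %in% c("A", "C", "G", "T")
  ctx[known & second == "G"] <- "CG"
  ctx[known & second != "G" & third == "G"] <- "CHG"
  ctx[known & second != "G" & third != "G"] <- "CHH"
  ctx
}

.genome_as_character <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named by chromosome")
    toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
}

#' Classify the sequence context of cytosines
#'
#' Determines whether each cytosine lies in a CG, CHG or CHH context
#' (H = A, C or T), reading the trinucleotide 5'->3' on the cytosine's own
#' strand; minus-strand cytosines are read on the reverse complement.
#'
#' @param genome A named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @param chrom Chromosome id (scalar or vector recycled against `pos`).
#' @param pos 1-based position vector; the base at `(pos, strand)` must be a
#'   cytosine on that strand.
#' @param strand `"+"` or `"-"`, vectorised.
#' @return Character vector in `c("CG","CHG","CHH")`, or `NA` where fewer
#'   than two downstream bases exist or an N intervenes.
#' @examples
#' classify_context(c(chr = "ACGTT"), "chr", 2, "+") # "CG"
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  seqs <- .genome_as_character(genome)
  n <- max(length(pos), length(strand), length(chrom))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(chrom %in% names(seqs))) {
    stop("unknown chromosome: ", paste(setdiff(unique(chrom), names(seqs)), collapse = ", "))
  }
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    s <- seqs[[ch]]
    len <- nchar(s)
    idx <- which(chrom == ch)
    p <- pos[idx]
    if (any(p < 1L | p > len)) stop("position outside chromosome ", ch)
    st <- strand[idx]
    base <- substring(s, p, p)
    base[st == "-"] <- .revcomp_chars(base[st == "-"])
    if (any(base != "C")) {
      stop("base at (", ch, ":", p[base != "C"][1], ",",
           st[base != "C"][1], ") is not a cytosine on that strand")
    }
    tri <- character(length(p))
    plus <- st == "+"
    if (any(plus)) {
      ok <- p[plus] + 2L <= len
      tri[plus] <- ifelse(ok, substring(s, p[plus], p[plus] + 2L), "C")
    }
    if (any(!plus)) {
      ok <- p[!plus] - 2L >= 1L
      raw <- ifelse(ok, substring(s, pmax(p[!plus] - 2L, 1L), p[!plus]), "C")
      # reverse complement so the trinucleotide reads 5'->3' on the minus strand
      tri[!plus] <- vapply(raw, function(x) {
        paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
      tri[!plus][!ok] <- "C"
    }
    out[idx] <- .context_from_tri(tri)
  }
  out
}

#' Enumerate every cytosine in a genome with its context
#'
#' Scans both strands and returns all cytosines whose context is defined
#' (at least two downstream bases, no N in the trinucleotide). Plus- and
#' minus-strand cytosines are distinct sites throughout the pipeline.
#'
#' @inheritParams classify_context
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`, `context`,
#'   `trinucleotide`, ordered by chromosome then position.
#' @export
enumerate_cytosines <- function(genome) {
  seqs <- .genome_as_character(genome)
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ch <- names(seqs)[i]
    chars <- strsplit(seqs[[i]], "")[[1]]
    len <- length(chars)
    p_plus <- which(chars == "C")
    p_minus <- which(chars == "G")
    tri_plus <- paste0(chars[p_plus],
                       c(chars, "N", "N")[p_plus + 1L],
                       c(chars, "N", "N")[p_plus + 2L])
    tri_plus[p_plus + 2L > len] <- "C"
    rc <- chartr("ACGTN", "TGCAN", chars)
    tri_minus <- paste0(rc[p_minus],
                        c("N", "N", rc)[p_minus + 1L],  # rc[p-1]
                        c("N", "N", rc)[p_minus])       # rc[p-2]
    tri_minus[p_minus - 2L < 1L] <- "C"
    df <- data.frame(
      chrom = ch,
      pos = c(p_plus, p_minus),
      strand = rep(c("+", "-"), c(length(p_plus), length(p_minus))),
      trinucleotide = c(tri_plus, tri_minus),
      stringsAsFactors = FALSE
    )
    df$context <- .context_from_tri(df$trinucleotide)
    df <- df[!is.na(df$context), , drop = FALSE]
    df <- df[order(df$pos, df$strand), , drop = FALSE]
    res[[i]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("chrom", "pos", "strand", "context", "trinucleotide")]
}

#' Methylation level of a site or pooled region
#'
#' ML = mC / (mC + umC), the fraction of reads supporting methylation.
#'
#' @param n_meth,n_unmeth Non-negative read counts (vectorised).
#' @return Numeric in `[0,1]`; `NA` where coverage is zero (the level is
#'   undefined, never reported as 0).
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  if (any(n_meth < 0, na.rm = TRUE) || any(n_unmeth < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  total <- n_meth + n_unmeth
  ifelse(total > 0, n_meth / total, NA_real_)
}

#' Estimate the bisulfite non-conversion rate from an unmethylated control
#'
#' The rate is the fraction of cytosines still read as cytosine at reference
#' cytosine positions of a spike-in known to be unmethylated (lambda phage).
#'
#' @param n_converted Reads converted (read as T) at control cytosines.
#' @param n_unconverted Reads not converted (read as C).
#' @return Rate in `[0,1]`.
#' @export
estimate_nonconversion <- function(n_converted, n_unconverted) {
  if (any(n_converted < 0) || any(n_unconverted < 0)) stop("counts must be non-negative")
  total <- sum(n_converted) + sum(n_unconverted)
  if (total == 0) stop("conversion control has zero coverage")
  sum(n_unconverted) / total
}

#' Correct a methylation level for bisulfite non-conversion
#'
#' Standard error-rate deconvolution: the expected observed level is
#' `true + (1 - true) * r`, so the corrected level is
#' `max(0, (ml - r) / (1 - r))`.
#'
#' @param ml Raw level(s) in `[0,1]` (`NA` passes through).
#' @param r Non-conversion rate in `[0,1)`.
#' @return Corrected level(s) in `[0,1]`.
#' @export
correct_level <- function(ml, r) {
  if (any(r < 0) || any(r >= 1)) stop("non-conversion rate must be in [0,1)")
  if (any(ml < 0 | ml > 1, na.rm = TRUE)) stop("methylation level must be in [0,1]")
  pmax(0, (ml - r) / (1 - r))
}

#' Call methylated cytosine positions
#'
#' A position is called methylated when its coverage passes `min_coverage`
#' and a one-sided binomial test of `n_meth` out of total against the
#' non-conversion rate `r` rejects at Benjamini-Hochberg adjusted q <
#' `alpha`. Positions failing the coverage gate are never called.
#'
#' @param sites Data frame with `n_meth` and `n_unmeth` columns (one row per
#'   cytosine), or `n_meth` may be given with `n_unmeth` as bare vectors.
#' @param r Non-conversion rate in `[0,1)`.
#' @param alpha BH false-discovery level (default 0.05).
#' @param min_coverage Minimum total reads for a position to be testable
#'   (default 5).
#' @return Logical vector, one element per site.
#' @export
call_methylated_sites <- function(sites, r, alpha = 0.05, min_coverage = 5) {
  if (is.data.frame(sites)) {
    n_meth <- sites$n_meth
    n_unmeth <- sites$n_unmeth
  } else {
    stop("sites must be a data frame with n_meth and n_unmeth columns")
  }
  if (r < 0 || r >= 1) stop("non-conversion rate must be in [0,1)")
  total <- n_meth + n_unmeth
  eligible <- total >= min_coverage
  p <- rep(NA_real_, length(total))
  p[eligible] <- stats::pbinom(n_meth[eligible] - 1L, total[eligible], r,
                               lower.tail = FALSE)
  q <- adjust_fdr(p)
  out <- rep(FALSE, length(total))
  out[eligible] <- q[eligible] < alpha
  out
}

#' Methylation density of a region
#'
#' The fraction of cytosine positions in a region that are called
#' methylated (distinct from the methylation *level*, which is read-based).
#'
#' @param methylated Logical vector of methylated-position flags for the
#'   cytosines in the region.
#' @return Fraction in `[0,1]`; `NA` for an empty region.
#' @export
methylation_density <- function(methylated) {
  if (length(methylated) == 0) return(NA_real_)
  mean(methylated)
}

#' Pool methylation counts in sliding windows
#'
#' Windows are anchored at position 1 of each chromosome and advance by
#' `step`; the final windows are truncated at the chromosome end. Counts of
#' member sites are pooled per context, and the pooled level is
#' sum(mC)/sum(mC+umC) (equal to the coverage-weighted mean of site levels).
#'
#' @param sites Data frame with `chrom`, `pos`, `context`, `n_meth`,
#'   `n_unmeth`, sorted by position within each chromosome.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param window,step Window size and step in bp (defaults 3000 and 600).
#' @return Data frame with one row per window x context: `chrom`, `start`,
#'   `end`, `context`, `n_meth`, `n_unmeth`, `level` (`NA` where no reads).
#' @export
sliding_windows <- function(sites, chrom_lengths, window = 3000, step = 600) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  dt <- data.table::as.data.table(sites)
  if (any(!dt$chrom %in% names(chrom_lengths))) stop("site on unknown chromosome")
  if (any(dt[, if (is.unsorted(pos)) TRUE else FALSE, by = chrom]$V1)) {
    stop("sites must be sorted by position within chromosome")
  }
  grids <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(1L, len, by = step)
    data.table::data.table(chrom = ch, win = seq_along(starts),
                           start = starts, end = pmin(starts + window - 1L, len))
  })
  grid <- data.table::rbindlist(grids)
  grid <- data.table::rbindlist(lapply(.CONTEXTS, function(cx) {
    data.table::copy(grid)[, context := cx]
  }))
  # windows containing pos: ceil((pos-window)/step) <= (i-1) <= floor((pos-1)/step)
  dt[, `:=`(i_min = pmax(0L, as.integer(ceiling((pos - window) / step))) + 1L,
            i_max = as.integer(floor((pos - 1) / step)) + 1L)]
  reps <- dt$i_max - dt$i_min + 1L
  expanded <- dt[rep(seq_len(.N), reps)]
  expanded[, win := rep(dt$i_min, reps) + (sequence(reps) - 1L)]
  counts <- expanded[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                     by = .(chrom, win, context)]
  out <- merge(grid, counts, by = c("chrom", "win", "context"), all.x = TRUE)
  out[is.na(n_meth), n_meth := 0L]
  out[is.na(n_unmeth), n_unmeth := 0L]
  out[, level := methylation_level(n_meth, n_unmeth)]
  data.table::setorder(out, chrom, win, context)
  as.data.frame(out[, .(chrom, start, end, context, n_meth, n_unmeth, level)])
}

#' Per-context, per-chromosome methylome summary
#'
#' For each sequence context and chromosome: site count, pooled
#' coverage-weighted mean level (non-conversion corrected), and, when
#' methylated-position flags are supplied, the fraction of positions called
#' methylated. Genome-wide rollups are appended with `chrom = "genome"`.
#' Contexts absent from the input are absent from the output (not zero).
#'
#' @param sites Data frame of cytosines with counts (`chrom`, `context`,
#'   `n_meth`, `n_unmeth`).
#' @param methylated Optional logical flags from [call_methylated_sites()].
#' @param r Non-conversion rate used to correct pooled levels (default 0).
#' @return Data frame: `chrom`, `context`, `n_sites`, `n_meth`, `n_total`,
#'   `level`, and `frac_methylated` when flags were given.
#' @export
genome_summary <- function(sites, methylated = NULL, r = 0) {
  if (nrow(sites) == 0) stop("no sites")
  dt <- data.table::as.data.table(sites)
  if (!is.null(methylated)) {
    stopifnot(length(methylated) == nrow(dt))
    dt[, methylated := methylated]
  }
  agg <- function(d, by) {
    res <- d[, {
      out <- list(n_sites = .N, n_meth = sum(n_meth),
                  n_total = sum(n_meth) + sum(n_unmeth))
      if (!is.null(methylated)) out$n_called <- sum(methylated)
      out
    }, by = by]
    res
  }
  per_chrom <- agg(dt, c("chrom", "context"))
  genome <- agg(dt, "context")
  genome[, chrom := "genome"]
  out <- data.table::rbindlist(list(per_chrom, genome), use.names = TRUE, fill = TRUE)
  out[, level := correct_level(ifelse(n_total > 0, n_meth / n_total, NA_real_), r)]
  if (!is.null(methylated)) {
    out[, frac_methylated := n_called / n_sites]
    out[, n_called := NULL]
  }
  data.table::setorder(out, chrom, context)
  as.data.frame(out)
}

#' Amplicon methylation level from cloned bisulfite-PCR sequences
#'
#' Over all clones of a bisulfite-PCR amplicon, the fraction of reference
#' cytosine positions still read as cytosine (non-converted, hence
#' methylated).
#'
#' @param clones Character vector of clone sequences, each the same length
#'   as the reference.
#' @param reference Reference amplicon sequence containing at least one C.
#' @return Level in `[0,1]`.
#' @export
amplicon_methylation_level <- function(clones, reference) {
  reference <- toupper(reference)
  clones <- toupper(clones)
  if (any(nchar(clones) != nchar(reference))) {
    stop("clone length differs from reference length")
  }
  c_pos <- which(strsplit(reference, "")[[1]] == "C")
  if (length(c_pos) == 0) stop("reference contains no cytosine")
  kept <- vapply(clones, function(cl) {
    sum(strsplit(cl, "")[[1]][c_pos] == "C")
  }, integer(1), USE.NAMES = FALSE)
  sum(kept) / (length(c_pos) * length(clones))
}
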