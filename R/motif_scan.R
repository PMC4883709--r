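#' Locate exact occurrences of a motif group's members
#'
#' Reports every exact match of any group member on the stored strand and of
#' its reverse complement (a `-` strand hit), anchored by the hit's 5'-most
#' base on the stored strand. A hit is kept when that anchor lies inside
#' `region` (TSS-relative, half-open). Overlapping hits are all reported.
#'
#' @param group a `motif_group` (or a character vector of member k-mers)
#' @param promoters a [promoter_set()]
#' @param region `c(start, end)` TSS-relative; defaults to the full window
#' @return data.frame gene_id, position, strand, member
#' @export
scan_motif <- function(group, promoters, region = NULL) {
  members <- if (inherits(group, "motif_group")) group$members else group
  region <- as.integer(region %||% promoters$region)
  dss <- Biostrings::DNAStringSet(promoters$sequences)
  ids <- gene_ids(promoters)
  starts <- promoters$start_offsets
  out <- list()
  for (m in unique(members)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") m else revcomp(m)
      hits <- Biostrings::vmatchPattern(pat, dss)
      st <- Biostrings::startIndex(hits)
      for (g in which(lengths(st) > 0)) {
        pos <- starts[g] + st[[g]] - 1L
        keep <- pos >= region[1] & pos < region[2]
        if (any(keep))
          out[[length(out) + 1L]] <- data.frame(
            gene_id = ids[g], position = pos[keep], strand = str,
            member = m, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), position = integer(0),
                      strand = character(0), member = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$gene_id, df$position, df$strand), , drop = FALSE]
}

# gene IDs (within `gene_subset` if given) with at least one hit in region
genes_with_motif <- function(group, promoters, region = NULL, gene_subset = NULL) {
  hits <- scan_motif(group, promoters, region)
  g <- unique(hits$gene_id)
  if (!is.null(gene_subset)) g <- intersect(g, gene_subset)
  g
}

#' Cover ratio: fraction of genes containing a motif
#'
#' `CR(A) = N(A) / N` over the given gene subset, where a gene counts when at
#' least one group member matches (either strand) with its anchor in `region`.
#'
#' @inheritParams scan_motif
#' @param gene_subset character vector of gene IDs (nonempty)
#' @return fraction in [0, 1]
#' @export
cover_ratio <- function(group, promoters, gene_subset, region = NULL) {
  if (length(gene_subset) == 0L) stop("gene_subset is empty")
  with_motif <- genes_with_motif(group, promoters, region, gene_subset)
  length(with_motif) / length(gene_subset)
}

#' Positional distribution of motif hits around the TSS
#'
#' Counts hits of the group per fixed-width window across `span`, per gene in
#' `gene_subset`, and normalizes by the average per-window frequency of the
#' reference set (all genes in `promoters`) over the same span.
#'
#' @inheritParams cover_ratio
#' @param window_bp window width in bp
#' @param span `c(lo, hi)` TSS-relative range to histogram; defaults to the
#'   promoter window. Genes contribute wherever sequence exists.
#' @return data.frame window_start, window_end, raw (hits per subset gene),
#'   normalized (raw divided by the reference mean per-window frequency)
#' @export
positional_distribution <- function(group, promoters, gene_subset,
                                    window_bp = 50L, span = NULL) {
  if (length(gene_subset) == 0L) stop("gene_subset is empty")
  span <- as.integer(span %||% promoters$region)
  breaks <- seq(span[1], span[2], by = window_bp)
  if (breaks[length(breaks)] < span[2]) breaks <- c(breaks, span[2])
  hits <- scan_motif(group, promoters, region = span)
  bin_counts <- function(ids, denom) {
    h <- hits[hits$gene_id %in% ids, , drop = FALSE]
    cnt <- if (nrow(h) == 0L) rep(0L, length(breaks) - 1L) else
      tabulate(findInterval(h$position, breaks, rightmost.closed = FALSE,
                            left.open = FALSE),
               nbins = length(breaks) - 1L)
    cnt / denom
  }
  raw <- bin_counts(gene_subset, length(gene_subset))
  ref <- bin_counts(gene_ids(promoters), length(promoters))
  ref_mean <- mean(ref)
  data.frame(window_start = breaks[-length(breaks)],
             window_end = breaks[-1],
             raw = raw,
             normalized = if (ref_mean > 0) raw / ref_mean else rep(NA_real_,
                                                                    length(raw)))
}

#' Upper-tail binomial enrichment P-value for a motif
#'
#' Compares the motif's occurrence count in the regulated genes' regions with
#' the genome-wide occurrence rate of all same-length windows: `k` = number of
#' hits in regulated genes, `n` = number of scanned windows (both strands) in
#' regulated genes, `p` = hits in all genes / windows in all genes, returning
#' `P(X >= k | n, p)`. Reported for description only; it never feeds ranking.
#'
#' @inheritParams cover_ratio
#' @param regulated character vector of regulated gene IDs
#' @return list(k, n, p, p_value, degenerate)
#' @export
binomial_enrichment_pvalue <- function(group, promoters, regulated,
                                       region = NULL) {
  word <- nchar((if (inherits(group, "motif_group")) group$members else group)[1])
  region <- as.integer(region %||% promoters$region)
  hits <- scan_motif(group, promoters, region)
  n_windows <- function(ids) {
    pr <- subset_region(promoters, region)
    keep <- intersect(ids, gene_ids(pr))
    sum(pmax(nchar(pr$sequences[keep]) - word + 1L, 0L)) * 2L  # both strands
  }
  all_ids <- gene_ids(promoters)
  k <- sum(hits$gene_id %in% regulated)
  n <- n_windows(regulated)
  k_all <- nrow(hits)
  n_all <- n_windows(all_ids)
  p <- if (n_all > 0) k_all / n_all else 0
  degenerate <- (p == 0 && k > 0) || setequal(regulated, all_ids)
  p_value <- if (p == 0) as.numeric(k == 0) else
    stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  list(k = k, n = n, p = p, p_value = p_value, degenerate = degenerate)
}

#' Export motif hits as a BED-like TSV
#' @param hits data.frame from [scan_motif()]
#' @param path output file
#' @export
write_hits <- function(hits, path) {
  word <- if (nrow(hits) > 0) nchar(hits$member[1]) else 0L
  df <- data.frame(gene_id = hits$gene_id, start = hits$position,
                   end = hits$position + word, member = hits$member,
                   strand = hits$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
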