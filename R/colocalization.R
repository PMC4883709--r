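#' Co-occurrence contingency counts for a motif pair
#'
#' Per gene, presence of motif A and of motif B in `region` (exact member
#' match, both strands) is tabulated in eight cells split by up-regulation
#' status: N(A|B|UP), N(!A|B|UP), N(A|!B|UP), N(!A|!B|UP) and the four `!UP`
#' analogues. Pairs whose groups share a member sequence are not evaluated.
#'
#' @param a,b `motif_group` objects
#' @param promoters a [promoter_set()]
#' @param up_labels named logical vector (TRUE = up-regulated) covering the
#'   promoter genes
#' @param region `c(start, end)` TSS-relative evaluation window
#' @return named numeric vector of the eight cells, plus attribute `skipped`
#'   if the groups share members (then counts are NA)
#' @export
pair_counts <- function(a, b, promoters, up_labels, region = c(-500L, 150L)) {
  mem_a <- if (inherits(a, "motif_group")) a$members else a
  mem_b <- if (inherits(b, "motif_group")) b$members else b
  cells <- c("A_B_UP", "nA_B_UP", "A_nB_UP", "nA_nB_UP",
             "A_B_nUP", "nA_B_nUP", "A_nB_nUP", "nA_nB_nUP")
  if (length(intersect(mem_a, mem_b)) > 0L) {
    out <- setNames(rep(NA_real_, 8L), cells)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  ids <- gene_ids(promoters)
  has_a <- ids %in% genes_with_motif(a, promoters, region)
  has_b <- ids %in% genes_with_motif(b, promoters, region)
  up <- as.logical(up_labels[ids])
  if (anyNA(up)) stop("up_labels must cover every promoter gene")
  out <- c(
    A_B_UP    = sum(has_a & has_b & up),
    nA_B_UP   = sum(!has_a & has_b & up),
    A_nB_UP   = sum(has_a & !has_b & up),
    nA_nB_UP  = sum(!has_a & !has_b & up),
    A_B_nUP   = sum(has_a & has_b & !up),
    nA_B_nUP  = sum(!has_a & has_b & !up),
    A_nB_nUP  = sum(has_a & !has_b & !up),
    nA_nB_nUP = sum(!has_a & !has_b & !up))
  attr(out, "skipped") <- FALSE
  out
}

#' Pearson chi-square statistic for a motif pair's co-occurrence
#'
#' The expected count of each UP cell is derived from the matching `!UP` cell
#' scaled to the UP total: `Ei = N(UP) * O(!UP cell) / N(!UP)`. The statistic
#' is `X^2 = sum over the four UP cells of (Oi - Ei)^2 / Ei`, with the P-value
#' from the chi-square upper tail with 3 degrees of freedom.
#'
#' @param counts eight-cell vector from [pair_counts()]
#' @return list(chi2, p_value, testable); untestable when any `Ei` = 0
#' @export
chi_square_pair <- function(counts) {
  if (anyNA(counts)) return(list(chi2 = NA_real_, p_value = NA_real_,
                                 testable = FALSE))
  up_cells <- counts[c("A_B_UP", "nA_B_UP", "A_nB_UP", "nA_nB_UP")]
  nup_cells <- counts[c("A_B_nUP", "nA_B_nUP", "A_nB_nUP", "nA_nB_nUP")]
  n_up <- sum(up_cells); n_nup <- sum(nup_cells)
  if (n_nup == 0) return(list(chi2 = NA_real_, p_value = NA_real_,
                              testable = FALSE))
  e <- n_up * nup_cells / n_nup
  if (any(e == 0)) return(list(chi2 = NA_real_, p_value = NA_real_,
                               testable = FALSE))
  chi2 <- sum((up_cells - e)^2 / e)
  list(chi2 = unname(chi2),
       p_value = stats::pchisq(chi2, df = 3, lower.tail = FALSE),
       testable = TRUE)
}

#' Conditional enrichment ratios EN1 and EN2 of motif A
#'
#' `EN1 = [N(A|B|UP)/N(B|UP)] / [N(A|!B|UP)/N(!B|UP)]` contrasts presence vs
#' absence of B among up-regulated genes; `EN2 = [N(A|B|UP)/N(B|UP)] /
#' [N(A|B|!UP)/N(B|!UP)]` contrasts up- vs non-up-regulated genes given B.
#'
#' @param counts eight-cell vector from [pair_counts()]
#' @return list(en1, en2, testable); untestable on any zero denominator
#' @export
enrichment_EN <- function(counts) {
  if (anyNA(counts)) return(list(en1 = NA_real_, en2 = NA_real_,
                                 testable = FALSE))
  n_b_up <- counts[["A_B_UP"]] + counts[["nA_B_UP"]]
  n_nb_up <- counts[["A_nB_UP"]] + counts[["nA_nB_UP"]]
  n_b_nup <- counts[["A_B_nUP"]] + counts[["nA_B_nUP"]]
  denom_ok <- n_b_up > 0 && n_nb_up > 0 && n_b_nup > 0
  if (!denom_ok) return(list(en1 = NA_real_, en2 = NA_real_, testable = FALSE))
  rate_ab_up <- counts[["A_B_UP"]] / n_b_up
  # a zero dividing rate gives Inf: extreme enrichment, still testable
  en1 <- rate_ab_up / (counts[["A_nB_UP"]] / n_nb_up)
  en2 <- rate_ab_up / (counts[["A_B_nUP"]] / n_b_nup)
  list(en1 = unname(en1), en2 = unname(en2), testable = TRUE)
}

#' Evaluate every unordered motif pair
#'
#' @param groups list of `motif_group`
#' @inheritParams pair_counts
#' @return data.frame: motif_a, motif_b, the eight cells, chi2, p_value, en1,
#'   en2, testable, skipped
#' @export
evaluate_pairs <- function(groups, promoters, up_labels,
                           region = c(-500L, 150L)) {
  if (length(groups) < 2L)
    return(data.frame(motif_a = character(0), motif_b = character(0)))
  idx <- utils::combn(length(groups), 2)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    a <- groups[[idx[1, j]]]; b <- groups[[idx[2, j]]]
    cts <- pair_counts(a, b, promoters, up_labels, region)
    chi <- chi_square_pair(cts)
    en <- enrichment_EN(cts)
    cbind(data.frame(motif_a = a$name, motif_b = b$name,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(cts)),
          data.frame(chi2 = chi$chi2, p_value = chi$p_value,
                     en1 = en$en1, en2 = en$en2,
                     testable = chi$testable && en$testable,
                     skipped = isTRUE(attr(cts, "skipped"))))
  })
  do.call(rbind, rows)
}

#' Select enriched, co-localized motif pairs
#'
#' Keeps testable pairs with EN1 > 1 and EN2 > 1, sorts by ascending P-value
#' (ties by pair name), and takes the first `n_mp`.
#'
#' @param pair_table data.frame from [evaluate_pairs()]
#' @param n_mp number of motif pairs to keep (Nmp)
#' @return the selected rows, with attribute `n_mp`
#' @export
select_enriched_pairs <- function(pair_table, n_mp) {
  if (n_mp < 0) stop("n_mp must be >= 0")
  if (nrow(pair_table) == 0L || n_mp == 0L) {
    sel <- pair_table[0, , drop = FALSE]
    attr(sel, "n_mp") <- 0L
    return(sel)
  }
  ok <- pair_table$testable & !pair_table$skipped &
    pair_table$en1 > 1 & pair_table$en2 > 1
  elig <- pair_table[which(ok), , drop = FALSE]
  elig <- elig[order(elig$p_value, elig$motif_a, elig$motif_b), , drop = FALSE]
  if (nrow(elig) < n_mp)
    warning("only ", nrow(elig), " eligible pair(s) for n_mp = ", n_mp)
  sel <- utils::head(elig, n_mp)
  attr(sel, "n_mp") <- nrow(sel)
  sel
}

#' Histogram of signed separations between two motifs
#'
#' For every gene in `gene_subset` and every co-occurring (hit A, hit B) pair
#' inside `region`, records the signed offset `position(A) - position(B)` and
#' bins it in `bin_bp`-wide bins centered on multiples of `bin_bp` (so the bin
#' around 0 is [-bin_bp/2, bin_bp/2)). Counts are normalized by the subset
#' size.
#'
#' @param a,b `motif_group` objects
#' @inheritParams pair_counts
#' @param gene_subset gene IDs to evaluate
#' @param bin_bp bin width (default 50, i.e. +/-25 around bin centers)
#' @return data.frame bin_center, count, frequency (count / |gene_subset|)
#' @export
separation_histogram <- function(a, b, promoters, gene_subset,
                                 region = c(-500L, 150L), bin_bp = 50L) {
  if (length(gene_subset) == 0L) stop("gene_subset is empty")
  hits_a <- scan_motif(a, promoters, region)
  hits_b <- scan_motif(b, promoters, region)
  seps <- integer(0)
  for (g in gene_subset) {
    pa <- hits_a$position[hits_a$gene_id == g]
    pb <- hits_b$position[hits_b$gene_id == g]
    if (length(pa) > 0L && length(pb) > 0L)
      seps <- c(seps, as.vector(outer(pa, pb, "-")))
  }
  width <- region[2] - region[1]
  centers <- seq(-ceiling(width / bin_bp) * bin_bp,
                 ceiling(width / bin_bp) * bin_bp, by = bin_bp)
  if (length(seps) == 0L)
    return(data.frame(bin_center = centers, count = 0L,
                      frequency = 0))
  idx <- floor(seps / bin_bp + 0.5)   # half-open bins [c - bin/2, c + bin/2)
  cnt <- vapply(centers / bin_bp, function(c0) sum(idx == c0), integer(1))
  data.frame(bin_center = centers, count = cnt,
             frequency = cnt / length(gene_subset))
}
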