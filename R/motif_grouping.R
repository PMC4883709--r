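#' Enumerate candidate k-mers from the most up-regulated genes
#'
#' Takes the `top_k` genes by descending expression ratio (ties broken by gene
#' ID) and returns the deduplicated set of all length-`word` substrings of
#' their stored (forward) promoter sequences, excluding any window containing
#' `N`.
#'
#' @param promoters a [promoter_set()]
#' @param expr an [expression_table()]
#' @param top_k number of top up-regulated genes to draw candidates from
#' @param word candidate length in bp
#' @return character vector of unique candidate k-mers
#' @export
enumerate_candidates <- function(promoters, expr, top_k = 50L, word = 8L) {
  pr <- pair_genes(promoters, expr)
  ids <- names(pr$expr)
  if (top_k > length(ids)) stop("top_k exceeds the number of paired genes")
  ord <- order(-as.numeric(pr$expr), ids)
  top <- ids[ord][seq_len(top_k)]
  seqs <- pr$promoters$sequences[top]
  if (all(nchar(seqs) < word)) stop("no promoter of at least ", word, " bp")
  out <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < word) return(character(0))
    substring(s, 1:(n - word + 1L), word:n)
  }), use.names = FALSE)
  unique(out[!grepl("N", out, fixed = TRUE)])
}

#' Rank scored candidates
#'
#' Descending score; ties broken lexicographically by sequence, so the ranking
#' is deterministic.
#'
#' @param scores data.frame as returned by [mama_score()]
#' @return the same data.frame, reordered
#' @export
rank_candidates <- function(scores) {
  scores[order(-scores$mama_score, scores$sequence), , drop = FALSE]
}

motif_group <- function(seed, members, seed_score) {
  structure(list(name = seed, seed = seed, members = members,
                 seed_score = seed_score, pcm = build_pcm(members)),
            class = "motif_group")
}

#' @export
print.motif_group <- function(x, ...) {
  cat(sprintf("motif_group %s: %d member(s), seed score %.4g\n",
              x$seed, length(x$members), x$seed_score))
  invisible(x)
}

#' Group similar high-scoring candidates into motifs
#'
#' Walks the ranked candidates in order. A candidate in the top `top_fraction`
#' of the ranking that is not yet a member of any group seeds a new group;
#' every strictly lower-ranked, still ungrouped candidate within Hamming
#' distance `max_mismatch` of the seed (forward orientation, equal length)
#' joins that group. Each candidate belongs to at most one group (the
#' highest-ranked eligible seed wins). Groups are returned in seed-rank order.
#'
#' @param ranked ranked data.frame from [rank_candidates()]
#' @param top_fraction fraction of top-ranked candidates eligible to seed
#' @param max_mismatch maximum Hamming distance for membership
#' @return list of `motif_group` objects
#' @export
group_motifs <- function(ranked, top_fraction = 0.05, max_mismatch = 2L) {
  n <- nrow(ranked)
  if (n == 0L) stop("ranked candidate list is empty")
  n_seed_zone <- floor(top_fraction * n)
  if (n_seed_zone == 0L) {
    warning("top_fraction selects no seed candidates; no groups formed")
    return(list())
  }
  seqs <- ranked$sequence
  word <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = word)
  grouped <- logical(n)
  groups <- list()
  for (i in seq_len(n_seed_zone)) {
    if (grouped[i]) next
    seed_chars <- mat[, i]
    dist <- colSums(mat != seed_chars)
    elig <- !grouped & dist <= max_mismatch & seq_len(n) >= i
    grouped[elig] <- TRUE
    groups[[length(groups) + 1L]] <-
      motif_group(seqs[i], seqs[elig], ranked$mama_score[i])
  }
  groups
}

#' Position-count matrix of a motif group's members
#'
#' @param members character vector of equal-length member k-mers
#' @return 4 x word integer matrix of A/C/G/T counts per position
#' @export
build_pcm <- function(members) {
  if (is.list(members)) members <- members$members
  if (length(members) == 0L) stop("no members")
  word <- nchar(members[1])
  if (any(nchar(members) != word)) stop("members must share one length")
  mat <- matrix(unlist(strsplit(members, "", fixed = TRUE), use.names = FALSE),
                nrow = word)
  pcm <- vapply(seq_len(word), function(j)
    tabulate(factor(mat[j, ], levels = c("A", "C", "G", "T")), nbins = 4L),
    integer(4))
  rownames(pcm) <- c("A", "C", "G", "T")
  pcm
}

#' Per-position base frequencies of a motif group
#' @param group a `motif_group` (or a PCM matrix)
#' @return 4 x word numeric matrix of frequencies (columns sum to 1)
#' @export
pcm_frequencies <- function(group) {
  pcm <- if (inherits(group, "motif_group")) group$pcm else group
  sweep(pcm, 2, colSums(pcm), "/")
}

#' Consensus sequence of a motif group (most frequent base per position)
#' @param group a `motif_group`
#' @return consensus string
#' @export
pcm_consensus <- function(group) {
  pcm <- if (inherits(group, "motif_group")) group$pcm else group
  paste(rownames(pcm)[apply(pcm, 2, which.max)], collapse = "")
}

#' Write motif groups in minimal MEME motif format
#'
#' @param groups list of `motif_group` objects
#' @param path output file
#' @param background background base frequencies (A C G T)
#' @export
write_meme <- function(groups, path, background = rep(0.25, 4)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2], background[3], background[4]),
               ""), con)
  for (g in groups) {
    fr <- pcm_frequencies(g)
    writeLines(sprintf("MOTIF %s", g$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(fr), length(g$members)), con)
    for (j in seq_len(ncol(fr)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         fr["A", j], fr["C", j], fr["G", j], fr["T", j]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Export motif groups as a TSV table
#' @param groups list of `motif_group`
#' @param path output file (NULL to just return the data.frame)
#' @return data.frame seed, seed_score, n_members, members (comma-joined)
#' @export
groups_table <- function(groups, path = NULL) {
  df <- data.frame(
    seed = vapply(groups, `[[`, character(1), "seed"),
    seed_score = vapply(groups, `[[`, numeric(1), "seed_score"),
    n_members = vapply(groups, function(g) length(g$members), integer(1)),
    members = vapply(groups, function(g) paste(g$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
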