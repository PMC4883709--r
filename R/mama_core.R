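#' Scoring parameters for expression-weighted k-mer scores
#'
#' @param nu integer >= 1; exponent applied to the window similarity
#'   (sensitivity to sequence similarity)
#' @param tau positive real; exponent applied to capped expression ratios
#'   (sensitivity to expression)
#' @param a_hat non-negative gap penalty: each mismatch stretch of length `d`
#'   between two exact-match runs contributes a factor `a_hat * d + 1` to the
#'   denominator of their cross term
#' @param highest_r_score cap on the expression ratio entering the score
#' @param down_policy what to do with ratios below 1: `"set_to_one"` (default),
#'   `"remove"` (gene excluded from both sums), or `"reciprocal"` (1/ratio)
#' @return object of class `mama_params`
#' @export
scoring_params <- function(nu = 1L, tau = 1, a_hat = 1.0,
                           highest_r_score = 10.0,
                           down_policy = c("set_to_one", "remove", "reciprocal")) {
  down_policy <- match.arg(down_policy)
  if (nu < 1 || nu != round(nu)) stop("nu must be an integer >= 1")
  if (tau <= 0) stop("tau must be > 0")
  if (a_hat < 0) stop("a_hat must be >= 0")
  if (highest_r_score < 1) stop("highest_r_score must be >= 1")
  structure(list(nu = as.integer(nu), tau = tau, a_hat = a_hat,
                 highest_r_score = highest_r_score, down_policy = down_policy),
            class = "mama_params")
}

#' Decompose an ungapped window comparison into match runs and gaps
#'
#' Position-by-position comparison of two equal-length sequences. Returns the
#' lengths of maximal runs of identical bases (`run_lengths`, in order) and the
#' number of mismatching positions between consecutive runs (`gaps`). `N`
#' matches nothing, not even another `N`.
#'
#' @param candidate,window equal-length DNA strings
#' @return list with `run_lengths` and `gaps` (class `match_decomposition`)
#' @export
match_runs <- function(candidate, window) {
  if (nchar(candidate) != nchar(window))
    stop("candidate and window must have equal length")
  a <- strsplit(toupper(candidate), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  m <- a == b & a != "N" & b != "N"
  r <- rle(m)
  run_lengths <- r$lengths[r$values]
  gaps <- integer(0)
  if (length(run_lengths) > 1L) {
    inner <- r$lengths[!r$values]
    # drop leading/trailing mismatch stretches: they separate no runs
    if (!r$values[1]) inner <- inner[-1]
    if (!r$values[length(r$values)]) inner <- inner[-length(inner)]
    gaps <- inner
  }
  structure(list(run_lengths = as.integer(run_lengths), gaps = as.integer(gaps)),
            class = "match_decomposition")
}

#' Window similarity score from a match decomposition
#'
#' `{ sum_x h_x! + sum_{x<y} h_x h_y / prod_{k=x}^{y-1} (a_hat d_{k,k+1} + 1) }^nu`
#' where `h_x` are maximal exact-match run lengths and `d` the mismatch counts
#' between consecutive runs. An empty decomposition scores 0.
#'
#' @param decomp a [match_runs()] result (or any list with `run_lengths`, `gaps`)
#' @param params a [scoring_params()]
#' @return non-negative similarity score
#' @export
h_score_window <- function(decomp, params = scoring_params()) {
  h <- decomp$run_lengths; d <- decomp$gaps
  x <- length(h)
  if (x == 0L) return(0)
  if (length(d) != max(0L, x - 1L)) stop("invalid decomposition: gaps/runs mismatch")
  s <- sum(factorial(h))
  if (x > 1L) {
    for (i in seq_len(x - 1L)) {
      denom <- 1
      for (j in (i + 1L):x) {
        denom <- denom * (params$a_hat * d[j - 1L] + 1)
        s <- s + h[i] * h[j] / denom
      }
    }
  }
  s^params$nu
}

#' Best window similarity of a candidate within one promoter
#'
#' Slides a window of the candidate's length over the promoter (step 1) and
#' over its reverse complement, returning the maximum [h_score_window()] over
#' all windows and both strands. A promoter shorter than the candidate scores 0.
#'
#' @param candidate DNA string (length 1..16)
#' @param promoter DNA string
#' @param params a [scoring_params()]
#' @return non-negative similarity score
#' @export
h_score_gene <- function(candidate, promoter, params = scoring_params()) {
  cand <- matrix(encode_dna(toupper(candidate)), nrow = 1)
  base <- cpp_scan_max(list(encode_dna(toupper(promoter))), cand, params$a_hat)
  as.numeric(base)^params$nu
}

#' Capped, policy-adjusted expression ratio
#'
#' Ratios below 1 are transformed by the down-regulation policy, then the
#' result is capped at `highest_r_score`. The exponent `tau` is NOT applied
#' here; it enters the weighted average. Vectorized; with policy `"remove"`,
#' down-regulated entries return `NA` (to be excluded by the caller).
#'
#' @param ratio positive numeric vector of expression ratios
#' @param params a [scoring_params()]
#' @return numeric vector of r_scores (NA where removed)
#' @export
r_score <- function(ratio, params = scoring_params()) {
  if (any(ratio <= 0)) stop("expression ratios must be > 0")
  r <- ratio
  down <- r < 1
  r[down] <- switch(params$down_policy,
                    set_to_one = 1,
                    reciprocal = 1 / r[down],
                    remove     = NA_real_)
  pmin(r, params$highest_r_score)
}

# genes x candidates matrix of max window similarities (nu applied),
# scanning both strands; candidates as character vector
h_score_matrix <- function(candidates, promoters, params) {
  cand <- t(vapply(toupper(candidates), encode_dna,
                   integer(nchar(candidates[1]))))
  proms <- lapply(promoters$sequences, encode_dna)
  base <- cpp_scan_max(proms, cand, params$a_hat)
  dimnames(base) <- list(gene_ids(promoters), candidates)
  base^params$nu
}

#' Expression-weighted similarity score of candidate k-mers
#'
#' For each candidate, computes the weighted average
#' `sum_n h(n) r(n)^tau / sum_n h(n)` over all paired genes `n`, where `h(n)`
#' is the best window similarity in gene `n`'s promoter (both strands) and
#' `r(n)` the capped, policy-adjusted expression ratio. Genes removed by the
#' down-regulation policy are excluded from both sums. Candidates with zero
#' total similarity score 0 with `n_contributing = 0`.
#'
#' @param candidates character vector of equal-length DNA k-mers
#' @param promoters a [promoter_set()]
#' @param expr an [expression_table()]; genes are paired with `promoters`
#' @param params a [scoring_params()]
#' @return data.frame with columns `sequence`, `mama_score`, `n_contributing`
#' @export
mama_score <- function(candidates, promoters, expr, params = scoring_params()) {
  pr <- pair_genes(promoters, expr)
  if (length(pr$promoters) == 0L) stop("empty gene set")
  r <- r_score(as.numeric(pr$expr), params)
  keep <- !is.na(r)
  if (!any(keep)) stop("all genes removed by down-regulation policy")
  proms <- promoter_set(pr$promoters$sequences[keep], pr$promoters$region,
                        start_offsets = setNames(
                          pr$promoters$start_offsets[keep],
                          gene_ids(pr$promoters)[keep]))
  H <- h_score_matrix(candidates, proms, params)    # genes x candidates
  w <- r[keep]^params$tau
  num <- as.numeric(crossprod(H, w))
  den <- colSums(H)
  score <- ifelse(den > 0, num / den, 0)
  data.frame(sequence = candidates,
             mama_score = score,
             n_contributing = as.integer(colSums(H > 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}
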