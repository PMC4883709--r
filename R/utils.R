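#' @useDynLib mama, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom pchisq runif rnorm setNames aggregate lm coef
#' @importFrom utils read.table write.table combn head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)

#' Encode a DNA string as integer codes (A=0, C=1, G=2, T=3, N=4)
#' @param x a single DNA string over {A,C,G,T,N}
#' @return integer vector of base codes
#' @keywords internal
encode_dna <- function(x) {
  codes <- DNA_CODES[strsplit(x, "", fixed = TRUE)[[1]]]
  if (anyNA(codes)) stop("sequence contains characters outside {A,C,G,T,N}")
  unname(codes)
}

#' Reverse complement of DNA strings
#'
#' N is its own complement. Vectorized over `x`.
#' @param x character vector of DNA strings
#' @return character vector of reverse complements
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Hamming distance between equal-length strings
#' @param a,b DNA strings of equal length
#' @return integer count of mismatching positions
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): strings must have equal length")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Area under the ROC curve from decision values
#'
#' Computed by trapezoidal integration of the ROC curve traced over all
#' thresholds on the decision values; ties in scores advance TPR and FPR
#' simultaneously, which is equivalent to counting tied pairs one-half.
#'
#' @param scores numeric decision values (larger = more positive)
#' @param labels vector in \{+1, -1\} (or logical, TRUE = positive)
#' @return AUC in [0, 1]
#' @export
auc_roc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, 1L, -1L)
  pos <- labels > 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("auc_roc(): both classes required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single ROC steps
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(tapply(p, grp, sum)[as.character(seq_len(max(grp)))])
  fp <- cumsum(tapply(!p, grp, sum)[as.character(seq_len(max(grp)))])
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
}

#' Geometric mean
#' @param x positive numeric vector
#' @keywords internal
geometric_mean <- function(x) exp(mean(log(x)))

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, i) (as.integer(seed) + 10007L * as.integer(i)) %% 2147483629L
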