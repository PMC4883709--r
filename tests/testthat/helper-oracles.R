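# Independent oracles, coded literally and kept separate from the package's
# implementation paths.

# Literal term-by-term window similarity: decompose by explicit scan, then
# sum factorials and every cross term h_x*h_y with an explicitly recomputed
# product of intervening gap factors.
oracle_h_window <- function(candidate, window, a_hat = 1, nu = 1) {
  a <- strsplit(candidate, "")[[1]]; b <- strsplit(window, "")[[1]]
  m <- (a == b) & (a != "N") & (b != "N")
  runs <- c(); gaps <- c()
  i <- 1; n <- length(m); last_end <- NA
  while (i <= n) {
    if (m[i]) {
      j <- i
      while (j <= n && m[j]) j <- j + 1
      if (length(runs) > 0) gaps <- c(gaps, i - last_end - 1)
      runs <- c(runs, j - i)
      last_end <- j - 1
      i <- j
    } else i <- i + 1
  }
  if (length(runs) == 0) return(0)
  total <- sum(factorial(runs))
  if (length(runs) > 1) {
    for (x in 1:(length(runs) - 1)) {
      for (y in (x + 1):length(runs)) {
        denom <- prod(a_hat * gaps[x:(y - 1)] + 1)
        total <- total + runs[x] * runs[y] / denom
      }
    }
  }
  total^nu
}

# Mann-Whitney AUC: fraction of (positive, negative) pairs ranked correctly,
# ties counted one half.
oracle_auc_mw <- function(scores, labels) {
  sp <- scores[labels > 0]; sn <- scores[labels <= 0]
  u <- 0
  for (p in sp) u <- u + sum(p > sn) + 0.5 * sum(p == sn)
  u / (length(sp) * length(sn))
}

# Exact upper-tail binomial sum (terms in log space so large n cannot
# overflow choose()).
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i)
    exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)), numeric(1)))
}

# Chi-square for the pair test: expectations from the !UP cells, df = 3.
oracle_chisq_pair <- function(counts) {
  o <- counts[c("A_B_UP", "nA_B_UP", "A_nB_UP", "nA_nB_UP")]
  ref <- counts[c("A_B_nUP", "nA_B_nUP", "A_nB_nUP", "nA_nB_nUP")]
  e <- sum(o) * ref / sum(ref)
  x2 <- sum((o - e)^2 / e)
  list(chi2 = unname(x2), p_value = stats::pchisq(x2, 3, lower.tail = FALSE))
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# construct a motif_group without going through discovery
make_group <- function(members, seed = members[1], score = 1) {
  structure(list(name = seed, seed = seed, members = members,
                 seed_score = score, pcm = build_pcm(members)),
            class = "motif_group")
}

# small promoter set with given sequences
ps <- function(seqs, region) promoter_set(seqs, region)
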