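test_that("match_runs decomposes comparisons correctly", {
  d <- match_runs("ACGTACGT", "ACGTACGT")
  expect_equal(d$run_lengths, 8L)
  expect_equal(d$gaps, integer(0))

  d <- match_runs("ACGTACGT", "ACGAACGT")
  expect_equal(d$run_lengths, c(3L, 4L))
  expect_equal(d$gaps, 1L)

  d <- match_runs("AAAAAAAA", "CCCCCCCC")
  expect_equal(d$run_lengths, integer(0))

  # N matches nothing, including N
  d <- match_runs("ACGTACGT", "ACNTACGT")
  expect_equal(d$run_lengths, c(2L, 5L))
  expect_error(match_runs("ACGT", "ACGTA"), "equal length")
})

test_that("h_score_window reproduces the worked anchors", {
  p1 <- scoring_params()
  expect_equal(h_score_window(match_runs("ACGTACGT", "ACGTACGT"), p1), 40320)
  expect_equal(h_score_window(match_runs("ACGTACGT", "ACGAACGT"), p1), 36)
  expect_equal(h_score_window(list(run_lengths = c(2L, 2L, 2L),
                                   gaps = c(1L, 1L)), p1), 11)
  expect_equal(h_score_window(match_runs("ACGTACGT", "ACGAACGT"),
                              scoring_params(nu = 2)), 1296)
  expect_equal(h_score_window(list(run_lengths = integer(0),
                                   gaps = integer(0)), p1), 0)
})

test_that("h_score_window equals the literal oracle on random pairs", {
  set.seed(11)
  for (i in 1:200) {
    a <- rand_dna(8)
    b <- rand_dna(8, alphabet = c("A", "C", "G", "T", "N"))
    a_hat <- sample(c(0.5, 1, 2), 1)
    nu <- sample(1:3, 1)
    p <- scoring_params(nu = nu, a_hat = a_hat)
    expect_identical(h_score_window(match_runs(a, b), p),
                     oracle_h_window(a, b, a_hat, nu))
  }
})

test_that("nu acts as a pure power on the window score", {
  set.seed(3)
  for (i in 1:50) {
    d <- match_runs(rand_dna(8), rand_dna(8))
    v1 <- h_score_window(d, scoring_params(nu = 1))
    v3 <- h_score_window(d, scoring_params(nu = 3))
    expect_equal(v3, v1^3)
  }
})

test_that("h_score_gene scans both strands and handles degenerate promoters", {
  p <- scoring_params()
  prom <- paste0(rand_dna(20), "ACGTACGA", rand_dna(20))
  expect_equal(h_score_gene("ACGTACGA", prom, p), 40320)
  expect_equal(h_score_gene("ACGTACGA", revcomp(prom), p), 40320)
  expect_equal(h_score_gene("ACGTACGA", strrep("N", 30), p), 0)
  expect_equal(h_score_gene("ACGTACGA", "ACG", p), 0)   # shorter than candidate
})

test_that("h_score_gene agrees with a window-by-window oracle scan", {
  set.seed(19)
  for (i in 1:25) {
    cand <- rand_dna(8)
    prom <- rand_dna(40)
    a_hat <- sample(c(0.5, 1, 2), 1)
    p <- scoring_params(a_hat = a_hat)
    wins <- substring(prom, 1:(40 - 7), 8:40)
    rc <- revcomp(prom)
    wins_rc <- substring(rc, 1:(40 - 7), 8:40)
    best <- max(vapply(c(wins, wins_rc), function(w)
      oracle_h_window(cand, w, a_hat, 1), numeric(1)))
    expect_equal(h_score_gene(cand, prom, p), best)
  }
})

test_that("an extra mismatch in the best window never increases h_score_gene", {
  set.seed(5)
  for (i in 1:20) {
    cand <- rand_dna(8)
    prom <- cand   # single-window promoter equal to the candidate
    p <- scoring_params()
    s0 <- h_score_gene(cand, prom, p)
    pos <- sample(8, 1)
    mutated <- prom
    substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                         substr(prom, pos, pos))[1]
    expect_lte(h_score_gene(cand, mutated, p), s0)
  }
})

test_that("r_score applies policy then cap, without tau", {
  p <- scoring_params()
  expect_equal(r_score(25, p), 10)
  expect_equal(r_score(0.3, p), 1)
  expect_equal(r_score(0.25, scoring_params(down_policy = "reciprocal")), 4)
  expect_equal(r_score(30, scoring_params(down_policy = "reciprocal")), 10)
  expect_true(is.na(r_score(0.5, scoring_params(down_policy = "remove"))))
  expect_equal(r_score(2.5, p), 2.5)
  expect_error(r_score(-1, p), "> 0")
})

test_that("mama_score is the h-weighted mean of capped ratios", {
  # two genes, both containing the candidate verbatim, capped ratios 10 and 1
  pr <- ps(c(g1 = paste0("TTTT", "ACGTACGA", "TTTT"),
             g2 = paste0("GGGG", "ACGTACGA", "GGGG")), c(-16L, 0L))
  ex <- expression_table(c(g1 = 25, g2 = 1))
  sc <- mama_score("ACGTACGA", pr, ex)
  expect_equal(sc$mama_score, 5.5)
  expect_equal(sc$n_contributing, 2L)

  # constant ratio c -> score c^tau regardless of sequences
  set.seed(2)
  prc <- ps(setNames(replicate(6, rand_dna(60)), paste0("g", 1:6)), c(-60L, 0L))
  exc <- expression_table(setNames(rep(3, 6), paste0("g", 1:6)))
  for (tau in c(1, 2, 3.5)) {
    sc <- mama_score("ACGTACGA", prc, exc, scoring_params(tau = tau))
    expect_equal(sc$mama_score, 3^tau, tolerance = 1e-12)
  }

  # candidate absent everywhere scores 0 (promoters of all N are unmatchable)
  prn <- ps(c(g1 = strrep("N", 30), g2 = strrep("N", 30)), c(-30L, 0L))
  exn <- expression_table(c(g1 = 5, g2 = 1))
  sc0 <- mama_score("ACGTACGA", prn, exn)
  expect_equal(sc0$mama_score, 0)
  expect_equal(sc0$n_contributing, 0L)
})

test_that("mama_score is strand symmetric and bounded", {
  set.seed(23)
  pr <- ps(setNames(replicate(30, rand_dna(80)), sprintf("g%02d", 1:30)),
           c(-80L, 0L))
  ex <- expression_table(setNames(exp(rnorm(30, 0, 0.5)) * 2,
                                  sprintf("g%02d", 1:30)))
  cands <- replicate(20, rand_dna(8))
  for (tau in c(1, 2)) {
    p <- scoring_params(tau = tau)
    s_fwd <- mama_score(cands, pr, ex, p)$mama_score
    s_rc <- mama_score(revcomp(cands), pr, ex, p)$mama_score
    expect_identical(s_fwd, s_rc)
    nz <- s_fwd[s_fwd > 0]
    expect_true(all(nz >= 1 - 1e-12 & nz <= 10^tau + 1e-9))
  }
})

test_that("down-policy remove excludes genes from both sums", {
  pr <- ps(c(g1 = paste0("TTTT", "ACGTACGA", "TTTT"),
             g2 = paste0("GGGG", "ACGTACGA", "GGGG")), c(-16L, 0L))
  ex <- expression_table(c(g1 = 4, g2 = 0.5))
  sc <- mama_score("ACGTACGA", pr, ex,
                   scoring_params(down_policy = "remove"))
  expect_equal(sc$mama_score, 4)   # only g1 remains
  expect_equal(sc$n_contributing, 1L)
})
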