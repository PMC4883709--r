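make_pair_world <- function() {
  # 10-gene fixture with hand-controlled presence of A and B; the all-T
  # background cannot contain either motif (or their reverse complements)
  A <- "ACGGTACA"; B <- "GTTCAGGC"
  seqs <- setNames(rep(strrep("T", 200), 10), sprintf("g%02d", 1:10))
  has_a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  has_b <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  up    <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  for (i in 1:10) {
    if (has_a[i]) substr(seqs[i], 21, 28) <- A
    if (has_b[i]) substr(seqs[i], 61, 68) <- B
  }
  list(pr = ps(seqs, c(-200L, 0L)), A = make_group(A), B = make_group(B),
       up = setNames(up, names(seqs)), has_a = has_a, has_b = has_b)
}

test_that("pair_counts matches brute-force tabulation on the 10-gene fixture", {
  w <- make_pair_world()
  cts <- pair_counts(w$A, w$B, w$pr, w$up, region = c(-200L, 0L))
  manual <- c(
    A_B_UP    = sum(w$has_a & w$has_b & w$up),
    nA_B_UP   = sum(!w$has_a & w$has_b & w$up),
    A_nB_UP   = sum(w$has_a & !w$has_b & w$up),
    nA_nB_UP  = sum(!w$has_a & !w$has_b & w$up),
    A_B_nUP   = sum(w$has_a & w$has_b & !w$up),
    nA_B_nUP  = sum(!w$has_a & w$has_b & !w$up),
    A_nB_nUP  = sum(w$has_a & !w$has_b & !w$up),
    nA_nB_nUP = sum(!w$has_a & !w$has_b & !w$up))
  expect_equal(cts, manual, ignore_attr = TRUE)
  expect_equal(sum(cts[1:4]), sum(w$up))
  expect_equal(sum(cts[5:8]), sum(!w$up))
})

test_that("groups sharing a member are skipped", {
  w <- make_pair_world()
  shared <- make_group(c("ACGGTACA", "GTTCAGGC"))
  cts <- pair_counts(w$A, shared, w$pr, w$up)
  expect_true(attr(cts, "skipped"))
  expect_true(all(is.na(cts)))
  expect_false(chi_square_pair(cts)$testable)
})

test_that("chi_square_pair reproduces the constructed anchors", {
  # Oi = (30,20,10,40); !UP cells (15,25,20,40) scaled to N(UP)=100 give
  # Ei = (15,25,20,40) * 100/100 -> X^2 = 15 + 1 + 5 + 0 = 21
  cts <- c(A_B_UP = 30, nA_B_UP = 20, A_nB_UP = 10, nA_nB_UP = 40,
           A_B_nUP = 15, nA_B_nUP = 25, A_nB_nUP = 20, nA_nB_nUP = 40)
  res <- chi_square_pair(cts)
  expect_equal(res$chi2, 21)
  expect_equal(res$p_value, stats::pchisq(21, 3, lower.tail = FALSE))

  # proportional tables give X^2 = 0, P = 1
  prop <- c(A_B_UP = 6, nA_B_UP = 4, A_nB_UP = 2, nA_nB_UP = 8,
            A_B_nUP = 12, nA_B_nUP = 8, A_nB_nUP = 4, nA_nB_nUP = 16)
  res0 <- chi_square_pair(prop)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p_value, 1)

  # doubling all counts doubles X^2
  expect_equal(chi_square_pair(cts * 2)$chi2, 42)

  # zero expected cell -> untestable
  cts0 <- cts; cts0["A_B_nUP"] <- 0
  expect_false(chi_square_pair(cts0)$testable)
})

test_that("chi_square_pair matches the oracle on random tables", {
  set.seed(73)
  for (i in 1:100) {
    cts <- setNames(sample(1:60, 8, replace = TRUE),
                    c("A_B_UP", "nA_B_UP", "A_nB_UP", "nA_nB_UP",
                      "A_B_nUP", "nA_B_nUP", "A_nB_nUP", "nA_nB_nUP"))
    res <- chi_square_pair(cts)
    orc <- oracle_chisq_pair(cts)
    expect_equal(res$chi2, orc$chi2, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p_value, tolerance = 1e-10)
  }
})

test_that("enrichment_EN computes both conditional ratios", {
  cts <- c(A_B_UP = 40, nA_B_UP = 10, A_nB_UP = 20, nA_nB_UP = 30,
           A_B_nUP = 20, nA_B_nUP = 30, A_nB_nUP = 10, nA_nB_nUP = 40)
  en <- enrichment_EN(cts)
  expect_equal(en$en1, (40 / 50) / (20 / 50))   # = 2
  expect_equal(en$en2, (40 / 50) / (20 / 50))   # = 2

  # independence with equal rates -> EN1 = EN2 = 1 on a symmetric fixture
  sym <- c(A_B_UP = 10, nA_B_UP = 10, A_nB_UP = 10, nA_nB_UP = 10,
           A_B_nUP = 10, nA_B_nUP = 10, A_nB_nUP = 10, nA_nB_nUP = 10)
  en_sym <- enrichment_EN(sym)
  expect_equal(en_sym$en1, 1)
  expect_equal(en_sym$en2, 1)

  # N(B|UP) = 0 -> untestable
  z <- sym; z[c("A_B_UP", "nA_B_UP")] <- 0
  expect_false(enrichment_EN(z)$testable)
})

test_that("select_enriched_pairs filters, sorts, and truncates", {
  tab <- data.frame(
    motif_a = c("m1", "m2", "m3", "m4"), motif_b = c("x", "x", "x", "x"),
    chi2 = c(10, 20, 5, 8),
    p_value = c(0.01, 0.001, 0.2, 0.05),
    en1 = c(2, 0.5, 3, 1.5), en2 = c(1.5, 2, 2, 1.2),
    testable = c(TRUE, TRUE, TRUE, FALSE),
    skipped = FALSE)
  expect_warning(sel <- select_enriched_pairs(tab, 5), "eligible")
  # m2 excluded (EN1 <= 1) despite lowest P; m4 untestable
  expect_equal(sel$motif_a, c("m1", "m3"))
  expect_equal(nrow(select_enriched_pairs(tab, 0)), 0L)
  expect_equal(select_enriched_pairs(tab, 1)$motif_a, "m1")
})

test_that("separation_histogram localizes planted separations and mirrors", {
  A <- "ACGGTACA"; B <- "GTTCAGGC"
  n <- 20
  seqs <- setNames(rep(strrep("T", 650), n), sprintf("g%02d", 1:n))
  for (g in names(seqs)) {
    substr(seqs[g], 101, 108) <- A      # offset -400
    substr(seqs[g], 251, 258) <- B      # offset -250: sep A - B = -150
  }
  pr <- ps(seqs, c(-500L, 150L))
  ga <- make_group(A); gb <- make_group(B)
  h <- separation_histogram(ga, gb, pr, names(seqs))
  expect_equal(h$bin_center[which.max(h$count)], -150L)
  expect_equal(sum(h$count), n)

  h_rev <- separation_histogram(gb, ga, pr, names(seqs))
  expect_equal(h_rev$bin_center[which.max(h_rev$count)], 150L)
  expect_equal(sum(h$count), sum(h_rev$count))
  expect_equal(h$count, rev(h_rev$count))

  # genes containing neither -> empty histogram
  pr0 <- ps(setNames(replicate(3, strrep("A", 100)), c("a", "b", "c")),
            c(-100L, 0L))
  h0 <- separation_histogram(make_group("CGCGCGCG"), make_group("GCGCGCGC"),
                             pr0, c("a", "b", "c"))
  expect_equal(sum(h0$count), 0)
})

test_that("jittered planted pairs keep the true separation in the modal bin", {
  set.seed(83)
  cfg <- synth_config(n_genes = 80, region = c(-500L, 150L), n_up = 40,
                      planted = list(plant_spec("ACGGTACA",
                        carrier_fraction_up = 1, carrier_fraction_bg = 0,
                        position_mode = "windowed", window = c(-480L, -200L),
                        partner = list(motif = "GTTCAGGC",
                                       separation_bp = 150L, jitter_bp = 10L))),
                      seed = 83)
  dat <- generate_synthetic(cfg)
  h <- separation_histogram(make_group("GTTCAGGC"), make_group("ACGGTACA"),
                            dat$promoters, dat$up_genes)
  expect_equal(h$bin_center[which.max(h$count)], 150L)
})
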