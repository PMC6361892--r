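test_that("test dispatcher follows Shapiro-Wilk and Levene outcomes", {
  set.seed(10)
  picks <- vapply(1:40, function(i) {
    choose_test(rnorm(40), rnorm(40))$test
  }, character(1L))
  expect_gt(mean(picks == "t"), 0.8)

  set.seed(11)
  a <- c(rnorm(20), 50)   # gross outlier: normality clearly violated
  expect_equal(choose_test(a, rnorm(21))$test, "mann_whitney")

  expect_warning(dec <- choose_test(rep(1, 5), rnorm(5)), "constant")
  expect_equal(dec$test, "mann_whitney")
  expect_error(choose_test(rnorm(2), rnorm(5)), "at least 3")
})

test_that("Mann-Whitney reproduces printed z / r and its exact p matches enumeration", {
  # z and r from a printed U with tie-free groups of 20 and 13
  zr <- mann_whitney_z(104, 20, 13)
  expect_equal(zr$z, -0.958, tolerance = 5e-4)
  expect_equal(round(zr$r, 2), -0.17)   # printed at 2 d.p.

  # data route agrees with the printed-U route
  set.seed(4)
  a <- rnorm(20); b <- rnorm(13)
  res <- mann_whitney(a, b)
  expect_equal(res$z, mann_whitney_z(res$value, 20, 13)$z, tolerance = 1e-12)
  expect_equal(res$effect_r, res$z / sqrt(33), tolerance = 1e-12)

  # worked example: A = [1,2], B = [3,4] => U = 0, exact two-tailed p = 1/3
  r2 <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r2$value, 0)
  expect_equal(r2$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r2$p_mode, "exact")
  expect_equal(r2$p, mw_exact_enum_oracle(c(1, 2), c(3, 4)), tolerance = 1e-12)

  # identical multisets => U = n1 n2 / 2 and z = 0
  r3 <- suppressWarnings(mann_whitney(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r3$value, 4.5)
  expect_equal(r3$z, 0)

  # ties force the asymptotic fallback when exact is requested
  expect_warning(r4 <- mann_whitney(c(1, 1, 2), c(1, 3, 4), p_mode = "exact"),
                 "ties")
  expect_equal(r4$p_mode, "asymptotic")
})

test_that("exact Mann-Whitney p agrees with the counting oracle over all n1*n2 <= 100", {
  # anchor the counting recurrence against raw enumeration first
  set.seed(6)
  for (k in 1:5) {
    a <- sample(100, 3); b <- sample(100, 4) + 0.5
    expect_equal(mw_exact_two_sided_oracle(mann_whitney(a, b)$value, 3, 4),
                 mw_exact_enum_oracle(a, b), tolerance = 1e-12)
  }
  set.seed(7)
  sizes <- subset(expand.grid(n1 = 1:12, n2 = 1:12), n1 * n2 <= 100 & n1 <= n2)
  for (k in seq_len(nrow(sizes))) {
    n1 <- sizes$n1[k]; n2 <- sizes$n2[k]
    a <- stats::runif(n1); b <- stats::runif(n2)
    res <- mann_whitney(a, b, p_mode = "exact")
    expect_equal(res$p, mw_exact_two_sided_oracle(res$value, n1, n2),
                 tolerance = 1e-10,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("2x2 Pearson chi-square (no continuity correction) reproduces printed values", {
  expect_equal(chi_square_2x2(matrix(c(11, 11, 9, 2), 2, 2))$value, 3.11,
               tolerance = 5e-3)
  expect_equal(chi_square_2x2(matrix(c(22, 11, 25, 2), 2, 2))$value, 5.88,
               tolerance = 5e-3)
  expect_equal(chi_square_2x2(matrix(c(14, 11, 7, 2), 2, 2))$value, 1.33,
               tolerance = 5e-3)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$value, 0)

  # invariant under transposition and row/column swaps
  tab <- matrix(c(11, 11, 9, 2), 2, 2)
  expect_equal(chi_square_2x2(t(tab))$value, chi_square_2x2(tab)$value)
  expect_equal(chi_square_2x2(tab[2:1, ])$value, chi_square_2x2(tab)$value)
  expect_equal(chi_square_2x2(tab[, 2:1])$value, chi_square_2x2(tab)$value)

  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
  expect_error(chi_square_2x2(matrix(1, 3, 3)), "2x2")
})

test_that("Spearman correlation handles monotone, tied and degenerate input", {
  expect_equal(spearman(1:10, (1:10)^2)$value, 1)
  expect_equal(spearman(1:10, -(1:10))$value, -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))$value, 0.8)
  # pairwise-complete handling
  expect_equal(spearman(c(1, 2, NA, 4, 5), c(2, 4, 9, 8, 10))$n1, 4L)
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  expect_error(spearman(1:2, 1:2), "3 complete pairs")
})

test_that("winsorize_max pulls all maxima to the next distinct value", {
  expect_equal(winsorize_max(c(0.1, 0.2, 0.9)), c(0.1, 0.2, 0.2))
  expect_equal(winsorize_max(c(3, 3, 3)), c(3, 3, 3))
  expect_equal(winsorize_max(c(1, 3, 3)), c(1, 1, 1))
  set.seed(8)
  for (k in 1:10) {
    v <- sample(20, 8, replace = TRUE)
    w <- winsorize_max(v)
    expect_lte(max(w), max(v))
    expect_gte(sum(w == max(w)), 2L)          # new max is always tied
    expect_equal(w[v < max(v)], v[v < max(v)])  # non-maxima untouched
    expect_equal(sort(unique(w)), setdiff(sort(unique(v)), max(v)))
  }
  na <- winsorize_max(c(1, NA, 5, 2))
  expect_equal(na, c(1, NA, 2, 2))
})

test_that("BH-FDR matches the hand step-up example and the literal definition", {
  worked <- bh_fdr(c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06), q = 0.05)
  expect_equal(worked$reject, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))

  expect_false(any(bh_fdr(rep(1, 5))$reject))
  expect_true(bh_fdr(0.04, q = 0.05)$reject)

  set.seed(9)
  for (k in 1:30) {
    m <- sample(1:8, 1L)
    p <- round(stats::runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1L)
    expect_equal(bh_fdr(p, q)$reject, bh_stepup_oracle(p, q),
                 info = paste(c(q, p), collapse = ","))
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("RRB subtype scores sum configured items with missingness per subtype", {
  tab <- data.frame(id = c("s1", "s2"),
                    item_67 = c(1, 2), item_68 = c(0, 1),
                    item_74 = c(2, NA), item_75 = c(1, 1),
                    item_77 = c(0, 3), item_78 = c(1, 0))
  sc <- rrb_subtype_scores(tab)
  expect_equal(sc$circumscribed_interests, c(1, 3))
  expect_equal(sc$repetitive_motor, c(1, 3))
  expect_equal(sc$insistence_on_sameness, c(3, NA_real_))  # missing item
  expect_equal(sc$id, c("s1", "s2"))

  expect_error(rrb_subtype_scores(tab, list(a = character(0))), "empty item set")
  expect_error(rrb_subtype_scores(tab, list(a = "item_99")), "unknown item")
  expect_error(rrb_subtype_scores(tab, list(a = "item_67", b = "item_67")),
               "disjoint")
})

test_that("correlation analysis mirrors the trait-by-measure layout with scoped FDR", {
  set.seed(12)
  n <- 12
  coupling <- runif(n)
  cohort <- data.frame(
    id = paste0("s", 1:n), group = "HR-ASD",
    global_dbwpli = coupling,
    selected_dbwpli = 0.9 * coupling,
    rrb = 2 + 5 * coupling,          # noiseless monotone trait
    social = rnorm(n))
  res <- correlation_analysis(cohort, group_filter = "HR-ASD",
                              scales = c("rrb", "social"),
                              fdr_q = 0.05, a_priori = "rrb")
  expect_equal(nrow(res), 4L)
  expect_equal(res$rho[res$scale == "rrb"], c(1, 1))
  expect_true(all(is.na(res$p_adjusted[res$a_priori])))
  expect_true(all(!is.na(res$p_adjusted[!res$a_priori])))

  expect_error(correlation_analysis(cohort, group_filter = "LR",
                                    scales = "rrb"), "no subjects")
  expect_error(correlation_analysis(cohort[1:3, ], scales = "rrb"),
               "at least 4")

  # null calibration: with no coupling-trait link the uncorrected rejection
  # rate stays near nominal and the FDR family rejects at most ~q
  set.seed(13)
  hits_raw <- 0; hits_fdr <- 0; reps <- 60
  for (r in 1:reps) {
    ch <- data.frame(group = "g", global_dbwpli = rnorm(15),
                     selected_dbwpli = rnorm(15),
                     s1 = rnorm(15), s2 = rnorm(15), s3 = rnorm(15))
    rr <- correlation_analysis(ch, scales = c("s1", "s2", "s3"), fdr_q = 0.05)
    hits_raw <- hits_raw + sum(rr$p < 0.05)
    hits_fdr <- hits_fdr + any(rr$reject)
  }
  expect_lt(hits_raw / (6 * reps), 0.12)
  expect_lt(hits_fdr / reps, 0.12)
})
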