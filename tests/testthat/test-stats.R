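test_that("exact Wilcoxon p-values match sign-pattern enumeration", {
  # frozen small cases, expected values from the 2^n enumeration oracle
  expect_equal(wilcoxon_signed_rank_exact(c(1, 2, 3))$p_two_sided, 0.25)
  expect_equal(wilcoxon_signed_rank_exact(1:8)$p_two_sided, 2 / 256)
  expect_equal(wilcoxon_signed_rank_exact(c(1, -1))$p_two_sided, 1.0)

  # random inputs (with ties and zeros) for all n <= 10
  set.seed(71)
  for (n in 2:10) {
    for (rep in 1:5) {
      d <- sample(-4:4, n, replace = TRUE)
      if (all(d == 0)) d[1] <- 1
      got <- wilcoxon_signed_rank_exact(d)
      expect_equal(got$p_two_sided, oracle_wilcoxon_p(d),
                   tolerance = 1e-12,
                   label = paste("n =", n, "d =", paste(d, collapse = ",")))
      expect_lte(got$statistic,
                 got$n_effective * (got$n_effective + 1) / 2)
    }
  }
  # agreement with the reference implementation when there are no ties
  d <- c(0.3, -1.2, 2.5, 0.7, -0.1, 1.9, 1.1, -2.2)
  expect_equal(wilcoxon_signed_rank_exact(d)$p_two_sided,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank_exact(c(0, 0)), "zero")
})

test_that("large-sample Wilcoxon falls back to a tie-corrected normal", {
  set.seed(72)
  d <- rnorm(40, 0.3)
  got <- wilcoxon_signed_rank_exact(d)
  expect_equal(got$method, "normal-approx")
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got$p_two_sided, ref, tolerance = 1e-6)
})

test_that("BKY two-stage FDR matches its hand-executed definition", {
  expect_equal(sum(bky_two_stage_fdr(c(1, 1, 1), q = 0.01)$discoveries), 0)

  # stage 1 at 0.0476 rejects 2 of 3, m0 = 1, stage 2 rejects 2
  got <- bky_two_stage_fdr(c(0.001, 0.02, 0.8), q = 0.05)
  expect_equal(got$discoveries, c(TRUE, TRUE, FALSE))
  expect_equal(got$m0, 1)

  # random p-lists against the independent step-up oracle
  set.seed(73)
  for (rep in 1:20) {
    m <- sample(5:60, 1)
    p <- c(runif(m - 3), runif(3, 0, 0.01))
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(bky_two_stage_fdr(p, q)$discoveries, oracle_bky(p, q),
                 label = paste("rep", rep))
  }
  expect_error(bky_two_stage_fdr(c(0.5, 1.2), 0.05), "0, 1")
})

test_that("BKY dominates plain BH on signal-bearing p-lists", {
  set.seed(74)
  for (rep in 1:20) {
    p <- c(rbeta(15, 0.1, 10), runif(35))   # 15 shifted alternatives
    q <- 0.05
    n_bky <- sum(bky_two_stage_fdr(p, q)$discoveries)
    n_bh <- sum(p.adjust(p, "BH") <= q)
    expect_gte(n_bky, n_bh)
  }
})

test_that("BKY controls empirical FDR on mixed simulations", {
  set.seed(75)
  q <- 0.05
  fdp <- replicate(300, {
    p <- c(pnorm(-abs(rnorm(20, 3))) * 2, runif(80))
    truth <- rep(c(TRUE, FALSE), c(20, 80))
    disc <- bky_two_stage_fdr(p, q)$discoveries
    if (!any(disc)) 0 else sum(disc & !truth) / sum(disc)
  })
  expect_lt(mean(fdp), q + 0.02)   # Monte-Carlo slack
})

test_that("Spearman rho and exact permutation p match brute force", {
  expect_equal(spearman_rho_p(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_rho_p(1:6, -(1:6))$rho, -1)

  set.seed(76)
  for (rep in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    got <- spearman_rho_p(x, y)
    expect_equal(got$method, "exact-permutation")
    expect_equal(got$p_two_sided, oracle_spearman_p(x, y),
                 tolerance = 1e-12)
  }
  # tied data still agree with the permutation oracle
  x <- c(1, 2, 2, 3, 4); y <- c(2, 1, 3, 3, 5)
  expect_equal(spearman_rho_p(x, y)$p_two_sided, oracle_spearman_p(x, y),
               tolerance = 1e-12)

  # invariance under strictly monotone transforms
  x <- rnorm(7); y <- rnorm(7)
  base <- spearman_rho_p(x, y)
  tr <- spearman_rho_p(exp(x), atan(y))
  expect_equal(tr$rho, base$rho, tolerance = 1e-12)
  expect_equal(tr$p_two_sided, base$p_two_sided, tolerance = 1e-12)

  expect_equal(spearman_rho_p(rep(1, 5), rnorm(5))$method,
               "undefined-constant")
  expect_error(spearman_rho_p(1:3, 1:3), "at least 4")
})

test_that("large-n Spearman p uses the t approximation", {
  set.seed(77)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- spearman_rho_p(x, y)
  expect_equal(got$method, "t-approx")
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-6)
})

test_that("ddCt fold changes follow the 2^-ddCt rule", {
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1.0)
  expect_equal(ddct_fold_change(20, 15, 21, 15), 0.5)
  expect_equal(ddct_fold_change(20, 15, 18, 15), 4.0)
  # reference drift cancels
  expect_equal(ddct_fold_change(20, 15, 21, 16), 1.0)
  expect_error(ddct_fold_change(20, 15, NA, 15), "Ct")
})
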