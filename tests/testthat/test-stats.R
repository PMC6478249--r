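random_within_data <- function(n_subj, within_levels, seed) {
  set.seed(seed)
  cells <- do.call(expand.grid, c(within_levels,
                                  list(stringsAsFactors = FALSE)))
  df <- cells[rep(seq_len(nrow(cells)), each = n_subj), , drop = FALSE]
  df$subject <- rep(sprintf("S%02d", seq_len(n_subj)), nrow(cells))
  df$y <- rnorm(nrow(df))
  df
}

test_that("repeated-measures F matches brute-force variance partitioning", {
  designs <- list(list(A = c("a1", "a2"), B = c("b1", "b2")),
                  list(A = c("a1", "a2"), B = c("b1", "b2"),
                       C = c("c1", "c2")),
                  list(A = c("a1", "a2", "a3"), B = c("b1", "b2")))
  for (i in seq_along(designs)) {
    for (seed in c(101, 202)) {
      df <- random_within_data(6, designs[[i]], seed)
      within <- names(designs[[i]])
      got <- rm_anova(df, dv = "y", within = within)
      ref <- oracle_rm_anova(df, dv = "y", within = within)
      got <- got[match(ref$effect, got$effect), ]
      expect_equal(got$F, ref$F, tolerance = 1e-10)
      expect_equal(got$df_num, ref$df_num)
      expect_equal(got$df_den, ref$df_den)
    }
  }
})

test_that("a factor with equal marginal means gets F = 0", {
  df <- random_within_data(8, list(A = c("a1", "a2"), B = c("b1", "b2")),
                           seed = 7)
  # force equal A-level marginal means without touching subject variance
  for (lev in unique(df$A)) {
    df$y[df$A == lev] <- df$y[df$A == lev] - mean(df$y[df$A == lev])
  }
  res <- rm_anova(df, dv = "y", within = c("A", "B"))
  expect_lt(res$F[res$effect == "A"], 1e-20)
})

test_that("two-level designs force sphericity and F equals squared paired t", {
  df <- random_within_data(9, list(A = c("a1", "a2"), B = c("b1", "b2")),
                           seed = 31)
  res <- rm_anova(df, dv = "y", within = c("A", "B"))
  expect_true(all(res$epsilon == 1))
  expect_true(all(res$p_gg == res$p))

  means <- function(filter_expr) {
    with(df, tapply(y, list(subject, A, B), mean))
  }
  m <- means()
  t_A <- paired_t(rowMeans(m[, "a1", ]), rowMeans(m[, "a2", ]))$t
  t_B <- paired_t(rowMeans(m[, , "b1"]), rowMeans(m[, , "b2"]))$t
  t_AB <- paired_t(m[, "a1", "b1"] - m[, "a1", "b2"],
                   m[, "a2", "b1"] - m[, "a2", "b2"])$t
  expect_equal(res$F[res$effect == "A"], t_A^2, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "B"], t_B^2, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "A:B"], t_AB^2, tolerance = 1e-8)
})

test_that("Greenhouse-Geisser epsilon matches the textbook formula", {
  # compound symmetry satisfies sphericity exactly
  cs <- matrix(0.3, 4, 4); diag(cs) <- 1
  expect_equal(gg_epsilon(cs), 1)
  expect_equal(gg_epsilon(diag(2) * 2.5), 1)  # k = 2 always 1
  set.seed(88)
  for (k in 3:5) {
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A)
    eps <- gg_epsilon(S)
    expect_equal(eps, oracle_gg(S), tolerance = 1e-10)
    expect_gt(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1)
  }
  expect_error(gg_epsilon(matrix(0, 3, 3)), "singular|degenerate")
  expect_error(gg_epsilon(matrix(1, 2, 3)), "square")
})

test_that("multi-df effects get the epsilon of their own cell covariance", {
  df <- random_within_data(10, list(block = c("b1", "b2", "b3", "b4"),
                                    go = c("Go", "NoGo")), seed = 55)
  res <- rm_anova(df, dv = "y", within = c("block", "go"))
  Y <- with(df, tapply(y, list(subject, block), mean))
  expect_equal(res$epsilon[res$effect == "block"], gg_epsilon(cov(Y)),
               tolerance = 1e-12)
  blk <- res[res$effect == "block", ]
  expect_equal(blk$p_gg,
               pf(blk$F, blk$epsilon * blk$df_num, blk$epsilon * blk$df_den,
                  lower.tail = FALSE), tolerance = 1e-12)
})

test_that("generalized eta squared stays within its bounds on null data", {
  for (seed in c(5, 6)) {
    df <- random_within_data(7, list(A = c("a1", "a2"), B = c("b1", "b2"),
                                     C = c("c1", "c2")), seed)
    res <- rm_anova(df, dv = "y", within = c("A", "B", "C"))
    expect_true(all(res$ges >= 0 & res$ges <= 1))
    expect_lte(sum(res$ges), 1)
  }
})

test_that("malformed ANOVA input is rejected", {
  df <- random_within_data(5, list(A = c("a1", "a2")), seed = 1)
  expect_error(rm_anova(rbind(df, df[1, ]), dv = "y", within = "A"),
               "aggregate")
  expect_error(rm_anova(df[-1, ], dv = "y", within = "A"), "incomplete")
  df_na <- df; df_na$y[2] <- NA
  expect_error(rm_anova(df_na, dv = "y", within = "A"), "missing")
})

test_that("paired t reports d = t / sqrt(n) and guards degenerate input", {
  set.seed(9)
  x <- rnorm(20, 0.4); y <- rnorm(20)
  res <- paired_t(x, y)
  expect_equal(res$cohens_d, res$t / sqrt(res$n_pairs), tolerance = 1e-12)
  expect_equal(res$df, 19)
  one <- paired_t(x, y, sided = "one")
  if (res$t > 0) expect_equal(one$p, res$p / 2, tolerance = 1e-12)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
  expect_error(paired_t(1, 2), "length")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_adjust(0.017, m = 2), 0.034)
  expect_equal(bonferroni_adjust(0.6, m = 2), 1)
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.2, m = 1), 0.2)
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
  expect_error(bonferroni_adjust(1.4), "0, 1")
})
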