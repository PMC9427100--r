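test_that("Clopper-Pearson intervals match exact binomial theory", {
  # closed form at x = 0: upper = 1 - (alpha/2)^(1/n)
  ci <- clopper_pearson(0, 8)
  expect_equal(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], 1 - 0.025^(1 / 8))
  expect_equal(unname(round(100 * ci, 1)), c(0, 36.9))
  expect_equal(unname(round(100 * clopper_pearson(33, 125), 1)),
               c(18.9, 35.0))
  expect_equal(round(clopper_pearson(4, 28)[["upper"]], 3), 0.327)
  expect_equal(clopper_pearson(5, 5)[["upper"]], 1)
  # independent oracle: stats::binom.test computes the same exact interval
  for (n in c(7, 40, 125)) {
    for (x in unique(c(0, 1, n %/% 3, n))) {
      expect_equal(unname(clopper_pearson(x, n)),
                   unname(binom.test(x, n)$conf.int[1:2]), tolerance = 1e-12)
    }
  }
  expect_error(clopper_pearson(5, 4), "x <= n")
  expect_error(clopper_pearson(0, 0), "n >= 1")
})

test_that("Clopper-Pearson endpoints are monotone in the success count", {
  for (n in c(10, 50, 125)) {
    b <- vapply(0:n, function(x) clopper_pearson(x, n), c(0, 0))
    expect_true(all(diff(b[1, ]) >= 0))
    expect_true(all(diff(b[2, ]) >= 0))
  }
})

test_that("Clopper-Pearson coverage is conservative on a simulation grid", {
  set.seed(20210)
  for (n in c(10, 50, 125)) {
    bounds <- vapply(0:n, function(x) clopper_pearson(x, n), c(0, 0))
    for (p in c(0.05, 0.25, 0.5)) {
      x <- rbinom(2000, n, p)
      covered <- bounds[1, x + 1] <= p & p <= bounds[2, x + 1]
      expect_gte(mean(covered), 0.95)
    }
  }
})

test_that("chi-square reproduces the published stratified comparisons", {
  disease <- contingency_2xk(c(11, 18, 4), c(40, 57, 28))
  res <- pearson_chi_square(disease)
  expect_identical(res$method, "chi_square")  # no correction for K = 3
  expect_equal(res$df, 2L)
  expect_equal(round(res$p_value, 2), 0.23)
  sponsor <- contingency_2xk(c(29, 4), c(58, 67))
  res2 <- pearson_chi_square(sponsor)
  expect_identical(res2$method, "chi_square_yates")
  expect_equal(res2$p_value, 8.1e-8, tolerance = 0.01)
  # equal stratum proportions give a null statistic
  flat <- pearson_chi_square(contingency_2xk(c(10, 10), c(40, 40)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("chi-square agrees with stats::chisq.test and the 2x2 closed form", {
  set.seed(91)
  for (rep in 1:25) {
    K <- sample(2:4, 1)
    totals <- sample(5:60, K, TRUE)
    succ <- vapply(totals, function(t) sample.int(t, 1) - 1L, 0L)
    if (sum(succ) == 0 || sum(succ) == sum(totals)) next
    tab <- contingency_2xk(succ, totals)
    m <- rbind(succ, totals - succ)
    mine <- pearson_chi_square(tab)
    ref <- suppressWarnings(chisq.test(m, correct = K == 2))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    if (K == 2) {
      # closed form for the uncorrected 2x2 statistic
      a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
      N <- sum(m)
      closed <- unname(N * (a * d - b * cc)^2 /
        (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2])))
      expect_equal(pearson_chi_square(tab, correct = FALSE)$statistic,
                   closed, tolerance = 1e-12)
    }
  }
  expect_error(pearson_chi_square(contingency_2xk(c(0, 0), c(5, 5))),
               "margin")
})

# classical two-sided 2x2 Fisher p by direct hypergeometric summation
fisher_2x2_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Fisher enumeration matches the 2x2 hypergeometric closed form", {
  set.seed(404)
  for (rep in 1:30) {
    t1 <- sample(3:40, 1); t2 <- sample(3:40, 1)
    s1 <- sample.int(t1 + 1, 1) - 1L; s2 <- sample.int(t2 + 1, 1) - 1L
    tab <- contingency_2xk(c(s1, s2), c(t1, t2))
    expect_equal(fisher_exact_2xk(tab)$p_value,
                 fisher_2x2_oracle(s1, t1 - s1, s2, t2 - s2),
                 tolerance = 1e-10)
  }
})

test_that("Fisher enumeration agrees with stats::fisher.test on 2xK tables", {
  set.seed(77)
  for (rep in 1:12) {
    K <- sample(3:4, 1)
    totals <- sample(4:25, K, TRUE)
    succ <- vapply(totals, function(t) sample.int(t + 1, 1) - 1L, 0L)
    tab <- contingency_2xk(succ, totals)
    ref <- fisher.test(rbind(succ, totals - succ))
    expect_equal(fisher_exact_2xk(tab)$p_value, ref$p.value,
                 tolerance = 1e-7)
  }
  # identical strata carry no evidence of association
  expect_equal(fisher_exact_2xk(contingency_2xk(c(5, 5), c(20, 20)))$p_value,
               1)
})

test_that("Fisher enumeration probabilities sum to one over the margin-fixed set", {
  # the modal table's p-value accumulates every table's probability
  for (tab in list(contingency_2xk(c(3, 6, 2), c(10, 20, 8)),
                   contingency_2xk(c(5, 5), c(18, 18)))) {
    M <- sum(tab$successes)
    grid <- expand.grid(lapply(tab$totals, function(t) 0:min(t, M)))
    grid <- grid[rowSums(grid) == M, , drop = FALSE]
    lp <- apply(grid, 1, function(s) sum(lchoose(tab$totals, s)))
    modal <- as.integer(grid[which.max(lp), ])
    p <- fisher_exact_2xk(contingency_2xk(modal, tab$totals))$p_value
    expect_equal(p, 1, tolerance = 1e-10)
  }
})

test_that("Fisher enumeration guard rejects infeasibly large tables", {
  expect_error(
    fisher_exact_2xk(contingency_2xk(rep(500, 6), rep(1000, 6)),
                     max_tables = 1e5),
    "guard")
})

test_that("Cohen's kappa matches hand-computed and reference values", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # agreement table (20, 10, 10, 5): observed = chance agreement, kappa = 0
  r1 <- rep(c("x", "x", "y", "y"), c(20, 10, 10, 5))
  r2 <- rep(c("x", "y", "x", "y"), c(20, 10, 10, 5))
  expect_equal(cohens_kappa(r1, r2), 0, tolerance = 1e-12)
  # reference implementation cross-check
  ref <- e1071::classAgreement(table(r1, r2))$kappa
  expect_equal(cohens_kappa(r1, r2), ref, tolerance = 1e-12)
  set.seed(12)
  s1 <- sample(letters[1:3], 200, TRUE)
  s2 <- sample(letters[1:3], 200, TRUE)
  expect_equal(cohens_kappa(s1, s2),
               e1071::classAgreement(table(factor(s1), factor(s2)))$kappa,
               tolerance = 1e-12)
  # symmetry and category relabeling
  expect_equal(cohens_kappa(s1, s2), cohens_kappa(s2, s1))
  map <- c(a = "z", b = "q", c = "w")
  expect_equal(cohens_kappa(map[s1], map[s2]), cohens_kappa(s1, s2))
  # degenerate marginals: chance agreement 1 only under perfect agreement
  expect_equal(cohens_kappa(rep("a", 5), rep("a", 5)), 1)
  near <- c(rep("a", 4), "b")
  expect_equal(cohens_kappa(rep("a", 5), near),
               e1071::classAgreement(table(factor(rep("a", 5),
                                                  levels = c("a", "b")),
                                           factor(near)))$kappa,
               tolerance = 1e-12)
})
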