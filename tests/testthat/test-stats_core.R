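test_that("class entropy matches the binary Shannon formula", {
  expect_equal(class_entropy(4, 4), 1.0)
  expect_equal(class_entropy(5, 0), 0.0)
  expect_equal(class_entropy(6, 2),
               -0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_error(class_entropy(0, 0), "empty")
})

test_that("discriminating score behaves as information gain", {
  expect_equal(discriminating_score(c(4, 4), c(4, 0), c(0, 4)), 1.0)
  expect_equal(discriminating_score(c(4, 4), c(2, 2), c(2, 2)), 0.0)
  expect_equal(discriminating_score(c(6, 2), c(3, 2), c(3, 0)),
               oracle_gain(c(6, 2), c(3, 2), c(3, 0)))
  # empty child contributes zero
  expect_equal(discriminating_score(c(3, 3), c(3, 3), c(0, 0)), 0.0)
  expect_error(discriminating_score(c(4, 4), c(3, 0), c(0, 4)), "inconsistent")
})

test_that("gain is non-negative and zero iff children keep the class mix", {
  set.seed(11)
  for (rep in 1:200) {
    parent <- c(sample(1:30, 1), sample(1:30, 1))
    left <- c(sample(0:parent[1], 1), sample(0:parent[2], 1))
    right <- parent - left
    g <- discriminating_score(parent, left, right)
    expect_gte(g, -1e-12)
    if (sum(left) > 0 && sum(right) > 0 &&
        isTRUE(all.equal(left[1] / sum(left), parent[1] / sum(parent)))) {
      expect_equal(g, 0)
    }
  }
})

test_that("mutual information matches brute-force cell summation", {
  expect_equal(mutual_information(matrix(c(2, 0, 0, 2), 2)), 1.0)
  expect_equal(mutual_information(matrix(1, 2, 2)), 0.0)
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(mutual_information(tab), oracle_mi(tab))
  expect_error(mutual_information(matrix(0, 2, 2)), "all-zero")
})

test_that("MI is symmetric and normalized MI lies in [0, 1]", {
  set.seed(7)
  for (rep in 1:50) {
    tab <- matrix(rpois(6, 3), 2, 3)
    if (sum(tab) == 0) next
    expect_equal(mutual_information(tab), mutual_information(t(tab)))
    if (oracle_entropy(rowSums(tab)) > 0 && oracle_entropy(colSums(tab)) > 0) {
      nmi <- normalized_mi(tab)
      expect_gte(nmi, 0); expect_lte(nmi, 1)
      expect_equal(nmi, oracle_mi(tab) /
                     max(oracle_entropy(rowSums(tab)),
                         oracle_entropy(colSums(tab))))
    }
  }
  expect_equal(normalized_mi(matrix(c(2, 0, 0, 2), 2)), 1.0)
  expect_equal(normalized_mi(matrix(1, 2, 2)), 0.0)
  expect_error(normalized_mi(matrix(c(2, 2, 0, 0), 2)), "constant margin")
})

test_that("trend test agrees with the closed form and a permutation oracle", {
  same <- rbind(c(10, 20, 30), c(10, 20, 30))
  res <- trend_test(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  tab <- rbind(c(10, 20, 30), c(30, 20, 10))
  res <- trend_test(tab)
  # closed-form cross-check with the stats package
  ref <- suppressWarnings(stats::prop.trend.test(tab[1, ], colSums(tab), 0:2))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value)

  # permutation oracle: only the case score-sum varies under label shuffles
  g <- rep(0:2, times = colSums(tab))
  n <- length(g); n_case <- sum(tab[1, ])
  sc <- sum(g); sc2 <- sum(g^2)
  stat_of <- function(sr) {
    n * (n * sr - n_case * sc)^2 / (n_case * (n - n_case) * (n * sc2 - sc^2))
  }
  set.seed(1)
  perm <- replicate(1e5, sum(g[sample.int(n, n_case)]))
  p_perm <- mean(stat_of(perm) >= res$statistic - 1e-9)
  expect_lt(abs(p_perm - res$p.value),
            4 * sqrt(p_perm * (1 - p_perm) / 1e5) + 2e-4)

  extreme <- trend_test(rbind(c(0, 0, 50), c(50, 0, 0)))
  expect_lt(extreme$p.value, 1e-6)
})

test_that("general chi-squared test computes Pearson X2 with df collapse", {
  same <- rbind(c(5, 10, 15), c(5, 10, 15))
  expect_equal(general_chi2_test(same)$statistic, 0)
  expect_equal(general_chi2_test(same)$p.value, 1)

  tab <- rbind(c(25, 0, 25), c(0, 50, 0))
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - exp_tab)^2 / exp_tab)
  res <- general_chi2_test(tab)
  expect_equal(res$statistic, hand)
  expect_equal(res$df, 2L)

  collapsed <- general_chi2_test(rbind(c(10, 0, 5), c(3, 0, 12)))
  expect_equal(collapsed$df, 1L)
  ref <- suppressWarnings(
    stats::chisq.test(cbind(c(10, 3), c(5, 12)), correct = FALSE))
  expect_equal(collapsed$statistic, unname(ref$statistic))
  expect_error(general_chi2_test(rbind(c(0, 0, 0), c(1, 2, 3))), "zero row")
})

test_that("exact HWE test matches full enumeration", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 10, 0), oracle_hwe(0, 10, 0))
  expect_equal(hwe_exact_test(21, 48, 31), oracle_hwe(21, 48, 31))
  set.seed(42)
  for (rep in 1:25) {
    cnt <- as.vector(rmultinom(1, 60, c(0.45, 0.4, 0.15)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]))
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})
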