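# BAG summaries and the rank-statistics battery, each checked against an
# independent oracle: brute-force enumeration (Mann-Whitney), the
# rank-difference closed form (Spearman), explicit rank/residual arithmetic
# (partial Spearman), R's own implementations where applicable, and
# Monte-Carlo coverage (Bland-Altman).

test_that("bag sign convention and simple summaries", {
  expect_equal(bag(54, 37), 17)   # older-appearing brain
  expect_equal(bag(40, 50), -10)  # younger-appearing brain
  expect_equal(bag(33, 33), 0)

  rec <- data.frame(bag = c(-2, 2))
  expect_equal(mae(rec), 2)
  expect_equal(mean_bag(rec)$mean, 0)
  expect_equal(mean_bag(rec)$sd, sd(c(-2, 2)))
  expect_equal(mae(data.frame(bag = rep(0, 5))), 0)
  set.seed(1)
  r2 <- data.frame(bag = rnorm(50))
  expect_gte(mae(r2), abs(mean_bag(r2)$mean))
  expect_error(mae(data.frame(bag = numeric(0))), "record")
})

test_that("Bland-Altman limits: arithmetic and Monte-Carlo coverage", {
  rec <- data.frame(age = c(40, 50, 60), predicted_age = c(43, 53, 63))
  ba <- bland_altman(rec)
  expect_equal(ba$mean_diff, 3)
  expect_equal(ba$lower_limit, 3)  # zero-variance differences
  expect_equal(ba$upper_limit, 3)

  set.seed(7)
  n <- 10000
  rec2 <- data.frame(age = runif(n, 20, 80))
  rec2$predicted_age <- rec2$age + rnorm(n, 2, 5)
  ba2 <- bland_altman(rec2)
  expect_equal(ba2$upper_limit - ba2$mean_diff,
               ba2$mean_diff - ba2$lower_limit, tolerance = 1e-12)
  d <- rec2$predicted_age - rec2$age
  coverage <- mean(d >= ba2$lower_limit & d <= ba2$upper_limit)
  expect_lt(abs(coverage - 0.95), 0.007)
  expect_error(bland_altman(rec[1, , drop = FALSE]), "two")
})

test_that("exact Mann-Whitney equals full enumeration", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")$p_value,
               2 / 6, tolerance = 1e-12)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")$statistic, 0)
  expect_equal(mann_whitney_u(c(5, 6, 7), c(5, 6, 7))$p_value, 1)

  # independent brute-force oracle (with ties), all n, m <= 8 sampled
  brute <- function(x, y) {
    r <- rank(c(x, y))
    n <- length(x)
    U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combs <- combn(length(r), n)
    U_all <- apply(combs, 2, function(ix) sum(r[ix])) - n * (n + 1) / 2
    c <- n * length(y) / 2
    mean(abs(U_all - c) >= abs(U_obs - c) - 1e-12)
  }
  set.seed(11)
  for (trial in 1:12) {
    n <- sample(1:8, 1); m <- sample(1:8, 1)
    x <- sample(1:6, n, replace = TRUE)  # ties likely
    y <- sample(1:6, m, replace = TRUE)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value, brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normal-approximation Mann-Whitney tracks the exact test", {
  # R's wilcox.test exact recursion is the oracle at n = m = 20 (no ties)
  set.seed(12)
  for (trial in 1:5) {
    x <- rnorm(20); y <- rnorm(20, 0.3)
    p_approx <- mann_whitney_u(x, y, mode = "normal_approx")$p_value
    p_exact <- wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    expect_lt(abs(p_approx - p_exact), 0.01)
  }
  # auto switches on pooled size
  expect_match(mann_whitney_u(rnorm(8), rnorm(8))$method, "exact")
  expect_match(mann_whitney_u(rnorm(9), rnorm(8))$method, "approx")
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Spearman: closed form, symmetry, degenerate input", {
  r <- spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$estimate, 1 - 6 * 4 / (4 * 15), tolerance = 1e-12) # 0.6
  expect_equal(spearman(1:10, (1:10)^3)$estimate, 1)
  set.seed(13)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman(x, y)$estimate, spearman(y, x)$estimate)
  expect_equal(spearman(x, y)$estimate,
               suppressWarnings(cor.test(x, y, method = "spearman")$estimate),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  # exact permutation p agrees with the t approximation in order of magnitude
  pe <- spearman(x[1:8], y[1:8], exact_perm = TRUE)$p_value
  pt <- spearman(x[1:8], y[1:8])$p_value
  expect_lt(abs(pe - pt), 0.15)
})

test_that("partial Spearman: reduction, oracle equivalence, conditioning", {
  set.seed(14)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(partial_spearman(x, y)$estimate, spearman(x, y)$estimate,
               tolerance = 1e-10)
  expect_equal(partial_spearman(x, y)$p_value, spearman(x, y)$p_value,
               tolerance = 1e-10)

  # independent brute force: explicit midranks + normal-equation residuals
  brute_partial <- function(x, y, Z) {
    mr <- function(v) rank(v, ties.method = "average")
    enc <- function(col) {
      if (length(unique(col)) <= 2) {
        u <- sort(unique(as.character(col)))
        as.numeric(as.character(col) == u[length(u)])
      } else mr(col)
    }
    M <- cbind(1, sapply(as.data.frame(Z), enc))
    px <- mr(x) - M %*% solve(t(M) %*% M, t(M) %*% mr(x))
    py <- mr(y) - M %*% solve(t(M) %*% M, t(M) %*% mr(y))
    sum(px * py) / sqrt(sum(px^2) * sum(py^2))
  }
  for (trial in 1:50) {
    n <- sample(12:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    Z <- data.frame(a = rnorm(n), s = sample(c("M", "F"), n, replace = TRUE))
    expect_equal(partial_spearman(x, y, Z)$estimate, brute_partial(x, y, Z),
                 tolerance = 1e-10)
  }

  # conditional independence: x = z + e1, y = z + e2
  set.seed(15)
  z <- rnorm(1000); x <- z + rnorm(1000); y <- z + rnorm(1000)
  expect_gt(spearman(x, y)$estimate, 0.3)  # confounded without adjustment
  expect_lt(abs(partial_spearman(x, y, data.frame(z = z))$estimate), 0.08)

  expect_error(partial_spearman(rnorm(20), rnorm(20),
                                data.frame(a = 1:20, b = 2 * (1:20))),
               "collinear")
})

test_that("Bonferroni threshold", {
  expect_equal(bonferroni(0.05, 102), 0.05 / 102)
  expect_equal(round(bonferroni(0.05, 102), 5), 0.00049)  # printed threshold
  expect_equal(bonferroni(0.05, 1), 0.05)
  m <- 1:20
  expect_true(all(diff(vapply(m, bonferroni, 0, alpha = 0.05)) < 0))
  expect_error(bonferroni(0.05, 0), "m")
  expect_error(bonferroni(1.2, 3), "alpha")
})

test_that("grouped comparison: identity, type-I error, power", {
  set.seed(16)
  n <- 40
  rec <- data.frame(bag = rnorm(n), lesion_volume = rexp(n),
                    age = runif(n, 20, 60),
                    sex = sample(c("M", "F"), n, replace = TRUE))

  # identical groups: duplicate the data across the two groups
  rec2 <- rbind(rec, rec)
  res <- compare_groups(rec2, rep(c(TRUE, FALSE), each = n),
                        variables = "lesion_volume")
  expect_equal(res$group_table$p_value, 1, tolerance = 1e-9)
  expect_equal(res$group_table$median_group1, res$group_table$median_group2)

  # type-I error of the group test under a random split
  set.seed(17)
  pvals <- replicate(400, {
    g <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(g) < 2 || sum(!g) < 2) return(NA_real_)
    compare_groups(rec, g, variables = "bag")$group_table$p_value
  })
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 0.03)

  # power: bag generated increasing in lesion_volume -> significant
  # positive partial correlation controlling age and sex
  set.seed(18)
  rec3 <- data.frame(lesion_volume = rexp(80), age = runif(80, 20, 60),
                     sex = sample(c("M", "F"), 80, replace = TRUE))
  rec3$bag <- 2 * rec3$lesion_volume + rnorm(80, 0, 1)
  res3 <- compare_groups(rec3, rec3$bag < median(rec3$bag),
                         variables = "lesion_volume")
  expect_gt(res3$correlation_table$partial_rho, 0)
  expect_lt(res3$correlation_table$partial_p, 0.001)

  expect_error(compare_groups(rec, rec$bag < 0, variables = "nope"),
               "absent")
  expect_error(compare_groups(rec, rep(TRUE, n), variables = "bag"),
               "two non-empty")
})
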