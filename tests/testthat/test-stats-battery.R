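test_that("D'Agostino-Pearson matches the frozen independent oracle", {
  # expected values frozen from an independent omnibus-K2 implementation
  x <- c(0.1, 0.9, 1.7, 2.1, 2.4, 3.3, 3.6, 4.1, 4.9, 5.2, 6.8, 7.0,
         8.5, 9.9, 12.0, 15.5)
  ht <- dagostino_pearson(x)
  expect_equal(unname(ht$statistic), 3.5681649231, tolerance = 1e-8)
  expect_equal(ht$p.value, 0.1679510919, tolerance = 1e-8)
  expect_equal(unname(ht$estimate["z_skew"]), 1.7444071210, tolerance = 1e-8)
  expect_equal(unname(ht$estimate["z_kurtosis"]), 0.7247128529,
               tolerance = 1e-8)

  ht2 <- dagostino_pearson(c(1:20, 26, 31))
  expect_equal(unname(ht2$statistic), 2.2204462669, tolerance = 1e-8)
  expect_equal(ht2$p.value, 0.3294854337, tolerance = 1e-8)

  # an exactly symmetric sample carries no skewness evidence
  expect_equal(unname(dagostino_pearson(1:20)$estimate["z_skew"]), 0)

  expect_error(dagostino_pearson(c(1, 2, 3, 4, 5)), "n >= 8")
  expect_error(dagostino_pearson(rep(2, 20)), "zero variance")
})

test_that("the normality test keeps its size and detects skew", {
  hits <- with_seed(101, {
    sum(replicate(100, dagostino_pearson(rnorm(5000))$p.value > 0.05))
  })
  expect_gte(hits, 90)

  pexp <- with_seed(202, dagostino_pearson(rexp(500))$p.value)
  expect_lt(pexp, 0.05)
})

test_that("identical groups give H = 0 and adjusted pairwise p = 1", {
  d <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                  value = rep(1:10, 3))
  kw <- kruskal.test(value ~ group, data = d)
  expect_equal(unname(kw$statistic), 0)
  dn <- dunn_test(d$value, d$group)
  expect_true(all(dn$p_adjusted == 1))
  expect_true(all(dn$z == 0))
})

test_that("Kruskal-Wallis H matches the brute-force rank oracle", {
  v <- c(1:5, 2:6, 10:14)
  g <- rep(c("g1", "g2", "g3"), each = 5)
  expect_equal(unname(kruskal.test(v, factor(g))$statistic),
               brute_force_H(v, g), tolerance = 1e-12)

  # and through compare_groups when the nonparametric branch fires
  set <- with_seed(7, data.frame(
    group = rep(c("a", "b", "c"), each = 40),
    value = c(rexp(40, 1), rexp(40, 0.8), rexp(40, 0.5))))
  rep_ <- compare_groups(set)
  expect_equal(rep_$branch, "kruskal-dunn")
  expect_equal(rep_$statistic, brute_force_H(set$value, set$group),
               tolerance = 1e-12)
})

test_that("the normality gate selects the branch the rule prescribes", {
  set <- with_seed(15, data.frame(
    group = rep(c("a", "b", "c"), each = 30),
    value = c(rnorm(30), rnorm(30), rexp(30))))   # one clearly non-normal
  permissive <- compare_groups(set, normality_rule = "any-normal")
  strict <- compare_groups(set, normality_rule = "all-normal")
  expect_equal(permissive$branch, "anova-oneway")
  expect_equal(strict$branch, "kruskal-dunn")
  expect_true(all(c("group", "n", "test", "p_value", "normal") %in%
                    names(permissive$normality)))

  two <- with_seed(16, data.frame(
    group = rep(rep(c("a", "b"), each = 15), 2),
    factor2 = rep(c("s1", "s2"), each = 30),
    value = rnorm(60)))
  r2 <- compare_groups(two, design = "two-way")
  expect_equal(r2$branch, "anova-twoway")

  # a zero-variance group cannot be normality-tested: treated as non-normal
  degen <- with_seed(17, data.frame(
    group = rep(c("a", "b"), each = 10),
    value = c(rep(1, 10), rnorm(10))))
  rd <- compare_groups(degen, normality_rule = "all-normal")
  expect_equal(rd$branch, "kruskal-dunn")
  expect_false(rd$normality$normal[rd$normality$group == "a"])

  expect_error(compare_groups(data.frame(group = "a", value = 1:5)),
               "2 groups")
  expect_error(compare_groups(data.frame(group = rep(c("a", "b"), c(3, 2)),
                                         value = 1:5)),
               "3 observations")
})

test_that("group comparison is invariant to row permutation", {
  set <- with_seed(23, data.frame(
    group = rep(c("a", "b", "c"), each = 15),
    value = c(rexp(15), rexp(15, 0.7), rexp(15, 0.4))))
  r1 <- compare_groups(set)
  r2 <- compare_groups(set[with_seed(5, sample(nrow(set))), ])
  expect_equal(r2$statistic, r1$statistic)
  expect_equal(r2$omnibus_p, r1$omnibus_p)
  expect_equal(r2$pairwise$p_adjusted, r1$pairwise$p_adjusted)
})

test_that("Dunn adjustment never lowers a p-value", {
  set <- with_seed(31, data.frame(
    group = rep(c("a", "b", "c", "d"), each = 12),
    value = rexp(48, rate = rep(c(1, 0.8, 0.6, 0.3), each = 12))))
  dn <- dunn_test(set$value, set$group, p_adjust = "bonferroni")
  expect_true(all(dn$p_adjusted >= dn$p_value))
  dh <- dunn_test(set$value, set$group, p_adjust = "holm")
  expect_true(all(dh$p_adjusted >= dh$p_value))
})

test_that("ROUT keeps false positives rare and catches gross outliers", {
  reps <- with_seed(41, replicate(100, sum(rout_outliers(rnorm(100)))))
  expect_gte(mean(reps <= 2), 0.95)

  x <- with_seed(43, rnorm(50))
  x[7] <- median(x) + 10 * mad(x)
  expect_true(rout_outliers(x)[7])

  const <- c(rep(3, 11), 8)
  expect_warning(flags <- rout_outliers(const), "zero MAD")
  expect_equal(which(flags), 12L)

  expect_error(rout_outliers(1:5), "n >= 10")
})

test_that("zero-MAD samples fall back with a warning", {
  x <- c(rep(5, 8), 6, 7)
  expect_warning(flags <- rout_outliers(x), "zero MAD")
  expect_true(all(flags[9:10]))
})

test_that("the flag -> exclude -> test order recovers the clean analysis", {
  clean <- with_seed(51, data.frame(
    group = rep(c("a", "b", "c"), each = 20),
    value = c(rnorm(20, 1), rnorm(20, 1.3), rnorm(20, 2))))
  r_clean <- compare_groups(clean)

  spiked <- rbind(clean,
                  data.frame(group = "a", value = 50))  # gross outlier
  flags <- logical(nrow(spiked))
  for (g in unique(spiked$group)) {
    i <- spiked$group == g
    flags[i] <- rout_outliers(spiked$value[i])
  }
  expect_equal(which(flags), nrow(spiked))   # only the injected point
  r_excl <- compare_groups(spiked[!flags, ])
  expect_equal(r_excl$omnibus_p, r_clean$omnibus_p)
  expect_equal(r_excl$branch, r_clean$branch)
})
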