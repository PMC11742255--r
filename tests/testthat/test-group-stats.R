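# Factorial tests, their nonparametric analogues and the correlation screen.

test_that("two-way ANOVA reduces to one-way and is location invariant", {
  set.seed(71)
  v <- rnorm(30); g <- gl(3, 10)
  ours <- two_way_anova(v, g)
  ref <- summary(aov(v ~ g))[[1]]
  expect_equal(ours$statistic, ref[1, "F value"])
  expect_equal(ours$p_value, ref[1, "Pr(>F)"])
  # location shift leaves F unchanged
  a <- gl(2, 12); b <- rep(gl(2, 6), 2); v2 <- rnorm(24)
  expect_equal(two_way_anova(v2 + 100, a, b)$statistic,
               two_way_anova(v2, a, b)$statistic, tolerance = 1e-9)
  expect_error(two_way_anova(rnorm(4), factor(c("x", "x", "y", "y")),
                             factor(c("p", "p", "p", "p"))), "empty")
})

test_that("Scheirer-Ray-Hare equals Kruskal-Wallis when one factor collapses", {
  set.seed(72)
  for (i in 1:5) {
    v <- rexp(36); g <- gl(3, 12)
    srh <- scheirer_ray_hare(v, g)
    kw <- kruskal.test(v, g)
    expect_equal(srh$statistic, unname(kw$statistic), tolerance = 1e-12)
    expect_equal(srh$p_value, kw$p.value, tolerance = 1e-12)
  }
  # with ties (mid-ranks + tie correction carried by the rank variance)
  v <- rep(1:4, each = 6); g <- gl(4, 6)
  expect_equal(scheirer_ray_hare(v, g)$statistic,
               unname(kruskal.test(v, g)$statistic), tolerance = 1e-12)
})

test_that("SRH is invariant to monotone transforms of the response", {
  set.seed(73)
  v <- rexp(32); a <- gl(2, 16); b <- rep(gl(2, 8), 2)
  h1 <- scheirer_ray_hare(v, a, b)$statistic
  h2 <- scheirer_ray_hare(exp(v), a, b)$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
  # degenerate all-tied response
  expect_equal(scheirer_ray_hare(rep(3, 16), gl(2, 8))$statistic, 0)
})

test_that("Wilcoxon p-values match exhaustive enumeration at small n", {
  # fully separated 5 vs 5: one-sided 1/252, two-sided 2/252
  res <- wilcoxon_pair(1:5, 6:10)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # enumeration oracle over all C(n_a + n_b, n_a) label assignments
  enum_p_less <- function(a, b) {
    pooled <- c(a, b); n <- length(pooled)
    rk <- rank(pooled)
    obs <- sum(rk[seq_along(a)])
    sums <- combn(n, length(a), function(ix) sum(rk[ix]))
    mean(sums <= obs)
  }
  set.seed(74)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(6, 1)
    ours <- suppressWarnings(stats::wilcox.test(a, b, alternative = "less",
                                                exact = TRUE))$p.value
    expect_equal(ours, enum_p_less(a, b), tolerance = 1e-12)
  }
  # identical groups: no evidence
  expect_gt(wilcoxon_pair(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.8)
  # label swap preserves the two-sided p
  set.seed(75); x <- rnorm(8); y <- rnorm(8, 0.5)
  expect_equal(wilcoxon_pair(x, y)$p_value, wilcoxon_pair(y, x)$p_value)
  expect_error(wilcoxon_pair(1:2, 1:5), "at least 3")
  # paired mode runs the signed-rank test
  expect_match(wilcoxon_pair(x, y, paired = TRUE)$method, "signed rank")
})

test_that("Spearman screen handles monotone, constant and null columns", {
  pred <- data.frame(up = 1:20, down = 20:1, flat = rep(1, 20))
  resp <- data.frame(y = (1:20)^2)
  sc <- spearman_screen(pred, resp)
  expect_equal(sc$rho["up", "y"], 1)
  expect_equal(sc$rho["down", "y"], -1)
  expect_true(is.na(sc$rho["flat", "y"]))
  expect_true("flat" %in% sc$flags)
  # independence: mean rho near zero over replicated null draws
  set.seed(76)
  rhos <- replicate(300, {
    spearman_screen(data.frame(x = rnorm(30)),
                    data.frame(y = rnorm(30)))$rho[1, 1]
  })
  expect_lt(abs(mean(rhos)), 0.02)
  # optional BH adjustment never lowers a p-value
  sc2 <- spearman_screen(pred[, 1:2], resp, adjust = "BH")
  expect_true(all(sc2$p >= sc$p[1:2, , drop = FALSE]))
  expect_error(spearman_screen(pred[1:3, ], resp[1:3, , drop = FALSE]),
               "at least 4")
})

test_that("normality gate routes by residual distribution and records it", {
  set.seed(77)
  g <- gl(2, 25)
  gate_norm <- normality_gate(rnorm(50), g)
  expect_equal(gate_norm$route, "parametric")
  gate_heavy <- normality_gate(rcauchy(50), g)
  expect_equal(gate_heavy$route, "nonparametric")
  # log-normal data: rescued by the log transform
  gate_ln <- normality_gate(exp(rnorm(50, sd = 2)), g)
  expect_equal(gate_ln$route, "parametric")
  expect_equal(gate_ln$transform, "log")
  # the routed comparison records method and transform
  fc <- factorial_compare(exp(rnorm(40, sd = 2)), gl(2, 20), rep(gl(2, 10), 2),
                          response_name = "resp")
  expect_true(all(fc$method %in% c("two_way_anova", "scheirer_ray_hare")))
  expect_true(all(fc$response == "resp"))
})
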