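test_that("day-1 normalization rescales each series by its first day", {
  tab <- data.frame(genotype = "g", replicate = 1, day = c(1, 3),
                    n_plated = c(10, 10), n_alive = c(8, 4))
  out <- normalize_day1(tab)
  expect_equal(out$norm_prop, c(1, 0.5))

  const <- data.frame(genotype = "g", replicate = 1, day = 1:4,
                      n_plated = 20, n_alive = 15)
  expect_equal(normalize_day1(const)$norm_prop, rep(1, 4))

  up <- data.frame(genotype = "g", replicate = 1, day = 1:2,
                   n_plated = c(10, 10), n_alive = c(8, 9))
  expect_equal(normalize_day1(up)$norm_prop[2], 1.125) # values > 1 permitted

  zero <- data.frame(genotype = "g", replicate = 1, day = 1:2,
                     n_plated = 10, n_alive = c(0, 0))
  expect_error(normalize_day1(zero), "day-1 proportion is zero")
  noday1 <- data.frame(genotype = "g", replicate = 1, day = 2:4,
                       n_plated = 10, n_alive = 5)
  expect_error(normalize_day1(noday1), "no day-1 row")
  bad <- data.frame(genotype = "g", replicate = 1, day = 1, n_plated = 5,
                    n_alive = 9)
  expect_error(normalize_day1(bad), "exceeds")
})

test_that("quasi-binomial fit recovers generating logistic coefficients", {
  s1 <- make_logistic_series(beta0 = 2, beta1 = -1)
  f1 <- fit_survival(s1)
  expect_equal(f1$half_life, 2, tolerance = 1e-6)
  expect_true(f1$converged)
  expect_true(f1$half_life_defined)

  s2 <- make_logistic_series(beta0 = 3, beta1 = -0.5, days = 1:14)
  expect_equal(fit_survival(s2)$half_life, 6, tolerance = 0.01)

  flat <- data.frame(genotype = "g", replicate = 1, day = 1:6, n_plated = 100,
                     norm_prop = 1)
  ff <- fit_survival(flat)
  expect_false(ff$half_life_defined)
  expect_true(is.na(ff$half_life))

  expect_error(fit_survival(s1[1:2, ]), "3 distinct days")

  # uniform scaling of plate sizes leaves the coefficients unchanged
  s3 <- s1; s3$n_plated <- s1$n_plated * 10
  expect_equal(coef(fit_survival(s3)), coef(fit_survival(s1)), tolerance = 1e-9)

  # methods
  expect_output(print(f1), "half-life")
  expect_equal(unname(predict(f1, data.frame(day = 2))), 0.5, tolerance = 1e-6)
  pdf(NULL); on.exit(dev.off())
  plot(f1)
})

test_that("normalized half-life ignores the absolute day-1 survival level", {
  g <- c(1, 0.75, 0.5, 0.25, 0.125)
  mk <- function(level) data.frame(genotype = "g", replicate = 1, day = 1:5,
                                   n_plated = 1000,
                                   n_alive = round(1000 * level * g))
  hi <- fit_survival_all(mk(0.8))
  lo <- fit_survival_all(mk(0.4))
  expect_equal(hi$half_life, lo$half_life, tolerance = 1e-9)
})

test_that("raw-response fits recover generator half-lives without bias", {
  res <- vapply(1:10, function(s) {
    tab <- simulate_survival(data.frame(label = c("hl3", "hl6"),
                                        half_life = c(3, 6), slope = c(-1, -1)),
                             n_reps = 4, days = 1:12, n_plated_mean = 100,
                             seed = s)
    fits <- fit_survival_all(tab, normalize = FALSE)
    c(mean(fits$half_life[fits$genotype == "hl3"]),
      mean(fits$half_life[fits$genotype == "hl6"]))
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 3), 0.25)
  expect_lt(abs(mean(res[2, ]) - 6), 0.25)
})

test_that("half-life comparison gates pooling on variance homogeneity", {
  same <- compare_halflives(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$variance_p, 1) # equal variances: Bartlett statistic 0
  expect_true(same$pooled)

  hand <- compare_halflives(c(2, 4), c(6, 8))
  expect_true(hand$pooled)
  expect_equal(hand$t, -2 * sqrt(2), tolerance = 1e-9)
  expect_equal(hand$df, 2)

  lev <- compare_halflives(c(2, 4, 3), c(6, 8, 7), variance_test = "levene")
  expect_equal(lev$variance_test, "levene")
  expect_true(lev$p < 0.05)

  const <- compare_halflives(c(5, 5), c(5, 5))
  expect_equal(const$t, 0)
  expect_equal(const$p, 1)

  expect_error(compare_halflives(1, c(2, 3)), "2 replicates")
})

test_that("half-life comparison p-values are uniform under the null", {
  set.seed(30)
  ps <- replicate(1000, {
    compare_halflives(rnorm(4, 5, 0.5), rnorm(4, 5, 0.5))$p
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif")$statistic), 0.05)
})

test_that("two-way interaction ANOVA detects nonadditivity and only that", {
  A <- rep(c(0, 1), each = 4)
  B <- rep(rep(c(0, 1), each = 2), 2)
  additive <- 1 + 2 * A - 1 * B
  tab <- interaction_anova(additive, A, B)
  expect_equal(tab$sumsq[tab$term == "A:B"], 0)

  set.seed(7)
  y <- additive + rnorm(8, 0, 0.3)
  t1 <- interaction_anova(y, A, B)
  t2 <- interaction_anova(c(y, y), c(A, A), c(B, B))
  expect_equal(t2$sumsq[t2$term == "A:B"], 2 * t1$sumsq[t1$term == "A:B"])

  # interacting truth is flagged
  yi <- y + 3 * A * B
  ti <- interaction_anova(yi, A, B)
  expect_lt(ti$p[ti$term == "A:B"], 0.01)

  expect_error(interaction_anova(y[1:7], A[1:7], B[1:7]), "replicates")
  expect_error(interaction_anova(y[1:6], A[1:6], B[1:6]), "empty")

  # balanced design matches the classical decomposition from aov
  cls <- summary(aov(y ~ factor(A) * factor(B)))[[1]]
  expect_equal(t1$sumsq[1:3], unname(cls[["Sum Sq"]][1:3]), tolerance = 1e-9)
})

test_that("aligned-rank-transform ANOVA aligns, ranks and tests one effect", {
  A <- factor(rep(1:2, each = 10))
  B <- factor(rep(rep(1:5, each = 2), 2))
  # no interaction, no noise: aligned responses all tie, F = 0
  y0 <- as.numeric(A) + 2 * as.numeric(B)
  r0 <- art_anova(y0, A, B, "interaction")
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  set.seed(8)
  y <- as.numeric(A) + 2 * as.numeric(B) + 4 * (A == 2 & B == 3) + rnorm(20, 0, 0.2)
  ri <- art_anova(y, A, B, "interaction")
  expect_lt(ri$p, 0.05)

  # main effect requests test their own alignment
  ra <- art_anova(y, A, B, "a")
  expect_true(is.finite(ra$F))
  expect_length(ra$df, 2)

  expect_error(art_anova(y[-(1:2)], A[-(1:2)], B[-(1:2)]), "empty cell")
})

test_that("Kruskal-Wallis wrapper matches the closed form and handles ties", {
  kw <- kruskal_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)
  expect_equal(kw$df, 1)

  flat <- kruskal_test(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)

  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  g <- rep(c("x", "y"), 4)
  expect_equal(kruskal_test(v, g)$H, kruskal_test(v, factor(g, c("y", "x")))$H)

  expect_error(kruskal_test(1:3, rep("a", 3)), "2 groups")
})

test_that("hatching plateau returns the earliest common-maximum timepoint", {
  hatch <- expand.grid(genotype = c("wt", "m1"), time = 12:18)
  hatch$prop_hatched <- ifelse(hatch$time >= 16, 0.95, 0.5 + 0.1 * (hatch$time - 12))
  expect_equal(hatch_plateau(hatch), 16)

  mono <- data.frame(genotype = "wt", time = 1:5, prop_hatched = seq(0.2, 1, 0.2))
  expect_equal(hatch_plateau(mono), 5)

  early <- data.frame(genotype = "wt", time = 1:4, prop_hatched = 0.9)
  expect_equal(hatch_plateau(early), 1)

  expect_error(hatch_plateau(data.frame(genotype = "wt", time = 1,
                                        prop_hatched = 1)), "2 timepoints")
})
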