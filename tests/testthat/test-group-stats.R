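# independent hand implementation of Welch's ANOVA for the oracle route
welch_by_hand <- function(values, group) {
  g <- split(values, group)
  n <- vapply(g, length, numeric(1))
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, stats::var, numeric(1))
  w <- n / v
  mw <- sum(w * m) / sum(w)
  k <- length(g)
  a <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / sum(w))^2 / (n - 1))
  b <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  f <- a / b
  df2 <- (k^2 - 1) / (3 * lambda)
  p <- stats::pf(f, k - 1, df2, lower.tail = FALSE)
  list(f = f, df1 = k - 1, df2 = df2, p = p)
}

test_that("Welch's ANOVA matches the textbook formula and the t-test", {
  withr::with_seed(71, {
    x <- c(stats::rnorm(12, 0, 1), stats::rnorm(9, 0.8, 2),
           stats::rnorm(15, -0.3, 0.5))
  })
  g <- rep(c("a", "b", "c"), c(12, 9, 15))
  res <- welch_anova(x, g)
  hand <- welch_by_hand(x, g)
  expect_equal(res$statistic, hand$f, tolerance = 1e-10)
  expect_equal(res$df2, hand$df2, tolerance = 1e-10)
  expect_equal(res$p_value, hand$p, tolerance = 1e-10)
  # two groups: p identical to two-sided Welch t-test, F = t^2
  x2 <- x[g != "c"]; g2 <- g[g != "c"]
  res2 <- welch_anova(x2, g2)
  tt <- stats::t.test(x2 ~ g2)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
})

test_that("Welch's ANOVA null and degenerate cases", {
  res <- welch_anova(c(5, 5, 5, 5, 5, 5), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(welch_anova(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3)),
               "degenerate")
  expect_error(welch_anova(c(1, 1, 1, 2, 3, 4), rep(c("a", "b"), each = 3)),
               "degenerate")
  expect_error(welch_anova(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("variance-ratio F-test has the documented identities", {
  a <- c(1.2, 3.4, 2.2, 4.8, 0.5)
  expect_equal(variance_ratio_test(a, a)$statistic, 1)
  expect_equal(variance_ratio_test(a, a)$p_value, 1)
  # doubling the scale quadruples F
  res <- variance_ratio_test(2 * a, a)
  expect_equal(res$statistic, 4)
  # two-sided p doubles the smaller tail
  b <- c(0.1, 0.2, 0.15, 0.12, 0.18, 0.11)
  res2 <- variance_ratio_test(a, b)
  f <- stats::var(a) / stats::var(b)
  expect_equal(res2$statistic, f)
  expect_equal(res2$p_value,
               2 * min(stats::pf(f, 4, 5), stats::pf(f, 4, 5,
                                                     lower.tail = FALSE)))
  expect_error(variance_ratio_test(a, c(3, 3, 3)), "zero variance")
})

test_that("Levene/Brown-Forsythe matches brute-force arithmetic", {
  withr::with_seed(13, {
    x <- c(stats::rnorm(10, 0, 1), stats::rnorm(12, 0, 3))
  })
  g <- rep(c("a", "b"), c(10, 12))
  res <- levene_test(x, g)
  # brute force: one-way ANOVA on |x - group median|
  z <- abs(x - stats::ave(x, g, FUN = stats::median))
  an <- stats::anova(stats::lm(z ~ factor(g)))
  expect_equal(res$statistic, an$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, an$`Pr(>F)`[1], tolerance = 1e-12)
  # equal-spread groups (one shifted) give a near-zero statistic
  y <- c(1, 2, 3, 4, 11, 12, 13, 14)
  res0 <- levene_test(y, rep(c("a", "b"), each = 4))
  expect_lt(res0$statistic, 1e-10)
  # doubling one group's spread increases the statistic
  y2 <- c(1, 2, 3, 4, 9, 11, 15, 17)
  expect_gt(levene_test(y2, rep(c("a", "b"), each = 4))$statistic,
            res0$statistic)
})

test_that("Games-Howell agrees with a scalar reimplementation", {
  withr::with_seed(97, {
    x <- c(stats::rnorm(8, 0, 1), stats::rnorm(11, 1, 2),
           stats::rnorm(9, -1, 0.6))
  })
  g <- rep(c("a", "b", "c"), c(8, 11, 9))
  res <- games_howell(x, g)
  expect_equal(nrow(res), 3)
  # independent scalar route
  for (i in seq_len(nrow(res))) {
    xa <- x[g == res$group1[i]]; xb <- x[g == res$group2[i]]
    se2 <- stats::var(xa) / length(xa) + stats::var(xb) / length(xb)
    tt <- (mean(xb) - mean(xa)) / sqrt(se2)
    df <- se2^2 / ((stats::var(xa) / length(xa))^2 / (length(xa) - 1) +
                     (stats::var(xb) / length(xb))^2 / (length(xb) - 1))
    p <- stats::ptukey(abs(tt) * sqrt(2), 3, df, lower.tail = FALSE)
    expect_equal(res$statistic[i], tt)
    expect_equal(res$p_value[i], p)
    expect_equal(sign(res$mean_diff[i]), sign(res$statistic[i]))
  }
})

test_that("Games-Howell handles identical and degenerate groups", {
  x <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- games_howell(x, g)
  expect_true(all(res$p_value > 0.999))
  # one constant pair flagged, the others still returned
  x2 <- c(5, 5, 5, 5, 5, 5, 1, 2, 3)
  res2 <- games_howell(x2, g)
  expect_true(res2$flagged[res2$group1 == "a" & res2$group2 == "b"])
  expect_false(any(res2$flagged[res2$group2 == "c"]))
})

test_that("Cliff's delta equals pairwise enumeration", {
  d <- cliffs_delta(c(1, 2, 3), c(2, 3, 4))
  expect_equal(d$value, -5 / 9)
  expect_equal(d$band, "large")
  expect_equal(cliffs_delta(4:6, 1:3)$value, 1)
  expect_equal(cliffs_delta(1:3, 1:3)$value, 0)
  # property: brute-force double loop on random samples up to n = 30
  withr::with_seed(55, {
    for (rep in 1:20) {
      a <- stats::rnorm(sample(2:30, 1))
      b <- stats::rnorm(sample(2:30, 1), mean = stats::runif(1, -1, 1))
      brute <- 0
      for (ai in a) for (bj in b) brute <- brute + sign(ai - bj)
      brute <- brute / (length(a) * length(b))
      expect_equal(cliffs_delta(a, b)$value, brute)
      # antisymmetry and monotone invariance
      expect_equal(cliffs_delta(b, a)$value, -brute)
      expect_equal(cliffs_delta(exp(a), exp(b))$value, brute)
    }
  })
  expect_error(cliffs_delta(numeric(0), 1:3), "non-empty")
})

test_that("omega-squared matches the hand formula and is below R^2", {
  # fixed one-way table: A = (1,2,3), B = (2,3,4), C = (6,7,8)
  x <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- factor(rep(c("A", "B", "C"), each = 3))
  fit <- stats::aov(x ~ g)
  om <- omega_squared(fit)
  # hand arithmetic: means 2, 3, 7; grand mean 4
  ss_b <- 3 * ((2 - 4)^2 + (3 - 4)^2 + (7 - 4)^2) # 42
  ss_w <- sum((x - rep(c(2, 3, 7), each = 3))^2)  # 6
  ms_w <- ss_w / 6
  expect_equal(om$value, (ss_b - 2 * ms_w) / (ss_b + ss_w + ms_w))
  expect_equal(om$value,
               omega_squared(list(ss_between = ss_b, df_between = 2,
                                  ss_within = ss_w, df_within = 6))$value)
  # null case: SS_between equal to its null expectation gives 0
  om0 <- omega_squared(list(ss_between = 2 * ms_w, df_between = 2,
                            ss_within = ss_w, df_within = 6))
  expect_equal(om0$value, 0)
  # omega^2 <= eta^2 on random decompositions
  withr::with_seed(91, {
    for (i in 1:20) {
      y <- stats::rnorm(30)
      gg <- factor(sample(c("a", "b", "c"), 30, replace = TRUE))
      tab <- stats::anova(stats::lm(y ~ gg))
      o <- omega_squared(list(ss_between = tab$`Sum Sq`[1],
                              df_between = tab$Df[1],
                              ss_within = tab$`Sum Sq`[2],
                              df_within = tab$Df[2]))$value
      eta <- tab$`Sum Sq`[1] / sum(tab$`Sum Sq`)
      expect_lte(o, eta)
    }
  })
})

test_that("Spearman correlation uses mid-ranks", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$rho, -1)
  # tied example checked by explicit mid-ranking
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 2, 3, 5, 5)
  rx <- rank(x); ry <- rank(y) # mid-ranks: 1.5 1.5 3 4.5 4.5
  expect_equal(spearman_cor(x, y)$rho, stats::cor(rx, ry))
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "constant")
})

test_that("PCA has the expected algebraic structure", {
  withr::with_seed(19, {
    x1 <- stats::rnorm(40)
    m <- cbind(a = x1, b = 2 * x1 + stats::rnorm(40, 0, 0.1),
               c = stats::rnorm(40))
  })
  p <- run_pca(m)
  expect_equal(sum(p$explained_variance), 3, tolerance = 1e-10)
  expect_equal(crossprod(p$loadings), diag(3), ignore_attr = TRUE,
               tolerance = 1e-10)
  # perfectly 1-D data: PC1 explains everything
  line <- cbind(1:10, 2 * (1:10))
  p1 <- run_pca(line, standardize = TRUE)
  expect_equal(p1$explained_fraction[1], 1)
  # 2-variable standardized PCA: PC1 along (1,1)/sqrt(2)
  two <- m[, 1:2]
  p2 <- run_pca(two)
  expect_equal(abs(p2$loadings[, 1]), rep(1 / sqrt(2), 2),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_error(run_pca(cbind(c(1, NA, 3), 1:3)), "missing")
  expect_error(run_pca(cbind(rep(1, 5), 1:5)), "zero-variance")
})

test_that("mixed-effects contrast reduces to OLS without batch variance", {
  withr::with_seed(23, {
    d <- tibble::tibble(
      genotype = rep(c("control", "deletion"), each = 20),
      batch = rep(rep(c("b1", "b2"), each = 10), 2),
      y = stats::rnorm(40) + rep(c(0, 1.5), each = 20)
    )
  })
  res <- fit_genotype_lme(d, "y")
  ols <- stats::lm(y ~ genotype, data = d)
  # with identical batch distributions the random effect collapses and
  # the fixed effect matches least squares
  expect_equal(res$estimate, unname(stats::coef(ols)[2]),
               tolerance = 0.05)
  expect_error(fit_genotype_lme(d[d$batch == "b1", ], "y"),
               "one batch")
  d2 <- d; d2$genotype <- "control"
  expect_error(fit_genotype_lme(d2, "y"), "genotype does not vary")
})

test_that("mixed-effects contrast recovers an injected genotype effect", {
  withr::with_seed(29, {
    nb <- 4; per <- 12
    batch <- rep(paste0("b", 1:nb), each = 2 * per)
    genotype <- rep(rep(c("control", "deletion"), each = per), nb)
    b_int <- stats::rnorm(nb, 0, 2)
    y <- 20 + 10 * (genotype == "deletion") + b_int[as.integer(factor(batch))] +
      stats::rnorm(length(batch), 0, 3)
    d <- tibble::tibble(y = y, genotype = genotype, batch = batch)
  })
  res <- fit_genotype_lme(d, "y")
  expect_lt(abs(res$estimate - 10), 3) # within ~3 residual SDs of truth
  expect_lt(res$p_value, 0.01)
  expect_true(res$df2 > 0 && res$df1 == 1)
})

test_that("ddct computes fold changes against the calibrator group", {
  d <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 3),
    group = rep(c("control", "control", "deletion"), each = 3),
    gene = rep(c("GAPDH", "ACTB", "NEUN"), 3),
    ct = c(18, 18, 24, 18, 18, 24, 18, 18, 23)
  )
  res <- ddct(d, "NEUN", c("GAPDH", "ACTB"))
  expect_equal(res$fold_change[res$sample_id == "s1"], 1)
  # one cycle lower in the deletion sample = 2x expression
  expect_equal(res$fold_change[res$sample_id == "s3"], 2)
  # shifting target and housekeeping together changes nothing
  d2 <- d; d2$ct <- d2$ct + 1
  expect_equal(ddct(d2, "NEUN", c("GAPDH", "ACTB"))$fold_change,
               res$fold_change)
  # missing gene errors name the sample and gene
  expect_error(ddct(d[-3, ], "NEUN", c("GAPDH", "ACTB")), "s1.*NEUN")
  expect_error(ddct(d, "NEUN", "GAPDH"), "exactly two")
  expect_error(ddct(d, "NEUN", c("GAPDH", "ACTB"),
                    calibrator_group = "x"), "empty")
})
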