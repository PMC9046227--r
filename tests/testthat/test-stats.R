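test_that("a two-group Dunnett family reduces to the plain t test", {
  set.seed(14)
  y <- c(rnorm(6), rnorm(6, 1)); g <- rep(c("ctrl", "trt"), each = 6)
  res <- anova_dunnett(y, g, reference_group = "ctrl")
  tt <- t.test(y[g == "trt"], y[g == "ctrl"], var.equal = TRUE)
  expect_equal(res$contrasts$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(res$contrasts$p, res$contrasts$p_adj, tolerance = 1e-9)
  # paired two groups reduce to the paired t test
  s <- rep(paste0("s", 1:6), 2)
  resb <- anova_dunnett(y, g, subject = s, reference_group = "ctrl")
  ttp <- t.test(y[g == "trt"], y[g == "ctrl"], paired = TRUE)
  expect_equal(resb$contrasts$p_adj, ttp$p.value, tolerance = 1e-9)
})

test_that("Dunnett adjusted p agrees with the multcomp reference", {
  set.seed(11)
  y <- rnorm(24); g <- factor(rep(letters[1:4], each = 6))
  mine <- anova_dunnett(y, g, reference_group = "a")
  ref <- summary(multcomp::glht(aov(y ~ g),
                                linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(mine$contrasts$p_adj, as.numeric(ref$test$pvalues),
               tolerance = 2e-3)
  # unbalanced design exercises the general-correlation route
  keep <- -c(1, 2, 7)
  mine_u <- anova_dunnett(y[keep], g[keep], reference_group = "a")
  ref_u <- summary(multcomp::glht(aov(y[keep] ~ droplevels(g[keep])),
                                  linfct = multcomp::mcp(`droplevels(g[keep])` = "Dunnett")))
  expect_equal(mine_u$contrasts$p_adj, as.numeric(ref_u$test$pvalues),
               tolerance = 2e-3)
})

test_that("balanced-case quadrature and multivariate-t integration agree", {
  R <- matrix(0.5, 4, 4); diag(R) <- 1
  for (q in c(1.5, 2.5, 3.2)) {
    quad <- 1 - immunoplate:::dunnett_equicorr_prob(q, 4, 18, 0.5)
    qmc <- 1 - as.numeric(mvtnorm::pmvt(
      lower = rep(-q, 4), upper = rep(q, 4), df = 18L, corr = R,
      algorithm = mvtnorm::GenzBretz(maxpts = 2e5, abseps = 1e-6)))
    expect_lt(abs(quad - qmc), 1e-4)
  }
})

test_that("family-wise error of the max contrast matches a permutation oracle", {
  set.seed(2026)
  g <- factor(rep(letters[1:4], each = 6)); gi <- as.integer(g)
  y <- rnorm(24) + c(0, 0.8, 0.4, 0)[gi]
  res <- anova_dunnett(y, g, reference_group = "a")
  tmax <- max(abs(res$contrasts$t))
  p_adj_max <- res$contrasts$p_adj[which.max(abs(res$contrasts$t))]
  max_t <- function(yy) {
    m <- tapply(yy, g, mean)
    se <- sqrt(mean(tapply(yy, g, var)) * (2 / 6))
    max(abs((m[-1] - m[1]) / se))
  }
  set.seed(99)
  perm <- replicate(1e4, max_t(sample(y)))
  expect_lt(abs(p_adj_max - mean(perm >= tmax)), 0.01)
})

test_that("adjusted p is monotone in |t| and never below raw p", {
  set.seed(17)
  for (i in 1:20) {
    y <- rnorm(24) + rep(rnorm(4, sd = 0.6), each = 6)
    res <- anova_dunnett(y, rep(letters[1:4], each = 6), reference_group = "a")
    ct <- res$contrasts
    expect_true(all(ct$p_adj >= ct$p - 1e-12))
    o <- order(abs(ct$t))
    expect_true(all(diff(ct$p_adj[o]) <= 1e-9))
  }
})

test_that("blocked analysis removes additive subject effects exactly", {
  set.seed(23)
  g <- rep(letters[1:3], each = 8)
  s <- rep(paste0("s", 1:8), 3)
  base <- rnorm(24)
  shift <- rep(rnorm(8, sd = 50), 3)  # huge subject effects
  res_raw <- anova_dunnett(base + shift, g, subject = s)
  centered <- (base + shift) - ave(base + shift, s)
  res_ctr <- anova_dunnett(centered, g, subject = s)
  expect_equal(res_raw$contrasts$t, res_ctr$contrasts$t, tolerance = 1e-8)
  # incomplete subjects are dropped with a warning
  expect_warning(anova_dunnett(base[-1] + shift[-1], g[-1], subject = s[-1]),
                 "incomplete")
})

test_that("identical constant groups degrade gracefully", {
  res <- anova_dunnett(rep(5, 18), rep(letters[1:3], each = 6))
  expect_true(is.na(res$f_value))
  expect_equal(res$contrasts$p_adj, c(1, 1))
  expect_match(res$flags, "degenerate")
})

test_that("Sidak formula and its limits", {
  expect_equal(sidak_adjust(0.05, 3), 1 - 0.95^3)
  expect_equal(sidak_adjust(0.05, 3), 0.142625)
  expect_equal(sidak_adjust(0, 7), 0)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
})

test_that("two-way ANOVA reports F tests and Sidak-adjusted cell contrasts", {
  set.seed(3)
  d <- expand.grid(A = c("ctrl", "trt"), B = c("naive", "LPS", "IL4"),
                   rep = 1:4)
  d$y <- rnorm(nrow(d)) + ifelse(d$A == "trt" & d$B == "LPS", 2, 0)
  res <- anova_twoway_sidak(d$y, d$A, d$B)
  ref <- anova(lm(y ~ A * B, data = d))
  expect_equal(res$f_table$f, ref[c("A", "B", "A:B"), "F value"])
  expect_equal(res$f_table$p, ref[c("A", "B", "A:B"), "Pr(>F)"])
  expect_equal(nrow(res$contrasts), 3)  # one A contrast per B level
  expect_equal(res$contrasts$p_adj, sidak_adjust(res$contrasts$p, 3),
               tolerance = 1e-12)
  # contrast estimates are the cell-mean differences
  cellm <- tapply(d$y, list(d$A, d$B), mean)
  expect_equal(res$contrasts$estimate[1], cellm["ctrl", "naive"] - cellm["trt", "naive"],
               tolerance = 1e-9)
  expect_error(anova_twoway_sidak(d$y[-(1:4)], d$A[-(1:4)], d$B[-(1:4)])
               , NA)  # still complete
  drop_cell <- d$A == "ctrl" & d$B == "naive"
  expect_error(anova_twoway_sidak(d$y[!drop_cell], d$A[!drop_cell], d$B[!drop_cell]),
               "empty cell")
})

test_that("simple linear regression is exact on exact data and validates input", {
  x <- 1:10
  fit <- linregress(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(linregress(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(linregress(rep(3, 5), rnorm(5)), "constant")
})

test_that("slope p values are uniform under the null", {
  set.seed(1234)
  pvals <- vapply(1:1000, function(i) {
    linregress(rnorm(30), rnorm(30))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("significance stars follow the figure-legend convention", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.03, 0.2, NA)),
               c("***", "**", "*", "", ""))
})
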