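test_that("Kruskal-Wallis H matches the hand rank formula", {
  g <- list(c(1.2, 3.4, 2.2), c(4.5, 6.1, 5.0), c(0.3, 0.9, 1.1))
  res <- kruskal_wallis(g)
  expect_equal(res$H, kw_oracle(g), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$group_ns, lengths(g))

  # identical groups: H = 0 (fully tied data)
  same <- list(rep(2, 4), rep(2, 4))
  expect_equal(suppressWarnings(kruskal_wallis(same))$H, 0)

  # rank-based: invariant under monotone transformation
  set.seed(2)
  a <- rexp(8); b <- rexp(10) + 0.5
  expect_equal(kruskal_wallis(list(a, b))$H,
               kruskal_wallis(list(log(a), log(b)))$H, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(a)), "two groups")
  expect_error(kruskal_wallis(list(a, numeric(0))), "at least 2")
})

test_that("Dunn post hoc matches a pooled-rank oracle", {
  g <- list(x = c(1, 3, 5, 7), y = c(2, 4, 6, 8), z = c(20, 22, 24, 26))
  res <- dunn_posthoc(g, adjustment = "none")
  # oracle: pooled ranks, tie-corrected pooled variance
  x <- unlist(g); r <- rank(x); N <- length(x)
  grp <- rep(names(g), lengths(g))
  rbar <- tapply(r, grp, mean)
  ties <- table(x)
  C <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- function(i, j) sqrt((N * (N + 1) / 12 - C) * (1 / 4 + 1 / 4))
  z_xy <- (rbar["x"] - rbar["y"]) / se()
  z_xz <- (rbar["x"] - rbar["z"]) / se()
  expect_equal(res$z[res$group_a == "x" & res$group_b == "y"], unname(z_xy),
               tolerance = 1e-12)
  expect_equal(res$z[res$group_a == "x" & res$group_b == "z"], unname(z_xz),
               tolerance = 1e-12)
  # the clearly-shifted group has the smallest adjusted p values
  bf <- dunn_posthoc(g, "bonferroni")
  pz <- bf$p_adjusted[bf$group_b == "z" | bf$group_a == "z"]
  pxy <- bf$p_adjusted[bf$group_a == "x" & bf$group_b == "y"]
  expect_true(all(pz < pxy))
  expect_true(all(bf$p_adjusted >= res$p[match(paste(bf$group_a, bf$group_b),
                                               paste(res$group_a, res$group_b))]))

  # identical groups: all z = 0
  expect_true(all(dunn_posthoc(list(rep(1, 3), rep(1, 3), rep(1, 3)))$z == 0))

  # two groups, no adjustment: same decision as Kruskal-Wallis at alpha 0.05
  set.seed(6)
  for (i in 1:25) {
    a <- rnorm(sample(4:9, 1)); b <- rnorm(sample(4:9, 1), mean = runif(1, 0, 2))
    d <- dunn_posthoc(list(a, b), "none")
    k <- kruskal_wallis(list(a, b))
    expect_equal(d$p < 0.05, k$p < 0.05)
  }
})

test_that("simple OLS reports the F/r2/df identity and matches the oracle", {
  x <- c(1, 2, 3, 4); y <- 2 * x + 1
  perfect <- simple_ols(x, y)
  expect_equal(perfect$r2, 1, tolerance = 1e-12)

  set.seed(10)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    xx <- rnorm(n); yy <- 1.5 * xx + rnorm(n)
    f <- simple_ols(xx, yy)
    o <- ols_oracle(xx, yy)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$r2, o$r2, tolerance = 1e-10)
    expect_equal(f$p, o$p, tolerance = 1e-10)
    # F = r2/(1-r2) * (n-2) identity
    expect_equal(f$F, f$r2 / (1 - f$r2) * (f$df[2]), tolerance = 1e-9)
    expect_equal(f$df, c(1L, n - 2L))
  }
  expect_error(simple_ols(rep(1, 5), rnorm(5)), "variance")
  expect_error(simple_ols(1:2, 1:2), "at least 3")
})

test_that("cohort summaries use the sample standard deviation", {
  md <- table1_fixture()
  fev1 <- stats::setNames(md$mean_fev1, md$patient_id)
  sm <- cohort_summaries(fev1, md)
  adult <- sm[sm$label == "adult", ]
  paed <- sm[sm$label == "paediatric", ]
  expect_equal(adult$n, 15)
  expect_equal(adult$mean, mean(md$mean_fev1[md$cohort == "adult"]))
  expect_equal(adult$sd, stats::sd(md$mean_fev1[md$cohort == "adult"]))
  expect_equal(paed$mean, mean(md$mean_fev1[md$cohort == "paediatric"]))

  # degenerate groups
  one <- stats::setNames(80, md$patient_id[1])
  expect_warning(s1 <- cohort_summaries(one, md), "single-patient")
  expect_equal(s1$sd, 0)
  expect_true(s1$sd_undefined)
  const <- stats::setNames(rep(5, 15), md$patient_id[md$cohort == "adult"])
  expect_equal(cohort_summaries(const, md)$sd, 0)
  expect_error(cohort_summaries(stats::setNames(1, "ghost"), md), "unknown")
})

test_that("process-lung-function regressions behave algebraically and under the null", {
  md <- table1_fixture()
  adults <- md[md$cohort == "adult", ]
  # when limitation is 0, pct_drift = 100 - pct_homogenizing and the two
  # slopes are exact negatives
  set.seed(15)
  ph <- runif(15, 20, 90)
  freqs <- data.frame(patient_id = adults$patient_id,
                      pct_homogenizing = ph, pct_drift = 100 - ph)
  regs <- process_lungfunction_regressions(freqs, md, cohorts = "adult")
  expect_equal(regs$adult$homogenizing$slope, -regs$adult$drift$slope,
               tolerance = 1e-10)
  expect_equal(regs$adult$homogenizing$r2, regs$adult$drift$r2,
               tolerance = 1e-10)

  # a known negative lung-function -> homogenizing link is recovered
  ph2 <- pmin(pmax(120 - 0.9 * adults$mean_fev1 + rnorm(15, 0, 4), 0), 100)
  freqs2 <- data.frame(patient_id = adults$patient_id,
                       pct_homogenizing = ph2, pct_drift = 100 - ph2)
  regs2 <- process_lungfunction_regressions(freqs2, md, cohorts = "adult")
  expect_lt(regs2$adult$homogenizing$slope, 0)
  expect_lt(regs2$adult$homogenizing$p, 0.05)

  # under independence the test rejects at about the nominal rate
  set.seed(16)
  rejections <- mean(replicate(200, {
    fr <- data.frame(patient_id = adults$patient_id,
                     pct_homogenizing = runif(15, 0, 100))
    fr$pct_drift <- 100 - fr$pct_homogenizing
    process_lungfunction_regressions(fr, md,
                                     cohorts = "adult")$adult$homogenizing$p < 0.05
  }))
  expect_lt(rejections, 0.12)

  expect_error(process_lungfunction_regressions(freqs[1:2, ], md,
                                                cohorts = "adult"),
               "fewer than 3")
})
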