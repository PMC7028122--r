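test_that("Gaussian normative fits use the ML scale and the 0.99 quantile", {
  set.seed(51)
  x <- rnorm(40, 3.3, 0.2)
  fit <- fit_normative(x, "gaussian")
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / length(x))   # n-denominator MLE
  expect_equal(unname(fit$parameters["mean"]), m, tolerance = 1e-12)
  expect_equal(unname(fit$parameters["sd"]), s, tolerance = 1e-12)
  expect_equal(fit$cutoff99, m + qnorm(0.99) * s, tolerance = 1e-12)
  expect_equal(fit$cutoff99, m + 2.3263 * s, tolerance = 1e-4)
  # the fitted CDF puts 99% of the population below the cutoff
  expect_equal(pnorm(fit$cutoff99, m, s), 0.99, tolerance = 1e-9)

  expect_warning(dg <- fit_normative(rep(3, 10), "gaussian"), "degenerate")
  expect_true(dg$degenerate)
  expect_equal(dg$cutoff99, 3)
  expect_error(fit_normative(1:3, "gaussian"), "at least 5")
})

test_that("Gamma normative fits recover known parameters and quantiles", {
  set.seed(52)
  x <- rgamma(2000, shape = 9, scale = 0.2)
  fit <- fit_normative(x, "gamma")
  expect_equal(unname(fit$parameters["shape"]), 9, tolerance = 0.10)
  truth_q99 <- qgamma(0.99, shape = 9, scale = 0.2)
  expect_equal(fit$cutoff99, truth_q99, tolerance = 0.03)
  expect_equal(pgamma(fit$cutoff99, shape = fit$parameters["shape"],
                      scale = fit$parameters["scale"]),
               0.99, tolerance = 1e-9, ignore_attr = TRUE)
  # the cutoff grows with the scale parameter (monotonicity)
  fit2 <- fit_normative(2 * x, "gamma")
  expect_gt(fit2$cutoff99, fit$cutoff99)
  expect_error(fit_normative(c(x[1:10], -1), "gamma"), "positive")
})

test_that("run pooling concatenates and gates on systematic differences", {
  set.seed(53)
  r1 <- rnorm(30, 3.3, 0.2)
  pooled <- combine_runs(r1, r1)
  expect_length(pooled, 60)
  expect_equal(mean(pooled), mean(r1), tolerance = 1e-12)
  expect_equal(attr(pooled, "gate_p"), 1)

  r2 <- r1 + rnorm(30, 0, 0.05)
  pooled2 <- combine_runs(r1, r2)
  expect_equal(mean(pooled2), mean(c(mean(r1), mean(r2))), tolerance = 1e-12)

  expect_warning(combine_runs(r1, r1 + 1), "systematic difference")
  expect_error(combine_runs(r1, r1[-1]), "paired")
})

test_that("pointwise norms join per-location fits to eccentricity", {
  coh <- cached_cohort()
  s1 <- search_rt_matrix(coh, 1); s2 <- search_rt_matrix(coh, 2)
  pooled <- rbind(s1, s2)
  pw <- pointwise_norms(pooled, coh$grid)
  expect_equal(nrow(pw), 62)
  expect_true(all(pw$cutoff99 > pw$median_rt))
  # power-law observers: medians rise with eccentricity
  expect_gt(cor(pw$ecc_deg, pw$median_rt, method = "spearman"), 0.75)

  sub <- refined_subset(coh$grid)
  pw22 <- pointwise_norms(pooled[, as.character(sub)], coh$grid,
                          power_fit = FALSE)
  expect_equal(nrow(pw22), 22)
  expect_setequal(pw22$loc, sub)
  expect_error(pointwise_norms(pooled[1:3, ], coh$grid), "at least 5")
})

test_that("the eccentricity power law round-trips noiseless coefficients", {
  g <- search_grid()
  ecc <- g$cells$ecc_deg[!g$cells$is_center]
  y <- -13.14 * ecc^-0.05 + 13.56
  fit <- fit_power(ecc, y)
  expect_equal(fit$a, -13.14, tolerance = 5e-4)
  expect_equal(fit$b, -0.05, tolerance = 5e-4)
  expect_equal(fit$c, 13.56, tolerance = 5e-4)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-6)

  # centred noise with the exponent pinned at 0 has no explanatory power
  set.seed(54)
  noise <- rnorm(40)
  flat <- fit_power(seq(1, 15, length.out = 40), noise + 2)
  expect_lt(flat$adj_r_squared, 0.5)
  expect_error(fit_power(c(-1, 2, 3, 4), 1:4), "positive")
  expect_error(fit_power(1:3, 1:3), "3 points")
})

test_that("the multi-start fit is at least as good as a random-restart oracle", {
  set.seed(55)
  ecc <- runif(30, 2, 16)
  y <- -5 * ecc^-0.3 + 4 + rnorm(30, 0, 0.05)
  fit <- fit_power(ecc, y)
  # independent 100-start oracle using plain nls
  best <- Inf
  for (k in 1:100) {
    st <- list(a = runif(1, -20, 20), b = runif(1, -1, 1),
               c = runif(1, 0, 8))
    sse <- tryCatch({
      f <- nls(y ~ a * ecc^b + c, start = st,
               control = nls.control(warnOnly = TRUE, maxiter = 100))
      sum(resid(f)^2)
    }, error = function(e) Inf)
    best <- min(best, sse)
  }
  expect_lte(fit$sse, best + 1e-8)
})

test_that("Spearman associations match a rank-then-Pearson oracle", {
  x <- c(3.1, 3.5, 3.2, 3.9, 3.4, 3.0, 3.7)
  expect_equal(spearman_assoc(x, sort(x)[rank(x)])$rho, 1)
  expect_equal(spearman_assoc(x, 10 - x)$rho, -1)

  set.seed(56)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  res <- spearman_assoc(a, b)
  oracle <- cor(rank(a), rank(b))
  expect_equal(res$rho, oracle, tolerance = 1e-12)
  expect_equal(res$n, 30)

  # shuffled scores: small rho, non-significant
  null <- spearman_assoc(a, sample(a))
  expect_lt(abs(null$rho), 0.35)
  expect_gt(null$p, 0.05)
  expect_error(spearman_assoc(1:3, 1:3), "at least 5")
})

test_that("classification against norms uses a strict cutoff", {
  set.seed(57)
  fit <- fit_normative(rnorm(100, 3.3, 0.15), "gaussian")
  expect_equal(classify_score(fit$cutoff99, fit), "within_norms")
  expect_equal(classify_score(fit$cutoff99 + 1e-9, fit), "outside_norms")
  expect_equal(classify_score(c(0, 10), fit),
               c("within_norms", "outside_norms"))

  # ~1% of draws from the fitted population classify outside
  draws <- rnorm(10000, fit$parameters["mean"], fit$parameters["sd"])
  frac <- mean(classify_score(draws, fit) == "outside_norms")
  expect_lt(abs(frac - 0.01), 0.005)   # within half a percentage point
})
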