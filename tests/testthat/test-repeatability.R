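test_that("Bland-Altman statistics match their closed forms and a brute-force loop", {
  # identical runs: zero bias, zero CoR
  x <- c(3.1, 3.4, 3.0, 3.8, 3.3)
  r0 <- bland_altman(x, x, ci = FALSE)
  expect_equal(r0$bias, 0)
  expect_equal(r0$cor95, 0)

  # differences with sample sd exactly 0.1 -> CoR95 = 0.196
  run1 <- c(3.0, 3.2, 3.4)
  run2 <- run1 + c(-0.1, 0, 0.1)    # sd of differences = 0.1
  r <- bland_altman(run1, run2, ci = FALSE)
  expect_equal(r$cor95, 0.196, tolerance = 1e-12)
  expect_equal(r$bias, 0)

  # random paired data vs an independent two-pass computation
  set.seed(41)
  a <- rnorm(20, 3.3, 0.2); b <- a + rnorm(20, 0.02, 0.12)
  res <- bland_altman(a, b, ci = FALSE)
  d <- numeric(20)
  for (i in 1:20) d[i] <- b[i] - a[i]
  m <- sum(d) / 20
  ss <- 0
  for (i in 1:20) ss <- ss + (d[i] - m)^2
  sd_oracle <- sqrt(ss / 19)
  expect_equal(res$bias, m, tolerance = 1e-12)
  expect_equal(res$sd_diff, sd_oracle, tolerance = 1e-12)
  expect_equal(res$cor95, 1.96 * sd_oracle, tolerance = 1e-12)
  expect_equal(res$loa_high - res$loa_low, 2 * res$cor95, tolerance = 1e-12)

  expect_error(bland_altman(1:5, 1:4), "same length")
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("CoR95 is scale-equivariant", {
  set.seed(42)
  a <- rnorm(15, 2, 0.5); b <- a + rnorm(15, 0, 0.2)
  base <- bland_altman(a, b, ci = FALSE)$cor95
  for (k in c(-2, 0.5, 10))
    expect_equal(bland_altman(k * a, k * b, ci = FALSE)$cor95,
                 abs(k) * base, tolerance = 1e-12)
})

test_that("BCa intervals behave like percentile intervals on symmetric data", {
  set.seed(43)
  x <- rnorm(40)
  ci_bca <- bca_ci(x, mean, n_boot = 4000, seed = 10)
  # percentile oracle on the same resampling scheme
  boots <- with(list(n = length(x)), {
    set.seed(10)
    vapply(1:4000, function(b) mean(x[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  ci_pct <- quantile(boots, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(attr(ci_bca, "z0")), 0.1)
  expect_lt(abs(attr(ci_bca, "acceleration")), 0.05)
  expect_equal(unname(ci_bca[1]), ci_pct[1], tolerance = 0.05)
  expect_equal(unname(ci_bca[2]), ci_pct[2], tolerance = 0.05)
})

test_that("BCa intervals are seeded, nested across levels, and handle degeneracy", {
  set.seed(44)
  x <- rgamma(25, 3)
  c1 <- bca_ci(x, mean, n_boot = 1000, seed = 5)
  c2 <- bca_ci(x, mean, n_boot = 1000, seed = 5)
  expect_identical(c1, c2)
  expect_lt(c1[1], mean(x)); expect_gt(c1[2], mean(x))

  c99 <- bca_ci(x, mean, n_boot = 1000, level = 0.99, seed = 5)
  expect_lte(c99[1], c1[1]); expect_gte(c99[2], c1[2])

  expect_warning(ci <- bca_ci(rep(2, 10), mean, n_boot = 100, seed = 1),
                 "degenerate")
  expect_equal(as.numeric(ci), c(2, 2), ignore_attr = TRUE)
})

test_that("BCa agrees with an established implementation on a fixed sample", {
  skip_if_not_installed("boot")
  set.seed(45)
  x <- rexp(30)
  ours <- bca_ci(x, mean, n_boot = 10000, seed = 3)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 10000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  # independent resampling streams: agreement to Monte-Carlo accuracy
  expect_equal(unname(ours[1]), ref[1], tolerance = 0.03)
  expect_equal(unname(ours[2]), ref[2], tolerance = 0.03)
})

test_that("refinement curves recover protocol length trade-offs", {
  # noiseless cohort: flat curve at zero
  tmpl <- observer_model(deterministic = TRUE, rt_noise_sd = 0,
                         face_stability_sd = 0, search_stability_sd = 0)
  coh0 <- generate_cohort(n_search = 5, n_faces = 4, seed = 2,
                          observer_template = tmpl)
  f1 <- faces_estimate_matrix(coh0, 1); f2 <- faces_estimate_matrix(coh0, 2)
  flat <- faces_refinement(f1, f2, c(1, 10, 50))
  expect_equal(flat$cor95, rep(0, 3), tolerance = 1e-12)

  # the full-length point equals Bland-Altman on the final thresholds
  coh <- cached_cohort()
  f1 <- faces_estimate_matrix(coh, 1); f2 <- faces_estimate_matrix(coh, 2)
  curve <- faces_refinement(f1, f2, c(1, 20, 50))
  ok <- is.finite(coh$participants$faces_run1)
  final <- bland_altman(coh$participants$faces_run1[ok],
                        coh$participants$faces_run2[ok], ci = FALSE)$cor95
  expect_equal(curve$cor95[curve$size == 50], final, tolerance = 1e-10)
  expect_error(faces_refinement(f1, f2, c(0, 10)), "1..n_trials")
})

test_that("search refinement recomputes medians per subset and validates the ladder", {
  coh <- cached_cohort()
  s1 <- search_rt_matrix(coh, 1); s2 <- search_rt_matrix(coh, 2)
  g <- coh$grid
  ladder <- search_ladder(g)
  curve <- search_refinement(s1, s2, ladder)
  expect_equal(curve$size, c(4, 12, 22, 62))
  expect_true(all(curve$cor95 >= 0))

  # the all-62 rung reduces to Bland-Altman on the overall medians
  m1 <- apply(s1, 1, median); m2 <- apply(s2, 1, median)
  expect_equal(curve$cor95[curve$size == 62],
               bland_altman(m1, m2, ci = FALSE)$cor95, tolerance = 1e-10)

  expect_error(search_refinement(s1, s2, list(c(1, 1, 2))), "duplicate")
  expect_error(search_refinement(s1, s2, list(c(9999))), "missing")
})
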