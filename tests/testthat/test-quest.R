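test_that("the psychometric function has the 4AFC Weibull form", {
  p0 <- psychometric_params(lapse_rate = 0)
  # guessing floor at zero dissimilarity
  expect_equal(prob_correct(0, 3.5, p0), 0.25)
  # asymptote without lapses
  expect_gt(prob_correct(1000, 3.5, p0), 1 - 1e-6)
  # at threshold: gamma + (1 - gamma) * (1 - e^-1)
  expect_equal(prob_correct(3.5, 3.5, p0), 0.25 + 0.75 * (1 - exp(-1)),
               tolerance = 1e-12)
  # monotone non-decreasing and bounded with lapses
  p <- psychometric_params()
  v <- vapply(seq(0, 10, by = 0.1), prob_correct, numeric(1),
              true_threshold = 3.2, params = p)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0.25 & v <= 1 - p$lapse_rate))
  expect_error(prob_correct(1, -3, p), "positive")
})

test_that("psychometric parameters are validated", {
  expect_error(psychometric_params(guess_rate = 1.2), "guess_rate")
  expect_error(psychometric_params(slope = 0), "slope")
  expect_error(psychometric_params(lapse_rate = 0.6), "lapse_rate")
  expect_error(psychometric_params(threshold_criterion = 0.1),
               "threshold_criterion")
})

test_that("the posterior update equals a naive per-gridpoint Bayes loop", {
  set.seed(11)
  for (rep in 1:5) {
    st <- quest_state(domain = seq(0.5, 8, length.out = 61))
    level <- runif(1, 1, 6)
    correct <- runif(1) < 0.7
    new <- quest_update(st, level, correct)

    # independent loop oracle
    post <- numeric(length(st$domain))
    for (i in seq_along(st$domain)) {
      pi <- prob_correct(level, st$domain[i], st$params)
      li <- if (correct) pi else 1 - pi
      post[i] <- st$posterior[i] * li
    }
    post <- post / sum(post)
    expect_equal(new$posterior, post, tolerance = 1e-12)
    expect_equal(sum(new$posterior), 1, tolerance = 1e-9)
  }
})

test_that("likelihood updates commute and responses move the estimate the right way", {
  st <- quest_state()
  a <- quest_update(quest_update(st, 3.0, TRUE), 4.0, FALSE)
  b <- quest_update(quest_update(st, 4.0, FALSE), 3.0, TRUE)
  expect_equal(a$posterior, b$posterior, tolerance = 1e-12)

  # a correct response never increases the posterior-mean estimate
  before <- threshold_estimate(st)
  expect_lte(threshold_estimate(quest_update(st, 3.5, TRUE)), before)
  expect_gte(threshold_estimate(quest_update(st, 3.5, FALSE)), before)
})

test_that("the threshold estimate is the posterior mean", {
  # uniform posterior on a symmetric domain -> midpoint
  st <- quest_state(domain = seq(2, 6, length.out = 41),
                    prior = rep(1, 41))
  expect_equal(threshold_estimate(st), 4, tolerance = 1e-12)
  expect_equal(next_level(st), 4, tolerance = 1e-12)

  # arbitrary posterior -> explicit weighted-sum loop
  set.seed(12)
  st2 <- quest_state(domain = seq(1, 7, length.out = 31),
                     prior = runif(31))
  s <- 0
  for (i in seq_along(st2$domain))
    s <- s + st2$domain[i] * st2$posterior[i]
  expect_equal(threshold_estimate(st2), s, tolerance = 1e-12)

  # no trials -> the prior mean
  st3 <- quest_state()
  expect_equal(threshold_estimate(st3),
               sum(st3$domain * st3$posterior), tolerance = 1e-12)
  expect_equal(nrow(st3$history), 0L)
})

test_that("stimulus placement stays inside the domain over random trial runs", {
  set.seed(13)
  for (rep in 1:10) {
    st <- quest_state()
    lo <- min(st$domain); hi <- max(st$domain)
    for (t in 1:30) {
      lev <- next_level(st)
      expect_gte(lev, lo); expect_lte(lev, hi)
      st <- quest_update(st, lev, runif(1) < 0.6)
      expect_false(is.na(threshold_estimate(st)))
    }
    expect_equal(sum(st$posterior), 1, tolerance = 1e-9)
  }
})

test_that("a run of correct responses drives the staircase down", {
  st <- quest_state()
  prior_mean <- threshold_estimate(st)
  for (t in 1:10) st <- quest_update(st, next_level(st), TRUE)
  expect_lt(next_level(st), prior_mean)
})

test_that("face sessions are reproducible and converge for a noise-free observer", {
  obs <- observer_model(face_threshold = 3.4)
  s1 <- run_face_session(obs, 50, seed = 7)
  s2 <- run_face_session(obs, 50, seed = 7)
  expect_identical(s1$trials, s2$trials)
  expect_equal(s1$final_threshold,
               s1$threshold_by_trial[s1$n_trials])
  expect_length(s1$threshold_by_trial, 50)
  expect_false(anyNA(s1$threshold_by_trial))
  dom <- range(s1$state$domain)
  expect_true(all(s1$threshold_by_trial >= dom[1] &
                    s1$threshold_by_trial <= dom[2]))

  # deterministic oracle observer: correct iff level >= truth
  det <- observer_model(face_threshold = 3.4, deterministic = TRUE)
  fs <- run_face_session(det, 50, seed = 1)
  grain <- diff(fs$state$domain[1:2])
  expect_lt(abs(fs$final_threshold - 3.4), grain)
})

test_that("threshold recovery is consistent: bias small at 50 trials and shrinking", {
  obs <- observer_model(face_threshold = 3.4)
  est50 <- vapply(1:120, function(s)
    run_face_session(obs, 50, seed = 1000 + s)$final_threshold, numeric(1))
  expect_lt(abs(median(est50) - 3.4), 0.1)

  # truncating the same sessions to 10 trials must be noisier
  est10 <- vapply(1:120, function(s)
    run_face_session(obs, 50, seed = 1000 + s)$threshold_by_trial[10],
    numeric(1))
  expect_gt(sd(est10), 0.9 * sd(est50))
})
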