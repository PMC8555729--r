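test_that("prior profiles have the intended shape and calibrated means", {
  contested <- sample_priors("contested", 10000, seed = 11)
  less <- sample_priors("less_contested", 10000, seed = 12)

  expect_true(all(contested %in% -8:8))
  expect_true(all(less %in% -8:8))
  # less-contested: neutral-heavy; contested: bimodal with strong beliefs
  expect_gte(mean(less == 0), 0.25)
  expect_lte(mean(contested == 0), 0.10)
  expect_gte(mean(abs(contested) >= 4), 0.50)
  # calibration targets for the two study topics
  expect_lt(abs(mean(contested) - 4.36), 1.0)
  expect_lt(abs(mean(less) - 2.59), 1.0)

  expect_length(sample_priors("contested", 1, seed = 1), 1)
  expect_error(sample_priors("nope", 10), "unknown topic profile")
})

test_that("rating model follows the linear prior-influence rule", {
  noise_free <- function(...) sim_config(10, "contested", sigma_rating = 0, ...)
  # no prior influence, no noise: rating is the signed evidence strength
  expect_equal(as.integer(simulate_rating(0L, 1, noise_free(alpha_gen = 4))), 4L)
  # prior pulls the rating: 4 + 0.25 * 8 = 6
  expect_equal(as.integer(simulate_rating(8L, 1,
    noise_free(alpha_gen = 4, gamma_gen = 0.25))), 6L)
  # clamping to the scale: 4 + 1.5 * (-8) = -8
  expect_equal(as.integer(simulate_rating(-8L, 1,
    noise_free(alpha_gen = 4, gamma_gen = 1.5))), -8L)
  expect_error(simulate_rating(9L, 1, noise_free()), "out of range")
})

test_that("confidence readout bins distance from criterion", {
  thr <- c(0.6, 1.2, 1.8, 2.4, 3.0)
  # noise-free: lowest bin -> 50, above top threshold -> 100
  expect_equal(simulate_confidence(0.1, 0, 0, thr), 50L)
  expect_equal(simulate_confidence(-0.1, 0, 0, thr), 50L)
  expect_equal(simulate_confidence(5, 0, 0, thr), 100L)
  expect_equal(simulate_confidence(2.0, 0, 0, thr), 80L)
  # perfectly ordered by distance when sigma_meta = 0
  x <- seq(-4, 4, by = 0.25)
  conf <- simulate_confidence(x, 0, 0, thr)
  expect_true(all(diff(conf[order(abs(x))]) >= 0))
  expect_error(simulate_confidence(1, 0, 0, c(1, 2, 3, 3, 4)),
               "increasing")
  expect_error(simulate_confidence(1, 0, -1, thr), "sigma_meta")
})

test_that("posterior updating is a convex prior/evidence combination", {
  det <- function(...) sim_config(10, "contested", sigma_update = 0, ...)
  # w = 1: pure prior weighting
  cfg <- det(w_prior_base = 1, w_meta_coupling = 0)
  expect_equal(simulate_posterior(5L, c(-3, 3), cfg, 1), 5L)
  # w = 0 with balanced ratings: neutral posterior
  cfg <- det(w_prior_base = 0, w_meta_coupling = 0)
  expect_equal(simulate_posterior(7L, c(-4, 4), cfg, 0), 0L)
  # 0.9 * 6 + 0.1 * 6 = 6
  cfg <- det(w_prior_base = 0.9, w_meta_coupling = 0, k_evidence = 1)
  expect_equal(simulate_posterior(6L, c(6, 6), cfg, 0), 6L)
  expect_error(simulate_posterior(6L, numeric(0), cfg, 0), "nonempty")
})

test_that("generated datasets have the right shape and are seed-deterministic", {
  cfg <- sim_config(10, "less_contested", n_endorse = 4, n_reject = 4, seed = 5)
  dat <- generate_dataset(cfg)
  expect_equal(nrow(dat$participants), 10)
  expect_equal(nrow(dat$trials), 80)
  expect_equal(sum(dat$trials$true_direction == 1), 40)
  expect_true(all(dat$trials$rating %in% -8:8))
  expect_true(all(dat$trials$confidence %in% confidence_levels()))
  expect_true(all(dat$participants$posterior %in% -8:8))

  again <- generate_dataset(sim_config(10, "less_contested", n_endorse = 4,
                                       n_reject = 4, seed = 5))
  expect_identical(dat$participants, again$participants)
  expect_identical(dat$trials, again$trials)
  # the generator does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_dataset(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("stronger meta-coupling never lowers polarization among noisy participants", {
  gpol <- vapply(c(0, 0.1, 0.2, 0.3, 0.4), function(wc) {
    cfg <- sim_config(1500, "contested", w_meta_coupling = wc,
                      sigma_meta = 1, sigma_meta_spread = 1, seed = 99)
    dat <- generate_dataset(cfg)
    hi <- dat$participants[dat$participants$true_sigma_meta >
                             median(dat$participants$true_sigma_meta), ]
    proportion_polarizers(hi)$g_pol
  }, numeric(1))
  expect_true(all(diff(gpol) >= 0))
})

test_that("the regression recovers the generative prior-influence slope", {
  # scaled-down replicate check; the acceptance suite runs the full grid
  hits <- vapply(1:25, function(s) {
    cfg <- sim_config(500, "less_contested", alpha_gen = 2, gamma_gen = 0.15,
                      gamma_meta_coupling = 0, sigma_rating = 2,
                      seed = 3000 + s)
    dat <- generate_dataset(cfg)
    avg <- average_interpretation(dat$trials, 1)
    m <- merge(avg, dat$participants[, c("participant_id", "prior")],
               by = "participant_id")
    f <- ols_fit(m$prior, m$mean_rating)
    abs(f$gamma - 0.15) <= 3 * f$se_gamma
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("with perfect metacognition the estimator recovers the generative discriminability", {
  # 400 trials/participant, sigma_meta = 0: estimated meta-d' matches the
  # generative latent separation 2 * alpha / sigma_rating. Binarized d'
  # itself is attenuated by the zero-ratings-are-incorrect coding (by
  # about 1/sigma_rating), so meta-d' sits above d' on this path.
  cfg <- sim_config(12, "less_contested", n_endorse = 200, n_reject = 200,
                    alpha_gen = 4, gamma_gen = 0, gamma_meta_coupling = 0,
                    sigma_rating = 4, sigma_meta = 0, sigma_meta_spread = 0,
                    t2_thresholds = seq(0.8, 4, by = 0.8), seed = 31)
  dat <- generate_dataset(cfg)
  md <- estimate_metad_per_participant(dat)
  latent_d <- 2 * cfg$alpha_gen / cfg$sigma_rating
  expect_lt(abs(mean(md, na.rm = TRUE) - latent_d), 0.15)
})

test_that("dataset CSV round-trips through the writer", {
  dir <- withr::local_tempdir()
  dat <- generate_dataset(sim_config(6, "contested", seed = 2))
  paths <- write_dataset(dat, dir)
  expect_true(all(file.exists(paths)))
  back <- read_study_csv(paths[2], paths[1])
  expect_equal(back$trials$rating, dat$trials$rating)
  expect_equal(back$participants$prior, dat$participants$prior)
  cfg <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(cfg$seed, 2)
})
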