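# Shared simulation helpers for the test suite.

# Binary-response SDT world that matches the meta-d' model exactly:
# evidence x ~ N(+-d/2, 1), response = sign(x) (never zero), confidence
# from the package's noisy-readout model on |x|.
sim_binary_sdt <- function(n, d, sigma_meta, thr = c(0.3, 0.6, 1.0, 1.5, 2.1),
                           seed = 1) {
  withr::with_seed(seed, {
    stim <- rep(c(1L, -1L), length.out = n)
    x <- rnorm(n, stim * d / 2, 1)
    list(rating = ifelse(x > 0, 2L, -2L), direction = stim,
         confidence = simulate_confidence(x, 0, sigma_meta, thr))
  })
}

fit_metad_trials <- function(trials) {
  est <- dprime(sdt_counts(trials$rating, trials$direction))
  fit <- metad_mle(tally_confidence(trials$rating, trials$direction,
                                    trials$confidence),
                   est$d_prime, est$criterion_c)
  list(d_prime = est$d_prime, criterion_c = est$criterion_c, fit = fit)
}

# Per-participant meta-d' estimates for a generated dataset; NA where the
# type-1 fit is degenerate or the MLE does not converge.
estimate_metad_per_participant <- function(dataset) {
  pp <- dataset$participants
  by_participant <- split(dataset$trials, dataset$trials$participant_id)
  md <- rep(NA_real_, nrow(pp))
  for (i in seq_len(nrow(pp))) {
    ti <- by_participant[[pp$participant_id[i]]]
    est <- dprime(sdt_counts(ti$rating, ti$true_direction))
    if (est$d_prime == 0) next
    fit <- metad_mle(tally_confidence(ti$rating, ti$true_direction,
                                      ti$confidence),
                     est$d_prime, est$criterion_c)
    if (fit$converged) md[i] <- fit$meta_d
  }
  md
}

# The frozen validation configuration for split-recovery checks: a
# population with wide metacognitive heterogeneity whose interpretation
# bias and prior weighting both couple to metacognitive noise.
headline_config <- function(seed, n = 500) {
  sim_config(n_participants = n, topic_profile = "contested",
             n_endorse = 20, n_reject = 20,
             sigma_meta = 1, sigma_meta_spread = 1,
             w_prior_base = 0.2, w_meta_coupling = 0.35,
             gamma_meta_coupling = 0.15, seed = seed)
}

# One replicate of the headline analysis: gamma (endorsing direction) and
# polarizer proportion in the low and high estimated-meta-d' splits.
headline_replicate <- function(seed, n = 500) {
  dat <- generate_dataset(headline_config(seed, n))
  pp <- dat$participants
  md <- estimate_metad_per_participant(dat)
  sp <- mean_split(md)
  out <- list()
  for (side in c("low", "high")) {
    ids <- pp$participant_id[!is.na(sp$assignment) & sp$assignment == side]
    avg <- average_interpretation(
      dat$trials[dat$trials$participant_id %in% ids, ], 1)
    m <- merge(avg, pp[, c("participant_id", "prior")], by = "participant_id")
    out[[paste0("gamma_", side)]] <- ols_fit(m$prior, m$mean_rating)$gamma
    out[[paste0("gpol_", side)]] <-
      proportion_polarizers(pp[pp$participant_id %in% ids, ])$g_pol
  }
  out
}

# Hand-written three-participant study whose statistics are all
# hand-checkable (used by the pipeline fixture test).
tiny_fixture <- function() {
  participants <- data.frame(
    participant_id = c("a", "b", "c"), topic = "t",
    prior = c(2L, 0L, -4L), posterior = c(5L, 0L, -2L),
    stringsAsFactors = FALSE
  )
  trials <- data.frame(
    participant_id = rep(c("a", "b", "c"), each = 4),
    topic = "t",
    text_id = rep(c("e1", "e2", "r1", "r2"), 3),
    true_direction = rep(c(1L, 1L, -1L, -1L), 3),
    rating = c(4L, 6L, -3L, -5L,
               1L, 3L, -1L, -3L,
               2L, 2L, -2L, -4L),
    confidence = c(90L, 100L, 80L, 90L,
                   60L, 70L, 50L, 60L,
                   70L, 80L, 70L, 90L),
    stringsAsFactors = FALSE
  )
  list(trials = trials, participants = participants)
}
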