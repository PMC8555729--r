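## Synthetic participant generator: priors, ratings, confidence, posteriors.

# Discretized truncated normal on the integer belief scale -8..8. End bins
# absorb the tails so the pmf always sums to 1.
discrete_normal_pmf <- function(mu, sd) {
  v <- -8:8
  p <- pnorm(v + 0.5, mu, sd) - pnorm(v - 0.5, mu, sd)
  p[1] <- pnorm(-7.5, mu, sd)
  p[17] <- 1 - pnorm(7.5, mu, sd)
  p / sum(p)
}

# Topic-profile pmfs over the 17-point prior-belief scale. Calibrated so the
# profile means land near the reference means 4.36 (contested) and 2.59
# (less contested), with the contested profile bimodal and the
# less-contested profile neutral-heavy.
prior_profile_pmf <- function(profile) {
  v <- -8:8
  switch(profile,
    contested = 0.80 * discrete_normal_pmf(6.5, 2.0) +
      0.20 * discrete_normal_pmf(-3.5, 2.5),
    less_contested = 0.25 * as.numeric(v == 0) +
      0.75 * discrete_normal_pmf(3.5, 3.0),
    stop("unknown topic profile: ", profile, call. = FALSE)
  )
}

#' Draw integer prior beliefs from a topic profile
#'
#' Samples prior beliefs on the integer 17-point scale (-8..8) from one of
#' two calibrated mixture profiles: `"contested"` is bimodal with most mass
#' at strong beliefs (population mean ~4.3, < 2% exactly neutral), while
#' `"less_contested"` places a quarter of its mass exactly at 0 with the
#' rest spread over moderate positive beliefs (population mean ~2.6).
#'
#' @param profile `"contested"` or `"less_contested"`.
#' @param n number of draws (>= 1).
#' @param seed optional integer seed; if supplied the draw is made under a
#'   local RNG state and is reproducible without touching the caller's RNG.
#' @return integer vector of length `n`, values in -8..8.
#' @examples
#' mean(sample_priors("contested", 1000, seed = 1))
#' @export
sample_priors <- function(profile, n, seed = NULL) {
  if (!profile %in% c("contested", "less_contested"))
    stop("unknown topic profile: ", profile, call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  pmf <- prior_profile_pmf(profile)
  draw <- function() sample(-8:8, size = n, replace = TRUE, prob = pmf)
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

clamp_belief <- function(x) pmin(8L, pmax(-8L, as.integer(round(x))))

#' Simulate an interpretation rating
#'
#' Generates a 17-point interpretation rating from the linear
#' prior-influence model: the latent interpretation is
#' `direction * alpha_gen + gamma * prior + noise`, then rounded and clamped
#' to the integer scale -8..8. With zero noise and zero prior influence the
#' rating is simply the (signed) evidence strength.
#'
#' @param prior integer prior belief(s) in -8..8.
#' @param true_direction +1 for an endorsing text, -1 for a rejecting text.
#' @param config a [sim_config()]; `alpha_gen`, `gamma_gen` and
#'   `sigma_rating` are used.
#' @param gamma optional per-participant slope overriding
#'   `config$gamma_gen` (the generator uses this to couple interpretation
#'   bias to metacognitive noise).
#' @return integer rating(s) in -8..8. The pre-rounding latent value is
#'   attached as attribute `"latent"` (the confidence model reads it).
#' @export
simulate_rating <- function(prior, true_direction, config, gamma = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (any(prior < -8 | prior > 8)) stop("prior out of range [-8, 8]", call. = FALSE)
  if (any(!true_direction %in% c(-1, 1)))
    stop("true_direction must be +1 or -1", call. = FALSE)
  if (is.null(gamma)) gamma <- config$gamma_gen
  n <- max(length(prior), length(true_direction))
  latent <- true_direction * config$alpha_gen + gamma * prior +
    rnorm(n, 0, config$sigma_rating)
  structure(clamp_belief(latent), latent = latent)
}

#' Simulate a confidence level from a noisy evidence readout
#'
#' The metacognitive readout is `y = evidence + noise`, with noise SD
#' `sigma_meta`; confidence is the bin of `|y - criterion|` under the five
#' thresholds, mapped to the six levels 50, 60, ..., 100. With
#' `sigma_meta = 0` confidence is a deterministic, monotone function of the
#' distance of the evidence from the criterion; as `sigma_meta` grows the
#' readout decouples from the evidence and estimated meta-d' falls toward 0.
#'
#' @param evidence_sample numeric latent evidence value(s).
#' @param decision_criterion the type-1 criterion (0 on the rating scale).
#' @param sigma_meta metacognitive readout noise SD (>= 0).
#' @param t2_thresholds increasing non-negative vector of 5 thresholds.
#' @return integer confidence level(s) in \{50, 60, 70, 80, 90, 100\}.
#' @export
simulate_confidence <- function(evidence_sample, decision_criterion, sigma_meta,
                                t2_thresholds) {
  check_t2_thresholds(t2_thresholds)
  if (sigma_meta < 0) stop("sigma_meta must be >= 0", call. = FALSE)
  y <- evidence_sample + rnorm(length(evidence_sample), 0, sigma_meta)
  bin <- findInterval(abs(y - decision_criterion), t2_thresholds)
  confidence_levels()[bin + 1L]
}

#' @rdname simulate_confidence
#' @export
confidence_levels <- function() as.integer(seq(50L, 100L, by = 10L))

#' Simulate a posterior belief
#'
#' Updates a prior belief toward the evidence with a convex combination
#' whose prior weight grows with the participant's metacognitive noise:
#' `w = min(1, w_prior_base + w_meta_coupling * participant_sigma_meta)`,
#' `posterior = clamp(round(w * prior + (1 - w) * k * mean(ratings) + eta))`,
#' where `eta` is posterior-elicitation noise with SD `config$sigma_update`
#' (set it to 0 for the deterministic rule). Larger metacognitive noise
#' never decreases the prior weight, so less metacognitively sensitive
#' participants update more in the direction of their prior.
#'
#' @param prior integer prior belief in -8..8.
#' @param ratings the participant's interpretation ratings (nonempty).
#' @param config a [sim_config()].
#' @param participant_sigma_meta the participant's metacognitive noise SD.
#' @return integer posterior belief in -8..8.
#' @export
simulate_posterior <- function(prior, ratings, config, participant_sigma_meta) {
  stopifnot(inherits(config, "sim_config"))
  if (length(ratings) == 0) stop("ratings must be nonempty", call. = FALSE)
  w <- min(1, config$w_prior_base + config$w_meta_coupling * participant_sigma_meta)
  eta <- if (config$sigma_update > 0) rnorm(1, 0, config$sigma_update) else 0
  clamp_belief(w * prior + (1 - w) * config$k_evidence * mean(ratings) + eta)
}

#' Generate a full synthetic study
#'
#' Simulates `n_participants` participants for one topic: priors from the
#' topic profile, per-participant metacognitive noise and prior-influence
#' slope, one rating + confidence pair per text, and a posterior belief.
#' Output is fully reproducible from `config$seed` and the caller's RNG
#' state is left untouched.
#'
#' @param config a [sim_config()].
#' @return a list with class `"sim_dataset"`:
#' \describe{
#'   \item{participants}{data frame with `participant_id`, `topic`,
#'     `prior`, `posterior` plus ground-truth columns `true_sigma_meta`,
#'     `true_gamma`, `true_w` used by recovery tests.}
#'   \item{trials}{data frame with `participant_id`, `topic`, `text_id`,
#'     `true_direction` (+1/-1), `rating`, `confidence`.}
#'   \item{config}{the generating config.}
#' }
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n <- cfg$n_participants
  topic <- cfg$topic_profile
  n_text <- cfg$n_endorse + cfg$n_reject
  directions <- c(rep(1L, cfg$n_endorse), rep(-1L, cfg$n_reject))
  text_ids <- sprintf("%s_text%02d", ifelse(directions == 1L, "end", "rej"),
                      seq_len(n_text))

  priors <- sample(-8:8, n, replace = TRUE, prob = prior_profile_pmf(topic))
  sigma_meta_i <- pmax(0, rnorm(n, cfg$sigma_meta, cfg$sigma_meta_spread))
  gamma_i <- pmax(0, cfg$gamma_gen + cfg$gamma_meta_coupling * sigma_meta_i)
  w_i <- pmin(1, cfg$w_prior_base + cfg$w_meta_coupling * sigma_meta_i)

  ids <- sprintf("p%04d", seq_len(n))
  posterior <- integer(n)
  trial_list <- vector("list", n)
  for (i in seq_len(n)) {
    rating <- simulate_rating(rep(priors[i], n_text), directions, cfg,
                              gamma = gamma_i[i])
    latent <- attr(rating, "latent")
    confidence <- simulate_confidence(latent, 0, sigma_meta_i[i],
                                      cfg$t2_thresholds)
    posterior[i] <- simulate_posterior(priors[i], as.integer(rating), cfg,
                                       sigma_meta_i[i])
    trial_list[[i]] <- data.frame(
      participant_id = ids[i], topic = topic, text_id = text_ids,
      true_direction = directions, rating = as.integer(rating),
      confidence = confidence, stringsAsFactors = FALSE
    )
  }

  participants <- data.frame(
    participant_id = ids, topic = topic, prior = priors, posterior = posterior,
    true_sigma_meta = sigma_meta_i, true_gamma = gamma_i, true_w = w_i,
    stringsAsFactors = FALSE
  )
  structure(list(participants = participants,
                 trials = do.call(rbind, trial_list),
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic study: %d participants ('%s'), %d trials, seed %d\n",
              nrow(x$participants), x$config$topic_profile, nrow(x$trials),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes `participants.csv`, `trials.csv` and `config.json` into `dir`.
#' Ground-truth columns are included in the participant table; the trial
#' table has exactly the analysis columns (`participant_id`, `topic`,
#' `text_id`, `true_direction`, `rating`, `confidence`).
#'
#' @param dataset a `"sim_dataset"` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("participants.csv", "trials.csv", "config.json"))
  utils::write.csv(dataset$participants, paths[1], row.names = FALSE)
  utils::write.csv(dataset$trials, paths[2], row.names = FALSE)
  jsonlite::write_json(unclass(dataset$config), paths[3],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
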