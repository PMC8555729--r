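#' Configuration for the synthetic participant generator
#'
#' Bundles every tunable of the generative model behind [generate_dataset()]
#' into a validated object, so that a dataset is fully determined by one
#' config (including its seed).
#'
#' The generative model is deliberately simple. Each simulated participant
#' holds an integer prior belief on the 17-point scale (drawn from a
#' topic-profile mixture, see [sample_priors()]), reads `n_endorse` texts
#' endorsing the proposition and `n_reject` texts rejecting it, and rates
#' each text on the same 17-point scale:
#' \deqn{rating = clamp(round(direction \cdot \alpha_{gen} +
#'   \gamma_i \cdot prior + \epsilon), -8, 8), \quad
#'   \epsilon \sim N(0, \sigma_{rating}^2)}
#' where \eqn{\gamma_i = \gamma_{gen} + \gamma_{meta} \sigma_{meta,i}} couples
#' belief-congruent distortion to the participant's metacognitive noise.
#' Confidence is a noisy readout of the distance of the latent evidence from
#' the decision criterion (see [simulate_confidence()]), and the posterior
#' belief is a prior/evidence convex combination whose prior weight grows
#' with metacognitive noise (see [simulate_posterior()]).
#'
#' @param n_participants number of simulated participants.
#' @param topic_profile `"contested"` (strong, bimodal priors; think climate
#'   change) or `"less_contested"` (neutral-heavy priors; think
#'   nanotechnology).
#' @param n_endorse,n_reject number of endorsing / rejecting texts per
#'   participant. Defaults follow the profile: 2+2 for `"contested"`,
#'   4+4 for `"less_contested"`.
#' @param alpha_gen latent evidence strength, in rating units; the generative
#'   analogue of the regression intercept (average interpretation).
#' @param gamma_gen baseline prior-influence coefficient (dimensionless);
#'   generative analogue of the regression slope.
#' @param gamma_meta_coupling increase of the per-participant prior-influence
#'   slope per unit of metacognitive noise. Zero decouples interpretation
#'   bias from metacognition (used by slope-recovery checks).
#' @param sigma_rating SD of interpretation noise, rating units.
#' @param sigma_meta population mean of the per-participant metacognitive
#'   readout noise SD (evidence units, >= 0). Zero means confidence tracks
#'   the evidence perfectly.
#' @param sigma_meta_spread SD of the per-participant draw around
#'   `sigma_meta` (truncated at zero). Zero gives a homogeneous population.
#' @param w_prior_base baseline weight of the prior in belief updating,
#'   in `[0, 1]`.
#' @param w_meta_coupling increase of the prior weight per unit of
#'   metacognitive noise, in `[0, 1]`.
#' @param k_evidence scale mapping the mean interpretation rating to belief
#'   units in the updating rule.
#' @param sigma_update SD of posterior-elicitation noise on the belief scale.
#'   Re-asking a belief is a noisy measurement; without this term the
#'   rounded convex-combination rule can virtually never produce a posterior
#'   more extreme than the prior. Set to 0 for the deterministic rule.
#' @param t2_thresholds increasing, non-negative vector of 5 thresholds
#'   binning `|evidence - criterion|` into the six confidence levels
#'   50..100. Default: equal-width bins over `[0, 3]` evidence units.
#' @param seed integer seed; identical configs reproduce identical datasets
#'   bit for bit.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @seealso [generate_dataset()], [sample_priors()]
#' @examples
#' cfg <- sim_config(n_participants = 20, seed = 42)
#' dat <- generate_dataset(cfg)
#' head(dat$trials)
#' @export
sim_config <- function(n_participants = 354,
                       topic_profile = c("contested", "less_contested"),
                       n_endorse = NULL,
                       n_reject = NULL,
                       alpha_gen = 4,
                       gamma_gen = 0.2,
                       gamma_meta_coupling = 0.1,
                       sigma_rating = 3,
                       sigma_meta = 0.75,
                       sigma_meta_spread = 0.75,
                       w_prior_base = 0.3,
                       w_meta_coupling = 0.2,
                       k_evidence = 1,
                       sigma_update = 1.5,
                       t2_thresholds = seq(0.6, 3, by = 0.6),
                       seed = 1L) {
  topic_profile <- match.arg(topic_profile)
  if (is.null(n_endorse)) n_endorse <- if (topic_profile == "contested") 2L else 4L
  if (is.null(n_reject)) n_reject <- if (topic_profile == "contested") 2L else 4L

  cfg <- list(
    n_participants = as.integer(n_participants),
    topic_profile = topic_profile,
    n_endorse = as.integer(n_endorse),
    n_reject = as.integer(n_reject),
    alpha_gen = alpha_gen,
    gamma_gen = gamma_gen,
    gamma_meta_coupling = gamma_meta_coupling,
    sigma_rating = sigma_rating,
    sigma_meta = sigma_meta,
    sigma_meta_spread = sigma_meta_spread,
    w_prior_base = w_prior_base,
    w_meta_coupling = w_meta_coupling,
    k_evidence = k_evidence,
    sigma_update = sigma_update,
    t2_thresholds = t2_thresholds,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  if (cfg$n_endorse < 1L || cfg$n_reject < 1L)
    stop("n_endorse and n_reject must both be >= 1", call. = FALSE)
  sds <- c(cfg$sigma_rating, cfg$sigma_meta, cfg$sigma_meta_spread, cfg$sigma_update)
  if (any(sds < 0)) stop("all noise SDs must be >= 0", call. = FALSE)
  ws <- c(cfg$w_prior_base, cfg$w_meta_coupling)
  if (any(ws < 0 | ws > 1)) stop("updating weights must lie in [0, 1]", call. = FALSE)
  check_t2_thresholds(cfg$t2_thresholds)
  invisible(cfg)
}

check_t2_thresholds <- function(t2) {
  if (length(t2) != 5L || any(!is.finite(t2)) || any(t2 < 0) ||
      any(diff(t2) <= 0)) {
    stop("t2_thresholds must be 5 non-negative, strictly increasing values",
         call. = FALSE)
  }
  invisible(t2)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration (sim_config)\n")
  cat(sprintf("  %d participants, profile '%s', %d endorsing + %d rejecting texts\n",
              x$n_participants, x$topic_profile, x$n_endorse, x$n_reject))
  cat(sprintf("  rating model: alpha = %.3g, gamma = %.3g (+%.3g per unit meta noise), sigma = %.3g\n",
              x$alpha_gen, x$gamma_gen, x$gamma_meta_coupling, x$sigma_rating))
  cat(sprintf("  meta noise: mean %.3g, spread %.3g; thresholds %s\n",
              x$sigma_meta, x$sigma_meta_spread,
              paste(format(x$t2_thresholds), collapse = ", ")))
  cat(sprintf("  updating: w = min(1, %.3g + %.3g * sigma_meta_i), k = %.3g, update noise %.3g\n",
              x$w_prior_base, x$w_meta_coupling, x$k_evidence, x$sigma_update))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
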