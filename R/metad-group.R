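## Group-level meta-d': pooled fit or an empirical-Bayes normal hierarchy
## on log M-ratio. With very few trials per participant the individual MLEs
## are unstable; pooling or shrinkage is then the reliable route to a group
## estimate.

#' Group meta-d' across participants
#'
#' Two estimators are available:
#' \describe{
#'   \item{`"pooled_mle"`}{sums the confidence counts and the type-1 counts
#'     over participants and fits a single meta-d' (one "supersubject").}
#'   \item{`"hierarchical"`}{fits each participant by ML, then places a
#'     normal population distribution over log M-ratio and returns
#'     empirical-Bayes posterior means. Hyperparameters (population mean
#'     `mu`, SD `tau`) are estimated by marginal maximum likelihood from
#'     the per-participant estimates and their delta-method standard
#'     errors; participants whose individual fit is unusable are assigned
#'     the population mean. M-ratios are floored at 0.01 before taking
#'     logs, so at-or-below-chance metacognition shrinks hard toward the
#'     population.}
#' }
#' Both estimators are deterministic given the data.
#'
#' @param confidence_counts list of `"confidence_counts"`, one per
#'   participant (>= 2).
#' @param sdt_counts list of `"sdt_counts"`, parallel to
#'   `confidence_counts`.
#' @param method `"pooled_mle"` or `"hierarchical"`.
#' @return for `"pooled_mle"`, a `"metad_fit"`. For `"hierarchical"`, an
#'   object of class `"metad_group"`: `mu_log_mratio`, `tau_log_mratio`,
#'   `group_m_ratio` (= exp(mu)), `group_meta_d` (= exp(mu) * mean d'),
#'   `participants` (data frame of raw and shrunk estimates), `n_used`.
#' @export
metad_group <- function(confidence_counts, sdt_counts,
                        method = c("pooled_mle", "hierarchical")) {
  method <- match.arg(method)
  n <- length(confidence_counts)
  if (n < 2) stop("group estimation needs at least 2 participants", call. = FALSE)
  if (length(sdt_counts) != n)
    stop("confidence_counts and sdt_counts must be parallel lists", call. = FALSE)

  if (method == "pooled_mle") {
    total_conf <- sum_confidence_counts(confidence_counts)
    total_sdt <- list(
      tp = sum(vapply(sdt_counts, `[[`, 0, "tp")),
      fp = sum(vapply(sdt_counts, `[[`, 0, "fp")),
      n_signal = sum(vapply(sdt_counts, `[[`, 0, "n_signal")),
      n_noise = sum(vapply(sdt_counts, `[[`, 0, "n_noise"))
    )
    est <- dprime(total_sdt)
    return(metad_mle(total_conf, est$d_prime, est$criterion_c))
  }

  ## hierarchical: per-participant ML, then normal-normal shrinkage
  fits <- vector("list", n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    est <- dprime(sdt_counts[[i]])
    d[i] <- est$d_prime
    fits[[i]] <- if (est$d_prime != 0)
      metad_mle(confidence_counts[[i]], est$d_prime, est$criterion_c)
    else NULL
  }
  meta_d <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$meta_d, 0)
  se_meta <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$se_meta_d, 0)
  conv <- vapply(fits, function(f) !is.null(f) && isTRUE(f$converged), TRUE)

  m_floor <- 0.01
  m_ratio <- pmax(meta_d / d, m_floor)
  log_m <- log(m_ratio)
  # delta method: Var(log(meta_d/d)) ~ Var(meta_d)/meta_d^2 at fixed d
  se_log <- se_meta / pmax(abs(meta_d), m_floor * abs(d))
  usable <- conv & is.finite(log_m) & is.finite(se_log) & se_log > 0
  if (sum(usable) < 2)
    stop("fewer than 2 usable individual fits; use method = 'pooled_mle'",
         call. = FALSE)
  # cap extreme SEs so near-degenerate fits do not dominate the hierarchy
  se_use <- pmin(se_log[usable], 10)
  y <- log_m[usable]

  nll <- function(par) {
    mu <- par[1]; tau <- exp(par[2])
    -sum(dnorm(y, mu, sqrt(tau^2 + se_use^2), log = TRUE))
  }
  opt <- nlminb(c(mean(y), log(max(sd(y), 0.1))), nll,
                lower = c(-10, log(1e-4)), upper = c(10, log(10)))
  mu <- opt$par[1]; tau <- exp(opt$par[2])

  shrunk <- rep(mu, n)
  w <- tau^2 / (tau^2 + pmin(se_log, 10)^2)
  ok <- usable
  shrunk[ok] <- w[ok] * log_m[ok] + (1 - w[ok]) * mu

  participants <- data.frame(
    d_prime = d,
    meta_d = meta_d,
    se_meta_d = se_meta,
    m_ratio = meta_d / d,
    log_m_ratio = log_m,
    shrunk_log_m_ratio = shrunk,
    shrunk_meta_d = exp(shrunk) * d,
    converged = conv,
    used_in_hierarchy = usable
  )
  structure(list(
    mu_log_mratio = mu,
    tau_log_mratio = tau,
    group_m_ratio = exp(mu),
    group_meta_d = exp(mu) * mean(d),
    participants = participants,
    n_used = sum(usable),
    convergence = opt$convergence == 0
  ), class = "metad_group")
}

#' @export
print.metad_group <- function(x, ...) {
  cat(sprintf("Hierarchical group meta-d': mu(log M-ratio) = %.3f, tau = %.3f\n",
              x$mu_log_mratio, x$tau_log_mratio))
  cat(sprintf("  group M-ratio = %.3f, group meta-d' = %.3f (%d of %d fits used)\n",
              x$group_m_ratio, x$group_meta_d, x$n_used, nrow(x$participants)))
  invisible(x)
}
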