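test_that("type-2 cell probabilities normalize and match quadrature", {
  crit <- c(-1.5, -1.0, -0.5, 0.5, 1.0, 1.5)   # k = 4, c_meta = 0
  p <- type2_probabilities(2, 0, crit)
  expect_equal(rowSums(p), c(s1 = 1, s2 = 1))

  # quadrature oracle: integrate the two Gaussians over each bin
  bounds <- c(-Inf, crit[1:3], 0, crit[4:6], Inf)
  for (mu in c(-1, 1)) {
    q <- vapply(seq_len(8), function(j) {
      integrate(dnorm, bounds[j], bounds[j + 1], mean = mu)$value
    }, numeric(1))
    expect_equal(unname(p[if (mu < 0) 1 else 2, ]), q, tolerance = 1e-6)
  }

  # chance-level metacognition: confidence distribution identical for the
  # two stimulus classes
  p0 <- type2_probabilities(0, 0.3, crit)
  expect_equal(p0[1, ], p0[2, ])
  expect_error(type2_probabilities(2, 0, c(-1, -2, -0.5, 0.5, 1, 2)),
               "increasing")
})

test_that("meta-d' recovers the generative sensitivity with perfect readout", {
  s <- sim_binary_sdt(10000, 2, 0, seed = 5)
  r <- fit_metad_trials(s)
  expect_true(r$fit$converged)
  expect_lt(abs(r$fit$meta_d - r$d_prime), 0.15)
  expect_lt(abs(r$fit$meta_d - 2), 0.15)
})

test_that("confidence carrying no information yields meta-d' near zero", {
  # readout noise far above the evidence scale, thresholds matched to it
  sm <- 50
  s <- sim_binary_sdt(10000, 2, sm, thr = sm * c(0.3, 0.6, 1.0, 1.5, 2.1),
                      seed = 3)
  r <- fit_metad_trials(s)
  expect_lt(abs(r$fit$meta_d), 0.1)

  # confidence shuffled independently of accuracy
  s <- sim_binary_sdt(10000, 2, 0, seed = 8)
  s$confidence <- withr::with_seed(9, sample(s$confidence))
  r <- fit_metad_trials(s)
  expect_lt(abs(r$fit$meta_d), 0.1)
})

test_that("estimated meta-d' is monotone non-increasing in readout noise", {
  md <- vapply(c(0, 0.5, 1, 2), function(sm) {
    s <- sim_binary_sdt(10000, 2, sm, seed = 7)
    fit_metad_trials(s)$fit$meta_d
  }, numeric(1))
  expect_true(all(diff(md) <= 0.1))
  expect_lt(md[4], md[1])
})

test_that("meta-d' is invariant to overall confidence bias", {
  # scaling all thresholds shifts how readily high confidence is used,
  # which moves mean confidence but must not move meta-d'
  base <- c(0.3, 0.6, 1.0, 1.5, 2.1)
  fits <- lapply(c(0.5, 1, 2), function(scale) {
    s <- sim_binary_sdt(10000, 2, 0.5, thr = scale * base, seed = 11)
    list(mean_conf = mean(s$confidence), meta_d = fit_metad_trials(s)$fit$meta_d)
  })
  conf <- vapply(fits, `[[`, 0, "mean_conf")
  md <- vapply(fits, `[[`, 0, "meta_d")
  expect_gt(max(conf) - min(conf), 10)          # the bias manipulation bites
  expect_lt(max(md) - min(md), 0.1)             # the estimate does not move
})

test_that("the MLE agrees with an exhaustive grid search on a small k=2 table", {
  # two confidence levels; conditioning on the response side makes the
  # likelihood separable, so an exhaustive grid is cheap and independent
  withr::with_seed(21, {
    stim <- rep(c(1L, -1L), each = 30)
    x <- rnorm(60, stim * 1.2 / 2, 1)
    rating <- ifelse(x > 0, 2L, -2L)
    hiconf <- abs(x) > 0.8
  })
  k <- 2
  cell <- ifelse(rating > 0, k + hiconf + 1L, k - hiconf)
  counts <- structure(list(
    k = k,
    nr_s1 = tabulate(cell[stim == -1L], 2 * k),
    nr_s2 = tabulate(cell[stim == 1L], 2 * k),
    levels = c(50L, 100L)
  ), class = "confidence_counts")
  est <- dprime(sdt_counts(rating, stim))
  fit <- metad_mle(counts, est$d_prime, est$criterion_c)

  # oracle: exhaustive grid; for each meta_d the two criteria optimize
  # independently (each touches only one response side)
  n1 <- counts$nr_s1 + if (any(c(counts$nr_s1, counts$nr_s2) == 0)) 0.25 else 0
  n2 <- counts$nr_s2 + if (any(c(counts$nr_s1, counts$nr_s2) == 0)) 0.25 else 0
  c_rel <- est$criterion_c / est$d_prime
  inc <- seq(0.02, 4, by = 0.01)
  best_ll <- -Inf; best_m <- NA
  for (m in seq(-3, 3, by = 0.005)) {
    cm <- c_rel * m
    mus <- c(-m / 2, m / 2)
    ll_rej <- rowSums(vapply(1:2, function(si) {
      n <- if (si == 1) n1 else n2
      p1 <- pnorm(cm - inc - mus[si]); p2 <- pnorm(cm - mus[si]) - p1
      p1[p1 < 1e-12] <- 1e-12; p2[p2 < 1e-12] <- 1e-12
      n[1] * log(p1 / (p1 + p2)) + n[2] * log(p2 / (p1 + p2))
    }, numeric(length(inc))))
    ll_end <- rowSums(vapply(1:2, function(si) {
      n <- if (si == 1) n1 else n2
      p4 <- 1 - pnorm(cm + inc - mus[si]); p3 <- 1 - pnorm(cm - mus[si]) - p4
      p3[p3 < 1e-12] <- 1e-12; p4[p4 < 1e-12] <- 1e-12
      n[3] * log(p3 / (p3 + p4)) + n[4] * log(p4 / (p3 + p4))
    }, numeric(length(inc))))
    ll <- max(ll_rej) + max(ll_end)
    if (ll > best_ll) { best_ll <- ll; best_m <- m }
  }
  expect_lt(abs(fit$meta_d - best_m), 0.01)
})

test_that("zero cells are padded and flagged", {
  s <- sim_binary_sdt(40, 2, 0, seed = 2)
  r <- fit_metad_trials(s)
  expect_true(r$fit$padding_applied)
  expect_true(is.finite(r$fit$meta_d))
  expect_error(metad_mle(tally_confidence(s$rating, s$direction, s$confidence),
                         0, 0), "nonzero")
})

test_that("pooled group estimate matches the individual for identical participants", {
  s <- sim_binary_sdt(2000, 2, 0.5, seed = 4)
  tc <- tally_confidence(s$rating, s$direction, s$confidence)
  cts <- sdt_counts(s$rating, s$direction)
  est <- dprime(cts)
  single <- metad_mle(tc, est$d_prime, est$criterion_c)
  pooled <- metad_group(rep(list(tc), 5), rep(list(cts), 5),
                        method = "pooled_mle")
  expect_lt(abs(pooled$meta_d - single$meta_d), 0.1)
  expect_error(metad_group(list(tc), list(cts)), "at least 2")
})

test_that("hierarchical group estimate brackets a heterogeneous population", {
  # reference points: large-sample estimates for the two pure noise levels
  pure <- vapply(c(0, 2), function(sm) {
    fit_metad_trials(sim_binary_sdt(10000, 2, sm, seed = 50 + sm))$fit$meta_d
  }, numeric(1))

  conf_list <- list(); sdt_list <- list()
  i <- 0
  for (sm in rep(c(0, 2), each = 8)) {
    i <- i + 1
    s <- sim_binary_sdt(200, 2, sm, seed = 100 + i)
    conf_list[[i]] <- tally_confidence(s$rating, s$direction, s$confidence)
    sdt_list[[i]] <- sdt_counts(s$rating, s$direction)
  }
  grp <- metad_group(conf_list, sdt_list, method = "hierarchical")
  expect_gte(grp$group_meta_d, min(pure) - 0.3)
  expect_lte(grp$group_meta_d, max(pure) + 0.3)
  expect_equal(nrow(grp$participants), 16)
  # shrinkage keeps every posterior mean inside the raw range
  raw <- grp$participants$log_m_ratio[grp$participants$used_in_hierarchy]
  shr <- grp$participants$shrunk_log_m_ratio[grp$participants$used_in_hierarchy]
  expect_true(all(shr >= min(raw) - 1e-8 & shr <= max(raw) + 1e-8))
})
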