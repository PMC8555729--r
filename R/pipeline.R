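## End-to-end analysis: SDT coding -> meta-d' -> taxonomy -> moderation,
## plus the orchestrating run_pipeline() with CSV/JSON reports.

#' Analyze a study (trial + participant tables) end to end
#'
#' Runs the full analysis per topic: per-participant type-1 SDT estimates
#' (d', c), meta-d' (individual ML or hierarchical empirical-Bayes),
#' belief-updating classification with subgroup percentages and polarizer
#' statistics, overall prior-influence regressions per direction of
#' evidence, mean-split moderation on d' and meta-d' with 3-sigma
#' significance flags and split-level polarizer statistics, and trial-level
#' prior/rating correlations with Fisher-z intervals.
#'
#' @param trials trial table (see [validate_input()] for the schema).
#' @param participants participant table.
#' @param estimator `"mle"` (per-participant maximum likelihood; fits that
#'   do not converge are dropped from meta-d' splits) or `"hierarchical"`
#'   (empirical-Bayes shrunk estimates feed the split).
#' @param ties tie rule for [mean_split()].
#' @param sign_reversal rule for [classify_updating()].
#' @return object of class `"study_analysis"`, a list of data frames:
#'   `participant_stats`, `subgroups`, `polarizers`, `regressions`,
#'   `splits`, `significance`, `correlations`, plus `settings`.
#' @export
analyze_study <- function(trials, participants,
                          estimator = c("mle", "hierarchical"),
                          ties = c("high", "low"),
                          sign_reversal = c("flip", "depolarizer")) {
  estimator <- match.arg(estimator)
  ties <- match.arg(ties)
  sign_reversal <- match.arg(sign_reversal)

  pstats <- list(); subgroups <- list(); polarizers <- list()
  regressions <- list(); splits <- list(); sigs <- list(); corrs <- list()

  for (tp in unique(participants$topic)) {
    pp <- participants[participants$topic == tp, , drop = FALSE]
    tt <- trials[trials$topic == tp, , drop = FALSE]
    ids <- pp$participant_id

    by_participant <- split(tt, tt$participant_id)
    conf_list <- vector("list", length(ids))
    sdt_list <- vector("list", length(ids))
    d <- cc <- md <- se <- rep(NA_real_, length(ids))
    conv <- rep(FALSE, length(ids))
    for (i in seq_along(ids)) {
      ti <- by_participant[[ids[i]]]
      if (is.null(ti) || nrow(ti) == 0) next
      sdt_list[[i]] <- sdt_counts(ti$rating, ti$true_direction)
      conf_list[[i]] <- tally_confidence(ti$rating, ti$true_direction,
                                         ti$confidence)
      est <- dprime(sdt_list[[i]])
      d[i] <- est$d_prime; cc[i] <- est$criterion_c
      if (estimator == "mle" && est$d_prime != 0) {
        fit <- metad_mle(conf_list[[i]], est$d_prime, est$criterion_c)
        if (fit$converged) {
          md[i] <- fit$meta_d; se[i] <- fit$se_meta_d; conv[i] <- TRUE
        }
      }
    }
    if (estimator == "hierarchical") {
      ok <- !vapply(sdt_list, is.null, TRUE) & is.finite(d) & d != 0
      grp <- metad_group(conf_list[ok], sdt_list[ok], method = "hierarchical")
      md[ok] <- grp$participants$shrunk_meta_d
      conv[ok] <- TRUE
    }

    cls <- classify_updating(pp$prior, pp$posterior,
                             sign_reversal = sign_reversal)
    pstats[[tp]] <- data.frame(
      participant_id = ids, topic = tp, prior = pp$prior,
      posterior = pp$posterior, updating_class = cls,
      d_prime = d, criterion_c = cc, meta_d = md, m_ratio = md / d,
      metad_converged = conv, stringsAsFactors = FALSE
    )

    sg <- subgroup_percentages(pp, sign_reversal = sign_reversal)
    sg$topic <- tp
    subgroups[[tp]] <- sg
    pol <- proportion_polarizers(pp, sign_reversal = sign_reversal)
    polarizers[[tp]] <- data.frame(
      topic = tp, group = "all", n = pol$n, n_pol = pol$n_pol,
      g_pol = pol$g_pol, delta_g = pol$delta_g, stringsAsFactors = FALSE
    )

    dir_label <- c(`1` = "endorsing", `-1` = "rejecting")
    fit_group <- function(sub_ids, label) {
      res <- list()
      for (dir in c(1, -1)) {
        avg <- average_interpretation(
          tt[tt$participant_id %in% sub_ids, , drop = FALSE], dir)
        m <- merge(avg, pp[, c("participant_id", "prior")],
                   by = "participant_id")
        fit <- tryCatch(ols_fit(m$prior, m$mean_rating),
                        error = function(e) NULL)
        if (is.null(fit)) next
        res[[dir_label[as.character(dir)]]] <- data.frame(
          topic = tp, group = label, direction = dir_label[as.character(dir)],
          alpha = fit$alpha, se_alpha = fit$se_alpha,
          gamma = fit$gamma, se_gamma = fit$se_gamma,
          rse = fit$rse, n = fit$n, stringsAsFactors = FALSE
        )
      }
      res
    }
    regressions[[tp]] <- do.call(rbind, unname(fit_group(ids, "all")))

    corr_group <- function(sub_ids, label) {
      res <- list()
      rows <- tt[tt$participant_id %in% sub_ids, , drop = FALSE]
      rows <- merge(rows, pp[, c("participant_id", "prior")],
                    by = "participant_id")
      for (dir in c(1, -1)) {
        sub <- rows[rows$true_direction == dir, , drop = FALSE]
        ci <- tryCatch(corr_fisher_ci(sub$prior, sub$rating),
                       error = function(e) NULL)
        if (is.null(ci)) next
        res[[dir_label[as.character(dir)]]] <- data.frame(
          topic = tp, group = label, direction = dir_label[as.character(dir)],
          r = ci$r, ci_low = ci$ci_low, ci_high = ci$ci_high, df = ci$df,
          stringsAsFactors = FALSE
        )
      }
      res
    }
    corrs[[paste0(tp, "_all")]] <- do.call(rbind, unname(corr_group(ids, "all")))

    for (var in c("d_prime", "meta_d")) {
      vals <- if (var == "d_prime") d else md
      sp <- tryCatch(mean_split(vals, ties = ties), error = function(e) NULL)
      if (is.null(sp)) next
      splits[[paste(tp, var)]] <- data.frame(
        topic = tp, variable = var, threshold = sp$threshold,
        n_high = sp$n_high, n_low = sp$n_low, stringsAsFactors = FALSE
      )
      group_fits <- list()
      for (side in c("low", "high")) {
        sub_ids <- ids[!is.na(sp$assignment) & sp$assignment == side]
        label <- paste(var, side, sep = "_")
        rows <- fit_group(sub_ids, label)
        group_fits[[side]] <- rows
        regressions[[paste(tp, label)]] <- do.call(rbind, unname(rows))
        pol <- proportion_polarizers(
          pp[pp$participant_id %in% sub_ids, , drop = FALSE],
          sign_reversal = sign_reversal)
        polarizers[[paste(tp, label)]] <- data.frame(
          topic = tp, group = label, n = pol$n, n_pol = pol$n_pol,
          g_pol = pol$g_pol, delta_g = pol$delta_g, stringsAsFactors = FALSE
        )
        corrs[[paste(tp, label)]] <- do.call(rbind,
                                             unname(corr_group(sub_ids, label)))
      }
      for (dir in c("endorsing", "rejecting")) {
        lo <- group_fits$low[[dir]]; hi <- group_fits$high[[dir]]
        if (is.null(lo) || is.null(hi)) next
        for (par in c("alpha", "gamma")) {
          fa <- list(alpha = lo$alpha, se_alpha = lo$se_alpha,
                     gamma = lo$gamma, se_gamma = lo$se_gamma)
          fb <- list(alpha = hi$alpha, se_alpha = hi$se_alpha,
                     gamma = hi$gamma, se_gamma = hi$se_gamma)
          sigs[[paste(tp, var, dir, par)]] <- data.frame(
            topic = tp, variable = var, direction = dir, parameter = par,
            low = fa[[par]], high = fb[[par]],
            result = three_sigma_compare(fa, fb, par),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }

  structure(list(
    participant_stats = do.call(rbind, c(unname(pstats),
                                         list(make.row.names = FALSE))),
    subgroups = do.call(rbind, c(unname(subgroups),
                                 list(make.row.names = FALSE))),
    polarizers = do.call(rbind, c(unname(polarizers),
                                  list(make.row.names = FALSE))),
    regressions = do.call(rbind, c(unname(regressions),
                                   list(make.row.names = FALSE))),
    splits = do.call(rbind, c(unname(splits), list(make.row.names = FALSE))),
    significance = do.call(rbind, c(unname(sigs),
                                    list(make.row.names = FALSE))),
    correlations = do.call(rbind, c(unname(corrs),
                                    list(make.row.names = FALSE))),
    settings = list(estimator = estimator, ties = ties,
                    sign_reversal = sign_reversal)
  ), class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("Study analysis (%d participants, %d topic(s); estimator '%s')\n",
              nrow(x$participant_stats),
              length(unique(x$participant_stats$topic)),
              x$settings$estimator))
  cat("Polarizer proportions:\n")
  print(x$polarizers[x$polarizers$group == "all", ], row.names = FALSE)
  invisible(x)
}

#' Pipeline configuration
#'
#' @param input `"simulate"` (generate data from `sim`) or `"csv"` (read
#'   `trials_path` / `participants_path`).
#' @param sim a [sim_config()] (simulate mode).
#' @param trials_path,participants_path CSV paths (csv mode).
#' @param mapping_path optional JSON file mapping the CSV's column names to
#'   the expected schema, e.g. `{"trials": {"subj": "participant_id"}}`;
#'   used by the `reproduce` CLI mode where deposited column names differ.
#' @param estimator,ties,sign_reversal analysis switches, see
#'   [analyze_study()].
#' @param out_dir output directory for reports.
#' @param seed integer seed recorded in the manifest; in simulate mode it
#'   overrides `sim$seed`.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = c("simulate", "csv"),
                            sim = sim_config(),
                            trials_path = NULL, participants_path = NULL,
                            mapping_path = NULL,
                            estimator = c("mle", "hierarchical"),
                            ties = c("high", "low"),
                            sign_reversal = c("flip", "depolarizer"),
                            out_dir = "polarmeta_out",
                            seed = NULL) {
  input <- match.arg(input)
  if (input == "csv" && (is.null(trials_path) || is.null(participants_path)))
    stop("csv mode needs trials_path and participants_path", call. = FALSE)
  if (!is.null(seed) && input == "simulate") sim$seed <- as.integer(seed)
  structure(list(
    input = input, sim = sim,
    trials_path = trials_path, participants_path = participants_path,
    mapping_path = mapping_path,
    estimator = match.arg(estimator), ties = match.arg(ties),
    sign_reversal = match.arg(sign_reversal),
    out_dir = out_dir,
    seed = if (is.null(seed)) sim$seed else as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a study from CSV, optionally renaming columns via a mapping file
#'
#' @inheritParams pipeline_config
#' @return list with `trials` and `participants` data frames.
#' @export
read_study_csv <- function(trials_path, participants_path,
                           mapping_path = NULL) {
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  participants <- utils::read.csv(participants_path, stringsAsFactors = FALSE)
  if (!is.null(mapping_path)) {
    map <- jsonlite::read_json(mapping_path, simplifyVector = TRUE)
    rename <- function(df, m) {
      if (is.null(m)) return(df)
      idx <- match(names(m), names(df))
      names(df)[idx[!is.na(idx)]] <- unlist(m)[!is.na(idx)]
      df
    }
    trials <- rename(trials, map$trials)
    participants <- rename(participants, map$participants)
  }
  list(trials = trials, participants = participants)
}

#' Run the full pipeline and write reports
#'
#' Simulates or ingests a study, validates it, analyzes it with
#' [analyze_study()] and writes every result table as CSV plus a JSON
#' manifest (package version, seed, analysis switches, validation summary)
#' into `config$out_dir`. Running the same config twice yields
#' byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the `"study_analysis"` object (with the manifest
#'   attached as attribute `"manifest"`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$input == "simulate") {
    dat <- generate_dataset(config$sim)
    trials <- dat$trials
    participants <- dat$participants
  } else {
    study <- read_study_csv(config$trials_path, config$participants_path,
                            config$mapping_path)
    trials <- study$trials
    participants <- study$participants
  }

  findings <- validate_input(trials, participants)
  if (nrow(findings) > 0) {
    stop("input validation failed:\n",
         paste(sprintf("  [%s] %s", findings$check, findings$detail),
               collapse = "\n"), call. = FALSE)
  }

  res <- analyze_study(trials, participants, estimator = config$estimator,
                       ties = config$ties,
                       sign_reversal = config$sign_reversal)

  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  for (nm in c("participant_stats", "subgroups", "polarizers", "regressions",
               "splits", "significance", "correlations")) {
    df <- res[[nm]]
    if (is.null(df)) df <- data.frame()
    utils::write.csv(df, file.path(out, paste0(nm, ".csv")), row.names = FALSE)
  }
  manifest <- list(
    package = "polarmeta",
    version = as.character(utils::packageVersion("polarmeta")),
    input = config$input,
    seed = config$seed,
    estimator = config$estimator,
    ties = config$ties,
    sign_reversal = config$sign_reversal,
    sim = if (config$input == "simulate") unclass(config$sim) else NULL,
    n_participants = nrow(participants),
    n_trials = nrow(trials),
    validation_findings = nrow(findings)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  attr(res, "manifest") <- manifest
  invisible(res)
}
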