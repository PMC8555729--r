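## Input validation for ingested study tables. Reports findings, never
## mutates data.

finding <- function(check, detail) {
  data.frame(check = check, detail = detail, stringsAsFactors = FALSE)
}

#' Validate a trial table and participant table
#'
#' Checks schema (required columns), value ranges (ratings in -8..8,
#' confidence in \{50..100\}, direction +/-1, beliefs in -8..8) and
#' referential integrity (every trial row must match a participant-topic
#' row; participant-topic pairs must be unique; trial counts per
#' participant must be constant within a topic). The data are never
#' modified.
#'
#' @param trials data frame with `participant_id`, `topic`, `text_id`,
#'   `true_direction`, `rating`, `confidence`.
#' @param participants data frame with `participant_id`, `topic`, `prior`,
#'   `posterior`.
#' @return data frame of findings (`check`, `detail`); zero rows means the
#'   input is clean.
#' @export
validate_input <- function(trials, participants) {
  out <- list()
  need_t <- c("participant_id", "topic", "text_id", "true_direction",
              "rating", "confidence")
  need_p <- c("participant_id", "topic", "prior", "posterior")
  miss_t <- setdiff(need_t, names(trials))
  miss_p <- setdiff(need_p, names(participants))
  if (length(miss_t))
    out <- c(out, list(finding("schema", paste(
      "trial table missing columns:", paste(miss_t, collapse = ", ")))))
  if (length(miss_p))
    out <- c(out, list(finding("schema", paste(
      "participant table missing columns:", paste(miss_p, collapse = ", ")))))
  if (length(miss_t) || length(miss_p))
    return(do.call(rbind, out))

  bad <- which(trials$rating < -8 | trials$rating > 8 |
                 trials$rating != round(trials$rating))
  for (i in bad)
    out <- c(out, list(finding("range", sprintf(
      "trial row %d: rating %s outside integer [-8, 8]", i, trials$rating[i]))))
  bad <- which(!trials$confidence %in% confidence_levels())
  for (i in bad)
    out <- c(out, list(finding("range", sprintf(
      "trial row %d: confidence %s not in {50,...,100}", i, trials$confidence[i]))))
  bad <- which(!trials$true_direction %in% c(-1, 1))
  for (i in bad)
    out <- c(out, list(finding("range", sprintf(
      "trial row %d: true_direction %s not in {+1, -1}", i,
      trials$true_direction[i]))))
  for (col in c("prior", "posterior")) {
    v <- participants[[col]]
    bad <- which(v < -8 | v > 8 | v != round(v))
    for (i in bad)
      out <- c(out, list(finding("range", sprintf(
        "participant row %d: %s %s outside integer [-8, 8]", i, col, v[i]))))
  }

  pkey <- paste(participants$participant_id, participants$topic, sep = "\r")
  dup <- which(duplicated(pkey))
  for (i in dup)
    out <- c(out, list(finding("integrity", sprintf(
      "duplicate participant-topic row: %s / %s",
      participants$participant_id[i], participants$topic[i]))))
  tkey <- paste(trials$participant_id, trials$topic, sep = "\r")
  orphan <- which(!tkey %in% pkey)
  for (i in orphan)
    out <- c(out, list(finding("integrity", sprintf(
      "trial row %d references unknown participant-topic: %s / %s",
      i, trials$participant_id[i], trials$topic[i]))))

  for (tp in unique(trials$topic)) {
    cnt <- table(trials$participant_id[trials$topic == tp])
    if (length(unique(as.integer(cnt))) > 1)
      out <- c(out, list(finding("counts", sprintf(
        "topic %s: trial counts per participant differ (%s)",
        tp, paste(sort(unique(as.integer(cnt))), collapse = ", ")))))
  }

  if (length(out) == 0)
    data.frame(check = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
}
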