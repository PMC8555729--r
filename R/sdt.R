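## Type-1 signal detection: response coding, counts, d' and criterion c.

#' Code an interpretation rating against the true evidence direction
#'
#' Ratings above 0 are endorsement responses, ratings below 0 rejection
#' responses. A rating of exactly 0 carries no direction and is coded as an
#' incorrect response whatever the true direction (it counts as a miss on
#' endorsing texts and as a false alarm on rejecting texts); as a response
#' it is grouped with rejections (`"reject_or_zero"`).
#'
#' @param rating integer rating(s) in -8..8.
#' @param true_direction +1 (endorsing text) or -1 (rejecting text).
#' @return data frame with columns `response`
#'   (`"endorse"`/`"reject_or_zero"`) and `correct` (logical).
#' @export
code_response <- function(rating, true_direction) {
  if (any(rating < -8 | rating > 8 | rating != round(rating)))
    stop("rating out of range [-8, 8] or non-integer", call. = FALSE)
  if (any(!true_direction %in% c(-1, 1)))
    stop("true_direction must be +1 or -1", call. = FALSE)
  response <- ifelse(rating > 0, "endorse", "reject_or_zero")
  correct <- (rating > 0 & true_direction == 1) |
    (rating < 0 & true_direction == -1)
  data.frame(response = response, correct = correct, stringsAsFactors = FALSE)
}

#' Tally signal-detection counts from coded trials
#'
#' Endorsing texts are the signal class, rejecting texts the noise class.
#' Hits are endorsement responses to endorsing texts; false alarms are
#' ratings >= 0 on rejecting texts (a zero rating is incorrect in both
#' directions, so it is a miss on the signal side and a false alarm on the
#' noise side).
#'
#' @param rating integer ratings in -8..8.
#' @param true_direction vector of +1/-1, same length.
#' @return object of class `"sdt_counts"`: `tp`, `fn`, `fp`, `tn`,
#'   `n_signal`, `n_noise`.
#' @export
sdt_counts <- function(rating, true_direction) {
  code_response(rating, true_direction)  # validates
  signal <- true_direction == 1
  out <- list(
    tp = sum(signal & rating > 0),
    fn = sum(signal & rating <= 0),
    fp = sum(!signal & rating >= 0),
    tn = sum(!signal & rating < 0),
    n_signal = sum(signal),
    n_noise = sum(!signal)
  )
  structure(out, class = "sdt_counts")
}

#' Task sensitivity d' and response criterion c
#'
#' Computes `d' = Z(tp_rate) - Z(fp_rate)` and
#' `c = -0.5 * (Z(tp_rate) + Z(fp_rate))`, with Z the standard normal
#' quantile function. Rates use the log-linear correction
#' `(count + 0.5) / (n + 1)` so that perfect performance stays finite; with
#' n signal = n noise = n trials the attainable d' is bounded by
#' `2 * Z((n + 0.5)/(n + 1))` (2.563 at n = 4, 1.935 at n = 2).
#'
#' @param counts an `"sdt_counts"` object, or a list with fields `tp`,
#'   `fp`, `n_signal`, `n_noise`.
#' @return object of class `"sdt_estimates"`: `d_prime`, `criterion_c`,
#'   `tp_rate`, `fp_rate`.
#' @examples
#' dprime(list(tp = 4, fp = 0, n_signal = 4, n_noise = 4))$d_prime  # 2.563
#' @export
dprime <- function(counts) {
  if (counts$n_signal < 1 || counts$n_noise < 1)
    stop("need at least one signal and one noise trial", call. = FALSE)
  tp_rate <- (counts$tp + 0.5) / (counts$n_signal + 1)
  fp_rate <- (counts$fp + 0.5) / (counts$n_noise + 1)
  structure(list(
    d_prime = qnorm(tp_rate) - qnorm(fp_rate),
    criterion_c = -0.5 * (qnorm(tp_rate) + qnorm(fp_rate)),
    tp_rate = tp_rate,
    fp_rate = fp_rate
  ), class = "sdt_estimates")
}

#' @export
print.sdt_estimates <- function(x, ...) {
  cat(sprintf("d' = %.3f, c = %.3f (TP rate %.3f, FP rate %.3f)\n",
              x$d_prime, x$criterion_c, x$tp_rate, x$fp_rate))
  invisible(x)
}

#' Tally response-by-confidence counts (the meta-d' input)
#'
#' Builds the standard 2k-cell count vectors per stimulus class. Cells are
#' ordered from high-confidence "reject" to high-confidence "endorse":
#' positions 1..k are rejection responses with confidence 100, 90, ..., 50
#' and positions k+1..2k endorsement responses with confidence 50, 60, ...,
#' 100. Zero ratings sit on the rejection-response side.
#'
#' @param rating integer ratings in -8..8.
#' @param true_direction vector of +1/-1.
#' @param confidence confidence levels in \{50, ..., 100\}.
#' @return object of class `"confidence_counts"`: `k` (= 6), `nr_s1`
#'   (rejecting-text trials), `nr_s2` (endorsing-text trials), `levels`.
#' @export
tally_confidence <- function(rating, true_direction, confidence) {
  if (length(rating) == 0) stop("no trials", call. = FALSE)
  levels <- confidence_levels()
  if (any(!confidence %in% levels))
    stop("invalid confidence level; must be one of ",
         paste(levels, collapse = ", "), call. = FALSE)
  coded <- code_response(rating, true_direction)
  k <- length(levels)
  conf_idx <- match(confidence, levels)                 # 1 = 50% ... 6 = 100%
  cell <- ifelse(coded$response == "endorse",
                 k + conf_idx,                          # endorse: k+1 .. 2k
                 k + 1L - conf_idx)                     # reject: k .. 1
  nr_s1 <- tabulate(cell[true_direction == -1], nbins = 2L * k)
  nr_s2 <- tabulate(cell[true_direction == 1], nbins = 2L * k)
  structure(list(k = k, nr_s1 = nr_s1, nr_s2 = nr_s2, levels = levels),
            class = "confidence_counts")
}

#' @export
print.confidence_counts <- function(x, ...) {
  cat(sprintf("Confidence counts (k = %d): %d rejecting-text, %d endorsing-text trials\n",
              x$k, sum(x$nr_s1), sum(x$nr_s2)))
  m <- rbind(`rejecting texts (S1)` = x$nr_s1, `endorsing texts (S2)` = x$nr_s2)
  colnames(m) <- c(paste0("R", rev(x$levels)), paste0("E", x$levels))
  print(m)
  invisible(x)
}

# Sum a list of confidence_counts objects cell by cell.
sum_confidence_counts <- function(counts_list) {
  k <- counts_list[[1]]$k
  structure(list(
    k = k,
    nr_s1 = Reduce(`+`, lapply(counts_list, `[[`, "nr_s1")),
    nr_s2 = Reduce(`+`, lapply(counts_list, `[[`, "nr_s2")),
    levels = counts_list[[1]]$levels
  ), class = "confidence_counts")
}
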