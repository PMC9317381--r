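#' Spearman-footrule score of an odor-dilution sorting response
#'
#' In the sorting task the subject arranges five odor dilutions in
#' ascending concentration. Each item's error is the absolute difference
#' between the rank the subject assigned and the true rank; the test score
#' is the sum over items (Spearman's footrule distance from the identity
#' ordering). Higher scores mean poorer sorting; a perfect sorting scores 0.
#'
#' @param assigned_order integer permutation of `1..n` (default task:
#'   n = 5): position i holds the true dilution rank the subject placed
#'   there.
#' @return nonnegative even integer; at most 12 for five items.
#' @examples
#' footrule_sort_score(c(1, 2, 3, 4, 5))  # perfect: 0
#' footrule_sort_score(c(5, 4, 3, 2, 1))  # full reversal: 12
#' @export
footrule_sort_score <- function(assigned_order) {
  n <- length(assigned_order)
  if (n < 2 || anyNA(assigned_order) ||
      !isTRUE(all.equal(sort(as.numeric(assigned_order)), as.numeric(seq_len(n)))))
    stop("'assigned_order' must be a permutation of 1..n (duplicate or missing position)")
  sum(abs(as.integer(assigned_order) - seq_len(n)))
}

#' Time-corrected sorting score
#'
#' Raw footrule score divided by the time the subject took, in errors per
#' second. Zero if and only if the sorting was perfect.
#'
#' @param score nonnegative sorting score.
#' @param duration task duration in seconds, > 0.
#' @return errors per second.
#' @export
time_corrected_score <- function(score, duration) {
  if (any(duration <= 0)) stop("'duration' must be positive")
  if (any(score < 0)) stop("'score' must be nonnegative")
  score / duration
}

#' TDI composite score and olfactory diagnosis
#'
#' The Sniffin' Sticks composite (TDI) is the sum of the threshold,
#' discrimination and identification subtest scores, ranging 1 to 48.
#' Diagnostic cut-offs: functional anosmia below 16.5, hyposmia from 16.5
#' to 30.5 (inclusive), normosmia above 30.5.
#'
#' @param olfthresh threshold subtest score in `[1, 16]`.
#' @param olfdis discrimination subtest score in `[0, 16]`.
#' @param olfident identification subtest score in `[0, 16]`.
#' @return list with `tdi` (numeric) and `diagnosis`
#'   (`"anosmia"`, `"hyposmia"` or `"normosmia"`).
#' @export
tdi_diagnosis <- function(olfthresh, olfdis, olfident) {
  if (olfthresh < 1 || olfthresh > 16)
    stop("'olfthresh' out of range [1, 16]")
  if (olfdis < 0 || olfdis > 16) stop("'olfdis' out of range [0, 16]")
  if (olfident < 0 || olfident > 16) stop("'olfident' out of range [0, 16]")
  tdi <- olfthresh + olfdis + olfident
  diagnosis <- if (tdi < 16.5) "anosmia"
  else if (tdi <= 30.5) "hyposmia"
  else "normosmia"
  list(tdi = tdi, diagnosis = diagnosis)
}

#' Per-nostril summary of the odor-distance (peanut butter) test
#'
#' The jar starts 30 cm from the nostril and is moved closer until the
#' odor is perceived; the perception distance is recorded three times per
#' nostril and the mean is the nostril's estimate.
#'
#' @param trials_left,trials_right numeric vectors of 3 distances in cm,
#'   each in `[0, 30]`.
#' @return list with `mean_left` and `mean_right`.
#' @export
peanut_summary <- function(trials_left, trials_right) {
  for (tr in list(trials_left, trials_right)) {
    if (length(tr) != 3) stop("exactly 3 trials per nostril required")
    if (any(tr < 0) || any(tr > 30))
      stop("distances must lie in [0, 30] cm (start distance 30)")
  }
  list(mean_left = mean(trials_left), mean_right = mean(trials_right))
}

#' Count correct trials of a forced-choice instrument
#'
#' The lateralization test scores 40 trials (20 per nostril); the
#' enantiomer discrimination test scores 4 odor pairs. The score is simply
#' the number of correct responses.
#'
#' @param trials logical vector of per-trial correctness.
#' @param instrument `"lateralization"` (40 trials) or `"enantiomer"`
#'   (4 trials); fixes the expected trial count.
#' @return integer count of correct trials.
#' @export
count_correct <- function(trials, instrument = c("lateralization", "enantiomer")) {
  instrument <- match.arg(instrument)
  expected <- c(lateralization = 40L, enantiomer = 4L)[[instrument]]
  if (length(trials) != expected)
    stop(sprintf("'%s' expects %d trials, got %d", instrument, expected,
                 length(trials)))
  if (!is.logical(trials) || anyNA(trials))
    stop("'trials' must be logical without missing values")
  sum(trials)
}

#' Importance-of-olfaction questionnaire subscale scores
#'
#' Each statement is rated 0 ("do not agree at all") to 3 ("completely
#' agree"). Six statements each feed the association, application and
#' consequence subscales (maximum 18 points per subscale); aggravation/lie
#' items carry no score and are ignored.
#'
#' @param items integer vector of item responses in `[0, 3]`.
#' @param subscale_map character vector (same length) assigning each item
#'   to `"association"`, `"application"`, `"consequence"` or `"lie"`.
#' @return named integer vector of the three subscale sums.
#' @export
importance_subscales <- function(items, subscale_map) {
  if (length(items) != length(subscale_map))
    stop("'items' and 'subscale_map' must have equal length")
  if (any(items < 0 | items > 3 | items != round(items)))
    stop("items must be integers in [0, 3]")
  main <- c("association", "application", "consequence")
  if (!all(subscale_map %in% c(main, "lie")))
    stop("unknown subscale label")
  counts <- table(factor(subscale_map, levels = main))
  if (any(counts != 6))
    stop("each main subscale must have exactly 6 items")
  out <- vapply(main, function(s) sum(items[subscale_map == s]), numeric(1))
  stats::setNames(as.integer(out), main)
}
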