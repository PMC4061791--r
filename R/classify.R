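#' Classify trials by between-system competition
#'
#' A trial is high-competition (`"C"`) when both systems are more than
#' `threshold` confident of category membership *and* predict different
#' categories; non-competition (`"NC"`) when exactly one system exceeds
#' the threshold (one system dominates and the decision is easy); and
#' `"undefined"` otherwise (both confident and agreeing, or neither
#' confident — typical early in training). The threshold is a strict
#' inequality: confidence exactly at `threshold` does not count as
#' confident.
#'
#' @param p_a_rb,p_a_ii Each system's p(A) (vectorized).
#' @param threshold Confidence cut, default 0.75.
#' @return Character vector in `c("C", "NC", "undefined")`.
#' @export
#' @examples
#' classify_competition(0.9, 0.1)    # "C"
#' classify_competition(0.9, 0.6)    # "NC"
#' classify_competition(0.9, 0.85)   # "undefined"
#' classify_competition(0.6, 0.6)    # "undefined"
classify_competition <- function(p_a_rb, p_a_ii, threshold = 0.75) {
  stopifnot(all(p_a_rb >= 0 & p_a_rb <= 1), all(p_a_ii >= 0 & p_a_ii <= 1),
            threshold >= 0.5, threshold < 1)
  conf_rb <- pmax(p_a_rb, 1 - p_a_rb)
  conf_ii <- pmax(p_a_ii, 1 - p_a_ii)
  hi_rb <- conf_rb > threshold
  hi_ii <- conf_ii > threshold
  differ <- .predicted_category(p_a_rb) != .predicted_category(p_a_ii)
  ifelse(hi_rb & hi_ii & differ, "C",
         ifelse(xor(hi_rb, hi_ii), "NC", "undefined"))
}

#' Select the best-fitting blocks by summed trial log-likelihood
#'
#' A block's fit is the sum of its trials' log-likelihoods; the top
#' `fraction` of blocks (ceiling) is returned. Blocks may be pooled across
#' subjects (give each block a unique id) or ranked within subject. Ties
#' break toward the lower block id.
#'
#' @param block Block identifier per trial (any vector; ranked by its sort
#'   order for tie-breaking).
#' @param log_likelihood Per-trial log-likelihoods (NA trials are dropped).
#' @param fraction Fraction of blocks to keep, default 1/3.
#' @return The selected block ids, best fit first.
#' @export
best_fit_blocks <- function(block, log_likelihood, fraction = 1/3) {
  stopifnot(length(block) == length(log_likelihood), fraction > 0,
            fraction <= 1)
  if (length(block) == 0L) stop("empty input")
  keep <- !is.na(log_likelihood)
  fits <- tapply(log_likelihood[keep], block[keep], sum)
  ids <- names(fits)
  ord <- order(-as.numeric(fits), ids)
  n_take <- ceiling(fraction * length(fits))
  out <- ids[ord][seq_len(n_take)]
  # restore the original type of the block ids where possible
  if (is.numeric(block)) out <- as.numeric(out)
  out
}

#' Tag each trial's off-system and its covert correctness
#'
#' The off-system is the system that lost the competition. Its predicted
#' category is the argmax of its own p(A) (exactly 0.5 predicts `"B"`),
#' and it is scored against the true category — covert learning the model
#' attributes to the system not driving behavior.
#'
#' @param trace A replayed or simulated trial table with columns `winner`
#'   (or `responsible`), `p_a_rb`, `p_a_ii`, `true_category`, and
#'   optionally `trial`.
#' @param threshold Confidence cut for the competition class.
#' @return A data.frame: `trial`, `winner`, `competition_class`,
#'   `off_system`, `off_system_prediction`, `off_system_correct`,
#'   `off_system_on_bound` (flags the measure-zero p(A) = 0.5 edge).
#' @export
tag_off_system <- function(trace, threshold = 0.75) {
  winner <- if ("winner" %in% names(trace)) trace$winner
  else trace$responsible
  if (is.null(winner)) stop("trace needs a 'winner' or 'responsible' column")
  stopifnot(all(c("p_a_rb", "p_a_ii", "true_category") %in% names(trace)))
  off <- ifelse(winner == "RB", "II", "RB")
  p_off <- ifelse(off == "RB", trace$p_a_rb, trace$p_a_ii)
  pred <- .predicted_category(p_off)
  data.frame(
    trial = if ("trial" %in% names(trace)) trace$trial
    else seq_len(nrow(trace)),
    winner = winner,
    competition_class = classify_competition(trace$p_a_rb, trace$p_a_ii,
                                             threshold),
    off_system = off,
    off_system_prediction = pred,
    off_system_correct = pred == trace$true_category,
    off_system_on_bound = p_off == 0.5,
    stringsAsFactors = FALSE
  )
}

#' Summarize behavior by block and competition class
#'
#' Per block and competition class: trial count, percentage of the block's
#' trials, mean accuracy and mean reaction time (when an `rt` column is
#' present). Classes with no trials appear with count 0 and NA statistics,
#' and the three percentages within a block sum to 100.
#'
#' @param classifications Output of [tag_off_system()] (or any table with
#'   `trial` and `competition_class`).
#' @param behavior The aligned behavior table with `trial`, `block`,
#'   `correct`, and optionally `rt`.
#' @return A data.frame with columns `block`, `class`, `n`, `pct`,
#'   `accuracy`, `rt`.
#' @export
summarize_by_class <- function(classifications, behavior) {
  stopifnot(all(c("trial", "competition_class") %in% names(classifications)),
            all(c("trial", "block", "correct") %in% names(behavior)))
  idx <- match(behavior$trial, classifications$trial)
  if (anyNA(idx)) stop("classifications do not cover all behavior trials")
  cls <- factor(classifications$competition_class[idx],
                levels = c("C", "NC", "undefined"))
  blocks <- sort(unique(behavior$block))
  has_rt <- "rt" %in% names(behavior)
  rows <- lapply(blocks, function(b) {
    in_b <- behavior$block == b
    lapply(levels(cls), function(cl) {
      sel <- in_b & cls == cl
      n <- sum(sel)
      data.frame(
        block = b, class = cl, n = n,
        pct = 100 * n / sum(in_b),
        accuracy = if (n > 0) mean(behavior$correct[sel]) else NA_real_,
        rt = if (has_rt && n > 0) mean(behavior$rt[sel], na.rm = TRUE)
        else NA_real_,
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}
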