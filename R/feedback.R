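#' The twelve feedback-routing policies
#'
#' On each trial one system wins the competition and drives the response,
#' and the trial is scored correct or incorrect against the true category.
#' A routing policy maps that (winner, correctness) pair to the set of
#' systems that then receive feedback and update. Policy 1 updates only the
#' winner; policy 2 updates both systems on every trial; the remaining
#' policies gate updates by feedback valence, by which system won, or both.
#' Policies whose clauses cover only part of the (winner, correctness)
#' grid route nothing on the remaining trials.
#'
#' @return A data.frame with columns `model_number` and `description`.
#' @export
feedback_policies <- function() {
  data.frame(
    model_number = 1:12,
    description = c(
      "The selected system gets feedback, on both correct and incorrect trials.",
      "Both systems get feedback on every trial.",
      "Feedback only occurs on correct trials and goes to both systems.",
      "Both systems get feedback on every incorrect trial.",
      "If RB is selected, both systems get feedback; if II is selected, only II does.",
      "If II is selected, both systems get feedback; if RB is selected, only RB does.",
      "If RB is selected on an incorrect trial, both systems get feedback; only II gets feedback on every other trial.",
      "If II is selected on an incorrect trial, both systems get feedback; only RB gets feedback on every other trial.",
      "RB receives feedback when selected on a correct trial; II receives feedback when selected on an incorrect trial.",
      "II receives feedback when selected on a correct trial; RB receives feedback when selected on an incorrect trial.",
      "Feedback only occurs on correct trials and goes to the selected system.",
      "Feedback only occurs on incorrect trials and goes to the selected system."
    ),
    stringsAsFactors = FALSE
  )
}

#' Route trial feedback to the systems a policy designates
#'
#' Pure function from (policy, winner, correctness) to the subset of
#' systems that update on the trial. Each routed system then applies
#' feedback against its OWN prediction versus the true category (its
#' boundary shifts and `ps` grows if it was wrong; `ps` shrinks if it was
#' right), independent of which system produced the overt response.
#'
#' @param model_number Integer policy id, 1 to 12.
#' @param winner `"RB"` or `"II"`, the system that drove the response.
#' @param correct Logical, whether the overt response matched the true
#'   category.
#' @return Character vector: a subset of `c("RB", "II")` (possibly empty).
#' @export
#' @examples
#' route_feedback(2, "RB", FALSE)   # both systems
#' route_feedback(12, "II", TRUE)   # no system
route_feedback <- function(model_number, winner, correct) {
  stopifnot(length(model_number) == 1L, model_number %in% 1:12,
            winner %in% c("RB", "II"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  other <- if (winner == "RB") "II" else "RB"
  both <- c("RB", "II")
  none <- character(0)
  switch(model_number,
    winner,                                                   # 1
    both,                                                     # 2
    if (correct) both else none,                              # 3
    if (!correct) both else none,                             # 4
    if (winner == "RB") both else "II",                       # 5
    if (winner == "II") both else "RB",                       # 6
    if (winner == "RB" && !correct) both else "II",           # 7
    if (winner == "II" && !correct) both else "RB",           # 8
    if (winner == "RB" && correct) "RB"
      else if (winner == "II" && !correct) "II" else none,    # 9
    if (winner == "II" && correct) "II"
      else if (winner == "RB" && !correct) "RB" else none,    # 10
    if (correct) winner else none,                            # 11
    if (!correct) winner else none                            # 12
  )
}
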