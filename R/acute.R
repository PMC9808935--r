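#' Entry distribution into the lifetime model
#'
#' The 30-day decision-tree stage and the first-year trial outcomes are
#' merged into a single entry distribution: patients land in NYHA classes
#' I-IV with the published 0-12-month probabilities, or in the death state
#' with the published first-year all-cause death probability. The
#' post-stroke states receive no mass at entry; acute strokes are handled as
#' costed adverse events and the stroke-state split begins inside the Markov
#' stage.
#'
#' @param arm `"TAVI"` or `"SAVR"`.
#' @param cfg A validated `"valvecea_config"`.
#' @return Named probability vector over [health_states()], summing to one.
#' @export
#' @examples
#' entry_distribution("TAVI", default_config())
entry_distribution <- function(arm, cfg) {
  arm <- .match_arm(arm)
  .assert_valid(cfg)
  e <- cfg$entry[[arm]]
  out <- stats::setNames(numeric(.N_STATES), health_states())
  out[.NYHA] <- e[paste0("NYHA", 1:4)]
  out[.DEAD] <- e[["death"]]
  out
}

#' Acute (procedure plus perioperative-event) cost per patient
#'
#' Expected first-stage cost for one strategy: the sum of every cost item
#' assigned to the arm's `PROCEDURE` phase, plus, for every `ACUTE_EVENT`
#' item, the item's cost weighted by the matching adverse-event probability
#' (taken at its published value). Patients who die at entry still accrue
#' the full acute cost: they were operated on.
#'
#' @inheritParams entry_distribution
#' @return A list of class `"valvecea_acute_cost"` with `arm`,
#'   `expected_cost` (IRR) and a named `breakdown` whose sum equals
#'   `expected_cost`.
#' @export
#' @examples
#' acute_cost("TAVI", default_config())$expected_cost
acute_cost <- function(arm, cfg) {
  arm <- .match_arm(arm)
  .assert_valid(cfg)
  breakdown <- numeric()
  for (it in cfg$costs) {
    for (a in it$assignment) {
      if (a$arm != arm) next
      contrib <- switch(a$phase,
        PROCEDURE = it$mean,
        ACUTE_EVENT = cfg$events[[arm]][[a$event]] * it$mean,
        PER_CYCLE_EVENT = NULL)  # accrues inside the Markov stage
      if (is.null(contrib)) next
      label <- if (a$phase == "ACUTE_EVENT") paste0(it$name, "@", a$event) else it$name
      breakdown[label] <- (if (label %in% names(breakdown)) breakdown[[label]] else 0) + contrib
    }
  }
  structure(list(arm = arm, expected_cost = sum(breakdown), breakdown = breakdown),
            class = "valvecea_acute_cost")
}
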