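#' Health states of the Markov model
#'
#' The lifetime model tracks nine mutually exclusive health states: the four
#' New York Heart Association (NYHA) functional classes, the same four classes
#' after a disabling major stroke, and death. Death is the unique absorbing
#' state. The order returned here is the canonical column order used by every
#' transition matrix, cohort trace and reward vector in the package.
#'
#' @return Character vector of the nine state labels.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("NYHA1", "NYHA2", "NYHA3", "NYHA4",
    "NYHA1_STROKE", "NYHA2_STROKE", "NYHA3_STROKE", "NYHA4_STROKE",
    "DEAD")
}

#' Treatment strategies
#'
#' Exactly two strategies are compared: transcatheter aortic valve
#' implantation (TAVI, the intervention) and surgical aortic valve
#' replacement (SAVR, the comparator).
#'
#' @return Character vector `c("TAVI", "SAVR")`.
#' @export
arms <- function() c("TAVI", "SAVR")

# index of the absorbing death state in health_states()
.DEAD <- 9L
.N_STATES <- 9L
.NYHA <- 1:4
.NYHA_STROKE <- 5:8

.match_arm <- function(arm) {
  arm <- match.arg(toupper(arm), arms())
  arm
}
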