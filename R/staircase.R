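#' Adaptive 3-down 1-up staircase
#'
#' `staircase_state()` initializes the state of a transformed up-down
#' staircase on SNR: after every incorrect response the SNR is raised by the
#' current step; after three consecutive correct responses it is lowered by
#' one step. The procedure converges on the SNR where the probability of a
#' correct response is `0.5^(1/3) = 0.794`. The step starts at `step_db` and
#' switches to `final_step_db` after the first reversal.
#'
#' @param start_snr_db Starting SNR in dB.
#' @param step_db Initial step size in dB.
#' @param final_step_db Step size after the first reversal.
#' @param floor_snr_db,ceiling_snr_db Clipping bounds for the SNR track.
#' @return An `aci_staircase` state list with fields `current_snr`,
#'   `consecutive_correct`, `step_db`, `final_step_db`, `floor_snr_db`,
#'   `ceiling_snr_db`, `n_reversals`, `last_direction`.
#' @export
staircase_state <- function(start_snr_db = 0, step_db = 2,
                            final_step_db = 1, floor_snr_db = -30,
                            ceiling_snr_db = 20) {
  if (start_snr_db < floor_snr_db || start_snr_db > ceiling_snr_db) {
    stop_input("start SNR outside [floor, ceiling]")
  }
  structure(
    list(current_snr = start_snr_db, consecutive_correct = 0L,
         step_db = step_db, final_step_db = final_step_db,
         floor_snr_db = floor_snr_db, ceiling_snr_db = ceiling_snr_db,
         n_reversals = 0L, last_direction = 0L),
    class = "aci_staircase"
  )
}

#' @rdname staircase_state
#' @param state An `aci_staircase` state.
#' @param correct Logical; was the response correct?
#' @return `staircase_update()`: the updated state.
#' @export
staircase_update <- function(state, correct) {
  direction <- 0L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct == 3L) {
      state$current_snr <- state$current_snr - state$step_db
      state$consecutive_correct <- 0L
      direction <- -1L
    }
  } else {
    state$current_snr <- state$current_snr + state$step_db
    state$consecutive_correct <- 0L
    direction <- 1L
  }
  if (direction != 0L) {
    if (state$last_direction != 0L && direction != state$last_direction) {
      state$n_reversals <- state$n_reversals + 1L
      if (state$n_reversals == 1L) state$step_db <- state$final_step_db
    }
    state$last_direction <- direction
  }
  state$current_snr <- min(max(state$current_snr, state$floor_snr_db),
                           state$ceiling_snr_db)
  state
}
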