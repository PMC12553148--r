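#' Controlled vocabulary of gait outcomes
#'
#' The 16 lower-limb kinematic and kinetic waveforms supported by the
#' modelling pipeline, one fitted model per outcome.  Kinetic outcomes are
#' mass-normalised.  The unit registry maps each outcome family to its units:
#' angles in degrees (`deg`), ground reaction forces in `N/kg`, joint moments
#' in `Nm/kg`, joint powers in `W/kg`.
#'
#' @return `gait_outcomes()` returns a data.frame with columns `outcome`,
#'   `family` and `units`, one row per supported outcome.
#' @examples
#' gait_outcomes()
#' outcome_units("grf_vertical")
#' @export
gait_outcomes <- function() {
  angles <- c(
    "hip_sagittal_angle", "hip_frontal_angle", "hip_transverse_angle",
    "knee_sagittal_angle", "ankle_sagittal_angle", "ankle_frontal_angle"
  )
  grf <- c("grf_ap", "grf_vertical")
  moments <- c(
    "hip_sagittal_moment", "hip_frontal_moment", "hip_transverse_moment",
    "knee_sagittal_moment", "ankle_sagittal_moment"
  )
  powers <- c("hip_sagittal_power", "knee_sagittal_power", "ankle_sagittal_power")
  data.frame(
    outcome = c(angles, grf, moments, powers),
    family = rep(c("angle", "grf", "moment", "power"),
                 times = c(length(angles), length(grf), length(moments), length(powers))),
    units = rep(c("deg", "N/kg", "Nm/kg", "W/kg"),
                times = c(length(angles), length(grf), length(moments), length(powers))),
    stringsAsFactors = FALSE
  )
}

#' @rdname gait_outcomes
#' @param outcome outcome name from the controlled vocabulary.
#' @export
outcome_units <- function(outcome) {
  reg <- gait_outcomes()
  i <- match(outcome, reg$outcome)
  if (anyNA(i)) {
    stop("unknown outcome(s): ", paste(outcome[is.na(i)], collapse = ", "),
         "; see gait_outcomes()", call. = FALSE)
  }
  reg$units[i]
}

#' Evaluation grid of the normalised gait cycle
#'
#' Gait cycles are time-normalised to 100 points between two consecutive
#' initial contacts of the same foot, indexed 0--99 (percent of cycle,
#' half-open \[0, 100)).
#'
#' @return integer vector `0:99`.
#' @export
gait_t_grid <- function() 0:99
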