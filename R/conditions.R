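#' Stimulus conditions
#'
#' The experiment sweeps a vertical post through the whisker array at three
#' angular speeds (90, 180, 360 degrees/s) and in two directions:
#' rostral-to-caudal (\code{"RC"}) and caudal-to-rostral (\code{"CR"}).
#' The fixed condition ordering used everywhere in the package is speed
#' ascending with RC before CR, giving condition indices j = 1..6.
#'
#' @return A data frame with columns \code{j}, \code{speed},
#'   \code{direction} and \code{label} (e.g. \code{"90_RC"}).
#' @export
conditions <- function() {
  speeds <- c(90, 180, 360)
  out <- data.frame(
    j = 1:6,
    speed = rep(speeds, each = 2),
    direction = rep(c("RC", "CR"), times = 3),
    stringsAsFactors = FALSE
  )
  out$label <- paste0(out$speed, "_", out$direction)
  out
}

#' Construct a validated stimulus condition
#'
#' @param speed Angular sweep speed in degrees/s; one of 90, 180, 360.
#' @param direction Sweep direction, \code{"RC"} or \code{"CR"}.
#' @return A list with elements \code{speed}, \code{direction} and the
#'   condition index \code{j}.
#' @export
condition <- function(speed, direction) {
  tab <- conditions()
  hit <- which(tab$speed == speed & tab$direction == direction)
  if (length(hit) != 1L)
    stop("invalid condition: speed must be one of 90/180/360 and direction RC/CR",
         call. = FALSE)
  list(speed = tab$speed[hit], direction = tab$direction[hit], j = tab$j[hit])
}

#' Condition index from speed and direction
#'
#' @inheritParams condition
#' @return Integer condition index in 1..6.
#' @export
condition_index <- function(speed, direction) condition(speed, direction)$j

#' Linear speed at the tip of the stimulation arm
#'
#' Converts the angular speed of the servo-mounted rod to the linear speed of
#' the post sweeping through the whisker array.
#'
#' @param angular_speed Angular speed in degrees/s.
#' @param arm_length Length of the rod carrying the post, in cm.
#' @return Linear speed in cm/s, rounded to the nearest integer.
#' @examples
#' post_linear_speed(90, 27)   # 42 cm/s
#' post_linear_speed(360, 27)  # 170 cm/s
#' @export
post_linear_speed <- function(angular_speed, arm_length) {
  assert_scalar_num(angular_speed, "angular_speed", positive = TRUE)
  assert_scalar_num(arm_length, "arm_length", positive = TRUE)
  round(angular_speed * pi / 180 * arm_length)
}
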