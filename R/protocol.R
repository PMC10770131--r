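#' The default 11-step assessment protocol
#'
#' The interactive assessment consists of 11 movement steps performed while
#' seated, three lasting 20 seconds and eight lasting 10 seconds, each
#' belonging to one of three task categories that provoke different tremor
#' regimes: `Resting` (arms at rest), `Postural` (arms held against gravity)
#' and `Kinetic` (voluntary targeted movement).
#'
#' Splitting the three 20-second steps in half yields 14 ten-second task
#' segments per participant, i.e. 14 segments x 2 wrists x 2 sensors x 3 axes
#' = 168 channels for the full protocol.
#'
#' @return A data frame with columns `step` (name), `duration` (seconds) and
#'   `category` (task category).
#' @export
#' @examples
#' default_protocol()
default_protocol <- function() {
  data.frame(
    step = c("relaxed1", "relaxed2", "stretch_hold", "lift_hold",
             "hold_weight", "point_finger", "drink_glass", "cross_arms",
             "touch_index", "touch_nose", "entrainment"),
    duration = c(20, 20, 10, 10, 10, 10, 10, 10, 10, 10, 20),
    category = c("Resting", "Resting", "Postural", "Postural", "Postural",
                 "Kinetic", "Kinetic", "Kinetic", "Kinetic", "Kinetic",
                 "Postural"),
    stringsAsFactors = FALSE
  )
}

#' Assessment steps removed before classification
#'
#' Three steps carrying no additional classification value are dropped by
#' default before feature extraction: "lift and hold", "point finger" and
#' "touch index".
#'
#' @return Character vector of step names.
#' @export
default_removed_steps <- function() {
  c("lift_hold", "point_finger", "touch_index")
}

.wrists <- c("left", "right")
.sensors <- c("acceleration", "rotation")
.axes <- c("x", "y", "z")
.conditions <- c("PD", "DD", "HC")
.genders <- c("male", "female")
.categories <- c("Resting", "Postural", "Kinetic")

validate_protocol <- function(protocol) {
  if (!is.data.frame(protocol) || nrow(protocol) == 0L)
    stop("protocol must be a non-empty data frame", call. = FALSE)
  needed <- c("step", "duration", "category")
  missing <- setdiff(needed, names(protocol))
  if (length(missing))
    stop("protocol lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(protocol$step))
    stop("protocol step names must be unique", call. = FALSE)
  if (any(protocol$duration <= 0))
    stop("protocol durations must be positive", call. = FALSE)
  bad <- setdiff(protocol$category, .categories)
  if (length(bad))
    stop("unknown task category: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(protocol)
}
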