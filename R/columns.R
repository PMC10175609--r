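#' Protocerebral-bridge column labels
#'
#' The 16 columns of the protocerebral bridge (PB) are labelled `L8 ... L1`
#' for the left hemisphere and `R1 ... R8` for the right, and mapped onto
#' positions 1 to 16 in that order. CL1a neurons occupy components 1-16 of a
#' network state, CL2 neurons components 17-32, both ordered by PB column.
#'
#' @return Character vector of the 16 column labels in position order.
#' @examples
#' pb_columns()[1]   # "L8"
#' pb_columns()[16]  # "R8"
#' @export
pb_columns <- function() {
  c(paste0("L", 8:1), paste0("R", 1:8))
}

#' Convert between PB column labels and positions
#'
#' @param x Column labels (character) for `column_position()`, or integer
#'   positions in 1..16 for `column_label()`.
#' @return Integer positions, or character labels.
#' @examples
#' column_position("L8")  # 1
#' column_label(16)       # "R8"
#' @export
column_position <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  p <- match(x, pb_columns())
  if (anyNA(p)) stop("unknown PB column label: ", paste(x[is.na(p)], collapse = ", "))
  p
}

#' @rdname column_position
#' @export
column_label <- function(x) {
  if (is.character(x)) return(x)
  if (any(x < 1L | x > 16L)) stop("PB column positions must lie in 1..16")
  pb_columns()[x]
}

# mirror column across the brain midline: L_k <-> R_k
mirror_position <- function(p) 17L - p

#' Motion directions and categories
#'
#' Eight simulated self-motion directions grouped into four categories of
#' opposing pairs: translation (forward/backward), yaw (left/right turn),
#' lift (up/down), and roll (counterclockwise/clockwise). Within each
#' category the first listed direction is the reference direction `A` of the
#' direction-selectivity scores.
#'
#' @return `motion_directions()`: character vector of the eight direction
#'   labels. `motion_categories()`: named list mapping each category to its
#'   ordered pair `c(A, B)` of direction labels.
#' @examples
#' motion_categories()$yaw  # c("yaw_left", "yaw_right")
#' @export
motion_directions <- function() {
  c("forward", "backward", "yaw_left", "yaw_right",
    "lift_up", "lift_down", "roll_ccw", "roll_cw")
}

#' @rdname motion_directions
#' @export
motion_categories <- function() {
  list(translation = c("forward", "backward"),
       yaw         = c("yaw_left", "yaw_right"),
       lift        = c("lift_up", "lift_down"),
       roll        = c("roll_ccw", "roll_cw"))
}

check_direction <- function(direction) {
  if (!direction %in% motion_directions())
    stop("unknown motion direction '", direction, "'; valid directions: ",
         paste(motion_directions(), collapse = ", "))
  direction
}

neuron_classes <- function() {
  c("TL", "CL1a", "CL2", "TB1", "CPU1", "CPU2", "CPU5", "CP1", "CP2", "PoU", "TU")
}
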