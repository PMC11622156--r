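#' The 24-2 test-point grid
#'
#' Builds the fixed 54-location 24-2 perimetry grid for one eye. Coordinates
#' are in degrees of eccentricity with the horizontal axis positive toward
#' the temporal retina of a right eye (OD): for OD the grid extends to 27
#' degrees only temporally (x = +27 at y = +/-3) and the physiologic blind
#' spot sits at (15, +/-3); for a left eye (OS) the grid is the mirror image
#' in x, with the blind spot at (-15, +/-3). The vertical axis is positive
#' superiorly.
#'
#' Ordering is deterministic: row-major from the superior row (y = 21) down
#' to the inferior row (y = -21), nasal to temporal within each row. For OD
#' that is ascending x; for OS descending x, so the i-th point of either
#' eye's grid is the same anatomic location.
#'
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @return A data frame with 54 rows and columns `x_deg`, `y_deg`,
#'   `is_blind_spot`, plus a `loc` key column (`"x:y"`).
#' @examples
#' g <- vf_grid_24_2("OD")
#' nrow(g)                 # 54
#' sum(g$is_blind_spot)    # 2
#' @export
vf_grid_24_2 <- function(eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  rows <- list(
    `21`  = c(-9, -3, 3, 9),
    `15`  = c(-15, -9, -3, 3, 9, 15),
    `9`   = c(-21, -15, -9, -3, 3, 9, 15, 21),
    `3`   = c(-21, -15, -9, -3, 3, 9, 15, 21, 27),
    `-3`  = c(-21, -15, -9, -3, 3, 9, 15, 21, 27),
    `-9`  = c(-21, -15, -9, -3, 3, 9, 15, 21),
    `-15` = c(-15, -9, -3, 3, 9, 15),
    `-21` = c(-9, -3, 3, 9)
  )
  ys <- as.integer(names(rows))
  x <- unlist(rows, use.names = FALSE)
  y <- rep(ys, lengths(rows))
  if (eye == "OS") x <- -x            # mirror; row order already nasal->temporal
  bs_x <- if (eye == "OD") 15L else -15L
  g <- data.frame(
    x_deg = as.integer(x),
    y_deg = as.integer(y),
    is_blind_spot = x == bs_x & abs(y) == 3L
  )
  g$loc <- paste0(g$x_deg, ":", g$y_deg)
  g
}

#' Non-blind-spot locations of the 24-2 grid
#'
#' @inheritParams vf_grid_24_2
#' @return The 52-row subset of [vf_grid_24_2()] with the two blind-spot
#'   locations removed.
#' @export
vf_grid_seeing <- function(eye = c("OD", "OS")) {
  g <- vf_grid_24_2(eye)
  g[!g$is_blind_spot, , drop = FALSE]
}

# location key helper shared across modules
.loc_key <- function(x, y) paste0(x, ":", y)
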