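# Arena and barrier geometry for bisected circular social arenas.
# Coordinates are millimetres. The barrier runs along the y-axis through the
# arena center, so the bisector is x = 0 and the two compartments are the
# sign of x: compartments[1] is x < 0 ("left"), compartments[2] is x > 0.

#' Specify a bisected circular social arena
#'
#' A social arena is a circular chamber split into two semicircular
#' compartments by a removable interaction barrier. Defaults follow the
#' standard array geometry: 30 mm diameter, 1.5 mm thick barrier.
#'
#' @param arena_id Identifier for the arena.
#' @param center Numeric length-2, arena center in mm.
#' @param diameter Arena diameter in mm (> 0).
#' @param barrier_thickness Barrier thickness in mm (>= 0, < diameter).
#' @param compartments Character length-2: labels of the x < 0 and x > 0
#'   compartments, in that order.
#' @return An object of class `arena_spec`.
#' @examples
#' a <- arena_spec()
#' barrier_distance(c(-15, 0), a, "left")  # semicircle pole: 14.25 mm
#' @export
arena_spec <- function(arena_id = "arena1", center = c(0, 0), diameter = 30,
                       barrier_thickness = 1.5,
                       compartments = c("left", "right")) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)),
            is.numeric(diameter), diameter > 0,
            is.numeric(barrier_thickness), barrier_thickness >= 0,
            barrier_thickness < diameter,
            length(compartments) == 2, !anyDuplicated(compartments))
  structure(list(arena_id = as.character(arena_id),
                 center = as.numeric(center),
                 diameter = as.numeric(diameter),
                 barrier_thickness = as.numeric(barrier_thickness),
                 compartments = as.character(compartments)),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec %s: %g mm diameter, %g mm barrier, compartments %s|%s>\n",
              x$arena_id, x$diameter, x$barrier_thickness,
              x$compartments[1], x$compartments[2]))
  invisible(x)
}

#' Specify an interaction barrier and its sensory channels
#'
#' The four barrier types gate which cues can pass between compartments:
#' clear acrylic passes visual cues, black acrylic blocks them; "open"
#' barriers have airflow channels passing olfactory cues, "solid" barriers
#' do not.
#'
#' @param barrier_type One of `"open_clear"`, `"solid_clear"`,
#'   `"open_black"`, `"solid_black"`.
#' @return An object of class `barrier_spec` with logical fields
#'   `allows_vision` and `allows_olfaction`.
#' @export
barrier_spec <- function(barrier_type = c("open_clear", "solid_clear",
                                          "open_black", "solid_black")) {
  barrier_type <- match.arg(barrier_type)
  allows_vision <- barrier_type %in% c("open_clear", "solid_clear")
  allows_olfaction <- barrier_type %in% c("open_clear", "open_black")
  structure(list(barrier_type = barrier_type,
                 allows_vision = allows_vision,
                 allows_olfaction = allows_olfaction),
            class = "barrier_spec")
}

#' @export
print.barrier_spec <- function(x, ...) {
  cat(sprintf("<barrier_spec %s: vision=%s, olfaction=%s>\n", x$barrier_type,
              x$allows_vision, x$allows_olfaction))
  invisible(x)
}

# Internal: sign of a compartment's x half-plane (-1 for compartments[1]).
.compartment_sign <- function(arena, compartment) {
  i <- match(compartment, arena$compartments)
  if (is.na(i)) {
    stop(sprintf("unknown compartment '%s' (arena has: %s)", compartment,
                 paste(arena$compartments, collapse = ", ")), call. = FALSE)
  }
  c(-1, 1)[i]
}

#' Barrier face segment of one compartment
#'
#' Each compartment sees its own face of the barrier: the chord-parallel
#' segment offset by half the barrier thickness from the bisector, clipped
#' to the arena circle.
#'
#' @param arena An [arena_spec()].
#' @param compartment Compartment label.
#' @return A 2x2 matrix; rows are the segment endpoints (x, y) in mm.
#' @export
barrier_face <- function(arena, compartment) {
  sgn <- .compartment_sign(arena, compartment)
  R <- arena$diameter / 2
  xo <- sgn * arena$barrier_thickness / 2
  h <- sqrt(max(R^2 - (arena$barrier_thickness / 2)^2, 0))
  cbind(x = arena$center[1] + c(xo, xo), y = arena$center[2] + c(-h, h))
}

#' Distance from a centroid to its compartment's barrier face
#'
#' Euclidean point-to-segment distance from a fly centroid to the face of
#' the interaction barrier bounding its own compartment. Samples outside the
#' arena circle or on the wrong side of the barrier are flagged out-of-bounds
#' and returned as `NA` (the caller decides whether to drop or clip them).
#'
#' @param position Numeric length-2 point, or an n x 2 matrix of points (mm).
#' @param arena An [arena_spec()].
#' @param compartment Compartment label the fly occupies.
#' @param tol Numerical tolerance (mm) for the in-compartment check.
#' @return Numeric vector of distances in mm; `NA` for out-of-bounds samples.
#' @export
barrier_distance <- function(position, arena, compartment, tol = 1e-6) {
  stopifnot(inherits(arena, "arena_spec"))
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  stopifnot(ncol(pos) == 2)
  sgn <- .compartment_sign(arena, compartment)
  R <- arena$diameter / 2
  xo <- arena$barrier_thickness / 2
  h <- sqrt(max(R^2 - xo^2, 0))
  px <- pos[, 1] - arena$center[1]
  py <- pos[, 2] - arena$center[2]
  inside <- (px^2 + py^2 <= (R + tol)^2) & (sgn * px >= xo - tol)
  # the face is the vertical segment x = sgn*xo, |y| <= h
  d <- sqrt((px - sgn * xo)^2 + pmax(abs(py) - h, 0)^2)
  d[!inside] <- NA_real_
  n_oob <- sum(!inside & is.finite(px))
  if (n_oob > 0) {
    warning(sprintf("%d sample(s) out of bounds for compartment '%s'; returned NA",
                    n_oob, compartment), call. = FALSE)
  }
  d
}

#' Y-maze arena specification
#'
#' Symmetric Y-shaped maze: three arms at 120 degree spacing with circular
#' arm ends. Defaults follow the standard array: 15.5 mm arms, 5.2 mm ends.
#'
#' @param arm_length Arm length in mm.
#' @param arm_end_diameter Diameter of the circular arm ends in mm.
#' @param center Numeric length-2, maze center in mm.
#' @param arm_angles Angular positions (degrees) of the three arm axes,
#'   listed in clockwise order so that arm `k+1` is the clockwise neighbor
#'   of arm `k`. Default: 90, -30, -150.
#' @return An object of class `ymaze_spec`.
#' @export
ymaze_spec <- function(arm_length = 15.5, arm_end_diameter = 5.2,
                       center = c(0, 0), arm_angles = c(90, -30, -150)) {
  stopifnot(arm_length > 0, arm_end_diameter > 0, length(center) == 2,
            length(arm_angles) == 3)
  structure(list(arm_length = arm_length, arm_end_diameter = arm_end_diameter,
                 center = as.numeric(center), arm_angles = as.numeric(arm_angles)),
            class = "ymaze_spec")
}
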