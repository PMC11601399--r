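#' Preferred angles of a ring layer
#'
#' Neuron k (1-based) prefers angle \code{2*pi*(k-1)/ring_size}.
#'
#' @param ring_size Number of neurons on the ring.
#' @return Radian angles in [0, 2*pi).
#' @export
ringAngles <- function(ring_size) {
  2 * pi * (seq_len(ring_size) - 1) / ring_size
}

#' Wrap an angle to [0, 2*pi)
#' @param a Angle(s) in radians.
#' @return Wrapped angle(s).
#' @export
wrapAngle <- function(a) a %% (2 * pi)

#' Smallest signed angular difference in radians
#' @param a,b Angles in radians.
#' @return \code{a - b} wrapped to [-pi, pi).
#' @keywords internal
circDiff <- function(a, b) ((a - b + pi) %% (2 * pi)) - pi

#' Encode a color angle as a population bump
#'
#' Circular Gaussian activity profile over a ring of color-tuned neurons,
#' peak-normalized to 1. With the defaults (20 neurons, tuning width 0.875
#' rad, activity floor 0.2) roughly half the ring - about 10 of 20 neurons -
#' is active above the floor.
#'
#' @param angle Color angle in radians (wrapped internally).
#' @param ring_size Number of neurons (>= 4).
#' @param tuning_width Gaussian tuning width sigma in radians (> 0).
#' @return Activity vector in [0, 1] of length \code{ring_size}.
#' @export
encodeColor <- function(angle, ring_size = 20, tuning_width = 0.875) {
  stopifnot(ring_size >= 4, tuning_width > 0)
  d <- circDiff(ringAngles(ring_size), wrapAngle(angle))
  exp(-d^2 / (2 * tuning_width^2))
}

#' Decode an angle from population activity
#'
#' Activity-weighted circular mean (population vector / resultant angle).
#'
#' @param activities Non-negative activity vector.
#' @param preferred_angles Preferred angle of each neuron (radians);
#'   defaults to a uniform ring.
#' @param floor Activity floor; if no activity exceeds it, no decode is
#'   possible and \code{NA} is returned (callers treat that as a
#'   non-response).
#' @return Decoded angle in [0, 2*pi), or \code{NA_real_}.
#' @export
decodePopulation <- function(activities,
                             preferred_angles = ringAngles(length(activities)),
                             floor = 0.1) {
  stopifnot(length(activities) == length(preferred_angles))
  a <- pmax(activities, 0)
  if (!any(a > floor)) return(NA_real_)
  wrapAngle(atan2(sum(a * sin(preferred_angles)),
                  sum(a * cos(preferred_angles))))
}

#' Signed circular error in degrees
#'
#' Shortest signed arc from target to response, on the half-open
#' convention [-180, 180) (so a 180-degree error reports as -180).
#'
#' @param response_angle,target_angle Radians.
#' @return Signed error in degrees.
#' @export
signedCircularError <- function(response_angle, target_angle) {
  stopifnot(is.finite(response_angle), is.finite(target_angle))
  d <- (response_angle - target_angle) * 180 / pi
  ((d + 180) %% 360) - 180
}

#' Reward from recall error
#'
#' Linear in absolute error, crossing zero at 90 degrees and clipped to
#' [-1, 1]: perfect recall earns +1, chance-level (uniform) responding is
#' reward-neutral in expectation, and errors beyond 90 degrees are punished.
#'
#' @param error_deg Signed error in degrees, in [-180, 180).
#' @return Reward in [-1, 1].
#' @export
rewardFromError <- function(error_deg) {
  stopifnot(all(error_deg >= -180), all(error_deg < 180))
  pmin(1, pmax(-1, 1 - abs(error_deg) / 90))
}

#' Generate a continuous-report episode
#'
#' \code{set_size} store trials - each pairing an iid uniform color angle
#' with a distinct discrete orientation - followed by one recall trial
#' probing a uniformly chosen stored orientation.
#'
#' @param set_size Number of items to store (N >= 1).
#' @param n_orientations Size of the discrete orientation inventory
#'   (>= \code{set_size}).
#' @param include_ignore Reserved; ignore trials are supported by the trial
#'   type but disabled by default.
#' @return A list of class \code{episode_spec} with elements
#'   \code{set_size}, \code{orientations} (0-based ids), \code{colors}
#'   (radians), \code{probe_index} (1-based index of the probed store
#'   trial), \code{probe_orientation}, \code{target_angle} and \code{lag}
#'   (intervening store trials between the probed item and recall).
#' @export
makeEpisode <- function(set_size, n_orientations = 8,
                        include_ignore = FALSE) {
  stopifnot(set_size >= 1)
  if (set_size > n_orientations)
    stop("set_size exceeds the orientation inventory (n_orientations)")
  oris <- sample.int(n_orientations, set_size) - 1L
  cols <- stats::runif(set_size, 0, 2 * pi)
  probe <- sample.int(set_size, 1)
  structure(list(set_size = as.integer(set_size),
                 orientations = oris,
                 colors = cols,
                 probe_index = probe,
                 probe_orientation = oris[probe],
                 target_angle = cols[probe],
                 lag = as.integer(set_size - probe)),
            class = "episode_spec")
}
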