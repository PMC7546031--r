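# Single shared implementation of the filopodium dynamics rules. Both the
# ground-truth labeller of the scene generator and the classifier applied to
# traced tracks call this function, so recovery tests compare like with like.
#
# Rules, applied to a per-frame length series (um; 0 or < min_length = absent):
#   * a dynamic event is counted at a frame where a filopodium of length
#     >= min_length first appears, where an existing one disappears, or where
#     its length changes by more than `change_fraction` relative to the
#     previous frame;
#   * a filopodium is stable iff it is present (>= min_length) at every frame
#     of the window and its length never ranges by more than `change_fraction`
#     of the series minimum.
dynamics_rules <- function(lengths, min_length = 1.0, change_fraction = 0.5) {
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths < 0)) {
    stop("lengths must be finite and >= 0 (0 encodes absent)")
  }
  if (min_length <= 0) stop("min_length must be > 0")
  if (change_fraction <= 0) stop("change_fraction must be > 0")
  present <- lengths >= min_length
  n <- length(lengths)
  events <- 0L
  if (n >= 2L) {
    for (i in 2:n) {
      if (!present[i - 1L] && present[i]) {
        events <- events + 1L # appearance
      } else if (present[i - 1L] && !present[i]) {
        events <- events + 1L # disappearance
      } else if (present[i - 1L] && present[i] &&
                 abs(lengths[i] - lengths[i - 1L]) / lengths[i - 1L] >
                 change_fraction) {
        events <- events + 1L # > change_fraction extension or retraction
      }
    }
  }
  stable <- all(present) &&
    (max(lengths) - min(lengths)) / min(lengths) <= change_fraction
  list(dynamic_events = events, stable = stable)
}

#' Ground-truth dynamics labels for a scripted length series
#'
#' Applies the identical rule set as [classify_dynamics()] (one shared
#' implementation) directly to a ground-truth per-frame length series, giving
#' the oracle labels that recovery tests compare against.
#'
#' @param lengths per-frame filopodium lengths in um; 0 encodes absent.
#' @param min_length minimum length (um) for a protrusion to count as a
#'   filopodium; default 1.0.
#' @param change_fraction relative length change that counts as an
#'   extension/retraction event and bounds stability; default 0.5.
#' @return list with `dynamic_events` (integer count) and `stable` (flag).
#' @export
truth_event_labels <- function(lengths, min_length = 1.0, change_fraction = 0.5) {
  dynamics_rules(lengths, min_length, change_fraction)
}
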