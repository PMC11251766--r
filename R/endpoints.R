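#' Detect end-expiratory and end-inspiratory instants in a volume signal
#'
#' Finds the `n_peaks` most prominent local maxima (end inspiration, IN) and
#' local minima (end expiration, EX) of the enclosed-volume signal, subject
#' to a minimum temporal separation. Prominence is the classical topographic
#' definition: the drop from a peak down to the highest saddle separating it
#' from any higher peak. With `policy = "consecutive"` the earliest
#' `n_peaks` qualifying extrema are taken instead (consecutive breaths).
#' Ties are broken by earlier time. Frames flagged missing are bridged by
#' linear interpolation for detection only.
#'
#' @param signal A `breath_signal` tibble from [volume_signal()].
#' @param min_period_s Minimum separation between selected extrema of the
#'   same sign, seconds (default 1.5).
#' @param n_peaks Number of extrema of each sign to select (default 2).
#' @param policy `"prominent"` (default) or `"consecutive"`.
#' @param smooth_window Optional moving-average window (frames, odd); 0 = no
#'   smoothing (default).
#' @return An `endpoint_set` tibble: columns `subject_id`, `condition`,
#'   `instant` (`EX`/`IN`), `cycle`, `frame`, `time_s`, `volume_mm3`.
#' @export
detect_endpoints <- function(signal, min_period_s = 1.5, n_peaks = 2,
                             policy = c("prominent", "consecutive"),
                             smooth_window = 0) {
  policy <- match.arg(policy)
  if (min_period_s <= 0) stop_invalid("`min_period_s` must be > 0.")
  v <- signal$volume_mm3
  t <- signal$time_s
  if (anyNA(v)) {
    ok <- !is.na(v)
    if (sum(ok) < 3) stop_invalid("Too few complete frames for endpoint detection.",
                                  class = "respmorph_detection")
    v <- stats::approx(t[ok], v[ok], xout = t, rule = 2)$y
  }
  if (smooth_window > 1) {
    kern <- rep(1 / smooth_window, smooth_window)
    v <- stats::filter(v, kern, sides = 2)
    v <- as.numeric(v)
    v[is.na(v)] <- signal$volume_mm3[is.na(v)] # edges keep raw values
  }
  if (diff(range(v)) == 0) {
    stop_invalid("Volume signal is constant; no breathing endpoints detectable.",
                 class = "respmorph_detection")
  }
  dt <- stats::median(diff(t))
  min_sep <- max(1L, as.integer(round(min_period_s / dt)))

  pick <- function(x) { # maxima of x
    cand <- local_maxima(x)
    if (!length(cand)) {
      stop_invalid("No local extrema found in volume signal.", class = "respmorph_detection")
    }
    if (policy == "consecutive") {
      sel <- integer(0)
      for (i in cand) if (!length(sel) || i - sel[length(sel)] >= min_sep) sel <- c(sel, i)
      sel <- head(sel, n_peaks)
    } else {
      prom <- peak_prominence(x, cand)
      ord <- cand[order(-prom, cand)] # prominence desc, earlier first on ties
      sel <- integer(0)
      for (i in ord) {
        if (all(abs(i - sel) >= min_sep)) sel <- c(sel, i)
        if (length(sel) == n_peaks) break
      }
      sel <- sort(sel)
    }
    if (length(sel) < n_peaks) {
      stop_invalid(sprintf("Found only %d/%d separable extrema; signal too short or min_period_s too large.",
                           length(sel), n_peaks), class = "respmorph_detection")
    }
    sel
  }
  ins <- pick(v)
  exs <- pick(-v)
  frames <- c(exs, ins)
  out <- tibble::new_tibble(list(
    subject_id = rep(signal$subject_id[1], length(frames)),
    condition = rep(signal$condition[1], length(frames)),
    time_s = t[frames], volume_mm3 = signal$volume_mm3[frames],
    instant = rep(c("EX", "IN"), c(length(exs), length(ins))),
    cycle = c(seq_along(exs), seq_along(ins)),
    frame = frames), nrow = length(frames))
  class(out) <- c("endpoint_set", class(out))
  out
}

local_maxima <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  which(x[i] > x[i - 1] & x[i] >= x[i + 1]) + 1L
}

# topographic prominence of each peak: height above the highest saddle on the
# way to a strictly higher peak (or the global floor at the signal borders)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    right <- x[seq(p + 1, length(x))]
    lh <- which(left > h); rh <- which(right > h)
    lmin <- if (length(lh)) min(left[(max(lh) + 1):length(left)]) else min(c(left, h))
    rmin <- if (length(rh)) min(right[seq_len(min(rh) - 1)]) else min(c(right, h))
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Extract landmark configurations at breathing endpoints
#'
#' Returns the marker configuration of the trajectory at each detected
#' end-expiratory/end-inspiratory frame, tagged with `instant` and `cycle`.
#' Markers missing at an endpoint frame are kept as `NA` and should be
#' filled with [estimate_missing()] before morphometric analysis.
#'
#' @param traj A `trajectory_set`.
#' @param endpoints An `endpoint_set` for the same subject and condition.
#' @return Tidy configurations tibble (one row per marker per endpoint).
#' @export
extract_breath_configs <- function(traj, endpoints) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (any(endpoints$frame < 1 | endpoints$frame > dim(traj$coords)[1])) {
    stop_invalid("Endpoint frames outside trajectory range.")
  }
  out <- purrr::pmap(list(endpoints$instant, endpoints$cycle, endpoints$frame),
    function(instant, cycle, frame) {
      m <- traj$coords[frame, , , drop = TRUE]
      rownames(m) <- traj$marker_ids
      as_config_tibble(m, list(subject_id = traj$subject_id, posture = traj$posture,
                               condition = traj$condition, instant = instant,
                               cycle = cycle))
    })
  bind_rows(out)
}
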