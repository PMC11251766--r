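#' Specify a synthetic breathing cohort
#'
#' Bundles and validates the parameters of the synthetic chest-wall motion
#' generator. One spec describes one posture group measured in both breathing
#' conditions (QB: quiet breathing; REC: recovery breathing after exercise,
#' with larger compartment-specific amplitudes).
#'
#' The breathing model displaces every marker radially about the torso's
#' cranio-caudal axis: `r(t) = r0 * (1 + a * sin(2 pi f t))`, with `a` the
#' thoracic or abdominal fractional amplitude of the condition. End
#' expiration is the sine trough (phase 3pi/2) and end inspiration the crest
#' (phase pi/2). On top of this, each subject gets a fixed random template
#' perturbation, a rigid posture rotation (anterior flexion for SIT-like,
#' slight extension for STA-like), a random placement in the laboratory
#' frame, additive Gaussian marker noise, and contiguous dropout runs that
#' mimic marker occlusion.
#'
#' @param n_subjects Number of subjects.
#' @param posture `"SIT"` (ergometer-like, flexed) or `"STA"` (standing).
#' @param flexion_angle_deg Anterior trunk flexion (positive) or extension
#'   (negative) at the cranial end, degrees. Default 12 for SIT, -3 for STA.
#'   Applied as a progressive bend about the mediolateral axis (rotation
#'   angle grows linearly with height), so posture is a genuine shape
#'   change that survives Procrustes alignment, not a rigid tilt.
#' @param flexion_sd Between-subject sd of the flexion angle, degrees
#'   (default 4).
#' @param breathing_rate_hz Breathing frequency (breaths per second).
#' @param amp_thoracic_QB,amp_abdominal_QB,amp_thoracic_REC,amp_abdominal_REC
#'   Fractional radial expansion amplitudes (dimensionless, >= 0).
#' @param subject_aspect_sd Between-subject sd of the log anisotropic torso
#'   scale factors (tall/flat/narrow vs short/deep/wide trunks; default
#'   0.033).
#' @param subject_shape_sd Per-subject unstructured template perturbation
#'   sd, mm.
#' @param noise_sd Additive marker noise sd, mm.
#' @param dropout_prob Stationary per-frame per-marker missing probability.
#' @param sampling_rate_hz Sampling rate, Hz (60 SIT-like, 100 STA-like).
#' @param duration_s Recording duration, s (must cover >= 3 breath cycles).
#' @param seed Integer seed driving all randomness of the cohort.
#' @param template Marker template tibble; default [cw_template()].
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 14,
                        posture = c("SIT", "STA"),
                        flexion_angle_deg = NULL, flexion_sd = 4,
                        breathing_rate_hz = 0.25,
                        amp_thoracic_QB = 0.008, amp_abdominal_QB = 0.012,
                        amp_thoracic_REC = 0.035, amp_abdominal_REC = 0.045,
                        subject_aspect_sd = 0.033,
                        subject_shape_sd = 5, noise_sd = 0.5,
                        dropout_prob = 0.01,
                        sampling_rate_hz = NULL, duration_s = 20,
                        seed = 1L, template = cw_template()) {
  posture <- match.arg(posture)
  flexion_angle_deg <- flexion_angle_deg %||% if (posture == "SIT") 12 else -3
  sampling_rate_hz <- sampling_rate_hz %||% if (posture == "SIT") 60 else 100
  amps <- c(amp_thoracic_QB, amp_abdominal_QB, amp_thoracic_REC, amp_abdominal_REC)
  if (any(!is.finite(amps)) || any(amps < 0)) stop_invalid("Amplitudes must be finite and >= 0.")
  if (dropout_prob < 0 || dropout_prob >= 1) stop_invalid("`dropout_prob` must be in [0, 1).")
  if (noise_sd < 0 || subject_shape_sd < 0 || subject_aspect_sd < 0 || flexion_sd < 0) {
    stop_invalid("Noise and shape sds must be >= 0.")
  }
  if (sampling_rate_hz <= 2 * breathing_rate_hz) {
    stop_invalid("`sampling_rate_hz` must exceed twice the breathing rate (Nyquist).")
  }
  if (duration_s * breathing_rate_hz < 3) {
    stop_invalid("`duration_s` must cover at least 3 full breath cycles.")
  }
  if (n_subjects < 1) stop_invalid("Need at least one subject.")
  structure(list(n_subjects = as.integer(n_subjects), posture = posture,
                 flexion_angle_deg = flexion_angle_deg, flexion_sd = flexion_sd,
                 breathing_rate_hz = breathing_rate_hz,
                 amp_thoracic_QB = amp_thoracic_QB, amp_abdominal_QB = amp_abdominal_QB,
                 amp_thoracic_REC = amp_thoracic_REC, amp_abdominal_REC = amp_abdominal_REC,
                 subject_aspect_sd = subject_aspect_sd,
                 subject_shape_sd = subject_shape_sd, noise_sd = noise_sd,
                 dropout_prob = dropout_prob, sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s, seed = as.integer(seed),
                 template = template),
            class = "cohort_spec")
}

new_trajectory_set <- function(subject_id, condition, posture, sampling_rate_hz,
                               marker_ids, coords, missing, time_s) {
  structure(list(subject_id = subject_id, condition = condition, posture = posture,
                 sampling_rate_hz = sampling_rate_hz, marker_ids = marker_ids,
                 coords = coords, missing = missing, time_s = time_s),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> subject %s, %s/%s, %d frames x %d markers @ %g Hz (%.2f%% missing)\n",
              x$subject_id, x$posture, x$condition, dim(x$coords)[1],
              length(x$marker_ids), x$sampling_rate_hz, 100 * mean(x$missing)))
  invisible(x)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
# contiguous occlusion runs: two-state Markov chain with geometric run lengths
# (mean visible run set so the stationary missing probability equals p)
dropout_mask <- function(n_frames, n_markers, p, fs, mean_run_s = 0.3) {
  mask <- matrix(FALSE, n_frames, n_markers)
  if (p <= 0) return(mask)
  run <- max(1, round(mean_run_s * fs))
  p_exit <- 1 / run
  p_enter <- p * p_exit / (1 - p)
  for (m in seq_len(n_markers)) {
    state <- runif(1) < p
    f <- 1L
    while (f <= n_frames) {
      len <- 1L + stats::rgeom(1, if (state) p_exit else p_enter)
      len <- min(len, n_frames - f + 1L)
      if (state) mask[f:(f + len - 1L), m] <- TRUE
      f <- f + len
      state <- !state
    }
  }
  mask
}

breathing_config <- function(base, region_amp, phase_value) {
  # radial scaling about the torso z-axis in the template frame
  g <- 1 + region_amp * phase_value
  cbind(base[, 1] * g, base[, 2] * g, base[, 3])
}

#' Simulate an OEP-like cohort with known ground truth
#'
#' Generates marker trajectories for every subject in both breathing
#' conditions (QB and REC) together with noise-free end-expiratory and
#' end-inspiratory configurations and the true functional size (FS),
#' functional shape (FSh) and tidal volume they imply.
#'
#' Reproducible: the same spec (including seed) yields bit-identical output.
#' Per-subject substreams are derived deterministically from the cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `trajectories` (list of `trajectory_set`, two
#'   per subject), `truth_configs` (tidy tibble of noise-free EX/IN
#'   configurations) and `truth_metrics` (tibble with `subject_id`,
#'   `condition`, `true_FS`, `true_FSh`, `true_tidal_volume`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tmpl <- spec$template
  base0 <- config_matrix(tmpl)
  k <- nrow(base0)
  region_th <- tmpl$region == "thoracic"
  fs <- spec$sampling_rate_hz
  nf <- as.integer(round(spec$duration_s * fs))
  time_s <- (seq_len(nf) - 1) / fs
  phase <- sin(2 * pi * spec$breathing_rate_hz * time_s)
  topo <- default_topology(tmpl)

  height <- max(base0[, 3])
  trajectories <- list()
  truth_cfg <- list()
  truth_met <- list()
  for (s in seq_len(spec$n_subjects)) {
    set.seed((spec$seed + 7919L * s) %% .Machine$integer.max)
    sid <- sprintf("%s%02d", spec$posture, s)
    # one dominant trunk-aspect factor: tall/flat/narrow vs short/deep/wide
    aspect <- rnorm(1, 0, spec$subject_aspect_sd)
    jitter <- rnorm(2, 0, spec$subject_aspect_sd / 4)
    scale3 <- c(exp(-aspect / 2 + jitter[1]), exp(-aspect / 2 + jitter[2]), exp(aspect))
    base <- sweep(base0, 2, scale3, `*`) +
      matrix(rnorm(3 * k, 0, spec$subject_shape_sd), k, 3)
    # progressive spinal bend: rotation about the mediolateral axis growing
    # linearly with height (a shape change, unlike a rigid tilt)
    flex_rad <- (spec$flexion_angle_deg + rnorm(1, 0, spec$flexion_sd)) * pi / 180
    theta <- flex_rad * base[, 3] / height
    ct <- cos(theta); st <- sin(theta)
    placement <- rot_z(runif(1, -15, 15))
    offset <- runif(3, -500, 500) * c(1, 1, 0)
    bend_place <- function(m) {
      ny <- m[, 2] * ct + m[, 3] * st
      nz <- m[, 3] * ct - m[, 2] * st
      cbind(m[, 1], ny, nz) %*% t(placement) +
        matrix(offset, nrow(m), 3, byrow = TRUE)
    }

    for (cond in c("QB", "REC")) {
      amp <- numeric(k)
      amp[region_th] <- spec[[paste0("amp_thoracic_", cond)]]
      amp[!region_th] <- spec[[paste0("amp_abdominal_", cond)]]

      ex_truth <- bend_place(breathing_config(base, amp, -1)) # sine phase 3pi/2
      in_truth <- bend_place(breathing_config(base, amp, +1)) # sine phase pi/2
      rownames(ex_truth) <- rownames(in_truth) <- tmpl$marker_id

      coords <- array(NA_real_, c(nf, k, 3))
      gx <- 1 + outer(phase, amp) # nf x k radial gains
      bx <- matrix(base[, 1], nf, k, byrow = TRUE) * gx
      by <- matrix(base[, 2], nf, k, byrow = TRUE) * gx
      bz <- matrix(base[, 3], nf, k, byrow = TRUE)
      CT <- matrix(ct, nf, k, byrow = TRUE); ST <- matrix(st, nf, k, byrow = TRUE)
      ny <- by * CT + bz * ST
      nz <- bz * CT - by * ST
      R <- placement
      coords[, , 1] <- bx * R[1, 1] + ny * R[1, 2] + nz * R[1, 3] + offset[1]
      coords[, , 2] <- bx * R[2, 1] + ny * R[2, 2] + nz * R[2, 3] + offset[2]
      coords[, , 3] <- bx * R[3, 1] + ny * R[3, 2] + nz * R[3, 3] + offset[3]
      if (spec$noise_sd > 0) {
        coords <- coords + array(rnorm(length(coords), 0, spec$noise_sd), dim(coords))
      }
      mask <- dropout_mask(nf, k, spec$dropout_prob, fs)
      for (d in 1:3) coords[, , d][mask] <- NA_real_

      trajectories[[paste(sid, cond, sep = "_")]] <-
        new_trajectory_set(sid, cond, spec$posture, fs, tmpl$marker_id,
                           coords, mask, time_s)

      cs_ex <- centroid_size(ex_truth); cs_in <- centroid_size(in_truth)
      truth_met[[paste(sid, cond)]] <- tibble(
        subject_id = sid, posture = spec$posture, condition = cond,
        true_FS = cs_in - cs_ex,
        true_FSh = procrustes_distance(ex_truth, in_truth, align = TRUE),
        true_tidal_volume = signed_volume(in_truth, topo$triangles) -
          signed_volume(ex_truth, topo$triangles))
      truth_cfg[[paste(sid, cond, "EX")]] <-
        as_config_tibble(ex_truth, list(subject_id = sid, posture = spec$posture,
                                        condition = cond, instant = "EX"))
      truth_cfg[[paste(sid, cond, "IN")]] <-
        as_config_tibble(in_truth, list(subject_id = sid, posture = spec$posture,
                                        condition = cond, instant = "IN"))
    }
  }
  list(trajectories = trajectories,
       truth_configs = bind_rows(truth_cfg),
       truth_metrics = bind_rows(truth_met))
}
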