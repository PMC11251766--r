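# Shared fixtures, built in code at test time.

tiny_cohort <- function(n_subjects = 3, noise_sd = 0, dropout_prob = 0,
                        subject_shape_sd = 4, duration_s = 16, seed = 42, ...) {
  cohort_spec(n_subjects = n_subjects, noise_sd = noise_sd,
              dropout_prob = dropout_prob, subject_shape_sd = subject_shape_sd,
              duration_s = duration_s, seed = seed, ...)
}

# simulate -> volumes -> endpoints -> configurations, as a tidy tibble
extract_cohort_configs <- function(sim, topo, min_period_s = 1.5) {
  dplyr::bind_rows(lapply(sim$trajectories, function(tr) {
    sig <- volume_signal(tr, topo)
    ep <- detect_endpoints(sig, min_period_s = min_period_s)
    extract_breath_configs(tr, ep)
  }))
}

# centroid sizes of every configuration in a tidy configurations tibble
cohort_cs_table <- function(configs) {
  configs |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("subject_id", "posture", "condition", "instant", "cycle")))) |>
    dplyr::summarise(
      centroid_size = centroid_size(dplyr::pick("marker_id", "x", "y", "z")),
      .groups = "drop")
}

# per-subject FS table of one simulated cohort; fast path used by the
# statistical-calibration checks
cohort_fs <- function(spec, min_period_s = 1.5, topo = NULL) {
  sim <- simulate_cohort(spec)
  topo <- topo %||% default_topology(spec$template)
  configs <- extract_cohort_configs(sim, topo, min_period_s = min_period_s)
  functional_size(cohort_cs_table(configs))
}

# same volume -> endpoints -> CS -> FS computation on matrix slices directly,
# skipping the tidy configuration layer (validated elsewhere); used where
# hundreds of cohorts are simulated
cohort_fs_fast <- function(spec, min_period_s = 1.5, topo = NULL) {
  sim <- simulate_cohort(spec)
  topo <- topo %||% default_topology(spec$template)
  rows <- lapply(sim$trajectories, function(tr) {
    ep <- detect_endpoints(volume_signal(tr, topo), min_period_s = min_period_s)
    cs <- vapply(ep$frame, function(f) centroid_size(tr$coords[f, , , drop = TRUE]),
                 numeric(1))
    tibble::tibble(subject_id = tr$subject_id, condition = tr$condition,
                   FS = mean(cs[ep$instant == "IN"]) - mean(cs[ep$instant == "EX"]))
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
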