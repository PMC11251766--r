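#' Configure an end-to-end analysis run
#'
#' Bundles everything [run_pipeline()] needs: either synthetic cohort specs
#' (one per posture group) or a directory of long-CSV trajectory files, the
#' endpoint-detection settings, the analysis scope, and the output
#' directory. The default design mirrors the two-posture study layout: 14
#' SIT-like subjects at 60 Hz and 13 STA-like subjects at 100 Hz, each
#' recorded in QB and REC.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohorts List of [cohort_spec()]s, one per posture group; default
#'   builds the 14 SIT + 13 STA design seeded from `seed`.
#' @param input_dir Directory of long-CSV trajectories to analyse instead of
#'   simulating (overrides `cohorts`).
#' @param scope `"both"` (default: joint GPA for exploration plus
#'   posture-specific GPAs for hypothesis testing), `"joint"`, or
#'   `"per-posture"`.
#' @param min_period_s,n_peaks,peak_policy Endpoint detection settings (see
#'   [detect_endpoints()]).
#' @param max_missing_frac Per-configuration refusal threshold for
#'   missing-landmark estimation.
#' @param pcs PCs used in the shape hypotheses (default `1:2`).
#' @param topology_file Optional JSON triangle list replacing the default
#'   template triangulation.
#' @param seed Integer master seed (drives cohort seeds when `cohorts` is
#'   `NULL`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, cohorts = NULL, input_dir = NULL,
                       scope = c("both", "joint", "per-posture"),
                       min_period_s = 1.5, n_peaks = 2,
                       peak_policy = "prominent", max_missing_frac = 0.2,
                       pcs = 1:2, topology_file = NULL, seed = 1L) {
  scope <- match.arg(scope)
  if (is.null(input_dir) && is.null(cohorts)) {
    cohorts <- list(
      SIT = cohort_spec(n_subjects = 14, posture = "SIT", seed = seed),
      STA = cohort_spec(n_subjects = 13, posture = "STA", seed = seed + 1000L)
    )
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop_invalid(sprintf("Input directory does not exist: %s", input_dir))
  }
  if (!is.null(topology_file) && !file.exists(topology_file)) {
    stop_invalid(sprintf("Topology file does not exist: %s", topology_file))
  }
  structure(list(out_dir = out_dir, cohorts = cohorts, input_dir = input_dir,
                 scope = scope, min_period_s = min_period_s, n_peaks = n_peaks,
                 peak_policy = peak_policy, max_missing_frac = max_missing_frac,
                 pcs = pcs, topology_file = topology_file, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full breathing-morphometrics pipeline
#'
#' Orchestrates simulate (or read) -> enclosed-volume signals -> endpoint
#' detection -> configuration extraction -> TPS missing-landmark estimation
#' -> GPA (joint and/or per posture) -> shape PCA -> FS/FSh -> Wilcoxon
#' hypothesis battery -> respiratory vectors -> mean-shape mesh warps, and
#' writes every intermediate as CSV (plus PLY warps and a JSON manifest)
#' under `config$out_dir`. Re-running the same configuration reproduces all
#' CSV outputs bit-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`configs`,
#'   `gpa_fits`, `pca_fits`, `cs_table`, `functional`, `tests`,
#'   `respiratory_vectors`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat(sprintf("respmorph %s run started\n", as.character(utils::packageVersion("respmorph"))),
      file = log_path)
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(sprintf("FAILED at stage '%s': %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "respmorph_stage_error")
    })
    logf("stage %-18s %6.2f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  template <- if (!is.null(config$cohorts)) config$cohorts[[1]]$template else cw_template()
  topo <- if (is.null(config$topology_file)) default_topology(template)
          else read_topology(config$topology_file)

  trajs <- stage("acquire", {
    if (!is.null(config$input_dir)) {
      paths <- list.files(config$input_dir, "\\.csv$", full.names = TRUE)
      if (!length(paths)) stop_invalid("No trajectory CSVs in input directory.")
      lapply(paths, read_trajectories)
    } else {
      sims <- lapply(config$cohorts, simulate_cohort)
      truth <- bind_rows(lapply(sims, `[[`, "truth_metrics"))
      readr::write_csv(truth, file.path(config$out_dir, "ground_truth.csv"), progress = FALSE)
      unlist(lapply(sims, `[[`, "trajectories"), recursive = FALSE)
    }
  })
  logf("trajectories: %d", length(trajs))

  extraction <- stage("extract", {
    res <- lapply(trajs, function(tr) {
      sig <- volume_signal(tr, topo)
      ep <- detect_endpoints(sig, min_period_s = config$min_period_s,
                             n_peaks = config$n_peaks, policy = config$peak_policy)
      list(endpoints = mutate(ep, posture = tr$posture),
           configs = extract_breath_configs(tr, ep))
    })
    list(endpoints = bind_rows(lapply(res, `[[`, "endpoints")),
         configs = bind_rows(lapply(res, `[[`, "configs")))
  })
  readr::write_csv(extraction$endpoints, file.path(config$out_dir, "endpoints.csv"),
                   progress = FALSE)

  configs <- stage("estimate-missing", {
    fill_missing_configs(extraction$configs, max_missing_frac = config$max_missing_frac)
  })
  write_configurations(configs, file.path(config$out_dir, "configurations.csv"))
  n_per_subject <- configs %>%
    distinct(.data$subject_id, .data$posture, .data$condition, .data$instant, .data$cycle) %>%
    dplyr::count(.data$subject_id)
  logf("configurations: %d (per subject: %s)", sum(n_per_subject$n),
       paste(unique(n_per_subject$n), collapse = ","))

  scopes <- switch(config$scope,
                   joint = "joint",
                   `per-posture` = unique(configs$posture),
                   both = c("joint", unique(configs$posture)))
  gpa_fits <- list(); pca_fits <- list()
  for (sc in scopes) {
    sub <- if (sc == "joint") configs else filter(configs, .data$posture == sc)
    fit <- stage(paste0("gpa-", sc), gpa(sub))
    pca <- stage(paste0("pca-", sc), shape_pca(fit))
    gpa_fits[[sc]] <- fit; pca_fits[[sc]] <- pca
    gd <- file.path(config$out_dir, paste0("gpa_", tolower(sc)))
    write_gpa(fit, gd)
    pd <- file.path(config$out_dir, paste0("pca_", tolower(sc)))
    dir.create(pd, showWarnings = FALSE)
    readr::write_csv(pca$scores, file.path(pd, "scores.csv"), progress = FALSE)
    readr::write_csv(tibble(pc = seq_along(pca$eigenvalues),
                            eigenvalue = pca$eigenvalues,
                            variance_fraction = pca$variance_fraction),
                     file.path(pd, "eigenvalues.csv"), progress = FALSE)
  }

  hyp_scopes <- setdiff(scopes, "joint")
  if (!length(hyp_scopes)) hyp_scopes <- "joint"
  cs_table <- gpa_fits[[scopes[1]]]$info # centroid sizes are scope-independent
  readr::write_csv(cs_table, file.path(config$out_dir, "centroid_sizes.csv"),
                   progress = FALSE)

  functional <- stage("functional-metrics", {
    fs <- functional_size(cs_table)
    fsh <- bind_rows(lapply(hyp_scopes, function(sc) functional_shape(gpa_fits[[sc]])))
    left_join(fs, fsh, by = intersect(names(fs), names(fsh)))
  })
  readr::write_csv(functional, file.path(config$out_dir, "functional_metrics.csv"),
                   progress = FALSE)

  scores <- bind_rows(lapply(hyp_scopes, function(sc) pca_fits[[sc]]$scores))
  tests <- stage("hypotheses", run_hypotheses(cs_table, functional, scores, pcs = config$pcs))
  readr::write_csv(tests, file.path(config$out_dir, "tests.csv"), progress = FALSE)

  rvec <- stage("respiratory-vectors", {
    bind_rows(lapply(names(pca_fits), function(sc) {
      mutate(respiratory_vectors(pca_fits[[sc]], pcs = config$pcs), scope = sc, .before = 1)
    }))
  })
  readr::write_csv(rvec, file.path(config$out_dir, "respiratory_vectors.csv"),
                   progress = FALSE)

  stage("warps", {
    wd <- file.path(config$out_dir, "warps")
    dir.create(wd, showWarnings = FALSE)
    tm <- template_mesh(template, topo)
    src <- config_matrix(template, topo$marker_ids)
    for (sc in hyp_scopes) {
      fit <- gpa_fits[[sc]]
      cells <- distinct(fit$info, .data$condition, .data$instant)
      for (i in seq_len(nrow(cells))) {
        rows <- which(fit$info$condition == cells$condition[i] &
                        fit$info$instant == cells$instant[i])
        target <- apply(fit$aligned[rows, , , drop = FALSE], c(2, 3), mean) *
          mean(fit$info$centroid_size[rows])
        rownames(target) <- fit$marker_ids
        warped <- warp_mesh(tm, src, target[topo$marker_ids, ])
        write_ply(warped, file.path(wd, sprintf("%s_%s_%s_mean.ply",
                                                tolower(sc), cells$condition[i],
                                                cells$instant[i])))
      }
    }
  })

  manifest <- list(
    package = "respmorph",
    version = as.character(utils::packageVersion("respmorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    scope = config$scope,
    n_trajectories = length(trajs),
    n_configurations = nrow(cs_table),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("run complete")
  invisible(list(configs = configs, gpa_fits = gpa_fits, pca_fits = pca_fits,
                 cs_table = cs_table, functional = functional, tests = tests,
                 respiratory_vectors = rvec, manifest = manifest))
}

#' Fill missing landmarks across a configuration set
#'
#' Applies [estimate_missing()] to every incomplete configuration, using the
#' subject-first reference policy of [complete_reference()].
#'
#' @param configs Tidy configurations tibble (NA coordinates = missing).
#' @param max_missing_frac Refusal threshold per configuration.
#' @return Completed configurations tibble, same row order.
#' @export
fill_missing_configs <- function(configs, max_missing_frac = 0.2) {
  parts <- configs_to_list(configs)
  incomplete <- which(vapply(parts$mats, anyNA, logical(1)))
  if (!length(incomplete)) return(configs)
  refs <- list()
  filled <- parts$mats
  for (i in incomplete) {
    subj <- parts$info$subject_id[i] %||% ""
    if (is.null(refs[[subj]])) refs[[subj]] <- complete_reference(configs, subj)
    cfg <- as_config_tibble(filled[[i]])
    est <- estimate_missing(cfg, refs[[subj]], max_missing_frac = max_missing_frac)
    filled[[i]] <- config_matrix(est)
  }
  out <- lapply(seq_along(filled), function(i) {
    m <- filled[[i]]
    rownames(m) <- parts$marker_ids
    as_config_tibble(m, as.list(parts$info[i, , drop = FALSE]))
  })
  bind_rows(out)
}

write_gpa <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(fit$aligned)[1]; k <- dim(fit$aligned)[2]
  flat <- t(vapply(seq_len(n), function(i) as.vector(t(fit$aligned[i, , ])), numeric(3 * k)))
  if (n == 1) flat <- matrix(flat, 1)
  colnames(flat) <- paste(rep(fit$marker_ids, each = 3), c("x", "y", "z"), sep = "_")
  readr::write_csv(bind_cols(fit$info, as_tibble(flat)),
                   file.path(dir, "aligned.csv"), progress = FALSE)
  readr::write_csv(as_config_tibble(fit$consensus), file.path(dir, "consensus.csv"),
                   progress = FALSE)
  dm <- as_tibble(as.data.frame(fit$distance_matrix), .name_repair = "minimal")
  names(dm) <- paste0("c", seq_len(ncol(dm)))
  readr::write_csv(dm, file.path(dir, "distances.csv"), progress = FALSE)
  writeLines(sprintf("configurations=%d landmarks=%d iterations=%d converged=%s tol=%g",
                     n, k, fit$iterations, fit$converged, fit$tol),
             file.path(dir, "log.txt"))
  invisible(dir)
}
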