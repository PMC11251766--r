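#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired Wilcoxon signed-rank test with the conventional
#' zero-difference drop. The exact distribution is used whenever the number
#' of non-zero differences is at most 25 and their absolute values are
#' untied; otherwise the normal approximation with continuity and tie
#' corrections is used. The p-value engine is `stats::wilcox.test()`; the
#' package's test suite cross-checks the exact branch against a full
#' 2^m sign-assignment enumeration.
#'
#' @param x,y Paired numeric samples of equal length (or `y = NULL` to test
#'   differences in `x` against zero).
#' @param method `"auto"` (default), `"exact"` or `"approx"`.
#' @return One-row tibble: `n_pairs`, `n_used` (non-zero differences),
#'   `statistic` (W, rank sum of positive differences), `p_value`,
#'   `direction` (sign of the median difference), `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1)) # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (is.null(y)) y <- rep(0, length(x))
  if (length(x) != length(y)) stop_invalid("Paired samples must have equal length.")
  d <- x - y
  d <- d[!is.na(d)]
  n_pairs <- length(d)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    stop_invalid("All paired differences are zero; the signed-rank test is degenerate.",
                 class = "respmorph_degenerate")
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- switch(method,
                  exact = TRUE,
                  approx = FALSE,
                  auto = m <= 25 && !ties)
  if (exact && ties) {
    stop_invalid("Exact method requested but |differences| contain ties.")
  }
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  md <- stats::median(d)
  tibble(n_pairs = n_pairs, n_used = m,
         statistic = unname(ht$statistic),
         p_value = ht$p.value,
         direction = if (md > 0) "greater" else if (md < 0) "less" else "zero",
         method = if (exact) "exact" else "approx")
}

significance_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Run the H1–H3 size and shape hypothesis battery
#'
#' Within each posture group, tests the three null hypotheses about size and
#' their shape analogues with paired two-sided Wilcoxon signed-rank tests:
#'
#' * **H1_size** — centroid size does not differ between EX and IN
#'   (tested within each breathing condition);
#' * **H2_size** — functional size (FS) does not differ between QB and REC;
#' * **H3_size** — centroid size at matched instants does not differ
#'   between QB and REC (tested at EX and at IN);
#' * **H1_shape** — PC scores (PC1 and PC2 of the posture-specific shape
#'   PCA) do not differ between EX and IN within each condition;
#' * **H2_shape** — functional shape (FSh) does not differ between QB and
#'   REC;
#' * **H3_shape** — PC scores at matched instants do not differ between QB
#'   and REC.
#'
#' Centroid sizes and PC scores are averaged over the two cycles per instant
#' before pairing, consistently with the FS/FSh definitions. Degenerate
#' cells (all differences zero) are reported with `NA` p-values and a note
#' rather than aborting the battery. No multiple-testing correction is
#' applied by default, matching the convention of reporting each hypothesis
#' at its nominal level; Holm adjustment across the battery is available.
#'
#' @param cs_table Tibble of centroid sizes (`subject_id`, `posture`,
#'   `condition`, `instant`, `cycle`, `centroid_size`).
#' @param functional Tibble with per subject x condition `FS` and `FSh`
#'   columns (join of [functional_size()] and [functional_shape()] output).
#' @param scores Tibble of PC scores with id columns, from posture-specific
#'   [shape_pca()] fits (may cover several postures).
#' @param pcs PCs tested in the shape hypotheses (default `1:2`).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Tibble with one row per test: `hypothesis`, `posture`,
#'   `contrast`, `variable`, `n_pairs`, `statistic`, `p_value`, `p_adj`,
#'   `direction`, `method`, `stars`, `note`.
#' @export
run_hypotheses <- function(cs_table, functional, scores, pcs = 1:2,
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  postures <- unique(cs_table$posture)
  pc_cols <- paste0("PC", pcs)

  cyc_mean <- function(df, value_col, extra = character(0)) {
    df %>%
      group_by(across(all_of(c("subject_id", "condition", "instant", extra)))) %>%
      summarise(value = mean(.data[[value_col]]), .groups = "drop")
  }

  paired_test <- function(df, split_col, a, b, hypothesis, posture, contrast, variable) {
    wide <- df %>%
      tidyr::pivot_wider(names_from = all_of(split_col), values_from = "value") %>%
      filter(!is.na(.data[[a]]) & !is.na(.data[[b]]))
    res <- tryCatch(wilcoxon_signed_rank(wide[[a]], wide[[b]]),
                    respmorph_degenerate = function(e) {
                      tibble(n_pairs = nrow(wide), n_used = 0L,
                             statistic = NA_real_, p_value = NA_real_,
                             direction = "zero", method = "none")
                    })
    dropped <- length(unique(df$subject_id)) - nrow(wide)
    if (dropped > 0) {
      inform(sprintf("%s %s %s: %d subject(s) excluded for incomplete pairing.",
                     hypothesis, posture, contrast, dropped))
    }
    bind_cols(tibble(hypothesis = hypothesis, posture = posture,
                     contrast = contrast, variable = variable),
              res,
              tibble(note = if (res$method == "none") "degenerate: all differences zero" else ""))
  }

  out <- list()
  for (po in postures) {
    cs_po <- filter(cs_table, .data$posture == po)
    cs_m <- cyc_mean(cs_po, "centroid_size")
    fun_po <- filter(functional, .data$posture == po)
    sc_po <- filter(scores, .data$posture == po)

    for (cond in unique(cs_m$condition)) { # H1_size
      out[[length(out) + 1]] <- paired_test(
        filter(cs_m, .data$condition == cond) %>% select(-"condition"),
        "instant", "IN", "EX", "H1_size", po, paste0("IN vs EX (", cond, ")"), "CS")
    }
    out[[length(out) + 1]] <- paired_test( # H2_size
      fun_po %>% select("subject_id", "condition", value = "FS"),
      "condition", "REC", "QB", "H2_size", po, "REC vs QB", "FS")
    for (inst in unique(cs_m$instant)) { # H3_size
      out[[length(out) + 1]] <- paired_test(
        filter(cs_m, .data$instant == inst) %>% select(-"instant"),
        "condition", "REC", "QB", "H3_size", po, paste0("REC vs QB (", inst, ")"), "CS")
    }
    for (pc in pc_cols) { # H1_shape
      sc_m <- cyc_mean(sc_po, pc)
      for (cond in unique(sc_m$condition)) {
        out[[length(out) + 1]] <- paired_test(
          filter(sc_m, .data$condition == cond) %>% select(-"condition"),
          "instant", "IN", "EX", "H1_shape", po, paste0("IN vs EX (", cond, ")"), pc)
      }
    }
    out[[length(out) + 1]] <- paired_test( # H2_shape
      fun_po %>% select("subject_id", "condition", value = "FSh"),
      "condition", "REC", "QB", "H2_shape", po, "REC vs QB", "FSh")
    for (pc in pc_cols) { # H3_shape
      sc_m <- cyc_mean(sc_po, pc)
      for (inst in unique(sc_m$instant)) {
        out[[length(out) + 1]] <- paired_test(
          filter(sc_m, .data$instant == inst) %>% select(-"instant"),
          "condition", "REC", "QB", "H3_shape", po, paste0("REC vs QB (", inst, ")"), pc)
      }
    }
  }
  res <- bind_rows(out)
  res$p_adj <- if (adjust == "holm") stats::p.adjust(res$p_value, "holm") else res$p_value
  res$stars <- significance_stars(res$p_adj)
  res
}
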