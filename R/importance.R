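#' Top-k markers by importance magnitude
#'
#' Ranks markers by `|importance|`, descending, ties broken by input
#' (marker) order, and returns the top `k` (capped at the vector length).
#'
#' @param importance named numeric vector of per-marker importances.
#' @param k number of markers to keep (default 1000).
#' @return tibble with columns `marker`, `importance`, `magnitude`, `rank`.
#' @export
top_k_select <- function(importance, k = 1000) {
  stopifnot(k >= 1)
  if (is.null(names(importance)))
    names(importance) <- paste0("M", seq_along(importance))
  mag <- abs(importance)
  ord <- order(-mag, seq_along(mag))
  keep <- ord[seq_len(min(k, length(importance)))]
  tibble::tibble(marker = names(importance)[keep],
                 importance = unname(importance[keep]),
                 magnitude = unname(mag[keep]),
                 rank = seq_along(keep))
}

#' Aggregate per-fold importances across outer folds
#'
#' Each fold's importance vector is reduced to its top-`k` magnitudes and
#' min-max normalized to `[0, 1]` over those magnitudes. Every marker that
#' reaches the top-k of at least one fold receives the average of its
#' normalized values across *all* folds, counting 0 where it is absent;
#' markers never in any top-k are excluded. A fold whose top-k magnitudes
#' are all equal contributes zeros (with a warning).
#'
#' @param fold_importances list of named numeric vectors (one per outer
#'   fold, same marker universe).
#' @param k top-k cutoff per fold (default 1000).
#' @return tibble with columns `marker`, `avg_importance`, `n_folds_top_k`,
#'   sorted by decreasing importance (ties by marker id).
#' @export
aggregate_across_folds <- function(fold_importances, k = 1000) {
  stopifnot(length(fold_importances) >= 1)
  n_folds <- length(fold_importances)
  norm_folds <- purrr::map(fold_importances, function(v) {
    top <- top_k_select(v, k)
    rng <- range(top$magnitude)
    if (rng[1] == rng[2]) {
      warning("constant importance vector in one fold contributes zeros")
      stats::setNames(rep(0, nrow(top)), top$marker)
    } else {
      stats::setNames((top$magnitude - rng[1]) / (rng[2] - rng[1]), top$marker)
    }
  })
  universe <- unique(unlist(purrr::map(norm_folds, names)))
  acc <- stats::setNames(rep(0, length(universe)), universe)
  cnt <- stats::setNames(rep(0L, length(universe)), universe)
  for (nf in norm_folds) {
    acc[names(nf)] <- acc[names(nf)] + nf
    cnt[names(nf)] <- cnt[names(nf)] + 1L
  }
  avg <- acc / n_folds
  tibble::tibble(marker = names(avg), avg_importance = unname(avg),
                 n_folds_top_k = unname(cnt)) |>
    dplyr::arrange(dplyr::desc(.data$avg_importance), .data$marker)
}

#' Filter aggregated importances relative to the maximum
#'
#' Retains markers whose `|avg_importance|` is at least
#' `fraction * max(|avg_importance|)`; raising the fraction never adds
#' markers.
#'
#' @param aggregated tibble from [aggregate_across_folds()].
#' @param fraction relative threshold in (0, 1) (default 0.01).
#' @export
relative_filter <- function(aggregated, fraction = 0.01) {
  stopifnot(fraction > 0, fraction < 1)
  if (nrow(aggregated) == 0) return(aggregated)
  thr <- fraction * max(abs(aggregated$avg_importance))
  dplyr::filter(aggregated, abs(.data$avg_importance) >= thr)
}

#' Score aggregated importances against the simulated ground truth
#'
#' Reproduces the per-model recovery statistics: the number of important
#' features (markers with nonzero fold-averaged importance), how many of
#' them are true background SNPs and the resulting true positive rate
#' (background SNPs found / important features), the detected causal SNPs
#' and their 1-based ranks among the important features (descending
#' averaged importance, ties by marker id) — each both unfiltered and
#' after the relative 1%-of-maximum filter.
#'
#' @param aggregated tibble from [aggregate_across_folds()].
#' @param truth ground-truth list of a `gs_phenotype` (fields
#'   `background_markers`, `causal_markers`, `gamma`, `beta`), or a
#'   `gs_phenotype` itself.
#' @param filter_fraction relative filter threshold (default 0.01).
#' @param model label echoed in the summary.
#' @return A `gs_importance_report`: list with `summary` (one-row tibble:
#'   `n_important`, `background_found`, `tpr`, `causal_detected`,
#'   `causal_total`, `causal_ranks`, and `*_filtered` variants) and
#'   `detail` (per-marker tibble with `avg_importance`, `is_causal`,
#'   `is_background`, `rank`).
#' @export
score_against_truth <- function(aggregated, truth, filter_fraction = 0.01,
                                model = "model") {
  if (inherits(truth, "gs_phenotype")) truth <- truth$truth
  important <- dplyr::filter(aggregated, .data$avg_importance != 0) |>
    dplyr::arrange(dplyr::desc(.data$avg_importance), .data$marker) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  is_causal = .data$marker %in% truth$causal_markers,
                  is_background = .data$marker %in% truth$background_markers)

  stats_of <- function(imp) {
    n_imp <- nrow(imp)
    bg <- sum(imp$is_background)
    detected <- imp$marker[imp$is_causal]
    ranks <- imp$rank[imp$is_causal]
    list(n_important = n_imp, background_found = bg,
         tpr = if (n_imp > 0) bg / n_imp else NA_real_,
         causal_detected = length(detected), ranks = sort(ranks))
  }
  unf <- stats_of(important)
  filt <- stats_of(
    important |>
      dplyr::filter(abs(.data$avg_importance) >=
                      filter_fraction * max(c(abs(important$avg_importance), 0))) |>
      dplyr::mutate(rank = dplyr::row_number()))

  summary <- tibble::tibble(
    model = model,
    n_important = unf$n_important,
    background_found = unf$background_found,
    tpr = unf$tpr,
    causal_detected = unf$causal_detected,
    causal_total = length(truth$causal_markers),
    causal_ranks = list(unf$ranks),
    n_important_filtered = filt$n_important,
    background_found_filtered = filt$background_found,
    tpr_filtered = filt$tpr,
    causal_detected_filtered = filt$causal_detected,
    causal_ranks_filtered = list(filt$ranks))
  structure(list(summary = summary, detail = important,
                 filter_fraction = filter_fraction),
            class = "gs_importance_report")
}

#' @export
print.gs_importance_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<gs_importance_report> %s: %d important features, TPR %.2f; causal %d/%d [%s]\n",
              s$model, s$n_important, s$tpr, s$causal_detected,
              s$causal_total,
              paste(s$causal_ranks[[1]], collapse = ",")))
  cat(sprintf("  after %g%%-of-max filter: %d features, TPR %.2f\n",
              100 * x$filter_fraction, s$n_important_filtered, s$tpr_filtered))
  invisible(x)
}

#' Correlate simulated effect sizes with aggregated importances
#'
#' Pairs the absolute simulated effect size of each marker (`beta` for
#' causal markers, `gamma` for background markers) with its fold-averaged
#' importance, keeps the markers where both are nonzero, and returns the
#' Pearson correlation and the paired table (the basis for the
#' effect-vs-importance scatter plots). The correlation is computed on the
#' untransformed pairs; plots may use log scales for display only.
#'
#' @param truth ground truth (as in [score_against_truth()]).
#' @param aggregated tibble from [aggregate_across_folds()].
#' @return list with `pearson_r` and `pairs` (tibble: `marker`, `effect`,
#'   `avg_importance`, `is_causal`).
#' @export
effect_importance_correlation <- function(truth, aggregated) {
  if (inherits(truth, "gs_phenotype")) truth <- truth$truth
  k <- length(truth$causal_markers)
  effects <- c(stats::setNames(abs(truth$beta[seq_len(k)]), truth$causal_markers),
               stats::setNames(abs(truth$gamma), truth$background_markers))
  tbl <- tibble::tibble(marker = names(effects), effect = unname(effects)) |>
    dplyr::inner_join(aggregated, by = "marker") |>
    dplyr::filter(.data$effect != 0, .data$avg_importance != 0) |>
    dplyr::mutate(is_causal = .data$marker %in% truth$causal_markers)
  if (nrow(tbl) < 3)
    stop("fewer than 3 markers with nonzero effect and importance; correlation undefined",
         call. = FALSE)
  list(pearson_r = stats::cor(tbl$effect, tbl$avg_importance),
       pairs = tbl)
}
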