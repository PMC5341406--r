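#' Per-cell interval slopes over the analysis window
#'
#' For every cell, computes the slopes between consecutive non-missing
#' samples inside the closed window `[t0_h, t1_h]` (actual time gaps in the
#' denominator, no imputation) and summarises them by mean and median.
#' Cells with fewer than two usable in-window samples — including cells that
#' died before the window opened — are flagged unusable rather than erroring.
#'
#' @param trajectories long-format trajectory tibble with columns
#'   `clone_id, cell_id, time_h, yfp` and optionally `fate`,
#'   `mitosis_times_h`.
#' @param config an [analysis_config()].
#' @return tibble with one row per cell: `clone_id, cell_id, fate, n_points,
#'   n_slopes, mean_slope, median_slope, central_slope, usable`.
#' @export
slope_summaries <- function(trajectories, config = analysis_config()) {
  stopifnot(all(c("clone_id", "cell_id", "time_h", "yfp") %in% names(trajectories)))
  if (!"fate" %in% names(trajectories)) trajectories$fate <- NA_character_
  tol <- 1e-9
  win <- trajectories |>
    filter(.data$time_h >= config$t0_h - tol,
           .data$time_h <= config$t1_h + tol,
           !is.na(.data$yfp)) |>
    arrange(.data$clone_id, .data$cell_id, .data$time_h)
  all_cells <- distinct(trajectories, .data$clone_id, .data$cell_id, .data$fate)
  s <- win |>
    group_by(.data$clone_id, .data$cell_id) |>
    summarise(n_points = n(),
              slopes = list(interval_slopes(.data$time_h, .data$yfp,
                                            config$slope_pairs)),
              .groups = "drop") |>
    mutate(n_slopes = map_int(.data$slopes, length),
           mean_slope = map_dbl(.data$slopes, function(s)
             if (length(s)) mean(s) else NA_real_),
           median_slope = map_dbl(.data$slopes, function(s)
             if (length(s)) median(s) else NA_real_),
           usable = .data$n_slopes >= 1) |>
    select(-"slopes")
  out <- all_cells |>
    left_join(s, by = c("clone_id", "cell_id")) |>
    mutate(n_points = ifelse(is.na(.data$n_points), 0L, .data$n_points),
           n_slopes = ifelse(is.na(.data$n_slopes), 0L, .data$n_slopes),
           usable = !is.na(.data$usable) & .data$usable,
           central_slope = if (config$central == "mean") .data$mean_slope
                           else .data$median_slope)
  as_tibble(out)
}

interval_slopes <- function(time_h, yfp, pairs = "consecutive") {
  if (length(time_h) < 2) return(numeric(0))
  if (pairs == "consecutive") {
    diff(yfp) / diff(time_h)
  } else {
    ij <- which(upper.tri(matrix(0, length(time_h), length(time_h))), arr.ind = TRUE)
    (yfp[ij[, 2]] - yfp[ij[, 1]]) / (time_h[ij[, 2]] - time_h[ij[, 1]])
  }
}

#' Split cells by the sign of their central slope
#'
#' Adds a `sign_group` column: `"pos"` for strictly positive central slopes,
#' `"neg"` otherwise (exact zeros join the non-increasing group, a fixed
#' convention for reproducibility); unusable cells get `NA`.
#'
#' @param summaries output of [slope_summaries()].
#' @return `summaries` with a `sign_group` column.
#' @export
split_by_sign <- function(summaries) {
  summaries |>
    mutate(sign_group = dplyr::case_when(
      !.data$usable | is.na(.data$central_slope) ~ NA_character_,
      .data$central_slope > 0 ~ "pos",
      TRUE ~ "neg"))
}

#' Minimum-group eligibility for the bimodality test
#'
#' A clone is eligible when both sign groups hold at least `n_min` cells.
#'
#' @param n_pos,n_neg sign-group sizes.
#' @param n_min minimum group size (the published procedure uses 10).
#' @return logical flag.
#' @export
check_eligibility <- function(n_pos, n_neg, n_min = 10) {
  n_pos >= n_min & n_neg >= n_min
}

#' Screen a panel of clones for bimodal dynamics
#'
#' Implements the bimodality definition: per-cell interval slopes over the
#' `[t0_h, t1_h]` window, sign-based splitting of cells into positive- and
#' negative-slope groups, removal of clones with fewer than `n_min` cells in
#' either group, the three-test consensus (Welch t, KS, Mann-Whitney)
#' comparing the two groups' central-slope distributions, and
#' Benjamini-Hochberg correction at `fdr_q` applied across eligible clones
#' (per test family by default). A clone is called bimodal when it is
#' eligible, all three raw p-values fall below `alpha`, and all three
#' survive BH.
#'
#' @param trajectories long-format trajectory tibble (see
#'   [slope_summaries()]).
#' @param config an [analysis_config()].
#' @return A tibble of class `bimodal_screen`, one row per clone:
#'   `clone_id, n_pos, n_neg, p_t, p_ks, p_mw, eligible, bh_t, bh_ks, bh_mw,
#'   is_bimodal`. The per-cell slope summaries are attached as attribute
#'   `"summaries"` and the configuration as `"config"`.
#' @examples
#' panel <- simulate_panel(6, 0.5, clone_config(n_cells = 60), seed = 3)
#' bimodality_screen(panel$trajectories)
#' @export
bimodality_screen <- function(trajectories, config = analysis_config()) {
  summaries <- split_by_sign(slope_summaries(trajectories, config))
  per_clone <- summaries |>
    filter(!is.na(.data$sign_group)) |>
    group_by(.data$clone_id) |>
    summarise(n_pos = sum(.data$sign_group == "pos"),
              n_neg = sum(.data$sign_group == "neg"),
              pos_slopes = list(.data$central_slope[.data$sign_group == "pos"]),
              neg_slopes = list(.data$central_slope[.data$sign_group == "neg"]),
              .groups = "drop") |>
    mutate(eligible = check_eligibility(.data$n_pos, .data$n_neg, config$n_min))

  tests <- pmap(list(per_clone$pos_slopes, per_clone$neg_slopes, per_clone$eligible),
                function(a, b, el) {
                  if (!el) return(tibble(p_t = NA_real_, p_ks = NA_real_,
                                         p_mw = NA_real_))
                  three_sample_tests(a, b)
                })
  res <- dplyr::bind_cols(select(per_clone, -"pos_slopes", -"neg_slopes"),
                          bind_rows(tests))
  res <- apply_bh_families(res, config)
  res <- res |>
    mutate(is_bimodal = .data$eligible &
             !is.na(.data$p_t) & .data$p_t < config$alpha &
             .data$p_ks < config$alpha & .data$p_mw < config$alpha &
             .data$bh_t & .data$bh_ks & .data$bh_mw) |>
    mutate(is_bimodal = !is.na(.data$is_bimodal) & .data$is_bimodal)
  structure(as_tibble(res), class = c("bimodal_screen", class(res)),
            summaries = summaries, config = config)
}

# BH across eligible clones, either per test family or pooled over 3m values.
apply_bh_families <- function(res, config) {
  res$bh_t <- res$bh_ks <- res$bh_mw <- FALSE
  el <- which(res$eligible & !is.na(res$p_t))
  if (length(el)) {
    if (config$bh_scope == "per_test") {
      res$bh_t[el] <- benjamini_hochberg(res$p_t[el], config$fdr_q)
      res$bh_ks[el] <- benjamini_hochberg(res$p_ks[el], config$fdr_q)
      res$bh_mw[el] <- benjamini_hochberg(res$p_mw[el], config$fdr_q)
    } else {
      pooled <- benjamini_hochberg(c(res$p_t[el], res$p_ks[el], res$p_mw[el]),
                                   config$fdr_q)
      m <- length(el)
      res$bh_t[el] <- pooled[seq_len(m)]
      res$bh_ks[el] <- pooled[m + seq_len(m)]
      res$bh_mw[el] <- pooled[2 * m + seq_len(m)]
    }
  }
  res
}
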