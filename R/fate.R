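#' Correlate slope dynamics with cell fate across bimodal clones
#'
#' For each selected clone, cells are divided by fate (died vs survived at
#' the end of the movie; censored cells are excluded) and the central-slope
#' distributions of the two fate groups are compared with the three-test
#' consensus. Benjamini-Hochberg correction at `fdr_q` is applied across the
#' analysed clones per test family. When a clone is significant in all three
#' tests (raw p < `alpha` and BH-passing), its direction is set by which
#' fate group has the larger median central slope; clones with a fate group
#' smaller than `fate_n_min` are flagged underpowered with direction
#' `"none"`.
#'
#' @param trajectories long-format trajectory tibble with a `fate` column
#'   (`"died"`, `"survived"`, anything else treated as censored).
#' @param screen optional [bimodality_screen()] result; when given, only
#'   clones with `is_bimodal = TRUE` are analysed.
#' @param config an [analysis_config()].
#' @return tibble of class `fate_screen`, one row per analysed clone:
#'   `clone_id, n_died, n_survived, p_t, p_ks, p_mw, bh_t, bh_ks, bh_mw,
#'   underpowered, direction`.
#' @export
fate_screen <- function(trajectories, screen = NULL, config = analysis_config()) {
  if (!is.null(screen)) {
    keep <- screen$clone_id[screen$is_bimodal]
    trajectories <- filter(trajectories, .data$clone_id %in% keep)
  }
  if (nrow(trajectories) == 0) {
    return(structure(tibble(clone_id = character(0), n_died = integer(0),
                            n_survived = integer(0), p_t = numeric(0),
                            p_ks = numeric(0), p_mw = numeric(0),
                            bh_t = logical(0), bh_ks = logical(0),
                            bh_mw = logical(0), underpowered = logical(0),
                            direction = character(0)),
                     class = c("fate_screen", "tbl_df", "tbl", "data.frame"),
                     config = config))
  }
  summaries <- slope_summaries(trajectories, config) |>
    filter(.data$usable, .data$fate %in% c("died", "survived"))
  per_clone <- summaries |>
    group_by(.data$clone_id) |>
    summarise(n_died = sum(.data$fate == "died"),
              n_survived = sum(.data$fate == "survived"),
              died_slopes = list(.data$central_slope[.data$fate == "died"]),
              surv_slopes = list(.data$central_slope[.data$fate == "survived"]),
              .groups = "drop") |>
    mutate(underpowered = .data$n_died < config$fate_n_min |
             .data$n_survived < config$fate_n_min)

  tests <- pmap(list(per_clone$died_slopes, per_clone$surv_slopes,
                     per_clone$underpowered),
                function(a, b, up) {
                  if (up) return(tibble(p_t = NA_real_, p_ks = NA_real_,
                                        p_mw = NA_real_))
                  three_sample_tests(a, b)
                })
  res <- dplyr::bind_cols(per_clone, bind_rows(tests))
  res$eligible <- !res$underpowered  # reuse the BH helper's column contract
  res <- apply_bh_families(res, config)
  res <- res |>
    mutate(
      significant = !.data$underpowered &
        !is.na(.data$p_t) & .data$p_t < config$alpha &
        .data$p_ks < config$alpha & .data$p_mw < config$alpha &
        .data$bh_t & .data$bh_ks & .data$bh_mw,
      med_died = map_dbl(.data$died_slopes, function(s)
        if (length(s)) median(s) else NA_real_),
      med_surv = map_dbl(.data$surv_slopes, function(s)
        if (length(s)) median(s) else NA_real_),
      direction = dplyr::case_when(
        !.data$significant ~ "none",
        .data$med_died > .data$med_surv ~ "increase_correlates_death",
        TRUE ~ "increase_correlates_survival")) |>
    select("clone_id", "n_died", "n_survived", "p_t", "p_ks", "p_mw",
           "bh_t", "bh_ks", "bh_mw", "underpowered", "direction")
  structure(as_tibble(res), class = c("fate_screen", class(res)),
            config = config)
}

#' Mitosis timing versus death
#'
#' Bins cells by whether any mitosis occurs at or before
#' `mitosis_cutoff_h` and reports the killed fraction per bin with binomial
#' standard errors and a two-proportion chi-square test (with continuity
#' correction). The default `"caption"` binning places cells without any
#' mitosis in the late bin (mitosis-in-first-12-h vs not); the alternative
#' `"strict_late"` binning keeps only cells with an observed late mitosis in
#' the late bin.
#'
#' @param cells tibble with one row per cell carrying `fate` and
#'   `mitosis_times_h` (either a `;`-joined string or a list-column of
#'   numeric vectors). Censored cells (fate not died/survived) are dropped.
#' @param cutoff_h early/late boundary in hours.
#' @param binning `"caption"` or `"strict_late"` (see Details).
#' @return list of class `mitosis_timing` with elements `bins` (tibble:
#'   `bin, n, n_killed, frac_killed, se`), `p_value`, `cutoff_h`, `binning`.
#' @export
mitosis_death_analysis <- function(cells, cutoff_h = 12,
                                   binning = c("caption", "strict_late")) {
  binning <- match.arg(binning)
  mt <- parse_mitosis_times(cells$mitosis_times_h)
  fate <- cells$fate
  keep <- fate %in% c("died", "survived")
  mt <- mt[keep]; fate <- fate[keep]
  has_early <- map_lgl(mt, function(v) length(v) > 0 && any(v <= cutoff_h))
  has_late <- map_lgl(mt, function(v) length(v) > 0 && any(v > cutoff_h))
  early <- has_early
  late <- if (binning == "caption") !has_early else (!has_early & has_late)
  count_bin <- function(sel) {
    n <- sum(sel); k <- sum(fate[sel] == "died")
    frac <- if (n > 0) k / n else NA_real_
    tibble(n = n, n_killed = k, frac_killed = frac,
           se = if (n > 0) sqrt(frac * (1 - frac) / n) else NA_real_)
  }
  bins <- bind_rows(early = count_bin(early), late = count_bin(late),
                    .id = "bin")
  p_value <- if (all(bins$n > 0)) {
    suppressWarnings(prop.test(bins$n_killed, bins$n)$p.value)
  } else NA_real_
  if (any(bins$n == 0)) warn("empty mitosis-timing bin; fraction undefined")
  structure(list(bins = bins, p_value = p_value, cutoff_h = cutoff_h,
                 binning = binning),
            class = "mitosis_timing")
}

parse_mitosis_times <- function(x) {
  if (is.list(x)) return(lapply(x, function(v) as.numeric(v)))
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Classify a mean dynamic profile as up, down or down-up
#'
#' Net relative changes over `[0, t_switch_h]` and `[t_switch_h, end]` are
#' normalised by the trajectory's range (making the classification invariant
#' under positive affine scaling) and compared against a dead-band
#' `epsilon`: a fall followed by a rise is `"down_up"`; otherwise the
#' overall change decides between `"up"` and `"down"`, with flat profiles
#' defaulting to `"down"`.
#'
#' @param time_h,level numeric vectors of the mean trajectory.
#' @param t_switch_h split point in hours (default 12).
#' @param epsilon dead-band as a fraction of the trajectory range.
#' @return one of `"up"`, `"down"`, `"down_up"`.
#' @export
classify_mean_profile <- function(time_h, level, t_switch_h = 12,
                                  epsilon = 0.05) {
  o <- order(time_h); time_h <- time_h[o]; level <- level[o]
  if (max(time_h) < t_switch_h)
    stop_bimodyn("trajectory does not span t_switch_h", "bimodyn_invalid_input")
  rng <- max(level) - min(level)
  if (rng <= 1e-9 * max(abs(level), 1)) return("down")  # constant profile
  at <- function(t) level[which.min(abs(time_h - t))]
  r1 <- (at(t_switch_h) - level[1]) / rng
  r2 <- (level[length(level)] - at(t_switch_h)) / rng
  total <- (level[length(level)] - level[1]) / rng
  if (r1 < -epsilon && r2 > epsilon) "down_up"
  else if (total > epsilon) "up"
  else "down"
}

#' Clone-by-time mean dynamics matrix
#'
#' Averages YFP over all cells of each clone at each time point.
#'
#' @param trajectories long-format trajectory tibble.
#' @return numeric matrix, rows = clones (named), columns = sorted times.
#' @export
mean_dynamics <- function(trajectories) {
  m <- trajectories |>
    filter(!is.na(.data$yfp)) |>
    group_by(.data$clone_id, .data$time_h) |>
    summarise(level = mean(.data$yfp), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "time_h", values_from = "level")
  out <- as.matrix(m[, -1, drop = FALSE])
  rownames(out) <- m$clone_id
  out[, order(as.numeric(colnames(out))), drop = FALSE]
}

#' Row-wise z-scoring of a dynamics matrix
#'
#' Centres and scales every row to mean zero and SD one; zero-variance rows
#' become all-zero and are flagged in the `"flagged"` attribute.
#'
#' @param m numeric matrix (proteins x time).
#' @return matrix of the same shape with attribute `"flagged"` (logical per
#'   row).
#' @export
normalize_dynamics_matrix <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop_bimodyn("need >= 2 time points", "bimodyn_invalid_input")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  flagged <- s == 0 | !is.finite(s)
  out <- (m - mu) / ifelse(flagged, 1, s)
  out[flagged, ] <- 0
  attr(out, "flagged") <- flagged
  out
}

#' Row ordering from hierarchical clustering of dynamics
#'
#' Hierarchical clustering with correlation distance (`1 - cor`) and average
#' linkage; ties broken deterministically by row index. Rows with zero
#' variance are placed last in input order.
#'
#' @param m normalised dynamics matrix (rows = proteins).
#' @return integer vector: row indices in leaf order.
#' @export
cluster_order <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) return(seq_len(nrow(m)))
  s <- apply(m, 1, sd)
  ok <- which(s > 0)
  if (length(ok) < 2) return(c(ok, setdiff(seq_len(nrow(m)), ok)))
  d <- as.dist(1 - cor(t(m[ok, , drop = FALSE])))
  hc <- hclust(d, method = "average")
  c(ok[hc$order], setdiff(seq_len(nrow(m)), ok))
}
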