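#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a bimodality screen
#'
#' @param x a `bimodal_screen`.
#' @param ... unused.
#' @return plain tibble, one row per clone.
#' @export
tidy.bimodal_screen <- function(x, ...) {
  as_tibble(unclass_screen(x))
}

#' One-row summary of a bimodality screen
#'
#' @param x a `bimodal_screen`.
#' @param ... unused.
#' @export
glance.bimodal_screen <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(n_clones = nrow(x), n_eligible = sum(x$eligible),
         n_bimodal = sum(x$is_bimodal),
         alpha = cfg$alpha, fdr_q = cfg$fdr_q,
         t0_h = cfg$t0_h, t1_h = cfg$t1_h, n_min = cfg$n_min)
}

#' Tidy a fate screen
#'
#' @param x a `fate_screen`.
#' @param ... unused.
#' @export
tidy.fate_screen <- function(x, ...) as_tibble(unclass_screen(x))

#' One-row summary of a fate screen
#'
#' @param x a `fate_screen`.
#' @param ... unused.
#' @export
glance.fate_screen <- function(x, ...) {
  tibble(n_clones = nrow(x),
         n_correlated = sum(x$direction != "none"),
         n_death_up = sum(x$direction == "increase_correlates_death"),
         n_survival_up = sum(x$direction == "increase_correlates_survival"),
         n_underpowered = sum(x$underpowered))
}

#' Tidy a mitosis-timing result
#'
#' @param x a `mitosis_timing`.
#' @param ... unused.
#' @return the per-bin tibble.
#' @export
tidy.mitosis_timing <- function(x, ...) x$bins

#' One-row summary of a mitosis-timing result
#'
#' @param x a `mitosis_timing`.
#' @param ... unused.
#' @export
glance.mitosis_timing <- function(x, ...) {
  tibble(frac_killed_early = x$bins$frac_killed[x$bins$bin == "early"],
         frac_killed_late = x$bins$frac_killed[x$bins$bin == "late"],
         p_value = x$p_value, cutoff_h = x$cutoff_h, binning = x$binning)
}

#' @export
print.mitosis_timing <- function(x, ...) {
  cat("Mitosis timing vs death (cutoff ", x$cutoff_h, " h, ", x$binning,
      " binning)\n", sep = "")
  print(x$bins)
  cat("two-proportion test p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

unclass_screen <- function(x) {
  attr(x, "summaries") <- NULL
  attr(x, "config") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @export
print.clone_sim <- function(x, ...) {
  cat("Simulated clone: ", nrow(x$truth), " cells, ",
      dplyr::n_distinct(x$trajectories$time_h), " time points, ",
      sum(x$truth$fate == "died"), " died",
      if (x$config$is_bimodal) ", bimodal" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.panel_sim <- function(x, ...) {
  cat("Simulated panel: ", nrow(x$clone_truth), " clones (",
      sum(x$clone_truth$is_bimodal), " bimodal), ",
      nrow(x$truth), " cells\n", sep = "")
  invisible(x)
}

#' @export
print.movie_sim <- function(x, ...) {
  d <- dim(x$red)
  cat("Rendered movie: ", d[1], "x", d[2], " px, ", d[3], " frames, ",
      nrow(x$cells), " tracks, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}
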