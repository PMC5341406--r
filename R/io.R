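#' Read a long-format trajectory table
#'
#' Reads and validates the trajectory CSV dialect: comma-separated, UTF-8,
#' header row, columns `clone_id, cell_id, time_h, yfp, fate, death_time_h,
#' mitosis_times_h` (the last three optional; `mitosis_times_h` is a
#' `;`-joined list field). Per-cell rows are returned sorted by time.
#'
#' @param path CSV file path.
#' @return validated trajectory tibble.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path))
    stop_bimodyn(paste0("file not found: ", path), "bimodyn_validation_error")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("clone_id", "cell_id", "time_h", "yfp")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop_bimodyn(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "bimodyn_validation_error")
  for (col in c("time_h", "yfp")) {
    bad <- which(!is.na(x[[col]]) & !is.finite(suppressWarnings(as.numeric(x[[col]]))))
    if (!is.numeric(x[[col]])) {
      coerced <- suppressWarnings(as.numeric(x[[col]]))
      bad <- which(!is.na(x[[col]]) & is.na(coerced))
      if (length(bad))
        stop_bimodyn(paste0("non-numeric `", col, "` at row(s) ",
                            paste(head(bad, 5), collapse = ", ")),
                     "bimodyn_validation_error")
      x[[col]] <- coerced
    }
  }
  key <- paste(x$clone_id, x$cell_id, x$time_h, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_bimodyn(paste0("duplicate (clone, cell, time) at row(s) ",
                        paste(head(dup, 5), collapse = ", ")),
                 "bimodyn_validation_error")
  if (!"fate" %in% names(x)) x$fate <- NA_character_
  if (!"death_time_h" %in% names(x)) x$death_time_h <- NA_real_
  if (!"mitosis_times_h" %in% names(x)) x$mitosis_times_h <- ""
  x$mitosis_times_h <- ifelse(is.na(x$mitosis_times_h), "",
                              as.character(x$mitosis_times_h))
  arrange(x, .data$clone_id, .data$cell_id, .data$time_h)
}

#' Write a trajectory table in the package CSV dialect
#'
#' @param trajectories trajectory tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(trajectories, path, progress = FALSE)
  invisible(path)
}

#' Write an image or label stack as multi-page TIFF
#'
#' Intensity stacks are written as 32-bit float; label stacks (integer
#' masks) as 16-bit. Frame order is time order.
#'
#' @param stack 3-D array (x, y, frame) or list of 2-D matrices.
#' @param path output TIFF path.
#' @param labels write as 16-bit integer label masks.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, labels = FALSE) {
  frames <- stack_to_list(stack)
  if (labels) {
    mx <- max(1, max(unlist(lapply(frames, max))))
    if (mx > 65535) stop_bimodyn("more than 65535 labels", "bimodyn_invalid_input")
    frames <- lapply(frames, function(f) f / 65535)
    tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  } else {
    frames <- lapply(frames, function(f) {
      storage.mode(f) <- "double"
      f
    })
    tiff::writeTIFF(frames, path, bits.per.sample = 32, compression = "none")
  }
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF path.
#' @param labels read 16-bit label masks back to integer labels.
#' @return 3-D array (x, y, frame).
#' @export
read_stack_tiff <- function(path, labels = FALSE) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (labels) frames <- lapply(frames, function(f) round(f * 65535))
  arr <- array(0, c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  arr
}

stack_to_list <- function(stack) {
  if (is.list(stack)) return(stack)
  if (length(dim(stack)) == 2) return(list(stack))
  lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
}

stack_to_array <- function(stack) {
  if (!is.list(stack)) return(stack)
  arr <- array(0, c(dim(stack[[1]]), length(stack)))
  for (i in seq_along(stack)) arr[, , i] <- stack[[i]]
  arr
}

#' Read or build a pipeline configuration
#'
#' A pipeline configuration is a named list with components `seed`,
#' `out_dir`, `panel` (arguments to [simulate_panel()]: `n_clones`,
#' `frac_bimodal`, `unimodal_drift`, plus [clone_config()] fields under
#' `clone`), `analysis` ([analysis_config()] fields) and optionally
#' `input_csv` to analyse an existing trajectory table instead of
#' simulating. Reading and writing round-trip identically.
#'
#' @param path YAML file path.
#' @return named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config named list of configuration values.
#' @export
as_pipeline_config <- function(config) {
  defaults <- list(seed = 1L, out_dir = ".", input_csv = NULL,
                   panel = list(n_clones = 10, frac_bimodal = 0.25,
                                unimodal_drift = -30, clone = list()),
                   analysis = list())
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  ana <- do.call(analysis_config, cfg$analysis)
  if (ana$t1_h <= ana$t0_h)
    stop_bimodyn("analysis window empty", "bimodyn_invalid_config")
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
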