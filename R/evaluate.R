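#' Mean per-cell IoU between predicted and ground-truth label masks
#'
#' For every ground-truth object in every frame, finds the predicted label
#' with the largest overlap and records their intersection-over-union; the
#' mean over all truth objects is returned. A truth object with no
#' overlapping prediction contributes 0.
#'
#' @param pred,truth integer label arrays (x, y, frame) or single matrices.
#' @return list with `mean_iou` and a per-object tibble `per_object`
#'   (`frame, truth_id, pred_id, iou`).
#' @export
segmentation_iou <- function(pred, truth) {
  pred <- stack_to_array(pred); truth <- stack_to_array(truth)
  stopifnot(all(dim(pred) == dim(truth)))
  rows <- list()
  for (f in seq_len(dim(truth)[3])) {
    tm <- truth[, , f]; pm <- pred[, , f]
    for (id in sort(unique(tm[tm > 0]))) {
      t_idx <- tm == id
      n_t <- sum(t_idx)
      overlap <- pm[t_idx]
      overlap <- overlap[overlap > 0]
      if (length(overlap) == 0) {
        rows[[length(rows) + 1]] <- tibble(frame = f - 1L, truth_id = id,
                                           pred_id = NA_integer_, iou = 0)
        next
      }
      tb <- table(overlap)
      best <- as.integer(names(tb)[which.max(tb)])
      inter <- max(tb)
      union <- n_t + sum(pm == best) - inter
      rows[[length(rows) + 1]] <- tibble(frame = f - 1L, truth_id = id,
                                         pred_id = best, iou = inter / union)
    }
  }
  per_object <- bind_rows(rows)
  list(mean_iou = mean(per_object$iou), per_object = per_object)
}

#' Attach ground-truth identities to tracked detections
#'
#' Labels every detection with the ground-truth track id found at (or, in a
#' small neighbourhood around) its centroid in the truth cell masks.
#'
#' @param detections detection tibble with `frame, x, y`.
#' @param truth_masks ground-truth cell label array from [render_movie()].
#' @return `detections` with a `truth_id` column (0 = unmatched).
#' @export
assign_truth_ids <- function(detections, truth_masks) {
  dim_px <- dim(truth_masks)[1]
  truth_id <- integer(nrow(detections))
  for (r in seq_len(nrow(detections))) {
    f <- detections$frame[r] + 1L
    x <- round(detections$x[r]); y <- round(detections$y[r])
    id <- 0L
    if (x >= 1 && x <= dim_px && y >= 1 && y <= dim_px)
      id <- truth_masks[x, y, f]
    if (id == 0L) {
      xs <- max(1, x - 3):min(dim_px, x + 3)
      ys <- max(1, y - 3):min(dim_px, y + 3)
      patch <- truth_masks[xs, ys, f]
      patch <- patch[patch > 0]
      if (length(patch)) id <- as.integer(names(which.max(table(patch))))
    }
    truth_id[r] <- id
  }
  detections$truth_id <- truth_id
  detections
}

#' Frame-to-frame link accuracy against ground truth
#'
#' A link (two consecutive-frame detections sharing a track id) counts as
#' correct when both detections carry the same non-zero ground-truth id, or
#' when the pair crosses a true parent/daughter boundary (mitosis).
#'
#' @param tracked output of [track_cells()].
#' @param truth_masks ground-truth cell label array.
#' @param truth_cells `cells` tibble from [render_movie()] (for
#'   parent/daughter relations).
#' @return list with `accuracy`, `n_links`, `n_correct`.
#' @export
link_accuracy <- function(tracked, truth_masks, truth_cells = NULL) {
  dets <- assign_truth_ids(tracked$detections, truth_masks)
  dets <- arrange(dets, .data$track_id, .data$frame)
  parent_of <- if (!is.null(truth_cells))
    setNames(truth_cells$parent_id, truth_cells$track_id) else NULL
  n_links <- 0L; n_correct <- 0L
  for (td in split(dets, dets$track_id)) {
    if (nrow(td) < 2) next
    for (i in seq_len(nrow(td) - 1)) {
      a <- td$truth_id[i]; b <- td$truth_id[i + 1]
      n_links <- n_links + 1L
      ok <- a > 0 && b > 0 &&
        (a == b ||
           (!is.null(parent_of) &&
              (identical(parent_of[[as.character(b)]], a) ||
                 identical(parent_of[[as.character(a)]], b))))
      if (isTRUE(ok)) n_correct <- n_correct + 1L
    }
  }
  list(accuracy = if (n_links) n_correct / n_links else NA_real_,
       n_links = n_links, n_correct = n_correct)
}

#' Precision/recall/F1 of detected events against ground truth
#'
#' Greedily matches each true event to the nearest unmatched detected event
#' of the same kind within `tol_h` hours.
#'
#' @param pred event tibble with `time_h` (and optionally `kind`).
#' @param truth event tibble with `time_h` (and optionally `kind`).
#' @param tol_h matching tolerance in hours.
#' @param kind restrict both tables to this kind if given.
#' @return list with `precision`, `recall`, `f1`, `n_matched`,
#'   `matched_dt_h` (absolute time errors of matches).
#' @export
event_f1 <- function(pred, truth, tol_h = 1, kind = NULL) {
  if (!is.null(kind)) {
    if ("kind" %in% names(pred)) pred <- pred[pred$kind == kind, ]
    if ("kind" %in% names(truth)) truth <- truth[truth$kind == kind, ]
  }
  n_p <- nrow(pred); n_t <- nrow(truth)
  used <- rep(FALSE, n_p)
  dts <- numeric(0)
  matched <- 0L
  if (n_t > 0 && n_p > 0) {
    for (i in order(truth$time_h)) {
      d <- abs(pred$time_h - truth$time_h[i])
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= tol_h) {
        used[j] <- TRUE
        matched <- matched + 1L
        dts <- c(dts, d[j])
      }
    }
  }
  precision <- if (n_p) matched / n_p else NA_real_
  recall <- if (n_t) matched / n_t else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = matched, matched_dt_h = dts)
}
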