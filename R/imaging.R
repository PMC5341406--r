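#' Flat-field and background correction of an image stack
#'
#' Divides every frame by the normalised flat-field (supplied, or estimated
#' as a heavily smoothed per-pixel median of the stack) and then subtracts a
#' per-frame background offset (a low quantile of the pixel values,
#' dominated by non-cell pixels), clipping at zero.
#'
#' @param stack 3-D array (x, y, frame) or list of matrices.
#' @param flatfield optional strictly positive matrix matching the frame
#'   dimensions.
#' @param bg_quantile quantile used as the per-frame background offset.
#' @return corrected 3-D array.
#' @export
background_correct <- function(stack, flatfield = NULL, bg_quantile = 0.05) {
  arr <- stack_to_array(stack)
  if (!is.null(flatfield)) {
    if (any(flatfield <= 0))
      stop_bimodyn("flatfield must be strictly positive", "bimodyn_invalid_input")
    if (!all(dim(flatfield) == dim(arr)[1:2]))
      stop_bimodyn("flatfield dimensions do not match frames", "bimodyn_invalid_input")
    ff <- flatfield / mean(flatfield)
  } else {
    # illumination estimate robust to (possibly stationary) cells: per-tile
    # low quantile of the temporal median image, smoothed back to full size
    med <- apply(arr, c(1, 2), median)
    ff <- tile_background_field(med)
  }
  out <- arr
  for (f in seq_len(dim(arr)[3])) {
    fr <- arr[, , f] / ff
    fr <- fr - quantile(fr, bg_quantile, names = FALSE)
    out[, , f] <- pmax(fr, 0)
  }
  out
}

tile_background_field <- function(med, n_tiles = 8, q = 0.1) {
  nx <- nrow(med); ny <- ncol(med)
  bx <- ceiling(nx / n_tiles); by <- ceiling(ny / n_tiles)
  coarse <- matrix(0, n_tiles, n_tiles)
  for (i in seq_len(n_tiles)) for (j in seq_len(n_tiles)) {
    xs <- ((i - 1) * bx + 1):min(i * bx, nx)
    ys <- ((j - 1) * by + 1):min(j * by, ny)
    coarse[i, j] <- quantile(med[xs, ys], q, names = FALSE)
  }
  full <- coarse[pmin(ceiling(seq_len(nx) / bx), n_tiles),
                 pmin(ceiling(seq_len(ny) / by), n_tiles)]
  sm <- as.matrix(EBImage::gblur(EBImage::Image(full), sigma = bx))
  # a near-dark background (e.g. a signal channel) carries no illumination
  # information: fall back to flat illumination
  if (mean(sm) <= 1e-8 * max(1, max(med)))
    return(matrix(1, nx, ny))
  pmax(sm / mean(sm), 0.1)
}

#' Segment nuclei and cells in one red-channel frame
#'
#' Nuclei: Otsu global threshold on the Gaussian-smoothed frame, split by a
#' distance-transform watershed and filtered by `min_nucleus_area`. Cells:
#' the lower threshold `cytoplasm_threshold_scale * Otsu` region-grown from
#' the nuclei by seeded propagation, so every nucleus label is contained in
#' exactly one cell label. A blank (degenerate) frame returns empty masks
#' with a warning rather than an error.
#'
#' @param red_frame 2-D numeric matrix.
#' @param params a [segmentation_params()].
#' @return list with integer label matrices `nuclei` and `cells`, and the
#'   Otsu `threshold`.
#' @export
segment_frame <- function(red_frame, params = segmentation_params()) {
  red_frame <- as.matrix(red_frame)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(red_frame),
                                 params$smoothing_sigma))
  rng <- range(sm)
  if (diff(rng) < 1e-12) {
    warn("blank frame: Otsu threshold degenerate, returning empty masks")
    z <- matrix(0L, nrow(red_frame), ncol(red_frame))
    return(list(nuclei = z, cells = z, threshold = NA_real_))
  }
  scaled <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
    diff(rng) + rng[1]
  nuc_bw <- sm > thr
  if (!any(nuc_bw)) {
    warn("no pixels above Otsu threshold, returning empty masks")
    z <- matrix(0L, nrow(red_frame), ncol(red_frame))
    return(list(nuclei = z, cells = z, threshold = thr))
  }
  dm <- EBImage::distmap(EBImage::Image(nuc_bw * 1))
  nuc_lab <- EBImage::watershed(dm, tolerance = params$watershed_footprint)
  nuc_lab <- as.matrix(EBImage::imageData(nuc_lab))
  counts <- tabulate(nuc_lab[nuc_lab > 0])
  drop <- which(counts < params$min_nucleus_area)
  if (length(drop)) nuc_lab[nuc_lab %in% drop] <- 0L
  nuc_lab <- relabel_consecutive(nuc_lab)

  if (max(nuc_lab) == 0) {
    z <- matrix(0L, nrow(red_frame), ncol(red_frame))
    return(list(nuclei = z, cells = z, threshold = thr))
  }
  cell_bw <- sm > params$cytoplasm_threshold_scale * thr
  cells <- EBImage::propagate(EBImage::Image(sm), EBImage::Image(nuc_lab),
                              mask = EBImage::Image(cell_bw * 1))
  cells <- as.matrix(EBImage::imageData(cells))
  cells[nuc_lab > 0] <- nuc_lab[nuc_lab > 0]
  storage.mode(cells) <- "integer"
  storage.mode(nuc_lab) <- "integer"
  list(nuclei = nuc_lab, cells = cells, threshold = thr)
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Per-cell features for one segmented frame
#'
#' Measures every cell label: centroid, nucleus and cell areas, contour
#' roundness (4*pi*area/perimeter^2 with chain-code perimeter), mean red
#' intensity in nucleus and cytoplasm (cell minus nucleus), mean yellow
#' intensity in both compartments and the total yellow signal over the cell.
#'
#' @param red_frame,yfp_frame background-corrected channel frames.
#' @param masks output of [segment_frame()].
#' @param frame_index 0-based frame index stored in the output.
#' @return tibble with one row per detected cell.
#' @export
detect_cells <- function(red_frame, yfp_frame, masks, frame_index = 0L) {
  cells <- masks$cells; nuclei <- masks$nuclei
  n_lab <- max(cells)
  if (n_lab == 0) {
    return(tibble(frame = integer(0), label = integer(0), x = numeric(0),
                  y = numeric(0), nucleus_area = numeric(0),
                  cell_area = numeric(0), roundness = numeric(0),
                  mean_red_nuc = numeric(0), mean_red_cyt = numeric(0),
                  mean_yfp_nuc = numeric(0), mean_yfp_cyt = numeric(0),
                  total_yfp_cell = numeric(0)))
  }
  idx <- which(cells > 0)
  lab <- cells[idx]
  xs <- (idx - 1) %% nrow(cells) + 1
  ys <- (idx - 1) %/% nrow(cells) + 1
  in_nuc <- nuclei[idx] > 0
  sum_by <- function(v, sel = TRUE) {
    out <- numeric(n_lab)
    t <- rowsum(v[sel], lab[sel])
    out[as.integer(rownames(t))] <- t[, 1]
    out
  }
  cell_area <- sum_by(rep(1, length(idx)))
  nuc_area <- sum_by(rep(1, length(idx)), in_nuc)
  cx <- sum_by(xs) / cell_area
  cy <- sum_by(ys) / cell_area
  red_v <- red_frame[idx]; yfp_v <- yfp_frame[idx]
  red_nuc <- sum_by(red_v, in_nuc) / pmax(nuc_area, 1)
  red_cyt_n <- cell_area - nuc_area
  red_cyt <- ifelse(red_cyt_n > 0, sum_by(red_v, !in_nuc) / pmax(red_cyt_n, 1),
                    NA_real_)
  yfp_nuc <- ifelse(nuc_area > 0, sum_by(yfp_v, in_nuc) / pmax(nuc_area, 1),
                    NA_real_)
  yfp_cyt <- ifelse(red_cyt_n > 0, sum_by(yfp_v, !in_nuc) / pmax(red_cyt_n, 1),
                    NA_real_)
  total_yfp <- sum_by(yfp_v)
  roundness <- label_roundness(cells, n_lab, cell_area)
  present <- which(cell_area > 0)
  tibble(frame = as.integer(frame_index), label = present,
         x = cx[present], y = cy[present],
         nucleus_area = nuc_area[present], cell_area = cell_area[present],
         roundness = roundness[present],
         mean_red_nuc = red_nuc[present], mean_red_cyt = red_cyt[present],
         mean_yfp_nuc = yfp_nuc[present], mean_yfp_cyt = yfp_cyt[present],
         total_yfp_cell = total_yfp[present])
}

# 4*pi*area / perimeter^2 with Vossepoel-Smeulders corrected chain length
label_roundness <- function(lab_mat, n_lab, areas) {
  out <- rep(NA_real_, n_lab)
  oc <- EBImage::ocontour(EBImage::Image(lab_mat))
  for (k in seq_along(oc)) {
    pts <- oc[[k]]
    if (is.null(pts) || nrow(pts) < 4) { out[k] <- 1; next }
    d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
    steps <- sqrt(rowSums(d^2))
    per <- 0.980 * sum(steps < 1.2) + 1.406 * sum(steps >= 1.2)
    out[k] <- 4 * pi * areas[k] / per^2
  }
  out
}

#' Segment and measure a whole movie
#'
#' Applies [segment_frame()] and [detect_cells()] to every frame of a
#' two-channel stack.
#'
#' @param red,yfp 3-D arrays (x, y, frame), background-corrected.
#' @param params a [segmentation_params()].
#' @return list with `detections` (tibble over all frames) and `masks`
#'   (list of per-frame `segment_frame()` outputs).
#' @export
segment_movie <- function(red, yfp, params = segmentation_params()) {
  n_frames <- dim(red)[3]
  masks <- vector("list", n_frames)
  dets <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    masks[[f]] <- segment_frame(red[, , f], params)
    dets[[f]] <- detect_cells(red[, , f], yfp[, , f], masks[[f]],
                              frame_index = f - 1L)
  }
  list(detections = bind_rows(dets), masks = masks)
}

#' Reverse-time greedy cell tracking
#'
#' Links detections from the last frame backwards: the link cost between a
#' cell and a candidate in the previous frame is the Euclidean centroid
#' distance plus `attr_weight * |delta log total YFP|` (pixel-equivalent);
#' links whose centroid distance exceeds `max_link_px` are refused. Links
#' are accepted greedily in increasing cost order. A detection in the
#' earlier frame claimed by two tracks is a backward merge: the lower-cost
#' track continues through it and the other track is recorded as a
#' candidate mitosis daughter splitting at that frame.
#'
#' @param detections tibble from [segment_movie()] / [detect_cells()].
#' @param max_link_px hard gate on centroid displacement per frame.
#' @param attr_weight weight (px per log-unit) of the intensity term.
#' @return list with `detections` (input plus `track_id`) and `merges`
#'   (tibble `frame, parent_track, child_track`: forward-time splits).
#' @export
track_cells <- function(detections, max_link_px = 50, attr_weight = 10) {
  if (nrow(detections) == 0)
    return(list(detections = mutate(detections, track_id = integer(0)),
                merges = tibble(frame = integer(0), parent_track = integer(0),
                                child_track = integer(0))))
  detections <- arrange(detections, .data$frame, .data$label)
  detections$track_id <- NA_integer_
  frames <- sort(unique(detections$frame), decreasing = TRUE)
  next_id <- 0L
  new_id <- function() { next_id <<- next_id + 1L; next_id }
  rows_f <- which(detections$frame == frames[1])
  for (r in rows_f) detections$track_id[r] <- new_id()
  merges <- list()

  for (k in seq_along(frames)[-1]) {
    f_cur <- frames[k - 1]; f_prev <- frames[k]
    if (f_cur - f_prev != 1) {
      # non-contiguous frames: start fresh tracks
      for (r in which(detections$frame == f_prev)) {
        detections$track_id[r] <- new_id()
      }
      next
    }
    A <- which(detections$frame == f_cur)   # later frame (already tracked)
    B <- which(detections$frame == f_prev)  # earlier frame
    if (length(B) == 0) next
    if (length(A) == 0) {
      for (r in B) detections$track_id[r] <- new_id()
      next
    }
    dx <- outer(detections$x[A], detections$x[B], "-")
    dy <- outer(detections$y[A], detections$y[B], "-")
    dist <- sqrt(dx^2 + dy^2)
    dlog <- abs(outer(log(pmax(detections$total_yfp_cell[A], 1e-12)),
                      log(pmax(detections$total_yfp_cell[B], 1e-12)), "-"))
    cost <- dist + attr_weight * dlog
    cost[dist > max_link_px] <- Inf
    claimed_A <- rep(FALSE, length(A))
    claims_B <- rep(0L, length(B))
    first_claim <- rep(NA_integer_, length(B))
    ord <- order(cost)
    for (o in ord) {
      if (!is.finite(cost[o])) break
      ai <- (o - 1) %% length(A) + 1
      bi <- (o - 1) %/% length(A) + 1
      if (claimed_A[ai] || claims_B[bi] >= 2L) next
      claimed_A[ai] <- TRUE
      claims_B[bi] <- claims_B[bi] + 1L
      if (claims_B[bi] == 1L) {
        first_claim[bi] <- ai
        detections$track_id[B[bi]] <- detections$track_id[A[ai]]
      } else {
        # backward merge: forward-time split at f_cur
        merges[[length(merges) + 1]] <- tibble(
          frame = f_cur,
          parent_track = detections$track_id[A[first_claim[bi]]],
          child_track = detections$track_id[A[ai]])
      }
    }
    for (bi in which(claims_B == 0L))
      detections$track_id[B[bi]] <- new_id()
  }
  list(detections = detections,
       merges = if (length(merges)) bind_rows(merges)
                else tibble(frame = integer(0), parent_track = integer(0),
                            child_track = integer(0)))
}

#' Detect a death event on one track
#'
#' Death is called at the first frame where the cell is rounded
#' (`roundness >= roundness_thr`) and its nuclear/cytoplasm red contrast has
#' fallen below `contrast_drop_thr` times the track's baseline contrast,
#' with the condition sustained for `persistence_frames` frames or followed
#' by track termination before the end of the movie.
#'
#' @param track_dets detections of a single track, one row per frame.
#' @param roundness_thr roundness threshold for the rounded state.
#' @param contrast_drop_thr fraction of baseline contrast counted as a
#'   collapse.
#' @param persistence_frames frames the state must persist.
#' @param movie_end_frame last frame index of the movie (0-based).
#' @param dt_h hours per frame.
#' @return one-row tibble (`track_id, kind, time_h, frame, score`) or `NULL`.
#' @export
detect_death <- function(track_dets, roundness_thr = 0.9,
                         contrast_drop_thr = 0.6, persistence_frames = 3,
                         movie_end_frame = max(track_dets$frame),
                         dt_h = 0.5) {
  td <- arrange(track_dets, .data$frame)
  n <- nrow(td)
  if (n < persistence_frames) return(NULL)
  contrast <- td$mean_red_nuc / td$mean_red_cyt
  baseline <- median(contrast[seq_len(min(5, n))], na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0) return(NULL)
  cand <- !is.na(td$roundness) & td$roundness >= roundness_thr &
    is.finite(contrast) & contrast <= contrast_drop_thr * baseline
  if (!any(cand)) return(NULL)
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  truncated <- max(td$frame) < movie_end_frame
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    sustained <- r$lengths[j] >= persistence_frames
    terminal <- (ends[j] == n) && truncated
    if (sustained || terminal) {
      f <- td$frame[starts[j]]
      return(tibble(track_id = td$track_id[1], kind = "death",
                    time_h = f * dt_h, frame = f,
                    score = min(1, r$lengths[j] / persistence_frames)))
    }
  }
  NULL
}

#' Detect death events for all tracks
#'
#' @param tracked output of [track_cells()].
#' @param dt_h hours per frame.
#' @inheritParams detect_death
#' @return tibble of death events (possibly empty).
#' @export
detect_deaths <- function(tracked, roundness_thr = 0.9,
                          contrast_drop_thr = 0.6, persistence_frames = 3,
                          dt_h = 0.5) {
  dets <- tracked$detections
  end_frame <- max(dets$frame)
  evs <- lapply(split(dets, dets$track_id), function(td) {
    if (nrow(td) < persistence_frames) return(NULL)
    detect_death(td, roundness_thr, contrast_drop_thr, persistence_frames,
                 movie_end_frame = end_frame, dt_h = dt_h)
  })
  out <- bind_rows(evs)
  if (nrow(out) == 0)
    out <- tibble(track_id = integer(0), kind = character(0),
                  time_h = numeric(0), frame = integer(0), score = numeric(0))
  out
}

#' Confirm mitosis events from backward merges
#'
#' A backward merge (two tracks joining onto one detection when the movie is
#' read end-to-start) is confirmed as mitosis when the parent track shows
#' rounding (`roundness >= roundness_thr`) within `window` frames of the
#' split, and no death was called on the parent at or before the split.
#'
#' @param tracked output of [track_cells()].
#' @param roundness_thr rounding threshold.
#' @param window frames around the split searched for rounding.
#' @param deaths optional death-event tibble from [detect_deaths()].
#' @param dt_h hours per frame.
#' @return tibble of mitosis events (`track_id` = parent, `daughter_track`,
#'   `time_h`, `frame`, `score`).
#' @export
detect_mitosis <- function(tracked, roundness_thr = 0.9, window = 2,
                           deaths = NULL, dt_h = 0.5) {
  merges <- tracked$merges
  dets <- tracked$detections
  out <- list()
  for (j in seq_len(nrow(merges))) {
    m <- merges[j, ]
    parent <- dets[dets$track_id == m$parent_track, ]
    near <- parent[abs(parent$frame - (m$frame - 1)) <= window, ]
    if (nrow(near) == 0 || !any(near$roundness >= roundness_thr, na.rm = TRUE))
      next
    if (!is.null(deaths) && nrow(deaths)) {
      d <- deaths[deaths$track_id == m$parent_track, ]
      if (nrow(d) && any(d$frame <= m$frame)) next
    }
    out[[length(out) + 1]] <- tibble(
      track_id = m$parent_track, kind = "mitosis",
      daughter_track = m$child_track,
      time_h = m$frame * dt_h, frame = m$frame,
      score = max(near$roundness, na.rm = TRUE))
  }
  if (length(out)) bind_rows(out)
  else tibble(track_id = integer(0), kind = character(0),
              daughter_track = integer(0), time_h = numeric(0),
              frame = integer(0), score = numeric(0))
}

#' Per-track trajectories from tracked detections
#'
#' Emits each track's total cell YFP signal at frame times converted to
#' hours, with the fate assigned from the detected events: `died` when a
#' death event was called, `survived` when the track reaches the last frame,
#' otherwise `censored`. A gap inside a track's frame span violates the
#' tracking contract and raises an error.
#'
#' @param tracked output of [track_cells()].
#' @param deaths,mitoses event tibbles from [detect_deaths()] /
#'   [detect_mitosis()].
#' @param dt_h hours per frame.
#' @param clone_id clone identifier for the output table.
#' @return long-format trajectory tibble in the package dialect.
#' @export
quantify_tracks <- function(tracked, deaths = NULL, mitoses = NULL,
                            dt_h = 0.5, clone_id = "movie") {
  dets <- arrange(tracked$detections, .data$track_id, .data$frame)
  end_frame <- max(dets$frame)
  deaths <- deaths %||% tibble(track_id = integer(0), frame = integer(0),
                               time_h = numeric(0))
  mitoses <- mitoses %||% tibble(track_id = integer(0), time_h = numeric(0))
  out <- lapply(split(dets, dets$track_id), function(td) {
    fr <- td$frame
    if (length(fr) > 1 && any(diff(fr) != 1))
      stop_bimodyn("track has a frame gap: tracking contract violated",
                   "bimodyn_tracking_error")
    id <- td$track_id[1]
    dd <- deaths[deaths$track_id == id, ]
    died <- nrow(dd) > 0
    if (died) td <- td[td$frame <= dd$frame[1], ]
    mt <- mitoses$time_h[mitoses$track_id == id]
    tibble(clone_id = clone_id,
           cell_id = sprintf("t%04d", id),
           time_h = td$frame * dt_h,
           yfp = td$total_yfp_cell,
           fate = if (died) "died"
                  else if (max(fr) == end_frame) "survived" else "censored",
           death_time_h = if (died) dd$time_h[1] else NA_real_,
           mitosis_times_h = paste(sprintf("%.10g", sort(mt)),
                                   collapse = ";"))
  })
  bind_rows(out)
}

#' Nuclear-to-cytoplasmic intensity ratio of one track
#'
#' Computes the per-frame ratio of mean nuclear to mean cytoplasmic yellow
#' intensity and flags a translocation when the median ratio in a late
#' window reaches `fold_thr` times the median in an early window. Frames
#' with an empty cytoplasm compartment yield missing ratios.
#'
#' @param track_dets detections of one track.
#' @param dt_h hours per frame.
#' @param early_frac,late_frac fractions of the track used as early/late
#'   windows.
#' @param fold_thr fold change calling a translocation.
#' @return list with `series` (tibble `time_h, ratio`), `flag`, `onset_h`
#'   (first crossing time, `NA` when not flagged) and the window medians.
#' @export
nuclear_cytoplasmic_ratio <- function(track_dets, dt_h = 0.5,
                                      early_frac = 0.25, late_frac = 0.25,
                                      fold_thr = 2) {
  td <- arrange(track_dets, .data$frame)
  ratio <- td$mean_yfp_nuc / td$mean_yfp_cyt
  bad <- !is.finite(ratio)
  if (any(bad)) {
    warn("empty compartment in some frames; ratio set to NA there")
    ratio[bad] <- NA_real_
  }
  n <- nrow(td)
  time_h <- td$frame * dt_h
  early <- seq_len(max(2, floor(early_frac * n)))
  late <- seq(n - max(2, floor(late_frac * n)) + 1, n)
  med_early <- median(ratio[early], na.rm = TRUE)
  med_late <- median(ratio[late], na.rm = TRUE)
  flag <- is.finite(med_early) && is.finite(med_late) &&
    med_late >= fold_thr * med_early
  onset <- NA_real_
  if (flag) {
    cross <- which(ratio >= fold_thr * med_early)
    if (length(cross)) onset <- time_h[cross[1]]
  }
  list(series = tibble(time_h = time_h, ratio = ratio),
       flag = flag, onset_h = onset,
       median_early = med_early, median_late = med_late)
}

#' Run the whole image-analysis chain on a two-channel movie
#'
#' Background-corrects both channels, segments and measures every frame,
#' tracks cells in reverse time, detects death and mitosis events, and
#' quantifies per-track trajectories.
#'
#' @param red,yfp raw 3-D stacks (x, y, frame).
#' @param params a [segmentation_params()].
#' @param dt_h hours per frame.
#' @param flatfield optional flat-field matrix applied to both channels.
#' @param max_link_px,attr_weight tracking parameters (see [track_cells()]).
#' @param roundness_thr,contrast_drop_thr,persistence_frames event-detection
#'   parameters.
#' @param clone_id clone identifier for the trajectory table.
#' @return list with `detections`, `masks`, `tracked`, `deaths`, `mitoses`,
#'   `trajectories`.
#' @export
analyze_movie <- function(red, yfp, params = segmentation_params(),
                          dt_h = 0.5, flatfield = NULL,
                          max_link_px = 50, attr_weight = 10,
                          roundness_thr = 0.9, contrast_drop_thr = 0.6,
                          persistence_frames = 3, clone_id = "movie") {
  red_c <- background_correct(red, flatfield)
  yfp_c <- background_correct(yfp, flatfield)
  seg <- segment_movie(red_c, yfp_c, params)
  tracked <- track_cells(seg$detections, max_link_px, attr_weight)
  deaths <- detect_deaths(tracked, roundness_thr, contrast_drop_thr,
                          persistence_frames, dt_h = dt_h)
  mitoses <- detect_mitosis(tracked, roundness_thr, deaths = deaths,
                            dt_h = dt_h)
  traj <- quantify_tracks(tracked, deaths, mitoses, dt_h = dt_h,
                          clone_id = clone_id)
  list(detections = seg$detections, masks = seg$masks, tracked = tracked,
       deaths = deaths, mitoses = mitoses, trajectories = traj)
}
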