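#' Render a synthetic two-channel movie from a simulated clone
#'
#' Turns a [simulate_clone()] result into a two-channel image stack with
#' per-frame ground-truth label masks and identity-linked tracks. The red
#' (constitutive marker) channel draws each cell as an elongated elliptical
#' cytoplasm containing a brighter elliptical nucleus; the yellow channel
#' spreads the cell's trajectory level uniformly over the cell (optionally
#' concentrating a fraction in the nucleus after a translocation onset).
#' Cells move by a bounded random walk with pairwise repulsion. Mitosis is
#' rendered as rounding for `mitosis_round_frames` frames followed by a
#' split into two daughters; death as rounding with collapse of the
#' nuclear/cytoplasm contrast for `death_linger_frames` frames, then
#' disappearance. Poisson shot noise and Gaussian read noise are added.
#'
#' @param sim a `clone_sim` from [simulate_clone()]; keep `n_cells` small
#'   enough for the frame (a placement error is raised otherwise).
#' @param optics an [optics_params()].
#' @param seed RNG seed for placement, motion and noise.
#' @return A list of class `movie_sim`: `red`, `yfp` (arrays x-y-frame),
#'   `nuc_masks`, `cell_masks` (label arrays keyed by track id), `tracks`
#'   (tibble `frame, track_id, x, y`), `events` (tibble `track_id, kind,
#'   time_h, frame, parent_id`), `cells` (track-level metadata), `dt_h`,
#'   `times_h`, `optics`.
#' @export
render_movie <- function(sim, optics = optics_params(), seed = 1L) {
  stopifnot(inherits(sim, "clone_sim"))
  local_rng(seed)
  cfg <- sim$config
  dt <- cfg$dt_h
  times <- seq(0, cfg$horizon_h, by = dt)
  n_frames <- length(times)
  dim_px <- optics$frame_px
  margin <- optics$cell_axis_px + 4
  n0 <- nrow(sim$truth)

  # --- per-track state ------------------------------------------------------
  # tracks 1..n0 are the simulated cells; daughters get ids n0+1, ...
  st <- new.env(parent = emptyenv())
  st$n_tracks <- n0
  tr <- list()  # per track: list(first, last, theta, ratio, bright, level, ...)

  level_matrix <- level_lookup(sim, times)

  place_positions <- function(n) {
    pos <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:200) {
        p <- runif(2, margin, dim_px - margin)
        if (i == 1 || all(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                                          matrix(p, i - 1, 2, byrow = TRUE))^2)) >=
                            optics$min_separation_px)) {
          pos[i, ] <- p; ok <- TRUE; break
        }
      }
      if (!ok) stop_bimodyn("could not place cells without overlap; use a larger frame or fewer cells",
                            "bimodyn_placement_error")
    }
    pos
  }
  pos0 <- place_positions(n0)

  frame_of <- function(t_h) as.integer(round(t_h / dt))  # 0-based

  for (i in seq_len(n0)) {
    truth_i <- sim$truth[i, ]
    death_frame <- if (truth_i$fate == "died")
      min(frame_of(truth_i$death_time_h), n_frames - 1L) else NA_integer_
    mts <- truth_i$mitosis_times[[1]]
    mts <- mts[mts > (optics$mitosis_round_frames + 1) * dt &
                 mts < cfg$horizon_h - dt]
    if (!is.na(death_frame))
      mts <- mts[frame_of(mts) < death_frame - optics$mitosis_round_frames]
    split_frame <- if (length(mts)) frame_of(mts[1]) else NA_integer_
    tr[[i]] <- list(
      id = i, cell_id = truth_i$cell_id, first = 0L,
      last = if (!is.na(death_frame))
        min(death_frame + optics$death_linger_frames, n_frames - 1L)
      else n_frames - 1L,
      death_frame = death_frame,
      death_time_h = truth_i$death_time_h,
      split_frame = split_frame, split_time_h = if (length(mts)) mts[1] else NA_real_,
      parent = NA_integer_,
      theta = runif(1, 0, pi),
      ratio = optics$cell_axis_ratio * runif(1, 0.9, 1.1),
      bright = runif(1, 0.85, 1.15),
      levels = level_matrix[i, ])
  }

  # truncate parents at their split and append daughter tracks
  i <- 1
  while (i <= length(tr)) {
    tk <- tr[[i]]
    if (!is.na(tk$split_frame) && tk$split_frame <= tk$last) {
      s <- tk$split_frame
      for (d in 1:2) {
        st$n_tracks <- st$n_tracks + 1L
        dtk <- tk
        dtk$id <- st$n_tracks
        dtk$first <- s
        dtk$parent <- tk$id
        dtk$split_frame <- NA_integer_  # daughters do not divide again
        dtk$theta <- runif(1, 0, pi)
        dtk$ratio <- optics$cell_axis_ratio * runif(1, 0.9, 1.1)
        dtk$bright <- tk$bright * runif(1, 0.95, 1.05)
        if (d == 2) { # side branch: no death, survives to the end
          dtk$death_frame <- NA_integer_; dtk$death_time_h <- NA_real_
          dtk$last <- n_frames - 1L
        }
        tr[[length(tr) + 1]] <- dtk
      }
      tr[[i]]$last <- s - 1L
      tr[[i]]$death_frame <- NA_integer_
    }
    i <- i + 1
  }
  n_tracks <- length(tr)

  # --- motion ---------------------------------------------------------------
  pos <- array(NA_real_, c(n_tracks, 2, n_frames))
  for (i in seq_len(n0)) pos[i, , 1] <- pos0[i, ]
  split_dir <- matrix(NA_real_, n_tracks, 2)
  for (f in seq_len(n_frames)) {
    fr <- f - 1L  # 0-based frame
    for (i in seq_len(n_tracks)) {
      tk <- tr[[i]]
      if (fr < tk$first || fr > tk$last) next
      if (fr == tk$first && fr > 0 && !is.na(tk$parent)) {
        # daughter: offset from parent's last position
        pp <- pos[tk$parent, , f - 1]
        if (is.na(split_dir[tk$parent, 1])) {
          ang <- runif(1, 0, 2 * pi)
          split_dir[tk$parent, ] <- c(cos(ang), sin(ang))
        }
        sgn <- if (sum(vapply(tr, function(z)
          identical(z$parent, tk$parent) && z$id < tk$id, logical(1)))) -1 else 1
        pos[i, , f] <- clamp_px(pp + sgn * split_dir[tk$parent, ] *
                                  optics$cell_axis_px * 0.65, margin, dim_px)
        next
      }
      if (fr == tk$first) next  # initial placement already set
      prev <- pos[i, , f - 1]
      prop <- clamp_px(prev + rnorm(2, 0, optics$motion_sd), margin, dim_px)
      others <- setdiff(which(!is.na(pos[, 1, f]) | !is.na(pos[, 1, f - 1])), i)
      crowd <- FALSE
      for (j in others) {
        pj <- if (!is.na(pos[j, 1, f])) pos[j, , f] else pos[j, , f - 1]
        same_family <- !is.na(tr[[i]]$parent) && identical(tr[[j]]$parent, tr[[i]]$parent)
        min_d <- if (same_family) optics$cell_axis_px * 1.1 else optics$min_separation_px
        if (sqrt(sum((prop - pj)^2)) < min_d) { crowd <- TRUE; break }
      }
      pos[i, , f] <- if (crowd) prev else prop
    }
  }

  # --- drawing --------------------------------------------------------------
  red <- array(optics$background_intensity, c(dim_px, dim_px, n_frames))
  yfp <- array(0, c(dim_px, dim_px, n_frames))
  nuc_masks <- array(0L, c(dim_px, dim_px, n_frames))
  cell_masks <- array(0L, c(dim_px, dim_px, n_frames))
  track_rows <- list()

  for (f in seq_len(n_frames)) {
    fr <- f - 1L
    red_f <- matrix(optics$background_intensity, dim_px, dim_px)
    yfp_f <- matrix(0, dim_px, dim_px)
    nm <- matrix(0L, dim_px, dim_px)
    cm <- matrix(0L, dim_px, dim_px)
    for (i in seq_len(n_tracks)) {
      tk <- tr[[i]]
      if (fr < tk$first || fr > tk$last) next
      p <- pos[i, , f]
      dying <- !is.na(tk$death_frame) && fr >= tk$death_frame
      rounding <- dying ||
        (!is.na(tk$split_frame) &&
           fr >= tk$split_frame - optics$mitosis_round_frames && fr <= tk$last)
      daughter_scale <- if (!is.na(tk$parent)) 0.85 else 1
      if (rounding) {
        r_eq <- sqrt(optics$cell_axis_px^2 / tk$ratio) * daughter_scale
        cell_px <- ellipse_pixels(p[1], p[2], r_eq, r_eq, 0, dim_px)
        rn <- sqrt(optics$nucleus_axis_px^2 / optics$nucleus_axis_ratio)
        nuc_px <- ellipse_pixels(p[1], p[2], rn, rn, 0, dim_px)
      } else {
        a <- optics$cell_axis_px * daughter_scale
        cell_px <- ellipse_pixels(p[1], p[2], a, a / tk$ratio, tk$theta, dim_px)
        nuc_px <- ellipse_pixels(p[1], p[2], optics$nucleus_axis_px * daughter_scale,
                                 optics$nucleus_axis_px * daughter_scale /
                                   optics$nucleus_axis_ratio, tk$theta, dim_px)
      }
      free <- cm[cell_px] == 0L
      cell_px <- cell_px[free]
      nuc_px <- nuc_px[nm[nuc_px] == 0L & cm[nuc_px] %in% c(0L, 0L)]
      nuc_px <- intersect(nuc_px, cell_px)
      if (length(cell_px) == 0) next
      cm[cell_px] <- i
      nm[nuc_px] <- i
      nuc_int <- if (dying) optics$dying_nucleus_intensity else optics$nucleus_intensity
      cyt_int <- if (dying) optics$dying_cytoplasm_intensity else optics$cytoplasm_intensity
      red_f[cell_px] <- cyt_int * tk$bright
      red_f[nuc_px] <- nuc_int * tk$bright
      # yellow: total over the cell equals level * yfp_scale * area
      lev <- tk$levels[f]
      if (!is.na(lev)) {
        total <- lev * optics$yfp_scale * length(cell_px)
        tf <- optics$translocate_frac
        if (tf > 0 && times[f] >= optics$translocate_onset_h &&
            length(nuc_px) > 0 && length(cell_px) > length(nuc_px)) {
          cyt_px <- setdiff(cell_px, nuc_px)
          yfp_f[cyt_px] <- total * (1 - tf) / length(cyt_px)
          yfp_f[nuc_px] <- total * tf / length(nuc_px)
        } else {
          yfp_f[cell_px] <- total / length(cell_px)
        }
      }
      track_rows[[length(track_rows) + 1]] <-
        tibble(frame = fr, track_id = i, x = p[1], y = p[2])
    }
    # optics: blur then noise
    red_b <- as.matrix(EBImage::gblur(EBImage::Image(red_f), optics$blur_sigma))
    yfp_b <- as.matrix(EBImage::gblur(EBImage::Image(yfp_f), optics$blur_sigma))
    if (optics$vignette_strength > 0) {
      vg <- vignette_field(dim_px, optics$vignette_strength)
      red_b <- red_b * vg; yfp_b <- yfp_b * vg
    }
    if (optics$photon_scale > 0) {
      red_b <- rpois(length(red_b), pmax(red_b, 0) * optics$photon_scale) /
        optics$photon_scale
      dim(red_b) <- c(dim_px, dim_px)
      yfp_b <- rpois(length(yfp_b), pmax(yfp_b, 0) * optics$photon_scale) /
        optics$photon_scale
      dim(yfp_b) <- c(dim_px, dim_px)
    }
    if (optics$read_noise_sd > 0) {
      red_b <- red_b + rnorm(length(red_b), 0, optics$read_noise_sd)
      yfp_b <- yfp_b + rnorm(length(yfp_b), 0, optics$read_noise_sd)
    }
    red[, , f] <- pmax(red_b, 0)
    yfp[, , f] <- pmax(yfp_b, 0)
    nuc_masks[, , f] <- nm
    cell_masks[, , f] <- cm
  }

  events <- bind_rows(lapply(tr, function(tk) {
    ev <- list()
    if (!is.na(tk$death_frame))
      ev[[length(ev) + 1]] <- tibble(track_id = tk$id, kind = "death",
                                     time_h = tk$death_time_h,
                                     frame = tk$death_frame,
                                     parent_id = NA_integer_)
    if (!is.na(tk$split_frame))
      ev[[length(ev) + 1]] <- tibble(track_id = tk$id, kind = "mitosis",
                                     time_h = tk$split_time_h,
                                     frame = tk$split_frame,
                                     parent_id = tk$id)
    bind_rows(ev)
  }))
  cells_meta <- bind_rows(lapply(tr, function(tk)
    tibble(track_id = tk$id, cell_id = tk$cell_id, parent_id = tk$parent,
           first_frame = tk$first, last_frame = tk$last)))

  structure(list(red = red, yfp = yfp, nuc_masks = nuc_masks,
                 cell_masks = cell_masks,
                 tracks = bind_rows(track_rows), events = events,
                 cells = cells_meta, dt_h = dt, times_h = times,
                 optics = optics),
            class = "movie_sim")
}

# carry-forward level lookup: cells x frames, NA once the cell is gone
level_lookup <- function(sim, times) {
  n <- nrow(sim$truth)
  out <- matrix(NA_real_, n, length(times))
  for (i in seq_len(n)) {
    ci <- sim$truth$cell_id[i]
    tt <- sim$trajectories[sim$trajectories$cell_id == ci, ]
    idx <- match(round(tt$time_h, 6), round(times, 6))
    v <- rep(NA_real_, length(times))
    v[idx] <- tt$yfp
    # carry the last observed level forward through rounding/linger frames
    lastv <- NA_real_
    for (f in seq_along(times)) {
      if (is.na(v[f])) v[f] <- lastv else lastv <- v[f]
    }
    out[i, ] <- v
  }
  out
}

clamp_px <- function(p, margin, dim_px) pmin(pmax(p, margin), dim_px - margin)

ellipse_pixels <- function(cx, cy, a, b, theta, dim_px) {
  r <- ceiling(max(a, b)) + 1
  xs <- max(1, floor(cx - r)):min(dim_px, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(dim_px, ceiling(cy + r))
  g <- expand.grid(x = xs, y = ys)
  dx <- g$x - cx; dy <- g$y - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  (g$y[inside] - 1L) * dim_px + g$x[inside]
}

vignette_field <- function(dim_px, strength) {
  cx <- (dim_px + 1) / 2
  d2 <- outer((seq_len(dim_px) - cx)^2, (seq_len(dim_px) - cx)^2, "+")
  1 - strength * d2 / max(d2)
}
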