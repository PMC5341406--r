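test_that("background correction: identities and vignette recovery", {
  frame <- matrix(5, 64, 64)
  stack <- array(frame, c(64, 64, 3))
  ff <- matrix(2, 64, 64)
  out <- background_correct(stack, ff)
  # uniform frame with flat flatfield: unchanged up to the subtracted offset
  expect_true(all(abs(out - 0) < 1e-9))

  # frame = true * flatfield: division recovers the true frame up to scale
  set.seed(5)
  true <- matrix(runif(64 * 64, 1, 2), 64, 64)
  vg <- 1 - 0.3 * (outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+") /
                     max(outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+")))
  obs <- array(true * vg, c(64, 64, 2))
  rec <- background_correct(obs, vg, bg_quantile = 0)
  # recovery up to the flat-field normalisation constant and the offset
  expected <- mean(vg) * (true - min(true))
  expect_lt(max(abs(rec[, , 1] - expected)), 1e-6)

  expect_error(background_correct(stack, matrix(0, 64, 64)),
               class = "bimodyn_invalid_input")
})

test_that("estimated flat-field flattens a vignetted sparse-cell stack", {
  # background 10 with a few bright blobs, imaged through a radial vignette
  set.seed(8)
  dim_px <- 128
  d2 <- outer((1:dim_px - 64.5)^2, (1:dim_px - 64.5)^2, "+")
  vg <- 1 - 0.35 * d2 / max(d2)
  blob_corner <- ellipse_mask(16, 16, 7, 7, 0, dim_px)
  blob_center <- ellipse_mask(64, 64, 7, 7, 0, dim_px)
  clean <- matrix(10, dim_px, dim_px)
  clean[blob_corner] <- 100
  clean[blob_center] <- 100
  stack <- array(0, c(dim_px, dim_px, 5))
  for (f in 1:5) stack[, , f] <- clean * vg + rnorm(dim_px^2, 0, 0.2)
  rec <- background_correct(stack)
  corner <- mean(rec[, , 1][blob_corner])
  center <- mean(rec[, , 1][blob_center])
  expect_lt(abs(corner / center - 1), 0.05)
})

test_that("blank frames yield empty masks with a warning, not an error", {
  expect_warning(seg <- segment_frame(matrix(0.5, 64, 64)))
  expect_equal(max(seg$nuclei), 0)
  expect_equal(max(seg$cells), 0)
})

test_that("two well-separated nuclei segment with accurate centroids", {
  frame <- matrix(0.02, 128, 128)
  frame[ellipse_mask(40, 40, 8, 8, 0, 128)] <- 1
  frame[ellipse_mask(90, 90, 8, 8, 0, 128)] <- 1
  seg <- segment_frame(frame)
  expect_equal(max(seg$nuclei), 2)
  d <- detect_cells(frame, frame * 0, seg, 0)
  got <- d[order(d$x), c("x", "y")]
  expect_lt(max(abs(got$x - c(40, 90))), 1)
  expect_lt(max(abs(got$y - c(40, 90))), 1)
})

test_that("touching equal discs are split into near-equal halves", {
  frame <- matrix(0.02, 128, 128)
  frame[ellipse_mask(54, 64, 10, 10, 0, 128)] <- 1
  frame[ellipse_mask(73, 64, 10, 10, 0, 128)] <- 1  # overlapping by 1 px
  seg <- segment_frame(frame)
  expect_equal(max(seg$nuclei), 2)
  areas <- tabulate(seg$nuclei[seg$nuclei > 0])
  expect_gte(min(areas) / max(areas), 0.8)
})

test_that("every nucleus label is contained in exactly one cell label", {
  fx <- eventful_movie(1)
  for (f in c(1, 20, 40)) {
    m <- fx$res$masks[[f]]
    idx <- m$nuclei > 0
    expect_true(all(m$cells[idx] == m$nuclei[idx]))
    expect_true(all(m$cells[idx] > 0))
  }
})

test_that("quantification is exact for uniform cells and linear in intensity", {
  mask <- ellipse_mask(64, 64, 12, 8, 0.4, 128)
  nuc <- ellipse_mask(64, 64, 6, 4, 0.4, 128)
  masks <- list(cells = matrix(as.integer(mask), 128, 128),
                nuclei = matrix(as.integer(nuc), 128, 128))
  frame <- matrix(0.02, 128, 128); frame[mask] <- 1
  yfp <- matrix(0, 128, 128); yfp[mask] <- 3.5
  d <- detect_cells(frame, yfp, masks, 0)
  # uniform-intensity cell of area A and level v: total = A * v
  expect_equal(d$cell_area, sum(mask))
  expect_equal(d$total_yfp_cell, d$cell_area * 3.5, tolerance = 1e-9)
  d2 <- detect_cells(frame, yfp * 7, masks, 0)
  expect_equal(d2$total_yfp_cell, 7 * d$total_yfp_cell, tolerance = 1e-12)
})

test_that("tracking refuses links beyond the gate instead of mislinking", {
  det <- function(frame, x, y, label) {
    tibble::tibble(frame = frame, label = label, x = x, y = y,
                   nucleus_area = 100, cell_area = 200, roundness = 0.8,
                   mean_red_nuc = 1, mean_red_cyt = 0.3,
                   mean_yfp_nuc = 1, mean_yfp_cyt = 1, total_yfp_cell = 200)
  }
  # two cells swap positions 100 px apart in one step
  dets <- dplyr::bind_rows(det(0, 10, 10, 1), det(0, 110, 10, 2),
                           det(1, 110, 10, 1), det(1, 10, 10, 2))
  tr <- track_cells(dets, max_link_px = 50)
  # positions are preserved, so the stationary interpretation links them;
  # now force genuine displacement beyond the gate
  dets2 <- dplyr::bind_rows(det(0, 10, 10, 1), det(0, 200, 10, 2),
                            det(1, 120, 10, 1), det(1, 90, 10, 2))
  tr2 <- track_cells(dets2, max_link_px = 50)
  expect_equal(dplyr::n_distinct(tr2$detections$track_id), 4)
  expect_equal(nrow(tr2$merges), 0)
  # and the empty case
  tr0 <- track_cells(dets[0, ])
  expect_equal(nrow(tr0$detections), 0)
})

test_that("stationary noiseless cells track end-to-end with exact identity", {
  fx <- stationary_movie()
  res <- analyze_movie(fx$mov$red, fx$mov$yfp, dt_h = 0.5)
  n_frames <- dim(fx$mov$red)[3]
  lens <- table(res$tracked$detections$track_id)
  expect_true(all(lens == n_frames))
  la <- link_accuracy(res$tracked, fx$mov$cell_masks, fx$mov$cells)
  expect_equal(la$accuracy, 1)
  # no-motion contract: detected centroids drift < 0.5 px
  drift <- vapply(split(res$tracked$detections, res$tracked$detections$track_id),
                  function(td) max(abs(td$x - td$x[1]), abs(td$y - td$y[1])),
                  numeric(1))
  expect_lt(max(drift), 0.5)
})

test_that("death calls: constant tracks give none; threshold is monotone", {
  fx <- eventful_movie(1)
  dets <- fx$res$tracked$detections
  end_frame <- max(dets$frame)
  const <- dets[dets$track_id == dets$track_id[1], ]
  const$roundness <- 0.8
  const$mean_red_nuc <- 1; const$mean_red_cyt <- 0.25
  expect_null(detect_death(const, movie_end_frame = end_frame))

  thrs <- c(0.7, 0.8, 0.9, 0.95, 1.05)
  calls <- vapply(thrs, function(th)
    nrow(detect_deaths(fx$res$tracked, roundness_thr = th)), integer(1))
  expect_true(all(diff(calls) <= 0))
})

test_that("rounding explained by death is not double-counted as mitosis", {
  fx <- eventful_movie(1)
  deaths <- fx$res$deaths
  mit <- detect_mitosis(fx$res$tracked, deaths = deaths, dt_h = 0.5)
  if (nrow(mit) && nrow(deaths)) {
    for (i in seq_len(nrow(mit))) {
      dd <- deaths[deaths$track_id == mit$track_id[i], ]
      if (nrow(dd)) expect_true(all(dd$frame > mit$frame[i]))
    }
  }
  expect_true(all(mit$kind == "mitosis"))
})

test_that("quantified trajectories end at the death call and flag censoring", {
  fx <- eventful_movie(1)
  traj <- fx$res$trajectories
  expect_true(all(traj$fate %in% c("died", "survived", "censored")))
  died <- traj[traj$fate == "died", ]
  for (cl in split(died, died$cell_id)) {
    expect_lte(max(cl$time_h), cl$death_time_h[1] + 1e-9)
  }
  # a frame gap inside a track violates the contract
  bad <- fx$res$tracked
  keep <- !(bad$detections$track_id == bad$detections$track_id[1] &
              bad$detections$frame == 5)
  bad$detections <- bad$detections[keep, ]
  expect_error(quantify_tracks(bad), class = "bimodyn_tracking_error")
})

test_that("nuclear/cytoplasmic ratio: unity for uniform signal, flags translocation", {
  td <- tibble::tibble(frame = 0:19, track_id = 1, roundness = 0.8,
                       mean_yfp_nuc = 2, mean_yfp_cyt = 2,
                       mean_red_nuc = 1, mean_red_cyt = 0.3)
  nc <- nuclear_cytoplasmic_ratio(td)
  expect_true(all(abs(nc$series$ratio - 1) < 1e-12))
  expect_false(nc$flag)

  cfg <- quiet_config(n_cells = 5, noise_sd = 0.02, common_drift = 0,
                      slope_down = 0, seed = 7)
  sim <- simulate_clone(cfg)
  mov <- render_movie(sim, optics_params(translocate_frac = 0.7,
                                         translocate_onset_h = 20), seed = 8)
  res <- analyze_movie(mov$red, mov$yfp, dt_h = 0.5)
  long <- res$tracked$detections |>
    dplyr::count(track_id) |>
    dplyr::filter(n == dim(mov$red)[3])
  flags <- onsets <- c()
  for (id in long$track_id) {
    nc <- nuclear_cytoplasmic_ratio(
      res$tracked$detections[res$tracked$detections$track_id == id, ])
    flags <- c(flags, nc$flag); onsets <- c(onsets, nc$onset_h)
  }
  expect_true(all(flags))
  expect_true(all(abs(onsets - 20) <= 1.5))
})
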