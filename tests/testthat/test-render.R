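test_that("zero-cell movies are pure noise with empty masks", {
  empty_sim <- structure(list(
    trajectories = tibble::tibble(clone_id = character(0),
                                  cell_id = character(0), time_h = numeric(0),
                                  yfp = numeric(0), fate = character(0),
                                  death_time_h = numeric(0),
                                  mitosis_times_h = character(0)),
    truth = tibble::tibble(clone_id = character(0), cell_id = character(0),
                           subpop = character(0), fate = character(0),
                           death_time_h = numeric(0),
                           mitosis_times = list()),
    config = clone_config(n_cells = 1, horizon_h = 2, t_switch_h = 1)),
    class = "clone_sim")
  mov <- render_movie(empty_sim, optics_params(frame_px = 64), seed = 1)
  expect_true(all(mov$cell_masks == 0))
  expect_true(all(mov$nuc_masks == 0))
  expect_lt(max(mov$red), 0.1)  # background + noise only
})

test_that("a stationary noiseless cell keeps its centroid within half a pixel", {
  fx <- stationary_movie()
  for (tk in split(fx$mov$tracks, fx$mov$tracks$track_id)) {
    expect_lt(max(abs(tk$x - tk$x[1])), 0.5)
    expect_lt(max(abs(tk$y - tk$y[1])), 0.5)
  }
})

test_that("rendered nuclei are brighter than cytoplasm for every cell and frame", {
  fx <- eventful_movie(1)
  mov <- fx$mov
  for (f in seq(1, dim(mov$red)[3], by = 8)) {
    cm <- mov$cell_masks[, , f]; nm <- mov$nuc_masks[, , f]
    red <- mov$red[, , f]
    for (id in setdiff(unique(as.vector(cm)), 0)) {
      nuc <- red[nm == id]
      cyt <- red[cm == id & nm != id]
      if (length(nuc) > 10 && length(cyt) > 10)
        expect_gt(mean(nuc), mean(cyt))
    }
  }
})

test_that("ground-truth masks are disjoint and tracks are gap-free", {
  fx <- eventful_movie(1)
  mov <- fx$mov
  # disjointness is structural (labels are single integers per pixel); check
  # nucleus-in-cell containment instead, plus track continuity
  expect_true(all(mov$cell_masks[mov$nuc_masks > 0] ==
                    mov$nuc_masks[mov$nuc_masks > 0]))
  for (tk in split(mov$tracks, mov$tracks$track_id)) {
    expect_true(all(diff(sort(tk$frame)) == 1))
  }
  # every track id present from its first to last frame matches cells meta
  meta <- mov$cells
  spans <- dplyr::summarise(dplyr::group_by(mov$tracks, track_id),
                            first = min(frame), last = max(frame))
  j <- dplyr::left_join(spans, meta, by = "track_id")
  expect_true(all(j$first == j$first_frame))
  expect_true(all(j$last == j$last_frame))
})

test_that("rendering is deterministic in the seed", {
  cfg <- quiet_config(n_cells = 3, seed = 5, horizon_h = 4, t_switch_h = 2)
  sim <- simulate_clone(cfg)
  a <- render_movie(sim, optics_params(frame_px = 192), seed = 9)
  b <- render_movie(sim, optics_params(frame_px = 192), seed = 9)
  expect_identical(a$red, b$red)
  expect_identical(a$yfp, b$yfp)
  expect_identical(a$tracks, b$tracks)
  c <- render_movie(sim, optics_params(frame_px = 192), seed = 10)
  expect_false(identical(a$red, c$red))
})

test_that("overcrowded placement raises a placement error", {
  sim <- simulate_clone(quiet_config(n_cells = 40, horizon_h = 2,
                                     t_switch_h = 1))
  expect_error(render_movie(sim, optics_params(frame_px = 64), seed = 1),
               class = "bimodyn_placement_error")
})

test_that("rendered trajectories correlate with the generating levels", {
  cfg <- quiet_config(n_cells = 8, noise_sd = 0, is_bimodal = TRUE,
                      frac_up = 0.5, seed = 9)
  sim <- simulate_clone(cfg)
  mov <- render_movie(sim, optics_params(photon_scale = 0, read_noise_sd = 0),
                      seed = 10)
  res <- analyze_movie(mov$red, mov$yfp, dt_h = 0.5)
  dets <- assign_truth_ids(res$tracked$detections, mov$cell_masks)
  cors <- vapply(split(dets, dets$track_id), function(td) {
    ci <- mov$cells$cell_id[mov$cells$track_id == td$truth_id[1]]
    tt <- sim$trajectories[sim$trajectories$cell_id == ci, ]
    m <- merge(data.frame(time_h = td$frame * 0.5, v = td$total_yfp_cell),
               tt, by = "time_h")
    cor(m$v, m$yfp)
  }, numeric(1))
  expect_true(all(cors >= 0.99))
})
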