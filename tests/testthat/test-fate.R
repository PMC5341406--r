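coupled_panel <- function(n_clones = 8, seed = 31) {
  base <- clone_config(n_cells = 200, p_death_up = 0.9, p_death_down = 0.1)
  simulate_panel(n_clones, 0.5, base, seed = seed)
}

test_that("fate screen recovers the generating death-coupled direction", {
  p <- coupled_panel()
  scr <- bimodality_screen(p$trajectories)
  fs <- fate_screen(p$trajectories, scr)
  expect_gt(nrow(fs), 0)
  expect_true(all(fs$direction == "increase_correlates_death"))
  expect_true(all(!fs$underpowered))
})

test_that("survival-coupled clones get the opposite direction", {
  base <- clone_config(n_cells = 200, p_death_up = 0.1, p_death_down = 0.9)
  p <- simulate_panel(4, 1, base, seed = 35)
  scr <- bimodality_screen(p$trajectories)
  fs <- fate_screen(p$trajectories, scr)
  expect_true(all(fs$direction == "increase_correlates_survival"))
})

test_that("all-survived clones are underpowered with direction none", {
  sim <- simulate_clone(quiet_config(n_cells = 60, is_bimodal = TRUE, seed = 2))
  fs <- fate_screen(sim$trajectories)
  expect_true(fs$underpowered)
  expect_equal(fs$direction, "none")
  expect_true(is.na(fs$p_t))
})

test_that("permuted fate labels rarely produce a direction", {
  p <- coupled_panel(n_clones = 6, seed = 41)
  scr <- bimodality_screen(p$trajectories)
  cfg <- analysis_config()
  summ <- attr(scr, "summaries")
  summ <- summ[summ$usable & summ$clone_id %in% scr$clone_id[scr$is_bimodal], ]
  set.seed(99)
  n_sig <- 0L; n_tot <- 0L
  for (r in 1:60) {
    res <- lapply(split(summ, summ$clone_id), function(cl) {
      f <- sample(cl$fate)
      a <- cl$central_slope[f == "died"]; b <- cl$central_slope[f == "survived"]
      if (length(a) < cfg$fate_n_min || length(b) < cfg$fate_n_min) return(NULL)
      three_sample_tests(a, b)
    })
    res <- dplyr::bind_rows(res)
    if (nrow(res) == 0) next
    sig <- res$p_t < cfg$alpha & res$p_ks < cfg$alpha & res$p_mw < cfg$alpha &
      benjamini_hochberg(res$p_t, cfg$fdr_q) &
      benjamini_hochberg(res$p_ks, cfg$fdr_q) &
      benjamini_hochberg(res$p_mw, cfg$fdr_q)
    n_sig <- n_sig + sum(sig); n_tot <- n_tot + length(sig)
  }
  rate <- n_sig / n_tot
  expect_lte(rate, cfg$fdr_q + 3 * sqrt(cfg$fdr_q * (1 - cfg$fdr_q) / n_tot))
})

test_that("mitosis-timing fractions are exact counts and extremes separate", {
  cells <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:40),
    mitosis_times_h = c(rep("5", 20), rep("18", 10), rep("", 10)),
    fate = c(rep("survived", 20), rep("died", 20)))
  md <- mitosis_death_analysis(cells, cutoff_h = 12)
  expect_equal(md$bins$frac_killed, c(0, 1))
  expect_equal(md$bins$n, c(20, 20))
  expect_lt(md$p_value, 1e-6)
  expect_equal(md$bins$se, sqrt(md$bins$frac_killed *
                                  (1 - md$bins$frac_killed) / md$bins$n))
})

test_that("strict-late binning drops never-dividing cells from the late bin", {
  cells <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:30),
    mitosis_times_h = c(rep("4", 10), rep("20", 10), rep("", 10)),
    fate = rep(c("died", "survived"), 15))
  cap <- mitosis_death_analysis(cells, binning = "caption")
  strict <- mitosis_death_analysis(cells, binning = "strict_late")
  expect_equal(cap$bins$n, c(10, 20))
  expect_equal(strict$bins$n, c(10, 10))
})

test_that("generated killed fractions are recovered within binomial error", {
  pool <- simulate_mitosis_pool(n_early = 161, n_late = 120,
                                p_killed_early = 0.35, p_killed_late = 0.82,
                                seed = 5)
  md <- mitosis_death_analysis(pool)
  g <- glance(md)
  expect_lt(abs(g$frac_killed_early - 0.35), 3 * sqrt(0.35 * 0.65 / 161))
  expect_lt(abs(g$frac_killed_late - 0.82), 3 * sqrt(0.82 * 0.18 / 120))
  expect_equal(md$bins$n, c(161, 120))
})

test_that("null mitosis-timing rejection rate is calibrated", {
  set.seed(7)
  rej <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    pool <- simulate_mitosis_pool(n_early = 500, n_late = 500,
                                  p_killed_early = 0.5, p_killed_late = 0.5,
                                  seed = 1000 + r)
    md <- mitosis_death_analysis(pool)
    if (md$p_value < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("mean-profile classification follows the definitional cases", {
  t <- seq(0, 24, 0.5)
  expect_equal(classify_mean_profile(t, 100 + 5 * t), "up")
  expect_equal(classify_mean_profile(t, 100 - 2 * t), "down")
  downup <- ifelse(t <= 12, 100 - (40 / 12) * t, 60 + (30 / 12) * (t - 12))
  expect_equal(classify_mean_profile(t, downup), "down_up")
  expect_equal(classify_mean_profile(t, rep(100, length(t))), "down")
  expect_error(classify_mean_profile(seq(0, 8, 0.5), rep(1, 17)),
               class = "bimodyn_invalid_input")
})

test_that("profile classification is invariant to positive affine scaling", {
  t <- seq(0, 24, 0.5)
  shapes <- list(100 + 5 * t,
                 100 - 2 * t,
                 ifelse(t <= 12, 100 - 3 * t, 64 + 4 * (t - 12)))
  for (y in shapes) {
    ref <- classify_mean_profile(t, y)
    for (a in c(0.01, 3)) for (b in c(0, 500)) {
      expect_equal(classify_mean_profile(t, a * y + b), ref)
    }
  }
})

test_that("row z-scoring and zero-variance flagging", {
  m <- rbind(c(1, 2, 3), c(5, 5, 5))
  z <- normalize_dynamics_matrix(m)
  expect_equal(mean(z[1, ]), 0)
  expect_equal(sd(z[1, ]), 1)
  expect_equal(z[2, ], c(0, 0, 0))
  expect_identical(attr(z, "flagged"), c(FALSE, TRUE))

  set.seed(13)
  big <- matrix(rnorm(100 * 48), 100)
  zb <- normalize_dynamics_matrix(big)
  expect_true(all(abs(rowMeans(zb)) < 1e-12))
  expect_true(all(abs(apply(zb, 1, sd) - 1) < 1e-12))
})

test_that("cluster order keeps identical rows adjacent and is permutation-stable", {
  set.seed(17)
  base <- rnorm(10)
  m <- rbind(a = base, b = base + rnorm(10, 0, 1e-6), c = -base,
             d = rnorm(10))
  ord <- cluster_order(normalize_dynamics_matrix(m))
  pos <- match(1:2, ord)
  expect_equal(abs(diff(pos)), 1)
  expect_identical(cluster_order(m[1, , drop = FALSE]), 1L)

  perm <- c(3, 1, 4, 2)
  ord_p <- cluster_order(normalize_dynamics_matrix(m[perm, ]))
  # identical rows (now at permuted positions) stay adjacent
  pos_p <- match(match(1:2, perm), ord_p)
  expect_equal(abs(diff(pos_p)), 1)
})
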