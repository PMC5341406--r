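#' Configuration for one synthetic clone
#'
#' Generative parameters for a single tagged-protein clone filmed for
#' `horizon_h` hours at `dt_h` sampling. Trajectories follow a common drift
#' until `t_switch_h`; in a bimodal clone a fraction `frac_up` of cells then
#' rises at `slope_up` while the rest fall at `slope_down` (fluorescence
#' units per hour). Measurement noise is multiplicative log-normal.
#' Death probability is coupled to the subpopulation (`p_death_up`,
#' `p_death_down`); death times follow a Normal(`death_time_mean_h`,
#' `death_time_sd_h`) law truncated to `(t_switch_h, horizon_h]`, matching
#' the observed onset of drug-induced death around 15 +/- 3 h.
#'
#' @param n_cells number of cells to simulate.
#' @param dt_h sampling interval in hours.
#' @param horizon_h movie length in hours.
#' @param baseline_level starting fluorescence level (arbitrary units).
#' @param common_drift drift applied to all cells before `t_switch_h` and,
#'   for the "down"/unimodal population, a baseline to which `slope_down`
#'   takes over after the switch (fluorescence/h).
#' @param t_switch_h divergence onset in hours.
#' @param is_bimodal whether the clone carries two subpopulations.
#' @param frac_up fraction of cells in the rising subpopulation.
#' @param slope_up,slope_down post-switch slopes (fluorescence/h).
#' @param noise_sd log-scale SD of multiplicative measurement noise.
#' @param cell_level_sd log-scale SD of a per-cell additive level offset
#'   (whole-curve vertical shift); 0 disables cell-to-cell level scatter.
#' @param p_death_up,p_death_down death probabilities per subpopulation.
#' @param death_time_mean_h,death_time_sd_h death-time law (hours).
#' @param mitosis_rate mitosis events per cell per day.
#' @param seed RNG seed.
#' @return an object of class `clone_config` (a validated list).
#' @export
clone_config <- function(n_cells = 200, dt_h = 0.5, horizon_h = 24,
                         baseline_level = 1000, common_drift = 0,
                         t_switch_h = 12, is_bimodal = FALSE, frac_up = 0.5,
                         slope_up = 45, slope_down = -45, noise_sd = 0.1,
                         cell_level_sd = 0,
                         p_death_up = 0.3, p_death_down = 0.3,
                         death_time_mean_h = 15, death_time_sd_h = 3,
                         mitosis_rate = 0.3, seed = 1L) {
  cfg <- list(
    n_cells = n_cells, dt_h = dt_h, horizon_h = horizon_h,
    baseline_level = baseline_level, common_drift = common_drift,
    t_switch_h = t_switch_h, is_bimodal = isTRUE(is_bimodal),
    frac_up = frac_up, slope_up = slope_up, slope_down = slope_down,
    noise_sd = noise_sd, cell_level_sd = cell_level_sd,
    p_death_up = p_death_up, p_death_down = p_death_down,
    death_time_mean_h = death_time_mean_h, death_time_sd_h = death_time_sd_h,
    mitosis_rate = mitosis_rate, seed = as.integer(seed))
  validate_clone_config(cfg)
  structure(cfg, class = "clone_config")
}

validate_clone_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_bimodyn(msg, "bimodyn_invalid_config")
  chk(is.numeric(cfg$n_cells) && cfg$n_cells >= 1, "n_cells must be a positive count")
  chk(cfg$dt_h > 0, "dt_h must be positive")
  chk(cfg$horizon_h >= cfg$t_switch_h, "horizon_h must be >= t_switch_h")
  chk(cfg$frac_up >= 0 && cfg$frac_up <= 1, "frac_up must lie in [0, 1]")
  for (p in c("p_death_up", "p_death_down"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must lie in [0, 1]"))
  chk(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  chk(cfg$cell_level_sd >= 0, "cell_level_sd must be non-negative")
  chk(cfg$death_time_sd_h > 0, "death_time_sd_h must be positive")
  chk(cfg$mitosis_rate >= 0, "mitosis_rate must be non-negative")
  chk(cfg$baseline_level > 0, "baseline_level must be positive")
  invisible(cfg)
}

#' Analysis configuration for the bimodality and fate procedures
#'
#' Defaults follow the published procedure: slopes are computed in the
#' 12-20 h window after drug addition, clones need at least 10 cells in
#' both sign groups, each of the three tests is read at alpha = 0.05, and
#' Benjamini-Hochberg is applied per test family at FDR q = 0.1.
#'
#' @param t0_h,t1_h analysis window in hours after drug addition.
#' @param n_min minimum cells per sign group for eligibility.
#' @param alpha per-test significance level.
#' @param fdr_q Benjamini-Hochberg false-discovery rate.
#' @param central central slope statistic, `"mean"` or `"median"`.
#' @param mitosis_cutoff_h early/late mitosis boundary in hours.
#' @param slope_pairs `"consecutive"` (default) computes slopes between
#'   consecutive time points; `"all"` between all pairs in the window.
#' @param bh_scope `"per_test"` (default) runs BH separately on each test's
#'   p-vector across clones; `"pooled"` runs one BH over all 3m values.
#' @param fate_n_min minimum cells per fate group for the fate comparison.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(t0_h = 12, t1_h = 20, n_min = 10, alpha = 0.05,
                            fdr_q = 0.1, central = c("mean", "median"),
                            mitosis_cutoff_h = 12,
                            slope_pairs = c("consecutive", "all"),
                            bh_scope = c("per_test", "pooled"),
                            fate_n_min = 10) {
  central <- match.arg(central)
  slope_pairs <- match.arg(slope_pairs)
  bh_scope <- match.arg(bh_scope)
  chk <- function(ok, msg) if (!ok) stop_bimodyn(msg, "bimodyn_invalid_config")
  chk(t1_h > t0_h, "t1_h must exceed t0_h")
  chk(n_min >= 1, "n_min must be >= 1")
  chk(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  chk(fdr_q > 0 && fdr_q < 1, "fdr_q must lie in (0, 1)")
  structure(list(t0_h = t0_h, t1_h = t1_h, n_min = n_min, alpha = alpha,
                 fdr_q = fdr_q, central = central,
                 mitosis_cutoff_h = mitosis_cutoff_h,
                 slope_pairs = slope_pairs, bh_scope = bh_scope,
                 fate_n_min = fate_n_min),
            class = "analysis_config")
}

#' Segmentation parameters for the red (nuclear marker) channel
#'
#' @param smoothing_sigma Gaussian smoothing SD in pixels applied before
#'   thresholding.
#' @param min_nucleus_area minimum nucleus area in px^2; smaller objects are
#'   discarded as debris.
#' @param watershed_footprint tolerance (in distance-map units) for the
#'   watershed split of touching nuclei.
#' @param cytoplasm_threshold_scale cell (cytoplasm) threshold as a fraction
#'   of the Otsu nuclear threshold, in (0, 1].
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 2, min_nucleus_area = 50,
                                watershed_footprint = 1,
                                cytoplasm_threshold_scale = 0.4) {
  chk <- function(ok, msg) if (!ok) stop_bimodyn(msg, "bimodyn_invalid_config")
  chk(smoothing_sigma > 0, "smoothing_sigma must be positive")
  chk(min_nucleus_area > 0, "min_nucleus_area must be positive")
  chk(watershed_footprint > 0, "watershed_footprint must be positive")
  chk(cytoplasm_threshold_scale > 0 && cytoplasm_threshold_scale <= 1,
      "cytoplasm_threshold_scale must lie in (0, 1]")
  structure(list(smoothing_sigma = smoothing_sigma,
                 min_nucleus_area = min_nucleus_area,
                 watershed_footprint = watershed_footprint,
                 cytoplasm_threshold_scale = cytoplasm_threshold_scale),
            class = "segmentation_params")
}

#' Optical/rendering parameters for synthetic movies
#'
#' Cells are drawn as elongated ellipses (cytoplasm) containing a brighter
#' elliptical nucleus; rounding (mitosis or death) is rendered as a disc.
#' Defaults are calibrated so that the default Otsu threshold separates the
#' bright nuclei from the dimmer cytoplasm and background.
#'
#' @param frame_px frame side length in pixels (square frames).
#' @param cell_axis_px cell ellipse semi-major axis in pixels.
#' @param cell_axis_ratio cell major/minor axis ratio for normal cells.
#' @param nucleus_axis_px nucleus semi-major axis in pixels.
#' @param nucleus_axis_ratio nucleus major/minor axis ratio.
#' @param nucleus_intensity,cytoplasm_intensity,background_intensity red
#'   channel intensities (arbitrary units in \[0, 1\]).
#' @param dying_nucleus_intensity,dying_cytoplasm_intensity red intensities
#'   of a dying cell: the nuclear/cytoplasm contrast collapses (envelope
#'   breakdown leaks the nuclear marker) while the nucleus stays bright
#'   enough to remain segmentable.
#' @param yfp_scale yellow-channel pixel intensity per unit of per-cell
#'   trajectory level, spread over the cell area.
#' @param blur_sigma Gaussian optical blur SD in pixels.
#' @param photon_scale photons per intensity unit for Poisson shot noise
#'   (larger = cleaner); 0 disables shot noise.
#' @param read_noise_sd additive Gaussian read noise SD; 0 disables.
#' @param motion_sd random-walk step SD in pixels per frame.
#' @param min_separation_px minimum centre-to-centre distance kept between
#'   cells at placement and during motion.
#' @param vignette_strength relative corner darkening of the simulated
#'   flat-field (0 = flat illumination).
#' @param death_linger_frames frames a rounded, low-contrast dying cell
#'   remains visible before disappearing.
#' @param mitosis_round_frames frames of parent rounding before the split.
#' @param translocate_frac fraction of yellow signal moved into the nucleus
#'   after `translocate_onset_h` (0 disables translocation rendering).
#' @param translocate_onset_h translocation onset time in hours.
#' @return an object of class `optics_params`.
#' @export
optics_params <- function(frame_px = 256, cell_axis_px = 18,
                          cell_axis_ratio = 2.8, nucleus_axis_px = 8,
                          nucleus_axis_ratio = 1.45,
                          nucleus_intensity = 1, cytoplasm_intensity = 0.25,
                          dying_nucleus_intensity = 0.48,
                          dying_cytoplasm_intensity = 0.34,
                          background_intensity = 0.02, yfp_scale = 1e-3,
                          blur_sigma = 1, photon_scale = 400,
                          read_noise_sd = 0.005, motion_sd = 1.5,
                          min_separation_px = 44, vignette_strength = 0,
                          death_linger_frames = 2, mitosis_round_frames = 2,
                          translocate_frac = 0, translocate_onset_h = 20) {
  chk <- function(ok, msg) if (!ok) stop_bimodyn(msg, "bimodyn_invalid_config")
  chk(frame_px >= 64, "frame_px must be >= 64")
  chk(cell_axis_px > nucleus_axis_px, "cell axis must exceed nucleus axis")
  chk(nucleus_intensity > cytoplasm_intensity,
      "nucleus must be brighter than cytoplasm")
  chk(cytoplasm_intensity > background_intensity,
      "cytoplasm must be brighter than background")
  chk(translocate_frac >= 0 && translocate_frac < 1,
      "translocate_frac must lie in [0, 1)")
  structure(list(frame_px = frame_px, cell_axis_px = cell_axis_px,
                 cell_axis_ratio = cell_axis_ratio,
                 nucleus_axis_px = nucleus_axis_px,
                 nucleus_axis_ratio = nucleus_axis_ratio,
                 nucleus_intensity = nucleus_intensity,
                 cytoplasm_intensity = cytoplasm_intensity,
                 dying_nucleus_intensity = dying_nucleus_intensity,
                 dying_cytoplasm_intensity = dying_cytoplasm_intensity,
                 background_intensity = background_intensity,
                 yfp_scale = yfp_scale, blur_sigma = blur_sigma,
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 motion_sd = motion_sd, min_separation_px = min_separation_px,
                 vignette_strength = vignette_strength,
                 death_linger_frames = death_linger_frames,
                 mitosis_round_frames = mitosis_round_frames,
                 translocate_frac = translocate_frac,
                 translocate_onset_h = translocate_onset_h),
            class = "optics_params")
}
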