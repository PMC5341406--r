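#' Simulate one clone's per-cell trajectories with ground truth
#'
#' Generates per-cell YFP trajectories for a single tagged-protein clone.
#' Every cell follows `baseline_level + common_drift * t` until
#' `t_switch_h`; afterwards cells in the "up" subpopulation rise at
#' `slope_up` and the rest fall at `slope_down`. Measurement noise is
#' multiplicative log-normal (`level * exp(eps)`, `eps ~ N(0, noise_sd^2)`).
#' Each cell dies with the probability of its subpopulation; death times are
#' Normal(`death_time_mean_h`, `death_time_sd_h`) truncated to
#' `(t_switch_h, horizon_h]`, and samples at or after the death time are
#' dropped (the cell is lost to segmentation, not measured as zero).
#' Mitoses arrive as a Poisson process (`mitosis_rate` per day); the level
#' halves at each division and one daughter lineage is followed.
#'
#' @param config a [clone_config()].
#' @param clone_id identifier stored in the output tables.
#' @return A list of class `clone_sim` with elements
#'   * `trajectories`: tibble with columns `clone_id, cell_id, time_h, yfp,
#'     fate, death_time_h, mitosis_times_h` (long format, one row per
#'     retained sample; `mitosis_times_h` is a `;`-joined string),
#'   * `truth`: one row per cell with `subpop`, `fate`, `death_time_h` and a
#'     `mitosis_times` list-column,
#'   * `config`: the input configuration.
#' @examples
#' sim <- simulate_clone(clone_config(n_cells = 20, seed = 7))
#' head(sim$trajectories)
#' @export
simulate_clone <- function(config, clone_id = "clone01") {
  if (!inherits(config, "clone_config")) config <- do.call(clone_config, config)
  validate_clone_config(config)
  local_rng(config$seed)
  times <- seq(0, config$horizon_h, by = config$dt_h)
  n <- as.integer(config$n_cells)

  subpop <- rep("down", n)
  if (config$is_bimodal) {
    n_up <- round(config$frac_up * n)
    subpop[seq_len(n_up)] <- "up"
    subpop <- subpop[sample.int(n)]
  }

  cell_ids <- sprintf("c%03d", seq_len(n))
  keep_t <- vector("list", n); keep_y <- vector("list", n)
  fate_v <- character(n); death_v <- numeric(n); mit_v <- character(n)
  mit_list <- vector("list", n)
  for (i in seq_len(n)) {
    slope <- if (subpop[i] == "up") config$slope_up else config$slope_down
    offset <- if (config$cell_level_sd > 0)
      config$baseline_level * (exp(rnorm(1, 0, config$cell_level_sd)) - 1) else 0
    path <- mean_path(times, config, slope) + offset

    n_mit <- rpois(1, config$mitosis_rate * config$horizon_h / 24)
    mit_times <- if (n_mit > 0) sort(runif(n_mit, 0, config$horizon_h)) else numeric(0)
    if (n_mit > 0) {
      halving <- 0.5^vapply(times, function(t) sum(mit_times <= t), numeric(1))
      path <- path * halving
    }
    path <- pmax(path, config$baseline_level * 1e-6)

    p_death <- if (subpop[i] == "up") config$p_death_up else config$p_death_down
    died <- runif(1) < p_death
    death_time <- if (died)
      rtrunc_norm(1, config$death_time_mean_h, config$death_time_sd_h,
                  config$t_switch_h, config$horizon_h) else NA_real_

    eps <- if (config$noise_sd > 0) rnorm(length(times), 0, config$noise_sd)
           else rep(0, length(times))
    yfp <- path * exp(eps)
    keep <- if (died) times < death_time else rep(TRUE, length(times))

    keep_t[[i]] <- times[keep]
    keep_y[[i]] <- yfp[keep]
    fate_v[i] <- if (died) "died" else "survived"
    death_v[i] <- death_time
    mit_v[i] <- if (n_mit > 0)
      paste(sprintf("%.10g", mit_times), collapse = ";") else ""
    mit_list[[i]] <- mit_times
  }
  n_per <- lengths(keep_t)
  trajectories <- tibble(
    clone_id = clone_id,
    cell_id = rep(cell_ids, n_per),
    time_h = unlist(keep_t, use.names = FALSE),
    yfp = unlist(keep_y, use.names = FALSE),
    fate = rep(fate_v, n_per),
    death_time_h = rep(death_v, n_per),
    mitosis_times_h = rep(mit_v, n_per))
  truth <- tibble(clone_id = clone_id, cell_id = cell_ids, subpop = subpop,
                  fate = fate_v, death_time_h = death_v,
                  mitosis_times = mit_list)
  structure(list(trajectories = trajectories, truth = truth, config = config),
            class = "clone_sim")
}

# piecewise-linear deterministic mean level
mean_path <- function(times, config, slope) {
  pre <- config$baseline_level + config$common_drift * pmin(times, config$t_switch_h)
  post <- slope * pmax(times - config$t_switch_h, 0)
  pre + post
}

# Truncated-normal sampling by inverse CDF on (lower, upper].
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

# Moments of the truncated law; used by callers and tests as the reference.
trunc_norm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd; b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = m, sd = sqrt(v))
}

#' Simulate a panel of clones emulating a protein screen
#'
#' Generates `n_clones` clones of which `round(frac_bimodal * n_clones)`
#' are bimodal; the rest are unimodal decliners driven by a strong common
#' drift. Which clones are bimodal is shuffled deterministically from the
#' master seed, and each clone receives its own derived seed.
#'
#' @param n_clones number of clones.
#' @param frac_bimodal fraction of bimodal clones in \[0, 1\].
#' @param base_config [clone_config()] used for every clone (the bimodal
#'   flag, drift and per-clone seed are overridden per clone).
#' @param seed master seed.
#' @param unimodal_drift common drift (fluorescence/h) given to unimodal
#'   clones before and after the switch.
#' @return A list of class `panel_sim` with `trajectories` and `truth`
#'   tibbles pooled over clones, a per-clone `clone_truth` tibble
#'   (`clone_id`, `is_bimodal`, `seed`) and the `base_config`.
#' @export
simulate_panel <- function(n_clones, frac_bimodal, base_config = clone_config(),
                           seed = 1L, unimodal_drift = -30) {
  if (n_clones < 1) stop_bimodyn("n_clones must be >= 1", "bimodyn_invalid_config")
  if (frac_bimodal < 0 || frac_bimodal > 1)
    stop_bimodyn("frac_bimodal must lie in [0, 1]", "bimodyn_invalid_config")
  n_bim <- round(frac_bimodal * n_clones)
  flags <- rep(FALSE, n_clones)
  flags[seq_len(n_bim)] <- TRUE
  local_rng(derive_seed(seed, "panel-shuffle"))
  flags <- flags[sample.int(n_clones)]

  clone_ids <- sprintf("clone%03d", seq_len(n_clones))
  sims <- vector("list", n_clones)
  seeds <- integer(n_clones)
  for (k in seq_len(n_clones)) {
    seeds[k] <- derive_seed(seed, "clone", clone_ids[k])
    cfg <- unclass(base_config)
    cfg$is_bimodal <- flags[k]
    cfg$seed <- seeds[k]
    if (!flags[k]) {
      cfg$common_drift <- unimodal_drift
      cfg$slope_down <- unimodal_drift
    }
    sims[[k]] <- simulate_clone(do.call(clone_config, cfg), clone_id = clone_ids[k])
  }
  structure(list(
    trajectories = bind_rows(lapply(sims, `[[`, "trajectories")),
    truth = bind_rows(lapply(sims, `[[`, "truth")),
    clone_truth = tibble(clone_id = clone_ids, is_bimodal = flags, seed = seeds),
    base_config = base_config),
    class = "panel_sim")
}

#' Simulate a pooled mitosis-timing/fate cohort
#'
#' Builds a cell pool mirroring a mitosis-timing analysis: `n_early` cells
#' show a mitosis before `cutoff_h` and are killed with probability
#' `p_killed_early`; `n_late` cells show no early mitosis (half of them a
#' late mitosis, half none) and are killed with probability `p_killed_late`.
#'
#' @param n_early,n_late bin sizes.
#' @param p_killed_early,p_killed_late killed fractions used as generating
#'   probabilities.
#' @param cutoff_h early/late boundary (hours).
#' @param horizon_h movie length (hours).
#' @param seed RNG seed.
#' @return tibble with `cell_id`, `mitosis_times_h` (string), `fate`.
#' @export
simulate_mitosis_pool <- function(n_early = 161, n_late = 120,
                                  p_killed_early = 0.35, p_killed_late = 0.82,
                                  cutoff_h = 12, horizon_h = 24, seed = 1L) {
  local_rng(seed)
  n <- n_early + n_late
  early <- c(rep(TRUE, n_early), rep(FALSE, n_late))
  mit <- character(n)
  for (i in seq_len(n)) {
    if (early[i]) {
      mit[i] <- sprintf("%.10g", runif(1, 0.5, cutoff_h - 1e-6))
    } else {
      mit[i] <- if (runif(1) < 0.5)
        sprintf("%.10g", runif(1, cutoff_h + 0.5, horizon_h - 1))
      else ""
    }
  }
  p <- ifelse(early, p_killed_early, p_killed_late)
  fate <- ifelse(runif(n) < p, "died", "survived")
  tibble(cell_id = sprintf("c%04d", seq_len(n)),
         mitosis_times_h = mit, fate = fate)
}
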