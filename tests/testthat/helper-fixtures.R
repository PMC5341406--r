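# Shared fixtures and independent oracles for the test suite.

# clone config with the stochastic extras (death, mitosis) switched off
quiet_config <- function(...) {
  args <- utils::modifyList(
    list(p_death_up = 0, p_death_down = 0, mitosis_rate = 0, seed = 1L),
    list(...))
  do.call(clone_config, args)
}

# Lazily built, cached rendered-movie fixtures (rendering is the slow part).
.fixtures <- new.env(parent = emptyenv())

eventful_movie <- function(k = 1) {
  key <- paste0("eventful", k)
  if (is.null(.fixtures[[key]])) {
    cfg <- clone_config(n_cells = 12, noise_sd = 0.05, is_bimodal = TRUE,
                        frac_up = 0.5, mitosis_rate = 0.6,
                        p_death_up = 0.5, p_death_down = 0.5, seed = 10 + k)
    sim <- simulate_clone(cfg)
    mov <- render_movie(sim, optics_params(), seed = 20 + k)
    res <- analyze_movie(mov$red, mov$yfp, dt_h = mov$dt_h)
    .fixtures[[key]] <- list(sim = sim, mov = mov, res = res)
  }
  .fixtures[[key]]
}

stationary_movie <- function() {
  if (is.null(.fixtures$stationary)) {
    cfg <- quiet_config(n_cells = 6, noise_sd = 0, is_bimodal = FALSE,
                        common_drift = 0, slope_down = 0, seed = 3)
    sim <- simulate_clone(cfg)
    mov <- render_movie(sim, optics_params(motion_sd = 0, photon_scale = 0,
                                           read_noise_sd = 0), seed = 4)
    .fixtures$stationary <- list(sim = sim, mov = mov)
  }
  .fixtures$stationary
}

# literal step-up enumeration of the Benjamini-Hochberg rule, kept
# independent of the package implementation
bh_oracle <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ps <- sort(p)
  passing <- which(ps <= seq_len(m) * q / m)
  if (length(passing) == 0) return(rep(FALSE, m))
  thr <- ps[max(passing)]
  p <= thr
}

# filled ellipse mask as a plain matrix (independent of the renderer)
ellipse_mask <- function(cx, cy, a, b, theta = 0, dim_px = 128) {
  g <- expand.grid(x = seq_len(dim_px), y = seq_len(dim_px))
  dx <- g$x - cx; dy <- g$y - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  matrix((xr / a)^2 + (yr / b)^2 <= 1, dim_px, dim_px)
}
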