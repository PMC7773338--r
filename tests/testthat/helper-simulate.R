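# Shared fixture builders; everything is generated in code at test time.

# homogeneous Poisson train on [0, dur)
sim_poisson_train <- function(rate, dur, seed) {
  set.seed(seed)
  st <- cumsum(stats::rexp(ceiling(rate * dur * 1.5) + 50, rate))
  st[st < dur]
}

# sinusoidally rate-modulated (theta-rhythmic) Poisson train
sim_rhythmic_train <- function(rate0, f, depth, dur, seed, dt = 0.001) {
  set.seed(seed)
  t <- seq(dt, dur, by = dt)
  lam <- rate0 * (1 + depth * cos(2 * pi * f * t))
  t[stats::runif(length(t)) < lam * dt]
}

# quick foraging trajectory
quick_trajectory <- function(duration = 600, seed = 1, ...) {
  simulate_trajectory(trajectory_config(duration = duration, seed = seed,
                                        ...))
}

# small complete session with a grid cell and a theta LFP
quick_session <- function(duration = 720, seed = 5, cells = NULL) {
  if (is.null(cells)) {
    cells <- list(g1 = grid_spec(spacing = 42, peak_rate = 6))
  }
  make_session(trajectory_config(duration = duration, seed = seed),
               cell_specs = cells, lfp = lfp_spec(noise_sd = 0.2),
               epoch_length = 180, seed = seed)
}

# smoothed white-noise rate surface (a null map for grid scoring)
smooth_map_noise <- function(nb) {
  gridtheta:::smooth_map(matrix(stats::rnorm(nb^2), nb, nb), 1)
}

wrap_phase <- function(p) p %% (2 * pi)

# condition membership mask on a time grid
in_epochs_vec <- function(t, epochs, condition = NULL) {
  if (!is.null(condition)) epochs <- epochs[epochs$condition == condition, ]
  gridtheta:::in_epochs(t, epochs)
}

# spike train with epoch-wise constant rates laid down deterministically
# (regular spacing) so epoch mean rates are exact
regular_epoch_train <- function(epochs, rates) {
  unlist(lapply(seq_len(nrow(epochs)), function(i) {
    n <- round(rates[i] * (epochs$end[i] - epochs$start[i]))
    if (n == 0) return(numeric(0))
    seq(epochs$start[i], epochs$end[i] - 1e-9, length.out = n + 1)[1:n]
  }))
}
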