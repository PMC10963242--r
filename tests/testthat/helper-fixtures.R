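# Shared fixtures: all synthetic, built in code at test time.

# A clean (noise-free) record with known ground truth.
clean_record <- function(heart_rate = 72, duration = 2.1, seed = 1, ...) {
  generate_record(beat_config(heart_rate = heart_rate, ...), no_noise(),
                  duration = duration, seed = seed)
}

# Best cycle of a clean record, plus its truth table and onset offset.
clean_best_cycle <- function(heart_rate = 72, seed = 1, ...) {
  gr <- clean_record(heart_rate = heart_rate, seed = seed, ...)
  rec <- preprocess_record(gr$record)
  cycles <- segment_cycles(rec, detect_systolic_peaks(rec))
  best <- select_best_cycle(cycles)
  list(cycle = best, truth = gr$truth,
       onset_t = (best$onset_index - 1) / rec$fs, record = rec)
}

# A single-Gaussian pulse cycle with analytically known shape.
gaussian_cycle <- function(mu = 0.3, s = 0.06, duration = 0.8, fs = 1000,
                           amplitude = 1) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  ppg_cycle(amplitude * exp(-(tt - mu)^2 / (2 * s^2)), onset_index = 1L, fs = fs)
}

# Tiny deterministic feature fixture for selection oracles.
toy_matrix <- function(n = 5, p = 2, seed = 11) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("F", seq_len(p))))
  y <- stats::rnorm(n)
  list(X = X, y = y)
}
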