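# Deterministic quasi-irregular NN series used by the frozen-oracle tests.
oracle_nn <- function(n = 400L) {
  i <- seq_len(n)
  nn_series(850 + 35 * sin(0.3 * i) + 20 * cos(1.7 * i) + 12 * sin(0.71 * i))
}

# A complete 5-min segment for a given channel, on-grid.
make_segment <- function(channel, values, fs, slot = 12L, day = 0L,
                         subject = "s1") {
  rec <- channel_recording(channel, day * 86400 + slot * 300, fs, values)
  segs <- segment_day(rec, day, subject_id = subject)
  segs[[which(vapply(segs, function(s) s$slot, integer(1)) == slot)]]
}

# Brute-force BH step-up: reject while p_(i) <= i/m * q, adjusted values by
# direct minimization (independent of stats::p.adjust).
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    i <- ord[k]
    adj[i] <- min(1, min(p[ord[k:m]] * m / seq(k, m)))
  }
  adj
}

# Small interval-style dataset with a planted linear feature-outcome coupling.
planted_dataset <- function(n_subj = 10L, n_int = 7L, slope = 1,
                            noise = 0.3, seed = 1L) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", seq_len(n_subj)), each = n_int)
  y0 <- rnorm(n_subj); y1 <- y0 + rnorm(n_subj, 0.2, 0.4)
  y <- unlist(lapply(seq_len(n_subj), function(s) {
    gompertz_series(y0[s], y1[s], n_int)
  }))
  x_signal <- slope * y + rnorm(length(y), 0, noise)
  data.frame(subject_id = subj, interval = rep(seq_len(n_int), n_subj),
             age = rep(sample(50:70, n_subj, TRUE), each = n_int),
             sex = rep(sample(0:1, n_subj, TRUE), each = n_int),
             f_signal = x_signal,
             f_noise1 = rnorm(length(y)), f_noise2 = rnorm(length(y)),
             f_noise3 = rnorm(length(y)),
             y = y)
}
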