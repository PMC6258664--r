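# fixture builders shared across the suite (all generated in code)

# a sine-carrier channel with a piecewise amplitude envelope
sine_channel <- function(env, freq = 80, fs = 1000, muscle = "M1",
                         movement = "A1", phase = 0) {
  n <- length(env)
  channel_signal(env * sin(2 * pi * freq * seq_len(n) / fs + phase),
                 fs, muscle, movement)
}

# six-channel recording built from one generator function(muscle) -> values
make_recording <- function(movement, gen, fs = 1000) {
  movement_recording(movement, lapply(paste0("M", 1:6), function(m)
    channel_signal(gen(m), fs, m, movement)))
}

# small band-limited-noise subject via the simulator at reduced size
quick_sim_config <- function(n_cs, n_healthy, effect_size = 1, seed = 1,
                             fs = 500, duration_s = 3, missing_rate = 0) {
  simulation_config(n_cs, n_healthy, fs = fs, duration_s = duration_s,
                    effect_size = effect_size, missing_rate = missing_rate,
                    seed = seed)
}

# tabular fixture: subject-grouped feature table of gaussian noise columns,
# optionally with planted informative columns (shifted by the label)
noise_table <- function(n_subjects, n_features, reps = 3, seed = 1,
                        informative = integer(0), shift = 2) {
  set.seed(seed)
  subj <- sprintf("s%03d", seq_len(n_subjects))
  lab <- rep(c(1L, 0L), length.out = n_subjects)
  df <- data.frame(
    subject_id = rep(subj, each = reps),
    label = rep(lab, each = reps),
    repetition = rep(seq_len(reps), n_subjects))
  X <- matrix(rnorm(nrow(df) * n_features), nrow(df), n_features,
              dimnames = list(NULL, sprintf("F%04d", seq_len(n_features))))
  for (j in informative) X[, j] <- X[, j] + shift * df$label
  feature_table(cbind(df, as.data.frame(X)), canonical = FALSE)
}

# brute-force concordant-pair AUC (independent oracle)
auc_pair_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force best-gain stump search (independent oracle for the booster)
stump_oracle <- function(X, g, h, lambda, gamma) {
  G <- sum(g); H <- sum(h)
  parent <- G^2 / (H + lambda)
  best <- list(gain = 0, feature = NA, threshold = NA)
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      L <- X[, j] < thr
      GL <- sum(g[L]); HL <- sum(h[L])
      GR <- G - GL; HR <- H - HL
      gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent) - gamma
      if (gain > best$gain + 1e-12) best <- list(gain = gain, feature = j,
                                                 threshold = thr)
    }
  }
  best
}
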