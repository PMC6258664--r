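# ---- movement-level features: FRR (2, A1 only) + DU (7) + ACI (15) + UN (9) + SYM (12)

#' Sliding-window RMS envelope
#'
#' RMS over `win_s`-second windows with 50% overlap. Windows are indexed by
#' their centers.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param win_s window length in seconds (default 0.1).
#' @return list with `t` (window-center times, s), `env` (RMS values),
#'   `win_s`.
#' @export
rms_envelope <- function(x, fs, win_s = 0.1) {
  wn <- max(2L, round(win_s * fs))
  step <- max(1L, wn %/% 2L)
  starts <- seq(1L, length(x) - wn + 1L, by = step)
  x2 <- c(0, cumsum(x^2))
  env <- sqrt((x2[starts + wn] - x2[starts]) / wn)
  list(t = (starts + (wn - 1) / 2 - 1) / fs, env = env, win_s = wn / fs)
}

#' Cervical flexion-relaxation ratio (family FRR, 2 values, A1 only)
#'
#' For each cervical erector spinae channel (M3 left, M4 right):
#' FRR = max smoothed-RMS envelope during the motion thirds divided by the
#' mean envelope during the middle hold third. Only envelope windows fully
#' contained in a phase contribute. Healthy paraspinal muscles relax in full
#' flexion (high FRR); loss of that relaxation marks pathology.
#'
#' @param recording a [movement_recording()] with `movement == "A1"`.
#' @param win_s envelope window length in seconds.
#' @return named numeric vector `FRR_1` (M3), `FRR_2` (M4).
#' @export
frr <- function(recording, win_s = 0.1) {
  stopifnot(inherits(recording, "movement_recording"))
  if (recording$movement != "A1")
    stop("FRR is defined only for movement A1 (bow)")
  fs <- recording$fs
  dur <- recording$n / fs
  b1 <- dur / 3; b2 <- 2 * dur / 3
  out <- vapply(c("M3", "M4"), function(mus) {
    e <- rms_envelope(recording$channels[[mus]]$values, fs, win_s)
    half <- e$win_s / 2
    lo <- e$t - half; hi <- e$t + half
    motion <- hi <= b1 | lo >= b2
    hold <- lo >= b1 & hi <= b2
    if (!any(motion) || !any(hold))
      stop("recording too short for FRR phase windows")
    denom <- mean(e$env[hold])
    if (denom <= 0) stop("silent hold phase")
    max(e$env[motion]) / denom
  }, numeric(1))
  names(out) <- c("FRR_1", "FRR_2")
  out
}

# median frequency alone, for the symmetry features
median_frequency <- function(x, fs) {
  as.numeric(frequency_domain_features(x, fs = fs)[["FF_01"]])
}

#' Movement-level features (families DU, ACI, UN, SYM; 43 values)
#'
#' DU (7): per-channel activation duration in seconds (envelope above 20% of
#' its 95th percentile) plus the overall duration where any channel is
#' active. ACI (15): Pearson correlation of the RMS envelopes of all 15
#' unordered channel pairs (ordered (1,2), (1,3), ..., (5,6); 0 when an
#' envelope is constant). UN (9): the six channel shares of total movement
#' energy, the normalized Shannon entropy of the share vector, its
#' coefficient of variation, and the maximum share. SYM (12): for the three
#' left/right muscle pairs (M1/M6, M2/M5, M3/M4): RMS ratio, median-frequency
#' ratio, zero-lag normalized envelope cross-correlation, and the energy
#' difference index (EL - ER)/(EL + ER).
#'
#' @param recording a [movement_recording()].
#' @param win_s envelope window length in seconds.
#' @param du_rel_threshold activation threshold as a fraction of the 95th
#'   envelope percentile.
#' @return named numeric vector of length 43.
#' @export
movement_features <- function(recording, win_s = 0.1,
                              du_rel_threshold = 0.2) {
  stopifnot(inherits(recording, "movement_recording"))
  fs <- recording$fs
  dur <- recording$n / fs
  vals <- lapply(recording$channels, function(ch) ch$values)
  energies <- vapply(vals, function(v) sum(v^2), numeric(1))
  if (sum(energies) <= 0) stop("zero total energy in recording")
  envs <- lapply(vals, function(v) rms_envelope(v, fs, win_s)$env)

  # DU: activation durations
  active <- lapply(envs, function(e) {
    thr <- du_rel_threshold * quantile(e, 0.95, names = FALSE)
    e > thr
  })
  nw <- length(envs[[1]])
  du_ch <- vapply(active, function(a) dur * sum(a) / nw, numeric(1))
  du_all <- dur * sum(Reduce(`|`, active)) / nw
  du <- c(du_ch, du_all)

  # ACI: envelope co-activation correlations, pairs in lexicographic order
  pairs <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  aci <- apply(pairs, 1, function(ij) {
    a <- envs[[ij[1]]]; b <- envs[[ij[2]]]
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  })

  # UN: energy shares
  shares <- energies / sum(energies)
  ent <- -sum(ifelse(shares > 0, shares * log(shares), 0)) / log(6)
  cv <- sd(shares) / mean(shares)
  un <- c(shares, ent, cv, max(shares))

  # SYM: left/right pairs
  sym_pairs <- list(c("M1", "M6"), c("M2", "M5"), c("M3", "M4"))
  sym <- unlist(lapply(sym_pairs, function(pr) {
    l <- vals[[pr[1]]]; r <- vals[[pr[2]]]
    el <- envs[[pr[1]]]; er <- envs[[pr[2]]]
    rms_ratio <- sqrt(mean(l^2)) / sqrt(mean(r^2))
    mf_ratio <- median_frequency(l, fs) / median_frequency(r, fs)
    xc <- sum(el * er) / sqrt(sum(el^2) * sum(er^2))
    ei <- (sum(l^2) - sum(r^2)) / (sum(l^2) + sum(r^2))
    c(rms_ratio, mf_ratio, xc, ei)
  }))

  out <- c(du, aci, un, sym)
  names(out) <- c(sprintf("DU_%02d", 1:7), sprintf("ACI_%02d", 1:15),
                  sprintf("UN_%02d", 1:9), sprintf("SYM_%02d", 1:12))
  out
}

#' Extract the full 2949-dimensional feature vector of one sample
#'
#' Concatenates, in canonical order, for each movement A1..A7: the
#' movement-scope families (FRR for A1 only, then DU, ACI, UN, SYM) and the
#' per-channel blocks M1..M6 (TF, FF, WL, WLP, AR, EY). A1 contributes 423
#' values, each other movement 421.
#'
#' @param sample a [subject_sample()].
#' @return named numeric vector of length 2949, names equal to
#'   [canonical_feature_names()].
#' @export
extract_sample <- function(sample) {
  stopifnot(inherits(sample, "subject_sample"))
  blocks <- lapply(MOVEMENTS, function(mov) {
    rec <- sample$recordings[[mov]]
    v <- numeric(0)
    if (mov == "A1") {
      v <- c(v, with_feature_context(paste0(mov, "_FRR"), frr(rec)))
    }
    v <- c(v, with_feature_context(paste0(mov, "_mov"),
                                   movement_features(rec)))
    for (mus in MUSCLES) {
      v <- c(v, with_feature_context(paste0(mov, "_", mus),
                                     channel_features(rec$channels[[mus]])))
    }
    v
  })
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- canonical_feature_names()
  out
}

# re-raise extractor errors tagged with the offending feature block
with_feature_context <- function(tag, expr) {
  tryCatch(expr, error = function(e)
    stop(tag, ": ", conditionMessage(e), call. = FALSE))
}

#' Extract a feature table from a cohort of samples
#'
#' @param samples list of [subject_sample()] objects.
#' @param missing_plan optional data.frame (`row`, `feature`) of cells to
#'   blank after extraction, e.g. from [simulate_cohort()].
#' @param progress print a dot every 10 samples.
#' @return a canonical `feature_table` with one row per sample.
#' @export
extract_cohort <- function(samples, missing_plan = NULL, progress = FALSE) {
  canon <- canonical_feature_names()
  mat <- matrix(NA_real_, nrow = length(samples), ncol = length(canon),
                dimnames = list(NULL, canon))
  meta <- data.frame(subject_id = character(length(samples)),
                     label = integer(length(samples)),
                     repetition = integer(length(samples)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    mat[i, ] <- extract_sample(s)
    meta$subject_id[i] <- s$subject_id
    meta$label[i] <- s$label
    meta$repetition[i] <- s$repetition
    if (progress && i %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  if (!is.null(missing_plan) && nrow(missing_plan) > 0) {
    for (k in seq_len(nrow(missing_plan)))
      mat[missing_plan$row[k], missing_plan$feature[k]] <- NA_real_
  }
  feature_table(cbind(meta, as.data.frame(mat)))
}

#' Mean-imputation of missing feature cells
#'
#' `class_mean` (training time, labels known): missing cells in CS rows are
#' filled with the column mean over observed CS rows, healthy rows with the
#' healthy-row means. `global_mean` (inference time): column means over all
#' rows, or externally supplied `means` (e.g. computed on a training set).
#' Observed cells are never altered.
#'
#' @param table a `feature_table`.
#' @param mode `"class_mean"` or `"global_mean"`.
#' @param means optional named numeric vector of column means to use with
#'   `mode = "global_mean"`.
#' @return the imputed `feature_table`.
#' @export
impute_missing <- function(table, mode = c("class_mean", "global_mean"),
                           means = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "feature_table"))
  fc <- feature_cols(table)
  mat <- feature_matrix(table)
  if (!anyNA(mat) && is.null(means)) return(table)
  if (mode == "class_mean") {
    if (anyNA(table$label)) stop("class_mean imputation needs labels")
    for (cl in unique(table$label)) {
      rows <- which(table$label == cl)
      sub <- mat[rows, , drop = FALSE]
      miss_cols <- which(colSums(is.na(sub)) > 0)
      for (j in miss_cols) {
        obs <- sub[, j][!is.na(sub[, j])]
        if (length(obs) == 0)
          stop("column ", fc[j], " entirely missing within class ", cl)
        sub[is.na(sub[, j]), j] <- mean(obs)
      }
      mat[rows, ] <- sub
    }
  } else {
    if (is.null(means)) means <- colMeans(mat, na.rm = TRUE)
    miss_cols <- which(colSums(is.na(mat)) > 0)
    for (j in miss_cols) {
      m <- means[[fc[j]]]
      if (is.null(m) || is.na(m))
        stop("column ", fc[j], " entirely missing (no mean available)")
      mat[is.na(mat[, j]), j] <- m
    }
  }
  out <- table
  out[, fc] <- mat
  out
}
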