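#' @useDynLib cervemg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats ar fft plogis qlogis quantile rnorm sd var cor pt
#'   setNames
#' @importFrom utils head tail
NULL

MUSCLES <- paste0("M", 1:6)
MOVEMENTS <- paste0("A", 1:7)

MUSCLE_LABELS <- c(
  M1 = "left sternocleidomastoid",
  M2 = "left upper trapezius",
  M3 = "left cervical erector spinae",
  M4 = "right cervical erector spinae",
  M5 = "right upper trapezius",
  M6 = "right sternocleidomastoid"
)

MOVEMENT_LABELS <- c(
  A1 = "bow", A2 = "head backwards", A3 = "left flexion", A4 = "right flexion",
  A5 = "left rotation", A6 = "right rotation", A7 = "hands up"
)

# family sizes of the per-channel (scope = "channel") and per-movement
# (scope = "movement") feature blocks; these close the printed schema counts
# 63 per channel, 45 movement-level for A1 (43 elsewhere), 2949 in total
CHANNEL_FAMILY_SIZES <- c(TF = 11, FF = 14, WL = 7, WLP = 16, AR = 14, EY = 1)
MOVEMENT_FAMILY_SIZES <- c(DU = 7, ACI = 15, UN = 9, SYM = 12)
FRR_SIZE <- 2L

#' Construct a single-muscle sEMG trace
#'
#' One muscle channel recorded during one neck movement: a vector of
#' amplitudes, its sampling rate, and the muscle/movement identity.
#'
#' @param values numeric vector of amplitudes (millivolt-scale, arbitrary
#'   units); all finite.
#' @param fs sampling rate in Hz (> 0).
#' @param muscle one of `"M1"`..`"M6"` (M1/M6 sternocleidomastoid, M2/M5 upper
#'   trapezius, M3/M4 cervical erector spinae; left then right).
#' @param movement one of `"A1"`..`"A7"` (bow, head backwards, left/right
#'   flexion, left/right rotation, hands up).
#' @return an object of class `channel_signal`.
#' @export
channel_signal <- function(values, fs, muscle, movement) {
  muscle <- match.arg(muscle, MUSCLES)
  movement <- match.arg(movement, MOVEMENTS)
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (anyNA(values) || !all(is.finite(values)))
    stop("channel values must all be finite")
  if (length(values) < fs)
    stop("channel must span at least 1 second (length >= fs)")
  structure(list(values = values, fs = fs, muscle = muscle,
                 movement = movement),
            class = "channel_signal")
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal> %s (%s) during %s (%s): %d samples @ %g Hz\n",
              x$muscle, MUSCLE_LABELS[[x$muscle]], x$movement,
              MOVEMENT_LABELS[[x$movement]], length(x$values), x$fs))
  invisible(x)
}

#' Construct a six-channel movement recording
#'
#' All six muscle channels recorded synchronously during one movement.
#' Channels are truncated to the shortest common length.
#'
#' @param movement one of `"A1"`..`"A7"`.
#' @param channels list of exactly 6 [channel_signal()] objects, one per
#'   muscle M1..M6, all with the same sampling rate and movement.
#' @return an object of class `movement_recording`; `$channels` is a named
#'   list keyed M1..M6.
#' @export
movement_recording <- function(movement, channels) {
  movement <- match.arg(movement, MOVEMENTS)
  if (length(channels) != 6L)
    stop("a movement recording needs exactly 6 channels, got ", length(channels))
  muscles <- vapply(channels, function(ch) ch$muscle, character(1))
  if (!setequal(muscles, MUSCLES))
    stop("channel muscles must be exactly M1..M6")
  names(channels) <- muscles
  channels <- channels[MUSCLES]
  fss <- vapply(channels, function(ch) ch$fs, numeric(1))
  if (length(unique(fss)) != 1L) stop("channels must share one sampling rate")
  if (any(vapply(channels, function(ch) ch$movement, character(1)) != movement))
    stop("all channels must carry movement ", movement)
  nmin <- min(vapply(channels, function(ch) length(ch$values), integer(1)))
  channels <- lapply(channels, function(ch) {
    ch$values <- ch$values[seq_len(nmin)]
    ch
  })
  structure(list(movement = movement, channels = channels,
                 fs = fss[[1]], n = nmin),
            class = "movement_recording")
}

#' Construct one acquisition session for one subject
#'
#' @param subject_id opaque subject identifier (character scalar).
#' @param label 1 for cervical spondylosis (CS), 0 for healthy.
#' @param repetition repetition index, 1..3 (each volunteer is recorded
#'   three times; each repetition is one sample).
#' @param recordings list of exactly 7 [movement_recording()] objects
#'   covering A1..A7.
#' @return an object of class `subject_sample`; `$recordings` keyed A1..A7.
#' @export
subject_sample <- function(subject_id, label, repetition, recordings) {
  if (!label %in% c(0, 1)) stop("label must be 0 (healthy) or 1 (CS)")
  if (!repetition %in% 1:3) stop("repetition must be 1, 2 or 3")
  if (length(recordings) != 7L)
    stop("a sample needs exactly 7 movement recordings, got ", length(recordings))
  movs <- vapply(recordings, function(r) r$movement, character(1))
  if (!setequal(movs, MOVEMENTS))
    stop("recording movements must be exactly A1..A7")
  names(recordings) <- movs
  structure(list(subject_id = as.character(subject_id),
                 label = as.integer(label),
                 repetition = as.integer(repetition),
                 recordings = recordings[MOVEMENTS]),
            class = "subject_sample")
}

#' @export
print.subject_sample <- function(x, ...) {
  cat(sprintf("<subject_sample> %s rep %d label %d (%s): 7 movements x 6 channels\n",
              x$subject_id, x$repetition, x$label,
              if (x$label == 1L) "CS" else "healthy"))
  invisible(x)
}

#' Canonical ordered feature namespace
#'
#' The fixed registry of all 2949 feature names: 423 for movement A1
#' (2 flexion-relaxation ratios + 43 movement-level + 6x63 per-channel)
#' and 421 for each of A2..A7 (43 + 6x63). Order: movements A1..A7; within
#' a movement, movement-scope families (FRR first, A1 only; then DU, ACI,
#' UN, SYM), then channel blocks M1..M6 each ordered TF, FF, WL, WLP, AR, EY.
#'
#' Name grammar: `A<k>_FRR_<i>` / `A<k>_<FAM>_<i>` for movement scope,
#' `A<k>_M<j>_<FAM>_<i>` for channel scope.
#'
#' @return character vector of length 2949, identical across calls and
#'   platforms.
#' @export
canonical_feature_names <- function() {
  per_movement <- function(mov) {
    nm <- character(0)
    if (mov == "A1")
      nm <- c(nm, sprintf("%s_FRR_%d", mov, seq_len(FRR_SIZE)))
    for (fam in names(MOVEMENT_FAMILY_SIZES))
      nm <- c(nm, sprintf("%s_%s_%02d", mov, fam,
                          seq_len(MOVEMENT_FAMILY_SIZES[[fam]])))
    for (mus in MUSCLES)
      for (fam in names(CHANNEL_FAMILY_SIZES))
        nm <- c(nm, sprintf("%s_%s_%s_%02d", mov, mus, fam,
                            seq_len(CHANNEL_FAMILY_SIZES[[fam]])))
    nm
  }
  unlist(lapply(MOVEMENTS, per_movement), use.names = FALSE)
}

#' Parse canonical feature names into their components
#'
#' @param names character vector of canonical feature names.
#' @return data.frame with columns `name`, `movement`, `scope`
#'   (`"channel"`/`"movement"`), `muscle` (NA for movement scope), `family`,
#'   `index`.
#' @export
parse_feature_names <- function(names) {
  parts <- strsplit(names, "_", fixed = TRUE)
  len <- lengths(parts)
  if (any(!len %in% c(3L, 4L))) stop("malformed feature name(s)")
  scope <- ifelse(len == 4L, "channel", "movement")
  movement <- vapply(parts, `[[`, character(1), 1L)
  muscle <- ifelse(len == 4L, vapply(parts, `[[`, character(1), 2L), NA_character_)
  family <- mapply(function(p, l) p[[l - 1L]], parts, len)
  index <- as.integer(mapply(function(p, l) p[[l]], parts, len))
  data.frame(name = names, movement = movement, scope = scope,
             muscle = muscle, family = unname(family), index = index,
             stringsAsFactors = FALSE)
}

sidecar_path <- function(dir, sample_id) file.path(dir, paste0(sample_id, "_meta.yaml"))
movement_path <- function(dir, sample_id, mov)
  file.path(dir, paste0(sample_id, "_", mov, ".csv"))

#' Write a subject sample as a bundle of delimited files
#'
#' One CSV per movement (`<sample_id>_A<k>.csv`, header row of muscle
#' columns M1..M6) plus a YAML sidecar `<sample_id>_meta.yaml` carrying
#' subject id, label, repetition and sampling rate.
#'
#' @param sample a [subject_sample()].
#' @param dir output directory (created if absent).
#' @param sample_id file-name stem; defaults to `<subject_id>_r<repetition>`.
#' @return invisibly, the sample_id used.
#' @export
write_sample <- function(sample, dir, sample_id = NULL) {
  stopifnot(inherits(sample, "subject_sample"))
  if (is.null(sample_id))
    sample_id <- sprintf("%s_r%d", sample$subject_id, sample$repetition)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (mov in MOVEMENTS) {
    rec <- sample$recordings[[mov]]
    mat <- vapply(rec$channels, function(ch) ch$values, numeric(rec$n))
    data.table::fwrite(as.data.frame(mat), movement_path(dir, sample_id, mov))
  }
  meta <- list(subject_id = sample$subject_id, label = sample$label,
               repetition = sample$repetition,
               fs = sample$recordings[[1]]$fs)
  yaml::write_yaml(meta, sidecar_path(dir, sample_id))
  invisible(sample_id)
}

#' Read a subject sample from a bundle of delimited files
#'
#' Inverse of [write_sample()]. Channels within a movement are equalized by
#' truncation to the shortest. Missing movement files, missing channels and
#' non-numeric cells are hard errors.
#'
#' @param dir directory holding the bundle.
#' @param sample_id file-name stem of the bundle.
#' @return a validated [subject_sample()].
#' @export
read_sample <- function(dir, sample_id) {
  mp <- sidecar_path(dir, sample_id)
  if (!file.exists(mp)) stop("metadata sidecar absent: ", mp)
  meta <- yaml::read_yaml(mp)
  for (f in c("subject_id", "label", "repetition", "fs"))
    if (is.null(meta[[f]])) stop("sidecar lacks field ", f)
  recs <- lapply(MOVEMENTS, function(mov) {
    fp <- movement_path(dir, sample_id, mov)
    if (!file.exists(fp)) stop("movement ", mov, " absent: no file ", fp)
    dt <- data.table::fread(fp, header = TRUE, colClasses = "character")
    if (ncol(dt) < 6L)
      stop("movement ", mov, ": fewer than 6 channels (", ncol(dt), ")")
    if (!setequal(names(dt), MUSCLES))
      stop("movement ", mov, ": header must name muscles M1..M6")
    chans <- lapply(MUSCLES, function(mus) {
      v <- suppressWarnings(as.numeric(dt[[mus]]))
      bad <- which(is.na(v) & !is.na(dt[[mus]]) | is.na(dt[[mus]]))
      if (length(bad))
        stop("movement ", mov, " channel ", mus,
             ": non-numeric cell at row ", bad[1])
      channel_signal(v, meta$fs, mus, mov)
    })
    movement_recording(mov, chans)
  })
  subject_sample(meta$subject_id, meta$label, meta$repetition, recs)
}

#' Construct a feature table
#'
#' The tabular contract for all model stages: one row per (subject,
#' repetition), metadata columns `subject_id`, `label`, `repetition`, then
#' feature columns. Missing cells are `NA`.
#'
#' @param df data.frame with the metadata columns and numeric feature columns.
#' @param canonical require the feature columns to be exactly the canonical
#'   registry in canonical order (default TRUE; selection and modelling
#'   stages also accept reduced tables with `canonical = FALSE`).
#' @return a `feature_table` (a data.frame subclass).
#' @export
feature_table <- function(df, canonical = TRUE) {
  meta_cols <- c("subject_id", "label", "repetition")
  if (!all(meta_cols %in% names(df)))
    stop("feature table needs columns subject_id, label, repetition")
  feat <- setdiff(names(df), meta_cols)
  if (canonical) {
    canon <- canonical_feature_names()
    if (length(feat) != length(canon) || any(feat != canon)) {
      unknown <- setdiff(feat, canon)
      if (length(unknown))
        stop("unknown column(s): ", paste(head(unknown, 3), collapse = ", "))
      stop("non-canonical column order")
    }
  }
  df <- as.data.frame(df)[, c(meta_cols, feat)]
  df$label <- as.integer(df$label)
  structure(df, class = c("feature_table", "data.frame"),
            canonical = canonical)
}

#' Feature columns of a feature table
#' @param table a `feature_table`.
#' @return character vector of feature column names.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), c("subject_id", "label", "repetition"))
}

#' Feature matrix of a feature table
#' @param table a `feature_table`.
#' @return numeric matrix (rows = samples, columns = features).
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_cols(table), drop = FALSE])
}

#' Write / read a feature table as CSV
#'
#' Header row stores the canonical names; missing cells serialize as empty
#' fields; values round-trip to at least 12 significant digits. Reading a
#' file whose feature columns are not in canonical registry order is a hard
#' error.
#'
#' @param table a `feature_table`.
#' @param path CSV file path.
#' @return `write_feature_table`: invisibly, `path`; `read_feature_table`:
#'   a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  data.table::fwrite(as.data.frame(table), path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path, header = TRUE, na.strings = ""))
  feature_table(dt, canonical = TRUE)
}
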