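#' Partition an interval into four equal sub-streams
#'
#' Splits a half-open sample interval into four contiguous, equal-length,
#' ordered sub-intervals of length `floor(L / 4)`; any trailing remainder is
#' dropped. All per-channel feature families are computed per sub-stream, so
#' a task period always yields four values per scalar feature.
#'
#' @param interval 0-based half-open `[start, end)` sample interval.
#' @return A list of class `"substream_partition"` with `parent` and
#'   `substreams` (list of four intervals).
#' @export
partition_substreams <- function(interval) {
  L <- interval[[2L]] - interval[[1L]]
  if (L < 4) {
    stop(sprintf("interval of length %d cannot be split into 4 sub-streams", L),
         call. = FALSE)
  }
  len <- L %/% 4L
  subs <- lapply(0:3, function(k) {
    as.integer(c(interval[[1L]] + k * len, interval[[1L]] + (k + 1L) * len))
  })
  structure(list(parent = as.integer(interval), substreams = subs),
            class = "substream_partition")
}

ols_slope <- function(x, t) {
  tc <- t - mean(t)
  sum(tc * (x - mean(x))) / sum(tc^2)
}

#' Signal mean and slope features (SM & SS)
#'
#' For each of the four sub-streams, the arithmetic mean and the
#' ordinary-least-squares slope of value versus time (seconds). Output order
#' is `[m1, m2, m3, m4, s1, s2, s3, s4]` (8-dimensional).
#'
#' @param series numeric vector the partition indexes into.
#' @param partition a [partition_substreams()] result.
#' @param sampling_rate Hz; converts sample index to seconds for the slope.
#' @return Numeric vector of length 8.
#' @export
feature_sm_ss <- function(series, partition, sampling_rate) {
  vals <- lapply(partition$substreams, function(iv) slice_interval(series, iv))
  means <- vapply(vals, mean, numeric(1))
  slopes <- vapply(vals, function(x) {
    ols_slope(x, seq_along(x) / sampling_rate)
  }, numeric(1))
  c(means, slopes)
}

#' Contrast-to-noise-ratio features (CNR)
#'
#' For sub-stream k: `(mean_k - mean_rest) / sqrt(var_k + var_rest)`, with
#' unbiased (n - 1) sample variances. The rest segment provides the noise
#' reference.
#'
#' @param series numeric vector the partition indexes into.
#' @param partition a [partition_substreams()] result.
#' @param rest numeric vector of rest-period samples.
#' @return Numeric vector of length 4.
#' @export
feature_cnr <- function(series, partition, rest) {
  m_rest <- mean(rest)
  v_rest <- stats::var(rest)
  vapply(partition$substreams, function(iv) {
    x <- slice_interval(series, iv)
    denom <- stats::var(x) + v_rest
    if (denom == 0) {
      stop("CNR undefined: task and rest segments both have zero variance",
           call. = FALSE)
    }
    (mean(x) - m_rest) / sqrt(denom)
  }, numeric(1))
}

trailing_moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  n <- length(x)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - window, 0L)
  widths <- seq_len(n) - lo
  (cs - c(0, cs)[lo + 1L]) / widths
}

#' Moving-average features
#'
#' Applies a trailing moving average (default window 10 samples = 1 s at
#' 10 Hz) to the task-period series, then takes the smoothed signal's mean
#' over each sub-stream.
#'
#' @param series numeric vector the partition indexes into.
#' @param partition a [partition_substreams()] result.
#' @param window smoothing window in samples.
#' @return Numeric vector of length 4.
#' @export
feature_moving_average <- function(series, partition, window = 10L) {
  sm <- trailing_moving_average(series, window)
  vapply(partition$substreams, function(iv) mean(slice_interval(sm, iv)),
         numeric(1))
}

#' Differential-entropy features (DE)
#'
#' Differential entropy of each sub-stream under a Gaussian model,
#' `0.5 * log(2 * pi * e * var)` in nats, with the unbiased sample variance.
#' This estimator is exactly translation invariant and satisfies
#' `DE(c * x) = DE(x) + log(|c|)`.
#'
#' @param series numeric vector the partition indexes into.
#' @param partition a [partition_substreams()] result.
#' @param eps_floor optional positive variance floor for degenerate
#'   sub-streams; by default a zero-variance sub-stream is an error.
#' @return Numeric vector of length 4 (nats).
#' @export
feature_differential_entropy <- function(series, partition, eps_floor = NULL) {
  vapply(partition$substreams, function(iv) {
    v <- stats::var(slice_interval(series, iv))
    if (v == 0) {
      if (is.null(eps_floor)) {
        stop("differential entropy undefined for a constant sub-stream",
             call. = FALSE)
      }
      v <- eps_floor
    }
    0.5 * log(2 * pi * exp(1) * v)
  }, numeric(1))
}

feature_families <- c("SMSS", "CNR", "MOVAVG", "DE")

feature_dim <- function(family) {
  if (family == "SMSS") 8L else 4L
}

# Compute one feature vector for a single channel series restricted to a
# task stream (already concatenated), given the rest samples.
compute_family <- function(family, stream, rest, sampling_rate, window, eps_floor) {
  part <- partition_substreams(c(0L, length(stream)))
  switch(family,
    SMSS = feature_sm_ss(stream, part, sampling_rate),
    CNR = feature_cnr(stream, part, rest),
    MOVAVG = feature_moving_average(stream, part, window),
    DE = feature_differential_entropy(stream, part, eps_floor),
    stop(sprintf("unknown feature family '%s' (valid: %s)", family,
                 paste(feature_families, collapse = ", ")), call. = FALSE)
  )
}

#' Extract a feature matrix and labels from a cohort
#'
#' For one `(family, channel)` pair, computes one feature row per
#' participant and task condition. The task stream is the concatenation, in
#' temporal order, of that condition's block samples (`rows = "task"`, the
#' default), or each block individually (`rows = "block"`, used by the
#' segmentation demonstration where every sub-block is its own sample).
#' 2-back rows get the positive label 1; 1-back rows get 0. Channels are
#' never mixed within one matrix.
#'
#' @param cohort a `"nirs_cohort"` (typically preprocessed).
#' @param family one of `"SMSS"`, `"CNR"`, `"MOVAVG"`, `"DE"`.
#' @param channel channel name.
#' @param rows `"task"` or `"block"` row granularity.
#' @param window moving-average window (samples), `MOVAVG` only.
#' @param eps_floor optional DE variance floor, `DE` only.
#' @return A list of class `"snc_features"`: `X` (numeric matrix), `y`
#'   (integer 0/1 labels), `participant` (id per row), `family`, `channel`.
#' @export
extract_features <- function(cohort, family, channel,
                             rows = c("task", "block"),
                             window = 10L, eps_floor = NULL) {
  rows <- match.arg(rows)
  family <- match.arg(family, feature_families)
  X <- list(); y <- integer(0); pid <- character(0)
  for (rec in cohort) {
    if (!channel %in% colnames(rec$channels)) {
      stop(sprintf("channel '%s' not present in recording %s", channel,
                   rec$participant_id), call. = FALSE)
    }
    series <- rec$channels[, channel]
    rest <- slice_interval(series, rec$rest_interval)
    for (label in c("1-back", "2-back")) {
      blocks <- rec$task_blocks[rec$task_blocks$label == label, , drop = FALSE]
      if (nrow(blocks) == 0L) next
      streams <- if (rows == "task") {
        list(unlist(lapply(seq_len(nrow(blocks)), function(b) {
          slice_interval(series, c(blocks$start[b], blocks$end[b]))
        }), use.names = FALSE))
      } else {
        lapply(seq_len(nrow(blocks)), function(b) {
          slice_interval(series, c(blocks$start[b], blocks$end[b]))
        })
      }
      for (stream in streams) {
        X[[length(X) + 1L]] <- compute_family(family, stream, rest,
                                              rec$sampling_rate, window,
                                              eps_floor)
        y <- c(y, if (label == "2-back") 1L else 0L)
        pid <- c(pid, rec$participant_id)
      }
    }
  }
  structure(list(X = do.call(rbind, X), y = y, participant = pid,
                 family = family, channel = channel),
            class = "snc_features")
}

#' Write / read a feature table as CSV
#'
#' Columns: `participant_id, channel, family, task_label, f1..f8`; families
#' with 4-dimensional vectors leave `f5..f8` empty.
#'
#' @param features an `"snc_features"` object.
#' @param path CSV path.
#' @return `path` (write) or an `"snc_features"` (read).
#' @export
write_features <- function(features, path) {
  X8 <- matrix(NA_real_, nrow = nrow(features$X), ncol = 8L)
  X8[, seq_len(ncol(features$X))] <- features$X
  df <- data.frame(participant_id = features$participant,
                   channel = features$channel, family = features$family,
                   task_label = features$y, X8)
  names(df)[5:12] <- paste0("f", 1:8)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  family <- unique(df$family)
  channel <- unique(df$channel)
  if (length(family) != 1L || length(channel) != 1L) {
    stop("a features file must hold exactly one (family, channel) pair",
         call. = FALSE)
  }
  X <- as.matrix(df[, paste0("f", seq_len(feature_dim(family))), drop = FALSE])
  dimnames(X) <- NULL
  structure(list(X = X, y = as.integer(df$task_label),
                 participant = as.character(df$participant_id),
                 family = family, channel = channel),
            class = "snc_features")
}
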