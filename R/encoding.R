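#' Frame sequence container
#'
#' @param frames list of 2-D non-negative numeric matrices, all of one
#'   shape (height x width).
#' @param frame_interval time between consecutive frames (ms).
#' @param label optional class id.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_interval = 10, label = NULL) {
  if (!length(frames)) stop("frame_sequence: empty sequence", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frame_sequence: all frames must share one shape", call. = FALSE)
  structure(list(frames = frames, frame_interval = frame_interval,
                 label = label),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence %d frames of %dx%d, %.1f ms apart%s>\n",
              length(x$frames), d[1], d[2], x$frame_interval,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Encoder configuration
#'
#' @param T_max maximum encoding time per value (ms, the window each
#'   square-cosine neuron spreads its spike over); must not exceed the
#'   frame interval of the sequences it encodes.
#' @param n_encoding_neurons_per_value number of cosine encoding
#'   neurons per pooled pixel (the population size of the latency
#'   code).
#' @param diff_threshold_fraction fraction of the sequence-wide maximal
#'   difference magnitude above which a receptor fires, in \[0, 1\].
#' @param pool_size side of the square max-pooling block (frames are
#'   zero-padded when it does not divide the frame dims).
#' @param use_scan_filter run the scan-based background filter before
#'   differencing.
#' @param activity_threshold pixel activity threshold of the scan
#'   filter.
#' @param latency_coding expand each pooled event into square-cosine
#'   spike latencies; when `FALSE` each event is a single spike at its
#'   frame-slot start (the DVS-style raw event mode).
#' @param square_cosine use the squared-cosine latency map (default);
#'   `FALSE` selects the raw-cosine variant `T cos(d + i pi / n)`
#'   with negative times clipped to 0.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(T_max = 8,
                           n_encoding_neurons_per_value = 2,
                           diff_threshold_fraction = 0.25,
                           pool_size = 2,
                           use_scan_filter = TRUE,
                           activity_threshold = 0.1,
                           latency_coding = TRUE,
                           square_cosine = TRUE) {
  stopifnot(T_max > 0, n_encoding_neurons_per_value >= 1,
            diff_threshold_fraction >= 0, diff_threshold_fraction <= 1,
            pool_size >= 1)
  structure(list(T_max = T_max,
                 n_encoding_neurons_per_value =
                   as.integer(n_encoding_neurons_per_value),
                 diff_threshold_fraction = diff_threshold_fraction,
                 pool_size = as.integer(pool_size),
                 use_scan_filter = use_scan_filter,
                 activity_threshold = activity_threshold,
                 latency_coding = latency_coding,
                 square_cosine = square_cosine),
            class = "encoder_config")
}

#' Scan-based background filter
#'
#' Removes global position (camera jitter, background drift) from a
#' sequence: per frame, the bounding box and the center of gravity of
#' pixels above `activity_threshold` are computed; a fixed-size crop --
#' the sequence-wide maximal bounding box -- is then re-centered on
#' each frame's center of gravity. Frames with no active pixels yield
#' centered zero crops.
#'
#' @param seq a [frame_sequence()].
#' @param activity_threshold pixel activity threshold.
#' @return A [frame_sequence()] of crops (all the same size).
#' @export
scan_filter <- function(seq, activity_threshold = 0.1) {
  stats <- lapply(seq$frames, function(f) {
    # activity measured above the frame minimum, so a constant offset
    # added to every pixel leaves the filter (and the whole encoding
    # pipeline, which is difference-based downstream) unchanged
    act <- which(f - min(f) > activity_threshold, arr.ind = TRUE)
    if (!nrow(act)) return(NULL)
    mass <- f[act] - min(f)
    list(h = diff(range(act[, 1])) + 1L, w = diff(range(act[, 2])) + 1L,
         cog = c(sum(act[, 1] * mass), sum(act[, 2] * mass)) / sum(mass))
  })
  active <- !vapply(stats, is.null, logical(1))
  if (!any(active)) {
    d <- dim(seq$frames[[1]])
    crop_h <- max(1L, d[1] %/% 2L); crop_w <- max(1L, d[2] %/% 2L)
  } else {
    crop_h <- max(vapply(stats[active], `[[`, integer(1), "h"))
    crop_w <- max(vapply(stats[active], `[[`, integer(1), "w"))
  }
  crops <- vector("list", length(seq$frames))
  for (k in seq_along(seq$frames)) {
    f <- seq$frames[[k]]
    # out-of-frame fill uses the frame minimum (the background level),
    # which keeps the downstream difference code offset-invariant
    crop <- matrix(min(f), crop_h, crop_w)
    s <- stats[[k]]
    if (!is.null(s)) {
      r0 <- round(s$cog[1] - (crop_h + 1) / 2)  # crop row i = frame row r0+i
      c0 <- round(s$cog[2] - (crop_w + 1) / 2)
      rows <- (r0 + 1):(r0 + crop_h)
      cols <- (c0 + 1):(c0 + crop_w)
      ok_r <- rows >= 1 & rows <= nrow(f)
      ok_c <- cols >= 1 & cols <= ncol(f)
      crop[which(ok_r), which(ok_c)] <- f[rows[ok_r], cols[ok_c],
                                          drop = FALSE]
    }
    crops[[k]] <- crop
  }
  frame_sequence(crops, seq$frame_interval, seq$label)
}

#' Temporal-difference receptor encoding
#'
#' The sensory receptors respond to the difference between
#' time-adjacent frames: per consecutive pair, the elementwise absolute
#' difference is compared with `threshold * max(M_s)`, the fraction of
#' the sequence-wide maximal difference magnitude; a receptor emits an
#' event (1) where the difference reaches the threshold.
#'
#' @param seq a [frame_sequence()] with at least 2 frames.
#' @param config an [encoder_config()] (only
#'   `diff_threshold_fraction` is used).
#' @return A list with `events` (list of binary matrices, one per frame
#'   transition), `magnitude` (the normalized difference magnitudes in
#'   \[0, 1\], zero where no event) and `frame_interval`.
#' @export
temporal_difference_encode <- function(seq, config = encoder_config()) {
  nf <- length(seq$frames)
  if (nf < 2) stop("temporal_difference_encode: need >= 2 frames",
                   call. = FALSE)
  diffs <- lapply(seq_len(nf - 1),
                  function(k) abs(seq$frames[[k + 1]] - seq$frames[[k]]))
  m_max <- max(vapply(diffs, max, numeric(1)))
  thr <- config$diff_threshold_fraction * m_max
  events <- lapply(diffs, function(d) (d >= thr & d > 0) * 1L)
  magnitude <- if (m_max > 0) {
    lapply(seq_along(diffs), function(k) diffs[[k]] / m_max * events[[k]])
  } else {
    events
  }
  list(events = events, magnitude = magnitude,
       frame_interval = seq$frame_interval)
}

#' Square-cosine latency encoding of one value
#'
#' A population of `n` cosine encoding neurons converts a real value
#' `d`, already normalized into `[0, pi]`, into `n` spike times
#' `t_s(i) = T cos^2(d + i pi / n)`, each within the window `[0, T]`.
#' The squared form keeps every latency non-negative; the raw-cosine
#' variant (`square_cosine = FALSE`) clips negative times to 0.
#'
#' @param value the normalized value `d` in `[0, pi]`.
#' @param config an [encoder_config()].
#' @return Numeric vector of `n` spike times in `[0, T_max]`.
#' @export
square_cosine_encode <- function(value, config = encoder_config()) {
  if (value < 0 || value > pi)
    stop("square_cosine_encode: value must be normalized into [0, pi]",
         call. = FALSE)
  i <- seq_len(config$n_encoding_neurons_per_value)
  phase <- value + i * pi / config$n_encoding_neurons_per_value
  if (config$square_cosine) config$T_max * cos(phase)^2
  else pmax(config$T_max * cos(phase), 0)
}

#' Max-pool event frames into encoding-neuron spike trains
#'
#' Each `pool_size x pool_size` block of the event frames maps to one
#' pooled pixel: the block fires at a frame transition if any of its
#' pixels has an event there (max over the block); the pooled magnitude
#' is the max magnitude in the block. With `latency_coding` each firing
#' pooled pixel is expanded by [square_cosine_encode()] within its
#' frame slot, its normalized magnitude mapped linearly to `[0, pi]`,
#' over `n` encoding neurons per pooled pixel; otherwise one spike per
#' event at the slot start.
#'
#' @param encoded output of [temporal_difference_encode()] (or an
#'   equivalent list of binary event frames, for DVS-style streams).
#' @param config an [encoder_config()].
#' @return A [spike_train_set()] with
#'   `pooled_pixels * n_encoding_neurons_per_value` sources; source
#'   `(p - 1) * n + i` is encoding neuron `i` of pooled pixel `p`
#'   (pixels in column-major order).
#' @export
max_pool_spikes <- function(encoded, config = encoder_config()) {
  ev <- encoded$events
  mag <- encoded$magnitude %||% ev
  p <- config$pool_size
  d <- dim(ev[[1]])
  ph <- ceiling(d[1] / p)
  pw <- ceiling(d[2] / p)
  n_per <- if (config$latency_coding) config$n_encoding_neurons_per_value
           else 1L
  n_sources <- ph * pw * n_per
  duration <- length(ev) * encoded$frame_interval
  rows_blk <- ((seq_len(d[1]) - 1L) %/% p) + 1L
  cols_blk <- ((seq_len(d[2]) - 1L) %/% p) + 1L
  neuron <- integer(0); time <- numeric(0)
  for (k in seq_along(ev)) {
    if (!any(ev[[k]] > 0)) next
    # block max of event indicator and of magnitude
    pooled <- matrix(0, ph, pw)
    mg <- mag[[k]]
    idx <- which(ev[[k]] > 0, arr.ind = TRUE)
    for (j in seq_len(nrow(idx))) {
      bi <- rows_blk[idx[j, 1]]; bj <- cols_blk[idx[j, 2]]
      pooled[bi, bj] <- max(pooled[bi, bj], mg[idx[j, 1], idx[j, 2]])
    }
    slot0 <- (k - 1) * encoded$frame_interval
    hit <- which(pooled > 0)
    for (pix in hit) {
      if (config$latency_coding) {
        ts <- square_cosine_encode(pooled[pix] * pi, config)
        neuron <- c(neuron, (pix - 1L) * n_per + seq_len(n_per))
        time <- c(time, slot0 + pmin(ts, encoded$frame_interval))
      } else {
        neuron <- c(neuron, pix)
        time <- c(time, slot0)
      }
    }
  }
  spike_train_set(neuron, time, n_sources = n_sources, duration = duration)
}

#' Encode a frame sequence into spike trains
#'
#' The full front-end pipeline: scan-based background filtering,
#' temporal-difference receptor encoding, max-pooling, and
#' square-cosine latency expansion. A constant sequence therefore
#' produces an empty spike train, and the code is invariant to adding
#' a constant offset to all frames.
#'
#' @param seq a [frame_sequence()].
#' @param config an [encoder_config()].
#' @return A [spike_train_set()] of duration
#'   `(n_frames - 1) * frame_interval`.
#' @export
encode_sequence <- function(seq, config = encoder_config()) {
  if (config$use_scan_filter)
    seq <- scan_filter(seq, config$activity_threshold)
  max_pool_spikes(temporal_difference_encode(seq, config), config)
}

#' Number of encoding neurons a configuration produces for a sequence
#'
#' @param frame_shape height/width of the (possibly scan-filtered)
#'   frames entering the pooling stage.
#' @param config an [encoder_config()].
#' @return Integer source count.
#' @export
encoded_source_count <- function(frame_shape, config = encoder_config()) {
  p <- config$pool_size
  n_per <- if (config$latency_coding) config$n_encoding_neurons_per_value
           else 1L
  as.integer(ceiling(frame_shape[1] / p) * ceiling(frame_shape[2] / p) *
               n_per)
}
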