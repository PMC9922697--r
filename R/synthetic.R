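#' Synthetic moving-object task configuration
#'
#' Desk-scale stand-in for the video/event action-recognition
#' benchmarks: labelled clips of a single object (bar or blob)
#' translating across a small frame with a class-specific direction
#' (and optionally speed), plus Gaussian pixel noise. Class identity
#' lives in the spatio-temporal motion pattern, not in any single
#' frame -- the structural property the reservoir pipeline assumes.
#'
#' @param n_classes number of motion classes (>= 2); classes take the
#'   first `n_classes` rows of `directions`/`speeds`.
#' @param frames_per_clip frames per clip (>= 2).
#' @param frame_shape (height, width) of each frame.
#' @param clips_per_class clips generated per class.
#' @param pixel_noise_sd Gaussian pixel noise sd (intensities are in
#'   \[0, 1\] before noise; noisy values are clipped at 0).
#' @param object_kind `"bar"` or `"blob"`.
#' @param object_size object extent in pixels.
#' @param directions per-class unit-ish motion vectors (rows =
#'   classes, columns = d_row, d_col).
#' @param speeds per-class speeds in pixels per frame.
#' @param frame_interval ms between frames.
#' @param seed integer seed.
#' @return An object of class `synthetic_task_config`.
#' @export
synthetic_task_config <- function(n_classes = 3,
                                  frames_per_clip = 20,
                                  frame_shape = c(16, 16),
                                  clips_per_class = 30,
                                  pixel_noise_sd = 0.15,
                                  object_kind = c("bar", "blob"),
                                  object_size = 5,
                                  directions = rbind(c(0, 1), c(0, -1),
                                                     c(1, 0), c(-1, 0),
                                                     c(1, 1)),
                                  speeds = rep(1, 5),
                                  frame_interval = 10,
                                  seed = 1L) {
  object_kind <- match.arg(object_kind)
  stopifnot(n_classes >= 2, frames_per_clip >= 2,
            n_classes <= nrow(directions), n_classes <= length(speeds))
  if (object_size >= min(frame_shape))
    stop("synthetic_task_config: object larger than frame", call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 frames_per_clip = as.integer(frames_per_clip),
                 frame_shape = as.integer(frame_shape),
                 clips_per_class = as.integer(clips_per_class),
                 pixel_noise_sd = pixel_noise_sd,
                 object_kind = object_kind,
                 object_size = as.integer(object_size),
                 directions = directions, speeds = speeds,
                 frame_interval = frame_interval,
                 seed = as.integer(seed)),
            class = "synthetic_task_config")
}

# Render one frame: object at (continuous) center position, intensity 1.
render_frame <- function(center, config) {
  h <- config$frame_shape[1]; w <- config$frame_shape[2]
  f <- matrix(0, h, w)
  half <- (config$object_size - 1) / 2
  wrap <- function(i, n) ((round(i) - 1) %% n) + 1
  if (config$object_kind == "bar") {
    rows <- wrap(center[1] + (-half:half), h)
    f[rows, wrap(center[2], w)] <- 1
  } else {
    for (dr in -half:half) for (dc in -half:half)
      if (dr^2 + dc^2 <= half^2 + 0.5)
        f[wrap(center[1] + dr, h), wrap(center[2] + dc, w)] <- 1
  }
  f
}

#' Generate a labelled synthetic dataset
#'
#' Each clip renders its class's object translating with the class
#' direction and speed (wrapping around the frame edges), with Gaussian
#' pixel noise clipped at 0. The start position is jittered uniformly
#' *orthogonally* to the motion direction only: along the motion axis
#' every clip of a class shares its phase. With a fully random phase
#' the two directions of one axis would have identical class-mean frame
#' tensors (each class orbit averages to a uniform blur), making the
#' label linearly unrecoverable from raw pixels in principle;
#' orthogonal-only jitter keeps intra-class spatial variability while
#' leaving the class signal in the spatio-temporal trajectory.
#'
#' @param config a [synthetic_task_config()].
#' @return List of [frame_sequence()]s (length
#'   `n_classes * clips_per_class`), each with its `label` set.
#' @export
generate_dataset <- function(config = synthetic_task_config()) {
  h <- config$frame_shape[1]
  w <- config$frame_shape[2]
  with_seed(config$seed, {
    clips <- list()
    for (cls in seq_len(config$n_classes)) {
      dir <- config$directions[cls, ] * config$speeds[cls]
      perp <- if (all(config$directions[cls, ] == 0)) c(1, 1) else
        c(-config$directions[cls, 2], config$directions[cls, 1])
      for (r in seq_len(config$clips_per_class)) {
        j <- sample.int(max(h, w), 1) - 1L
        start <- round(c(h, w) / 2) + j * perp
        frames <- lapply(seq_len(config$frames_per_clip) - 1, function(k) {
          f <- render_frame(start + k * dir, config)
          if (config$pixel_noise_sd > 0)
            f <- pmax(f + matrix(rnorm(length(f), 0, config$pixel_noise_sd),
                                 nrow(f)), 0)
          f
        })
        clips[[length(clips) + 1L]] <-
          frame_sequence(frames, config$frame_interval, label = cls)
      }
    }
    clips
  })
}

#' Generate DVS-style event streams
#'
#' Emulates an event camera watching the noiseless moving object:
#' an event is emitted at every pixel whose rendered intensity changes
#' between consecutive frames (threshold 0), mapped to
#' (source = pixel index, time = transition time). By construction this
#' equals the temporal-difference receptor encoding of the noiseless
#' clip with threshold fraction 0, which the tests verify through the
#' independent encoding-module path.
#'
#' @param config a [synthetic_task_config()] (noise is ignored; event
#'   cameras respond to the rendered motion).
#' @return List of [spike_train_set()]s, one per clip, each with a
#'   `label` attribute; sources index pixels in column-major order.
#' @export
generate_event_stream <- function(config = synthetic_task_config()) {
  noiseless <- config
  noiseless$pixel_noise_sd <- 0
  clips <- generate_dataset(noiseless)
  lapply(clips, function(clip) {
    neuron <- integer(0); time <- numeric(0)
    for (k in seq_len(length(clip$frames) - 1)) {
      changed <- which(clip$frames[[k + 1]] != clip$frames[[k]])
      neuron <- c(neuron, changed)
      time <- c(time, rep((k - 1) * clip$frame_interval, length(changed)))
    }
    st <- spike_train_set(neuron, time,
                          n_sources = prod(config$frame_shape),
                          duration = (length(clip$frames) - 1) *
                            clip$frame_interval)
    attr(st, "label") <- clip$label
    st
  })
}

#' Stratified train/test split
#'
#' @param dataset list of labelled clips (or any objects with a
#'   `label` element or attribute).
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed integer seed.
#' @return List with `train` and `test` (disjoint, exhaustive, class
#'   balance preserved per class up to rounding).
#' @export
train_test_split <- function(dataset, test_fraction = 0.5, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- vapply(dataset, clip_label, numeric(1))
  classes <- unique(labels)
  sizes <- vapply(classes, function(cls) sum(labels == cls), numeric(1))
  if (any(sizes < 2))
    stop("train_test_split: class ", classes[which(sizes < 2)[1]],
         " has < 2 clips", call. = FALSE)
  # largest-remainder allocation: per-class test counts sum to
  # round(test_fraction * N) while staying within one clip of
  # test_fraction * n_c for each class
  targets <- diff(c(0, round(cumsum(test_fraction * sizes))))
  test_idx <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      idx <- which(labels == classes[k])
      idx[sample.int(length(idx), targets[k])]
    }))
  })
  list(train = dataset[-test_idx], test = dataset[sort(test_idx)])
}

clip_label <- function(clip) {
  lb <- if (!is.null(clip$label)) clip$label else attr(clip, "label")
  if (is.null(lb)) NA_real_ else as.numeric(lb)
}
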