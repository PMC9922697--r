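test_that("dataset generation counts, labels and determinism", {
  cfg <- synthetic_task_config(n_classes = 3, clips_per_class = 5,
                               seed = 1)
  ds <- generate_dataset(cfg)
  expect_equal(length(ds), 15)
  expect_equal(as.numeric(table(vapply(ds, `[[`, numeric(1), "label"))),
               rep(5, 3))
  # deterministic under seed
  ds2 <- generate_dataset(cfg)
  expect_equal(ds[[4]]$frames, ds2[[4]]$frames)
  expect_error(synthetic_task_config(object_size = 20), "larger")
})

test_that("class directions show up as opposite centroid displacements", {
  cfg <- synthetic_task_config(n_classes = 2, clips_per_class = 3,
                               pixel_noise_sd = 0, frames_per_clip = 6,
                               frame_shape = c(24, 24), object_size = 3,
                               directions = rbind(c(0, 1), c(0, -1)),
                               seed = 2)
  ds <- generate_dataset(cfg)
  # centroid-tracking oracle on interior (non-wrapping) transitions
  col_centroid <- function(f) {
    idx <- which(f > 0.5, arr.ind = TRUE)
    mean(idx[, 2])
  }
  disp <- function(clip) {
    cc <- vapply(clip$frames, col_centroid, numeric(1))
    d <- diff(cc)
    stats::median(d)  # wrap transitions are outliers; median is robust
  }
  d1 <- vapply(ds[1:3], disp, numeric(1))     # rightward class
  d2 <- vapply(ds[4:6], disp, numeric(1))     # leftward class
  expect_true(all(d1 > 0))
  expect_true(all(d2 < 0))
})

test_that("event streams match the difference encoding and grow with
           speed", {
  cfg <- synthetic_task_config(n_classes = 2, clips_per_class = 2,
                               seed = 3,
                               directions = rbind(c(0, 1), c(1, 0)))
  ev <- generate_event_stream(cfg)
  expect_equal(length(ev), 4)
  # equality with the encoding-module path on the noiseless clip
  noiseless <- cfg; noiseless$pixel_noise_sd <- 0
  clips <- generate_dataset(noiseless)
  enc0 <- encoder_config(use_scan_filter = FALSE,
                         diff_threshold_fraction = 0, pool_size = 1,
                         latency_coding = FALSE)
  for (i in seq_along(ev)) {
    st <- encode_sequence(clips[[i]], enc0)
    expect_equal(st$neuron, ev[[i]]$neuron)
    expect_equal(st$time, ev[[i]]$time)
  }
  # a static object produces an empty stream
  static <- synthetic_task_config(n_classes = 2, clips_per_class = 1,
                                  seed = 4, speeds = c(0, 0),
                                  directions = rbind(c(0, 1), c(0, -1)))
  expect_true(all(vapply(generate_event_stream(static),
                         function(s) length(s$time), numeric(1)) == 0))
  # event count non-decreasing with object speed (blob: less overlap)
  counts <- vapply(c(1, 2, 4), function(sp) {
    c5 <- synthetic_task_config(n_classes = 2, clips_per_class = 2,
                                object_kind = "blob", seed = 5,
                                speeds = c(sp, sp))
    sum(vapply(generate_event_stream(c5), function(s) length(s$time),
               numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("stratified split is disjoint, exhaustive and balanced", {
  cfg <- synthetic_task_config(n_classes = 2, clips_per_class = 5,
                               seed = 6)
  ds <- generate_dataset(cfg)
  sp <- train_test_split(ds, 0.5, seed = 1)
  labs <- function(x) vapply(x, `[[`, numeric(1), "label")
  expect_equal(length(sp$train), 5)
  expect_equal(length(sp$test), 5)
  # class balance preserved up to the unavoidable one-clip rounding
  expect_true(all(abs(as.numeric(table(labs(sp$test))) - 2.5) <= 0.5))
  # union is the dataset, intersection empty
  key <- function(x) vapply(x, function(c) paste(c$frames[[1]],
                                                 collapse = ","),
                            character(1))
  expect_setequal(c(key(sp$train), key(sp$test)), key(ds))
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_identical(key(train_test_split(ds, 0.5, seed = 9)$train),
                   key(train_test_split(ds, 0.5, seed = 9)$train))
  expect_error(train_test_split(ds[c(1, 6)], 0.5, seed = 1), "< 2 clips")
})

test_that("the label lives in the temporal structure, not single frames", {
  # a linear classifier on raw flattened noiseless 2-class clips
  # reaches > 90%...
  cfg <- synthetic_task_config(n_classes = 2, clips_per_class = 15,
                               pixel_noise_sd = 0, seed = 7,
                               directions = rbind(c(0, 1), c(0, -1)))
  ds <- generate_dataset(cfg)
  X <- t(vapply(ds, function(cl) unlist(cl$frames), numeric(16 * 16 * 20)))
  y <- vapply(ds, `[[`, numeric(1), "label")
  tr <- c(1:10, 16:25); te <- setdiff(1:30, tr)
  m <- fit_linear_classifier(X[tr, ], y[tr])
  expect_gt(classification_accuracy(m, X[te, ], y[te]), 0.9)

  # ...while single-frame class-conditional pixel histograms overlap at
  # noise_sd >= 0.3 (per-frame intensity distributions are alike)
  cfgn <- cfg; cfgn$pixel_noise_sd <- 0.3
  dsn <- generate_dataset(cfgn)
  mean_int <- function(cl) vapply(cl$frames, mean, numeric(1))
  m1 <- unlist(lapply(dsn[y == 1], mean_int))
  m2 <- unlist(lapply(dsn[y == 2], mean_int))
  br <- range(c(m1, m2))
  h1 <- hist(m1, breaks = seq(br[1], br[2], length.out = 20),
             plot = FALSE)$density
  h2 <- hist(m2, breaks = seq(br[1], br[2], length.out = 20),
             plot = FALSE)$density
  overlap <- sum(pmin(h1, h2)) / sum(h1)
  expect_gt(overlap, 0.5)
})
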