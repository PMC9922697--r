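test_that("scan filter recenters activity on its center of gravity", {
  z <- matrix(0, 9, 9)
  # all-zero frames: zero crops of the configured size
  out0 <- scan_filter(frame_sequence(list(z, z)))
  expect_true(all(vapply(out0$frames, function(f) all(f == 0), logical(1))))

  # single active pixel: 1x1 bounding box, crop centered on it
  f1 <- z; f1[3, 7] <- 1
  out1 <- scan_filter(frame_sequence(list(f1)))
  expect_equal(dim(out1$frames[[1]]), c(1, 1))
  expect_equal(out1$frames[[1]][1, 1], 1)

  # rigid translation: crops identical after re-centering
  blob <- z; blob[3:5, 2:4] <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3)
  shifted <- z; shifted[5:7, 5:7] <- blob[3:5, 2:4]
  out2 <- scan_filter(frame_sequence(list(blob, shifted)))
  expect_equal(out2$frames[[1]], out2$frames[[2]])
})

test_that("temporal differences threshold on the sequence-wide maximum", {
  f <- matrix(0, 4, 4)
  g <- f; g[2, 2] <- 1
  # constant sequence: no receptor fires
  const <- temporal_difference_encode(frame_sequence(list(f, f, f)),
                                      encoder_config())
  expect_true(all(vapply(const$events, sum, numeric(1)) == 0))
  expect_error(temporal_difference_encode(frame_sequence(list(f)),
                                          encoder_config()), "frames")

  # one step change: events only at that transition
  seq1 <- frame_sequence(list(f, f, g, g))
  ev <- temporal_difference_encode(seq1, encoder_config())$events
  expect_equal(vapply(ev, sum, numeric(1)), c(0, 1, 0))

  # zero threshold: every nonzero change fires
  h <- f; h[1, 1] <- 0.05; h[3, 3] <- 0.9
  ev0 <- temporal_difference_encode(
    frame_sequence(list(f, h)),
    encoder_config(diff_threshold_fraction = 0))$events
  expect_equal(sum(ev0[[1]]), 2)
})

test_that("square-cosine latencies follow T cos^2(d + i pi / n)", {
  cfg1 <- encoder_config(T_max = 10, n_encoding_neurons_per_value = 1)
  expect_equal(square_cosine_encode(0, cfg1), 10 * cos(pi)^2)  # = T
  cfg2 <- encoder_config(T_max = 10, n_encoding_neurons_per_value = 2)
  expect_equal(square_cosine_encode(pi / 2, cfg2),
               c(10 * cos(pi)^2, 10 * cos(3 * pi / 2)^2))      # T, 0
  # all outputs within [0, T] for any d
  for (d in seq(0, pi, length.out = 25)) {
    ts <- square_cosine_encode(d, encoder_config(
      T_max = 7, n_encoding_neurons_per_value = 5))
    expect_true(all(ts >= 0 & ts <= 7))
  }
  expect_error(square_cosine_encode(4, cfg1), "normalized")
  # raw-cosine variant clips negatives to zero
  raw <- square_cosine_encode(pi / 2, encoder_config(
    T_max = 10, n_encoding_neurons_per_value = 4, square_cosine = FALSE))
  expect_true(all(raw >= 0 & raw <= 10))
})

test_that("max pooling equals the brute-force block max", {
  set.seed(20)
  ev <- list(events = list(matrix(rbinom(16, 1, 0.4), 4, 4)),
             magnitude = list(matrix(runif(16), 4, 4)))
  ev$magnitude[[1]] <- ev$magnitude[[1]] * ev$events[[1]]
  ev$frame_interval <- 10
  st <- max_pool_spikes(ev, encoder_config(pool_size = 2,
                                           latency_coding = FALSE))
  # brute force: exhaustive loop over 2x2 blocks
  fired <- integer(0)
  for (bi in 1:2) for (bj in 1:2) {
    blk <- ev$events[[1]][(2 * bi - 1):(2 * bi), (2 * bj - 1):(2 * bj)]
    if (max(blk) > 0) fired <- c(fired, (bj - 1) * 2 + bi)
  }
  expect_setequal(st$neuron, fired)
  # pooled event count never exceeds the unpooled count
  expect_lte(length(st$neuron), sum(ev$events[[1]]))

  # pool_size 1 without latency coding is the identity on events
  st1 <- max_pool_spikes(ev, encoder_config(pool_size = 1,
                                            latency_coding = FALSE))
  expect_setequal(st1$neuron, which(ev$events[[1]] > 0))

  # 2x2 frame with one active pixel pools to one neuron, one event
  one <- list(events = list(matrix(c(0, 1, 0, 0), 2, 2)),
              magnitude = list(matrix(c(0, 1, 0, 0), 2, 2)),
              frame_interval = 10)
  st2 <- max_pool_spikes(one, encoder_config(pool_size = 2,
                                             latency_coding = FALSE))
  expect_equal(length(st2$neuron), 1)
  expect_equal(st2$n_sources, 1)
})

test_that("encode_sequence composes the stages with stated invariants", {
  cfg <- synthetic_task_config(n_classes = 2, clips_per_class = 1,
                               pixel_noise_sd = 0, seed = 2,
                               directions = rbind(c(0, 1), c(0, -1)))
  clips <- generate_dataset(cfg)
  enc <- encoder_config(use_scan_filter = FALSE)

  # constant sequence encodes to an empty train
  const <- frame_sequence(rep(list(matrix(0.4, 6, 6)), 5))
  expect_equal(length(encode_sequence(const, enc)$time), 0)

  # determinism
  s1 <- encode_sequence(clips[[1]], enc)
  expect_identical(s1, encode_sequence(clips[[1]], enc))

  # left vs right movers give different spike trains
  s2 <- encode_sequence(clips[[2]], enc)
  expect_false(identical(s1$neuron, s2$neuron) &&
                 identical(s1$time, s2$time))

  # all spike times within [0, duration]
  expect_true(all(s1$time >= 0 & s1$time <= s1$duration))
  expect_equal(s1$duration, (cfg$frames_per_clip - 1) * 10)

  # invariance to a constant intensity offset (difference-based code)
  off <- frame_sequence(lapply(clips[[1]]$frames, function(f) f + 2.5),
                        clips[[1]]$frame_interval)
  s_off <- encode_sequence(off, encoder_config())
  s_raw <- encode_sequence(clips[[1]], encoder_config())
  expect_equal(s_off$neuron, s_raw$neuron)
  expect_equal(s_off$time, s_raw$time)
})

test_that("frame sequences round-trip through the text format", {
  cfg <- synthetic_task_config(n_classes = 2, clips_per_class = 1,
                               seed = 4)
  clip <- generate_dataset(cfg)[[1]]
  tmp <- tempfile()
  write_frame_sequence(clip, tmp)
  back <- read_frame_sequence(tmp)
  expect_equal(back$frames, clip$frames, tolerance = 1e-6)
  expect_equal(back$label, clip$label)
})
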