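#' Read/write spike trains as two-column text
#'
#' Plain whitespace-separated text with a header: `neuron` (1-based
#' source id) and `time_ms`. `n_sources` and `duration` are stored as
#' `#` comment lines so the container round-trips exactly.
#'
#' @param spikes a [spike_train_set()].
#' @param path file path.
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a [spike_train_set()].
#' @export
write_spike_trains <- function(spikes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_sources %d", spikes$n_sources),
               sprintf("# duration %.10g", spikes$duration),
               "neuron time_ms"), con)
  if (n_events(spikes))
    write.table(data.frame(spikes$neuron, spikes$time), con,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  hdr <- readLines(path, n = 2)
  n_sources <- as.integer(sub("# n_sources ", "", hdr[1]))
  duration <- as.numeric(sub("# duration ", "", hdr[2]))
  df <- tryCatch(read.table(path, header = TRUE, comment.char = "#"),
                 error = function(e) data.frame(neuron = integer(0),
                                                time_ms = numeric(0)))
  spike_train_set(df[[1]], df[[2]], n_sources, duration)
}

#' Read/write a synapse set as an edge-list file
#'
#' Tab-separated columns `pre`, `post`, `weight`, `class`, `plastic`
#' plus, when present, the per-synapse STDP parameter and trace
#' columns.
#'
#' @param syn a synapse set data frame.
#' @param path file path.
#' @return `write_synapses` returns `path` invisibly; `read_synapses`
#'   returns the data frame.
#' @export
write_synapses <- function(syn, path) {
  write.table(syn, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_synapses
#' @export
read_synapses <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read/write a neuron population as a parameter table
#'
#' One row per neuron with every per-neuron parameter and state array
#' as a column (positions included when placed), so trained networks
#' can be checkpointed as plain text.
#'
#' @param pop a `neuron_population`.
#' @param path file path.
#' @return `write_population` returns `path` invisibly;
#'   `read_population` returns a `neuron_population`.
#' @export
write_population <- function(pop, path) {
  df <- data.frame(tau_m = pop$tau_m, R_m = pop$R_m, a = pop$a,
                   v_threshold = pop$v_threshold, v_reset = pop$v_reset,
                   refractory = pop$refractory,
                   is_excitatory = pop$is_excitatory,
                   membrane = pop$membrane)
  if (!is.null(pop$position)) {
    df$pos_x <- pop$position[, 1]
    df$pos_y <- pop$position[, 2]
    df$pos_z <- pop$position[, 3]
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  pop <- neuron_population(tau_m = df$tau_m,
                           is_excitatory = df$is_excitatory,
                           R_m = df$R_m, a = df$a,
                           v_threshold = df$v_threshold,
                           v_reset = df$v_reset,
                           refractory = df$refractory)
  pop$membrane <- df$membrane
  if (!is.null(df$pos_x))
    pop$position <- cbind(x = df$pos_x, y = df$pos_y, z = df$pos_z)
  pop
}

#' Read/write a state matrix with labels
#'
#' @param F a `state_matrix` (see [build_state_matrix()]).
#' @param path file path.
#' @return `write_state_matrix` returns `path` invisibly;
#'   `read_state_matrix` returns the matrix with its `labels`
#'   attribute.
#' @export
write_state_matrix <- function(F, path) {
  df <- as.data.frame(unclass(F))
  df$label <- attr(F, "labels")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_matrix
#' @export
read_state_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  labels <- df$label
  df$label <- NULL
  structure(as.matrix(df), labels = labels,
            class = c("state_matrix", "matrix"), dimnames = NULL)
}

#' Read/write a frame sequence as long-format text
#'
#' Columns `frame`, `row`, `col`, `value` (zeros omitted), with shape
#' and metadata in `#` header lines.
#'
#' @param seq a [frame_sequence()].
#' @param path file path.
#' @return `write_frame_sequence` returns `path` invisibly;
#'   `read_frame_sequence` returns a [frame_sequence()].
#' @export
write_frame_sequence <- function(seq, path) {
  d <- dim(seq$frames[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# shape %d %d %d", length(seq$frames), d[1], d[2]),
               sprintf("# frame_interval %.10g", seq$frame_interval),
               sprintf("# label %s", seq$label %||% "NA"),
               "frame row col value"), con)
  for (k in seq_along(seq$frames)) {
    nz <- which(seq$frames[[k]] != 0, arr.ind = TRUE)
    if (nrow(nz))
      write.table(data.frame(k, nz[, 1], nz[, 2],
                             seq$frames[[k]][nz]), con,
                  row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_frame_sequence
#' @export
read_frame_sequence <- function(path) {
  hdr <- readLines(path, n = 3)
  shape <- as.integer(strsplit(sub("# shape ", "", hdr[1]), " ")[[1]])
  fi <- as.numeric(sub("# frame_interval ", "", hdr[2]))
  lb <- sub("# label ", "", hdr[3])
  label <- if (identical(lb, "NA")) NULL else as.numeric(lb)
  df <- tryCatch(read.table(path, header = TRUE, comment.char = "#"),
                 error = function(e) NULL)
  frames <- lapply(seq_len(shape[1]), function(k) {
    f <- matrix(0, shape[2], shape[3])
    if (!is.null(df)) {
      rows <- df[df$frame == k, ]
      if (nrow(rows)) f[cbind(rows$row, rows$col)] <- rows$value
    }
    f
  })
  frame_sequence(frames, fi, label)
}
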