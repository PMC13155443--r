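#' Translocation trace parameters
#'
#' Parameters of the simulated ionic-current trace for one particle class.
#' The simulator emits a constant open-pore baseline plus Gaussian noise;
#' translocation events are rectangular current blockades whose depth and
#' dwell time are drawn per event from class-specific normal distributions,
#' with event starts placed uniformly given a Poisson event count.
#'
#' @param baseline Mean open-pore current (arbitrary current units).
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param event_rate Expected translocation events per second (Poisson, >= 0).
#' @param amplitude_mean,amplitude_sd Blockade depth distribution; positive
#'   depths deflect the current below baseline.
#' @param dwell_mean,dwell_sd Event duration distribution in seconds
#'   (truncated > 0); `dwell_mean` must be positive.
#' @return An object of class `trace_params`.
#' @export
trace_params <- function(baseline = 10, noise_sd = 0.05, event_rate = 8,
                         amplitude_mean = 1.5, amplitude_sd = 0.15,
                         dwell_mean = 0.002, dwell_sd = 0.0005) {
  if (noise_sd < 0) stop_fmt("noise_sd must be >= 0")
  if (event_rate < 0) stop_fmt("event_rate must be >= 0")
  if (dwell_mean <= 0) stop_fmt("dwell_mean must be > 0")
  structure(list(baseline = baseline, noise_sd = noise_sd,
                 event_rate = event_rate,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 dwell_mean = dwell_mean, dwell_sd = dwell_sd),
            class = "trace_params")
}

#' Default three-class nanopore parameter sets
#'
#' Class parameter sets emulating empty, ssDNA-filled and dsDNA-filled capsid
#' signatures: identical baseline and noise, increasingly deep current
#' blockades (0.5, 1.5 and 3.0 units below a baseline of 10).
#'
#' @return Named list of [trace_params()] for classes `empty`, `single`,
#'   `double`.
#' @export
nanopore_class_params <- function() {
  list(empty  = trace_params(amplitude_mean = 0.5),
       single = trace_params(amplitude_mean = 1.5),
       double = trace_params(amplitude_mean = 3.0))
}

#' Simulate an ionic-current trace
#'
#' @param params A [trace_params()].
#' @param duration_s Trace duration in seconds (> 0).
#' @param sample_rate Samples per second.  The default of 250,000 makes a
#'   1-second segment contain 250,000 points.
#' @param class_kind Class index or name recorded on the trace.
#' @param seed Integer seed; the trace is fully reproducible from it.
#' @return An object of class `signal_trace`: `samples` (numeric vector of
#'   length `round(duration_s * sample_rate)`), `sample_rate`, `class_kind`,
#'   `seed`.
#' @export
simulate_trace <- function(params, duration_s, sample_rate = 250000,
                           class_kind = 1L, seed = 1L) {
  stopifnot(inherits(params, "trace_params"))
  if (duration_s <= 0) stop_fmt("duration_s must be > 0")
  if (sample_rate <= 0) stop_fmt("sample_rate must be > 0")
  n <- round(duration_s * sample_rate)
  samples <- with_seed(seed, {
    x <- rep(params$baseline, n)
    if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
    n_events <- if (params$event_rate > 0)
      stats::rpois(1, params$event_rate * duration_s) else 0L
    if (n_events > 0) {
      starts <- sort(stats::runif(n_events, 0, duration_s))
      depths <- stats::rnorm(n_events, params$amplitude_mean, params$amplitude_sd)
      dwells <- abs(stats::rnorm(n_events, params$dwell_mean, params$dwell_sd))
      dwells[dwells == 0] <- params$dwell_mean
      for (e in seq_len(n_events)) {
        i0 <- floor(starts[e] * sample_rate) + 1
        i1 <- min(n, i0 + max(1L, round(dwells[e] * sample_rate)) - 1L)
        if (i0 <= n) x[i0:i1] <- x[i0:i1] - depths[e]
      }
    }
    x
  })
  structure(list(samples = samples, sample_rate = sample_rate,
                 class_kind = class_kind, seed = as.integer(seed)),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz (%.3f s), class %s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, format(x$class_kind)))
  invisible(x)
}

#' Read a trace from a two-column CSV
#'
#' Imports a raw current recording stored as `time_s,current` rows at a fixed
#' sampling interval.
#'
#' @param path CSV path with header `time_s,current`.
#' @param class_kind Class index or name to record on the trace.
#' @return A `signal_trace`; the sample rate is inferred from the first two
#'   time stamps.
#' @export
read_trace_csv <- function(path, class_kind = 1L) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "current") %in% names(df)))
    stop_fmt("trace CSV needs columns 'time_s' and 'current'")
  if (nrow(df) < 2L) stop_fmt("trace CSV needs at least two rows")
  rate <- 1 / diff(df$time_s[1:2])
  structure(list(samples = as.numeric(df$current), sample_rate = rate,
                 class_kind = class_kind, seed = NA_integer_),
            class = "signal_trace")
}

#' Split a trace into fixed-duration segments
#'
#' Consecutive non-overlapping windows of `round(segment_s * sample_rate)`
#' samples; a trailing partial window is dropped so all segments have equal
#' length.  A segment longer than the trace yields an empty list.
#'
#' @param trace A `signal_trace`.
#' @param segment_s Segment duration in seconds (> 0).
#' @return List of equal-length numeric vectors.
#' @export
segment_trace <- function(trace, segment_s = 1) {
  stopifnot(inherits(trace, "signal_trace"))
  if (segment_s <= 0) stop_fmt("segment_s must be > 0")
  L <- round(segment_s * trace$sample_rate)
  n_seg <- length(trace$samples) %/% L
  if (n_seg == 0L) return(list())
  lapply(seq_len(n_seg), function(i)
    trace$samples[((i - 1) * L + 1):(i * L)])
}

#' Segment-image render configuration
#'
#' @param width,height Output size in pixels.
#' @param y_limits Fixed `(lo, hi)` current range shared by all segments, so
#'   that vertical scale never leaks class information.  Values outside the
#'   range are clipped with a warning.
#' @param line_rgb,background_rgb Stroke and background colors in `[0, 1]`.
#' @return An object of class `render_config`.
#' @export
render_config <- function(width = 32, height = 32, y_limits = c(5.5, 10.5),
                          line_rgb = c(0.10, 0.20, 0.70),
                          background_rgb = c(1, 1, 1)) {
  if (width <= 0 || height <= 0) stop_fmt("width and height must be > 0")
  if (y_limits[1] >= y_limits[2]) stop_fmt("y_limits must satisfy lo < hi")
  structure(list(width = as.integer(width), height = as.integer(height),
                 y_limits = as.numeric(y_limits),
                 line_rgb = as.numeric(line_rgb),
                 background_rgb = as.numeric(background_rgb)),
            class = "render_config")
}

#' Render one segment as an RGB image
#'
#' Deterministic axis-free line plot of current versus within-segment time.
#' Each pixel column covers an equal share of the samples and is painted over
#' the min-max vertical extent of its samples (extended to meet the previous
#' column so the trace is connected), on the fixed `y_limits` scale.
#'
#' @param window Non-empty numeric vector of current samples.
#' @param config A [render_config()].
#' @return Numeric array `height x width x 3` with 8-bit-quantized values.
#' @export
render_segment <- function(window, config = render_config()) {
  stopifnot(inherits(config, "render_config"))
  L <- length(window)
  if (L == 0L) stop_fmt("cannot render an empty window")
  W <- config$width; H <- config$height
  lo <- config$y_limits[1]; hi <- config$y_limits[2]
  if (min(window) < lo || max(window) > hi) {
    warning("segment values outside y_limits were clipped", call. = FALSE)
    window <- pmin(pmax(window, lo), hi)
  }
  # Pixel row for a current value: row 1 = top = hi.
  to_row <- function(y) pmin(pmax(floor((hi - y) / (hi - lo) * H) + 1L, 1L), H)
  bounds <- floor(seq_len(W) * L / W)
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  img <- array(rep(config$background_rgb, each = H * W), c(H, W, 3))
  prev_last <- NULL
  for (x in seq_len(W)) {
    seg <- window[starts[x]:bounds[x]]
    r1 <- to_row(max(seg)); r2 <- to_row(min(seg))
    if (!is.null(prev_last)) {   # connect to the previous column's endpoint
      pr <- to_row(prev_last)
      r1 <- min(r1, pr); r2 <- max(r2, pr)
    }
    prev_last <- seg[length(seg)]
    for (ch in 1:3) img[r1:r2, x, ch] <- config$line_rgb[ch]
  }
  quantize8(img)
}

#' Generate a synthetic nanopore segment-image dataset
#'
#' Simulates one trace per class, segments it into fixed-duration windows and
#' renders each window as an RGB image labeled with its class name.  Per-class
#' image counts equal `floor(duration_s / segment_s)`.
#'
#' @param class_specs Named list (>= 2 classes, unique names); each element is
#'   a list with `params` (a [trace_params()]) and `duration_s`.  Defaults to
#'   the three balanced AAV-like classes of [nanopore_class_params()] at 120 s
#'   each.
#' @param sample_rate Samples per second (default 250,000).
#' @param segment_s Segment duration in seconds (default 1).
#' @param render A [render_config()].
#' @param seed Integer seed controlling all traces.
#' @return An [image_dataset()] with a lexicographically ordered vocabulary.
#' @export
make_nanopore_dataset <- function(class_specs = NULL, sample_rate = 250000,
                                  segment_s = 1, render = render_config(),
                                  seed = 1L) {
  if (is.null(class_specs)) {
    class_specs <- lapply(nanopore_class_params(), function(p)
      list(params = p, duration_s = 120))
  }
  nm <- names(class_specs)
  if (is.null(nm) || any(nm == "")) stop_fmt("class_specs must be a named list")
  if (anyDuplicated(nm)) stop_fmt("duplicate class names in class_specs")
  if (length(class_specs) < 2L) stop_fmt("need at least 2 classes")
  vocab <- class_vocabulary(sort(nm))
  imgs <- list(); labels <- integer(0)
  n_clipped <- 0L
  for (cls in vocab$names) {
    spec <- class_specs[[cls]]
    tr <- simulate_trace(spec$params, spec$duration_s, sample_rate,
                         class_kind = cls,
                         seed = derive_seed(seed, match(cls, vocab$names)))
    wins <- segment_trace(tr, segment_s)
    for (w in wins) {
      imgs[[length(imgs) + 1L]] <- withCallingHandlers(
        render_segment(w, render),
        warning = function(cond) {
          if (grepl("clipped", conditionMessage(cond))) {
            n_clipped <<- n_clipped + 1L
            invokeRestart("muffleWarning")
          }
        })
    }
    labels <- c(labels, rep(match(cls, vocab$names), length(wins)))
  }
  if (n_clipped > 0)
    warning(sprintf("%d of %d segments had values outside y_limits (clipped)",
                    n_clipped, length(imgs)), call. = FALSE)
  if (length(imgs) == 0L) stop_fmt("no segments produced; traces shorter than segment_s")
  arr <- array(0, c(length(imgs), render$height, render$width, 3))
  for (i in seq_along(imgs)) arr[i, , , ] <- imgs[[i]]
  image_dataset(arr, labels, vocab)
}

# Deterministic template mask for one stand-in class on a size x size grid.
stand_in_template <- function(class_id, size) {
  g <- expand.grid(h = seq_len(size), w = seq_len(size))
  u <- (g$w - 0.5) / size
  v <- (g$h - 0.5) / size
  r <- sqrt((u - 0.5)^2 + (v - 0.5)^2)
  mask <- switch(class_id,
    r < 0.30,                                       # 1 filled disk
    r > 0.22 & r < 0.38,                            # 2 ring
    abs(v - 0.5) < 0.12,                            # 3 horizontal bar
    abs(u - 0.5) < 0.12,                            # 4 vertical bar
    abs(v - 0.5) < 0.08 | abs(u - 0.5) < 0.08,      # 5 plus
    abs(u - v) < 0.09 | abs(u + v - 1) < 0.09,      # 6 X
    abs(u - v) < 0.12,                              # 7 diagonal
    sqrt((u - 0.3)^2 + (v - 0.3)^2) < 0.16 |        # 8 two dots
      sqrt((u - 0.7)^2 + (v - 0.7)^2) < 0.16,
    pmax(abs(u - 0.5), abs(v - 0.5)) > 0.24 &       # 9 square frame
      pmax(abs(u - 0.5), abs(v - 0.5)) < 0.40,
    v < 0.22 | (abs(u - 0.5) < 0.10 & v < 0.85)     # 10 T shape
  )
  matrix(as.numeric(mask), size, size)
}

# Integer-shift a matrix, padding with zeros.
shift_matrix <- function(m, dh, dw) {
  s <- nrow(m)
  out <- matrix(0, s, s)
  src_h <- seq_len(s) - dh; src_w <- seq_len(s) - dw
  ok_h <- src_h >= 1 & src_h <= s; ok_w <- src_w >= 1 & src_w <= s
  out[ok_h, ok_w] <- m[src_h[ok_h], src_w[ok_w]]
  out
}

#' Generate a separable multi-class stand-in image dataset
#'
#' Each class is a distinct deterministic template shape (disk, ring, bars,
#' cross, ...) perturbed per sample by an integer spatial jitter and additive
#' Gaussian pixel noise.  Separability is controlled by `jitter_sd` and
#' `noise_sd`: at zero both, all same-class images are identical; as noise
#' grows, held-out accuracy of any classifier decays toward chance.
#'
#' @param n_classes Number of classes (2..10).
#' @param per_class Images per class (>= 1).
#' @param image_size Side length in pixels (square images).
#' @param jitter_sd Standard deviation, in pixels, of the per-sample integer
#'   translation of the template.
#' @param noise_sd Standard deviation of the additive pixel noise.
#' @param seed Integer seed.
#' @return An [image_dataset()] with classes `c01..cNN`, `per_class` images
#'   each, in class-block order.
#' @export
make_stand_in_dataset <- function(n_classes = 10, per_class = 100,
                                  image_size = 24, jitter_sd = 1,
                                  noise_sd = 0.05, seed = 1L) {
  if (n_classes < 2L) stop_fmt("need at least 2 classes")
  if (n_classes > 10L) stop_fmt("at most 10 template classes are available")
  if (per_class < 1L) stop_fmt("per_class must be >= 1")
  vocab <- class_vocabulary(sprintf("c%02d", seq_len(n_classes)))
  N <- n_classes * per_class
  arr <- array(0, c(N, image_size, image_size, 3))
  labels <- rep(seq_len(n_classes), each = per_class)
  templates <- lapply(seq_len(n_classes), stand_in_template, size = image_size)
  with_seed(seed, {
    for (i in seq_len(N)) {
      tm <- templates[[labels[i]]]
      if (jitter_sd > 0) {
        dh <- round(stats::rnorm(1, 0, jitter_sd))
        dw <- round(stats::rnorm(1, 0, jitter_sd))
        tm <- shift_matrix(tm, dh, dw)
      }
      if (noise_sd > 0) tm <- tm + stats::rnorm(length(tm), 0, noise_sd)
      tm <- quantize8(clip01(tm))
      for (ch in 1:3) arr[i, , , ch] <- tm
    }
  })
  image_dataset(arr, labels, vocab)
}

#' Inject random label flips into a dataset
#'
#' Chooses `count` distinct samples uniformly without replacement and replaces
#' each assigned label by a uniformly chosen *different* class.  The original
#' assignments are preserved in the dataset's `true_labels` (existing true
#' labels, if any, are kept).
#'
#' @param dataset An [image_dataset()].
#' @param count Number of labels to flip, `0 <= count <= N`.
#' @param seed Integer seed.
#' @return List with `dataset` (the modified copy) and `injection`, a
#'   `noise_injection` record: data frame `flipped` with columns
#'   `index, original_label, modified_label`, plus `seed` and `count`.
#' @export
inject_mislabels <- function(dataset, count, seed = 1L) {
  N <- n_samples(dataset)
  if (count < 0 || count > N) stop_fmt("count must be within 0..%d", N)
  K <- dataset$vocabulary$K
  out <- dataset
  if (count > 0 && is.null(out$true_labels)) out$true_labels <- out$labels
  flipped <- with_seed(seed, {
    idx <- if (count > 0) sort(sample.int(N, count)) else integer(0)
    orig <- out$labels[idx]
    new <- vapply(orig, function(o) {
      others <- setdiff(seq_len(K), o)
      if (length(others) == 1L) others else sample(others, 1L)
    }, integer(1))
    data.frame(index = idx, original_label = orig, modified_label = new)
  })
  out$labels[flipped$index] <- flipped$modified_label
  injection <- structure(list(flipped = flipped, seed = as.integer(seed),
                              count = as.integer(count),
                              vocabulary = dataset$vocabulary),
                         class = "noise_injection")
  list(dataset = out, injection = injection)
}

#' @export
print.noise_injection <- function(x, ...) {
  cat(sprintf("<noise_injection> %d flipped labels (seed %d)\n", x$count, x$seed))
  invisible(x)
}

#' Write / read a noise-injection record as JSON
#'
#' @param injection A `noise_injection` record.
#' @param path Output JSON path.
#' @return `write_injection` returns `path` invisibly; `read_injection`
#'   returns the reconstructed record.
#' @export
write_injection <- function(injection, path) {
  stopifnot(inherits(injection, "noise_injection"))
  x <- list(seed = injection$seed, count = injection$count,
            classes = injection$vocabulary$names,
            flipped = list(
              index = injection$flipped$index,
              original_label = injection$vocabulary$names[injection$flipped$original_label],
              modified_label = injection$vocabulary$names[injection$flipped$modified_label]))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_injection
#' @export
read_injection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("seed", "count", "classes", "flipped"))
    if (is.null(x[[key]])) stop_fmt("injection schema error: missing '%s'", key)
  vocab <- class_vocabulary(x$classes)
  fl <- x$flipped
  flipped <- data.frame(
    index = as.integer(fl$index %||% integer(0)),
    original_label = label_index(fl$original_label %||% character(0), vocab),
    modified_label = label_index(fl$modified_label %||% character(0), vocab))
  structure(list(flipped = flipped, seed = as.integer(x$seed),
                 count = as.integer(x$count), vocabulary = vocab),
            class = "noise_injection")
}
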