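#' Shape specification for the event simulator
#'
#' @param geometry one of `"triangle"`, `"square"`, `"circle"`.
#' @param size shape size in px at dataset resolution (circle diameter /
#'   square or triangle side).
#' @param position numeric length-2 centre `(x, y)` in continuous 0-based
#'   dataset-resolution px.
#' @param orientation rotation in radians (fixed per movie).
#' @return object of class `shape_spec`.
#' @export
shape_spec <- function(geometry = c("triangle", "square", "circle"),
                       size, position, orientation = 0) {
  geometry <- match.arg(geometry)
  if (size <= 0) stop("shape_spec: size must be positive")
  stopifnot(length(position) == 2)
  structure(list(geometry = geometry, size = size,
                 position = as.numeric(position), orientation = orientation),
            class = "shape_spec")
}

#' Motion specification for the event simulator
#'
#' @param translation_velocity length-2 `(vx, vy)` px/timestep, or an
#'   `n_shapes` x 2 matrix for per-shape velocities.
#' @param scale_velocity size change in px/timestep (0 for the spatial
#'   dataset; signed for the temporal dataset), scalar or per-shape vector.
#' @param dataset_kind `"spatial"` or `"temporal"`.
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(translation_velocity = c(0, 0), scale_velocity = 0,
                        dataset_kind = c("spatial", "temporal")) {
  dataset_kind <- match.arg(dataset_kind)
  tv <- if (is.matrix(translation_velocity)) translation_velocity else
    matrix(translation_velocity, 1, 2)
  structure(list(translation_velocity = tv,
                 scale_velocity = scale_velocity,
                 dataset_kind = dataset_kind),
            class = "motion_spec")
}

# Contour sample points (continuous coordinates, origin at the shape centre,
# unrotated) at arc-length spacing `spacing`; per-edge half-open sampling so
# that symmetry rotations map sample sets onto themselves exactly.
contour_points <- function(geometry, size, spacing = 0.4) {
  half <- size / 2
  if (geometry == "circle") {
    m <- max(8L, ceiling(pi * size / spacing))
    th <- 2 * pi * (0:(m - 1)) / m
    return(cbind(half * cos(th), half * sin(th)))
  }
  corners <- switch(geometry,
    square = cbind(c(half, half, -half, -half), c(-half, half, half, -half)),
    triangle = {
      R <- size / sqrt(3)
      ang <- pi / 2 + 2 * pi * (0:2) / 3
      cbind(R * cos(ang), R * sin(ang))
    })
  k <- nrow(corners)
  edge_len <- sqrt(rowSums((corners[c(2:k, 1), ] - corners)^2))
  m <- max(2L, ceiling(edge_len[1] / spacing))  # equal-length edges
  tpar <- (0:(m - 1)) / m
  pts <- lapply(seq_len(k), function(e) {
    a <- corners[e, ]; b <- corners[if (e == k) 1 else e + 1, ]
    cbind(a[1] + tpar * (b[1] - a[1]), a[2] + tpar * (b[2] - a[2]))
  })
  do.call(rbind, pts)
}

# High-resolution contour pixels of a shape: integer (x, y) 0-based pixel
# coordinates at resolution `resolution * factor`, deduplicated (1-px stroke).
shape_pixels_highres <- function(spec, resolution, factor) {
  pts <- contour_points(spec$geometry, spec$size * factor,
                        spacing = 0.4)
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  cx <- (spec$position[1] + 0.5) * factor - 0.5
  cy <- (spec$position[2] + 0.5) * factor - 0.5
  x <- floor(cx + co * pts[, 1] - si * pts[, 2] + 0.5)
  y <- floor(cy + si * pts[, 1] + co * pts[, 2] + 0.5)
  n <- resolution * factor
  keep <- x >= 0 & x < n & y >= 0 & y < n
  x <- x[keep]; y <- y[keep]
  key <- x + y * n
  keep2 <- !duplicated(key)
  cbind(x = x[keep2], y = y[keep2])
}

#' Render a shape contour as a binary high-resolution raster
#'
#' Renders the outline of a shape (1-px stroke, no anti-aliasing) at the
#' supersampled working resolution used by the simulator. The shape's `size`
#' and `position` are interpreted at dataset resolution (`resolution /
#' factor`); all geometry is evaluated in the high-resolution space to retain
#' sub-pixel accuracy.
#'
#' @param spec a [shape_spec()].
#' @param resolution high-resolution raster size in px (default 2400).
#' @param factor supersampling factor relative to dataset resolution
#'   (default 8, i.e. dataset resolution 300 for the default raster).
#' @return a `resolution` x `resolution` binary matrix (rows = y, cols = x).
#' @export
render_shape <- function(spec, resolution = 2400L, factor = 8L) {
  stopifnot(inherits(spec, "shape_spec"))
  px <- shape_pixels_highres(spec, resolution %/% factor, factor)
  out <- matrix(0L, resolution, resolution)
  out[px[, "y"] + 1L + px[, "x"] * as.integer(resolution)] <- 1L
  out
}

# area-downsampled intensity frame at dataset resolution from a list of
# shape specs (sparse accumulation; never allocates the high-res grid)
render_frame <- function(shape_specs, resolution, factor) {
  fr <- numeric(resolution * resolution)
  for (sp in shape_specs) {
    if (sp$size < 1 / factor) next
    px <- shape_pixels_highres(sp, resolution, factor)
    if (!nrow(px)) next
    lo <- (px[, "x"] %/% factor) * resolution + (px[, "y"] %/% factor) + 1L
    tab <- tabulate(lo, nbins = resolution * resolution)
    fr <- fr + tab
  }
  matrix(fr / factor^2, resolution, resolution)
}

#' Convert an intensity frame difference to polarity events
#'
#' Per-pixel integrate-to-threshold event generation mimicking an event
#' camera: the signed difference between consecutive frames is added to a
#' per-pixel accumulator; wherever the accumulator reaches `+threshold` a
#' positive event is emitted and `threshold` subtracted, and symmetrically
#' for negative events (at most one event per polarity per pixel per frame).
#'
#' @param frame_t,frame_prev intensity matrices at dataset resolution.
#' @param accumulator per-pixel accumulator matrix (same size).
#' @param threshold event threshold (> 0).
#' @return list with `events` (H x W x 2 binary array, polarity 1 = positive,
#'   2 = negative) and the updated `accumulator`.
#' @export
frames_to_events <- function(frame_t, frame_prev, accumulator, threshold) {
  stopifnot(threshold > 0, all(dim(frame_t) == dim(frame_prev)),
            all(dim(frame_t) == dim(accumulator)))
  acc <- accumulator + (frame_t - frame_prev)
  pos <- acc >= threshold
  neg <- acc <= -threshold
  acc[pos] <- acc[pos] - threshold
  acc[neg] <- acc[neg] + threshold
  ev <- array(0L, dim = c(nrow(acc), ncol(acc), 2L))
  ev[, , 1][pos] <- 1L
  ev[, , 2][neg] <- 1L
  list(events = ev, accumulator = acc)
}

#' Generate one sparse event movie
#'
#' Renders the trajectory of a set of shape contours in a supersampled space,
#' area-downsamples every frame to dataset resolution, converts consecutive
#' frame differences to polarity events via the integrate-to-threshold model,
#' overlays Bernoulli background noise, and attaches per-frame sub-pixel
#' ground-truth coordinates. Deterministic for a fixed seed.
#'
#' Under the default (per-movie) noise convention, each pixel independently
#' receives one noise event of random polarity somewhere in the movie with
#' probability `noise_rate / 1000`; the per-frame alternative applies that
#' probability independently at every frame.
#'
#' @param shape_specs list of [shape_spec()] (starting geometry); may be
#'   empty for a noise-only movie.
#' @param motion a [motion_spec()].
#' @param noise_rate Bernoulli background-noise rate in per mille.
#' @param seed integer seed.
#' @param resolution dataset resolution (px, default 300).
#' @param factor supersampling factor (default 8; working space
#'   `resolution * factor`).
#' @param n_frames number of event frames (default 50).
#' @param threshold event threshold, as a calibrated fraction of the nominal
#'   downsampled intensity of a 1-px stroke (`1 / factor`); see the package
#'   vignette for the calibration against the dataset's activation rates.
#' @param noise_convention `"per_movie"` (default) or `"per_frame"`.
#' @return object of class `event_movie` with `frames` (H x W x 2 x T binary
#'   integer array), `labels` (T x n_shapes x 2 continuous px, (x, y)), and
#'   `meta`.
#' @export
generate_movie <- function(shape_specs, motion, noise_rate = 5, seed = 1L,
                           resolution = 300L, factor = 8L, n_frames = 50L,
                           threshold = 0.92 / factor,
                           noise_convention = c("per_movie", "per_frame")) {
  noise_convention <- match.arg(noise_convention)
  stopifnot(inherits(motion, "motion_spec"))
  set.seed(seed)
  ns <- length(shape_specs)
  tv <- motion$translation_velocity
  if (ns > 0 && nrow(tv) == 1) tv <- tv[rep(1, ns), , drop = FALSE]
  sv <- rep(motion$scale_velocity, length.out = max(ns, 1))
  H <- resolution
  frames <- array(0L, dim = c(H, H, 2L, n_frames))
  labels <- array(NA_real_, dim = c(n_frames, max(ns, 1L), 2L))
  acc <- matrix(0, H, H)
  clamped <- FALSE
  state <- function(t) {
    # shape specs at integer frame t (t = 0 is the pre-movie reference frame)
    lapply(seq_len(ns), function(j) {
      sp <- shape_specs[[j]]
      pos <- sp$position + tv[j, ] * t
      cl <- pmin(pmax(pos, 0), H - 1e-9)
      if (any(cl != pos)) clamped <<- TRUE
      sz <- max(sp$size + sv[j] * t, 0)
      shape_spec(sp$geometry, size = max(sz, 1e-9), position = cl,
                 orientation = sp$orientation)
    })
  }
  prev <- render_frame(state(0L), H, factor)
  for (t in seq_len(n_frames)) {
    st <- state(t)
    cur <- render_frame(st, H, factor)
    fe <- frames_to_events(cur, prev, acc, threshold)
    frames[, , , t] <- fe$events
    acc <- fe$accumulator
    prev <- cur
    for (j in seq_len(ns)) labels[t, j, ] <- st[[j]]$position
  }
  if (noise_rate > 0) {
    p <- noise_rate / 1000
    if (noise_convention == "per_movie") {
      hit <- which(runif(H * H) < p)
      if (length(hit)) {
        tf <- sample.int(n_frames, length(hit), replace = TRUE)
        pol <- sample.int(2L, length(hit), replace = TRUE)
        idx <- hit + (pol - 1L) * H * H + (tf - 1L) * 2L * H * H
        frames[idx] <- 1L
      }
    } else {
      for (t in seq_len(n_frames)) {
        hit <- which(runif(H * H) < p)
        if (length(hit)) {
          pol <- sample.int(2L, length(hit), replace = TRUE)
          frames[hit + (pol - 1L) * H * H + (t - 1L) * 2L * H * H] <- 1L
        }
      }
    }
  }
  structure(list(
    frames = frames, labels = labels,
    meta = list(seed = seed, resolution = resolution, factor = factor,
                n_frames = n_frames, threshold = threshold,
                noise_rate = noise_rate, noise_convention = noise_convention,
                kind = motion$dataset_kind,
                scale_velocity = motion$scale_velocity,
                translation_velocity = tv,
                shapes = shape_specs, clamped = clamped)),
    class = "event_movie")
}

#' @export
print.event_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("event movie: %d frames of %dx%d px, %d shapes, sparsity %.3g per mille\n",
              d[4], d[1], d[2], dim(x$labels)[2], sparsity(x)))
  invisible(x)
}

#' Active-pixel fraction of an event movie, in per mille
#'
#' Fraction of nonzero entries over time x height x width, with the two
#' polarities OR-ed together.
#'
#' @param movie an [generate_movie()] result.
#' @return sparsity in per mille.
#' @export
sparsity <- function(movie) {
  stopifnot(inherits(movie, "event_movie"))
  d <- dim(movie$frames)
  active <- movie$frames[, , 1, ] | movie$frames[, , 2, ]
  1000 * sum(active) / (d[1] * d[2] * d[4])
}

log_uniform <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Generate a dataset of event movies
#'
#' The spatial kind varies the starting shape size (log-uniform over
#' `size_range`) at fixed size over time; the temporal kind varies the scale
#' velocity (log-uniform magnitude over `velocity_range`, random sign per
#' shape) at a fixed starting size. Translation velocities are per-shape and
#' per-axis: magnitude uniform over `velocity_range` with random sign for the
#' spatial kind, and uniform on `(-translation_scale, translation_scale)` for
#' the temporal kind (calibrated so the dataset's overall activation rates
#' match the nominal 1--3 per mille regime; see the package vignette).
#' Positions and orientations are random; each movie contains one triangle,
#' one square and one circle. An 80/20 train/validation split is recorded.
#'
#' @param kind `"spatial"` or `"temporal"`.
#' @param n_movies number of movies.
#' @param seed master seed; each movie derives a child seed via
#'   [split_seed()].
#' @param resolution dataset resolution (default 300 px).
#' @param size_range starting-size range (px) for the spatial kind.
#' @param velocity_range scale-velocity magnitude range (px/step) for the
#'   temporal kind (also the translation magnitude range of the spatial
#'   kind).
#' @param start_size starting size (px) for the temporal kind.
#' @param translation_scale half-width of the temporal-kind translation
#'   component distribution (px/step).
#' @param scale_velocity optional fixed scale-velocity magnitude overriding
#'   the log-uniform draw (temporal kind; used for per-velocity evaluation).
#' @param noise_rate,n_frames,factor,threshold passed to [generate_movie()].
#' @param validation_fraction held-out fraction (default 0.2).
#' @return object of class `event_dataset`: list of movies plus `split`
#'   (`"train"` / `"validation"` per movie) and the generation parameters.
#' @export
make_dataset <- function(kind = c("spatial", "temporal"), n_movies, seed,
                         resolution = 300L, size_range = c(10, 80),
                         velocity_range = c(0.16, 1.28), start_size = 17,
                         translation_scale = 0.50, scale_velocity = NULL,
                         noise_rate = 5, n_frames = 50L, factor = 8L,
                         threshold = 0.92 / factor,
                         validation_fraction = 0.2) {
  kind <- match.arg(kind)
  stopifnot(n_movies >= 1)
  seeds <- split_seed(seed, n_movies)
  geoms <- c("triangle", "square", "circle")
  movies <- vector("list", n_movies)
  for (i in seq_len(n_movies)) {
    set.seed(seeds[i])
    if (kind == "spatial") {
      size0 <- log_uniform(1, size_range[1], size_range[2])
      sv <- rep(0, 3)
      tv <- matrix(sample(c(-1, 1), 6, TRUE) *
                     runif(6, velocity_range[1], velocity_range[2]), 3, 2)
    } else {
      size0 <- start_size
      v <- if (is.null(scale_velocity)) {
        log_uniform(1, velocity_range[1], velocity_range[2])
      } else scale_velocity
      # balanced direction mix: every movie holds at least one growing and
      # one shrinking shape, and the assignment of directions to the three
      # geometries cycles through all six arrangements so any dataset slice
      # is direction- and geometry-balanced
      patterns <- list(c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1),
                       c(-1, -1, 1), c(-1, 1, -1), c(1, -1, -1))
      sv <- patterns[[(i - 1L) %% 6L + 1L]] * v
      tv <- matrix(runif(6, -translation_scale, translation_scale), 3, 2)
    }
    pos <- matrix(runif(6, 0.25 * resolution, 0.75 * resolution), 3, 2)
    shapes <- lapply(1:3, function(j) {
      shape_spec(geoms[j], size = size0, position = pos[j, ],
                 orientation = runif(1, 0, 2 * pi))
    })
    mo <- motion_spec(tv, sv, kind)
    movies[[i]] <- generate_movie(
      shapes, mo, noise_rate = noise_rate, seed = seeds[i],
      resolution = resolution, factor = factor, n_frames = n_frames,
      threshold = threshold)
    movies[[i]]$meta$size0 <- size0
    movies[[i]]$meta$scale_speed <- abs(sv[1])
  }
  n_train <- round((1 - validation_fraction) * n_movies)
  split <- rep(c("train", "validation"),
               c(n_train, n_movies - n_train))
  structure(list(movies = movies, kind = kind, seed = seed, split = split,
                 params = list(resolution = resolution,
                               size_range = size_range,
                               velocity_range = velocity_range,
                               start_size = start_size,
                               translation_scale = translation_scale,
                               noise_rate = noise_rate,
                               n_frames = n_frames, factor = factor,
                               threshold = threshold)),
            class = "event_dataset")
}

#' @export
print.event_dataset <- function(x, ...) {
  cat(sprintf("event dataset (%s kind): %d movies at %d px, %d train / %d validation\n",
              x$kind, length(x$movies), x$params$resolution,
              sum(x$split == "train"), sum(x$split == "validation")))
  invisible(x)
}

#' Export an event movie as a CSV event list
#'
#' Columns `t, x, y, polarity` (all 0-based; `t` in frames; polarity 1 =
#' positive, -1 = negative).
#'
#' @param movie an `event_movie`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_event_movie <- function(movie, path) {
  stopifnot(inherits(movie, "event_movie"))
  d <- dim(movie$frames)
  idx <- which(movie$frames != 0L, arr.ind = TRUE)
  df <- data.frame(t = idx[, 4] - 1L, x = idx[, 2] - 1L, y = idx[, 1] - 1L,
                   polarity = ifelse(idx[, 3] == 1L, 1L, -1L))
  df <- df[order(df$t, df$y, df$x), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
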