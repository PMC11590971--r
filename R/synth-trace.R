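#' Closed driving-path geometry
#'
#' A closed polyline (last vertex joins the first) in metres. The path must
#' contain exactly one longest straight edge: the analysis gates all
#' comparisons on passes over that segment, so an ambiguous longest straight
#' is a configuration error.
#'
#' @param vertices numeric n x 2 matrix of x/y coordinates (m), n >= 3,
#'   given in traversal order; the closing edge is implicit.
#' @return List of class `path_spec`: `vertices`, `edges` (tibble with
#'   from/to coordinates, `length`, `bearing` in degrees), `longest_edge`
#'   (row index), `perimeter`.
#' @export
path_spec <- function(vertices) {
  v <- as.matrix(vertices)
  assert_that(ncol(v) == 2 && nrow(v) >= 3, "need an n x 2 matrix, n >= 3")
  nxt <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  d <- nxt - v
  len <- sqrt(rowSums(d^2))
  assert_that(all(len > 0), "degenerate (zero-length) edge")
  bearing <- (atan2(d[, 2], d[, 1]) * 180 / pi) %% 360
  longest <- which(len > max(len) - 1e-9)
  if (length(longest) > 1)
    stop("ambiguous longest straight: two edges of equal maximal length",
         call. = FALSE)
  structure(list(
    vertices = v,
    edges = tibble::tibble(x0 = v[, 1], y0 = v[, 2], x1 = nxt[, 1],
                           y1 = nxt[, 2], length = len, bearing = bearing),
    longest_edge = longest,
    perimeter = sum(len)
  ), class = "path_spec")
}

#' Simulate a constant-speed traversal of a closed path
#'
#' The vehicle moves along the polyline at constant speed; per-sample
#' heading equals the current edge bearing plus optional noise, and the
#' position gets optional isotropic jitter. Ground truth records the
#' entry/exit times of every pass over the longest straight edge.
#'
#' @param path a [path_spec()].
#' @param duration traversal duration, s.
#' @param speed vehicle speed, m/s (default 11.11, i.e. 40 km/h).
#' @param fs position sampling rate, Hz.
#' @param pos_noise_sd isotropic position noise, m.
#' @param heading_noise_sd heading noise, degrees.
#' @param t0 time of the first sample (s), for streams sharing one clock.
#' @param seed RNG seed for the noise (`NULL` leaves the RNG alone).
#' @return List: `trace` (tibble `t, x, y, heading`) and `truth` (tibble of
#'   longest-straight passes `pass_index, start, end`).
#' @export
generate_trace <- function(path, duration, speed = 11.11, fs = 10,
                           pos_noise_sd = 0, heading_noise_sd = 0,
                           t0 = 0, seed = NULL) {
  assert_that(inherits(path, "path_spec"), "need a path_spec")
  assert_that(duration > 0 && speed > 0, "duration and speed must be positive")
  t_rel <- seq(0, duration - 1 / fs, by = 1 / fs)
  s <- (speed * t_rel) %% path$perimeter
  cum <- c(0, cumsum(path$edges$length))
  edge_idx <- findInterval(s, cum, rightmost.closed = TRUE)
  edge_idx[edge_idx > nrow(path$edges)] <- nrow(path$edges)
  frac <- (s - cum[edge_idx]) / path$edges$length[edge_idx]
  x <- path$edges$x0[edge_idx] +
    frac * (path$edges$x1[edge_idx] - path$edges$x0[edge_idx])
  y <- path$edges$y0[edge_idx] +
    frac * (path$edges$y1[edge_idx] - path$edges$y0[edge_idx])
  heading <- path$edges$bearing[edge_idx]
  if (pos_noise_sd > 0 || heading_noise_sd > 0) {
    gen <- function() {
      x <<- x + rnorm(length(x), 0, pos_noise_sd)
      y <<- y + rnorm(length(y), 0, pos_noise_sd)
      heading <<- (heading + rnorm(length(heading), 0, heading_noise_sd)) %% 360
    }
    if (is.null(seed)) gen() else with_seed(seed, gen())
  }
  # truth: time intervals on the longest edge (from noise-free arc length)
  on_edge <- edge_idx == path$longest_edge
  runs <- rle(on_edge)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  truth <- tibble::tibble(
    start = t0 + t_rel[starts[runs$values]],
    end = t0 + t_rel[ends[runs$values]] + 1 / fs
  )
  truth$pass_index <- seq_len(nrow(truth))
  trace <- tibble::tibble(t = t0 + t_rel, x = x, y = y, heading = heading)
  list(trace = trace, truth = truth[, c("pass_index", "start", "end")])
}
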