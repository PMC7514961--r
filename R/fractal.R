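# Box-counting (binary box) dimension of a sampled waveform. The polyline
# through the samples is normalised to the unit square (time to [0,1],
# amplitude affinely to [0,1]; flat signals map to the constant 1/2), the
# square is tiled by delta x delta boxes anchored at the origin, and the
# boxes touched by the curve are counted column by column. The dimension is
# the least-squares slope of log N_delta against log(1/delta) over dyadic
# scales delta_i = 2^(i-1) * delta_t.

normalise_curve <- function(x) {
  n <- length(x)
  if (n < 2L) stop("box counting needs at least 2 samples", call. = FALSE)
  rng <- range(x)
  y <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else rep(0.5, n)
  list(y = y, t = (seq_len(n) - 1) / (n - 1))
}

#' Count covering boxes at one grid scale
#'
#' With the waveform normalised to the unit square, counts the delta x delta
#' boxes (grid anchored at the origin) touched by the linearly interpolated
#' polyline: for each time column the vertical box span between the column's
#' curve minimum and maximum is counted, and the counts are summed over
#' columns.
#'
#' @param record A [heart_sound_record()] or numeric vector (>= 2 samples).
#' @param delta Grid size in normalised units, in (0, 1].
#' @return A positive integer box count.
#' @export
count_boxes <- function(record, delta) {
  x <- if (inherits(record, "heart_sound_record")) record$samples else as.numeric(record)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0 || delta > 1) {
    stop("`delta` must be a single value in (0, 1]", call. = FALSE)
  }
  nc <- normalise_curve(x)
  y <- nc$y
  t <- nc$t
  n <- length(y)
  dt <- 1 / (n - 1)
  m <- delta / dt

  if (abs(m - round(m)) < 1e-9 && round(m) >= 1) {
    # column boundaries coincide with sample times: each column's extrema are
    # attained at its samples
    m <- as.integer(round(m))
    starts <- seq.int(0L, n - 2L, by = m)   # 0-based first sample of column
    cmin <- rep(Inf, length(starts))
    cmax <- rep(-Inf, length(starts))
    for (k in 0:m) {
      idx <- starts + k
      ok <- idx <= n - 1L
      v <- y[idx[ok] + 1L]
      cmin[ok] <- pmin(cmin[ok], v)
      cmax[ok] <- pmax(cmax[ok], v)
    }
  } else {
    # general grid: add the interpolated curve value at every interior column
    # boundary, crediting it to both adjacent columns
    ncol_grid <- ceiling(1 / delta - 1e-12)
    bounds <- delta * seq_len(ncol_grid - 1L)
    bounds <- bounds[bounds < 1]
    vb <- if (length(bounds)) stats::approx(t, y, xout = bounds)$y else numeric(0)
    col_pts <- pmin(floor(t / delta), ncol_grid - 1L)
    cols <- c(col_pts, floor(bounds / delta) - 1L, floor(bounds / delta))
    vals <- c(y, vb, vb)
    keep <- cols >= 0 & cols <= ncol_grid - 1L
    cmin <- tapply(vals[keep], cols[keep], min)
    cmax <- tapply(vals[keep], cols[keep], max)
  }
  sum(floor(cmax / delta) - floor(cmin / delta) + 1)
}

#' Box-counting dimension estimate
#'
#' Computes box counts at the dyadic scales
#' \eqn{\delta_i = 2^{i-1} \delta_t}, \eqn{i = 1 \ldots i_{max}}, where
#' \eqn{\delta_t} is the (normalised) sample spacing, then fits
#' \eqn{\log N_\delta} against \eqn{\log(1/\delta)} by ordinary least
#' squares. The slope is the dimension estimate; for a curve in the plane it
#' lies in \eqn{[0, 2]} (about 1 for smooth signals, about 1.5 for a
#' Brownian path).
#'
#' @param record A [heart_sound_record()] or numeric vector.
#' @param i_max Number of dyadic scales (>= 3). Default
#'   `floor(log2(N)) - 4`, which keeps at least 16 samples in the coarsest
#'   column.
#' @return An object of class `box_count_curve` with fields `scales`,
#'   `counts`, `log_points`, `slope`, `intercept` and `r_squared`.
#' @export
box_dimension <- function(record, i_max = NULL) {
  x <- if (inherits(record, "heart_sound_record")) record$samples else as.numeric(record)
  n <- length(x)
  if (is.null(i_max)) i_max <- max(3L, floor(log2(n)) - 4L)
  if (i_max < 3L) {
    stop("`i_max` must be >= 3 (a 2-point fit is not a regression)", call. = FALSE)
  }
  if (n < 2L^i_max) {
    stop(sprintf("record too short for %d dyadic scales: %d samples, need >= %d",
                 i_max, n, 2L^i_max), call. = FALSE)
  }
  dt <- 1 / (n - 1)
  scales <- 2^(seq_len(i_max) - 1) * dt
  counts <- vapply(scales, function(d) count_boxes(x, d), numeric(1))
  lx <- log(1 / scales)
  ly <- log(counts)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(scales = scales, counts = counts,
         log_points = cbind(log_inv_delta = lx, log_count = ly),
         slope = slope, intercept = intercept, r_squared = r2),
    class = "box_count_curve"
  )
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat(sprintf("<box_count_curve> %d scales, D_B = %.4f (r^2 = %.4f)\n",
              length(x$scales), x$slope, x$r_squared))
  invisible(x)
}
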