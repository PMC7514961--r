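# Wavelet-packet decomposition by a periodized orthogonal filter-bank
# cascade. A full fixed-depth tree is computed (no best-basis pruning): at
# level 4 this yields the 16 terminal nodes (4,0)...(4,15) in natural (Paley)
# order, whose coefficient two-norms and energy distribution are the feature
# primitives of the classifier.

# Standard Daubechies scaling (low-pass) filter taps, h0..h(2N-1).
# sum(h) = sqrt(2), sum(h^2) = 1; the high-pass filter is the usual
# quadrature mirror g[k] = (-1)^k h[L-1-k].
daubechies_lowpass <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.4829629131445341, 0.8365163037378079,
          0.2241438680420134, -0.1294095225512604),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
          0.0328830116668852, -0.0105974017850690),
  db6 = c(0.1115407433501095, 0.4946238903984533, 0.7511339080210959,
          0.3152503517091982, -0.2262646939654400, -0.1297668675672625,
          0.0975016055873225, 0.0275228655303053, -0.0315820393180312,
          0.0005538422009938, 0.0047772575110106, -0.0010773010849955)
)

wavelet_filters <- function(wavelet) {
  h <- daubechies_lowpass[[wavelet]]
  if (is.null(h)) {
    stop(sprintf("unknown wavelet '%s'; available: %s", wavelet,
                 paste(names(daubechies_lowpass), collapse = ", ")),
         call. = FALSE)
  }
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  list(h = h, g = g)
}

# One periodized analysis step: x (even length N) -> list(approx, detail),
# each of length N/2, with y[i] = sum_k f[k] x[(2i + k) mod N].
wpt_step <- function(x, h, g) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  m <- n %/% 2L
  L <- length(h)
  idx <- (outer(2L * (seq_len(m) - 1L), 0:(L - 1L), "+") %% n) + 1L
  xm <- matrix(x[idx], nrow = m, ncol = L)
  list(approx = as.numeric(xm %*% h), detail = as.numeric(xm %*% g))
}

#' Wavelet-packet decomposition of a heart-sound record
#'
#' Decomposes the record with a periodized orthogonal filter bank down to
#' `level`, returning all `2^level` terminal-node coefficient sequences in
#' natural (Paley) order. The signal is zero-padded to the next multiple of
#' `2^level`; with periodization the transform is orthogonal, so the total
#' coefficient energy equals the signal energy (Parseval).
#'
#' @param record A [heart_sound_record()] (or bare numeric vector).
#' @param wavelet Wavelet name; `"db6"` (default), `"db1"`, `"db2"` or `"db4"`.
#' @param level Decomposition depth (default 4, giving 16 nodes).
#' @return An object of class `wavelet_packet_table` with fields `level`,
#'   `node_coeffs` (list of `2^level` numeric vectors), `wavelet_name` and
#'   `boundary_mode`.
#' @export
wpt_decompose <- function(record, wavelet = "db6", level = 4L) {
  x <- if (inherits(record, "heart_sound_record")) record$samples else as.numeric(record)
  if (level < 1L) stop("`level` must be >= 1", call. = FALSE)
  min_len <- 2L^level
  if (length(x) < min_len) {
    stop(sprintf("record too short for level %d: %d samples given, minimum is %d",
                 level, length(x), min_len), call. = FALSE)
  }
  filt <- wavelet_filters(wavelet)
  pad <- (min_len - length(x) %% min_len) %% min_len
  if (pad > 0L) x <- c(x, numeric(pad))

  nodes <- list(x)
  for (j in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (k in seq_along(nodes)) {
      s <- wpt_step(nodes[[k]], filt$h, filt$g)
      nxt[[2L * k - 1L]] <- s$approx
      nxt[[2L * k]] <- s$detail
    }
    nodes <- nxt
  }
  names(nodes) <- sprintf("(%d,%d)", level, seq_along(nodes) - 1L)
  structure(
    list(level = as.integer(level), node_coeffs = nodes,
         wavelet_name = wavelet, boundary_mode = "periodization"),
    class = "wavelet_packet_table"
  )
}

#' @export
print.wavelet_packet_table <- function(x, ...) {
  cat(sprintf("<wavelet_packet_table> %s, level %d, %d nodes of %d coefficients\n",
              x$wavelet_name, x$level, length(x$node_coeffs),
              length(x$node_coeffs[[1]])))
  invisible(x)
}

#' Two-norms of the terminal-node coefficient sequences
#'
#' Entry k is \eqn{\sqrt{\sum_i S_{jk}(i)^2}} for terminal node k, in node
#' order. For a level-4 decomposition the 16 values form the subband-energy
#' feature block of the classifier.
#'
#' @param table A [wpt_decompose()] result.
#' @return Numeric vector of `2^level` nonnegative norms.
#' @export
node_norms <- function(table) {
  stopifnot(inherits(table, "wavelet_packet_table"))
  vapply(table$node_coeffs, function(s) sqrt(sum(s^2)), numeric(1))
}

#' Energy distribution across terminal nodes
#'
#' Computes per-node energies \eqn{E_{jk} = \sum_i S_{jk}(i)^2}, their total
#' \eqn{E}, and the fractions \eqn{\epsilon_{jk} = E_{jk}/E}, which sum to 1.
#'
#' @param table A [wpt_decompose()] result with nonzero total energy.
#' @return An object of class `node_energy_spectrum` with fields `energies`,
#'   `total` and `fractions`.
#' @export
energy_spectrum <- function(table) {
  stopifnot(inherits(table, "wavelet_packet_table"))
  e <- vapply(table$node_coeffs, function(s) sum(s^2), numeric(1))
  total <- sum(e)
  if (total <= 0) {
    stop("zero-energy signal has undefined entropy", call. = FALSE)
  }
  structure(list(energies = e, total = total, fractions = e / total),
            class = "node_energy_spectrum")
}

#' Wavelet-packet energy entropy
#'
#' Shannon entropy (natural log) of the node energy fractions:
#' \eqn{H = -\sum_k \epsilon_{jk} \ln \epsilon_{jk}}, with
#' \eqn{0 \ln 0 := 0}. Low when the signal's energy concentrates in one
#' subband, maximal (\eqn{\ln 16} for 16 nodes) when spread uniformly.
#'
#' @param spectrum A [energy_spectrum()] result, or a bare vector of
#'   nonnegative fractions summing to 1.
#' @return A single nonnegative entropy value.
#' @export
energy_entropy <- function(spectrum) {
  eps <- if (inherits(spectrum, "node_energy_spectrum")) {
    spectrum$fractions
  } else {
    as.numeric(spectrum)
  }
  nz <- eps > 0
  -sum(eps[nz] * log(eps[nz]))
}
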