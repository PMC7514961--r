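# Independent oracles used across the suite. Each re-derives the quantity it
# checks through a different computational route than the package.

# --- wavelet filter-bank oracle -------------------------------------------
# Standard db6 scaling taps (same published constants the package freezes;
# the oracle is about the cascade structure, computed here by a literal
# convolve-and-downsample loop).
DB6_H <- c(0.1115407433501095, 0.4946238903984533, 0.7511339080210959,
           0.3152503517091982, -0.2262646939654400, -0.1297668675672625,
           0.0975016055873225, 0.0275228655303053, -0.0315820393180312,
           0.0005538422009938, 0.0047772575110106, -0.0010773010849955)
DB6_G <- (-1)^(0:11) * rev(DB6_H)

# one periodized analysis step as an explicit per-coefficient loop
oracle_wpt_step <- function(x, f) {
  n <- length(x)
  m <- n %/% 2L
  out <- numeric(m)
  for (i in 0:(m - 1L)) {
    acc <- 0
    for (k in 0:(length(f) - 1L)) acc <- acc + f[k + 1L] * x[((2L * i + k) %% n) + 1L]
    out[i + 1L] <- acc
  }
  out
}

# full cascade to `level`, natural (Paley) node order
oracle_wpt <- function(x, level) {
  nodes <- list(x)
  for (j in seq_len(level)) {
    nxt <- list()
    for (nd in nodes) {
      nxt <- c(nxt, list(oracle_wpt_step(nd, DB6_H), oracle_wpt_step(nd, DB6_G)))
    }
    nodes <- nxt
  }
  nodes
}

# --- box-counting rasterization oracle ------------------------------------
# Marks every box visited by a dense walk along the normalised polyline.
# Columns are closed intervals (a point on a column boundary belongs to both
# neighbouring columns), rows are floor(v/delta), matching the plain
# column-span definition of the covering.
oracle_count_boxes <- function(x, delta) {
  n <- length(x)
  rng <- range(x)
  y <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else rep(0.5, n)
  t <- (seq_len(n) - 1) / (n - 1)
  ncol_grid <- ceiling(1 / delta - 1e-12)
  boxes <- new.env(hash = TRUE)
  mark <- function(col, row) {
    if (col >= 0 && col <= ncol_grid - 1L) {
      assign(paste(col, row), TRUE, envir = boxes)
    }
  }
  mark_point <- function(ti, vi) {
    col <- min(floor(ti / delta), ncol_grid - 1L)
    row <- floor(vi / delta)
    mark(col, row)
    if (abs(ti / delta - round(ti / delta)) < 1e-12 && ti > 0) {
      mark(round(ti / delta) - 1L, row)  # boundary point: both columns
    }
  }
  for (i in seq_len(n - 1L)) {
    t1 <- t[i]; t2 <- t[i + 1L]; v1 <- y[i]; v2 <- y[i + 1L]
    K <- max(16L, ceiling(abs(v2 - v1) / delta * 16))
    ts <- seq(t1, t2, length.out = K + 1L)
    vs <- v1 + (ts - t1) / (t2 - t1) * (v2 - v1)
    for (k in seq_along(ts)) mark_point(ts[k], vs[k])
    # exact column-boundary crossings within the segment
    jlo <- ceiling(t1 / delta + 1e-12); jhi <- floor(t2 / delta - 1e-12)
    if (jhi >= jlo) {
      for (j in jlo:jhi) {
        tb <- j * delta
        vb <- v1 + (tb - t1) / (t2 - t1) * (v2 - v1)
        mark_point(tb, vb)
      }
    }
  }
  length(ls(boxes))
}

# --- TWSVM primal brute force ----------------------------------------------
# Exact minimiser of the (ridge-regularised) primal
#   1/2 ||H w||^2 + ridge/2 ||w||^2 + cc * sum_i max(0, 1 + g_i' w)
# by exhaustive enumeration (for the second twin problem, whose hinge is
# max(0, 1 - g_i' w), call with -G) of the three KKT states of every hinge term
# (strictly inactive / at the kink with multiplier in [0, cc] / strictly
# active). Exact up to the linear solves; independent of the dual route.
oracle_primal_plane <- function(H, G, cc, ridge = 1e-6, tol = 1e-9) {
  p <- ncol(H); m2 <- nrow(G)
  M <- crossprod(H) + diag(ridge, p)
  obj <- function(w) {
    0.5 * sum((H %*% w)^2) + 0.5 * ridge * sum(w^2) +
      cc * sum(pmax(0, 1 + drop(G %*% w)))
  }
  best <- NULL; best_obj <- Inf
  states <- as.matrix(expand.grid(rep(list(0:2), m2)))
  for (r in seq_len(nrow(states))) {
    st <- states[r, ]
    E <- which(st == 1L); S2 <- which(st == 2L)
    GE <- G[E, , drop = FALSE]
    rhs1 <- -cc * if (length(S2)) colSums(G[S2, , drop = FALSE]) else numeric(p)
    k <- length(E)
    KKT <- rbind(cbind(M, t(GE)), cbind(GE, matrix(0, k, k)))
    sol <- tryCatch(solve(KKT, c(rhs1, rep(-1, k))), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_len(p)]; lam <- sol[-seq_len(p)]
    viol <- drop(G %*% w) + 1
    ok <- all(viol[st == 0L] <= tol) && all(viol[S2] >= -tol) &&
      (k == 0L || all(lam >= -tol & lam <= cc + tol))
    if (ok) {
      o <- obj(w)
      if (o < best_obj) { best_obj <- o; best <- w }
    }
  }
  list(w = best, objective = best_obj)
}

# kernel design matrices for both planes of a fitted/pending problem
plane_matrices <- function(X, y, kernel, sigma, standardize = FALSE) {
  if (standardize) {
    X <- scale(X)
  }
  A <- X[y == 1, , drop = FALSE]
  B <- X[y == -1, , drop = FALSE]
  Kmat <- function(P) {
    if (kernel == "linear") P %*% t(X) else gaussian_kernel(P, X, sigma)
  }
  list(H1 = cbind(Kmat(A), 1), G1 = cbind(Kmat(B), 1),
       H2 = cbind(Kmat(B), 1), G2 = cbind(Kmat(A), 1))
}

primal_obj_fn <- function(H, G, cc, ridge = 1e-6) {
  function(w) {
    0.5 * sum((H %*% w)^2) + 0.5 * ridge * sum(w^2) +
      cc * sum(pmax(0, 1 + drop(G %*% w)))
  }
}

# --- misc fixtures ----------------------------------------------------------
toy_separable <- function() {
  list(X = rbind(c(0, 0), c(0, 1), c(1, 0), c(3, 3), c(3, 4), c(4, 3)),
       y = c(1, 1, 1, -1, -1, -1))
}

two_moons <- function(n, noise = 0.1, seed = 1) {
  set.seed(seed)
  n1 <- n %/% 2; n2 <- n - n1
  t1 <- runif(n1, 0, pi); t2 <- runif(n2, 0, pi)
  X <- rbind(cbind(cos(t1), sin(t1)),
             cbind(1 - cos(t2), 0.5 - sin(t2)))
  X <- X + matrix(rnorm(2 * n, sd = noise), ncol = 2)
  list(X = X, y = c(rep(1, n1), rep(-1, n2)))
}
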