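test_that("Gaussian kernel closed forms and PSD property hold", {
  expect_equal(gaussian_kernel(matrix(1:3, 1), matrix(1:3, 1), 2)[1, 1], 1)
  s <- 0.7
  expect_equal(gaussian_kernel(matrix(0, 1), matrix(s * sqrt(2), 1), s)[1, 1],
               exp(-1), tolerance = 1e-12)
  set.seed(41)
  X <- matrix(rnorm(60), 15)
  K <- gaussian_kernel(X, X, 1.3)
  expect_equal(K, t(K))
  expect_true(all(diag(K) == 1))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(gaussian_kernel(X, X, 0), "positive")
  expect_error(gaussian_kernel(X, matrix(rnorm(10), 5, 2), 1), "columns")
})

test_that("the dual path matches the primal brute force on the separable toy", {
  toy <- toy_separable()
  m <- twsvm_fit(toy$X, toy$y, c1 = 1, c2 = 1, kernel = "linear",
                 standardize = FALSE)
  expect_equal(unname(predict(m, toy$X)), toy$y)

  pm <- plane_matrices(toy$X, toy$y, "linear", NA)
  or1 <- oracle_primal_plane(pm$H1, pm$G1, 1)
  or2 <- oracle_primal_plane(pm$H2, -pm$G2, 1)
  f1 <- primal_obj_fn(pm$H1, pm$G1, 1)
  f2 <- function(w) {
    0.5 * sum((pm$H2 %*% w)^2) + 0.5e-6 * sum(w^2) +
      sum(pmax(0, 1 - drop(pm$G2 %*% w)))
  }
  expect_lt(abs(f1(c(m$u1, m$b1)) - or1$objective), 1e-5)
  expect_lt(abs(f2(c(m$u2, m$b2)) - or2$objective), 1e-5)
})

test_that("dual path matches the brute force on random kernel instances (m <= 20)", {
  set.seed(42)
  for (trial in 1:6) {
    m1 <- sample(3:10, 1); m2 <- sample(3:8, 1)
    X <- rbind(matrix(rnorm(m1 * 3), m1), matrix(rnorm(m2 * 3), m2) + 1.5)
    y <- c(rep(1, m1), rep(-1, m2))
    cc <- 2
    mod <- twsvm_fit(X, y, c1 = cc, c2 = cc, sigma1 = 1.3, sigma2 = 1.3,
                     standardize = FALSE)
    pm <- plane_matrices(X, y, "gaussian", 1.3)
    or1 <- oracle_primal_plane(pm$H1, pm$G1, cc)
    or2 <- oracle_primal_plane(pm$H2, -pm$G2, cc)
    f1 <- primal_obj_fn(pm$H1, pm$G1, cc)
    f2 <- function(w) {
      0.5 * sum((pm$H2 %*% w)^2) + 0.5e-6 * sum(w^2) +
        cc * sum(pmax(0, 1 - drop(pm$G2 %*% w)))
    }
    expect_lt(abs(f1(c(mod$u1, mod$b1)) - or1$objective), 1e-5)
    expect_lt(abs(f2(c(mod$u2, mod$b2)) - or2$objective), 1e-5)
    # oracle plane pair classifies identically to the package model
    den1 <- sqrt(drop(crossprod(or1$w[1:(m1 + m2)],
                                gaussian_kernel(X, X, 1.3) %*% or1$w[1:(m1 + m2)])))
    den2 <- sqrt(drop(crossprod(or2$w[1:(m1 + m2)],
                                gaussian_kernel(X, X, 1.3) %*% or2$w[1:(m1 + m2)])))
    Kx <- gaussian_kernel(X, X, 1.3)
    d1 <- abs(drop(Kx %*% or1$w[1:(m1 + m2)]) + or1$w[m1 + m2 + 1]) / den1
    d2 <- abs(drop(Kx %*% or2$w[1:(m1 + m2)]) + or2$w[m1 + m2 + 1]) / den2
    expect_equal(unname(predict(mod, X)), unname(ifelse(d1 < d2, 1, -1)))
  }
})

test_that("dual solutions satisfy their box constraints", {
  set.seed(43)
  X <- rbind(matrix(rnorm(24), 8), matrix(rnorm(21), 7) + 1)
  y <- c(rep(1, 8), rep(-1, 7))
  for (cc in c(0.1, 1, 3.5)) {
    m <- twsvm_fit(X, y, c1 = cc, c2 = 2 * cc)
    expect_true(all(m$alpha >= -1e-10 & m$alpha <= cc + 1e-10))
    expect_true(all(m$gamma >= -1e-10 & m$gamma <= 2 * cc + 1e-10))
  }
})

test_that("mirrored classes give mirrored planes", {
  A <- rbind(c(1, 2), c(2, 1), c(1.5, 1.5))
  m <- twsvm_fit(rbind(A, -A), c(1, 1, 1, -1, -1, -1), c1 = 1, c2 = 1,
                 kernel = "linear", standardize = FALSE)
  # with B = -A and a linear kernel, plane 2 is the reflection of plane 1
  # through the origin: same u, opposite offset
  expect_equal(m$u2, m$u1, tolerance = 1e-6)
  expect_lt(abs(m$b1) - abs(m$b2), 1e-6)
  expect_lt(abs(m$b1 + m$b2), 1e-6)
  # the origin is equidistant from both planes; the tie goes to normal (-1)
  d0 <- decision_distances(m, c(0, 0))
  expect_equal(unname(d0[1, "d1"]), unname(d0[1, "d2"]), tolerance = 1e-12)
  expect_equal(unname(predict(m, c(0, 0))), -1)
})

test_that("an exact tie in distances is assigned to the normal class", {
  toy <- toy_separable()
  m <- twsvm_fit(toy$X, toy$y, kernel = "linear", standardize = FALSE)
  # force d1 == d2 by making both planes identical
  m$u2 <- m$u1; m$b2 <- m$b1; m$plane_norms[2] <- m$plane_norms[1]
  expect_true(all(predict(m, toy$X) == -1))
})

test_that("swapping the classes swaps the planes and flips every prediction", {
  tm <- two_moons(60, seed = 5)
  m_ab <- twsvm_fit(tm$X, tm$y, c1 = 1, c2 = 2, sigma1 = 1, sigma2 = 0.8)
  m_ba <- twsvm_fit(tm$X, -tm$y, c1 = 2, c2 = 1, sigma1 = 0.8, sigma2 = 1)
  set.seed(6)
  grid <- matrix(rnorm(40), ncol = 2)
  d_ab <- decision_distances(m_ab, grid)
  d_ba <- decision_distances(m_ba, grid)
  expect_equal(unname(d_ba[, "d1"]), unname(d_ab[, "d2"]), tolerance = 1e-6)
  expect_equal(unname(d_ba[, "d2"]), unname(d_ab[, "d1"]), tolerance = 1e-6)
  expect_equal(unname(predict(m_ba, grid)), unname(-predict(m_ab, grid)))
})

test_that("predictions are invariant to permuting the training rows", {
  tm <- two_moons(40, seed = 7)
  m1 <- twsvm_fit(tm$X, tm$y, sigma1 = 1, sigma2 = 1)
  set.seed(8)
  perm <- sample(nrow(tm$X))
  m2 <- twsvm_fit(tm$X[perm, ], tm$y[perm], sigma1 = 1, sigma2 = 1)
  grid <- matrix(rnorm(60), ncol = 2)
  expect_equal(unname(predict(m1, grid)), unname(predict(m2, grid)))
})

test_that("a point constructed on plane 1 has distance zero to it", {
  toy <- toy_separable()
  m <- twsvm_fit(toy$X, toy$y, kernel = "linear", standardize = FALSE)
  w <- drop(crossprod(m$C_train, m$u1))  # effective linear weights
  x_star <- -m$b1 * w / sum(w^2)
  d <- decision_distances(m, x_star)
  expect_lt(d[1, "d1"], 1e-9)
})

test_that("distances match a naive double-loop kernel expansion", {
  tm <- two_moons(30, seed = 9)
  m <- twsvm_fit(tm$X, tm$y, sigma1 = 1.2, sigma2 = 0.9, standardize = FALSE)
  x <- c(0.3, 0.4)
  f1 <- 0; f2 <- 0
  for (j in seq_len(nrow(m$C_train))) {
    k1 <- exp(-sum((x - m$C_train[j, ])^2) / (2 * m$sigma1^2))
    k2 <- exp(-sum((x - m$C_train[j, ])^2) / (2 * m$sigma2^2))
    f1 <- f1 + k1 * m$u1[j]
    f2 <- f2 + k2 * m$u2[j]
  }
  n1 <- 0; n2 <- 0
  for (i in seq_len(nrow(m$C_train))) {
    for (j in seq_len(nrow(m$C_train))) {
      kij1 <- exp(-sum((m$C_train[i, ] - m$C_train[j, ])^2) / (2 * m$sigma1^2))
      kij2 <- exp(-sum((m$C_train[i, ] - m$C_train[j, ])^2) / (2 * m$sigma2^2))
      n1 <- n1 + m$u1[i] * kij1 * m$u1[j]
      n2 <- n2 + m$u2[i] * kij2 * m$u2[j]
    }
  }
  d <- decision_distances(m, x)
  expect_equal(unname(d[1, "d1"]), abs(f1 + m$b1) / sqrt(n1), tolerance = 1e-9)
  expect_equal(unname(d[1, "d2"]), abs(f2 + m$b2) / sqrt(n2), tolerance = 1e-9)
})

test_that("on the separable toy, slack vanishes as the penalty grows", {
  toy <- toy_separable()
  slack1 <- function(cc) {
    m <- twsvm_fit(toy$X, toy$y, c1 = cc, c2 = cc, kernel = "linear",
                   standardize = FALSE)
    K <- toy$X %*% t(toy$X)
    viol <- 1 + drop(K[toy$y == -1, ] %*% m$u1 + m$b1)
    sum(pmax(0, viol))
  }
  s <- vapply(c(0.01, 1, 100), slack1, numeric(1))
  expect_true(all(diff(s) <= 1e-8))
  expect_lt(s[3], 1e-3)
})

test_that("two-moons data is separated with the Gaussian kernel", {
  tm <- two_moons(200, seed = 1)
  m <- twsvm_fit(tm$X, tm$y, c1 = 1, c2 = 1, sigma1 = 1, sigma2 = 1,
                 standardize = FALSE)
  expect_gte(mean(predict(m, tm$X) == tm$y), 0.95)
})

test_that("fit validates inputs and models survive a save/load round trip", {
  expect_error(twsvm_fit(matrix(rnorm(10), 5), rep(1, 5)), "both classes")
  expect_error(twsvm_fit(matrix(rnorm(10), 5), c(1, 1, 0, -1, -1)), "\\+1 or -1")
  tm <- two_moons(20, seed = 2)
  m <- twsvm_fit(tm$X, tm$y)
  expect_error(decision_distances(m, c(1, 2, 3)), "expected 2 features")

  path <- withr::local_tempfile(fileext = ".rds")
  twsvm_save(m, path)
  m2 <- twsvm_load(path)
  expect_equal(predict(m2, tm$X), predict(m, tm$X))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(twsvm_load(bad), "twin-SVM model")
})
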