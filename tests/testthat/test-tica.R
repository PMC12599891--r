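test_that("tiled_conv_forward equals the brute-force oracle", {
  withr::with_seed(1, {
    for (i in 1:20) {
      s <- sample(2:4, 1); k <- sample(1:3, 1)
      L <- sample(1:3, 1); C <- sample(1:2, 1)
      n <- s + sample(2:6, 1)
      W <- init_tiled_weights(L, k, s, C, seed = i, project = FALSE)
      x <- array(stats::rnorm(n * n * C), c(n, n, C))
      stride <- sample(1:2, 1)
      expect_lt(max(abs(tiled_conv_forward(x, W, stride) -
                          brute_tiled_conv(x, W, stride))), 1e-10)
    }
  })
})

test_that("tiling follows the distance-k rule (hand-computed 1-D case)", {
  banks <- array(0, c(1, 2, 2, 1))
  banks[1, 1, 1, 1] <- 1; banks[1, 2, 1, 1] <- 2
  W <- tiled_weights(banks, tile_k = 2, rf_s = 1, n_maps = 1)
  expect_equal(as.vector(tiled_conv_forward(c(1, 0, 0, 1), W)),
               c(1, 0, 0, 2))
})

test_that("degenerate cases: zero input, dense reduction, rf too large", {
  W <- init_tiled_weights(2, 2, 3, 1, seed = 3, project = FALSE)
  expect_equal(tiled_conv_forward(array(0, c(6, 6, 1)), W),
               array(0, c(2, 4, 4)))
  # receptive field covering the input = one dense projection per map
  Wd <- init_tiled_weights(3, 2, 5, 1, seed = 4, project = FALSE)
  x <- withr::with_seed(5, array(stats::rnorm(25), c(5, 5, 1)))
  got <- tiled_conv_forward(x, Wd)
  mats <- vapply(1:3, function(l) sum(Wd$banks[l, 1, 1, ] * as.vector(x)),
                 numeric(1))
  expect_equal(as.vector(got), mats, tolerance = 1e-12)
  expect_error(tiled_conv_forward(array(0, c(3, 3, 1)), Wd), "larger")
})

test_that("localize zeroes outside supports and is idempotent", {
  st <- tiled_structure(c(6, 6, 1), rf_s = 3, tile_k = 2, n_maps = 2)
  Wm <- withr::with_seed(6, matrix(stats::rnorm(st$n_units * st$n_inputs),
                                   st$n_units))
  loc <- localize(Wm, st)
  expect_identical(localize(loc, st), loc)
  for (p in c(1, 7, st$n_pos)) {
    r <- st$n_pos + p                      # a map-2 row
    expect_identical(loc[r, st$idx[p, ]], Wm[r, st$idx[p, ]])
    expect_true(all(loc[r, -st$idx[p, ]] == 0))
  }
})

test_that("tie_weights averages tying classes in RF coordinates", {
  # 1-D layout: 2 positions per tying class, rf 1
  st <- tiled_structure(c(4, 1, 1), rf_s = 1, tile_k = 2, n_maps = 1)
  Wm <- matrix(0, 4, 4)
  Wm[1, 1] <- 1; Wm[3, 3] <- 3            # class 1: positions 1 and 3
  Wm[2, 2] <- 5; Wm[4, 4] <- 7            # class 2: positions 2 and 4
  tied <- tie_weights(Wm, st)
  expect_equal(tied[1, 1], 2); expect_equal(tied[3, 3], 2)
  expect_equal(tied[2, 2], 6); expect_equal(tied[4, 4], 6)
  expect_identical(tie_weights(tied, st), tied)
})

test_that("orthogonalize_local_rf performs Loewdin orthonormalization", {
  # diag(2, 3) over a shared full receptive field -> identity
  st <- tiled_structure(c(2, 1, 1), rf_s = 2, tile_k = 1, n_maps = 2)
  got <- orthogonalize_local_rf(diag(c(2, 3)), st)
  expect_equal(got, diag(2), tolerance = 1e-12)
  # fixed point on already-orthonormal rows
  q <- qr.Q(qr(withr::with_seed(10, matrix(stats::rnorm(4), 2))))
  expect_equal(orthogonalize_local_rf(q, st), q, tolerance = 1e-10)
  # bank form: every tile-offset group ends orthonormal
  W <- init_tiled_weights(3, 2, 4, 2, seed = 11, project = FALSE)
  Wo <- orthogonalize_local_rf(W)
  for (cu in 1:2) for (cv in 1:2) {
    G <- matrix(Wo$banks[, cu, cv, ], nrow = 3)
    expect_lt(max(abs(G %*% t(G) - diag(3))), 1e-8)
  }
  # rank-deficient group is rejected with a diagnostic
  Wbad <- W
  Wbad$banks[2, 1, 1, ] <- Wbad$banks[1, 1, 1, ]
  expect_error(orthogonalize_local_rf(Wbad), "rank-deficient")
})

test_that("expanded weights satisfy all structural constraints", {
  st <- tiled_structure(c(8, 8, 1), rf_s = 4, tile_k = 2, n_maps = 2)
  W <- init_tiled_weights(2, 2, 4, 1, seed = 12)
  v <- verify_tiled_structure(W, st)
  expect_equal(v$tying, 0)
  expect_equal(v$locality, 0)
  expect_lt(v$orthonormality, 1e-8)
})

test_that("tica_activation implements the pooled square-root energy", {
  # V = identity, epsilon = 0 -> |W x|
  Wm <- withr::with_seed(13, matrix(stats::rnorm(6), 2, 3))
  x <- c(0.3, -1, 2)
  expect_equal(tica_activation(x, Wm, diag(2), 0), abs(as.vector(Wm %*% x)))
  # hand-computed pooling example
  expect_equal(tica_activation(c(3, 4), diag(2),
                               rbind(c(1, 1), c(0, 1)), 0), c(5, 4))
  # zero input -> sqrt(epsilon) everywhere
  expect_equal(tica_activation(c(0, 0), diag(2), diag(2), 1e-4),
               rep(1e-2, 2))
})

test_that("tica_objective sums pooled activations and is 1-homogeneous", {
  s <- small_tica_setting(21)
  x1 <- s$patches[1, ]
  expect_equal(tica_objective(matrix(x1, 1), s$W, s$V, 1e-8, s$st),
               sum(tica_activation(array(x1, c(8, 8, 1)), s$W, s$V, 1e-8,
                                   stride = 2)))
  f1 <- tica_objective(s$patches, s$W, s$V, 0, s$st)
  f3 <- tica_objective(3 * s$patches, s$W, s$V, 0, s$st)
  expect_equal(f3, 3 * f1, tolerance = 1e-10)
  zero <- matrix(0, 4, 64)
  expect_equal(tica_objective(zero, s$W, s$V, 0, s$st), 0)
  expect_error(tica_objective(matrix(0, 0, 64), s$W, s$V, 1e-8, s$st),
               "empty")
})

test_that("tica_gradient matches central finite differences (banks)", {
  withr::with_seed(30, {
    for (rep in 1:10) {
      s <- small_tica_setting(seed = 100 + rep)
      g <- tica_gradient(s$patches, s$W, s$V, 1e-8, s$st)
      fd <- array(0, dim(s$W$banks))
      h <- 1e-6
      for (i in seq_along(fd)) {
        Wp <- s$W; Wp$banks[i] <- Wp$banks[i] + h
        Wm <- s$W; Wm$banks[i] <- Wm$banks[i] - h
        fd[i] <- (tica_objective(s$patches, Wp, s$V, 1e-8, s$st) -
                    tica_objective(s$patches, Wm, s$V, 1e-8, s$st)) / (2 * h)
      }
      expect_lt(max(abs(fd - g)) / max(abs(g)), 1e-5)
    }
  })
})

test_that("tica_gradient: matrix form, linearity in the batch, guards", {
  Wm <- withr::with_seed(31, matrix(stats::rnorm(8), 2, 4))
  X <- withr::with_seed(32, matrix(stats::rnorm(12), 3, 4))
  V <- rbind(c(1, 1), c(0, 1))
  g <- tica_gradient(X, Wm, V, 1e-8)
  fd <- matrix(0, 2, 4); h <- 1e-6
  for (i in seq_along(fd)) {
    Wp <- Wm; Wp[i] <- Wp[i] + h
    Wn <- Wm; Wn[i] <- Wn[i] - h
    fd[i] <- (tica_objective(X, Wp, V, 1e-8) -
                tica_objective(X, Wn, V, 1e-8)) / (2 * h)
  }
  expect_lt(max(abs(fd - g)) / max(abs(g)), 1e-5)
  # duplicated batch -> exactly doubled gradient; zero batch -> zero
  expect_equal(tica_gradient(rbind(X, X), Wm, V, 1e-8), 2 * g,
               tolerance = 1e-12)
  expect_equal(tica_gradient(matrix(0, 3, 4), Wm, V, 1e-8),
               matrix(0, 2, 4))
  expect_error(tica_gradient(X, Wm, V, 0), "epsilon")
})

test_that("pretrain_tica: projection-only, determinism, descent", {
  s <- small_tica_setting(40)
  # max_outer = 0: structural projection of W0, no descent step
  p0 <- pretrain_tica(s$patches, s$W, s$V,
                      tica_config(max_outer = 0), s$st)
  expect_equal(p0$weights$banks, orthogonalize_local_rf(s$W)$banks,
               tolerance = 1e-12)
  expect_length(p0$trace, 1L)
  # determinism
  cfg <- tica_config(max_outer = 15, seed = 3)
  a <- pretrain_tica(s$patches, NULL, s$V, cfg, s$st)
  b <- pretrain_tica(s$patches, NULL, s$V, cfg, s$st)
  expect_identical(a$weights$banks, b$weights$banks)
  # strict descent and structural constraints at every accepted step
  expect_true(all(diff(a$trace) < 0))
  expect_true(all(a$violations$tying <= 1e-6))
  expect_true(all(a$violations$locality == 0))
  expect_true(all(a$violations$orthonormality <= 1e-8))
  expect_error(pretrain_tica(matrix(0, 0, 64), NULL, s$V, cfg, s$st),
               "empty")
})

test_that("pooling topology is a fixed 0/1 neighborhood with wrap-around", {
  st <- tiled_structure(c(8, 8, 1), rf_s = 4, tile_k = 2, n_maps = 2,
                        stride = 2)
  V <- pooling_topology(st, radius = 1)
  expect_true(all(V %in% c(0, 1)))
  expect_true(all(rowSums(V) >= 1))
  expect_equal(dim(V), c(st$n_units, st$n_units))
  # interior pooled unit sums a 3x3 same-map neighborhood
  expect_true(all(rowSums(V) == 9))
  # no cross-map pooling
  m1 <- seq_len(st$n_pos); m2 <- st$n_pos + m1
  expect_true(all(V[m1, m2] == 0) && all(V[m2, m1] == 0))
  # 1-D grids degrade to 3-neighbor pooling
  st1 <- tiled_structure(c(6, 1, 1), rf_s = 1, tile_k = 2, n_maps = 1)
  expect_true(all(rowSums(pooling_topology(st1)) == 3))
})

test_that("sample_gaf_patches cuts reproducible in-range patches", {
  gs <- make_separable_gaf(4, side = 16)
  P <- sample_gaf_patches(gs, 10, 8, seed = 5)
  expect_equal(dim(P), c(10L, 8 * 8 * 3))
  expect_true(all(P >= -1 - 1e-12 & P <= 1 + 1e-12))
  expect_identical(P, sample_gaf_patches(gs, 10, 8, seed = 5))
  expect_error(sample_gaf_patches(gs, 5, 32, seed = 1), "exceeds")
})
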