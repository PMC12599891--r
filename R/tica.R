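#' Tiled convolution structure (geometry)
#'
#' Describes how a bank of localized filters is laid over an input tensor:
#' receptive fields of side `rf_s` placed on a stride grid, `n_maps` feature
#' maps, and weight tying with period `tile_k` (two output units of the same
#' map whose grid offsets are congruent modulo `tile_k` share one filter;
#' nearer units are untied). The structure carries the per-position support
#' index matrix used to expand, localize and verify weight matrices.
#'
#' @param input_dim integer vector `c(h, w, channels)` (a length-1 or -2
#'   value is promoted: `n` -> `c(n, 1, 1)`, `c(h, w)` -> `c(h, w, 1)`).
#' @param rf_s receptive-field side (>= 1, <= input sides where > 1).
#' @param tile_k tying period (>= 1).
#' @param n_maps number of feature maps (>= 1).
#' @param stride grid stride (>= 1).
#' @return object of class `tiled_structure`.
#' @export
tiled_structure <- function(input_dim, rf_s, tile_k, n_maps, stride = 1L) {
  input_dim <- as.integer(input_dim)
  if (length(input_dim) == 1L) input_dim <- c(input_dim, 1L, 1L)
  if (length(input_dim) == 2L) input_dim <- c(input_dim, 1L)
  h <- input_dim[1]; w <- input_dim[2]; C <- input_dim[3]
  rf_s <- as.integer(rf_s); tile_k <- as.integer(tile_k)
  n_maps <- as.integer(n_maps); stride <- as.integer(stride)
  rf_w <- min(rf_s, w)   # RF never exceeds a singleton dimension
  rf_h <- rf_s
  if (rf_h > h || rf_w > w)
    stop("receptive field larger than input (rf_s = ", rf_s, ")")
  us <- seq(1L, h - rf_h + 1L, by = stride)
  vs <- seq(1L, w - rf_w + 1L, by = stride)
  oh <- length(us); ow <- length(vs)
  n_pos <- oh * ow
  # support offsets, column-major over (du, dv, ch)
  off <- as.vector(outer(0:(rf_h - 1L),
                         as.vector(outer((0:(rf_w - 1L)) * h,
                                         (seq_len(C) - 1L) * h * w, "+")),
                         "+"))
  ssc <- length(off)                       # rf_h * rf_w * C
  pos_u <- rep(us, times = ow); pos_v <- rep(vs, each = oh)
  base <- pos_u + (pos_v - 1L) * h
  idx <- outer(base, off, "+")             # [n_pos, ssc]
  gu <- rep(seq_len(oh), times = ow); gv <- rep(seq_len(ow), each = oh)
  class_id <- ((gu - 1L) %% tile_k) * tile_k + ((gv - 1L) %% tile_k) + 1L
  structure(list(in_h = h, in_w = w, channels = C,
                 rf_s = rf_s, rf_h = rf_h, rf_w = rf_w,
                 tile_k = tile_k, n_maps = n_maps, stride = stride,
                 out_h = oh, out_w = ow, n_pos = n_pos, ssc = ssc,
                 n_inputs = h * w * C, n_units = n_maps * n_pos,
                 idx = idx, class_id = class_id,
                 n_classes = tile_k * tile_k),
            class = "tiled_structure")
}

#' @export
print.tiled_structure <- function(x, ...) {
  cat(sprintf(paste0("<tiled_structure> input %dx%dx%d, rf %d, tile %d, ",
                     "%d maps, stride %d -> grid %dx%d (%d units)\n"),
              x$in_h, x$in_w, x$channels, x$rf_s, x$tile_k, x$n_maps,
              x$stride, x$out_h, x$out_w, x$n_units))
  invisible(x)
}

#' First-layer tiled weight bank
#'
#' Holds the free parameters of a tiled convolutional layer: one filter of
#' `rf_s * rf_s * channels` coefficients per (map, tile offset). The banks
#' are independent of the input size, so filters pretrained on small patches
#' initialize convolution over full images.
#'
#' @param banks numeric array `[n_maps, tile_k, tile_k, ssc]`.
#' @param tile_k,rf_s,n_maps,channels structure parameters.
#' @return object of class `tiled_weights`.
#' @export
tiled_weights <- function(banks, tile_k, rf_s, n_maps, channels = 1L) {
  stopifnot(is.array(banks), length(dim(banks)) == 4L)
  structure(list(banks = banks, tile_k = as.integer(tile_k),
                 rf_s = as.integer(rf_s), n_maps = as.integer(n_maps),
                 channels = as.integer(channels)),
            class = "tiled_weights")
}

#' Random tiled weights
#'
#' Standard-normal initialization followed by the structural projection
#' (local Loewdin orthonormalization of each tile-offset group), so the
#' returned banks already satisfy tying, locality and local orthonormality.
#'
#' @param n_maps,tile_k,rf_s,channels layer shape.
#' @param seed integer seed.
#' @param ssc optional override of the per-filter coefficient count (used
#'   for degenerate 1-D receptive fields); default `rf_s^2 * channels`.
#' @param project apply the orthonormalization projection (default TRUE).
#' @return a `tiled_weights` object.
#' @export
init_tiled_weights <- function(n_maps, tile_k, rf_s, channels = 1L,
                               seed = 1L, ssc = NULL, project = TRUE) {
  ssc <- ssc %||% (rf_s * rf_s * channels)
  banks <- withr::with_seed(as.integer(seed),
    array(stats::rnorm(n_maps * tile_k * tile_k * ssc),
          c(n_maps, tile_k, tile_k, ssc)))
  W <- tiled_weights(banks, tile_k, rf_s, n_maps, channels)
  if (project) W <- orthogonalize_local_rf(W)
  W
}

# banks as a [n_maps*tile_k^2, ssc] matrix, row (l, class c) = (l-1)*k^2 + c
.banks_matrix <- function(W) {
  d <- dim(W$banks); L <- d[1]; k <- d[2]; ssc <- d[4]
  out <- matrix(0, L * k * k, ssc)
  for (l in seq_len(L)) for (cu in seq_len(k)) for (cv in seq_len(k))
    out[(l - 1L) * k * k + (cu - 1L) * k + cv, ] <- W$banks[l, cu, cv, ]
  out
}

.matrix_to_banks <- function(M, W) {
  d <- dim(W$banks); L <- d[1]; k <- d[2]
  for (l in seq_len(L)) for (cu in seq_len(k)) for (cv in seq_len(k))
    W$banks[l, cu, cv, ] <- M[(l - 1L) * k * k + (cu - 1L) * k + cv, ]
  W
}

#' Tiled convolution forward pass
#'
#' Every output unit at grid offset `(u, v)` of map `l` computes the dot
#' product of its receptive-field patch with
#' `banks[l, u mod k, v mod k]`; there is no bias term. With `tile_k = 1`
#' this is a standard convolution; with a receptive field covering the input
#' it reduces to a dense projection.
#'
#' @param input numeric array `[h, w, channels]` (vector/matrix promoted).
#' @param W a `tiled_weights`.
#' @param stride grid stride.
#' @return array `[n_maps, out_h, out_w]` of feature maps.
#' @export
tiled_conv_forward <- function(input, W, stride = 1L) {
  stopifnot(inherits(W, "tiled_weights"))
  dm <- dim(input) %||% length(input)
  st <- tiled_structure(dm, W$rf_s, W$tile_k, W$n_maps, stride)
  x <- as.vector(input)
  P <- matrix(x[st$idx], st$n_pos, st$ssc)
  Z <- P %*% t(.banks_matrix(W))           # [n_pos, L*k^2]
  k2 <- st$n_classes
  out <- array(0, c(st$n_maps, st$out_h, st$out_w))
  for (l in seq_len(st$n_maps)) {
    cols <- (l - 1L) * k2 + st$class_id
    out[l, , ] <- Z[cbind(seq_len(st$n_pos), cols)]
  }
  out
}

#' Expand a tiled weight bank to the full weight matrix
#'
#' Row `unit = (l-1)*n_pos + pos` of the result is the effective weight
#' vector of that unit over the flattened input: its bank filter scattered
#' onto its receptive-field support, zero elsewhere.
#'
#' @param W a `tiled_weights`.
#' @param st a [tiled_structure()] compatible with `W`.
#' @return `[n_units, n_inputs]` matrix.
#' @export
expand_tiled_weights <- function(W, st) {
  M <- matrix(0, st$n_units, st$n_inputs)
  k2 <- st$n_classes
  B <- .banks_matrix(W)
  for (l in seq_len(st$n_maps)) for (p in seq_len(st$n_pos)) {
    M[(l - 1L) * st$n_pos + p, st$idx[p, ]] <- B[(l - 1L) * k2 +
                                                   st$class_id[p], ]
  }
  M
}

#' Localize a weight matrix
#'
#' Sets every entry outside a unit's receptive-field support to exactly 0;
#' entries inside the support are untouched. Idempotent.
#'
#' @param W `[n_units, n_inputs]` matrix (or a `tiled_weights`, returned
#'   unchanged: bank parametrization is local by construction).
#' @param st a [tiled_structure()].
#' @return matrix of the same shape.
#' @export
localize <- function(W, st) {
  if (inherits(W, "tiled_weights")) return(W)
  out <- matrix(0, nrow(W), ncol(W))
  for (l in seq_len(st$n_maps)) for (p in seq_len(st$n_pos)) {
    r <- (l - 1L) * st$n_pos + p
    out[r, st$idx[p, ]] <- W[r, st$idx[p, ]]
  }
  out
}

#' Tie weights across tile-congruent units
#'
#' Within each tying class (map `l`, grid offsets congruent modulo
#' `tile_k`), every member row is replaced by the arithmetic mean of the
#' class, taken in receptive-field-local coordinates. The result satisfies
#' the tying invariant exactly.
#'
#' @param W `[n_units, n_inputs]` matrix (or `tiled_weights`, returned
#'   unchanged).
#' @param st a [tiled_structure()].
#' @return matrix of the same shape.
#' @export
tie_weights <- function(W, st) {
  if (inherits(W, "tiled_weights")) return(W)
  out <- W
  for (l in seq_len(st$n_maps)) for (c in seq_len(st$n_classes)) {
    ps <- which(st$class_id == c)
    if (length(ps) == 0L) next
    rows <- (l - 1L) * st$n_pos + ps
    loc <- matrix(vapply(seq_along(ps),
                         function(i) W[rows[i], st$idx[ps[i], ]],
                         numeric(st$ssc)),
                  nrow = st$ssc)            # [ssc, n_members]
    m <- rowMeans(loc)
    for (i in seq_along(ps)) out[rows[i], st$idx[ps[i], ]] <- m
  }
  out
}

# Loewdin (symmetric) orthonormalization of the rows of G.
.loewdin <- function(G, group_name = "group") {
  E <- G %*% t(G)
  ee <- eigen(E, symmetric = TRUE)
  if (any(ee$values < 1e-12 * max(ee$values, 1)))
    stop("rank-deficient receptive-field group: ", group_name)
  (ee$vectors %*% (t(ee$vectors) / sqrt(ee$values))) %*% G
}

#' Orthonormalize weights within local receptive-field groups
#'
#' A local group is the set of `n_maps` units sharing one receptive field
#' (same grid position across maps); their filters are made orthonormal by
#' the symmetric (Loewdin) transform `(G G^T)^(-1/2) G`. Applied to a
#' `tiled_weights` bank this runs per tile offset; applied to an expanded
#' matrix it runs per grid position (all positions of one tile class
#' receive the identical transform, so exact tying is preserved).
#'
#' @param W a `tiled_weights` or an expanded `[n_units, n_inputs]` matrix.
#' @param st a [tiled_structure()]; required for the matrix form.
#' @return same type as `W`, with `G G^T = I` within each group.
#' @export
orthogonalize_local_rf <- function(W, st = NULL) {
  if (inherits(W, "tiled_weights")) {
    d <- dim(W$banks); L <- d[1]; k <- d[2]
    for (cu in seq_len(k)) for (cv in seq_len(k)) {
      G <- matrix(W$banks[, cu, cv, ], nrow = L)
      W$banks[, cu, cv, ] <- .loewdin(G, sprintf("tile offset (%d,%d)",
                                                 cu, cv))
    }
    return(W)
  }
  stopifnot(!is.null(st))
  out <- W
  for (p in seq_len(st$n_pos)) {
    rows <- (seq_len(st$n_maps) - 1L) * st$n_pos + p
    G <- W[rows, st$idx[p, ], drop = FALSE]
    out[rows, st$idx[p, ]] <- .loewdin(G, sprintf("position %d", p))
  }
  out
}

#' Verify tying, locality and local orthonormality
#'
#' @param W a `tiled_weights`.
#' @param st a [tiled_structure()].
#' @return list with `tying`, `locality`, `orthonormality`: the maximum
#'   absolute violation of each structural constraint in the expanded
#'   weight matrix.
#' @export
verify_tiled_structure <- function(W, st) {
  M <- expand_tiled_weights(W, st)
  tying <- 0; locality <- 0; orth <- 0
  outside <- matrix(TRUE, st$n_units, st$n_inputs)
  for (l in seq_len(st$n_maps)) for (p in seq_len(st$n_pos))
    outside[(l - 1L) * st$n_pos + p, st$idx[p, ]] <- FALSE
  locality <- max(abs(M[outside]), 0)
  for (l in seq_len(st$n_maps)) for (c in seq_len(st$n_classes)) {
    ps <- which(st$class_id == c)
    if (length(ps) < 2L) next
    loc <- vapply(seq_along(ps),
                  function(i) M[(l - 1L) * st$n_pos + ps[i],
                                st$idx[ps[i], ]],
                  numeric(st$ssc))
    tying <- max(tying, max(abs(loc - loc[, 1])))
  }
  for (p in seq_len(st$n_pos)) {
    rows <- (seq_len(st$n_maps) - 1L) * st$n_pos + p
    G <- M[rows, st$idx[p, ], drop = FALSE]
    orth <- max(orth, max(abs(G %*% t(G) - diag(st$n_maps))))
  }
  list(tying = tying, locality = locality, orthonormality = orth)
}

#' Pooling topology
#'
#' The fixed nonnegative 0/1 matrix `V` mapping simple (first-layer) units
#' to pooled TICA units: one pooled unit per simple unit, summing the
#' squared responses of the spatial neighborhood of radius `radius` within
#' the same feature map, with wrap-around at the grid borders. Degenerates
#' to a 3-neighbor 1-D topology on 1-D grids. `V` is never updated by
#' learning.
#'
#' @param st a [tiled_structure()].
#' @param radius neighborhood radius (default 1).
#' @return `[n_units, n_units]` 0/1 matrix of class `pooling_topology`.
#' @export
pooling_topology <- function(st, radius = 1L) {
  oh <- st$out_h; ow <- st$out_w; np <- st$n_pos; L <- st$n_maps
  dus <- -radius:radius
  dvs <- if (ow == 1L) 0L else -radius:radius
  if (oh == 1L) dus <- 0L
  V <- matrix(0, L * np, L * np)
  for (p in seq_len(np)) {
    u <- (p - 1L) %% oh; v <- (p - 1L) %/% oh
    nb <- unique(as.vector(outer((u + dus) %% oh,
                                 ((v + dvs) %% ow) * oh, "+"))) + 1L
    for (l in seq_len(L)) {
      base <- (l - 1L) * np
      V[base + p, base + nb] <- 1
    }
  }
  structure(V, class = c("pooling_topology", "matrix", "array"),
            radius = radius, layout = c(L, oh, ow))
}

# ---- batched simple-unit responses -----------------------------------------

# Patch-position design matrix: PM[(t-1)*n_pos + p, j] = value of patch t at
# support coordinate j of position p. Built once per batch; every objective,
# gradient and forward evaluation is then a single matrix product.
.build_pm <- function(patches, st) {
  T <- nrow(patches)
  PM <- matrix(0, T * st$n_pos, st$ssc)
  for (j in seq_len(st$ssc))
    PM[, j] <- as.vector(t(patches[, st$idx[, j], drop = FALSE]))
  PM
}

# Z[t, unit] with unit = (l-1)*n_pos + pos; accepts a prebuilt PM cache.
.simple_responses <- function(patches, W, st, pm = NULL) {
  T <- if (is.null(pm)) nrow(patches) else nrow(pm) / st$n_pos
  PM <- pm %||% .build_pm(patches, st)
  ZB <- PM %*% t(.banks_matrix(W))
  k2 <- st$n_classes
  Z <- matrix(0, T, st$n_units)
  nr <- nrow(ZB)
  for (l in seq_len(st$n_maps)) {
    colv <- rep((l - 1L) * k2 + st$class_id, times = T)
    vals <- ZB[seq_len(nr) + (colv - 1L) * nr]
    Z[, (l - 1L) * st$n_pos + seq_len(st$n_pos)] <-
      t(matrix(vals, st$n_pos, T))
  }
  Z
}

.as_patch_matrix <- function(patches) {
  if (is.matrix(patches)) return(patches)
  if (is.list(patches))
    return(do.call(rbind, lapply(patches, as.vector)))
  matrix(as.vector(patches), nrow = 1)
}

# ---- TICA objective / gradient ---------------------------------------------

#' Pooled TICA activation for one input pattern
#'
#' `p_i = sqrt(epsilon + sum_k V[i,k] * z_k^2)` where `z` are the
#' first-layer simple-unit responses: `W %*% x` for a plain weight matrix,
#' or the flattened tiled convolution output for a `tiled_weights`.
#'
#' @param x input pattern (vector or array).
#' @param W weight matrix `[m, n]` or `tiled_weights`.
#' @param V pooling matrix `[M, m]`.
#' @param epsilon smoothing constant inside the square root (>= 0).
#' @param stride grid stride for the tiled form.
#' @return nonnegative numeric vector of length `M`.
#' @export
tica_activation <- function(x, W, V, epsilon = 1e-8, stride = 1L) {
  z <- if (inherits(W, "tiled_weights")) {
    out <- tiled_conv_forward(x, W, stride)
    as.vector(aperm(out, c(2, 3, 1)))      # unit order (l-1)*n_pos + pos
  } else as.vector(W %*% as.vector(x))
  sqrt(epsilon + as.vector(V %*% z^2))
}

# unit-order flattening helper for [L, oh, ow] maps
.flatten_units <- function(maps) as.vector(aperm(maps, c(2, 3, 1)))

#' TICA objective over a batch
#'
#' `f = sum_t sum_i p_i(x_t; W, V)`: the summed square-root pooled energies
#' of every pattern in the batch. With `epsilon = 0` this is positively
#' homogeneous of degree 1 in the input scale. Minimizing it under the
#' local orthonormality constraint spreads the filters into independent,
#' topographically pooled components.
#'
#' @param patches batch: matrix `[T, n_inputs]`, list of arrays, or single
#'   array.
#' @param W weight matrix or `tiled_weights`.
#' @param V pooling matrix.
#' @param epsilon smoothing constant.
#' @param st [tiled_structure()]; required when `W` is a `tiled_weights`.
#' @param pm optional cached design matrix from the internal builder.
#' @return scalar objective value.
#' @export
tica_objective <- function(patches, W, V, epsilon = 1e-8, st = NULL,
                           pm = NULL) {
  patches <- if (is.null(pm)) .as_patch_matrix(patches) else patches
  if (!is.null(pm) || is.matrix(patches)) {
    if ((is.null(pm) && nrow(patches) == 0L)) stop("empty batch")
  }
  Z <- if (inherits(W, "tiled_weights")) {
    stopifnot(!is.null(st))
    .simple_responses(patches, W, st, pm)
  } else patches %*% t(W)
  if (nrow(Z) == 0L) stop("empty batch")
  sum(sqrt(epsilon + Z^2 %*% t(V)))
}

#' Gradient of the TICA objective
#'
#' Exact gradient of [tica_objective()] with respect to the free
#' parameters: the full matrix `W` for the plain form, or the untied bank
#' parameters for the tiled form (the chain rule sums the gradients of all
#' tied copies into their shared bank; `reduce = "mean"` instead averages
#' them, which equals the Algorithm-of-record composition
#' `tie_weights(localize(dW))` used during pretraining).
#'
#' @param patches batch (matrix `[T, n_inputs]` or list of arrays).
#' @param W weight matrix or `tiled_weights`.
#' @param V pooling matrix.
#' @param epsilon smoothing constant, must be > 0 (differentiability).
#' @param st [tiled_structure()] for the tiled form.
#' @param reduce `"sum"` (true gradient) or `"mean"` over tied copies.
#' @param pm optional cached design matrix.
#' @return matrix like `W` (plain form) or bank array like `W$banks`.
#' @export
tica_gradient <- function(patches, W, V, epsilon = 1e-8, st = NULL,
                          reduce = c("sum", "mean"), pm = NULL) {
  reduce <- match.arg(reduce)
  if (!(epsilon > 0))
    stop("epsilon must be > 0 for gradient computation")
  patches <- if (is.null(pm)) .as_patch_matrix(patches) else patches
  if (inherits(W, "tiled_weights")) {
    stopifnot(!is.null(st))
    PM <- pm %||% .build_pm(patches, st)
    Z <- .simple_responses(patches, W, st, PM)
    dZ <- .tica_dZ(Z, V, epsilon)
    T <- nrow(dZ)
    G <- array(0, dim(W$banks))
    class_rep <- rep(st$class_id, times = T)
    k <- st$tile_k
    for (l in seq_len(st$n_maps)) {
      dZl <- dZ[, (l - 1L) * st$n_pos + seq_len(st$n_pos), drop = FALSE]
      v <- as.vector(t(dZl))               # aligned with PM rows
      for (c in seq_len(st$n_classes)) {
        rows <- which(class_rep == c)
        if (length(rows) == 0L) next
        g <- crossprod(PM[rows, , drop = FALSE], v[rows])
        if (reduce == "mean") g <- g / sum(st$class_id == c)
        cu <- (c - 1L) %/% k + 1L; cv <- (c - 1L) %% k + 1L
        G[l, cu, cv, ] <- g
      }
    }
    G
  } else {
    Z <- patches %*% t(W)
    dZ <- .tica_dZ(Z, V, epsilon)
    t(dZ) %*% patches
  }
}

# d f / d Z for f = sum sqrt(epsilon + Z^2 V^T)
.tica_dZ <- function(Z, V, epsilon) {
  P2 <- Z^2 %*% t(V)
  2 * Z * ((0.5 / sqrt(epsilon + P2)) %*% V)
}

#' Line-search configuration for TICA pretraining
#'
#' @param epsilon square-root smoothing constant (> 0).
#' @param alpha0 initial line-search step (the descent starts at step 1).
#' @param alpha_decay step halving factor, in (0, 1).
#' @param max_inner maximum step halvings per outer iteration; an exhausted
#'   inner search is treated as convergence.
#' @param max_outer maximum outer (gradient) iterations.
#' @param tol relative objective decrease below which the outer loop stops.
#' @param seed integer seed (used when weights are initialized internally).
#' @return object of class `tica_config`.
#' @export
tica_config <- function(epsilon = 1e-8, alpha0 = 1, alpha_decay = 0.5,
                        max_inner = 30L, max_outer = 100L, tol = 1e-4,
                        seed = 1L) {
  if (!(alpha_decay > 0 && alpha_decay < 1))
    stop("alpha_decay must be in (0, 1)")
  if (!(tol > 0)) stop("tol must be > 0")
  structure(list(epsilon = epsilon, alpha0 = alpha0,
                 alpha_decay = alpha_decay,
                 max_inner = as.integer(max_inner),
                 max_outer = as.integer(max_outer), tol = tol,
                 seed = as.integer(seed)),
            class = "tica_config")
}

#' Unsupervised TICA pretraining of a tiled weight bank (line search)
#'
#' Projected gradient descent on the TICA objective over an unlabeled patch
#' batch. Each outer iteration computes the objective and its gradient,
#' then proposes `W - alpha * g` with `alpha` starting at `alpha0` and
#' halving until the structurally projected candidate (localize, tie
#' weights, orthonormalize local receptive-field groups, applied in that
#' order) strictly improves the objective. The outer loop stops on relative
#' decrease below `config$tol`, after `config$max_outer` iterations, or
#' when an inner search exhausts `config$max_inner` halvings without
#' improvement (treated as convergence). With `max_outer = 0` the
#' structural projection of `W0` is returned without any descent step.
#'
#' @param patches unlabeled patch batch: matrix `[T, n_inputs]` or list of
#'   arrays (typically patches cut from sober-class GAF images).
#' @param W0 initial `tiled_weights` (or `NULL` to initialize from
#'   `config$seed`).
#' @param V pooling matrix from [pooling_topology()] (or `NULL` for the
#'   default radius-1 topology).
#' @param config a [tica_config()].
#' @param st the [tiled_structure()] describing the patch geometry.
#' @param verify record structural violations after every accepted step
#'   (costs one weight expansion per step).
#' @return list with `weights` (trained `tiled_weights`), `trace` (objective
#'   after projection of `W0` and after every accepted step; strictly
#'   decreasing), `converged`, `n_outer`, `violations` (data.frame, one row
#'   per accepted step, when `verify`).
#' @export
pretrain_tica <- function(patches, W0 = NULL, V = NULL,
                          config = tica_config(), st, verify = TRUE) {
  stopifnot(inherits(st, "tiled_structure"))
  patches <- .as_patch_matrix(patches)
  if (nrow(patches) == 0L) stop("empty patch batch")
  if (ncol(patches) != st$n_inputs)
    stop("patch width ", ncol(patches), " != structure n_inputs ",
         st$n_inputs)
  V <- V %||% pooling_topology(st)
  W <- W0 %||% init_tiled_weights(st$n_maps, st$tile_k, st$rf_s,
                                  st$channels, seed = config$seed,
                                  ssc = st$ssc, project = FALSE)
  W <- orthogonalize_local_rf(W)           # project the start point
  PM <- .build_pm(patches, st)
  f_old <- tica_objective(patches, W, V, config$epsilon, st, pm = PM)
  trace <- f_old
  viol <- list()
  converged <- FALSE
  n_outer <- 0L
  while (n_outer < config$max_outer) {
    n_outer <- n_outer + 1L
    g <- tica_gradient(patches, W, V, config$epsilon, st,
                       reduce = "mean", pm = PM)
    alpha <- config$alpha0
    accepted <- FALSE
    for (inner in seq_len(config$max_inner)) {
      cand <- W
      cand$banks <- W$banks - alpha * g
      cand <- orthogonalize_local_rf(cand)  # localize+tie are structural
      f_new <- tica_objective(patches, cand, V, config$epsilon, st,
                              pm = PM)
      if (f_new < f_old) { accepted <- TRUE; break }
      alpha <- alpha * config$alpha_decay
    }
    if (!accepted) {                        # exhausted line search
      converged <- TRUE
      message("pretrain_tica: inner line search exhausted after ",
              n_outer, " outer iterations; treating as convergence")
      break
    }
    W <- cand
    trace <- c(trace, f_new)
    if (verify)
      viol[[length(viol) + 1L]] <- verify_tiled_structure(W, st)
    if ((f_old - f_new) / abs(f_old) < config$tol) {
      converged <- TRUE
      f_old <- f_new
      break
    }
    f_old <- f_new
  }
  list(weights = W, trace = trace, converged = converged,
       n_outer = n_outer,
       violations = if (length(viol))
         do.call(rbind, lapply(viol, as.data.frame)) else NULL)
}

#' Cut square patches from a set of GAF images
#'
#' Uniformly samples `n_patches` patches of side `patch_side` (all
#' channels) from random images and positions; used to build the
#' unsupervised pretraining batch from sober-class images.
#'
#' @param gs a `gaf_set`.
#' @param n_patches number of patches.
#' @param patch_side patch side length.
#' @param seed integer seed.
#' @return matrix `[n_patches, patch_side^2 * channels]`.
#' @export
sample_gaf_patches <- function(gs, n_patches, patch_side, seed = 1L) {
  stopifnot(length(gs$images) > 0L)
  side <- dim(gs$images[[1]])[1]
  C <- dim(gs$images[[1]])[3]
  if (patch_side > side) stop("patch_side exceeds image side")
  withr::with_seed(as.integer(seed), {
    out <- matrix(0, n_patches, patch_side^2 * C)
    for (i in seq_len(n_patches)) {
      im <- gs$images[[sample.int(length(gs$images), 1L)]]
      u <- sample.int(side - patch_side + 1L, 1L)
      v <- sample.int(side - patch_side + 1L, 1L)
      out[i, ] <- as.vector(im[u:(u + patch_side - 1L),
                               v:(v + patch_side - 1L), , drop = FALSE])
    }
    out
  })
}
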