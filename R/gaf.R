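#' Rescale a sequence to [-1, 1]
#'
#' Min-max rescaling `2*(x - min)/(max - min) - 1`; the minimum maps to -1
#' and the maximum to 1. This is the prerequisite of the angular encoding
#' (values must lie in the domain of arccos).
#'
#' @param x numeric vector with `max(x) > min(x)`.
#' @return numeric vector in `[-1, 1]`.
#' @export
rescale_unit <- function(x) {
  rng <- range(x)
  if (!(rng[2] > rng[1]))
    stop("degenerate cycle: constant sequence cannot be rescaled")
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Gramian angular field of a rescaled sequence
#'
#' Maps the rescaled series to polar angles `phi_i = arccos(x_i)` and forms
#' the summation field `G_ij = cos(phi_i + phi_j)`, computed in the
#' equivalent algebraic form
#' `x_i x_j - sqrt(1 - x_i^2) sqrt(1 - x_j^2)`, which is exactly symmetric
#' with diagonal `2 x_i^2 - 1`. With `method = "gadf"` the difference field
#' `sin(phi_i - phi_j)` is returned instead (antisymmetric).
#'
#' @param x numeric vector with all `|x_i| <= 1` (values within `1e-12` of
#'   the bound are clamped; larger excursions are an error).
#' @param method `"gasf"` (default, summation) or `"gadf"` (difference).
#' @return n x n matrix with entries in `[-1, 1]`.
#' @export
gasf_encode <- function(x, method = c("gasf", "gadf")) {
  method <- match.arg(method)
  if (any(abs(x) > 1 + 1e-12))
    stop("input to gasf_encode must lie in [-1, 1]")
  x <- pmin(1, pmax(-1, x))
  s <- sqrt(pmax(0, 1 - x^2))
  if (method == "gasf") outer(x, x) - outer(s, s)
  else outer(s, x) - outer(x, s)
}

#' Piecewise aggregate approximation
#'
#' Reduces a series to `out_len` values by averaging over `out_len` equal
#' contiguous bins (used to encode desk-scale images from long cycles).
#'
#' @param x numeric vector, `length(x) >= out_len`.
#' @param out_len output length.
#' @return numeric vector of length `out_len`.
#' @export
paa <- function(x, out_len) {
  n <- length(x)
  if (out_len > n) stop("out_len must not exceed length(x)")
  if (out_len == n) return(x)
  bins <- ceiling(seq_len(n) / (n / out_len))
  as.numeric(tapply(x, bins, mean))
}

#' Encode one gait cycle as a GAF image
#'
#' Each axis of the cycle window is independently min-max rescaled to
#' `[-1, 1]` and angular-encoded; the per-axis fields are stacked as
#' channels in fixed axis order (x, y, z). The image side equals the cycle's
#' resample length (optionally reduced by [paa()] first). A constant axis
#' cannot be rescaled: the cycle is skipped with a warning and `NULL` is
#' returned so that batch encoding can continue.
#'
#' @param cycle a `gait_cycle` (see [validate_cycles()]).
#' @param paa_len optional piecewise-aggregate length applied per axis
#'   before encoding.
#' @param method `"gasf"` or `"gadf"`.
#' @return a `gaf_image` (list with `pixels` n x n x 3 array,
#'   `channel_axes`, `source_cycle_id`, `label`, `subject_id`), or `NULL`
#'   for a degenerate cycle.
#' @export
encode_cycle <- function(cycle, paa_len = NULL, method = "gasf") {
  stopifnot(inherits(cycle, "gait_cycle"))
  win <- cycle$window
  if (!is.null(paa_len))
    win <- t(apply(win, 1, paa, out_len = paa_len))
  n <- ncol(win)
  px <- array(NA_real_, c(n, n, nrow(win)))
  for (a in seq_len(nrow(win))) {
    xr <- tryCatch(rescale_unit(win[a, ]), error = function(e) NULL)
    if (is.null(xr)) {
      warning("degenerate cycle skipped: constant axis ", a, " in ",
              cycle$cycle_id)
      return(NULL)
    }
    px[, , a] <- gasf_encode(xr, method)
  }
  structure(list(pixels = px,
                 channel_axes = rownames(win) %||% c("x", "y", "z"),
                 source_cycle_id = cycle$cycle_id,
                 label = cycle$label,
                 subject_id = cycle$subject_id),
            class = "gaf_image")
}

#' Encode a cycle set as a GAF image set
#'
#' @param cs a `cycle_set` or plain list of `gait_cycle`.
#' @param paa_len,method passed to [encode_cycle()].
#' @return a `gaf_set`: list with `images` (list of n x n x 3 arrays),
#'   `labels`, `subject_ids`, `cycle_ids`, `side`.
#' @export
encode_cycles <- function(cs, paa_len = NULL, method = "gasf") {
  cycles <- if (inherits(cs, "cycle_set")) cs$cycles else cs
  imgs <- list(); labs <- character(0); subs <- character(0)
  ids <- character(0)
  for (cyc in cycles) {
    gi <- encode_cycle(cyc, paa_len, method)
    if (is.null(gi)) next
    imgs[[length(imgs) + 1L]] <- gi$pixels
    labs <- c(labs, gi$label); subs <- c(subs, gi$subject_id)
    ids <- c(ids, gi$source_cycle_id)
  }
  structure(list(images = imgs, labels = labs, subject_ids = subs,
                 cycle_ids = ids,
                 side = if (length(imgs)) dim(imgs[[1]])[1] else NA_integer_),
            class = "gaf_set")
}

#' @export
print.gaf_set <- function(x, ...) {
  cat(sprintf("<gaf_set> %d images, side %s: %s\n", length(x$images),
              x$side,
              paste(sprintf("%s=%d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Subset a gaf_set
#'
#' @param gs a `gaf_set`.
#' @param idx integer or logical index.
#' @return a `gaf_set` with the selected images.
#' @export
gaf_subset <- function(gs, idx) {
  structure(list(images = gs$images[idx], labels = gs$labels[idx],
                 subject_ids = gs$subject_ids[idx],
                 cycle_ids = gs$cycle_ids[idx], side = gs$side),
            class = "gaf_set")
}

#' Export a GAF image as an 8-bit PNG (visualization only)
#'
#' Quantizes each channel from `[-1, 1]` to `[0, 255]`. The learning
#' pipeline always consumes the float tensors; PNG export exists purely for
#' inspection and is lossy by construction.
#'
#' @param img a `gaf_image` or n x n x 3 array.
#' @param path output file path.
#' @return invisibly, `path` (or `NULL` if no PNG device is available).
#' @export
write_gaf_png <- function(img, path) {
  px <- if (inherits(img, "gaf_image")) img$pixels else img
  rgb01 <- (pmin(1, pmax(-1, px)) + 1) / 2
  ok <- tryCatch({
    grDevices::png(path, width = dim(px)[1], height = dim(px)[2])
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new(); graphics::plot.window(0:1, 0:1)
    graphics::rasterImage(rgb01, 0, 0, 1, 1, interpolate = FALSE)
    TRUE
  }, error = function(e) FALSE)
  invisible(if (ok) path else NULL)
}
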