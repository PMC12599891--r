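# Shared fixtures: everything is generated in code at test time.

# class presets with all generator knobs identical (labels differ only);
# used by the null-information control
null_presets <- function() {
  base <- class_presets()$sober
  lapply(c(sober = "sober", alcohol = "alcohol", marijuana = "marijuana"),
         function(l) gait_class_params(
           l, step_rate_hz = base$step_rate_hz,
           stride_time_cv = base$stride_time_cv, sway_amp = base$sway_amp,
           harmonic_weights = base$harmonic_weights,
           noise_sd = base$noise_sd))
}

# brute-force tiled convolution oracle (independent of the implementation)
brute_tiled_conv <- function(input, W, stride = 1L) {
  d <- dim(input); s <- W$rf_s; k <- W$tile_k
  us <- seq(1L, d[1] - s + 1L, by = stride)
  vs <- seq(1L, d[2] - s + 1L, by = stride)
  out <- array(0, c(W$n_maps, length(us), length(vs)))
  for (l in seq_len(W$n_maps)) for (ui in seq_along(us))
    for (vi in seq_along(vs)) {
      patch <- input[us[ui]:(us[ui] + s - 1L),
                     vs[vi]:(vs[vi] + s - 1L), , drop = FALSE]
      b <- W$banks[l, (ui - 1L) %% k + 1L, (vi - 1L) %% k + 1L, ]
      out[l, ui, vi] <- sum(as.vector(patch) * b)
    }
  out
}

# exhaustive salient-point oracle: strict interior minima, then greedy by
# depth (ties -> earlier index) under the separation constraint
brute_salient <- function(x, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(vapply(2:(n - 1), function(i)
    x[i - 1] > x[i] && x[i] < x[i + 1], logical(1))) + 1L
  kept <- integer(0)
  for (j in cand[order(x[cand], cand)])
    if (all(abs(kept - j) >= min_sep)) kept <- c(kept, j)
  sort(kept)
}

# tiny two-class gaf_set with trivially separable deterministic patterns
make_separable_gaf <- function(n_per_class = 10L, side = 16L) {
  t1 <- seq(0, 2 * pi, length.out = side)
  imgs <- list(); labs <- character(0); subs <- character(0)
  for (i in seq_len(2 * n_per_class)) {
    lab <- if (i <= n_per_class) "alcohol" else "marijuana"
    f <- if (lab == "alcohol") 1 else 3
    x <- rescale_unit(sin(f * t1 + 0.1 * i))
    g <- gasf_encode(x)
    imgs[[i]] <- array(rep(g, 3), c(side, side, 3))
    labs <- c(labs, lab)
    subs <- c(subs, sprintf("%s_s%02d", lab, i))
  }
  structure(list(images = imgs, labels = labs, subject_ids = subs,
                 cycle_ids = sprintf("c%03d", seq_along(imgs)),
                 side = side),
            class = "gaf_set")
}

# small tiled setting reused across tica tests
small_tica_setting <- function(seed = 1L) {
  st <- tiled_structure(c(8, 8, 1), rf_s = 4, tile_k = 2, n_maps = 2,
                        stride = 2)
  list(st = st,
       V = pooling_topology(st),
       W = init_tiled_weights(2, 2, 4, 1, seed = seed),
       patches = withr::with_seed(seed, matrix(stats::rnorm(5 * 64), 5)))
}
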