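# Shared fixtures and small independent oracles for the test suite.

# small geometry used where full 640x480 frames would be wasteful
small_geom <- function(w = 64L, h = 48L, ppd = 2, fps = 60)
  screen_geometry(w, h, ppd, fps)

# centroid (in pixels, 0-based) of non-background pixels of one frame
frame_centroid <- function(frame, bg = c(0, 0, 0)) {
  mask <- frame[, , 1] != bg[1] | frame[, , 2] != bg[2] | frame[, , 3] != bg[3]
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

# best circular column shift aligning frame b to frame a (brute force)
best_circular_shift <- function(a, b) {
  ra <- as.numeric(to_luminance(a)[1, ])
  rb <- as.numeric(to_luminance(b)[1, ])
  w <- length(ra)
  scores <- vapply(0:(w - 1), function(s)
    sum(ra * rb[((seq_len(w) - 1 - s) %% w) + 1]), numeric(1))
  which.max(scores) - 1L
}

# exhaustive-enumeration oracle: expected VR over all 2^8 choice paths,
# each path weighted by its Bernoulli probability
enum_expected_vr <- function(p) {
  paths <- as.matrix(expand.grid(rep(list(c(1L, -1L)), 8L)))
  tubes <- apply(paths, 1, tube_from_choices)
  k <- rowSums(paths == 1L)
  probs <- p^k * (1 - p)^(8 - k)
  sum(probs * tubes)
}

# mean VR of simulate_maze over n_mazes replicate mazes
mc_mean_vr <- function(p, n_mazes, n_flies = 25L, loss = 0, seed = 1L) {
  seeds <- withr::with_seed(seed, sample.int(1e7, n_mazes))
  vrs <- vapply(seq_len(n_mazes), function(i)
    visual_response(simulate_maze(n_flies, p, loss, 1L, seeds[i])),
    numeric(1))
  vrs
}
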