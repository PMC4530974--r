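# Independent naive 2-D convolution oracle for the gradient module:
# direct double sum over the 11 x 5 kernel with edge-replication padding,
# followed by the same clamp-and-normalize contract.
naive_gradient <- function(frame, orientation) {
  k <- edge_kernel(orientation)
  H <- nrow(frame); W <- ncol(frame)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  g <- matrix(0, H, W)
  for (z in seq_len(H)) for (x in seq_len(W)) {
    acc <- 0
    for (u in 1:11) for (v in 1:5)
      acc <- acc + k[u, v] * frame[cl(z - (u - 6L), H), cl(x - (v - 3L), W)]
    g[z, x] <- acc
  }
  g[g < 0] <- 0
  mn <- min(g); mx <- max(g)
  if (mx > mn) (g - mn) / (mx - mn) else matrix(0, H, W)
}

# a frame with a sharp horizontal step (dark above, bright below)
step_frame <- function(H = 40, W = 12, edge = 20, lo = 0, hi = 1) {
  f <- matrix(lo, H, W)
  f[edge:H, ] <- hi
  f
}

# wrap a single difference vector as a pair of surface sets for metric tests
sets_from_diffs <- function(d) {
  base <- matrix(100, length(d), 1)
  list(a = surface_set(list(ILM = base + d), check = FALSE),
       b = surface_set(list(ILM = base), check = FALSE))
}

# small flat phantom used by fast pipeline tests
small_flat_spec <- function(n_frames = 2L) {
  phantom_spec(n_frames = n_frames, n_rows = 300L, n_cols = 120L,
               lateral_amp = 0, frame_amp = 0, pit_depth = 0,
               speckle_shape = Inf, name = "test_flat")
}

exact_cfg <- function() pipeline_config(downsample_factor = 1, smooth_window = 1)

# align a truth surface matrix to a (possibly cropped) segmentation grid
aligned_truth <- function(seg, truth, lab) {
  m <- seg$surfaces$surfaces[[lab]]
  truth$surfaces[[lab]][seq_len(nrow(m)) + seg$surfaces$column_offset,
                        seq_len(ncol(m)) + seg$surfaces$frame_offset,
                        drop = FALSE]
}
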