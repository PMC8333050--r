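# Brute-force direct-sum oracles and small fixture builders. The oracles are
# plain triple-sum implementations, independent of the spectral code paths
# they check.

# circular convolution with the delta-at-centre identity convention
brute_convolve <- function(A, B) {
  d <- dim(A)
  c0 <- floor(d / 2)
  out <- array(0, d)
  for (z in 0:(d[1] - 1)) for (y in 0:(d[2] - 1)) for (x in 0:(d[3] - 1)) {
    s <- 0
    for (i in 0:(d[1] - 1)) for (j in 0:(d[2] - 1)) for (k in 0:(d[3] - 1)) {
      s <- s + A[i + 1, j + 1, k + 1] *
        B[((z + c0[1] - i) %% d[1]) + 1,
          ((y + c0[2] - j) %% d[2]) + 1,
          ((x + c0[3] - k) %% d[3]) + 1]
    }
    out[z + 1, y + 1, x + 1] <- s
  }
  out
}

# circular correlation (a star b)(xi) = sum_y a(y) b(y + xi), zero lag at
# the centred voxel floor(d/2)
brute_correlate <- function(A, B) {
  d <- dim(A)
  c0 <- floor(d / 2)
  out <- array(0, d)
  for (z in 0:(d[1] - 1)) for (y in 0:(d[2] - 1)) for (x in 0:(d[3] - 1)) {
    xi <- c(z, y, x) - c0
    s <- 0
    for (i in 0:(d[1] - 1)) for (j in 0:(d[2] - 1)) for (k in 0:(d[3] - 1)) {
      s <- s + A[i + 1, j + 1, k + 1] *
        B[((i + xi[1]) %% d[1]) + 1, ((j + xi[2]) %% d[2]) + 1,
          ((k + xi[3]) %% d[3]) + 1]
    }
    out[z + 1, y + 1, x + 1] <- s
  }
  out
}

rand_volume <- function(shape, seed) {
  set.seed(seed)
  ObjectVolume(array(runif(prod(shape)), shape))
}

# a 1D non-negative signal with compact support embedded on a circular grid
toy_signal_1d <- function(n, support, seed) {
  set.seed(seed)
  v <- rep(0, n)
  v[support] <- runif(length(support))
  ObjectVolume(v)
}

delta_volume <- function(shape, at) {
  a <- array(0, shape)
  a[at[1], at[2], at[3]] <- 1
  ObjectVolume(a)
}

rel_err <- function(got, want) {
  max(abs(got - want)) / max(abs(want))
}

# uniform-over-support init for 1D/2D de-autocorrelation toys
uniform_init_like <- function(v) {
  a <- volData(v)
  ObjectVolume(array(as.numeric(a > 0), dim(a)), voxelPitch(v))
}

# measure the FWHM of a recovered bead in an aligned reconstruction,
# averaged over the three axes. Bead candidates (brightest first, windows
# free of `avoid` structure) are re-centred on the local maximum of the
# aligned reconstruction -- standard bead-measurement practice, and needed
# because the recovered point source may sit a few voxels off the nominal
# position. The first cleanly measurable bead wins.
bead_fwhm <- function(recon, truth, beads_only, avoid = NULL,
                      half_window = 5L) {
  al <- alignToTruth(recon, truth)
  ar <- volData(al)
  bt <- volData(beads_only)
  d <- dim(bt)
  cand <- which(bt > 0, arr.ind = TRUE)
  ok <- apply(cand, 1, function(p)
    all(p > 2 * half_window) && all(p <= d - 2 * half_window))
  cand <- cand[ok, , drop = FALSE]
  cand <- cand[order(bt[cand], decreasing = TRUE), , drop = FALSE]
  av <- if (is.null(avoid)) array(0, d) else volData(avoid)
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, ]
    idx <- lapply(1:3, function(ax)
      (p[ax] - half_window):(p[ax] + half_window))
    if (sum(av[idx[[1]], idx[[2]], idx[[3]]]) > 0) next
    # re-centre on the local maximum of the reconstruction
    loc <- ar[idx[[1]], idx[[2]], idx[[3]]]
    mx <- which(loc == max(loc), arr.ind = TRUE)[1, ]
    p2 <- p + mx - (half_window + 1L)
    idx2 <- lapply(1:3, function(ax)
      (p2[ax] - half_window):(p2[ax] + half_window))
    wv <- ObjectVolume(ar[idx2[[1]], idx2[[2]], idx2[[3]]],
                       voxelPitch(recon))
    f <- tryCatch(mean(vapply(1:3, function(ax) fwhm(wv, ax), numeric(1))),
                  error = function(e) NA_real_)
    if (!is.na(f)) return(f)
  }
  stop("no cleanly measurable bead found")
}
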