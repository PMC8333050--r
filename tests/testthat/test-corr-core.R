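test_that("spectral convolution matches the direct-sum oracle and its algebra", {
  a <- rand_volume(c(5, 5, 5), seed = 101)
  b <- rand_volume(c(5, 5, 5), seed = 102)

  bf <- brute_convolve(volData(a), volData(b))
  expect_lt(rel_err(volData(convolveVol(a, b, "circular")), bf), 1e-10)

  # delta at the central voxel is the identity in both modes
  dlt <- delta_volume(c(5, 5, 5), c(3, 3, 3))
  for (mode in c("circular", "linear-padded"))
    expect_lt(max(abs(volData(convolveVol(dlt, b, mode)) - volData(b))),
              1e-12)

  # commutativity
  expect_equal(volData(convolveVol(a, b, "linear-padded")),
               volData(convolveVol(b, a, "linear-padded")))

  # mass conservation of the full linear convolution
  full <- convolveVol(a, b, "linear-padded", outSize = "full")
  expect_equal(sum(volData(full)), sum(volData(a)) * sum(volData(b)),
               tolerance = 1e-12)

  # shape mismatch in circular mode is a geometry error
  expect_error(convolveVol(a, rand_volume(c(4, 5, 5), 1), "circular"),
               class = "acorrtomo_geometry_error")
})

test_that("correlation obeys the lag convention and matches brute force", {
  a <- rand_volume(c(5, 5, 5), seed = 103)
  b <- rand_volume(c(5, 5, 5), seed = 104)

  bf <- brute_correlate(volData(a), volData(b))
  expect_lt(rel_err(volData(correlateVol(a, b, "circular")), bf), 1e-10)

  # correlate(delta_p, delta_q) is a delta at lag q - p
  d1 <- delta_volume(c(7, 7, 7), c(2, 3, 4))
  d2 <- delta_volume(c(7, 7, 7), c(5, 6, 3))
  cc <- correlateVol(d1, d2, "circular")
  peak <- which(volData(cc) > 0.5, arr.ind = TRUE)
  expect_equal(as.integer(peak - matrix(centerIndex(cc), 1)),
               c(3L, 3L, -1L))

  # correlate(a, b) = flip(correlate(b, a))
  c1 <- correlateVol(a, b, "linear-padded")
  c2 <- flipVol(correlateVol(b, a, "linear-padded"))
  expect_lt(max(abs(volData(c1) - volData(c2))), 1e-12)
})

test_that("auto-correlation is centred, symmetric and shift-invariant", {
  # a single delta anywhere maps to a delta at the centre
  d <- delta_volume(c(6, 6, 6), c(2, 5, 1))
  A <- autocorrelate(d, "circular")
  want <- array(0, c(6, 6, 6)); want[4, 4, 4] <- 1
  expect_equal(volData(A), want)

  a <- rand_volume(c(6, 6, 6), seed = 105)
  A <- autocorrelate(a, "circular")
  # centre value is sum of squares; maximum at centre (Cauchy-Schwarz)
  ci <- centerIndex(A)
  expect_equal(volData(A)[ci[1], ci[2], ci[3]], sum(volData(a)^2),
               tolerance = 1e-12)
  expect_equal(max(volData(A)), volData(A)[ci[1], ci[2], ci[3]])
  # centro-symmetry about the centre
  expect_lt(max(abs(volData(A) - volData(flipVol(A)))), 1e-12)

  # exact (bitwise) invariance to circular integer shifts
  a2 <- shiftVolume(a, c(2, -1, 3))
  expect_identical(volData(autocorrelate(a2, "circular")), volData(A))

  # Parseval: total sum is (sum a)^2 in linear-padded mode
  Ap <- autocorrelate(a, "linear-padded")
  expect_equal(sum(volData(Ap)), sum(volData(a))^2, tolerance = 1e-10)

  # padded-mode shift invariance for compact support away from edges
  set.seed(7)
  cmp <- array(0, c(9, 9, 9)); cmp[4:6, 4:6, 4:6] <- runif(27)
  v <- ObjectVolume(cmp)
  A1 <- autocorrelate(v, "linear-padded")
  A2 <- autocorrelate(shiftVolume(v, c(1, -2, 1)), "linear-padded")
  expect_lt(rel_err(volData(A2), volData(A1)), 1e-10)
})

test_that("the convolution-correlation commutation identity holds", {
  # A{a * b} = A{a} * A{b}, checked spectrally against itself on the
  # circular algebra where it is exact
  a <- rand_volume(c(8, 8, 8), seed = 106)
  b <- rand_volume(c(8, 8, 8), seed = 107)
  lhs <- autocorrelate(convolveVol(a, b, "circular"), "circular")
  rhs <- convolveVol(autocorrelate(a, "circular"),
                     autocorrelate(b, "circular"), "circular")
  expect_lt(rel_err(volData(lhs), volData(rhs)), 1e-8)
})

test_that("flip is an involution with the expected fixed points", {
  a <- rand_volume(c(5, 6, 7), seed = 108)
  expect_identical(volData(flipVol(flipVol(a))), volData(a))

  # a centred symmetric Gaussian maps to itself
  g <- renderPSF(PSFModel(sigmaLateral = 1, sigmaScan = 1), 0)
  expect_lt(max(abs(volData(flipVol(g)) - volData(g))), 1e-15)

  # a delta at lag s maps to a delta at -s
  d <- delta_volume(c(7, 7, 7), c(5, 4, 2))
  fd <- flipVol(d)
  peak <- which(volData(fd) > 0.5, arr.ind = TRUE)
  expect_equal(as.integer(peak), c(3L, 4L, 6L))
})

test_that("LagVolume enforces the centred zero-lag convention", {
  expect_error(new("LagVolume", data = array(0, c(4, 4, 4)),
                   centerIndex = c(1L, 1L, 1L), mode = "circular"),
               "centerIndex")
  lv <- LagVolume(array(0, c(5, 4, 7)))
  expect_equal(centerIndex(lv), c(3L, 3L, 4L))
})
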