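test_that("phantom generation is deterministic with the declared support", {
  p1 <- generatePhantom("bead_field", c(48, 48, 48), list(nBeads = 10),
                        seed = 3)
  p2 <- generatePhantom("bead_field", c(48, 48, 48), list(nBeads = 10),
                        seed = 3)
  expect_identical(volData(p1), volData(p2))
  # exactly k point sources
  expect_equal(sum(volData(p1) > 0), 10L)
  # empty phantom
  p0 <- generatePhantom("bead_field", c(32, 32, 32), list(nBeads = 0),
                        seed = 1)
  expect_equal(sum(volData(p0)), 0)
  # zero margin on every face
  pv <- generatePhantom("vessel_tree", c(48, 48, 48), list(), seed = 5)
  arr <- volData(pv)
  expect_true(all(arr >= 0))
  expect_gt(sum(arr > 0), 0)
  expect_equal(sum(arr[1:10, , ]) + sum(arr[39:48, , ]) +
               sum(arr[, 1:10, ]) + sum(arr[, , 39:48]), 0)
  # impossible margin is a geometry error
  expect_error(generatePhantom("shell", c(12, 12, 12),
                               list(margin = 6), seed = 1),
               class = "acorrtomo_geometry_error")
})

test_that("rendered PSFs have the declared rotated covariance", {
  m <- PSFModel(sigmaLateral = 1.5, sigmaScan = 4.5)
  h <- renderPSF(m, 30)
  expect_equal(sum(volData(h)), 1, tolerance = 1e-12)

  arr <- volData(h)
  ctr <- (dim(arr) + 1) / 2
  z <- slice.index(arr, 1) - ctr[1]
  y <- slice.index(arr, 2) - ctr[2]
  x <- slice.index(arr, 3) - ctr[3]
  got <- c(sum(arr * z * z), sum(arr * x * x), sum(arr * z * x),
           sum(arr * y * y))
  R <- matrix(c(cos(-pi / 6), sin(-pi / 6), -sin(-pi / 6), cos(-pi / 6)),
              2, 2, byrow = TRUE)
  C <- R %*% diag(c(4.5^2, 1.5^2)) %*% t(R)
  want <- c(C[1, 1], C[2, 2], C[1, 2], 1.5^2)
  expect_lt(max(abs(got - want) / abs(want)), 0.01)

  # angle 0: principal axes on the grid, peak at the centre
  h0 <- renderPSF(m, 0)
  peak <- which(volData(h0) == max(volData(h0)), arr.ind = TRUE)
  expect_equal(as.numeric(peak), (dim(volData(h0)) + 1) / 2)
  # Gaussian inversion symmetry: 180 degrees is identical to 0
  expect_equal(volData(renderPSF(m, 180)), volData(h0), tolerance = 1e-14)

  # too-small support is a truncation error
  tiny <- PSFModel(sigmaLateral = 1.5, sigmaScan = 4.5,
                   support = c(9, 9, 9))
  expect_error(renderPSF(tiny, 0), class = "acorrtomo_validation_error")
})

test_that("volume rotation maps axes correctly and round-trips", {
  # 90 degrees moves a bright voxel from the +x axis to the +z axis
  v <- array(0, c(21, 5, 21)); v[11, 3, 16] <- 1
  ov <- ObjectVolume(v)
  r <- rotateVolume(ov, 90, order = 1)
  peak <- which(volData(r) > 0.5, arr.ind = TRUE)
  expect_equal(as.integer(peak), c(16L, 3L, 11L))

  # zero angle is the identity
  expect_identical(volData(rotateVolume(ov, 0)), v)

  # 30 degree round trip on a smooth phantom, interior voxels
  ph <- generatePhantom("bead_field", c(32, 32, 32),
                        list(margin = 9, nBeads = 6), seed = 7)
  h <- renderPSF(PSFModel(sigmaLateral = 1.5, sigmaScan = 1.5), 0)
  sm <- convolveVol(ph, embedVolume(h, dim(ph)), "circular")
  rt <- rotateVolume(rotateVolume(sm, 30, 3), -30, 3)
  inter <- 9:24
  a0 <- volData(sm)[inter, inter, inter]
  a1 <- volData(rt)[inter, inter, inter]
  expect_lt(sqrt(sum((a1 - a0)^2) / sum(a0^2)), 2e-2)
})

test_that("simulated views follow the measurement model", {
  ph <- generatePhantom("bead_field", c(32, 32, 32),
                        list(margin = 10, nBeads = 5), seed = 2)
  m <- PSFModel(sigmaLateral = 1, sigmaScan = 2)

  # base case: single view, no shift, no noise equals phantom * h
  vs <- simulateViews(ph, m, 0, shiftLaw = NULL, seed = 4)
  want <- convolveVol(ph, embedVolume(renderPSF(m, 0), dim(ph)), "circular")
  expect_equal(volData(getView(vs, 1)), volData(want), tolerance = 1e-14)

  # a full turn in 30 degree steps yields 12 views
  vs12 <- simulateViews(ph, m, seq(0, 330, 30), shiftLaw = list(max = 4),
                        seed = 9)
  expect_equal(nViews(vs12), 12L)
  expect_equal(trueShifts(vs12)[1, ], c(0, 0, 0))

  # determinism
  vs12b <- simulateViews(ph, m, seq(0, 330, 30), shiftLaw = list(max = 4),
                         seed = 9)
  expect_identical(lapply(vs12@views, volData),
                   lapply(vs12b@views, volData))

  # mass conservation with a unit-sum PSF (reference-frame path is exact)
  for (i in seq_len(nViews(vs12)))
    expect_equal(sum(volData(getView(vs12, i))), sum(volData(ph)),
                 tolerance = 5e-3)

  # two-path equivalence: rotate-then-blur vs blur-with-rotated-PSF at 90
  # degrees (rotation is an exact grid permutation there)
  va <- simulateViews(ph, m, c(0, 90), shiftLaw = NULL, seed = 11,
                      path = "rotate_psf")
  vb <- preprocessViews(simulateViews(ph, m, c(0, 90), shiftLaw = NULL,
                                      seed = 11, path = "rotate_object"))
  expect_lt(rel_err(volData(getView(vb, 2)), volData(getView(va, 2))), 1e-3)

  # end-to-end shift invariance of the auto-correlation
  vshift <- shiftVolume(getView(vs, 1), c(3, -2, 4))
  expect_identical(volData(autocorrelate(vshift, "circular")),
                   volData(autocorrelate(getView(vs, 1), "circular")))

  # a missing seed is a validation error
  expect_error(simulateViews(ph, m, 0, seed = NULL),
               class = "acorrtomo_validation_error")
})
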