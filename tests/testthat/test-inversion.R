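test_that("the I-divergence has its closed-form values and properties", {
  expect_equal(iDivergence(array(2, c(1, 1, 1)), array(1, c(1, 1, 1))),
               2 * log(2) - 1, tolerance = 1e-12)
  x <- volData(autocorrelate(rand_volume(c(5, 5, 5), 21), "circular"))
  expect_equal(iDivergence(x, x), 0, tolerance = 1e-12)
  expect_gt(iDivergence(x, x * 1.3), 0)
})

test_that("exact solutions are fixed points of both updates", {
  ph <- generatePhantom("bead_field", c(24, 24, 24),
                        list(margin = 8, nBeads = 4), seed = 2)
  chi <- sanitizeAcorr(autocorrelate(ph, "circular"))

  st <- ssStep(newSolverState(ph, "SS"), chi)
  expect_lt(max(abs(volData(st@iterate) - volData(ph))) /
            max(volData(ph)), 1e-12)

  # the flip-symmetrized "printed" variant only fixes centro-symmetric
  # objects: its first term samples the mirrored support
  sym <- ObjectVolume(volData(ph) + volData(flipVol(ph)))
  chis <- sanitizeAcorr(autocorrelate(sym, "circular"))
  stp <- ssStep(newSolverState(sym, "SS"), chis, bracket = "printed")
  expect_lt(max(abs(volData(stp@iterate) - volData(sym))) /
            max(volData(sym)), 1e-12)
  sta <- ssStep(newSolverState(ph, "SS"), chi, bracket = "printed")
  expect_gt(max(abs(volData(sta@iterate) - volData(ph))), 1e-3)

  # AU fixed point: chi = (o star o) * H with the rendered kernel
  h <- embedVolume(renderPSF(PSFModel(1, 1, 2), 0), c(24, 24, 24))
  H <- autocorrelate(h, "circular", canonicalize = FALSE)
  view <- convolveVol(ph, h, "circular")
  chi_mu <- sanitizeAcorr(autocorrelate(view, "circular",
                                        canonicalize = FALSE))
  st <- auStep(newSolverState(ph, "AU"), chi_mu, H)
  expect_lt(max(abs(volData(st@iterate) - volData(ph))) /
            max(volData(ph)), 1e-12)
})

test_that("multiplicative updates preserve the support", {
  truth <- toy_signal_1d(16, 5:11, seed = 31)
  chi <- sanitizeAcorr(autocorrelate(truth, "circular"))
  init <- uniform_init_like(truth)
  vinit <- volData(init)
  vinit[3, 1, 1] <- 0   # outside the support anyway; also zero one inside
  vinit[6, 1, 1] <- 0
  res <- solveAcorr(chi, "SS", init = ObjectVolume(vinit), nIter = 200,
                    checkpointEvery = 50)
  expect_equal(volData(res$recon)[3, 1, 1], 0)
  expect_equal(volData(res$recon)[6, 1, 1], 0)
  expect_true(all(volData(res$recon) >= 0))
})

test_that("SS recovers a 1D signal up to flip and shift from a uniform start", {
  truth <- ObjectVolume(c(rep(0, 4), 0, 0, 1, 2, 1, 0, 0, rep(0, 5)))
  chi <- sanitizeAcorr(autocorrelate(truth, "circular"))
  init <- ObjectVolume(c(rep(0, 4), rep(1, 7), rep(0, 5)))
  res <- solveAcorr(chi, "SS", init = init, nIter = 4000,
                    checkpointEvery = 500)
  tr <- divergenceTrace(res$state)
  expect_lt(tr$idiv[nrow(tr)], 1e-9)
  expect_gt(recoveryScore(res$recon, truth), 1 - 1e-6)
  # mass consistency at the fixed point: (sum o)^2 = sum chi
  expect_lt(abs(sum(volData(res$recon))^2 - sum(volData(chi))) /
            sum(volData(chi)), 1e-3)
})

test_that("the SS divergence trace is non-increasing at every checkpoint", {
  for (seed in 1:10) {
    truth <- toy_signal_1d(24, 8:17, seed = 400 + seed)
    chi <- sanitizeAcorr(autocorrelate(truth, "circular"))
    res <- solveAcorr(chi, "SS", init = uniform_init_like(truth),
                      nIter = 600, checkpointEvery = 50)
    d <- divergenceTrace(res$state)$idiv
    expect_true(all(diff(d) <= 1e-9 * (1 + abs(d[-length(d)]))),
                info = sprintf("seed %d", seed))
  }
})

test_that("the printed bracket variant is not monotone; the classic one is", {
  set.seed(908)
  v <- rep(0, 24); v[8:17] <- runif(10)
  truth <- ObjectVolume(v)
  chi <- sanitizeAcorr(autocorrelate(truth, "circular"))
  init <- uniform_init_like(truth)
  rp <- solveAcorr(chi, "SS", init = init, nIter = 400,
                   checkpointEvery = 1, bracket = "printed")
  rc <- solveAcorr(chi, "SS", init = init, nIter = 400, checkpointEvery = 1)
  dp <- divergenceTrace(rp$state)$idiv
  dc <- divergenceTrace(rc$state)$idiv
  expect_gt(max(diff(dp)), 1e-6)            # genuine transient increase
  expect_true(all(diff(dc) <= 1e-9 * (1 + abs(dc[-length(dc)]))))
})

test_that("AU with a delta anchor reproduces the SS solution", {
  truth <- toy_signal_1d(32, 10:22, seed = 55)
  chi <- sanitizeAcorr(autocorrelate(truth, "circular"))
  init <- uniform_init_like(truth)
  dirac <- LagVolume(volData(delta_volume(c(32, 1, 1), c(17, 1, 1))))
  ss <- solveAcorr(chi, "SS", init = init, nIter = 4000)
  au <- solveAcorr(chi, "AU", H = dirac, init = init, nIter = 4000)
  dss <- divergenceTrace(ss$state)
  dau <- divergenceTrace(au$state)
  expect_lt(abs(dss$idiv[nrow(dss)] - dau$idiv[nrow(dau)]), 1e-6)
})

test_that("AU deconvolves a known blur that SS leaves in place", {
  # two point sources blurred by a known 1D Gaussian (kernel centred at the
  # delta-identity voxel floor(n/2))
  n <- 32
  g <- exp(-0.5 * ((1:n) - 17)^2 / 1.8^2)
  g <- ObjectVolume(g / sum(g))
  gl <- autocorrelate(g, "circular", canonicalize = FALSE)
  sharp <- ObjectVolume(replace(rep(0, n), c(13, 21), 1))
  blur <- convolveVol(sharp, g, "circular")
  blur <- ObjectVolume(pmax(volData(blur), 0))
  chi <- sanitizeAcorr(autocorrelate(blur, "circular",
                                     canonicalize = FALSE))
  ss <- solveAcorr(chi, "SS", init = blur, nIter = 5000)
  au <- solveAcorr(chi, "AU", H = gl, init = blur, nIter = 5000)
  width <- function(v) {
    x <- volData(v); x <- x / max(x); sum(x > 0.5)
  }
  expect_lt(width(au$recon), width(ss$recon))
  # AU restores the two separated sources
  pk <- which(volData(au$recon) > 0.3 * max(volData(au$recon)))
  expect_equal(length(pk), 2L)
})

test_that("solver plumbing honours its contracts", {
  truth <- toy_signal_1d(16, 5:11, seed = 77)
  chi <- sanitizeAcorr(autocorrelate(truth, "circular"))
  init <- uniform_init_like(truth)

  # zero iterations returns the init
  res <- solveAcorr(chi, "SS", init = init, nIter = 0)
  expect_equal(volData(res$recon), volData(init))

  # AU without H is a validation error
  expect_error(solveAcorr(chi, "AU", init = init, nIter = 5),
               class = "acorrtomo_validation_error")

  # a zero-mass init is degenerate
  expect_error(solveAcorr(chi, "SS",
                          init = ObjectVolume(rep(0, 16)), nIter = 5),
               class = "acorrtomo_degenerate_error")

  # early stop on a converged problem
  res2 <- solveAcorr(chi, "SS", init = init, nIter = 5000,
                     checkpointEvery = 100, tol = 1e-10)
  expect_lt(res2$state@t, 5000L)

  # deterministic given inputs
  ra <- solveAcorr(chi, "SS", init = init, nIter = 50)
  rb <- solveAcorr(chi, "SS", init = init, nIter = 50)
  expect_identical(volData(ra$recon), volData(rb$recon))
})
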