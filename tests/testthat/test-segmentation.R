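# Intensity normalization, Hessian vesselness, candidate extraction.

test_that("intensity normalization uses the population SD within the mask", {
  vals <- array(0, c(3, 3, 3))
  mask <- array(FALSE, c(3, 3, 3))
  mask[1:3, 1, 1] <- TRUE
  vals[mask] <- c(1, 2, 3)
  out <- normalizeIntensity(imageVolume(vals, 1), mask)
  expect_equal(imageData(out)[mask], c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_true(all(imageData(out)[!mask] == 0))
  # idempotence up to floating tolerance
  out2 <- normalizeIntensity(out, mask)
  expect_equal(imageData(out2), imageData(out), tolerance = 1e-12)
  # degenerate constant image errors
  vals[mask] <- 5
  expect_error(normalizeIntensity(imageVolume(vals, 1), mask), "constant")
})

test_that("Hessian eigenvalues: constant volume, analytic quadratic, ordering", {
  dm <- c(24L, 24L, 24L)
  flat <- imageVolume(array(1, dm), 1)
  e0 <- hessianEigenvalues(flat, 1)
  expect_true(all(abs(e0$l1) < 1e-12 & abs(e0$l2) < 1e-12 &
                    abs(e0$l3) < 1e-12))
  # bright ridge along z: f = -(x^2 + y^2); Hessian diag(-2, -2, 0),
  # scale-normalized by scale^2 = 4
  x <- seq_len(dm[1]) - 12.5
  f <- -outer(outer(x^2, x^2, `+`), rep(0, dm[3]), `+`)
  eg <- hessianEigenvalues(imageVolume(f, 1), 2)
  ctr <- c(12, 12, 12)
  l <- c(eg$l1[ctr[1], ctr[2], ctr[3]], eg$l2[ctr[1], ctr[2], ctr[3]],
         eg$l3[ctr[1], ctr[2], ctr[3]])
  expect_equal(l[1], 0, tolerance = 1e-6)
  expect_equal(l[2], -8, tolerance = 1e-6)
  expect_equal(l[3], -8, tolerance = 1e-6)
  # |l1| <= |l2| <= |l3| everywhere
  tr <- cleanPhantom(seed = 8, grid = 32L)
  en <- hessianEigenvalues(tr$image, 1.05)
  expect_true(all(abs(en$l1) <= abs(en$l2) + 1e-12))
  expect_true(all(abs(en$l2) <= abs(en$l3) + 1e-12))
})

test_that("vesselness formula reproduces analytic tube/plate/null cases", {
  mk <- function(l1, l2, l3) list(l1 = array(l1, c(1, 1, 1)),
                                  l2 = array(l2, c(1, 1, 1)),
                                  l3 = array(l3, c(1, 1, 1)))
  expect_equal(as.vector(vesselnessFromEigen(mk(0, 0, 0), gamma = 5)), 0)
  # ideal bright tube (0, -5, -5): (1 - e^-2) * 1 * (1 - e^-1)
  v <- vesselnessFromEigen(mk(0, -5, -5), alpha = 0.5, beta = 0.5,
                           gamma = 5)
  expect_equal(as.vector(v), (1 - exp(-2)) * (1 - exp(-1)),
               tolerance = 1e-6)
  # ideal bright plate (0, 0, -5) is suppressed
  expect_equal(as.vector(vesselnessFromEigen(mk(0, 0, -5), gamma = 5)), 0)
  # bright-tube polarity: positive l2/l3 give zero response
  expect_equal(as.vector(vesselnessFromEigen(mk(0, 5, 5), gamma = 5)), 0)
})

test_that("vesselness is bounded in [0,1] and zero on constant input", {
  tr <- cleanPhantom(seed = 8, grid = 32L)
  norm <- normalizeIntensity(tr$image, regionMasks(tr)$brain)
  v <- vesselnessFilter(norm, vesselnessParams())
  expect_true(all(v >= 0 & v <= 1))
  vflat <- vesselnessFilter(imageVolume(array(0, c(16, 16, 16)), 0.7),
                            vesselnessParams(),
                            mask = array(TRUE, c(16, 16, 16)))
  expect_true(all(vflat == 0))
})

test_that("oracle equivalence: closed-form eigen-solve matches per-voxel eigen()", {
  # independent route: same Gaussian-derivative Hessian entries, but a
  # brute-force symmetric eigen-decomposition per voxel
  set.seed(42)
  dm <- c(8L, 8L, 8L)
  img <- imageVolume(array(stats::rnorm(prod(dm)), dm), 1)
  scale <- 1.5
  sm <- pvstwin:::gaussianSmooth(imageData(img), rep(scale, 3))
  sh <- function(a, ax, by) pvstwin:::shiftArray(a, ax, by)
  d2 <- function(ax) (sh(sm, ax, 1) - 2 * sm + sh(sm, ax, -1))
  dc <- function(a1, a2) {
    g <- (sh(sm, a1, 1) - sh(sm, a1, -1)) / 2
    (sh(g, a2, 1) - sh(g, a2, -1)) / 2
  }
  s2 <- scale^2
  H11 <- d2(1) * s2; H22 <- d2(2) * s2; H33 <- d2(3) * s2
  H12 <- dc(1, 2) * s2; H13 <- dc(1, 3) * s2; H23 <- dc(2, 3) * s2
  eg <- hessianEigenvalues(img, scale)
  for (lin in seq_len(prod(dm))) {
    H <- matrix(c(H11[lin], H12[lin], H13[lin],
                  H12[lin], H22[lin], H23[lin],
                  H13[lin], H23[lin], H33[lin]), 3, 3)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[order(abs(ev))]
    expect_equal(c(eg$l1[lin], eg$l2[lin], eg$l3[lin]), ev,
                 tolerance = 1e-8)
  }
})

test_that("candidate extraction respects masks, threshold and connectivity", {
  dm <- c(10L, 10L, 10L)
  v <- array(0, dm)
  wm <- array(FALSE, dm); bg <- array(FALSE, dm)
  wm[2:6, 2:3, 2:6] <- TRUE   # 50 voxels
  v[wm] <- 1
  # threshold 1.0: V <= 1 everywhere, nothing strictly above
  cand <- extractCandidates(v, wm, bg, vesselnessParams(threshold = 1))
  expect_equal(nVoxels(cand), 0L)
  # threshold 0.5 keeps all 50 WM voxels as WM-tagged components
  cand <- extractCandidates(v, wm, bg, vesselnessParams(threshold = 0.5))
  expect_equal(nVoxels(cand), 50L)
  expect_true(all(cand@region == "WM"))
  # misaligned masks error
  expect_error(extractCandidates(v, wm[1:9, , ], bg[1:9, , ],
                                 vesselnessParams()), "grid")
  # overlapping masks error
  expect_error(extractCandidates(v, wm, wm, vesselnessParams()),
               "disjoint")
})

test_that("components straddling regions are tagged by majority, ties toward WM", {
  dm <- c(10L, 4L, 4L)
  v <- array(0, dm)
  wm <- array(FALSE, dm); bg <- array(FALSE, dm)
  wm[1:3, 2, 2] <- TRUE; bg[4:5, 2, 2] <- TRUE
  v[1:5, 2, 2] <- 1   # one 26-connected run: 3 WM + 2 BG voxels
  cand <- extractCandidates(v, wm, bg, vesselnessParams(threshold = 0.5))
  expect_equal(length(cand@region), 1L)
  expect_equal(cand@region, "WM")
  wm2 <- array(FALSE, dm); bg2 <- array(FALSE, dm)
  wm2[1:2, 2, 2] <- TRUE; bg2[3:4, 2, 2] <- TRUE
  v2 <- array(0, dm); v2[1:4, 2, 2] <- 1
  cand2 <- extractCandidates(v2, wm2, bg2, vesselnessParams(threshold = 0.5))
  expect_equal(cand2@region, "WM")  # 2-2 tie broken toward WM
})

test_that("raising the threshold never adds candidate voxels", {
  tr <- cleanPhantom(seed = 13, grid = 48L)
  masks <- regionMasks(tr)
  norm <- normalizeIntensity(tr$image, masks$brain)
  v <- vesselnessFilter(norm, vesselnessParams())
  prev <- Inf
  for (th in c(0.05, 0.1, 0.2, 0.4)) {
    n <- nVoxels(extractCandidates(v, masks$wm, masks$bg,
                                   vesselnessParams(threshold = th)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("26-connectivity joins diagonal voxels into one component", {
  dm <- c(6L, 6L, 6L)
  v <- array(0, dm); wm <- array(TRUE, dm); bg <- array(FALSE, dm)
  v[2, 2, 2] <- 1; v[3, 3, 3] <- 1   # diagonal neighbours
  cand <- extractCandidates(v, wm, bg, vesselnessParams(threshold = 0.5))
  expect_equal(length(cand@region), 1L)
  expect_equal(nVoxels(cand), 2L)
})
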