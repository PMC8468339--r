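test_that("unitary transform convention: DC, roundtrip, Parseval", {
  k <- forward_kspace(matrix(3, 32, 32))
  expect_equal(Mod(k$data[17, 17]), 3 * 32, tolerance = 1e-10)
  off_dc <- Mod(k$data); off_dc[17, 17] <- 0
  expect_lt(max(off_dc), 1e-10)

  set.seed(1)
  img <- matrix(runif(48 * 40), 48, 40)
  k2 <- forward_kspace(img)
  expect_lt(max(abs(inverse_recon(k2) - img)), 1e-10)
  expect_equal(sum(Mod(k2$data)^2), sum(img^2), tolerance = 1e-9)
  # Hermitian symmetry for real input
  ku <- mrisim:::ifftshift2(k2$data)
  neg <- function(n) c(1, n:2)
  expect_lt(max(Mod(ku - Conj(ku[neg(48), neg(40)]))), 1e-10)
})

test_that("magnitude reconstruction is phase-invariant and zero-preserving", {
  z <- kspace_slice(matrix(0 + 0i, 16, 16))
  expect_true(all(inverse_recon(z) == 0))
  set.seed(2)
  k <- forward_kspace(matrix(runif(256), 16, 16))
  rot <- kspace_slice(k$data * exp(1i * 0.7), k$geometry)
  expect_equal(inverse_recon(rot), inverse_recon(k), tolerance = 1e-12)
})

test_that("thermal noise honours sigma = 0, determinism and the Rayleigh law", {
  k <- point_kspace(32, 32)
  expect_identical(add_thermal_noise(k, 0, seed = 5), k)
  n1 <- add_thermal_noise(k, 0.3, seed = 5)
  n2 <- add_thermal_noise(k, 0.3, seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(add_thermal_noise(k, 0.3, seed = 6)$data, n1$data))
  expect_error(add_thermal_noise(k, -1), ">= 0")

  # air region of a magnitude image: Rayleigh with scale sigma
  sigma <- 2
  kz <- kspace_slice(matrix(0 + 0i, 100, 100))
  mag <- inverse_recon(add_thermal_noise(kz, sigma, seed = 11))
  ks <- stats::ks.test(as.vector(mag),
                       function(q) 1 - exp(-q^2 / (2 * sigma^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("spikes add plane waves with the offset's cycle count", {
  z <- kspace_slice(matrix(0 + 0i, 128, 128), simple_geometry(128, 128))
  const <- inverse_recon(add_spike(z, c(0, 0), 4))
  expect_lt(diff(range(const)), 1e-12)

  rec <- inverse_recon(add_spike(z, c(0, 8), 1), complex = TRUE)
  rp <- Re(rec[1, ])
  crossings <- sum(diff(sign(rp)) != 0) / 2
  expect_equal(crossings, 8)

  k <- point_kspace(32, 32)
  back <- add_spike(add_spike(k, c(3, -5), 2 + 1i), c(3, -5), -2 - 1i)
  expect_lt(max(Mod(back$data - k$data)), 1e-12)
  expect_error(add_spike(k, c(40, 0), 1), "outside")
})

test_that("periodic motion creates ghosts at matrix_phase/period offsets", {
  k <- point_kspace(128, 128, fov = 256)
  expect_identical(add_motion(k, 0, 8), k)
  expect_error(add_motion(k, 1, 1.5), "period")
  for (p in c(4, 8, 16)) {
    rec <- inverse_recon(add_motion(k, amplitude_mm = 0.5, period_lines = p))
    ghosts <- rec
    ghosts[, 65] <- 0                     # remove the parent column
    # all spurious energy sits at multiples of 128/p along phase
    hot <- which(ghosts > 1e-9, arr.ind = TRUE)
    expect_true(all((hot[, 2] - 65) %% (128 / p) == 0),
                label = sprintf("period %d offsets", p))
    # the largest ghost is the first harmonic
    peak <- which(ghosts == max(ghosts), arr.ind = TRUE)
    expect_equal(abs(unname(peak[1, 2]) - 65), 128 / p)
  }
})

test_that("ghost pixel offsets depend on line counts, not the FOV", {
  k1 <- point_kspace(64, 64, fov = 200)
  k2 <- point_kspace(64, 64, fov = 400)
  ghost_cols <- function(k) {
    rec <- inverse_recon(add_motion(k, 0.8, 8))
    rec[, 33] <- 0
    sort(unique(which(rec > 1e-9, arr.ind = TRUE)[, 2]))
  }
  expect_identical(ghost_cols(k1), ghost_cols(k2))
})

test_that("echo-train attenuation scales lines per the linear ordering", {
  sl <- list(pd = matrix(1, 64, 64), t2 = matrix(80, 64, 64))
  k <- point_kspace(64, 64)
  sq1 <- sequence_params("FSE", te = 80, tr = 3000, etl = 1,
                         echo_spacing = 10)
  a1 <- apply_etl_attenuation(k, sl, sq1)
  ratio <- Mod(a1$data / k$data)
  expect_lt(max(ratio) / min(ratio) - 1, 1e-12)    # uniform scale
  expect_equal(ratio[1, 1], exp(-80 / 80), tolerance = 1e-12)

  # infinite T2 -> identity
  sl_inf <- list(pd = matrix(1, 64, 64), t2 = matrix(1e12, 64, 64))
  sq8 <- sequence_params("FSE", te = 80, tr = 3000, etl = 8,
                         echo_spacing = 10)
  a_inf <- apply_etl_attenuation(k, sl_inf, sq8)
  expect_lt(max(Mod(a_inf$data - k$data)), 1e-9)

  # oracle: point-spread functions from the line-weight vector alone
  times <- mrisim:::fse_line_times(64, 80, 8, 10)
  w8 <- exp(-times / 80)
  w1 <- rep(exp(-80 / 80), 64)
  psf <- function(w) abs(stats::fft(w, inverse = TRUE)) / 64
  fw <- function(p) { p <- p / max(p); sum(p >= 0.5) }
  expect_gte(fw(psf(w8)), fw(psf(w1)))
  # etl = 8 spreads energy off the central pixel
  off_centre <- function(p) 1 - max(p)^2 / sum(p^2)
  expect_gt(off_centre(psf(w8)), off_centre(psf(w1)))

  rec8 <- inverse_recon(apply_etl_attenuation(k, sl, sq8))
  expect_gt(off_centre(rec8[33, ]), off_centre(inverse_recon(a1)[33, ]))
  expect_error(apply_etl_attenuation(k, sl, sequence_params("SE", 20, 500)),
               "FSE")
})

test_that("partial-Fourier reconstruction is exact for zero-phase images", {
  set.seed(4)
  img <- matrix(runif(64 * 64), 64, 64)
  k <- forward_kspace(img)
  expect_identical(half_fourier_recon(k, 1), inverse_recon(k))
  expect_lt(max(abs(half_fourier_recon(k, 0.55) - img)), 1e-9)
  expect_error(half_fourier_recon(k, 0.5), "fraction")

  # a linear image phase breaks plain conjugate synthesis
  ph <- exp(1i * outer(seq(0, 2, length.out = 64), rep(1, 64)))
  kp <- kspace_slice(mrisim:::fftshift2(stats::fft(img * ph)) / 64)
  err_phase <- max(abs(half_fourier_recon(kp, 0.55) - img))
  expect_gt(err_phase, 1e-6)
})

test_that("wrap-around folds the oversampled FOV; no-phase-wrap crops it", {
  g <- simple_geometry(nf = 32, np = 32, fov = 128, oversampling = 1.5)
  over <- matrix(0, 32, 48)
  # object fully inside the nominal FOV: folding changes nothing
  over[10, 25] <- 1
  fold <- apply_wraparound(over, g, "fold")
  expect_equal(dim(fold), c(32L, 32L))
  crop <- apply_wraparound(over, g, "crop")
  expect_equal(fold, crop)
  # a point beyond +FOV/2 reappears near -FOV/2
  over2 <- matrix(0, 32, 48)
  over2[10, 44] <- 1                     # nominal index would be 36 > 32
  fold2 <- apply_wraparound(over2, g, "fold")
  expect_equal(which(fold2[10, ] > 0), 4L)   # 36 - 32
  crop2 <- apply_wraparound(over2, g, "crop")
  expect_equal(sum(crop2), 0)
})
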