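#' k-space representation of one slice
#'
#' Complex (freq x phase) matrix holding the 2-D spatial-frequency content
#' of a contrast image under the package's fixed transform convention:
#' unitary discrete Fourier transform with the DC component at the matrix
#' centre (`floor(n/2) + 1` on each axis). The unitary scaling makes
#' Parseval's identity exact, so a thermal-noise standard deviation in
#' k-space means the same thing in image space.
#'
#' @param data complex matrix.
#' @param geometry optional `plan_geometry` the matrix refers to.
#' @return an object of class `kspace_slice` with a `normalization` tag
#'   `"unitary/dc-centred"`.
#' @export
kspace_slice <- function(data, geometry = NULL) {
  if (!is.matrix(data)) abort_invalid("k-space data must be a matrix")
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    abort_invalid("k-space entries must be finite")
  structure(list(data = data, geometry = geometry,
                 normalization = "unitary/dc-centred"),
            class = "kspace_slice")
}

#' @export
print.kspace_slice <- function(x, ...) {
  cat(sprintf("kspace_slice: %d x %d (%s), peak |k| = %.4g\n",
              nrow(x$data), ncol(x$data), x$normalization, max(Mod(x$data))))
  invisible(x)
}

#' Forward transform: contrast image to k-space
#'
#' Unitary 2-D DFT with DC shifted to the matrix centre. For a real input
#' the result is Hermitian-symmetric, which is what partial-Fourier
#' reconstruction exploits.
#'
#' @param image real (or complex) matrix.
#' @param geometry optional `plan_geometry` carried along as metadata.
#' @return a `kspace_slice`.
#' @export
forward_kspace <- function(image, geometry = NULL) {
  if (!is.matrix(image) || any(!is.finite(Re(image))))
    abort_invalid("image must be a finite matrix")
  kspace_slice(fftshift2(stats::fft(image)) / sqrt(length(image)), geometry)
}

#' Inverse transform: k-space to image
#'
#' Magnitude of the unitary inverse DFT; set `complex = TRUE` to keep the
#' complex image (used internally by partial-Fourier reconstruction).
#'
#' @param k a `kspace_slice`.
#' @param complex return the complex image instead of its magnitude.
#' @return a real magnitude matrix (default) or complex matrix.
#' @export
inverse_recon <- function(k, complex = FALSE) {
  stopifnot(inherits(k, "kspace_slice"))
  img <- stats::fft(ifftshift2(k$data), inverse = TRUE) / sqrt(length(k$data))
  if (complex) img else Mod(img)
}

#' Add circular complex Gaussian thermal noise in k-space
#'
#' Adds i.i.d. complex Gaussian noise (standard deviation `sigma` per real
#' and imaginary component) to every entry. Under the unitary convention the
#' image-domain noise has the same per-component sigma, so the background of
#' the magnitude image follows a Rayleigh law with scale `sigma`.
#'
#' @param k a `kspace_slice`.
#' @param sigma noise scale (>= 0); 0 returns the input unchanged.
#' @param seed integer seed; the operator is deterministic given it.
#' @return a `kspace_slice`.
#' @export
add_thermal_noise <- function(k, sigma, seed = 1L) {
  stopifnot(inherits(k, "kspace_slice"))
  if (!is_scalar_number(sigma) || sigma < 0)
    abort_invalid("sigma must be >= 0")
  if (sigma == 0) return(k)
  set.seed(derive_seed(seed, "thermal"))
  n <- length(k$data)
  noise <- complex(real = stats::rnorm(n, sd = sigma),
                   imaginary = stats::rnorm(n, sd = sigma))
  kspace_slice(k$data + matrix(noise, nrow(k$data)), k$geometry)
}

#' Inject a radio-frequency spike at one k-space location
#'
#' Adds a complex amplitude at the given offset from DC. The reconstruction
#' gains a superposed plane-wave ("corduroy") stripe whose integer cycle
#' counts across the image equal the spike's offset.
#'
#' @param k a `kspace_slice`.
#' @param location integer 2-vector: (freq, phase) offset from DC in cycles
#'   per field of view.
#' @param amplitude complex spike amplitude.
#' @return a `kspace_slice`.
#' @export
add_spike <- function(k, location, amplitude) {
  stopifnot(inherits(k, "kspace_slice"))
  nf <- nrow(k$data); np <- ncol(k$data)
  i <- dc_index(nf) + location[1]
  j <- dc_index(np) + location[2]
  if (i < 1 || i > nf || j < 1 || j > np)
    abort_invalid(sprintf("spike offset (%d, %d) outside the %d x %d matrix",
                          location[1], location[2], nf, np))
  out <- k$data
  out[i, j] <- out[i, j] + amplitude
  kspace_slice(out, k$geometry)
}

#' Apply periodic-motion phase modulation (ghosting)
#'
#' Models rigid in-plane translation along the frequency axis that follows a
#' sinusoid over the phase-encoding loop: line `j` acquires the linear phase
#' `exp(-2i * pi * k_f * d_j)` with
#' `d_j = amplitude * sin(2 * pi * (j - 1) / period)`. A motion period of
#' `p` lines replicates the object into ghosts displaced along phase by
#' multiples of `matrix_phase / p` pixels.
#'
#' @param k a `kspace_slice`.
#' @param amplitude_mm peak displacement, mm (0 returns the input).
#' @param period_lines motion period in phase-encode lines (>= 2).
#' @param geometry a `plan_geometry` supplying the frequency field of view
#'   (defaults to the slice's own geometry).
#' @return a `kspace_slice`.
#' @export
add_motion <- function(k, amplitude_mm, period_lines, geometry = k$geometry) {
  stopifnot(inherits(k, "kspace_slice"))
  if (!is_scalar_number(period_lines) || period_lines < 2)
    abort_invalid("period_lines must be >= 2")
  if (!is_scalar_number(amplitude_mm) || amplitude_mm < 0)
    abort_invalid("amplitude_mm must be >= 0")
  if (amplitude_mm == 0) return(k)
  if (is.null(geometry)) abort_invalid("geometry needed to express k_f in 1/mm")
  nf <- nrow(k$data); np <- ncol(k$data)
  kf <- (seq_len(nf) - dc_index(nf)) / geometry$fov_freq     # cycles / mm
  d <- amplitude_mm * sin(2 * pi * (seq_len(np) - 1) / period_lines)
  mod <- exp(-2i * pi * outer(kf, d))
  kspace_slice(k$data * mod, k$geometry)
}

# per-line echo times of a linear-ordered FSE echo train, centre lines at
# the echo closest to TE; returns a length-np vector of times (ms)
fse_line_times <- function(np, te, etl, echo_spacing) {
  lines_per_echo <- ceiling(np / etl)
  block <- (seq_len(np) - 1) %/% lines_per_echo          # 0-based echo block
  b_dc <- block[dc_index(np)]
  n_star <- min(max(round(te / echo_spacing), 1), etl)   # echo closest to TE
  echo_no <- ((block - b_dc + (n_star - 1)) %% etl) + 1
  pmax(te + (echo_no - n_star) * echo_spacing, 0)
}

#' Apply fast-spin-echo echo-train attenuation as a k-space filter
#'
#' Each phase-encode line is attenuated by `exp(-t_j / t2_eff)` where `t_j`
#' is the echo time at which the line is acquired under linear echo-train
#' ordering with the centre lines collected at the echo closest to TE, and
#' `t2_eff` is the proton-density-weighted mean T2 of the slice. With
#' `etl = 1` every line carries the same factor `exp(-te / t2_eff)` — a pure
#' global scale that leaves contrast untouched; with longer trains the
#' line-dependent decay blurs the point-spread function along phase.
#'
#' @param k a `kspace_slice`.
#' @param resliced_slice one slice entry of a `resliced_stack` (needs `pd`
#'   and `t2`).
#' @param seq a `sequence_params` with `family = "FSE"`.
#' @return a `kspace_slice`.
#' @export
apply_etl_attenuation <- function(k, resliced_slice, seq) {
  stopifnot(inherits(k, "kspace_slice"))
  if (!inherits(seq, "sequence_params") || seq$family != "FSE")
    abort_invalid("apply_etl_attenuation requires an FSE sequence")
  np <- ncol(k$data)
  w <- as.vector(resliced_slice$pd)
  t2_eff <- if (sum(w) > 0) sum(w * as.vector(resliced_slice$t2)) / sum(w)
            else Inf
  times <- fse_line_times(np, seq$te, seq$etl, seq$echo_spacing)
  scale <- exp(-times / t2_eff)
  kspace_slice(sweep(k$data, 2, scale, `*`), k$geometry)
}

#' Partial-Fourier (half-Fourier) reconstruction
#'
#' Keeps the first `ceiling(fraction * matrix_phase) + overscan` phase-encode
#' lines (counted from the most negative phase frequency) and synthesises
#' the missing lines by Hermitian conjugation of their acquired mirror
#' lines, then inverse transforms. No phase correction is applied: for a
#' real (zero-phase) image the fill is exact, while any image phase leaves a
#' visible reconstruction error — which is the teaching point.
#'
#' @param k a `kspace_slice`.
#' @param fraction acquired fraction of phase lines, in (0.5, 1\]. A
#'   fraction of 1 reproduces [inverse_recon()] exactly.
#' @param overscan extra acquired lines beyond the nominal fraction.
#' @return real magnitude image.
#' @export
half_fourier_recon <- function(k, fraction, overscan = 0L) {
  stopifnot(inherits(k, "kspace_slice"))
  if (!is_scalar_number(fraction) || fraction <= 0.5 || fraction > 1)
    abort_invalid("fraction must lie in (0.5, 1]")
  nf <- nrow(k$data); np <- ncol(k$data)
  n_keep <- min(np, as.integer(ceiling(fraction * np)) + as.integer(overscan))
  if (n_keep == np) return(inverse_recon(k))
  ku <- ifftshift2(k$data)               # unshifted grid: DC at [1, 1]
  # stored (centred) column j corresponds to unshifted column:
  cols_unshifted <- ifftshift2(matrix(rep(seq_len(np), each = nf), nf))[1, ]
  missing_u <- cols_unshifted[(n_keep + 1):np]
  neg <- function(v, n) ((n - (v - 1)) %% n) + 1   # index of -frequency
  negu_rows <- neg(seq_len(nf), nf)
  for (v in missing_u) ku[, v] <- Conj(ku[negu_rows, neg(v, np)])
  Mod(stats::fft(ku, inverse = TRUE) / sqrt(length(ku)))
}

#' Fold or crop a phase-oversampled image to the nominal field of view
#'
#' When the no-phase-wrap option is off (`mode = "fold"`), tissue outside
#' the nominal phase field of view aliases back in: the oversampled extent
#' is folded by periodic summation,
#' `I_out(p) = sum_m I_over(p + m * matrix_phase)`, aligned on the image
#' centre. With no-phase-wrap on (`mode = "crop"`) the oversampled
#' reconstruction is simply centre-cropped, and no replica appears.
#'
#' @param image real matrix on the oversampled (freq x phase) grid.
#' @param geometry the `plan_geometry` defining the nominal phase matrix.
#' @param mode `"fold"` (simulate wrap-around) or `"crop"` (no phase wrap).
#' @return matrix with `matrix_phase` phase columns.
#' @export
apply_wraparound <- function(image, geometry, mode = c("fold", "crop")) {
  mode <- match.arg(mode)
  np <- geometry$matrix_phase
  n_over <- ncol(image)
  if (n_over < np)
    abort_invalid("image has fewer phase samples than the nominal matrix")
  if (n_over == np) return(image)
  shift <- dc_index(n_over) - dc_index(np)
  if (mode == "crop") return(image[, shift + seq_len(np), drop = FALSE])
  out <- matrix(0, nrow(image), np)
  for (j in seq_len(n_over)) {
    p <- ((j - shift - 1) %% np) + 1
    out[, p] <- out[, p] + image[, j]
  }
  out
}

#' Artifact and k-space manipulation configuration
#'
#' Bundles the trainer-facing artifact toggles applied to each slice of one
#' acquisition, in the fixed order: echo-train attenuation, motion, spikes,
#' thermal noise, then partial-Fourier / wrap handling at reconstruction.
#'
#' @param thermal_sigma k-space noise scale (>= 0).
#' @param spikes list of `list(location = c(kf, kp), amplitude = z)` entries.
#' @param motion `NULL` or `list(amplitude_mm =, period_lines =)`.
#' @param half_fourier `NULL` (off) or
#'   `list(fraction = f, overscan = 0)` with `f` in (0.5, 1\].
#' @param wraparound_on simulate phase wrap (fold) instead of cropping the
#'   oversampled field of view.
#' @return an object of class `artifact_config`.
#' @export
artifact_config <- function(thermal_sigma = 0, spikes = list(), motion = NULL,
                            half_fourier = NULL, wraparound_on = FALSE) {
  if (!is_scalar_number(thermal_sigma) || thermal_sigma < 0)
    abort_invalid("thermal_sigma must be >= 0")
  if (!is.null(motion)) {
    if (is.null(motion$amplitude_mm) || is.null(motion$period_lines) ||
        motion$period_lines < 2)
      abort_invalid("motion needs amplitude_mm and period_lines >= 2")
  }
  if (!is.null(half_fourier)) {
    if (is.null(half_fourier$fraction) || half_fourier$fraction <= 0.5 ||
        half_fourier$fraction > 1)
      abort_invalid("half_fourier fraction must lie in (0.5, 1]")
    if (is.null(half_fourier$overscan)) half_fourier$overscan <- 0L
  }
  for (sp in spikes)
    if (is.null(sp$location) || length(sp$location) != 2L ||
        is.null(sp$amplitude))
      abort_invalid("each spike needs a 2-vector location and an amplitude")
  structure(list(thermal_sigma = thermal_sigma, spikes = spikes,
                 motion = motion, half_fourier = half_fourier,
                 wraparound_on = isTRUE(wraparound_on)),
            class = "artifact_config")
}
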