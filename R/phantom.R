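#' Tissue specification for phantom construction
#'
#' A tissue is a geometric primitive filled with homogeneous MR properties:
#' proton density `pd` (dimensionless, in \[0, 1\]), longitudinal relaxation
#' time `t1` and transverse relaxation time `t2` (both milliseconds). A
#' pathology is modelled simply as one more tissue painted over the
#' anatomy it replaces.
#'
#' @param name tissue label.
#' @param pd proton density in \[0, 1\].
#' @param t1,t2 relaxation times in ms; `t2 <= t1` is enforced.
#' @param shape one of `"ellipsoid"`, `"box"`, `"slab"`.
#' @param centre 3-vector, mm.
#' @param semi_axes 3-vector of ellipsoid semi-axes / box half-sizes, mm.
#'   For a slab only the third component (half-thickness) is used.
#' @param rotation Euler angles (degrees) applied about the world z, y, x
#'   axes in that order.
#' @return an object of class `tissue_spec`.
#' @export
#' @examples
#' tissue_spec("white matter", pd = 0.7, t1 = 600, t2 = 80,
#'             centre = c(0, 0, 0), semi_axes = c(60, 80, 50))
tissue_spec <- function(name, pd, t1, t2, shape = "ellipsoid",
                        centre = c(0, 0, 0), semi_axes = c(1, 1, 1),
                        rotation = c(0, 0, 0)) {
  stopifnot_scalar(pd, "pd", 0, 1)
  stopifnot_scalar(t1, "t1", 0, strict_lower = TRUE)
  stopifnot_scalar(t2, "t2", 0, strict_lower = TRUE)
  if (t2 > t1) abort_invalid(sprintf("tissue '%s': t2 (%g) exceeds t1 (%g)",
                                     name, t2, t1))
  shape <- match.arg(shape, c("ellipsoid", "box", "slab"))
  if (length(centre) != 3L || length(semi_axes) != 3L || length(rotation) != 3L)
    abort_invalid("centre, semi_axes and rotation must be 3-vectors")
  if (any(semi_axes <= 0)) abort_invalid("semi_axes must be positive")
  structure(list(name = name, pd = pd, t1 = t1, t2 = t2, shape = shape,
                 centre = as.numeric(centre), semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation)),
            class = "tissue_spec")
}

euler_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# world coordinates (n x 3) of all voxel centres of a grid
grid_world_coords <- function(dim, spacing, origin, orientation) {
  idx <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1,
                               j = seq_len(dim[2]) - 1,
                               k = seq_len(dim[3]) - 1))
  sweep(idx %*% diag(spacing) %*% t(orientation), 2, origin, `+`)
}

inside_shape <- function(spec, world) {
  local <- sweep(world, 2, spec$centre) %*% euler_matrix(spec$rotation)
  switch(spec$shape,
    ellipsoid = rowSums(sweep(local, 2, spec$semi_axes, `/`)^2) <= 1,
    box = abs(local[, 1]) <= spec$semi_axes[1] &
          abs(local[, 2]) <= spec$semi_axes[2] &
          abs(local[, 3]) <= spec$semi_axes[3],
    slab = abs(local[, 3]) <= spec$semi_axes[3])
}

#' Construct an anatomical tissue-property model
#'
#' Builds co-registered 3-D proton-density, T1 and T2 volumes (plus an
#' integer tissue-label volume) from a list of geometric tissue primitives.
#' Later tissues overwrite earlier ones where their shapes overlap, so a
#' lesion listed last simply replaces the healthy tissue it sits in.
#'
#' @param tissues non-empty list of [tissue_spec()] objects.
#' @param dim integer 3-vector of grid dimensions (each `>= 8`).
#' @param spacing voxel spacing, mm (positive 3-vector).
#' @param origin world coordinate of voxel (0, 0, 0), mm. Defaults to placing
#'   the grid centre at the world origin.
#' @param orientation 3x3 orthonormal direction matrix (columns are the world
#'   directions of the voxel axes).
#' @param jitter relative amplitude of optional multiplicative proton-density
#'   texture (0 disables; values are re-clipped to \[0, 1\]).
#' @param seed integer seed; only consumed by the texture jitter, so the
#'   phantom is bit-reproducible given `(tissues, grid, seed)`.
#' @return an `anatomical_model`: list of `pd`, `t1`, `t2`, `delta_b0`,
#'   `labels` arrays plus `spacing`, `origin`, `orientation`.
#' @export
#' @examples
#' m <- build_phantom(list(
#'   tissue_spec("csf", 1.0, 4000, 2000, semi_axes = c(20, 25, 18))),
#'   dim = c(32, 32, 32), spacing = c(4, 4, 4))
#' range(m$pd)
build_phantom <- function(tissues, dim = c(64, 64, 64), spacing = c(3, 3, 3),
                          origin = NULL, orientation = diag(3),
                          jitter = 0, seed = 1L) {
  if (!length(tissues)) abort_invalid("tissue list must be non-empty")
  if (inherits(tissues, "tissue_spec")) tissues <- list(tissues)
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 8L))
    abort_invalid("grid dimensions must be a 3-vector with every axis >= 8")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_invalid("spacing must be three positive lengths (mm)")
  check_orientation(orientation)
  if (is.null(origin)) origin <- -orientation %*% ((dim - 1) / 2 * spacing)
  origin <- as.numeric(origin)

  world <- grid_world_coords(dim, spacing, origin, orientation)
  pd <- t1 <- t2 <- rep(0, nrow(world))
  t1[] <- 1; t2[] <- 1  # positive sentinel where no tissue (pd = 0)
  labels <- rep(0L, nrow(world))
  for (i in seq_along(tissues)) {
    sp <- tissues[[i]]
    if (!inherits(sp, "tissue_spec")) abort_invalid("tissues must be tissue_spec objects")
    m <- inside_shape(sp, world)
    pd[m] <- sp$pd; t1[m] <- sp$t1; t2[m] <- sp$t2; labels[m] <- i
  }
  if (jitter > 0) {
    set.seed(derive_seed(seed, "phantom/texture"))
    pd <- pmin(1, pmax(0, pd * (1 + jitter * stats::rnorm(length(pd)))))
  }
  model <- structure(list(
    pd = array(pd, dim), t1 = array(t1, dim), t2 = array(t2, dim),
    delta_b0 = array(0, dim), labels = array(labels, dim),
    spacing = as.numeric(spacing), origin = origin,
    orientation = orientation), class = "anatomical_model")
  validate_anatomical_model(model)
  model
}

check_orientation <- function(orientation) {
  if (!is.matrix(orientation) || any(dim(orientation) != 3L) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-9 ||
      abs(abs(det(orientation)) - 1) > 1e-9)
    abort_invalid("orientation must be a 3x3 orthonormal matrix")
  invisible(orientation)
}

#' Validate the invariants of an anatomical model
#'
#' Checks that all component volumes share one grid, that proton density is
#' within \[0, 1\], that relaxation times are positive with `t2 <= t1`
#' wherever tissue is present, and that the direction matrix is orthonormal.
#'
#' @param model an `anatomical_model`.
#' @return the model, invisibly; an error describes the first violation.
#' @export
validate_anatomical_model <- function(model) {
  if (!inherits(model, "anatomical_model")) abort_invalid("not an anatomical_model")
  d <- dim(model$pd)
  for (comp in c("t1", "t2", "delta_b0", "labels")) {
    v <- model[[comp]]
    if (!is.null(v) && !identical(dim(v), d))
      abort_invalid(sprintf("component '%s' grid differs from pd grid", comp),
                    class = "mrisim_format_error")
  }
  if (min(model$pd) < -1e-12 || max(model$pd) > 1 + 1e-12)
    abort_invalid("pd outside [0, 1]")
  tissue <- model$pd > 0
  if (any(model$t1[tissue] <= 0) || any(model$t2[tissue] <= 0))
    abort_invalid("t1 and t2 must be positive wherever pd > 0")
  if (any(model$t2[tissue] > model$t1[tissue] + 1e-12))
    abort_invalid("t2 > t1 detected inside tissue")
  if (length(model$spacing) != 3L || any(model$spacing <= 0))
    abort_invalid("spacing must be three positive lengths")
  check_orientation(model$orientation)
  invisible(model)
}

#' @export
print.anatomical_model <- function(x, ...) {
  d <- dim(x$pd)
  cat(sprintf("anatomical_model: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  pd range [%.3g, %.3g]; %d tissue labels; max |dB0| = %.3g ppm\n",
              min(x$pd), max(x$pd), length(setdiff(unique(as.vector(x$labels)), 0L)),
              max(abs(x$delta_b0))))
  invisible(x)
}

#' Default head-like demonstration phantom
#'
#' Nested ellipsoids with literature-typical 1.5 T relaxation values:
#' an outer scalp-fat shell, a CSF-filled skull interior, and deeper
#' grey-/white-matter ellipsoids. Intended as a convenient, recognisable
#' test object, not as an anatomical atlas.
#'
#' @inheritParams build_phantom
#' @return an `anatomical_model`.
#' @export
head_phantom <- function(dim = c(64, 64, 64), spacing = c(3.5, 3.5, 3.5),
                         seed = 1L) {
  tissues <- list(
    tissue_spec("scalp fat", 0.9, 260, 80, semi_axes = c(88, 104, 92)),
    tissue_spec("csf", 1.0, 4000, 2000, semi_axes = c(80, 96, 84)),
    tissue_spec("grey matter", 0.85, 900, 100, semi_axes = c(72, 88, 76)),
    tissue_spec("white matter", 0.7, 600, 80, semi_axes = c(52, 64, 56)),
    tissue_spec("ventricle csf", 1.0, 4000, 2000,
                semi_axes = c(14, 30, 12), centre = c(0, 8, 6)))
  build_phantom(tissues, dim = dim, spacing = spacing, seed = seed)
}

#' Synthesize a smooth main-field (B0) inhomogeneity map
#'
#' White Gaussian noise is low-pass filtered with an isotropic Gaussian
#' kernel of the requested correlation length and then rescaled so its
#' maximum absolute value equals `amplitude_ppm`. The field only needs to be
#' smooth and reproducible: it exists to demonstrate the consequences of an
#' unshimmed magnet, not to model a specific magnet.
#'
#' @param dim integer 3-vector of grid dimensions.
#' @param spacing voxel spacing, mm.
#' @param amplitude_ppm peak absolute field offset, parts per million (>= 0).
#' @param smoothness correlation length of the field, mm.
#' @param seed integer seed; the field is deterministic given it.
#' @return a 3-D array in ppm with `max(abs(.)) == amplitude_ppm`.
#' @export
make_b0_perturbation <- function(dim, spacing = c(1, 1, 1), amplitude_ppm = 1,
                                 smoothness = 20, seed = 1L) {
  if (!is_scalar_number(amplitude_ppm) || amplitude_ppm < 0)
    abort_invalid("amplitude_ppm must be >= 0")
  dim <- as.integer(dim)
  if (amplitude_ppm == 0) return(array(0, dim))
  set.seed(derive_seed(seed, "b0"))
  noise <- array(stats::rnorm(prod(dim)), dim)
  # circular Gaussian smoothing via FFT with a separable kernel;
  # sigma in voxels per axis
  sig <- rep_len(smoothness / spacing, 3)
  gax <- lapply(1:3, function(ax) {
    x <- seq_len(dim[ax]) - 1
    x <- pmin(x, dim[ax] - x)           # circular distance
    g <- exp(-0.5 * (x / max(sig[ax], 1e-6))^2)
    g / sum(g)
  })
  kern <- array(outer(outer(gax[[1]], gax[[2]]), gax[[3]]), dim)
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    prod(dim)
  sm * (amplitude_ppm / max(abs(sm)))
}
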