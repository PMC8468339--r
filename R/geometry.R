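#' Geometric prescription of one acquisition
#'
#' Captures everything a scanner console would record about slice geometry:
#' the orthonormal frequency/phase/slice axis triad, in-plane field of view
#' and matrix, slice thickness and centre-to-centre separation, number of
#' slices, stack centre, and the phase-oversampling factor used by the
#' no-phase-wrap option.
#'
#' Pixel (i, j) of slice s (1-based) is centred at world coordinate
#' `centre + ((i - 0.5)/Nf - 0.5) * fov_f * freq_axis
#'         + ((j - 0.5)/Np - 0.5) * fov_p * phase_axis
#'         + (s - 1 - (n_slices - 1)/2) * slice_separation * slice_axis`,
#' where for an oversampled plan `Np` and `fov_p` are the oversampled values
#' (pixel size is preserved; extra field of view is added symmetrically).
#'
#' @param freq_axis,phase_axis,slice_axis unit 3-vectors forming an
#'   orthonormal triad (checked to 1e-9).
#' @param fov_freq,fov_phase in-plane field of view, mm.
#' @param matrix_freq,matrix_phase acquisition matrix.
#' @param slice_thickness excited slab thickness, mm.
#' @param slice_separation centre-to-centre slice distance, mm (overlap
#'   allowed, must be positive).
#' @param n_slices number of slices.
#' @param centre stack centre, world mm.
#' @param phase_oversampling factor `>= 1`; values above 1 extend the phase
#'   field of view for wrap-free acquisition.
#' @return an object of class `plan_geometry`.
#' @export
plan_geometry <- function(freq_axis, phase_axis, slice_axis,
                          fov_freq, fov_phase, matrix_freq, matrix_phase,
                          slice_thickness, slice_separation = slice_thickness,
                          n_slices = 1L, centre = c(0, 0, 0),
                          phase_oversampling = 1) {
  axes <- cbind(as.numeric(freq_axis), as.numeric(phase_axis),
                as.numeric(slice_axis))
  if (nrow(axes) != 3L || max(abs(crossprod(axes) - diag(3))) > 1e-9)
    abort_invalid("freq/phase/slice axes must be an orthonormal triad")
  for (nm in c("fov_freq", "fov_phase", "slice_thickness", "slice_separation"))
    stopifnot_scalar(get(nm), nm, 0, strict_lower = TRUE)
  matrix_freq <- as.integer(matrix_freq); matrix_phase <- as.integer(matrix_phase)
  n_slices <- as.integer(n_slices)
  if (matrix_freq < 1L || matrix_phase < 1L || n_slices < 1L)
    abort_invalid("matrix sizes and n_slices must be positive integers")
  stopifnot_scalar(phase_oversampling, "phase_oversampling", 1)
  structure(list(freq_axis = axes[, 1], phase_axis = axes[, 2],
                 slice_axis = axes[, 3],
                 fov_freq = fov_freq, fov_phase = fov_phase,
                 matrix_freq = matrix_freq, matrix_phase = matrix_phase,
                 slice_thickness = slice_thickness,
                 slice_separation = slice_separation,
                 n_slices = n_slices, centre = as.numeric(centre),
                 phase_oversampling = phase_oversampling),
            class = "plan_geometry")
}

#' @export
print.plan_geometry <- function(x, ...) {
  cat(sprintf(
    "plan_geometry: %d x %d matrix, FOV %g x %g mm, %d slice(s) %g/%g mm\n",
    x$matrix_freq, x$matrix_phase, x$fov_freq, x$fov_phase, x$n_slices,
    x$slice_thickness, x$slice_separation))
  cat(sprintf("  centre (%s) mm, phase oversampling %.2f\n",
              paste(signif(x$centre, 4), collapse = ", "),
              x$phase_oversampling))
  invisible(x)
}

# effective (oversampled) phase matrix and field of view
effective_phase <- function(geom) {
  np <- as.integer(round(geom$matrix_phase * geom$phase_oversampling))
  list(matrix = np, fov = geom$fov_phase * np / geom$matrix_phase)
}

# world coordinates (n x 3 matrix) of every pixel centre of slice s,
# fastest along frequency, on the (possibly oversampled) grid
slice_world_coords <- function(geom, s, oversampled = TRUE) {
  nf <- geom$matrix_freq
  ph <- if (oversampled) effective_phase(geom)
        else list(matrix = geom$matrix_phase, fov = geom$fov_phase)
  uf <- ((seq_len(nf) - 0.5) / nf - 0.5) * geom$fov_freq
  up <- ((seq_len(ph$matrix) - 0.5) / ph$matrix - 0.5) * ph$fov
  us <- (s - 1 - (geom$n_slices - 1) / 2) * geom$slice_separation
  grid <- expand.grid(f = uf, p = up)
  sweep(cbind(grid$f, grid$p) %*% t(cbind(geom$freq_axis, geom$phase_axis)),
        2, geom$centre + us * geom$slice_axis, `+`)
}

#' Canonical axial/sagittal/coronal plan centred on a model
#'
#' Builds the standard orthogonal prescriptions expressed in the model's own
#' direction axes: axial slices select along the model's third axis, coronal
#' along the second, sagittal along the first. By default the frequency axis
#' is assigned to the longer in-plane anatomical extent; pass
#' `swap_encoding = TRUE` to flip the phase/frequency assignment.
#'
#' @param kind `"axial"`, `"sagittal"` or `"coronal"`.
#' @param model an `anatomical_model` supplying centre and axes.
#' @param matrix length-1 or length-2 acquisition matrix (freq, phase).
#' @param fov length-1 or length-2 field of view, mm.
#' @param thickness,separation slice thickness / separation, mm.
#' @param n_slices number of slices.
#' @param swap_encoding flip the default phase/frequency assignment.
#' @param phase_oversampling see [plan_geometry()].
#' @return a `plan_geometry`.
#' @export
canonical_plan <- function(kind, model, matrix = 128, fov = 240,
                           thickness = 5, separation = thickness,
                           n_slices = 1L, swap_encoding = FALSE,
                           phase_oversampling = 1) {
  kind <- match.arg(kind, c("axial", "sagittal", "coronal"))
  matrix <- rep_len(matrix, 2); fov <- rep_len(fov, 2)
  ax <- model$orientation
  d <- dim(model$pd)
  centre <- as.numeric(model$origin + ax %*% ((d - 1) / 2 * model$spacing))
  inplane <- switch(kind, axial = c(1L, 2L), coronal = c(1L, 3L),
                    sagittal = c(2L, 3L))
  slice_ax <- setdiff(1:3, inplane)
  extents <- d * model$spacing
  # frequency along the longer anatomical in-plane extent
  if (extents[inplane[1]] < extents[inplane[2]]) inplane <- rev(inplane)
  if (swap_encoding) inplane <- rev(inplane)
  plan_geometry(ax[, inplane[1]], ax[, inplane[2]], ax[, slice_ax],
                fov_freq = fov[1], fov_phase = fov[2],
                matrix_freq = matrix[1], matrix_phase = matrix[2],
                slice_thickness = thickness, slice_separation = separation,
                n_slices = n_slices, centre = centre,
                phase_oversampling = phase_oversampling)
}

# vectorised trilinear interpolation of several co-registered volumes at
# continuous 0-based voxel indices (n x 3). Corner weights are computed
# once and shared across volumes; outside the grid each volume returns its
# own fill value. Returns a list parallel to `vols`.
trilinear_multi <- function(vols, idx, fills) {
  d <- dim(vols[[1]])
  if (any(d < 2)) abort_invalid("volume must have at least 2 voxels per axis")
  eps <- 1e-9
  out_mask <- idx[, 1] < -eps | idx[, 1] > d[1] - 1 + eps |
              idx[, 2] < -eps | idx[, 2] > d[2] - 1 + eps |
              idx[, 3] < -eps | idx[, 3] > d[3] - 1 + eps
  ix <- pmin(pmax(idx[, 1], 0), d[1] - 1)
  iy <- pmin(pmax(idx[, 2], 0), d[2] - 1)
  iz <- pmin(pmax(idx[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(ix), d[1] - 2); y0 <- pmin(floor(iy), d[2] - 2)
  z0 <- pmin(floor(iz), d[3] - 2)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  base <- x0 + d[1] * (y0 + d[2] * z0) + 1    # linear index of corner 000
  o100 <- 1; o010 <- d[1]; o001 <- d[1] * d[2]
  w000 <- (1 - fx) * (1 - fy) * (1 - fz); w100 <- fx * (1 - fy) * (1 - fz)
  w010 <- (1 - fx) * fy * (1 - fz);       w110 <- fx * fy * (1 - fz)
  w001 <- (1 - fx) * (1 - fy) * fz;       w101 <- fx * (1 - fy) * fz
  w011 <- (1 - fx) * fy * fz;             w111 <- fx * fy * fz
  lapply(seq_along(vols), function(vi) {
    A <- vols[[vi]]
    # uniform volumes (e.g. an all-zero field map) need no interpolation
    if (A[1] == A[length(A)] && !any(A != A[1])) {
      v <- rep(A[1], nrow(idx)); v[out_mask] <- fills[vi]; return(v)
    }
    v <- A[base] * w000 + A[base + o100] * w100 +
         A[base + o010] * w010 + A[base + o100 + o010] * w110 +
         A[base + o001] * w001 + A[base + o100 + o001] * w101 +
         A[base + o010 + o001] * w011 + A[base + o100 + o010 + o001] * w111
    v[out_mask] <- fills[vi]
    v
  })
}

trilinear <- function(A, idx, fill = 0) {
  trilinear_multi(list(A), idx, fill)[[1]]
}

# nearest-neighbour lookup for label volumes
nearest <- function(A, idx, fill = 0L) {
  d <- dim(A)
  eps <- 1e-9
  out_mask <- idx[, 1] < -eps | idx[, 1] > d[1] - 1 + eps |
              idx[, 2] < -eps | idx[, 2] > d[2] - 1 + eps |
              idx[, 3] < -eps | idx[, 3] > d[3] - 1 + eps
  ii <- pmin(pmax(round(idx), 0), rep(d - 1, each = nrow(idx)))
  v <- A[ii + 1]
  v[out_mask] <- fill
  v
}

#' Reslice an anatomical model onto a planned acquisition grid
#'
#' Resamples the tissue-property volumes at every pixel of the prescribed
#' stack. Each output value is the through-slice average of `n_sub`
#' equispaced sub-planes across the slice thickness (midpoint-centred) of
#' trilinear interpolation at the pixel's world coordinate; labels use
#' nearest-neighbour from the central sub-plane. Coordinates outside the
#' model map to 0 for proton density and field offset and to a 1 ms sentinel
#' for T1/T2, so a zero-proton-density voxel never divides by zero
#' downstream.
#'
#' @param model an `anatomical_model`.
#' @param geom a `plan_geometry`.
#' @param n_sub number of through-slice sub-planes (default 5; 1 gives pure
#'   in-plane sampling).
#' @return a `resliced_stack`: per-slice lists of `pd`, `t1`, `t2`,
#'   `delta_b0` matrices on the (freq x oversampled-phase) grid, plus
#'   `labels` and the geometry.
#' @export
reslice <- function(model, geom, n_sub = 5L) {
  validate_anatomical_model(model)
  if (!inherits(geom, "plan_geometry")) abort_invalid("geom must be a plan_geometry")
  n_sub <- as.integer(n_sub)
  if (n_sub < 1L) abort_invalid("n_sub must be >= 1")
  nf <- geom$matrix_freq
  np <- effective_phase(geom)$matrix
  # world -> continuous voxel index transform
  w2i <- diag(1 / model$spacing) %*% t(model$orientation)
  sub_off <- ((seq_len(n_sub) - 0.5) / n_sub - 0.5) * geom$slice_thickness
  npix <- nf * np
  vols <- list(model$pd, model$t1, model$t2, model$delta_b0)
  fills <- c(0, 1, 1, 0)
  slices <- vector("list", geom$n_slices)
  for (s in seq_len(geom$n_slices)) {
    base <- slice_world_coords(geom, s)
    # all sub-planes of this slice in one interpolation batch
    idx <- do.call(rbind, lapply(sub_off, function(off)
      sweep(sweep(base, 2, off * geom$slice_axis, `+`), 2, model$origin) %*%
        t(w2i)))
    vals <- trilinear_multi(vols, idx, fills)
    sub_mean <- function(v) matrix(rowMeans(matrix(v, npix, n_sub)), nf, np)
    mid <- sweep(base, 2, model$origin) %*% t(w2i)
    slices[[s]] <- list(
      pd = sub_mean(vals[[1]]), t1 = sub_mean(vals[[2]]),
      t2 = sub_mean(vals[[3]]), delta_b0 = sub_mean(vals[[4]]),
      labels = if (is.null(model$labels)) NULL
               else matrix(nearest(model$labels, mid), nf, np))
  }
  structure(list(slices = slices, geometry = geom, n_sub = n_sub),
            class = "resliced_stack")
}

#' @export
print.resliced_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("resliced_stack: %d slice(s) of %d x %d (freq x phase incl. oversampling)\n",
              length(x$slices), nrow(x$slices[[1]]$pd), ncol(x$slices[[1]]$pd)))
  invisible(x)
}
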