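# Shared fixtures, built in code at test time.

# two nested ellipsoids on a small grid: outer grey-matter-like shell,
# inner CSF-like core
two_tissue_phantom <- function(dim = c(32, 32, 32), spacing = c(7, 7, 7)) {
  build_phantom(list(
    tissue_spec("outer", 0.7, 900, 90, semi_axes = c(90, 90, 90)),
    tissue_spec("inner", 1.0, 4000, 2000, semi_axes = c(45, 45, 45))),
    dim = dim, spacing = spacing)
}

# a single homogeneous ellipsoid
uniform_phantom <- function(pd = 0.8, t1 = 900, t2 = 90,
                            dim = c(32, 32, 32), spacing = c(7, 7, 7)) {
  build_phantom(list(
    tissue_spec("tissue", pd, t1, t2, semi_axes = c(95, 95, 95))),
    dim = dim, spacing = spacing)
}

# identity-resampling plan for a model: axes = model orientation, matrix =
# grid size, fov = grid extent, one slice per voxel plane
identity_plan <- function(model) {
  d <- dim(model$pd); sp <- model$spacing
  centre <- as.numeric(model$origin +
    model$orientation %*% ((d - 1) / 2 * sp))
  plan_geometry(model$orientation[, 1], model$orientation[, 2],
                model$orientation[, 3],
                fov_freq = d[1] * sp[1], fov_phase = d[2] * sp[2],
                matrix_freq = d[1], matrix_phase = d[2],
                slice_thickness = sp[3], slice_separation = sp[3],
                n_slices = d[3], centre = centre)
}

simple_geometry <- function(nf = 64, np = 64, fov = 256, n_slices = 1,
                            oversampling = 1) {
  plan_geometry(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), fov, fov, nf, np,
                slice_thickness = 5, n_slices = n_slices,
                phase_oversampling = oversampling)
}

# a point object k-space slice on an nf x np grid
point_kspace <- function(nf = 128, np = 128, fov = 256) {
  img <- matrix(0, nf, np)
  img[floor(nf / 2) + 1, floor(np / 2) + 1] <- 1
  forward_kspace(img, simple_geometry(nf, np, fov))
}

# random small binary item matrix with non-degenerate totals
random_binary_matrix <- function(n = 12, k = 5) {
  repeat {
    m <- matrix(rbinom(n * k, 1, runif(1, 0.3, 0.7)), n, k)
    ok <- tryCatch({ kr20(m); TRUE }, error = function(e) FALSE)
    if (ok) return(m)
  }
}
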