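#' Assemble an acquisition protocol
#'
#' A protocol is an ordered list of named entries, each pairing a geometric
#' prescription with sequence parameters, an artifact configuration and an
#' optional list of saturation bands — the unit a trainer prepares and a
#' trainee executes.
#'
#' @param name protocol name.
#' @param entries list of entries; each entry is a list with fields `name`,
#'   `geometry` (`plan_geometry`), `sequence` (`sequence_params`),
#'   `artifacts` (`artifact_config`, optional) and `bands` (list of
#'   `saturation_band`, optional).
#' @param coil a [coil_profile()].
#' @param patient_position recorded into output provenance; does not alter
#'   the physics.
#' @return an object of class `mri_protocol`.
#' @export
mri_protocol <- function(name, entries, coil = coil_profile("homogeneous"),
                         patient_position = "head_first_supine") {
  if (!length(entries)) abort_invalid("protocol must contain at least one entry")
  nms <- vapply(entries, function(e) e$name %||% "", "")
  if (any(nms == "")) abort_invalid("every protocol entry needs a name")
  if (anyDuplicated(nms)) abort_invalid("entry names must be unique")
  for (e in entries) {
    if (!inherits(e$geometry, "plan_geometry"))
      abort_invalid(sprintf("entry '%s': geometry must be a plan_geometry", e$name))
    if (!inherits(e$sequence, "sequence_params"))
      abort_invalid(sprintf("entry '%s': sequence must be a sequence_params", e$name))
  }
  structure(list(name = name, entries = entries, coil = coil,
                 patient_position = patient_position),
            class = "mri_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mri_protocol <- function(x, ...) {
  cat(sprintf("mri_protocol '%s': %d entr%s, coil %s, position %s\n",
              x$name, length(x$entries),
              if (length(x$entries) == 1) "y" else "ies",
              x$coil$kind, x$patient_position))
  for (e in x$entries)
    cat(sprintf("  - %s: %s %dx%d\n", e$name, e$sequence$family,
                e$geometry$matrix_freq, e$geometry$matrix_phase))
  invisible(x)
}

#' Execute a protocol: the full simulation pipeline
#'
#' For each entry, in order: reslice the model onto the planned grid
#' (including phase oversampling), evaluate sequence contrast with
#' saturation bands and coil weighting, handle phase wrap (fold when the
#' no-phase-wrap option is off, centre-crop otherwise), transform each
#' slice to k-space, apply echo-train attenuation (FSE), motion modulation,
#' spikes and thermal noise, and reconstruct the magnitude image (via
#' partial-Fourier synthesis when configured). Identical
#' `(model, protocol, seed)` always produce bit-identical images: every
#' stochastic stage draws from a sub-seed derived from the root seed and a
#' stage label.
#'
#' @param model an `anatomical_model`.
#' @param protocol an `mri_protocol`.
#' @param seed integer root seed for all stochastic artifact stages.
#' @param n_sub through-slice sub-planes used by [reslice()].
#' @return a `session_result`: per-entry image stacks
#'   (freq x phase x slice arrays), optional k-space magnitude dumps, and a
#'   provenance record sufficient to re-run the session.
#' @export
run_protocol <- function(model, protocol, seed = 1L, n_sub = 5L) {
  validate_anatomical_model(model)
  if (!inherits(protocol, "mri_protocol"))
    abort_invalid("protocol must be an mri_protocol")
  results <- list()
  for (e in protocol$entries) {
    res <- tryCatch(
      run_entry(model, e, protocol$coil, seed, n_sub),
      mrisim_validation_error = function(err) {
        abort_invalid(sprintf("entry '%s': %s", e$name, conditionMessage(err)))
      })
    results[[e$name]] <- res
  }
  structure(list(
    images = lapply(results, `[[`, "image"),
    kspace = lapply(results, `[[`, "kspace"),
    geometries = stats::setNames(lapply(protocol$entries, `[[`, "geometry"),
                                 vapply(protocol$entries, `[[`, "", "name")),
    provenance = list(protocol = protocol$name,
                      patient_position = protocol$patient_position,
                      seed = seed, n_sub = n_sub,
                      entries = vapply(protocol$entries, `[[`, "", "name"),
                      package_version = as.character(utils::packageVersion("mrisim")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "session_result")
}

run_entry <- function(model, entry, coil, seed, n_sub) {
  geom <- entry$geometry
  seqp <- entry$sequence
  art <- entry$artifacts %||% artifact_config()
  bands <- entry$bands %||% list()
  rs <- reslice(model, geom, n_sub = n_sub)
  cs <- contrast_stack(rs, seqp, bands = bands, coil = coil)
  nf <- geom$matrix_freq; np <- geom$matrix_phase
  stack <- array(0, c(nf, np, geom$n_slices))
  kdump <- vector("list", geom$n_slices)
  for (s in seq_len(geom$n_slices)) {
    img <- apply_wraparound(cs$slices[[s]], geom,
                            mode = if (art$wraparound_on) "fold" else "crop")
    k <- forward_kspace(img, geom)
    if (seqp$family == "FSE") {
      # restrict the resliced maps to the nominal phase FOV for t2_eff
      sl <- cs_slice_nominal(rs$slices[[s]], geom, art$wraparound_on)
      k <- apply_etl_attenuation(k, sl, seqp)
    }
    if (!is.null(art$motion))
      k <- add_motion(k, art$motion$amplitude_mm, art$motion$period_lines, geom)
    for (sp in art$spikes) k <- add_spike(k, sp$location, sp$amplitude)
    k <- add_thermal_noise(k, art$thermal_sigma,
                           derive_seed(seed, paste0("noise/", entry$name, "/", s)))
    stack[, , s] <- if (!is.null(art$half_fourier))
      half_fourier_recon(k, art$half_fourier$fraction, art$half_fourier$overscan)
    else inverse_recon(k)
    kdump[[s]] <- Mod(k$data)
  }
  list(image = stack, kspace = kdump)
}

# crop the per-slice property maps to the nominal phase matrix (the fold
# branch also uses the central region; t2_eff is a robust slice average)
cs_slice_nominal <- function(slice, geom, fold) {
  np <- geom$matrix_phase
  shift <- dc_index(ncol(slice$pd)) - dc_index(np)
  idx <- shift + seq_len(np)
  list(pd = slice$pd[, idx, drop = FALSE], t2 = slice$t2[, idx, drop = FALSE])
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("session_result: %d entr%s (seed %d)\n", length(x$images),
              if (length(x$images) == 1) "y" else "ies", x$provenance$seed))
  for (nm in names(x$images)) {
    d <- dim(x$images[[nm]])
    cat(sprintf("  - %s: %d x %d x %d, intensity range [%.4g, %.4g]\n", nm,
                d[1], d[2], d[3], min(x$images[[nm]]), max(x$images[[nm]])))
  }
  invisible(x)
}

#' Write a session's reconstructed stacks and provenance to disk
#'
#' Each entry's magnitude stack is written as NIfTI-1 with the plan's
#' orientation, origin and pixel size in the affine; the provenance record
#' is written as a JSON sidecar. Optionally dumps per-slice k-space
#' magnitude matrices as plain-text tables for teaching displays.
#'
#' @param session a `session_result`.
#' @param dir output directory.
#' @param dump_kspace also write k-space magnitude dumps.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, dump_kspace = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(session$images)) {
    g <- session$geometries[[nm]]
    pix <- c(g$fov_freq / g$matrix_freq, g$fov_phase / g$matrix_phase,
             g$slice_separation)
    orient <- cbind(g$freq_axis, g$phase_axis, g$slice_axis)
    origin <- as.numeric(slice_world_coords(g, 1, oversampled = FALSE)[1, ])
    write_volume(session$images[[nm]],
                 file.path(dir, paste0(nm, ".nii.gz")), pix, origin, orient)
    if (dump_kspace)
      for (s in seq_along(session$kspace[[nm]]))
        utils::write.table(
          session$kspace[[nm]][[s]],
          file.path(dir, sprintf("%s_kspace_slice%02d.txt", nm, s)),
          row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(session$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
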