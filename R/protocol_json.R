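canonical_axes <- function(kind) {
  switch(kind,
    axial = list(f = c(1, 0, 0), p = c(0, 1, 0), s = c(0, 0, 1)),
    coronal = list(f = c(1, 0, 0), p = c(0, 0, 1), s = c(0, 1, 0)),
    sagittal = list(f = c(0, 1, 0), p = c(0, 0, 1), s = c(1, 0, 0)),
    NULL)
}

num_vec <- function(x) as.numeric(unlist(x))

#' Validate and resolve a protocol document
#'
#' Parses a JSON protocol document (path, JSON string, or an already-parsed
#' list), fills documented defaults, normalizes units and constructs the
#' resolved [mri_protocol()]. Problems are *returned*, not raised: on
#' failure the result is a `protocol_errors` object, a character vector of
#' `"json.path: message"` entries covering every problem found.
#'
#' Geometry may be given either as explicit `freq_axis`/`phase_axis`/
#' `slice_axis` unit vectors or as `"orientation": "axial" | "coronal" |
#' "sagittal"` (resolved in world axes). Defaults: matrix 128 x 128, FOV
#' 240 x 240 mm, thickness 5 mm, separation = thickness, 1 slice, centre at
#' the world origin, no oversampling; sequences require `family`, `te`,
#' `tr` plus their family-specific parameters.
#'
#' @param document path to a JSON file, a JSON string, or a list.
#' @return an `mri_protocol`, or a `protocol_errors` character vector.
#' @export
validate_protocol <- function(document) {
  doc <- if (is.character(document) && length(document) == 1L)
    jsonlite::fromJSON(document, simplifyVector = FALSE)
  else document
  errs <- character()
  note <- function(path, msg) errs <<- c(errs, sprintf("%s: %s", path, msg))

  name <- doc$name %||% "unnamed"
  coil <- tryCatch({
    c0 <- doc$coil %||% list(kind = "homogeneous")
    coil_profile(c0$kind %||% "homogeneous",
                 num_vec(c0$reference %||% c(0, 0, 0)),
                 c0$falloff %||% 100)
  }, error = function(e) { note("coil", conditionMessage(e)); NULL })

  if (is.null(doc$entries) || !length(doc$entries)) {
    note("entries", "protocol must contain at least one entry")
    return(structure(errs, class = "protocol_errors"))
  }
  entries <- list()
  for (i in seq_along(doc$entries)) {
    e <- doc$entries[[i]]
    path <- sprintf("entries[%d]", i)
    ename <- e$name %||% sprintf("entry%d", i)
    geom <- resolve_geometry(e$geometry %||% list(), paste0(path, ".geometry"),
                             note)
    seqp <- resolve_sequence(e$sequence, paste0(path, ".sequence"), note)
    art <- tryCatch({
      a <- e$artifacts %||% list()
      spikes <- lapply(a$spikes %||% list(), function(sp)
        list(location = num_vec(sp$location),
             amplitude = complex(real = sp$amplitude_re %||% sp$amplitude %||% 0,
                                 imaginary = sp$amplitude_im %||% 0)))
      artifact_config(a$thermal_sigma %||% 0, spikes,
                      if (!is.null(a$motion)) a$motion,
                      if (!is.null(a$half_fourier)) a$half_fourier,
                      isTRUE(a$wraparound_on))
    }, error = function(err) {
      note(paste0(path, ".artifacts"), conditionMessage(err)); NULL })
    bands <- tryCatch(
      lapply(e$bands %||% list(), function(b)
        saturation_band(num_vec(b$centre), num_vec(b$normal), b$thickness,
                        b$suppression %||% 0)),
      error = function(err) {
        note(paste0(path, ".bands"), conditionMessage(err)); list() })
    entries[[i]] <- list(name = ename, geometry = geom, sequence = seqp,
                         artifacts = art, bands = bands)
  }
  nms <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(nms))
    note("entries", sprintf("duplicate entry names: %s",
                            paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  if (length(errs)) return(structure(unique(errs), class = "protocol_errors"))
  mri_protocol(name, entries, coil = coil,
               patient_position = doc$patient_position %||% "head_first_supine")
}

resolve_geometry <- function(g, path, note) {
  tryCatch({
    if (!is.null(g$orientation)) {
      ax <- canonical_axes(g$orientation)
      if (is.null(ax))
        abort_invalid(sprintf(
          "unknown orientation '%s' (allowed: axial, coronal, sagittal)",
          g$orientation))
    } else if (!is.null(g$freq_axis)) {
      ax <- list(f = num_vec(g$freq_axis), p = num_vec(g$phase_axis),
                 s = num_vec(g$slice_axis))
    } else ax <- canonical_axes("axial")
    mat <- rep_len(num_vec(g$matrix %||% 128), 2)
    fov <- rep_len(num_vec(g$fov %||% 240), 2)
    thick <- g$thickness %||% 5
    plan_geometry(ax$f, ax$p, ax$s, fov[1], fov[2], mat[1], mat[2],
                  thick, g$separation %||% thick, g$n_slices %||% 1L,
                  num_vec(g$centre %||% c(0, 0, 0)),
                  g$phase_oversampling %||% 1)
  }, error = function(e) { note(path, conditionMessage(e)); NULL })
}

resolve_sequence <- function(s, path, note) {
  if (is.null(s)) { note(path, "sequence block is required"); return(NULL) }
  allowed <- c("SE", "FSE", "GRE_SPOILED", "IR_SE")
  if (is.null(s$family) || !s$family %in% allowed) {
    note(paste0(path, ".family"),
         sprintf("unknown sequence family '%s' (allowed: %s)",
                 s$family %||% "<missing>", paste(allowed, collapse = ", ")))
    return(NULL)
  }
  if (is.null(s$te) || is.null(s$tr)) {
    note(path, "te and tr are required")
    return(NULL)
  }
  tryCatch(
    sequence_params(s$family, s$te, s$tr, ti = s$ti, flip_deg = s$flip_deg,
                    etl = s$etl, echo_spacing = s$echo_spacing,
                    shimming_on = isTRUE(s$shimming_on),
                    field_strength_t = s$field_strength_t %||% 1.5),
    error = function(e) { note(path, conditionMessage(e)); NULL })
}

#' @export
print.protocol_errors <- function(x, ...) {
  cat("protocol validation failed:\n")
  for (e in x) cat("  -", e, "\n")
  invisible(x)
}
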