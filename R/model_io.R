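nifti_affine <- function(spacing, origin, orientation) {
  aff <- diag(4)
  aff[1:3, 1:3] <- orientation %*% diag(spacing)
  aff[1:3, 4] <- origin
  aff
}

write_volume <- function(arr, path, spacing, origin, orientation,
                         datatype = "double") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  aff <- nifti_affine(spacing, origin, orientation)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  list(data = array(as.vector(img), dim(img)),
       spacing = as.numeric(spacing),
       origin = as.numeric(aff[1:3, 4]),
       orientation = aff[1:3, 1:3] %*% diag(1 / spacing))
}

#' Write an anatomical model to disk
#'
#' Each tissue-property volume is stored as one NIfTI-1 file (64-bit float,
#' so voxel values round-trip bit-exactly; labels as 32-bit integers) with
#' the spatial metadata in the sform/qform affine, and a JSON manifest ties
#' the components together.
#'
#' @param model an `anatomical_model`.
#' @param dir output directory (created if needed).
#' @param name basename used for the component files and manifest.
#' @return path of the written manifest, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, dir, name = "model") {
  validate_anatomical_model(model)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comp_file <- function(comp) file.path(dir, sprintf("%s_%s.nii.gz", name, comp))
  manifest <- list()
  for (comp in c("pd", "t1", "t2", "delta_b0")) {
    write_volume(model[[comp]], comp_file(comp), model$spacing, model$origin,
                 model$orientation)
    manifest[[comp]] <- basename(comp_file(comp))
  }
  if (!is.null(model$labels)) {
    write_volume(model$labels, comp_file("labels"), model$spacing,
                 model$origin, model$orientation, datatype = "int32")
    manifest$labels <- basename(comp_file("labels"))
  } else manifest["labels"] <- list(NULL)
  mpath <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, null = "null")
  invisible(mpath)
}

#' Read an anatomical model from a manifest
#'
#' @param path path to the JSON manifest written by [write_model()] (component
#'   paths inside it are resolved relative to the manifest's directory). A
#'   manifest without a `delta_b0` entry yields an all-zero field map.
#' @return an `anatomical_model`.
#' @export
read_model <- function(path) {
  manifest <- jsonlite::read_json(path)
  dir <- dirname(path)
  need <- c("pd", "t1", "t2")
  if (!all(need %in% names(manifest)))
    abort_invalid(sprintf("manifest lacks required components: %s",
                          paste(setdiff(need, names(manifest)), collapse = ", ")),
                  class = "mrisim_format_error")
  vols <- list()
  for (comp in c("pd", "t1", "t2", "delta_b0", "labels")) {
    if (is.null(manifest[[comp]])) next
    vols[[comp]] <- read_volume(file.path(dir, manifest[[comp]]))
  }
  ref <- vols$pd
  for (comp in names(vols))
    if (!identical(dim(vols[[comp]]$data), dim(ref$data)))
      abort_invalid(sprintf("component '%s' dimensions %s differ from pd %s",
                            comp, paste(dim(vols[[comp]]$data), collapse = "x"),
                            paste(dim(ref$data), collapse = "x")),
                    class = "mrisim_format_error")
  model <- structure(list(
    pd = ref$data, t1 = vols$t1$data, t2 = vols$t2$data,
    delta_b0 = if (is.null(vols$delta_b0)) array(0, dim(ref$data))
               else vols$delta_b0$data,
    labels = if (is.null(vols$labels)) NULL
             else array(as.integer(round(vols$labels$data)), dim(ref$data)),
    spacing = ref$spacing, origin = ref$origin,
    orientation = ref$orientation), class = "anatomical_model")
  validate_anatomical_model(model)
  model
}
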