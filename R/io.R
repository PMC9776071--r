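# NIfTI input/output for volumes, YAML for configs. Spacing is carried in
# pixdim; the grid origin is stored in the qform/sform offset.

nifti_with_geometry <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  xf <- diag(c(spacing, 1))
  xf[1:3, 4] <- origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  img
}

#' Write / read a label volume as integer NIfTI
#'
#' @param labels A `label_volume`.
#' @param path `.nii` or `.nii.gz` path.
#' @export
write_label_volume <- function(labels, path) {
  img <- nifti_with_geometry(labels$labels, labels$spacing, labels$origin)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  label_volume(array(as.integer(img), dim(img)),
               spacing = RNifti::pixdim(img)[1:3], origin = xf[1:3, 4])
}

#' Write / read a multi-contrast stack as one NIfTI file per channel
#'
#' Files are named `<prefix>_<channel>.nii.gz`.
#'
#' @param stack A `contrast_stack`.
#' @param prefix Path prefix.
#' @export
write_contrast_stack <- function(stack, prefix) {
  for (ch in names(stack$channels)) {
    img <- nifti_with_geometry(stack$channels[[ch]], stack$spacing,
                               stack$origin)
    RNifti::writeNifti(img, paste0(prefix, "_", ch, ".nii.gz"))
  }
  invisible(prefix)
}

#' @rdname write_contrast_stack
#' @param channels Channel names to read.
#' @export
read_contrast_stack <- function(prefix, channels = c("T1W", "T2W", "PDW",
                                                     "TOF")) {
  chans <- list()
  spacing <- NULL; origin <- NULL
  for (ch in channels) {
    img <- RNifti::readNifti(paste0(prefix, "_", ch, ".nii.gz"))
    chans[[ch]] <- array(as.numeric(img), dim(img))
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- RNifti::xform(img)[1:3, 4]
  }
  contrast_stack(chans, spacing, origin)
}

#' Read / write a case configuration as YAML
#'
#' @param path YAML file.
#' @return `read_case_config` returns the configuration list.
#' @export
read_case_config <- function(path) yaml::read_yaml(path)

#' @rdname read_case_config
#' @param config Configuration list (see [case_config()]).
#' @export
write_case_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
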