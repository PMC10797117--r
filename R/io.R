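#' Write a 2D/3D map as NIfTI-1 with spacing carried in the header
#'
#' @param arr numeric matrix or array.
#' @param grid an [image_grid()] giving in-plane spacing (mm).
#' @param path output file path (`.nii` / `.nii.gz`).
#' @param slice_thickness third-axis spacing (mm) for 3D arrays.
#' @return the path, invisibly.
#' @export
write_nifti_map <- function(arr, grid, path, slice_thickness = 1) {
  arr[is.na(arr)] <- 0
  pix <- c(grid$spacing, if (length(dim(arr)) > 2L) slice_thickness)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pix
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a JSON sidecar with acquisition and provenance metadata
#'
#' @param meta named list (TE, TI list, frame interval, seed, truth
#'   parameters, ...).
#' @param path output `.json` path.
#' @export
write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Stable 32-bit FNV-1a hash of a configuration
#'
#' Embedded in every output so a run can be traced back to the exact
#' configuration that produced it.
#'
#' @param config any JSON-serialisable list.
#' @return character scalar, 8 hex digits.
#' @export
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                 digits = NA)))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) h <- fnv_step(h, b, m)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# one FNV-1a step with exact 32-bit modular multiply via 16-bit split
fnv_step <- function(h, b, m) {
  hx <- h
  # xor on a 32-bit value represented as a double
  lo_h <- hx %% 65536; hi_h <- hx %/% 65536
  lo_b <- b %% 65536; hi_b <- b %/% 65536
  hx <- bitwXor(as.integer(lo_h), as.integer(lo_b)) +
    65536 * bitwXor(as.integer(hi_h), as.integer(hi_b))
  lo <- hx %% 65536; hi <- hx %/% 65536
  (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
}
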