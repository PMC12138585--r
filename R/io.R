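#' Write / read a region-metric or participant table as TSV
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return `path` invisibly / the data.frame.
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a scalar volume as NIfTI-1
#'
#' @param volume 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Isotropic voxel size in mm.
#' @return `path` invisibly / the array.
#' @export
write_volume <- function(volume, path, voxel_mm = 1) {
  RNifti::writeNifti(RNifti::asNifti(volume, pixdim = rep(voxel_mm, 3)), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim(v))
}

#' Write FOD amplitude samples as a 4-D NIfTI plus a direction sidecar
#'
#' The last axis of the NIfTI indexes the sampling direction; the sidecar
#' is a whitespace-separated text file of unit direction vectors, one row
#' per direction.
#'
#' @param fod `list(amplitudes = 4-D array, directions = n x 3 matrix)`.
#' @param path Output NIfTI path; the sidecar gets extension `.dirs.txt`.
#' @param voxel_mm Isotropic voxel size in mm.
#' @return `path` invisibly.
#' @export
write_fod <- function(fod, path, voxel_mm = 1) {
  RNifti::writeNifti(RNifti::asNifti(fod$amplitudes,
                                     pixdim = rep(voxel_mm, 3)), path)
  side <- sub("\\.nii(\\.gz)?$", ".dirs.txt", path)
  utils::write.table(fod$directions, side, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_fod
#' @export
read_fod <- function(path) {
  v <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".dirs.txt", path)
  list(amplitudes = array(as.numeric(v), dim(v)),
       directions = unname(as.matrix(utils::read.table(side))))
}
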