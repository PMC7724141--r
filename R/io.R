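#' Matrix and volume input/output helpers
#'
#' BOLD matrices travel either as tab-separated text (voxels in rows, TRs in
#' columns) or as NIfTI volumes (voxels along the first spatial axis, TR
#' along the fourth; requires the RNifti package).
#'
#' @name io
NULL

#' @param mat numeric matrix.
#' @param path file path.
#' @rdname io
#' @export
write_bold_tsv <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_bold_tsv <- function(path) {
  as.matrix(utils::read.delim(path, header = FALSE))
}

#' @param tr_s repetition time stored in the NIfTI header.
#' @rdname io
#' @export
write_bold_nifti <- function(mat, path, tr_s = 1.5) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI requires the RNifti package")
  }
  arr <- array(0, dim = c(nrow(mat), 1, 1, ncol(mat)))
  arr[, 1, 1, ] <- mat
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, tr_s))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname io
#' @export
read_bold_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI requires the RNifti package")
  }
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  matrix(arr, nrow = prod(d[-length(d)]), ncol = d[length(d)])
}
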