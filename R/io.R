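# Reading and writing the pipeline's on-disk formats: labelled multi-page
# TIFF volumes, CSV tables, YAML configuration echoes.

#' Write a labelled volume as a multi-page TIFF
#'
#' Stores a 3D integer label array as one 16-bit greyscale page per ML (z)
#' slice. Labels must fit in 16 bits.
#'
#' @param volume 3D integer array (AP x DV x ML).
#' @param path Output file.
#' @export
write_label_tiff <- function(volume, path) {
  stopifnot(length(dim(volume)) == 3L)
  mx <- max(volume)
  if (mx > 65535) stop("labels exceed 16-bit range")
  pages <- lapply(seq_len(dim(volume)[3]), function(k)
    volume[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a labelled volume from a multi-page TIFF
#'
#' Inverse of \code{\link{write_label_tiff}}.
#'
#' @param path TIFF file.
#' @return 3D integer label array.
#' @export
read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) vol[, , k] <- pages[[k]]
  storage.mode(vol) <- "integer"
  vol
}

#' Write a data frame as CSV with a YAML metadata sidecar
#'
#' @param x Data frame.
#' @param path CSV path; metadata goes to \code{<path>.meta.yaml}.
#' @param meta Named list of metadata (tool version and config hash are
#'   added automatically when available).
#' @export
write_table_csv <- function(x, path, meta = list()) {
  utils::write.csv(x, path, row.names = FALSE)
  meta$written_by <- paste0("notomorph ",
                            as.character(utils::packageVersion("notomorph")))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
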