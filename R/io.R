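#' Read an image file as a gray-level matrix
#'
#' PNG is read with the png package; other formats (e.g. JPEG) go through
#' EBImage. RGB input is converted with the luma weights of
#' [toGrayscale()]; output values are scaled to \[0, 255\].
#'
#' @param path image file.
#' @return 2-D numeric matrix of gray levels in \[0, 255\].
#' @export
readImageGray <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    # EBImage stores (x, y[, c]); transpose to (row, col)
    a <- if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
  }
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) a <- toGrayscale(a[, , 1:3] * 255) / 255
    else a <- a[, , 1]
  }
  a * 255
}

#' Write a gray-level matrix as an 8-bit grayscale PNG
#'
#' @param image matrix with values in \[0, 255\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGrayPNG <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Read a dataset manifest and its images
#'
#' The manifest CSV must have columns `filename, mask_filename, label`;
#' paths are resolved relative to the manifest's directory. Missing mask
#' filenames (empty strings) yield images without masks.
#'
#' @param manifestPath path to the manifest CSV.
#' @return List of [LesionImage-class] objects.
#' @export
readDataset <- function(manifestPath) {
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("filename", "mask_filename", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  dir <- dirname(manifestPath)
  lapply(seq_len(nrow(man)), function(i) {
    img <- readImageGray(file.path(dir, man$filename[i]))
    msk <- NULL
    if (nzchar(man$mask_filename[i]))
      msk <- asBinary(readImageGray(file.path(dir, man$mask_filename[i])) >
                        127)
    lesionImage(img, mask = msk, label = man$label[i])
  })
}
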