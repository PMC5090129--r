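# Flat-binary array interchange with a JSON sidecar, plus optional PNG
# visualization output.

#' Write / read a numeric array as flat binary with a JSON sidecar
#'
#' Values are stored as little-endian float64 in raster order; a
#' \code{<path>.json} sidecar records shape, dtype, byte order and any
#' extra metadata so the file is self-describing.
#'
#' @param x numeric vector or matrix.
#' @param path output path for the binary payload.
#' @param shape integer dimensions (defaults to \code{dim(x)} or length).
#' @param meta named list of extra metadata stored in the sidecar.
#' @return \code{writeFlatArray}: the path, invisibly.
#' @export
writeFlatArray <- function(x, path, shape = NULL, meta = list()) {
  if (is.null(shape)) shape <- if (is.null(dim(x))) length(x) else dim(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  side <- c(list(shape = as.integer(shape), dtype = "float64",
                 byte_order = "little"), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param path path of the binary payload (sidecar at \code{<path>.json}).
#' @return \code{readFlatArray}: numeric vector with attribute
#'   \code{"meta"} (the sidecar list); matrices are not re-dimensioned, use
#'   the shape in the metadata.
#' @rdname writeFlatArray
#' @export
readFlatArray <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(side$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  attr(x, "meta") <- side
  x
}

#' Write / read an activity image
#'
#' @param image an \code{\link{activityImage}}.
#' @param path output path.
#' @export
writeActivityImage <- function(image, path) {
  writeFlatArray(image@pixels, path,
                 shape = c(image@gridSide, image@gridSide),
                 meta = list(kind = "activity_image",
                             pixel_size_mm = image@pixelSizeMm,
                             roi_masks = lapply(image@roiMasks, which)))
}

#' @rdname writeActivityImage
#' @export
readActivityImage <- function(path) {
  x <- readFlatArray(path)
  side <- attr(x, "meta")
  n <- side$shape[1]
  masks <- lapply(side$roi_masks, function(ix) {
    m <- logical(n * n)
    m[ix] <- TRUE
    m
  })
  activityImage(as.numeric(x), n, pixelSizeMm = side$pixel_size_mm,
                roiMasks = masks)
}

#' Write / read a sinogram
#'
#' @param sino a \code{\link{sinogram}}.
#' @param geometry the matching \code{\link{scanGeometry}}.
#' @param path output path.
#' @export
writeSinogram <- function(sino, geometry, path) {
  writeFlatArray(
    c(sino@counts, sino@noiseFree, sino@scatter), path,
    shape = c(3L, geometry@nBins, geometry@nViews),
    meta = list(kind = "sinogram", bin_size_mm = geometry@binSizeMm,
                layers = c("counts", "noise_free", "scatter"),
                randoms_fraction = sino@randomsFraction[1],
                efficiency = sino@efficiency[1],
                clamped = sino@clamped))
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  x <- readFlatArray(path)
  side <- attr(x, "meta")
  m <- side$shape[2] * side$shape[3]
  sinogram(x[seq_len(m)], noiseFree = x[m + seq_len(m)],
           scatter = x[2 * m + seq_len(m)],
           randomsFraction = side$randoms_fraction,
           efficiency = side$efficiency, clamped = side$clamped)
}

#' Write an image as PNG (visualization only)
#'
#' Min--max scales the image to [0, 1] (each image scaled by its own
#' minimum and maximum) and writes an 8-bit grayscale PNG.  Requires the
#' \pkg{png} package.
#'
#' @param image an \code{\link{activityImage}} or numeric matrix.
#' @param path output path.
#' @export
writeImagePNG <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG output")
  m <- if (is(image, "ActivityImage")) asImageMatrix(image)
       else as.matrix(image)
  rng <- range(m)
  scaled <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1])
            else m * 0
  png::writePNG(scaled, target = path)
  invisible(path)
}
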