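#' Read and write multi-page TIFF stacks
#'
#' One file per channel, one page per z-section, 16-bit. Intensities are
#' stored as integers (0..65535); 12-bit data round-trip losslessly.
#'
#' @param x a [FishStack-class].
#' @param path TIFF file path.
#' @param channel,pixelSizeNM,zSpacingNM metadata applied on read (TIFF
#'   carries no calibration tags here).
#' @return \code{writeFishStack} returns \code{path} invisibly;
#'   \code{readFishStack} returns a [FishStack-class].
#' @export
writeFishStack <- function(x, path) {
    stopifnot(is(x, "FishStack"))
    # EBImage frames map to z-sections; data are already [x, y, z]
    EBImage::writeImage(EBImage::Image(x@data / 65535), path,
                        type = "tiff", bits.per.sample = 16L)
    invisible(path)
}

#' @rdname writeFishStack
#' @export
readFishStack <- function(path, channel = "fish", pixelSizeNM = 76,
                          zSpacingNM = 345) {
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img) * 65535
    dimnames(a) <- NULL
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    FishStack(round(a), channel = channel, pixelSizeNM = pixelSizeNM,
              zSpacingNM = zSpacingNM)
}

#' Write and read centroid/intensity tables in the deposited CSV format
#'
#' One row per object with XYZ centroid positions (pixel units, 0-based)
#' and fluorescence intensity values, in stable column order; additional
#' columns are preserved after the canonical four. Provenance (and any
#' other metadata) is written as \code{#}-prefixed header comments that the
#' reader skips.
#'
#' @param df data.frame with at least columns \code{x}, \code{y}, \code{z};
#'   an \code{intensity} column is added as \code{NA} when absent.
#' @param path CSV file path.
#' @param comments character vector of header comment lines (without the
#'   leading \code{"# "}).
#' @return \code{writeDepositedCsv} returns \code{path} invisibly;
#'   \code{readDepositedCsv} returns the data.frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeDepositedCsv(data.frame(x = 1, y = 2, z = 0, intensity = 10), f)
#' readDepositedCsv(f)
#' @export
writeDepositedCsv <- function(df, path, comments = character(0)) {
    stopifnot(all(c("x", "y", "z") %in% names(df)))
    if (!"intensity" %in% names(df)) df$intensity <- NA_real_
    lead <- c("x", "y", "z", "intensity")
    df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comments) writeLines(paste("#", cm), con)
    write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeDepositedCsv
#' @export
readDepositedCsv <- function(path) {
    read.csv(path, comment.char = "#")
}
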