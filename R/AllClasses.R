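#' @import methods
#' @importFrom stats median var sd quantile rnorm runif rpois qnorm pnorm
#'   lm coef confint complete.cases setNames
#' @importFrom utils head tail write.table read.csv
NULL

setClassUnion("functionOrNULL", c("function", "NULL"))

#' 3D confocal image stack with acquisition calibration
#'
#' A voxel grid holding one imaging channel of a 3D confocal stack together
#' with its physical calibration. The array is indexed \code{[x, y, z]};
#' coordinates reported by all segmentation functions are 0-based and
#' pixel-centered, so voxel \code{[i, j, k]} has coordinates
#' \code{(i-1, j-1, k-1)}.
#'
#' @slot data numeric array, dim \code{c(nx, ny, nz)}; 12-bit intensities
#'   (0..4095) by convention, stored as doubles.
#' @slot channel channel role, \code{"fish"} or \code{"nuclei"}.
#' @slot pixelSizeNM lateral pixel size in nm (default 76).
#' @slot zSpacingNM z-section spacing in nm (default 345).
#'
#' @examples
#' st <- FishStack(array(100, c(32, 32, 5)), channel = "fish")
#' dim(st)
#' @export
setClass("FishStack", representation(
    data = "array",
    channel = "character",
    pixelSizeNM = "numeric",
    zSpacingNM = "numeric"
))

setValidity("FishStack", function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) return("data must be a 3D array [x, y, z]")
    if (any(dim(d) < 1L)) return("all dimensions must be positive")
    if (!object@channel %in% c("fish", "nuclei", "labels"))
        return("channel must be 'fish', 'nuclei' or 'labels'")
    if (object@pixelSizeNM <= 0 || object@zSpacingNM <= 0)
        return("calibration must be positive")
    TRUE
})

#' @param data numeric 3D array \code{[x, y, z]}.
#' @param channel channel role.
#' @param pixelSizeNM,zSpacingNM calibration in nm.
#' @rdname FishStack-class
#' @export
FishStack <- function(data, channel = "fish", pixelSizeNM = 76,
                      zSpacingNM = 345) {
    new("FishStack", data = data, channel = channel,
        pixelSizeNM = pixelSizeNM, zSpacingNM = zSpacingNM)
}

#' @rdname FishStack-class
#' @param x a \code{FishStack}.
#' @export
setMethod("dim", "FishStack", function(x) dim(x@data))

#' @rdname FishStack-class
#' @param object a \code{FishStack}.
#' @export
setMethod("show", "FishStack", function(object) {
    d <- dim(object@data)
    cat(sprintf("FishStack: %d x %d x %d voxels, channel '%s'\n",
                d[1], d[2], d[3], object@channel))
    cat(sprintf("  calibration: %.0f nm x-y pixels, %.0f nm z-spacing\n",
                object@pixelSizeNM, object@zSpacingNM))
    cat(sprintf("  intensity range: [%.1f, %.1f]\n",
                min(object@data), max(object@data)))
})

#' @rdname FishStack-class
#' @export
stackData <- function(x) x@data

#' @rdname FishStack-class
#' @export
pixelSizeNM <- function(x) x@pixelSizeNM

#' @rdname FishStack-class
#' @export
zSpacingNM <- function(x) x@zSpacingNM

#' Intensity-threshold scan for plateau-based cutoff selection
#'
#' Records the number of 2D connected objects found at each candidate
#' binarization cutoff, the detected plateau (the cutoff range over which
#' the object count is insensitive to the cutoff) and the cutoff selected
#' inside it. Stacks without an identifiable plateau have insufficient
#' signal-to-background and are flagged as failing quality control.
#'
#' @slot cutoffs increasing numeric vector of scanned cutoffs.
#' @slot counts integer vector of summed 2D object counts per cutoff.
#' @slot plateau integer indices (start, end) into \code{cutoffs}, or
#'   \code{c(NA, NA)} when no plateau was found.
#' @slot selected the selected cutoff (midpoint of the plateau), or \code{NA}.
#' @slot ok logical; \code{FALSE} signals the no-plateau quality failure.
#' @export
setClass("ThresholdScan", representation(
    cutoffs = "numeric",
    counts = "integer",
    plateau = "integer",
    selected = "numeric",
    ok = "logical"
))

setValidity("ThresholdScan", function(object) {
    if (length(object@cutoffs) != length(object@counts))
        return("cutoffs and counts must have equal length")
    if (is.unsorted(object@cutoffs, strictly = TRUE))
        return("cutoffs must be strictly increasing")
    if (object@ok) {
        p <- object@plateau
        if (anyNA(p) || p[1] > p[2]) return("invalid plateau interval")
        sel <- object@selected
        if (sel < object@cutoffs[p[1]] || sel > object@cutoffs[p[2]])
            return("selected cutoff must lie inside the plateau")
    }
    TRUE
})

#' @param object a \code{ThresholdScan}.
#' @rdname ThresholdScan-class
#' @export
setMethod("show", "ThresholdScan", function(object) {
    cat(sprintf("ThresholdScan: %d cutoffs in [%g, %g]\n",
                length(object@cutoffs), min(object@cutoffs),
                max(object@cutoffs)))
    if (object@ok) {
        p <- object@plateau
        cat(sprintf("  plateau: cutoffs %g..%g (%d steps), selected %g\n",
                    object@cutoffs[p[1]], object@cutoffs[p[2]],
                    p[2] - p[1] + 1L, object@selected))
    } else {
        cat("  no plateau found: sample fails quality control\n")
    }
})

#' @rdname ThresholdScan-class
#' @export
selectedCutoff <- function(x) x@selected

#' @rdname ThresholdScan-class
#' @export
scanOK <- function(x) x@ok

#' Rate parameters of the two-state (telegraph) transcription model
#'
#' The promoter toggles OFF -> ON at rate \code{kon} and ON -> OFF at rate
#' \code{koff} (per minute); while ON, transcription initiates at rate
#' \code{kini}; mature mRNA decays at rate \code{kdeg}. \code{ngtot} is the
#' number of independent gene copies in one simulation (default 1; paired
#' alleles are modelled by pairing two independent simulations).
#'
#' Average burst size is \code{kini/koff} transcripts per burst; average
#' burst frequency is \code{1/(1/kon + 1/koff)} bursts per minute.
#'
#' @slot kon,koff,kini,kdeg rates in 1/min.
#' @slot ngtot integer gene copy number per simulation.
#'
#' @examples
#' p <- TelegraphParams(kon = 0.1, koff = 1, kini = 10)
#' burstSize(p)       # 10 transcripts per burst
#' burstFrequency(p)  # 1/(1/0.1 + 1/1) per min
#' @export
setClass("TelegraphParams", representation(
    kon = "numeric", koff = "numeric", kini = "numeric",
    kdeg = "numeric", ngtot = "integer"
))

setValidity("TelegraphParams", function(object) {
    r <- c(object@kon, object@koff, object@kini, object@kdeg)
    if (any(!is.finite(r)) || any(r < 0)) return("all rates must be >= 0")
    if (object@ngtot < 1L) return("ngtot must be >= 1")
    TRUE
})

#' @param kon,koff,kini,kdeg rates in 1/min.
#' @param ngtot gene copies per simulation.
#' @rdname TelegraphParams-class
#' @export
TelegraphParams <- function(kon, koff, kini, kdeg = 0.04, ngtot = 1L) {
    new("TelegraphParams", kon = kon, koff = koff, kini = kini,
        kdeg = kdeg, ngtot = as.integer(ngtot))
}

#' @param object a \code{TelegraphParams}.
#' @rdname TelegraphParams-class
#' @export
setMethod("show", "TelegraphParams", function(object) {
    cat(sprintf(paste0("TelegraphParams: kon=%g koff=%g kini=%g kdeg=%g",
                       " /min, %d gene cop%s\n"),
                object@kon, object@koff, object@kini, object@kdeg,
                object@ngtot, if (object@ngtot == 1L) "y" else "ies"))
    if (object@koff > 0 && object@kon > 0)
        cat(sprintf("  burst size %.3g transcripts, burst frequency %.3g /min\n",
                    burstSize(object), burstFrequency(object)))
})

#' Elongation timing of a probed gene for nascent-RNA weighting
#'
#' \code{tauElong} is the time (min) for RNA polymerase to elongate from the
#' 5'-most probe-binding site to the 3' end of the transcription unit;
#' \code{tauProbe} is the time to traverse the probe-binding region itself.
#' A nascent transcript initiated less than \code{tauProbe} ago has only part
#' of the probe region transcribed and contributes weight 0.5; one initiated
#' between \code{tauProbe} and \code{tauElong} ago contributes weight 1; older
#' transcripts have left the gene (mature). Times derive from gene length at
#' an elongation rate of 1100 nt/min.
#'
#' @slot gene gene name.
#' @slot tauElong,tauProbe times in minutes, \code{0 < tauProbe <= tauElong}.
#' @slot elongRate elongation rate in nt/min.
#'
#' @seealso [nascentTiming()] for the built-in gene table.
#' @export
setClass("NascentTiming", representation(
    gene = "character", tauElong = "numeric", tauProbe = "numeric",
    elongRate = "numeric"
))

setValidity("NascentTiming", function(object) {
    if (object@tauProbe <= 0) return("tauProbe must be > 0")
    if (object@tauProbe > object@tauElong)
        return("tauProbe must be <= tauElong")
    if (object@elongRate <= 0) return("elongRate must be > 0")
    TRUE
})

#' @param object a \code{NascentTiming}.
#' @rdname NascentTiming-class
#' @export
setMethod("show", "NascentTiming", function(object) {
    cat(sprintf("NascentTiming '%s': tauElong=%.2f min, tauProbe=%.2f min (%g nt/min)\n",
                object@gene, object@tauElong, object@tauProbe,
                object@elongRate))
})

#' Bounded 3D Voronoi tessellation of nucleus centroids
#'
#' Partition of a rectangular volume into one convex polytope per nucleus
#' centroid, each consisting of all points closer to its centroid than to any
#' other. Cells are represented by their bounding half-space inequalities
#' (\code{A x <= b}), vertex lists and volumes; peripheral cells are clipped
#' to the bounding box.
#'
#' @slot centroids n x 3 matrix of generating points (same units as the box).
#' @slot box numeric length-6 vector \code{(xmin, xmax, ymin, ymax, zmin, zmax)}.
#' @slot cells list, one entry per centroid, each with elements
#'   \code{vertices} (matrix), \code{planes} (list \code{A}, \code{b}) and
#'   \code{volume}.
#' @export
setClass("VoronoiTessellation", representation(
    centroids = "matrix", box = "numeric", cells = "list"
))

setValidity("VoronoiTessellation", function(object) {
    if (ncol(object@centroids) != 3L) return("centroids must be n x 3")
    if (length(object@box) != 6L) return("box must be length 6")
    if (length(object@cells) != nrow(object@centroids))
        return("one cell per centroid required")
    TRUE
})

#' @param object a \code{VoronoiTessellation}.
#' @rdname VoronoiTessellation-class
#' @export
setMethod("show", "VoronoiTessellation", function(object) {
    vols <- vapply(object@cells, `[[`, numeric(1), "volume")
    b <- object@box
    boxvol <- prod(b[c(2, 4, 6)] - b[c(1, 3, 5)])
    cat(sprintf("VoronoiTessellation: %d cells in box %g x %g x %g\n",
                length(object@cells), b[2] - b[1], b[4] - b[3], b[6] - b[5]))
    cat(sprintf("  cell volumes sum to %.6g of box volume\n",
                sum(vols) / boxvol))
})

#' @rdname VoronoiTessellation-class
#' @export
cellVolumes <- function(x) vapply(x@cells, `[[`, numeric(1), "volume")
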