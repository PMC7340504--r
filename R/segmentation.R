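#' Diffraction-limited spot diameter in pixels
#'
#' Maps the diffraction-limited spot diameter (~600 nm for smFISH probes
#' emitting at 633 nm) to pixels at the acquisition pixel size (76 nm),
#' giving 8 pixels: the minimum 2D object size used throughout
#' segmentation and the radius-4 linkage/intensity circles.
#'
#' @param diameterNM spot diameter in nm.
#' @param pixelSizeNM lateral pixel size in nm.
#' @return integer number of pixels across.
#' @examples
#' spotDiameterPx()  # 8
#' @export
spotDiameterPx <- function(diameterNM = 600, pixelSizeNM = 76) {
    as.integer(round(diameterNM / pixelSizeNM))
}

#' Find 2D connected objects per z-section
#'
#' Binarizes each section at \code{cutoff} and returns the connected
#' components with at least \code{minPixels} member pixels. The 8-pixel
#' default size floor corresponds to the ~600 nm diffraction-limited spot
#' diameter at 76 nm pixels (8 pixels across). Connectivity is 8-connected
#' by default (4-connected optionally).
#'
#' @param stack a [FishStack-class] (or plain 3D array \code{[x, y, z]}).
#' @param cutoff intensity threshold; pixels strictly above it are
#'   foreground.
#' @param minPixels minimum object size in pixels (default 8).
#' @param connectivity 8 (default) or 4.
#' @return data.frame with one row per object: \code{id}, \code{z}
#'   (0-based section index), \code{x}, \code{y} (0-based pixel-mean
#'   centroid), \code{npx}, and a list-column \code{pixels} of linear
#'   indices into the section.
#' @export
findObjects2D <- function(stack, cutoff, minPixels = 8, connectivity = 8) {
    a <- if (is(stack, "FishStack")) stack@data else stack
    stopifnot(length(dim(a)) == 3L, minPixels >= 1)
    out <- vector("list", dim(a)[3])
    for (k in seq_len(dim(a)[3])) {
        bw <- a[, , k] > cutoff
        if (!any(bw)) next
        lab <- .label2d(bw, connectivity)
        idx <- which(lab > 0L)
        if (!length(idx)) next
        labs <- lab[idx]
        sizes <- tabulate(labs)
        keep <- which(sizes >= minPixels)
        if (!length(keep)) next
        # keep only pixels of retained components before any per-object work
        sel <- sizes[labs] >= minPixels
        idx <- idx[sel]; labs <- labs[sel]
        xs <- (idx - 1L) %% nrow(bw)          # 0-based x
        ys <- (idx - 1L) %/% nrow(bw)         # 0-based y
        ord <- order(labs)
        idx <- idx[ord]; labs <- labs[ord]; xs <- xs[ord]; ys <- ys[ord]
        grp <- split(seq_along(labs), labs)
        out[[k]] <- data.frame(
            z = k - 1L,
            x = vapply(grp, function(g) mean(xs[g]), numeric(1)),
            y = vapply(grp, function(g) mean(ys[g]), numeric(1)),
            npx = lengths(grp),
            pixels = I(lapply(grp, function(g) idx[g])))
    }
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(z = integer(0), x = numeric(0), y = numeric(0),
                          npx = integer(0), pixels = I(list()))
    out$id <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("id", "z", "x", "y", "npx", "pixels")]
}

## 2D connected-component labeling; EBImage::bwlabel is 4-connected, so for
## 8-connectivity bridge diagonal neighbours by dilating with a 2x2 brush
## before labeling and restricting labels to the original foreground.
## Labels are NOT compacted (gaps are allowed).
.label2d <- function(bw, connectivity = 8) {
    if (connectivity == 4) return(EBImage::imageData(EBImage::bwlabel(bw)))
    grown <- EBImage::dilate(EBImage::Image(bw * 1), matrix(1, 2, 2)) > 0
    lab <- EBImage::imageData(EBImage::bwlabel(grown))
    lab * bw
}

## number of 2D components with >= minPixels member pixels, summed over all
## sections: the counting path of the threshold scan (no centroids built)
.countObjects2D <- function(a, cutoff, minPixels, connectivity) {
    total <- 0L
    for (k in seq_len(dim(a)[3])) {
        bw <- a[, , k] > cutoff
        if (!any(bw)) next
        lab <- .label2d(bw, connectivity)
        sizes <- tabulate(lab[lab > 0L])
        total <- total + sum(sizes >= minPixels)
    }
    total
}

#' Scan binarization cutoffs and select one on the count plateau
#'
#' Applies every cutoff in \code{cutoffs} to the stack, sums the number of
#' 2D objects over all sections, and looks for the plateau: the longest run
#' of consecutive cutoffs over which the relative change in object count
#' per step stays below \code{tol} (default 2\%) while counts remain
#' positive. The selected cutoff is the plateau midpoint. When no run of at
#' least \code{minRun} steps exists the stack has insufficient
#' signal-to-background and the scan is flagged as failing quality control
#' (such samples are excluded from analysis, not silently defaulted).
#'
#' @inheritParams findObjects2D
#' @param cutoffs increasing numeric vector of candidate cutoffs.
#' @param tol maximum relative count change per step inside the plateau.
#' @param minRun minimum plateau length in steps.
#' @param minCountFrac candidate plateaus must hold at least this fraction
#'   of the scan's maximum object count; rejects the sparse flat tail of
#'   bright transcription sites surviving above the mature-spot range.
#' @return a [ThresholdScan-class].
#' @export
scanThresholds <- function(stack, cutoffs, minPixels = 8, tol = 0.02,
                           minRun = 3, minCountFrac = 0.05,
                           connectivity = 8) {
    stopifnot(length(cutoffs) >= 2, !is.unsorted(cutoffs, strictly = TRUE))
    a <- if (is(stack, "FishStack")) stack@data else stack
    counts <- vapply(cutoffs, function(ct)
        .countObjects2D(a, ct, minPixels, connectivity), integer(1))
    flat <- rep(FALSE, length(counts) - 1L)
    for (i in seq_along(flat)) {
        c0 <- counts[i]; c1 <- counts[i + 1L]
        flat[i] <- c0 > 0L && c1 > 0L && abs(c1 - c0) / c0 <= tol
    }
    # longest run of consecutive flat steps; ties go to the run with the
    # larger object count (the spot plateau, not a sparse bright tail)
    best <- c(0L, 0L); bestCount <- -Inf
    runStart <- NA_integer_; runLen <- 0L
    floorCount <- minCountFrac * max(counts)
    note <- function(start, len) {
        m <- mean(counts[start:(start + len)])
        if (m < floorCount) return()
        if (len > best[2] || (len == best[2] && m > bestCount)) {
            best <<- c(start, len); bestCount <<- m
        }
    }
    for (i in seq_along(flat)) {
        if (flat[i]) {
            if (runLen == 0L) runStart <- i
            runLen <- runLen + 1L
            note(runStart, runLen)
        } else runLen <- 0L
    }
    if (best[2] >= minRun) {
        lo <- best[1]; hi <- best[1] + best[2]  # cutoff indices
        mid <- cutoffs[lo + ((hi - lo) %/% 2L)]
        new("ThresholdScan", cutoffs = as.numeric(cutoffs), counts = counts,
            plateau = c(lo, hi), selected = mid, ok = TRUE)
    } else {
        new("ThresholdScan", cutoffs = as.numeric(cutoffs), counts = counts,
            plateau = c(NA_integer_, NA_integer_), selected = NA_real_,
            ok = FALSE)
    }
}

#' Link 2D objects across z-sections into 3D spots
#'
#' A genuine diffraction-limited spot appears in 2-3 consecutive
#' z-sections, so a 2D object is counted as a spot only when (1) it is
#' linked to at least one object in an adjacent section whose centroid lies
#' within \code{linkRadius} pixels in x-y, and (2) it is the largest object
#' of its linked group, which prevents one fluorescent spot from being
#' counted in several sections. Equal-size ties break deterministically by
#' (z, y, x) of the centroid. Groups spanning more than \code{maxSpan}
#' sections are kept but flagged.
#'
#' @param objects data.frame from [findObjects2D()].
#' @param linkRadius maximum x-y centroid distance (px) for linkage.
#' @param maxSpan section span above which a group is flagged.
#' @return data.frame with one row per 3D spot: \code{x}, \code{y}
#'   (centroid of the largest member object), \code{z} (its section),
#'   \code{npx}, \code{nSections}, \code{flagLong}, and a list-column
#'   \code{members} of member object ids.
#' @export
linkObjects3D <- function(objects, linkRadius = 4, maxSpan = 3) {
    n <- nrow(objects)
    empty <- data.frame(x = numeric(0), y = numeric(0), z = integer(0),
                        npx = integer(0), nSections = integer(0),
                        flagLong = logical(0), members = I(list()))
    if (n == 0L) return(empty)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
    linked <- rep(FALSE, n)
    byZ <- split(seq_len(n), objects$z)
    zs <- as.integer(names(byZ))
    for (zi in seq_along(zs)) {
        nxt <- which(zs == zs[zi] + 1L)
        if (!length(nxt)) next
        a <- byZ[[zi]]; b <- byZ[[nxt]]
        dx <- outer(objects$x[a], objects$x[b], "-")
        dy <- outer(objects$y[a], objects$y[b], "-")
        hit <- which(dx * dx + dy * dy <= linkRadius^2, arr.ind = TRUE)
        if (nrow(hit)) {
            linked[a[hit[, 1]]] <- TRUE
            linked[b[hit[, 2]]] <- TRUE
            for (r in seq_len(nrow(hit))) union(a[hit[r, 1]], b[hit[r, 2]])
        }
    }
    keep <- which(linked)               # criterion 1: must have a partner
    if (!length(keep)) return(empty)
    roots <- vapply(keep, find, integer(1))
    groups <- split(keep, roots)
    rows <- lapply(groups, function(g) {
        # criterion 2: record only the largest member (tie-break z, y, x)
        o <- objects[g, ]
        best <- g[order(-o$npx, o$z, o$y, o$x)[1]]
        span <- max(o$z) - min(o$z) + 1L
        data.frame(x = objects$x[best], y = objects$y[best],
                   z = objects$z[best], npx = objects$npx[best],
                   nSections = span, flagLong = span > maxSpan,
                   members = I(list(objects$id[g])))
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$z, out$y, out$x), ]
    rownames(out) <- NULL
    out
}

#' Integrated spot intensity over a fixed circle
#'
#' Sums pixel intensities in the 2D disk of radius \code{radius} (default
#' 4 px, the diffraction limit) about the spot centroid, in the spot's
#' representative section. The fixed measurement area decouples intensity
#' from the segmentation cutoff. Centroids closer than \code{radius} to the
#' x-y border are measured on the clipped disk and flagged.
#'
#' @inheritParams findObjects2D
#' @param x,y,z spot centroid (0-based; z is the section index). Vectors
#'   are accepted.
#' @param radius disk radius in pixels.
#' @return data.frame with \code{intensity}, \code{peak} (maximum pixel in
#'   the disk) and \code{clipped}.
#' @export
measureIntensity <- function(stack, x, y, z, radius = 4) {
    a <- if (is(stack, "FishStack")) stack@data else stack
    d <- dim(a)
    n <- length(x)
    stopifnot(length(y) == n, length(z) == n)
    off <- expand.grid(dx = -floor(radius):floor(radius),
                       dy = -floor(radius):floor(radius))
    off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
    intensity <- numeric(n); peak <- numeric(n); clipped <- logical(n)
    for (i in seq_len(n)) {
        cx <- round(x[i]) + 1L; cy <- round(y[i]) + 1L; cz <- round(z[i]) + 1L
        stopifnot(cz >= 1L, cz <= d[3])
        px <- cx + off$dx; py <- cy + off$dy
        ok <- px >= 1L & px <= d[1] & py >= 1L & py <= d[2]
        clipped[i] <- !all(ok)
        vals <- a[cbind(px[ok], py[ok], cz)]
        intensity[i] <- sum(vals)
        peak[i] <- max(vals)
    }
    data.frame(intensity = intensity, peak = peak, clipped = clipped)
}

#' Full mature-mRNA spot segmentation of one stack
#'
#' Runs the plateau threshold scan, 2D object detection at the selected
#' cutoff, 2D-to-3D linking, and fixed-radius intensity measurement.
#'
#' @inheritParams scanThresholds
#' @inheritParams linkObjects3D
#' @param cutoffs candidate cutoffs for the scan; by default 40 values
#'   spanning background to the stack maximum.
#' @param radius intensity-measurement disk radius (px).
#' @return list with \code{spots} (data.frame: x, y, z, npx, nSections,
#'   intensity, peak, clipped, flagLong), \code{scan} (the
#'   [ThresholdScan-class]) and \code{cutoff}.
#' @export
segmentSpots <- function(stack, cutoffs = NULL, minPixels = 8,
                         linkRadius = 4, radius = 4, tol = 0.02,
                         minRun = 3, connectivity = 8) {
    a <- if (is(stack, "FishStack")) stack@data else stack
    if (is.null(cutoffs)) {
        # span background to the top of the mature-spot brightness range;
        # the 99.5th percentile keeps the rare, far brighter transcription-
        # site voxels from stretching the grid into the site regime
        lo <- quantile(a, 0.5); hi <- quantile(a, 0.995)
        if (hi <= lo + 1) stop("stack has no dynamic range to scan")
        cutoffs <- seq(lo, hi, length.out = 60)
    }
    scan <- scanThresholds(stack, cutoffs, minPixels = minPixels, tol = tol,
                           minRun = minRun, connectivity = connectivity)
    if (!scanOK(scan))
        stop("no plateau in the threshold scan: insufficient ",
             "signal-to-background; sample fails quality control")
    obj <- findObjects2D(stack, selectedCutoff(scan), minPixels,
                         connectivity)
    spots <- linkObjects3D(obj, linkRadius = linkRadius)
    if (nrow(spots)) {
        m <- measureIntensity(stack, spots$x, spots$y, spots$z, radius)
        spots <- cbind(spots[, setdiff(names(spots), "members")], m,
                       members = spots$members)
    } else {
        spots$intensity <- numeric(0); spots$peak <- numeric(0)
        spots$clipped <- logical(0)
    }
    list(spots = spots, scan = scan, cutoff = selectedCutoff(scan))
}

#' Segment transcription sites and normalize to nascent units
#'
#' Bright nuclear transcription sites are segmented independently of mature
#' spots (their brightest plane is not always their largest, so they are
#' frequently misidentified by the mature-spot pass). The stack is
#' re-binarized at \code{siteFactor} (default 2.5) times the median mature
#' peak-pixel intensity, objects are linked and measured as for mature
#' spots, and each candidate's intensity is divided by the median mature
#' integrated intensity to give normalized nascent units. Only candidates
#' with at least \code{detectionCutoff} (default 2.0) units - twice the
#' intensity of a single mature mRNA - are reported as transcription sites.
#'
#' @inheritParams segmentSpots
#' @param matureSpots mature-spot data.frame from [segmentSpots()] (needs
#'   \code{intensity} and \code{peak} columns).
#' @param siteFactor pixel-cutoff multiplier on the median mature peak.
#' @param detectionCutoff minimum normalized units for a reported site.
#' @return data.frame of sites: x, y, z, npx, intensity, \code{units}
#'   (normalized nascent units).
#' @export
segmentSites <- function(stack, matureSpots, siteFactor = 2.5,
                         detectionCutoff = 2.0, minPixels = 8,
                         linkRadius = 4, radius = 4, connectivity = 8) {
    if (nrow(matureSpots) == 0 || !is.finite(median(matureSpots$intensity)) ||
        median(matureSpots$intensity) <= 0)
        stop("no measurable mature spots: cannot normalize transcription ",
             "sites for this stack")
    medPeak <- median(matureSpots$peak)
    medInt <- median(matureSpots$intensity)
    cutoff <- siteFactor * medPeak
    obj <- findObjects2D(stack, cutoff, minPixels, connectivity)
    cand <- linkObjects3D(obj, linkRadius = linkRadius)
    if (nrow(cand) == 0)
        return(data.frame(x = numeric(0), y = numeric(0), z = integer(0),
                          npx = integer(0), intensity = numeric(0),
                          units = numeric(0)))
    m <- measureIntensity(stack, cand$x, cand$y, cand$z, radius)
    units <- m$intensity / medInt
    keep <- units >= detectionCutoff
    out <- data.frame(x = cand$x, y = cand$y, z = cand$z, npx = cand$npx,
                      intensity = m$intensity, units = units)[keep, ]
    rownames(out) <- NULL
    out
}
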