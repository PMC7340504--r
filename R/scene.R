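#' Specification of a synthetic smFISH scene
#'
#' Describes a ground-truthed synthetic two-channel confocal stack: a FISH
#' channel containing diffraction-limited mature-mRNA spots of homogeneous
#' intensity plus a smaller population of brighter, variable transcription
#' sites inside nuclei, and a nuclear channel of non-overlapping disk stacks.
#' Rendering is fully determined by the spec and its seed.
#'
#' Optics default to the acquisition constants of the imaging protocol the
#' pipeline targets: 76 nm x-y pixels, 345 nm z-spacing, and a lateral spot
#' FWHM of ~600 nm (8 pixels), so each spot is visible in 2-3 consecutive
#' z-sections.
#'
#' @slot dims integer (nx, ny, nz) voxel dimensions.
#' @slot pixelSizeNM,zSpacingNM calibration in nm.
#' @slot nSpots number of mature mRNA spots.
#' @slot spotAmpMean,spotAmpSD peak-amplitude distribution of mature spots
#'   (unimodal Gaussian, 12-bit units).
#' @slot nSites number of transcription sites (at most one per nucleus).
#' @slot siteMultiplierRange amplitude multipliers of sites relative to the
#'   mean mature amplitude, drawn uniformly; must be >= 1.
#' @slot nNuclei,nucleusRadius,nucleusHalfHeight nucleus count, lateral
#'   radius (px) and half-height (z-sections; each nucleus spans
#'   \code{2*halfHeight + 1} sections).
#' @slot background,noiseSD constant background level and additive Gaussian
#'   noise SD (shot-noise approximation).
#' @slot psfSigmaLateralNM lateral Gaussian PSF sigma in nm (default from a
#'   600 nm FWHM).
#' @slot sectionThicknessNM optical section thickness in nm (default 700);
#'   the axial profile of a spot is the slab integral over each section, so
#'   overlapping sections (700 nm thick, 345 nm apart) see nearly the full
#'   intensity.
#' @slot psfSigmaAxialNM residual axial blur in nm softening the slab edges
#'   (default 100).
#' @slot profile optional function \code{f(x, y)} giving the relative
#'   expected expression at lateral position (pixels); used to weight spot
#'   placement and site assignment (a synthetic morphogen gradient).
#' @slot minSeparation minimum lateral spot separation (px) for spots fewer
#'   than 4 z-sections apart (default 16, almost 5 lateral PSF sigmas), so
#'   neighbouring spots stay resolvable: closer pairs bridge above
#'   threshold where their Gaussian tails sum.
#' @slot zPlacement \code{"subvoxel"} (default) places spots at continuous
#'   z; \code{"integer"} centres every spot on a section, the idealised
#'   geometry in which all spots share identical per-section weights.
#' @slot seed integer RNG seed.
#'
#' @examples
#' sp <- SceneSpec(dims = c(128, 128, 12), nSpots = 40, nSites = 3,
#'                 nNuclei = 6, seed = 1)
#' sc <- renderScene(sp)
#' dim(sc$fish)
#' @export
setClass("SceneSpec", representation(
    dims = "integer",
    pixelSizeNM = "numeric", zSpacingNM = "numeric",
    nSpots = "integer", spotAmpMean = "numeric", spotAmpSD = "numeric",
    nSites = "integer", siteMultiplierRange = "numeric",
    nNuclei = "integer", nucleusRadius = "numeric",
    nucleusHalfHeight = "integer",
    background = "numeric", noiseSD = "numeric",
    psfSigmaLateralNM = "numeric", sectionThicknessNM = "numeric",
    psfSigmaAxialNM = "numeric",
    profile = "functionOrNULL",
    minSeparation = "numeric",
    zPlacement = "character",
    seed = "integer"
))

setValidity("SceneSpec", function(object) {
    if (length(object@dims) != 3L || any(object@dims < 1L))
        return("dims must be three positive integers (nx, ny, nz)")
    if (object@pixelSizeNM <= 0 || object@zSpacingNM <= 0)
        return("calibration must be positive")
    if (object@nSpots < 0 || object@nSites < 0 || object@nNuclei < 0)
        return("counts must be non-negative")
    if (any(object@siteMultiplierRange < 1))
        return("site multipliers must be >= 1")
    if (object@nSites > 0 && object@nSites > object@nNuclei)
        return("at most one transcription site per nucleus")
    if (object@spotAmpMean <= 0) return("spotAmpMean must be positive")
    if (object@noiseSD < 0) return("noiseSD must be >= 0")
    if (!object@zPlacement %in% c("subvoxel", "integer"))
        return("zPlacement must be 'subvoxel' or 'integer'")
    TRUE
})

#' @param dims,pixelSizeNM,zSpacingNM,nSpots,spotAmpMean,spotAmpSD see slots.
#' @param nSites,siteMultiplierRange,nNuclei,nucleusRadius see slots.
#' @param nucleusHalfHeight,background,noiseSD see slots.
#' @param psfSigmaLateralNM,sectionThicknessNM,psfSigmaAxialNM see slots.
#' @param profile,minSeparation,zPlacement,seed see slots.
#' @rdname SceneSpec-class
#' @export
SceneSpec <- function(dims = c(256L, 256L, 16L), pixelSizeNM = 76,
                      zSpacingNM = 345, nSpots = 200L, spotAmpMean = 400,
                      spotAmpSD = 30, nSites = 0L,
                      siteMultiplierRange = c(3, 8), nNuclei = 0L,
                      nucleusRadius = 32, nucleusHalfHeight = 4L,
                      background = 100, noiseSD = 8,
                      psfSigmaLateralNM = 600 / (2 * sqrt(2 * log(2))),
                      sectionThicknessNM = 700,
                      psfSigmaAxialNM = 100, profile = NULL,
                      minSeparation = 16, zPlacement = "subvoxel",
                      seed = 1L) {
    new("SceneSpec", dims = as.integer(dims), pixelSizeNM = pixelSizeNM,
        zSpacingNM = zSpacingNM, nSpots = as.integer(nSpots),
        spotAmpMean = spotAmpMean, spotAmpSD = spotAmpSD,
        nSites = as.integer(nSites),
        siteMultiplierRange = siteMultiplierRange,
        nNuclei = as.integer(nNuclei), nucleusRadius = nucleusRadius,
        nucleusHalfHeight = as.integer(nucleusHalfHeight),
        background = background, noiseSD = noiseSD,
        psfSigmaLateralNM = psfSigmaLateralNM,
        sectionThicknessNM = sectionThicknessNM,
        psfSigmaAxialNM = psfSigmaAxialNM, profile = profile,
        minSeparation = minSeparation, zPlacement = zPlacement,
        seed = as.integer(seed))
}

#' @param object a \code{SceneSpec}.
#' @rdname SceneSpec-class
#' @export
setMethod("show", "SceneSpec", function(object) {
    d <- object@dims
    cat(sprintf("SceneSpec: %d x %d x %d voxels, seed %d\n",
                d[1], d[2], d[3], object@seed))
    cat(sprintf("  %d mature spots (amp %g +/- %g), %d sites (x%g..%g), %d nuclei (r=%g px)\n",
                object@nSpots, object@spotAmpMean, object@spotAmpSD,
                object@nSites, object@siteMultiplierRange[1],
                object@siteMultiplierRange[2], object@nNuclei,
                object@nucleusRadius))
})

## Patch of one diffraction-limited blob, peak `amp` at 0-based subvoxel
## position (x, y, z), as (index ranges, values) to add into the stack.
## Lateral profile is Gaussian (sxy in px). The axial profile models optical
## sectioning: each section integrates a slab of half-thickness h2
## (sections), softened by the residual axial blur sz, so neighbouring
## (overlapping) sections see almost the full intensity and sections beyond
## the slab almost none. This confines a spot to 2-3 consecutive z-sections.
## (Returned as a patch rather than adding inside a helper so the caller's
## stack array stays modify-in-place.)
.blobPatch <- function(d, x, y, z, amp, sxy, sz, h2) {
    rx <- ceiling(4 * sxy)
    rz <- ceiling(h2 + 4 * sz)
    xi <- max(1L, floor(x + 1 - rx)):min(d[1], ceiling(x + 1 + rx))
    yi <- max(1L, floor(y + 1 - rx)):min(d[2], ceiling(y + 1 + rx))
    zi <- max(1L, floor(z + 1 - rz)):min(d[3], ceiling(z + 1 + rz))
    gx <- exp(-((xi - 1 - x)^2) / (2 * sxy^2))
    gy <- exp(-((yi - 1 - y)^2) / (2 * sxy^2))
    dz <- zi - 1 - z
    gz <- pnorm((dz + h2) / sz) - pnorm((dz - h2) / sz)
    gz <- gz / (pnorm(h2 / sz) - pnorm(-h2 / sz))
    list(xi = xi, yi = yi, zi = zi,
         vals = amp * outer(outer(gx, gy), gz))
}

## Sample n lateral positions in [margin, nx-1-margin] x [margin, ny-1-margin],
## optionally weighted by profile(x, y), with a lateral hard-core constraint
## against points fewer than zSep sections away in z.
.placeSpots <- function(n, d, margin, minSep, zSep, profile, zRange) {
    if (n == 0L) return(matrix(numeric(0), 0, 3))
    lo <- c(margin, margin, zRange[1])
    hi <- c(d[1] - 1 - margin, d[2] - 1 - margin, zRange[2])
    if (any(hi <= lo)) stop("scene too small for the requested margins")
    wmax <- 1
    if (!is.null(profile)) {
        gx <- seq(lo[1], hi[1], length.out = 32)
        gy <- seq(lo[2], hi[2], length.out = 32)
        wmax <- max(outer(gx, gy, profile))
        if (!is.finite(wmax) || wmax <= 0)
            stop("profile must be positive somewhere in the scene")
    }
    pts <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    maxTries <- 200L * n
    cell <- max(minSep, 1)
    grid <- new.env(hash = TRUE, parent = emptyenv())
    keyOf <- function(p) paste(floor(p[1] / cell), floor(p[2] / cell))
    while (placed < n) {
        tries <- tries + 1L
        if (tries > maxTries)
            stop(sprintf(paste0("could not place %d spots with minimum ",
                                "separation %g in a %d x %d x %d volume; ",
                                "the scene is infeasibly dense"),
                         n, minSep, d[1], d[2], d[3]))
        p <- lo + runif(3) * (hi - lo)
        if (!is.null(profile) && runif(1) > profile(p[1], p[2]) / wmax) next
        cx <- floor(p[1] / cell); cy <- floor(p[2] / cell)
        ok <- TRUE
        for (ix in (cx - 1L):(cx + 1L)) for (iy in (cy - 1L):(cy + 1L)) {
            ids <- grid[[paste(ix, iy)]]
            if (is.null(ids)) next
            q <- pts[ids, , drop = FALSE]
            lat <- sqrt((q[, 1] - p[1])^2 + (q[, 2] - p[2])^2)
            if (any(lat < minSep & abs(q[, 3] - p[3]) < zSep)) { ok <- FALSE; break }
        }
        if (!ok) next
        placed <- placed + 1L
        pts[placed, ] <- p
        k <- keyOf(p)
        grid[[k]] <- c(grid[[k]], placed)
    }
    pts
}

## Nucleus centers on a jittered square grid: guarantees non-overlap.
.placeNuclei <- function(n, d, radius, gap = 6) {
    if (n == 0L) return(matrix(numeric(0), 0, 2))
    spacing <- 2 * radius + gap
    margin <- radius + 2
    cx <- seq(margin, d[1] - 1 - margin, by = spacing)
    cy <- seq(margin, d[2] - 1 - margin, by = spacing)
    if (length(cx) * length(cy) < n)
        stop(sprintf("cannot place %d non-overlapping nuclei of radius %g in %d x %d",
                     n, radius, d[1], d[2]))
    pos <- as.matrix(expand.grid(x = cx, y = cy))
    pos <- pos[sample.int(nrow(pos), n), , drop = FALSE]
    pos + matrix(runif(2 * n, -gap / 3, gap / 3), n, 2)
}

#' Render a synthetic smFISH scene with ground truth
#'
#' Produces a two-channel 3D stack from a [SceneSpec-class]: the FISH
#' channel holds mature mRNA spots rendered as anisotropic 3D Gaussians
#' (lateral FWHM ~600 nm; each spot visible in 2-3 consecutive z-sections)
#' plus brighter transcription sites placed inside nuclei; the nuclear
#' channel holds non-overlapping disk stacks ("pancakes") per nucleus.
#' Constant background and additive Gaussian noise are applied and values
#' are clipped to the 12-bit range. Identical spec (including seed) gives
#' bit-identical stacks.
#'
#' @param spec a [SceneSpec-class].
#' @return list with \code{fish} and \code{nuclei} ([FishStack-class]) and
#'   \code{truth}, a list of data.frames: \code{spots} (x, y, z 0-based
#'   subvoxel centroids, amplitude, nearest-nucleus id), \code{sites}
#'   (centroid, owning nucleus, amplitude multiplier = true nascent units)
#'   and \code{nuclei} (id, centroid, radius).
#' @export
renderScene <- function(spec) {
    stopifnot(is(spec, "SceneSpec"))
    validObject(spec)
    set.seed(spec@seed)
    d <- spec@dims
    sxy <- spec@psfSigmaLateralNM / spec@pixelSizeNM       # px
    sz <- spec@psfSigmaAxialNM / spec@zSpacingNM           # sections
    h2 <- 0.5 * spec@sectionThicknessNM / spec@zSpacingNM  # slab half-depth

    # capacity guard: spots conflict when closer than minSeparation in x-y
    # and fewer than 4 sections apart in z, so pack per 4-section band at a
    # conservative fraction of the random-sequential-adsorption limit
    bands <- max(1, floor(d[3] / 4))
    margin0 <- ceiling(2.5 * sxy) + 1
    discArea <- pi * (spec@minSeparation / 2)^2
    capacity <- max(bands * 0.45 * (d[1] - 2 * margin0) *
                    (d[2] - 2 * margin0) / max(discArea, 1), bands)
    if (spec@nSpots > capacity)
        stop(sprintf(paste0("%d spots exceed the packing capacity (~%d) of ",
                            "this volume at minimum separation %g; enlarge ",
                            "the scene or reduce the count"),
                     spec@nSpots, round(capacity), spec@minSeparation))

    # nuclei ---------------------------------------------------------------
    nucXY <- .placeNuclei(spec@nNuclei, d, spec@nucleusRadius)
    hh <- spec@nucleusHalfHeight
    if (spec@nNuclei > 0L) {
        zc <- if (d[3] >= 2 * hh + 1)
            runif(spec@nNuclei, hh, d[3] - 1 - hh)
        else rep((d[3] - 1) / 2, spec@nNuclei)
        nuclei <- data.frame(id = seq_len(spec@nNuclei),
                             x = nucXY[, 1], y = nucXY[, 2], z = zc,
                             radius = spec@nucleusRadius)
    } else {
        nuclei <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                             z = numeric(0), radius = numeric(0))
    }

    # mature spots ----------------------------------------------------------
    margin <- ceiling(2.5 * sxy) + 1
    zmargin <- 1
    pts <- .placeSpots(spec@nSpots, d, margin, spec@minSeparation, 4,
                       spec@profile, c(zmargin, d[3] - 1 - zmargin))
    if (spec@zPlacement == "integer") pts[, 3] <- round(pts[, 3])
    amps <- pmax(rnorm(spec@nSpots, spec@spotAmpMean, spec@spotAmpSD),
                 0.25 * spec@spotAmpMean)
    spots <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        amplitude = amps)

    # transcription sites: inside a nucleus, near its centroid --------------
    if (spec@nSites > 0L) {
        w <- rep(1, spec@nNuclei)
        if (!is.null(spec@profile))
            w <- pmax(vapply(seq_len(spec@nNuclei),
                             function(i) spec@profile(nuclei$x[i], nuclei$y[i]),
                             numeric(1)), 0)
        if (sum(w) <= 0) w <- rep(1, spec@nNuclei)
        owner <- sample.int(spec@nNuclei, spec@nSites, prob = w)
        th <- runif(spec@nSites, 0, 2 * pi)
        rr <- runif(spec@nSites, 0, 0.3 * spec@nucleusRadius)
        mult <- runif(spec@nSites, spec@siteMultiplierRange[1],
                      spec@siteMultiplierRange[2])
        sites <- data.frame(
            x = nuclei$x[owner] + rr * cos(th),
            y = nuclei$y[owner] + rr * sin(th),
            z = pmin(pmax(nuclei$z[owner] + runif(spec@nSites, -1, 1),
                          zmargin), d[3] - 1 - zmargin),
            nucleus = owner, multiplier = mult,
            amplitude = mult * spec@spotAmpMean)
    } else {
        sites <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                            nucleus = integer(0), multiplier = numeric(0),
                            amplitude = numeric(0))
    }

    # ground-truth cell membership: nearest nucleus centroid in physical units
    if (nrow(nuclei) > 0 && nrow(spots) > 0) {
        aniso <- spec@zSpacingNM / spec@pixelSizeNM
        nn <- function(px, py, pz) {
            d2 <- outer(px, nuclei$x, "-")^2 + outer(py, nuclei$y, "-")^2 +
                (aniso * outer(pz, nuclei$z, "-"))^2
            max.col(-d2, ties.method = "first")
        }
        spots$nucleus <- nn(spots$x, spots$y, spots$z)
    } else {
        spots$nucleus <- rep(NA_integer_, nrow(spots))
    }

    # render ----------------------------------------------------------------
    fish <- array(spec@background, dim = d)
    blobs <- rbind(spots[, c("x", "y", "z", "amplitude")],
                   sites[, c("x", "y", "z", "amplitude")])
    for (i in seq_len(nrow(blobs))) {
        p <- .blobPatch(d, blobs$x[i], blobs$y[i], blobs$z[i],
                        blobs$amplitude[i], sxy, sz, h2)
        fish[p$xi, p$yi, p$zi] <- fish[p$xi, p$yi, p$zi] + p$vals
    }
    if (spec@noiseSD > 0)
        fish <- fish + rnorm(length(fish), 0, spec@noiseSD)
    fish <- round(pmin(pmax(fish, 0), 4095))

    nuc <- array(spec@background, dim = d)
    if (nrow(nuclei) > 0) {
        xg <- 0:(d[1] - 1); yg <- 0:(d[2] - 1)
        nucAmp <- 1500 * runif(nrow(nuclei), 0.85, 1.15)
        for (i in seq_len(nrow(nuclei))) {
            disk <- outer((xg - nuclei$x[i])^2, (yg - nuclei$y[i])^2, "+") <=
                spec@nucleusRadius^2
            zlo <- max(1L, round(nuclei$z[i]) - hh + 1L)
            zhi <- min(d[3], round(nuclei$z[i]) + hh + 1L)
            for (k in zlo:zhi) nuc[, , k] <- nuc[, , k] + nucAmp[i] * disk
        }
    }
    if (spec@noiseSD > 0)
        nuc <- nuc + rnorm(length(nuc), 0, spec@noiseSD)
    nuc <- round(pmin(pmax(nuc, 0), 4095))

    list(fish = FishStack(fish, "fish", spec@pixelSizeNM, spec@zSpacingNM),
         nuclei = FishStack(nuc, "nuclei", spec@pixelSizeNM, spec@zSpacingNM),
         truth = list(spots = spots, sites = sites, nuclei = nuclei))
}
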