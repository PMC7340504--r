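#' Segment nuclei per 2D section
#'
#' Classical per-section nucleus segmentation of the nuclear-stain channel:
#' Gaussian smoothing, Otsu thresholding, and marker-based splitting of
#' touching nuclei by watershed on the distance map, with an expected
#' nuclear radius (default 32 px) setting the minimum accepted area.
#'
#' @param stack nuclear-channel [FishStack-class] (or 3D array).
#' @param expectedRadius expected nuclear radius in pixels.
#' @param smoothSigma Gaussian smoothing sigma (px).
#' @param minAreaFrac minimum object area as a fraction of the expected
#'   disk area \eqn{\pi r^2}.
#' @return integer label array of the same dimensions; 0 is background and
#'   each nucleus section is a distinct positive label (labels are unique
#'   within each section only; see [stackNuclei3D()]).
#' @export
segmentNuclei2D <- function(stack, expectedRadius = 32, smoothSigma = 2,
                            minAreaFrac = 0.25) {
    a <- if (is(stack, "FishStack")) stack@data else stack
    stopifnot(length(dim(a)) == 3L)
    d <- dim(a)
    labs <- array(0L, d)
    minArea <- minAreaFrac * pi * expectedRadius^2
    for (k in seq_len(d[3])) {
        img <- EBImage::Image(a[, , k] / 4095)
        sm <- EBImage::gblur(img, sigma = smoothSigma)
        rng <- range(sm)
        if (diff(rng) < 0.02) next            # blank section
        th <- EBImage::otsu(sm, range = rng)
        bw <- sm > th
        if (!any(bw)) next
        dm <- EBImage::distmap(bw)
        ws <- EBImage::watershed(dm, tolerance = expectedRadius / 4, ext = 1)
        lab <- EBImage::imageData(ws)
        sizes <- tabulate(lab[lab > 0])
        drop <- which(sizes < minArea)
        if (length(drop)) lab[lab %in% drop] <- 0L
        u <- sort(unique(lab[lab > 0]))
        if (length(u)) lab[] <- match(lab, c(0L, u), nomatch = 1L) - 1L
        labs[, , k] <- lab
    }
    labs
}

#' Stack per-section nucleus masks into 3D "pancake" objects
#'
#' Greedy forward pass through z: each 2D object is linked to the object in
#' the next section with which it shares the most pixels, inheriting its
#' identity. Objects that end up in a single section are disregarded (a
#' genuine nucleus spans several sections). Note the greedy pass can merge
#' two nuclei if both maximally overlap one object in the next section;
#' this mirrors the reference behaviour and is not corrected.
#'
#' @param labels integer label array from [segmentNuclei2D()] (per-section
#'   labels) or a pre-segmented 16-bit label stack in which every nucleus
#'   object is one grey level.
#' @param minSections minimum number of linked sections (default 2).
#' @return list with \code{nuclei} (data.frame: id, x, y, z centroid in
#'   0-based pixels/sections, npx, nSections) and \code{labels3d} (relabeled
#'   3D array).
#' @export
stackNuclei3D <- function(labels, minSections = 2) {
    d <- dim(labels)
    stopifnot(length(d) == 3L)
    # global ids: (z, per-section label)
    glab <- array(0L, d)
    nextId <- 0L
    idsPerZ <- vector("list", d[3])
    for (k in seq_len(d[3])) {
        lk <- labels[, , k]
        u <- sort(unique(lk[lk > 0]))
        if (!length(u)) next
        gl <- match(lk, u, nomatch = 0L)
        gl[gl > 0] <- gl[gl > 0] + nextId
        glab[, , k] <- gl
        idsPerZ[[k]] <- nextId + seq_along(u)
        nextId <- nextId + length(u)
    }
    if (nextId == 0L)
        return(list(nuclei = data.frame(id = integer(0), x = numeric(0),
                                        y = numeric(0), z = numeric(0),
                                        npx = integer(0),
                                        nSections = integer(0)),
                    labels3d = glab))
    parent <- seq_len(nextId)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_len(d[3] - 1L)) {
        a <- glab[, , k]; b <- glab[, , k + 1L]
        both <- a > 0L & b > 0L
        if (!any(both)) next
        ov <- table(a[both], b[both])
        for (r in seq_len(nrow(ov))) {
            j <- which.max(ov[r, ])
            if (ov[r, j] > 0) {
                ra <- find(as.integer(rownames(ov)[r]))
                rb <- find(as.integer(colnames(ov)[j]))
                if (ra != rb) parent[ra] <- rb
            }
        }
    }
    root <- vapply(seq_len(nextId), find, integer(1))
    idx <- which(glab > 0L)
    gl <- root[glab[idx]]
    co <- arrayInd(idx, d)
    # per-root stats
    sp <- split(seq_along(idx), gl)
    zsec <- lapply(sp, function(s) unique(co[s, 3]))
    keep <- names(sp)[lengths(zsec) >= minSections]
    relab <- setNames(seq_along(keep), keep)
    out <- array(0L, d)
    kk <- gl %in% as.integer(keep)
    out[idx[kk]] <- relab[as.character(gl[kk])]
    nuclei <- do.call(rbind, lapply(keep, function(r) {
        s <- sp[[r]]
        data.frame(id = relab[[r]], x = mean(co[s, 1]) - 1,
                   y = mean(co[s, 2]) - 1, z = mean(co[s, 3]) - 1,
                   npx = length(s),
                   nSections = length(unique(co[s, 3])))
    }))
    if (is.null(nuclei))
        nuclei <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                             z = numeric(0), npx = integer(0),
                             nSections = integer(0))
    rownames(nuclei) <- NULL
    list(nuclei = nuclei, labels3d = out)
}

## ---- bounded 3D Voronoi by half-space intersection -----------------------

## vertices of {x : A x <= b} by enumerating plane triples, with tolerance
.polyVertices <- function(A, b, tol = 1e-9) {
    m <- nrow(A)
    verts <- matrix(numeric(0), 0, 3)
    support <- list()
    combs <- utils::combn(m, 3)
    for (c in seq_len(ncol(combs))) {
        tri <- combs[, c]
        M <- A[tri, , drop = FALSE]
        if (abs(det(M)) < 1e-12) next
        v <- solve(M, b[tri])
        if (all(A %*% v <= b + tol * (1 + abs(b)))) {
            verts <- rbind(verts, as.numeric(v))
        }
    }
    unique(round(verts, 9))
}

## volume of the convex polytope with vertex set V (interior point known
## to be inside): sum of tetrahedra over facet fans via the planes
.polyVolume <- function(verts, A, b, tol = 1e-7) {
    if (nrow(verts) < 4) return(0)
    inner <- colMeans(verts)
    vol <- 0
    for (f in seq_len(nrow(A))) {
        on <- which(abs(A[f, ] %*% t(verts) - b[f]) <
                    tol * (1 + abs(b[f])))
        if (length(on) < 3) next
        fv <- verts[on, , drop = FALSE]
        # order facet vertices around the facet normal
        nrm <- A[f, ] / sqrt(sum(A[f, ]^2))
        ctr <- colMeans(fv)
        u <- fv[1, ] - ctr; u <- u - sum(u * nrm) * nrm
        if (sqrt(sum(u^2)) < 1e-12) next
        u <- u / sqrt(sum(u^2))
        w <- c(nrm[2] * u[3] - nrm[3] * u[2],
               nrm[3] * u[1] - nrm[1] * u[3],
               nrm[1] * u[2] - nrm[2] * u[1])
        rel <- sweep(fv, 2, ctr)
        ang <- atan2(rel %*% w, rel %*% u)
        fv <- fv[order(ang), , drop = FALSE]
        for (i in 2:(nrow(fv) - 1)) {
            M <- rbind(fv[1, ] - inner, fv[i, ] - inner, fv[i + 1, ] - inner)
            vol <- vol + abs(det(M)) / 6
        }
    }
    vol
}

#' Bounded 3D Voronoi tessellation of nucleus centroids
#'
#' Builds the Voronoi cell of every centroid - the convex region of all
#' points closer to it than to any other centroid - clipped to a bounding
#' box. Each cell is the intersection of the box half-spaces with the
#' perpendicular-bisector half-spaces towards the other centroids; the cell
#' boundaries are the points equidistant between two centroids. Bisectors
#' are taken from the nearest neighbours first and every computed vertex is
#' verified against all remaining centroids (missing planes are added and
#' the cell recomputed), so the result is exact.
#'
#' When \code{physicalUnits = TRUE} (default) z-coordinates are scaled by
#' the z-spacing to pixel-size ratio before tessellating, so distances are
#' isotropic in nm; pass the calibration of the source stack.
#'
#' @param centroids n x 3 matrix (x, y, z in pixels/sections).
#' @param box bounding box \code{c(xmin, xmax, ymin, ymax, zmin, zmax)} in
#'   the same pixel/section coordinates (typically the image extent).
#' @param physicalUnits scale z for anisotropy?
#' @param pixelSizeNM,zSpacingNM calibration used for the scaling.
#' @param kNeighbors number of nearest-neighbour bisectors tried before the
#'   exactness check pass.
#' @return a [VoronoiTessellation-class] (in the scaled coordinates; slot
#'   \code{centroids} holds the scaled points).
#' @export
tessellate <- function(centroids, box, physicalUnits = TRUE,
                       pixelSizeNM = 76, zSpacingNM = 345, kNeighbors = 16) {
    centroids <- as.matrix(centroids)
    stopifnot(ncol(centroids) == 3, length(box) == 6)
    # merge duplicate centroids
    key <- apply(round(centroids, 9), 1, paste, collapse = "/")
    if (anyDuplicated(key)) {
        warning("duplicate centroids merged before tessellation")
        centroids <- centroids[!duplicated(key), , drop = FALSE]
    }
    n <- nrow(centroids)
    stopifnot(n >= 1)
    zscale <- if (physicalUnits) zSpacingNM / pixelSizeNM else 1
    P <- centroids
    P[, 3] <- P[, 3] * zscale
    B <- box
    B[5:6] <- B[5:6] * zscale
    if (any(centroids[, 1] < box[1] | centroids[, 1] > box[2] |
            centroids[, 2] < box[3] | centroids[, 2] > box[4] |
            centroids[, 3] < box[5] | centroids[, 3] > box[6]))
        stop("all centroids must lie inside the bounding box")

    boxA <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                  c(0, 0, -1), c(0, 0, 1))
    boxb <- c(-B[1], B[2], -B[3], B[4], -B[5], B[6])

    cells <- vector("list", n)
    for (i in seq_len(n)) {
        others <- setdiff(seq_len(n), i)
        d2 <- colSums((t(P[others, , drop = FALSE]) - P[i, ])^2)
        cand <- others[order(d2)][seq_len(min(kNeighbors, length(others)))]
        repeat {
            A <- boxA; b <- boxb
            for (j in cand) {
                nj <- P[j, ] - P[i, ]
                A <- rbind(A, nj)
                b <- c(b, sum(nj * (P[i, ] + P[j, ]) / 2))
            }
            V <- .polyVertices(A, b)
            if (nrow(V) < 4) stop("degenerate Voronoi cell encountered")
            # exactness: every vertex must be no closer to any other centroid
            viol <- integer(0)
            rest <- setdiff(others, cand)
            if (length(rest)) {
                di <- colSums((t(V) - P[i, ])^2)
                for (j in rest) {
                    dj <- colSums((t(V) - P[j, ])^2)
                    if (any(dj < di - 1e-7)) viol <- c(viol, j)
                }
            }
            if (!length(viol)) {
                cells[[i]] <- list(vertices = V,
                                   planes = list(A = A, b = b),
                                   volume = .polyVolume(V, A, b))
                break
            }
            cand <- c(cand, viol)
        }
    }
    new("VoronoiTessellation", centroids = P, box = B, cells = cells)
}

#' Assign spot centroids to Voronoi cells
#'
#' Tests every point against the half-space inequalities of each cell (a
#' dot-product membership test against the convex hull). Points exactly on
#' a shared facet break ties to the lowest owning-nucleus index; points
#' outside the bounding box are dropped and counted.
#'
#' @param tess a [VoronoiTessellation-class].
#' @param points m x 3 matrix of spot centroids (x, y, z in the same
#'   pixel/section coordinates used to build the tessellation).
#' @param physicalUnits,pixelSizeNM,zSpacingNM apply the same z scaling as
#'   the tessellation.
#' @return list with \code{cell} (integer vector, NA for dropped points)
#'   and \code{nDropped}.
#' @export
assignPoints <- function(tess, points, physicalUnits = TRUE,
                         pixelSizeNM = 76, zSpacingNM = 345) {
    stopifnot(is(tess, "VoronoiTessellation"))
    points <- as.matrix(points)
    if (ncol(points) != 3) stop("points must be m x 3")
    zscale <- if (physicalUnits) zSpacingNM / pixelSizeNM else 1
    Q <- points
    Q[, 3] <- Q[, 3] * zscale
    B <- tess@box
    inside <- Q[, 1] >= B[1] & Q[, 1] <= B[2] &
              Q[, 2] >= B[3] & Q[, 2] <= B[4] &
              Q[, 3] >= B[5] & Q[, 3] <= B[6]
    cell <- rep(NA_integer_, nrow(Q))
    tol <- 1e-9
    for (i in seq_along(tess@cells)) {
        pend <- which(inside & is.na(cell))
        if (!length(pend)) break
        pl <- tess@cells[[i]]$planes
        ok <- rep(TRUE, length(pend))
        lhs <- pl$A %*% t(Q[pend, , drop = FALSE])
        ok <- apply(lhs <= pl$b + tol * (1 + abs(pl$b)), 2, all)
        cell[pend[ok]] <- i            # lowest index wins on shared facets
    }
    list(cell = cell, nDropped = sum(!inside))
}

#' Build virtual cells from nuclei, spots and sites
#'
#' Tessellates the image volume from nucleus centroids and assigns mature
#' mRNA spots and transcription sites to the resulting virtual cells.
#'
#' @param nuclei nucleus data.frame from [stackNuclei3D()].
#' @param spots mature-spot data.frame (columns x, y, z).
#' @param sites transcription-site data.frame (columns x, y, z, units).
#' @param box bounding box in pixel/section coordinates.
#' @inheritParams tessellate
#' @return list with \code{cells} (data.frame: nucleus id, centroid,
#'   nMRNA, nSites, \code{nascentUnits} = summed units of assigned sites,
#'   \code{maxSiteUnits}), \code{spotCell} and \code{siteCell} (assignment
#'   vectors) and \code{dropReport}.
#' @export
buildVirtualCells <- function(nuclei, spots, sites, box,
                              physicalUnits = TRUE, pixelSizeNM = 76,
                              zSpacingNM = 345) {
    stopifnot(nrow(nuclei) >= 1)
    tess <- tessellate(as.matrix(nuclei[, c("x", "y", "z")]), box,
                       physicalUnits, pixelSizeNM, zSpacingNM)
    asg <- assignPoints(tess, as.matrix(spots[, c("x", "y", "z")]),
                        physicalUnits, pixelSizeNM, zSpacingNM)
    sasg <- if (nrow(sites))
        assignPoints(tess, as.matrix(sites[, c("x", "y", "z")]),
                     physicalUnits, pixelSizeNM, zSpacingNM)
    else list(cell = integer(0), nDropped = 0L)
    nMRNA <- tabulate(asg$cell, nbins = nrow(nuclei))
    nSites <- tabulate(sasg$cell, nbins = nrow(nuclei))
    units <- rep(0, nrow(nuclei))
    maxu <- rep(0, nrow(nuclei))
    if (nrow(sites)) {
        ok <- !is.na(sasg$cell)
        if (any(ok)) {
            agg <- tapply(sites$units[ok], sasg$cell[ok], sum)
            units[as.integer(names(agg))] <- agg
            mg <- tapply(sites$units[ok], sasg$cell[ok], max)
            maxu[as.integer(names(mg))] <- mg
        }
    }
    cells <- data.frame(nucleus = nuclei$id, x = nuclei$x, y = nuclei$y,
                        z = nuclei$z, nMRNA = nMRNA, nSites = nSites,
                        nascentUnits = units, maxSiteUnits = maxu)
    list(cells = cells, tessellation = tess, spotCell = asg$cell,
         siteCell = sasg$cell,
         dropReport = c(spots = asg$nDropped, sites = sasg$nDropped))
}
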