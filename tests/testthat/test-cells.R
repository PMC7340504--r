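test_that("well-separated rendered nuclei are labeled per section and recovered in 3D", {
    spec <- SceneSpec(dims = c(512, 512, 12), nSpots = 0, nNuclei = 50,
                      nucleusRadius = 20, nucleusHalfHeight = 3, seed = 17)
    sc <- renderScene(spec)
    labs <- segmentNuclei2D(sc$nuclei, expectedRadius = 20)
    # a central section holds all 50 labels
    mid <- round(mean(sc$truth$nuclei$z)) + 1
    expect_equal(max(labs[, , mid]), 50)
    st <- stackNuclei3D(labs)
    expect_gte(nrow(st$nuclei) / 50, 0.85)
    # centroids agree with truth
    d2 <- outer(st$nuclei$x, sc$truth$nuclei$x, "-")^2 +
          outer(st$nuclei$y, sc$truth$nuclei$y, "-")^2
    expect_lt(max(sqrt(apply(d2, 1, min))), 3)
})

test_that("a blank nuclear section produces zero labels", {
    a <- array(100, c(64, 64, 3)) + array(rnorm(64 * 64 * 3, 0, 3), c(64, 64, 3))
    labs <- segmentNuclei2D(a, expectedRadius = 16)
    expect_true(all(labs == 0))
})

test_that("pancake stacking links identical disks and drops single-section objects", {
    labs <- array(0L, c(40, 40, 6))
    disk <- outer((1:40 - 15)^2, (1:40 - 15)^2, "+") <= 64
    for (k in 1:5) labs[, , k][disk] <- 1L          # sections 1-5
    labs[30:38, 30:38, 3] <- 2L                     # single-section square
    st <- stackNuclei3D(labs)
    expect_equal(nrow(st$nuclei), 1)
    expect_equal(st$nuclei$nSections, 5L)
    expect_equal(st$nuclei$x, 14, tolerance = 0.01)  # 0-based center
    expect_equal(st$nuclei$z, 2, tolerance = 0.01)   # mean of sections 0..4
})

test_that("laterally adjacent non-overlapping columns stay distinct nuclei", {
    labs <- array(0L, c(60, 40, 4))
    d1 <- outer((1:60 - 15)^2, (1:40 - 20)^2, "+") <= 49
    d2 <- outer((1:60 - 40)^2, (1:40 - 20)^2, "+") <= 49
    for (k in 1:4) { labs[, , k][d1] <- 1L; labs[, , k][d2] <- 2L }
    st <- stackNuclei3D(labs)
    expect_equal(nrow(st$nuclei), 2)
})

test_that("two centroids split the box at the perpendicular bisector", {
    tess <- tessellate(rbind(c(0, 5, 5), c(10, 5, 5)), c(0, 10, 0, 10, 0, 10),
                       physicalUnits = FALSE)
    vols <- cellVolumes(tess)
    expect_equal(vols, c(500, 500))
    # all vertices of the shared facet lie on x = 5
    v1 <- tess@cells[[1]]$vertices
    expect_true(any(abs(v1[, 1] - 5) < 1e-9))
    expect_true(all(v1[, 1] <= 5 + 1e-9))
})

test_that("a single centroid owns the whole box", {
    tess <- tessellate(matrix(c(3, 4, 5), 1), c(0, 10, 0, 8, 0, 6),
                       physicalUnits = FALSE)
    expect_equal(cellVolumes(tess), 480)
})

test_that("random tessellations conserve the box volume", {
    set.seed(11)
    C <- cbind(runif(100, 0, 40), runif(100, 0, 50), runif(100, 0, 25))
    box <- c(0, 40, 0, 50, 0, 25)
    tess <- tessellate(C, box, physicalUnits = FALSE)
    expect_equal(sum(cellVolumes(tess)), 40 * 50 * 25, tolerance = 1e-6)
})

test_that("duplicate centroids are merged with a warning", {
    C <- rbind(c(1, 1, 1), c(1, 1, 1), c(5, 5, 5))
    expect_warning(tess <- tessellate(C, c(0, 6, 0, 6, 0, 6),
                                      physicalUnits = FALSE), "duplicate")
    expect_equal(length(tess@cells), 2)
})

test_that("interior-point assignment equals the nearest-centroid rule", {
    set.seed(4)
    C <- cbind(runif(40, 0, 30), runif(40, 0, 30), runif(40, 0, 12))
    box <- c(0, 30, 0, 30, 0, 12)
    tess <- tessellate(C, box, physicalUnits = FALSE)
    pts <- cbind(runif(200, 0, 30), runif(200, 0, 30), runif(200, 0, 12))
    asg <- assignPoints(tess, pts, physicalUnits = FALSE)
    d2 <- outer(pts[, 1], C[, 1], "-")^2 + outer(pts[, 2], C[, 2], "-")^2 +
          outer(pts[, 3], C[, 3], "-")^2
    expect_equal(asg$cell, max.col(-d2, ties.method = "first"))
    expect_equal(asg$nDropped, 0)
})

test_that("a point between two nuclei goes to the nearer; outside points are dropped", {
    tess <- tessellate(rbind(c(0, 5, 5), c(10, 5, 5)), c(0, 10, 0, 10, 0, 10),
                       physicalUnits = FALSE)
    asg <- assignPoints(tess, rbind(c(4, 5, 5), c(11, 5, 5)),
                        physicalUnits = FALSE)
    expect_equal(asg$cell, c(1L, NA_integer_))
    expect_equal(asg$nDropped, 1)
    # exactly on the bisector plane: lowest owning index wins
    tie <- assignPoints(tess, rbind(c(5, 5, 5)), physicalUnits = FALSE)
    expect_equal(tie$cell, 1L)
})

test_that("assignment conserves points: assigned + dropped = total", {
    set.seed(6)
    C <- cbind(runif(20, 0, 20), runif(20, 0, 20), runif(20, 0, 10))
    tess <- tessellate(C, c(0, 20, 0, 20, 0, 10), physicalUnits = FALSE)
    pts <- cbind(runif(300, -2, 22), runif(300, -2, 22), runif(300, -1, 11))
    asg <- assignPoints(tess, pts, physicalUnits = FALSE)
    expect_equal(sum(!is.na(asg$cell)) + asg$nDropped, 300)
})

test_that("RNAs are assigned to their ground-truth cells for separated nuclei", {
    spec <- SceneSpec(dims = c(384, 384, 14), nSpots = 250, nNuclei = 25,
                      nSites = 0, seed = 23)
    sc <- renderScene(spec)
    d <- dim(sc$fish)
    box <- c(0, d[1] - 1, 0, d[2] - 1, 0, d[3] - 1)
    tess <- tessellate(as.matrix(sc$truth$nuclei[, c("x", "y", "z")]), box)
    asg <- assignPoints(tess, as.matrix(sc$truth$spots[, c("x", "y", "z")]))
    expect_gte(mean(asg$cell == sc$truth$spots$nucleus, na.rm = TRUE), 0.9)
})

test_that("virtual cells carry consistent counts in both anisotropy modes", {
    sc <- standardScene()
    seg <- standardSegmentation()
    labs <- segmentNuclei2D(sc$nuclei)
    nuc <- stackNuclei3D(labs)
    d <- dim(sc$fish)
    box <- c(0, d[1] - 1, 0, d[2] - 1, 0, d[3] - 1)
    for (phys in c(TRUE, FALSE)) {
        vc <- buildVirtualCells(nuc$nuclei, seg$seg$spots, seg$sites, box,
                                physicalUnits = phys)
        expect_equal(sum(vc$cells$nMRNA) + vc$dropReport[["spots"]],
                     nrow(seg$seg$spots))
        expect_equal(sum(vc$cells$nSites) + vc$dropReport[["sites"]],
                     nrow(seg$sites))
        expect_true(all(vc$cells$nSites == 0 | vc$cells$nascentUnits > 0))
    }
})
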