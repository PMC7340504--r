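test_that("2D objects respect the 8-pixel size floor and pixel-mean centroids", {
    a <- array(0, c(32, 32, 1))
    a[5:11, 5, 1] <- 100                      # 7-pixel line: below floor
    expect_equal(nrow(findObjects2D(a, 50)), 0)
    a[5:11, 6, 1] <- 100                      # now 14 pixels
    obj <- findObjects2D(a, 50)
    expect_equal(nrow(obj), 1)
    expect_equal(obj$npx, 14L)
    expect_equal(obj$x, mean(c(4:10, 4:10)))  # 0-based pixel mean
    expect_equal(obj$y, mean(c(rep(4, 7), rep(5, 7))))
})

test_that("connectivity switch separates diagonal components", {
    a <- array(0, c(20, 20, 1))
    a[2:5, 2:4, 1] <- 100                     # block A (12 px)
    a[6:9, 5:7, 1] <- 100                     # block B, diagonal touch at (5,4)/(6,5)
    expect_equal(nrow(findObjects2D(a, 50, minPixels = 8, connectivity = 8)), 1)
    expect_equal(nrow(findObjects2D(a, 50, minPixels = 8, connectivity = 4)), 2)
})

test_that("noise-free equal-amplitude spots give a flat plateau containing the cutoff", {
    # section-centred spots: all share identical per-section weights, the
    # idealised geometry where the count curve is exactly flat between cliffs
    spec <- SceneSpec(dims = c(256, 256, 16), nSpots = 200, spotAmpSD = 0,
                      noiseSD = 0, nNuclei = 0, zPlacement = "integer",
                      seed = 9)
    sc <- renderScene(spec)
    scan <- scanThresholds(sc$fish, seq(120, 420, by = 15))
    expect_true(scanOK(scan))
    p <- scan@plateau
    expect_gte(selectedCutoff(scan), scan@cutoffs[p[1]])
    expect_lte(selectedCutoff(scan), scan@cutoffs[p[2]])
    # 3D spot count at the selected cutoff within +/- 5% of ground truth
    obj <- findObjects2D(sc$fish, selectedCutoff(scan))
    spots <- linkObjects3D(obj)
    expect_lt(abs(nrow(spots) - 200) / 200, 0.05)
})

test_that("a blank stack yields a decreasing count curve and a quality flag", {
    spec <- SceneSpec(dims = c(128, 128, 8), nSpots = 0, nNuclei = 0,
                      background = 100, noiseSD = 6, seed = 2)
    sc <- renderScene(spec)
    scan <- scanThresholds(sc$fish, seq(112, 200, by = 5))
    expect_false(scanOK(scan))
    expect_true(is.na(selectedCutoff(scan)))
    pos <- scan@counts[scan@counts > 0]
    if (length(pos) > 1) expect_true(all(diff(pos) <= 0))
    expect_error(segmentSpots(sc$fish, cutoffs = seq(112, 200, by = 5)),
                 "quality control")
})

test_that("linking keeps the largest object of a group and drops singletons", {
    obj <- data.frame(id = 1:4,
                      z = c(1L, 2L, 3L, 7L),
                      x = c(10, 10.5, 10.2, 30),
                      y = c(10, 10.1, 9.8, 30),
                      npx = c(10L, 12L, 9L, 20L))
    obj$pixels <- I(as.list(1:4))
    sp <- linkObjects3D(obj)
    expect_equal(nrow(sp), 1)             # isolated z=7 object dropped
    expect_equal(sp$z, 2L)                # largest (12 px) wins
    expect_equal(sp$npx, 12L)
    expect_equal(sp$nSections, 3L)
    expect_identical(sort(unlist(sp$members)), 1:3)
})

test_that("no 2D object is claimed by two different 3D spots", {
    seg <- standardSegmentation()$seg
    members <- unlist(seg$spots$members)
    expect_equal(anyDuplicated(members), 0L)
})

test_that("chains longer than 3 sections are flagged, not dropped", {
    obj <- data.frame(id = 1:5, z = 1:5,
                      x = rep(10, 5) + 0.1 * (1:5), y = rep(10, 5),
                      npx = c(9L, 10L, 15L, 10L, 9L))
    obj$pixels <- I(as.list(1:5))
    sp <- linkObjects3D(obj)
    expect_equal(nrow(sp), 1)
    expect_true(sp$flagLong)
})

test_that("fixed-circle intensity is exact on uniform images and linear", {
    a <- array(7, c(32, 32, 3))
    m <- measureIntensity(a, 15, 15, 1)
    nDisk <- sum(outer((-4:4)^2, (-4:4)^2, "+") <= 16)
    expect_equal(m$intensity, 7 * nDisk)
    expect_false(m$clipped)
    m2 <- measureIntensity(a * 2, 15, 15, 1)
    expect_equal(m2$intensity, 2 * m$intensity)
    # clipped disk near the border is flagged
    expect_true(measureIntensity(a, 1, 15, 1)$clipped)
})

test_that("measured intensities preserve a 3:1 rendered amplitude ratio", {
    # two hand-built Gaussian spots, no noise, amplitudes 600 and 200
    a <- array(0, c(64, 64, 3))
    g <- function(cx, cy, amp) {
        for (x in 1:64) for (y in 1:64)
            a[x, y, 2] <<- a[x, y, 2] +
                amp * exp(-((x - 1 - cx)^2 + (y - 1 - cy)^2) / (2 * 3.35^2))
    }
    g(18, 20, 600)
    g(45, 40, 200)
    m <- measureIntensity(a, c(18, 45), c(20, 40), c(1, 1))
    expect_equal(m$intensity[1] / m$intensity[2], 3, tolerance = 0.02)
})

test_that("intensity measurement is independent of the segmentation cutoff", {
    sc <- standardScene()
    seg <- standardSegmentation()$seg
    p <- seg$scan@plateau
    c1 <- seg$scan@cutoffs[p[1]]; c2 <- seg$scan@cutoffs[p[2]]
    s1 <- linkObjects3D(findObjects2D(sc$fish, c1))
    s2 <- linkObjects3D(findObjects2D(sc$fish, c2))
    # counts stable across the plateau
    expect_lt(abs(nrow(s1) - nrow(s2)) / nrow(s1), 0.05)
    # shared spots get identical intensities from the fixed-radius circle
    d2 <- outer(s1$x, s2$x, "-")^2 + outer(s1$y, s2$y, "-")^2
    pair <- which(d2 < 1 & abs(outer(s1$z, s2$z, "-")) <= 1, arr.ind = TRUE)
    i1 <- measureIntensity(sc$fish, s1$x[pair[, 1]], s1$y[pair[, 1]],
                           s1$z[pair[, 1]])
    i2 <- measureIntensity(sc$fish, s2$x[pair[, 2]], s2$y[pair[, 2]],
                           s2$z[pair[, 2]])
    expect_gt(nrow(pair), 0.9 * nrow(s1))
    expect_equal(median(abs(i1$intensity - i2$intensity) / i1$intensity), 0,
                 tolerance = 0.02)
})

test_that("sites are detected with units near truth; dim candidates are excluded", {
    sc <- standardScene()
    seg <- standardSegmentation()
    sites <- seg$sites
    tr <- sc$truth$sites
    expect_equal(nrow(sites), nrow(tr))
    m <- matchTruth(sites, tr, radius = 6)
    expect_equal(m$recall, 1)
    # normalized units approximate the true amplitude multiplier
    ord <- apply(m$hits, 1, which.max)
    expect_equal(sites$units, tr$multiplier[ord], tolerance = 0.25)
    # genuinely mature spots all stay below the 2.0-unit detection cutoff
    spots <- seg$seg$spots
    nearSite <- apply(outer(spots$x, tr$x, "-")^2 +
                      outer(spots$y, tr$y, "-")^2 <= 36, 1, any)
    units <- spots$intensity / median(spots$intensity)
    expect_lt(max(units[!nearSite]), 2)
})

test_that("site calling is invariant to a global intensity scale", {
    sc <- standardScene()
    seg <- standardSegmentation()$seg
    sites1 <- segmentSites(sc$fish, seg$spots)
    scaled <- stackData(sc$fish) * 3
    spots3 <- seg$spots
    spots3$intensity <- spots3$intensity * 3
    spots3$peak <- spots3$peak * 3
    sites3 <- segmentSites(scaled, spots3)
    expect_equal(nrow(sites1), nrow(sites3))
    expect_equal(sites1$units, sites3$units, tolerance = 1e-10)
})

test_that("site segmentation aborts without mature spots to normalize by", {
    a <- array(100, c(64, 64, 6))
    empty <- data.frame(x = numeric(0), y = numeric(0), z = integer(0),
                        intensity = numeric(0), peak = numeric(0))
    expect_error(segmentSites(a, empty), "mature")
})

test_that("detected spots match a brute-force maxima oracle on a small stack", {
    spec <- SceneSpec(dims = c(32, 32, 10), nSpots = 2, noiseSD = 0,
                      background = 50, minSeparation = 10, seed = 31)
    sc <- renderScene(spec)
    a <- stackData(sc$fish)
    oracle <- bruteForceSpots(a, background = 50)
    spots <- linkObjects3D(findObjects2D(a, 150))
    expect_equal(nrow(spots), nrow(oracle))
    d2 <- outer(spots$x, oracle$x, "-")^2 + outer(spots$y, oracle$y, "-")^2
    expect_true(all(apply(d2, 1, min) <= 4))
})

test_that("standard fixture is recovered with high recall and low FDR", {
    sc <- standardScene()
    seg <- standardSegmentation()$seg
    m <- matchTruth(seg$spots, sc$truth$spots)
    expect_gte(m$recall, 0.95)
    expect_lte(m$fdr, 0.05)
    # centroid accuracy: mean displacement within 2 pixels of truth
    d2 <- outer(seg$spots$x, sc$truth$spots$x, "-")^2 +
          outer(seg$spots$y, sc$truth$spots$y, "-")^2
    expect_lt(mean(sqrt(apply(d2, 1, min))), 2)
})

test_that("the diffraction-limited diameter maps to 8 pixels", {
    expect_identical(spotDiameterPx(), 8L)
    expect_identical(spotDiameterPx(600, 76), 8L)
})
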