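# Shared fixtures, rendered once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
    .fixtures[[name]]
}

# standard mid-size scene: 120 spots, 4 sites, 4 nuclei
standardScene <- function() fixture("standard", function() {
    spec <- SceneSpec(dims = c(192, 192, 14), nSpots = 120, nSites = 4,
                      nNuclei = 4, siteMultiplierRange = c(4, 8), seed = 7)
    c(renderScene(spec), list(spec = spec))
})

standardSegmentation <- function() fixture("standardSeg", function() {
    sc <- standardScene()
    seg <- segmentSpots(sc$fish)
    sites <- segmentSites(sc$fish, seg$spots)
    list(seg = seg, sites = sites)
})

# match detected spots against truth within a lateral radius and z slack
matchTruth <- function(det, truth, radius = 4, zSlack = 2) {
    if (nrow(det) == 0 || nrow(truth) == 0)
        return(list(recall = 0, fdr = NA_real_))
    d2 <- outer(det$x, truth$x, "-")^2 + outer(det$y, truth$y, "-")^2
    zd <- abs(outer(det$z, truth$z, "-"))
    hit <- (d2 <= radius^2) & (zd <= zSlack)
    list(recall = mean(apply(hit, 2, any)),
         fdr = mean(!apply(hit, 1, any)),
         hits = hit)
}

# Independent brute-force spot enumeration for small noise-free stacks:
# find strict local maxima above background, then greedily cluster maxima
# closer than `radius` in x-y and 1 in z (one spot each). Shares no code
# with the threshold/link pipeline.
bruteForceSpots <- function(a, background, minHeight = 5) {
    d <- dim(a)
    maxima <- NULL
    for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
        v <- a[x, y, z]
        if (v <= background + minHeight) next
        nb <- a[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1)]
        nb[2, 2, 2] <- -Inf
        if (v > max(nb)) maxima <- rbind(maxima, c(x - 1, y - 1, z - 1, v))
    }
    if (is.null(maxima)) return(data.frame(x = numeric(0), y = numeric(0),
                                           z = numeric(0)))
    maxima <- maxima[order(-maxima[, 4]), , drop = FALSE]
    kept <- matrix(numeric(0), 0, 3)
    for (i in seq_len(nrow(maxima))) {
        p <- maxima[i, 1:3]
        if (nrow(kept)) {
            lat <- sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2)
            if (any(lat <= 4 & abs(kept[, 3] - p[3]) <= 2)) next
        }
        kept <- rbind(kept, p)
    }
    data.frame(x = kept[, 1], y = kept[, 2], z = kept[, 3])
}

# small three-replicate pipeline configuration used by pipeline and
# determinism tests
pipelineConfig <- function(outDir, seed = 5, bootstrap = 0L) {
    scene <- list(dims = c(256, 256, 12), nSpots = 150, nSites = 6,
                  nNuclei = 9, siteMultiplierRange = c(4, 8))
    list(seed = seed, outputDir = outDir, axis = "border", landmark = 0,
         scenes = list(scene, scene, scene), bootstrap = bootstrap)
}
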