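#' Run the full smFISH quantification pipeline on synthetic replicates
#'
#' Executes, per replicate: scene rendering (or stack loading), mature-spot
#' segmentation, transcription-site calling, nucleus segmentation and
#' stacking, Voronoi cell assignment and per-cell output; then registers
#' the replicates along the chosen axis, pools overlapping bins and writes
#' per-bin summaries. Every output CSV embeds a header comment with the
#' config hash and the seed, so a run is reproducible from its config
#' alone; identical config + seed gives byte-identical outputs.
#'
#' The configuration is a named list (or the path of a YAML file with the
#' same structure):
#' \describe{
#'   \item{seed}{root integer seed; per-replicate seeds derive from it.}
#'   \item{outputDir}{directory for CSV outputs and the QC report.}
#'   \item{scenes}{list of [SceneSpec-class] objects, one per replicate
#'     (their own seeds are overridden by the derived seeds), or a list of
#'     lists of \code{SceneSpec()} arguments when read from YAML.}
#'   \item{axis, landmark, binWidth}{binning parameters ([binCells()]).}
#'   \item{siteFactor, detectionCutoff, linkRadius, minPixels}{segmentation
#'     parameters.}
#'   \item{maxOffset}{registration search range ([registerReplicates()]).}
#'   \item{bootstrap}{resamples for per-bin CIs (0 disables).}
#' }
#'
#' @param config named list or YAML file path.
#' @return invisibly, a list with \code{cells} (per-replicate data.frames),
#'   \code{pooled} (pooled binned cells), \code{summary} (per-bin summary
#'   data.frame), \code{offsets}, and \code{qc} (plateau bounds, cutoffs,
#'   drop counts and parameters actually used).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- .fillConfig(config)
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    cfgHash <- digest::digest(cfg[setdiff(names(cfg), "outputDir")])
    stamp <- c(sprintf("burstFISH pipeline, config %s", cfgHash),
               sprintf("seed %d", cfg$seed))

    nRep <- length(cfg$scenes)
    cellsPerRep <- vector("list", nRep)
    binnedPerRep <- vector("list", nRep)
    profiles <- vector("list", nRep)
    qc <- list(config = cfg[setdiff(names(cfg), c("scenes", "outputDir"))],
               replicates = list())

    for (r in seq_len(nRep)) {
        spec <- cfg$scenes[[r]]
        if (!is(spec, "SceneSpec")) spec <- do.call(SceneSpec, spec)
        spec@seed <- cfg$seed * 1000L + r       # derived replicate seed
        scene <- renderScene(spec)

        seg <- segmentSpots(scene$fish, minPixels = cfg$minPixels,
                            linkRadius = cfg$linkRadius)
        sites <- segmentSites(scene$fish, seg$spots,
                              siteFactor = cfg$siteFactor,
                              detectionCutoff = cfg$detectionCutoff,
                              minPixels = cfg$minPixels,
                              linkRadius = cfg$linkRadius)

        labs <- segmentNuclei2D(scene$nuclei)
        nuc <- stackNuclei3D(labs)
        if (nrow(nuc$nuclei) == 0)
            stop("replicate ", r, ": no 3D nuclei segmented; pipeline halted")
        d <- dim(scene$fish)
        box <- c(0, d[1] - 1, 0, d[2] - 1, 0, d[3] - 1)
        vc <- buildVirtualCells(nuc$nuclei, seg$spots, sites, box,
                                pixelSizeNM = spec@pixelSizeNM,
                                zSpacingNM = spec@zSpacingNM)

        binned <- binCells(vc$cells, axis = cfg$axis,
                           landmark = cfg$landmark, binWidth = cfg$binWidth)
        cellsPerRep[[r]] <- vc$cells
        binnedPerRep[[r]] <- binned
        profiles[[r]] <- .binProfile(binned)
        qc$replicates[[r]] <- list(
            plateau = seg$scan@plateau, cutoff = seg$cutoff,
            nSpots = nrow(seg$spots), nSites = nrow(sites),
            nNuclei = nrow(nuc$nuclei), dropReport = vc$dropReport)

        writeDepositedCsv(
            cbind(vc$cells[, c("x", "y", "z")],
                  intensity = NA_real_,
                  vc$cells[, c("nucleus", "nMRNA", "nSites", "nascentUnits")]),
            file.path(cfg$outputDir, sprintf("cells_rep%d.csv", r)),
            comments = c(stamp, sprintf("replicate %d", r)))
        writeDepositedCsv(
            seg$spots[, c("x", "y", "z", "intensity")],
            file.path(cfg$outputDir, sprintf("spots_rep%d.csv", r)),
            comments = c(stamp, sprintf("replicate %d", r)))
    }

    # registration + pooling ------------------------------------------------
    offsets <- if (nRep >= 2)
        registerReplicates(profiles, maxOffset = cfg$maxOffset)
    else 0L
    pooled <- poolReplicates(binnedPerRep, offsets)
    qc$offsets <- offsets

    ciStats <- if (cfg$bootstrap > 0)
        c("medianMRNA", "fractionSite", "fano") else NULL
    set.seed(cfg$seed)
    summ <- do.call(rbind, lapply(sort(unique(pooled$bin)), function(b) {
        g <- pooled[pooled$bin == b, ]
        s <- summarizeBin(g$nMRNA, g$nSites > 0,
                          siteUnits = g$maxSiteUnits[g$nSites > 0],
                          mode = "allCells", ciStats = ciStats,
                          nResamples = cfg$bootstrap)
        cbind(data.frame(axis = cfg$axis, bin = b), s)
    }))
    utils::write.csv(summ, file.path(cfg$outputDir, "bin_summary.csv"),
                     row.names = FALSE)
    writeLines(yaml::as.yaml(.qcSerializable(qc)),
               file.path(cfg$outputDir, "qc_report.yaml"))

    invisible(list(cells = cellsPerRep, pooled = pooled, summary = summ,
                   offsets = offsets, qc = qc))
}

.fillConfig <- function(config) {
    defaults <- list(seed = 1L, outputDir = tempfile("burstfish_run_"),
                     axis = "border", landmark = 0, binWidth = 64,
                     siteFactor = 2.5, detectionCutoff = 2.0,
                     linkRadius = 4, minPixels = 8, maxOffset = 5,
                     bootstrap = 0L)
    unknown <- setdiff(names(config), c(names(defaults), "scenes"))
    if (length(unknown)) stop("unknown config fields: ",
                              paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, config)
    if (is.null(cfg$scenes) || !length(cfg$scenes))
        stop("config must provide at least one scene")
    cfg$seed <- as.integer(cfg$seed)
    cfg
}

## per-bin mRNA spot sums, on a common 0-based bin index range
.binProfile <- function(binned, nBins = max(binned$bin) + 1L) {
    p <- numeric(nBins)
    agg <- tapply(binned$nMRNA, binned$bin, sum)
    p[as.integer(names(agg)) + 1L] <- agg
    p
}

.qcSerializable <- function(x) {
    rapply(x, function(v) {
        if (is.function(v)) "<function>" else v
    }, how = "replace")
}
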