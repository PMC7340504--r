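#' Bin virtual cells along a developmental axis
#'
#' Cells are partitioned into contiguous spatial bins of \code{binWidth}
#' pixels (default 64, about one nucleus diameter) by the position of their
#' nuclear centroid. For the DV axis the distance is \code{|y - landmark|}
#' (the DV-midline y-coordinate) and the dorsal/ventral side is tracked;
#' for the border-to-boundary axis it is \code{x - landmark} (the pouch
#' border x-coordinate). Bins are half-open \code{[k*w, (k+1)*w)}: a
#' centroid at exactly one bin width lands in bin 1, not bin 0.
#'
#' @param cells data.frame of virtual cells (columns x, y at least).
#' @param axis \code{"dv"} or \code{"border"}.
#' @param landmark the DV-midline y (for \code{"dv"}) or pouch-border x
#'   (for \code{"border"}), in pixels; required.
#' @param binWidth bin width in pixels.
#' @return the input with added columns \code{distance}, \code{bin}
#'   (0-based index) and, for the DV axis, \code{side} ("dorsal" for
#'   \code{y < landmark}).
#' @export
binCells <- function(cells, axis = c("dv", "border"), landmark,
                     binWidth = 64) {
    axis <- match.arg(axis)
    if (missing(landmark) || is.null(landmark) || !is.finite(landmark))
        stop("a landmark coordinate (DV midline y or pouch border x) is ",
             "required to bin cells")
    if (axis == "dv") {
        cells$distance <- abs(cells$y - landmark)
        cells$side <- ifelse(cells$y < landmark, "dorsal", "ventral")
    } else {
        cells$distance <- cells$x - landmark
        if (any(cells$distance < 0))
            warning(sum(cells$distance < 0),
                    " cells lie outside the pouch border (negative distance)")
    }
    cells$bin <- floor(cells$distance / binWidth)
    cells
}

#' Summary statistics of one spatial bin
#'
#' Computes the per-bin statistics of the binned virtual-cell data: median
#' mRNAs per cell, the fraction of cells with at least one transcription
#' site, the median nascent units per site, and the Fano factor
#' (variance/mean of the mRNA-per-cell distribution; 1 for a Poisson birth-
#' death process, >1 for bursty transcription). Medians are used because
#' the count distributions are long-tailed.
#'
#' Two denominators for the site fraction are supported:
#' \code{"mrnaCells"} restricts to cells containing at least one mature
#' mRNA, \code{"allCells"} uses every cell in the bin. The median nascent
#' units are suppressed (NA) when fewer than \code{minSiteFrac} of cells
#' have a site or fewer than \code{minSites} sites exist, where the sample
#' is too small.
#'
#' @param mrna integer vector of mRNA counts per cell in the bin.
#' @param hasSite logical vector, same length: cell has >= 1 site.
#' @param siteUnits numeric vector of nascent units of the sites in the
#'   bin (one entry per site).
#' @param mode site-fraction denominator (see Details).
#' @param minSiteFrac,minSites floors below which the nascent median is
#'   suppressed.
#' @param ciStats character vector of statistics to bootstrap
#'   (\code{"medianMRNA"}, \code{"fractionSite"}, \code{"fano"},
#'   \code{"medianNascent"}), or NULL for none.
#' @param nResamples,level,seed bootstrap settings (see [bootstrapCI()]).
#' @return one-row data.frame: \code{n}, \code{medianMRNA},
#'   \code{fractionSite}, \code{medianNascent}, \code{fano}, plus
#'   \code{<stat>Low}/\code{<stat>High} columns for bootstrapped stats.
#' @export
summarizeBin <- function(mrna, hasSite, siteUnits = numeric(0),
                         mode = c("mrnaCells", "allCells"),
                         minSiteFrac = 0.05, minSites = 15,
                         ciStats = NULL, nResamples = 10000, level = 0.95,
                         seed = NULL) {
    mode <- match.arg(mode)
    stopifnot(length(mrna) >= 1, length(hasSite) == length(mrna))
    if (!is.null(seed)) set.seed(seed)
    denom <- if (mode == "mrnaCells") mrna > 0 else rep(TRUE, length(mrna))
    frac <- if (any(denom)) mean(hasSite[denom]) else NA_real_
    mu <- mean(mrna)
    fano <- if (mu > 0) var(mrna) / mu else NA_real_
    fracAll <- mean(hasSite)
    medNas <- if (fracAll >= minSiteFrac && length(siteUnits) >= minSites)
        median(siteUnits) else NA_real_
    out <- data.frame(n = length(mrna), medianMRNA = median(mrna),
                      fractionSite = frac, medianNascent = medNas,
                      fano = fano)
    for (st in ciStats) {
        ci <- switch(st,
            medianMRNA = bootstrapCI(mrna, median, nResamples, level),
            fano = bootstrapCI(mrna, function(v) if (mean(v) > 0)
                var(v) / mean(v) else NA_real_, nResamples, level),
            fractionSite = bootstrapCI(as.numeric(hasSite[denom]), mean,
                                       nResamples, level),
            medianNascent = if (!is.na(medNas))
                bootstrapCI(siteUnits, median, nResamples, level)
            else c(NA_real_, NA_real_),
            stop("unknown ciStat: ", st))
        out[[paste0(st, "Low")]] <- ci[1]
        out[[paste0(st, "High")]] <- ci[2]
    }
    out
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated bootstrap interval of a statistic: the
#' bias correction comes from the fraction of the bootstrap distribution
#' below the point estimate, the acceleration from the jackknife skewness.
#' Degenerate (all-equal) samples collapse to a zero-width interval at the
#' point estimate.
#'
#' @param values numeric vector (length >= 2).
#' @param statistic function of a numeric vector returning one number.
#' @param nResamples number of bootstrap resamples (default 10000).
#' @param level confidence level.
#' @param seed optional seed (set locally).
#' @return numeric \code{c(lower, upper)}.
#' @examples
#' bootstrapCI(rnorm(50), mean, nResamples = 2000, seed = 1)
#' @export
bootstrapCI <- function(values, statistic, nResamples = 10000,
                        level = 0.95, seed = NULL) {
    n <- length(values)
    stopifnot(n >= 2)
    if (!is.null(seed)) set.seed(seed)
    t0 <- statistic(values)
    if (length(unique(values)) == 1L) return(c(t0, t0))
    idx <- matrix(sample.int(n, n * nResamples, replace = TRUE), nResamples)
    tb <- apply(idx, 1, function(i) statistic(values[i]))
    tb <- tb[is.finite(tb)]
    if (!length(tb)) return(c(NA_real_, NA_real_))
    # bias correction
    z0 <- qnorm(pmin(pmax(mean(tb < t0) + 0.5 * mean(tb == t0),
                          1 / (2 * length(tb))),
                     1 - 1 / (2 * length(tb))))
    # acceleration from the jackknife
    tj <- vapply(seq_len(n), function(i) statistic(values[-i]), numeric(1))
    dj <- mean(tj) - tj
    denom <- sum(dj^2)^1.5
    a <- if (denom > 0) sum(dj^3) / (6 * denom) else 0
    alpha <- (1 - level) / 2
    zlo <- qnorm(alpha); zhi <- qnorm(1 - alpha)
    adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
    q <- quantile(tb, probs = c(adj(zlo), adj(zhi)), names = FALSE,
                  type = 6)
    q
}

#' Register replicate bin profiles by cross-correlation
#'
#' Replicate discs lack an unambiguous landmark, so their spatial-bin
#' profiles (per-bin mRNA spot sums) are registered to the first replicate
#' by the integer bin offset that maximizes the cross-correlation, up to
#' \code{maxOffset} bins. Flat profiles carry no registerable structure
#' and get offset 0 with a warning.
#'
#' @param profiles list of numeric vectors (per-bin mRNA sums), first is
#'   the reference.
#' @param maxOffset maximum |offset| searched, in bins.
#' @return integer vector of offsets, one per replicate (first is 0). An
#'   offset of +k means the replicate's bin i matches reference bin i + k.
#' @export
registerReplicates <- function(profiles, maxOffset = 5) {
    stopifnot(is.list(profiles), length(profiles) >= 2)
    ref <- profiles[[1]]
    vapply(seq_along(profiles), function(r) {
        if (r == 1L) return(0L)
        p <- profiles[[r]]
        if (sd(p) == 0 || sd(ref) == 0) {
            warning("flat profile in replicate ", r,
                    ": no registerable structure, using offset 0")
            return(0L)
        }
        offs <- -maxOffset:maxOffset
        cc <- vapply(offs, function(k) {
            # replicate bin i aligns with reference bin i + k
            i <- seq_along(p)
            j <- i + k
            ok <- j >= 1 & j <= length(ref)
            if (sum(ok) < 3) return(-Inf)
            x <- p[i[ok]]; y <- ref[j[ok]]
            if (sd(x) == 0 || sd(y) == 0) return(-Inf)
            stats::cor(x, y)
        }, numeric(1))
        offs[which.max(cc)]
    }, integer(1))
}

#' Pool registered replicate bins
#'
#' Shifts each replicate's bin indices by its registration offset and
#' concatenates the cells of overlapping bins.
#'
#' @param reps list of binned cell data.frames (with a \code{bin} column).
#' @param offsets integer offsets from [registerReplicates()].
#' @return one data.frame with \code{bin} replaced by the registered index
#'   and a \code{replicate} column added.
#' @export
poolReplicates <- function(reps, offsets) {
    stopifnot(length(reps) == length(offsets))
    do.call(rbind, lapply(seq_along(reps), function(r) {
        d <- reps[[r]]
        d$bin <- d$bin + offsets[r]
        d$replicate <- r
        d
    }))
}

#' Regression of transcription-site fraction on mRNA count
#'
#' Cells are binned by the number of mRNAs they contain; the fraction of
#' cells in each bin with a transcription site is regressed on the bin's
#' mean mRNA count by unweighted least squares. The slope and its
#' parametric 95\% confidence interval discriminate the bursting modes: a
#' positive slope is the signature of frequency-modulated expression.
#'
#' @param mrna integer mRNA counts per cell.
#' @param hasSite logical per cell.
#' @param countBinWidth width of the mRNA-count bins.
#' @param minCells minimum cells per count bin to enter the fit.
#' @param level confidence level of the parametric CI.
#' @return list with \code{slope}, \code{intercept}, \code{ci} (slope CI),
#'   \code{fit} (the \code{lm}), and \code{bins} (count, fraction, n).
#' @export
regressSiteFraction <- function(mrna, hasSite, countBinWidth = 5,
                                minCells = 10, level = 0.95) {
    stopifnot(length(mrna) == length(hasSite))
    b <- floor(mrna / countBinWidth)
    agg <- do.call(rbind, lapply(split(seq_along(mrna), b), function(i)
        data.frame(count = mean(mrna[i]), fraction = mean(hasSite[i]),
                   n = length(i))))
    agg <- agg[agg$n >= minCells, ]
    if (nrow(agg) < 3)
        stop("need at least 3 mRNA-count bins with >= ", minCells,
             " cells for the regression")
    fit <- lm(fraction ~ count, data = agg)
    ci <- suppressWarnings(confint(fit, "count", level = level))
    list(slope = unname(coef(fit)["count"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         ci = as.numeric(ci), fit = fit, bins = agg,
         df = fit$df.residual)
}
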