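#' @useDynLib burstFISH, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Burst descriptors of a telegraph parameter set
#'
#' Average burst size is the expected number of initiations per ON period,
#' \code{kini/koff}; average burst frequency is the inverse of the mean
#' OFF + ON cycle time, \code{1/(1/kon + 1/koff)} per minute.
#'
#' @param params a [TelegraphParams-class] object.
#' @return a positive number.
#' @examples
#' burstSize(TelegraphParams(0.1, 1, 20))       # 20
#' burstFrequency(TelegraphParams(0.1, 1, 20))  # 0.0909...
#' @export
burstSize <- function(params) params@kini / params@koff

#' @rdname burstSize
#' @export
burstFrequency <- function(params) 1 / (1 / params@kon + 1 / params@koff)

## Rate bounds used by the study's parameter sweeps (1/min).
.RATE_BOUNDS <- list(kini = c(0.2, 60), kon = c(0.008, 38),
                     koff = c(0.016, 20))

#' Built-in elongation-timing table
#'
#' Returns the [NascentTiming-class] object for one of the probed genes.
#' \code{tauElong} values (min): brk 1.35, dad 2.05, sens 5.15, salm 5.30,
#' omb 3.05, at an elongation rate of 1100 nt/min. The probe-region traversal
#' time \code{tauProbe} is not tabulated independently; by default it is
#' taken as \code{probeFraction * tauElong} (default 0.8), i.e. the probe
#' cassette occupies most of the region downstream of the 5'-most probe.
#'
#' @param gene one of \code{"brk"}, \code{"dad"}, \code{"sens"},
#'   \code{"salm"}, \code{"omb"}.
#' @param probeFraction fraction of \code{tauElong} taken as \code{tauProbe}.
#' @param tauProbe explicit probe traversal time (min), overriding
#'   \code{probeFraction}.
#' @return a [NascentTiming-class] object.
#' @examples
#' nascentTiming("brk")
#' @export
nascentTiming <- function(gene = c("brk", "dad", "sens", "salm", "omb"),
                          probeFraction = 0.8, tauProbe = NULL) {
    gene <- match.arg(gene)
    te <- c(brk = 1.35, dad = 2.05, sens = 5.15, salm = 5.30, omb = 3.05)[[gene]]
    tp <- if (is.null(tauProbe)) probeFraction * te else tauProbe
    new("NascentTiming", gene = gene, tauElong = te, tauProbe = tp,
        elongRate = 1100)
}

#' Exact Gillespie simulation of the telegraph model
#'
#' Runs the stochastic simulation algorithm for one gene copy set: starting
#' with zero mRNAs and the promoter OFF, each step draws an exponential
#' waiting time with mean \code{1/r_tot} (the summed propensity of the
#' enabled reactions) and picks a reaction with probability proportional to
#' its rate. Initiation is enabled only while the promoter is ON.
#'
#' @param params a [TelegraphParams-class] object.
#' @param nEvents number of reaction events to simulate (default 10000,
#'   enough to approximate the stationary state at the default rates).
#' @param seed optional integer seed (set locally).
#' @return a list with \code{trajectory} (data.frame: \code{time},
#'   \code{event} in \{"on","off","init","deg"\}, \code{ng}, \code{nm}),
#'   \code{finalTime}, \code{finalNM}, \code{finalNG} and \code{absorbed}
#'   (\code{TRUE} when all propensities vanished before \code{nEvents}).
#' @examples
#' tr <- gillespieRun(TelegraphParams(1, 1, 5), nEvents = 200, seed = 1)
#' tail(tr$trajectory)
#' @export
gillespieRun <- function(params, nEvents = 10000, seed = NULL) {
    stopifnot(is(params, "TelegraphParams"), nEvents >= 1)
    if (!is.null(seed)) set.seed(seed)
    out <- .ssa_trajectory_cpp(params@kon, params@koff, params@kini,
                               params@kdeg, params@ngtot, as.integer(nEvents))
    if (out$absorbed && length(out$time) == 0L)
        warning("all reaction rates are zero in the initial state; ",
                "the system is absorbing and no events occurred")
    ev <- c("on", "off", "init", "deg")[out$event]
    list(trajectory = data.frame(time = out$time, event = ev,
                                 ng = out$ng, nm = out$nm),
         finalTime = out$final_time, finalNM = out$final_nm,
         finalNG = out$final_ng, absorbed = out$absorbed)
}

#' Simulate a batch of independent alleles
#'
#' Runs \code{nRuns} independent Gillespie simulations and records, per run,
#' the sampled mature mRNA count and the ages (sampling time minus
#' initiation time) of all initiation events young enough to still be
#' nascent.
#'
#' By default (\code{tEnd = "auto"}) each run is sampled at a fixed time
#' chosen long after the relaxation times of decay and promoter switching,
#' so the sampled states follow the stationary master-equation distribution
#' exactly. Recording the state after a fixed number of reaction events
#' instead (\code{tEnd = NULL}) samples the embedded jump chain, which
#' over-represents event-dense burst periods; that mode is kept available
#' for comparison, with \code{nEvents} events per run.
#'
#' @inheritParams gillespieRun
#' @param nRuns number of independent simulations.
#' @param window maximum age (min) of initiations to retain; use at least
#'   \code{tauElong} of the gene to be scored.
#' @param tEnd \code{"auto"} (default), a positive sampling time in
#'   minutes, or \code{NULL} for event-count sampling.
#' @param nEvents events per run in event-count mode; in fixed-time mode a
#'   safety cap (raised automatically so runs reach \code{tEnd}).
#' @return list with \code{mature} (integer vector, length \code{nRuns}),
#'   \code{initAges} (list of numeric vectors), \code{absorbed} and
#'   \code{truncated} (runs that hit the event cap before \code{tEnd}).
#' @export
simulateAlleles <- function(params, nRuns, nEvents = 10000, window = 10,
                            tEnd = "auto", seed = NULL) {
    stopifnot(is(params, "TelegraphParams"), nRuns >= 1, nEvents >= 1)
    if (!is.null(seed)) set.seed(seed)
    cap <- as.integer(nEvents)
    if (is.null(tEnd)) {
        tEnd <- -1
    } else {
        if (identical(tEnd, "auto"))
            tEnd <- 15 * max(1 / params@kdeg,
                             1 / max(params@kon + params@koff, 1e-6))
        stopifnot(is.numeric(tEnd), tEnd > 0)
        # generous cap: mean stationary event rate times the horizon
        pon <- if (params@kon + params@koff > 0)
            params@kon / (params@kon + params@koff) else 0
        meanNM <- params@ngtot * pon * params@kini /
            max(params@kdeg, 1e-12)
        rate <- params@kon + params@koff + params@kini +
            params@kdeg * max(meanNM, 1)
        cap <- max(cap, as.integer(min(5e7, ceiling(3 * rate * tEnd))))
    }
    out <- .ssa_batch_cpp(params@kon, params@koff, params@kini, params@kdeg,
                          params@ngtot, cap, as.integer(nRuns), window,
                          tEnd)
    if (any(out$truncated))
        warning(sum(out$truncated), " runs hit the event cap before tEnd; ",
                "their state was sampled early")
    out
}

#' Probe-weighted nascent-RNA signal of one allele
#'
#' Converts initiation ages into normalized fluorescence units: a transcript
#' initiated less than \code{tauProbe} ago has the probe-binding region only
#' partially transcribed and contributes 0.5 units (the ensemble expectation
#' for partially transcribed RNAs); one aged between \code{tauProbe} and
#' \code{tauElong} carries the full probe cassette and contributes 1.0; older
#' transcripts have been released (they are mature) and contribute 0.
#'
#' @param ages numeric vector of initiation ages (min), or a trajectory list
#'   from [gillespieRun()].
#' @param timing a [NascentTiming-class] object.
#' @return the summed weight (a multiple of 0.5).
#' @examples
#' tm <- nascentTiming("brk", tauProbe = 1.35 * 0.5)
#' countNascent(c(0.1, 1.0, 10), tm)  # 0.5 + 1 + 0 = 1.5
#' @export
countNascent <- function(ages, timing) {
    stopifnot(is(timing, "NascentTiming"))
    if (is.list(ages)) {  # a gillespieRun() result
        tr <- ages$trajectory
        tinit <- tr$time[tr$event == "init"]
        ages <- ages$finalTime - tinit
    }
    sum(0.5 * (ages < timing@tauProbe) +
        1.0 * (ages >= timing@tauProbe & ages < timing@tauElong))
}

#' Randomly pair allele simulations into virtual cells
#'
#' Independent single-allele simulations are randomly paired to mimic the
#' two physically paired alleles of a nucleus, whose nascent transcripts
#' co-localize into a single transcription site. Paired mRNA and nascent
#' units are the pair sums; a site is called detected when the paired
#' nascent units reach \code{detectionCutoff} (default 2.0, the same cutoff
#' applied to imaging data).
#'
#' @param mature integer vector of per-allele mature counts.
#' @param nascent numeric vector of per-allele weighted nascent units.
#' @param detectionCutoff detection threshold in normalized units.
#' @param seed optional integer seed for the random pairing.
#' @return data.frame with one row per pair: \code{mrna}, \code{nascent},
#'   \code{detected}.
#' @examples
#' pairAlleles(c(3L, 1L), c(1, 1))$detected   # 2.0 units -> TRUE
#' @export
pairAlleles <- function(mature, nascent, detectionCutoff = 2.0, seed = NULL) {
    stopifnot(length(mature) == length(nascent), length(mature) >= 2)
    if (!is.null(seed)) set.seed(seed)
    n <- length(mature)
    if (n %% 2L == 1L) {
        warning("odd number of simulations; dropping one at random")
        drop <- sample.int(n, 1L)
        mature <- mature[-drop]; nascent <- nascent[-drop]
        n <- n - 1L
    }
    ord <- sample.int(n)
    i <- ord[seq(1L, n, by = 2L)]
    j <- ord[seq(2L, n, by = 2L)]
    units <- nascent[i] + nascent[j]
    data.frame(mrna = mature[i] + mature[j], nascent = units,
               detected = units >= detectionCutoff)
}

#' Paired-allele simulation summary for one parameter set
#'
#' Simulates \code{2 * nPairs} alleles, applies nascent weighting and random
#' pairing, and reports the transcription-site detection statistics: the
#' fraction of virtual cells whose paired nascent units reach the detection
#' cutoff, and the median nascent units among detected cells.
#'
#' @inheritParams gillespieRun
#' @inheritParams simulateAlleles
#' @param timing a [NascentTiming-class] object.
#' @param nPairs number of simulation pairs (default 1000).
#' @param detectionCutoff site-detection threshold in normalized units.
#' @return list with \code{pairs} (the [pairAlleles()] data.frame),
#'   \code{fractionDetected}, \code{medianNascentDetected} (NA when no pair
#'   is detected), \code{meanMRNA} and \code{medianMRNA}.
#' @export
simulatePairs <- function(params, timing, nPairs = 1000, nEvents = 10000,
                          detectionCutoff = 2.0, tEnd = "auto",
                          seed = NULL) {
    stopifnot(nPairs >= 1)
    if (!is.null(seed)) set.seed(seed)
    sim <- simulateAlleles(params, nRuns = 2L * nPairs, nEvents = nEvents,
                           window = timing@tauElong, tEnd = tEnd)
    nas <- vapply(sim$initAges, countNascent, numeric(1), timing = timing)
    pr <- pairAlleles(sim$mature, nas, detectionCutoff = detectionCutoff)
    det <- pr$nascent[pr$detected]
    list(pairs = pr,
         fractionDetected = mean(pr$detected),
         medianNascentDetected = if (length(det)) median(det) else NA_real_,
         meanMRNA = mean(pr$mrna), medianMRNA = median(pr$mrna))
}

#' Sweep one telegraph rate parameter
#'
#' Varies \code{kini} (modulating burst size alone, at fixed switching
#' rates) or \code{kon} (modulating burst frequency alone, at fixed burst
#' size), running [simulatePairs()] at each value. Values must stay within
#' the model's rate bounds: kini in [0.2, 60], kon in [0.008, 38], koff in
#' [0.016, 20] per minute.
#'
#' @param param which rate to vary: \code{"kini"}, \code{"kon"} or
#'   \code{"koff"}.
#' @param values numeric vector of rate values (1/min).
#' @param params baseline [TelegraphParams-class]; the swept slot is
#'   replaced at each value.
#' @inheritParams simulatePairs
#' @return data.frame with one row per value: the three rates, burst size
#'   and frequency, \code{fractionDetected} with a binomial 95% Monte-Carlo
#'   interval, and \code{medianNascent} among detected pairs.
#' @export
sweepParameter <- function(param = c("kini", "kon", "koff"), values, params,
                           timing, nPairs = 1000, nEvents = 10000,
                           detectionCutoff = 2.0, tEnd = "auto",
                           seed = NULL) {
    param <- match.arg(param)
    b <- .RATE_BOUNDS[[param]]
    if (any(values < b[1] | values > b[2]))
        stop(sprintf("%s values must lie within [%g, %g] /min",
                     param, b[1], b[2]))
    if (!is.null(seed)) set.seed(seed)
    rows <- lapply(values, function(v) {
        p <- params
        slot(p, param) <- v
        s <- simulatePairs(p, timing, nPairs = nPairs, nEvents = nEvents,
                           detectionCutoff = detectionCutoff, tEnd = tEnd)
        f <- s$fractionDetected
        mc <- f + c(-1.96, 1.96) * sqrt(f * (1 - f) / nPairs)
        data.frame(kon = p@kon, koff = p@koff, kini = p@kini,
                   burstSize = burstSize(p), burstFrequency = burstFrequency(p),
                   fractionDetected = f,
                   fracLow = max(0, mc[1]), fracHigh = min(1, mc[2]),
                   medianNascent = s$medianNascentDetected)
    })
    out <- do.call(rbind, rows)
    out$param <- param
    out$value <- values
    out
}

#' Map a (burst size, burst frequency) pair to telegraph rates
#'
#' The two burst descriptors under-determine the three rates; this policy
#' fixes the ratio \code{kon/koff} (default 1) so that
#' \code{koff = freq * (1 + ratio) / ratio}, \code{kon = ratio * koff} and
#' \code{kini = size * koff}. Combinations whose implied rates fall outside
#' the model bounds are infeasible and return \code{NULL}.
#'
#' @param size burst size (transcripts per burst).
#' @param freq burst frequency (1/min).
#' @param kdeg decay rate (1/min).
#' @param ratio the \code{kon/koff} ratio used to resolve the degeneracy.
#' @param ngtot gene copies per simulation.
#' @return a [TelegraphParams-class], or \code{NULL} when infeasible.
#' @export
ratesFromBursts <- function(size, freq, kdeg = 0.04, ratio = 1, ngtot = 1L) {
    koff <- freq * (1 + ratio) / ratio
    kon <- ratio * koff
    kini <- size * koff
    inb <- function(v, b) v >= b[1] & v <= b[2]
    if (!inb(kini, .RATE_BOUNDS$kini) || !inb(kon, .RATE_BOUNDS$kon) ||
        !inb(koff, .RATE_BOUNDS$koff)) return(NULL)
    TelegraphParams(kon = kon, koff = koff, kini = kini, kdeg = kdeg,
                    ngtot = ngtot)
}

#' Phase diagram of transcription-site detection
#'
#' Computes the fraction of virtual cells with a detectable transcription
#' site over a grid of burst sizes and burst frequencies, resolving each
#' grid point into rates via [ratesFromBursts()]. Grid points infeasible
#' under the rate bounds are reported as \code{NA}.
#'
#' @param sizes,freqs numeric grids of burst size and burst frequency.
#' @inheritParams simulatePairs
#' @inheritParams ratesFromBursts
#' @return list with \code{fraction} (matrix, sizes x freqs),
#'   \code{medianNascent} (same shape), and the input grids.
#' @export
phaseDiagram <- function(sizes, freqs, kdeg = 0.04, timing = nascentTiming("dad"),
                         nPairs = 1000, nEvents = 10000, ratio = 1,
                         detectionCutoff = 2.0, tEnd = "auto", seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    fr <- matrix(NA_real_, length(sizes), length(freqs),
                 dimnames = list(size = signif(sizes, 4),
                                 freq = signif(freqs, 4)))
    mn <- fr
    for (i in seq_along(sizes)) for (j in seq_along(freqs)) {
        p <- ratesFromBursts(sizes[i], freqs[j], kdeg = kdeg, ratio = ratio)
        if (is.null(p)) next
        s <- simulatePairs(p, timing, nPairs = nPairs, nEvents = nEvents,
                           detectionCutoff = detectionCutoff, tEnd = tEnd)
        fr[i, j] <- s$fractionDetected
        mn[i, j] <- s$medianNascentDetected
    }
    list(fraction = fr, medianNascent = mn, sizes = sizes, freqs = freqs)
}

#' Stationary distribution of the telegraph master equation
#'
#' Solves the chemical master equation of the two-state model on a truncated
#' state space (mRNA count 0..\code{nmMax}, active copies 0..\code{ngtot})
#' for its stationary distribution, by direct sparse solution of
#' \code{Q' p = 0} with normalization. This is the numerically exact
#' reference that the Gillespie sampler is validated against.
#'
#' @inheritParams gillespieRun
#' @param nmMax truncation of the mRNA state space; choose several times the
#'   stationary mean (a warning is issued when mass at the boundary exceeds
#'   1e-8).
#' @return list with \code{joint} (matrix \code{(nmMax+1) x (ngtot+1)} of
#'   probabilities), \code{marginal} (numeric vector over mRNA counts),
#'   \code{mean}, \code{variance} and \code{fano}.
#' @examples
#' st <- telegraphStationary(TelegraphParams(1, 1, 5), nmMax = 60)
#' st$fano
#' @export
telegraphStationary <- function(params, nmMax = 300) {
    stopifnot(is(params, "TelegraphParams"), nmMax >= 1)
    kon <- params@kon; koff <- params@koff
    kini <- params@kini; kdeg <- params@kdeg
    G <- params@ngtot
    nm <- 0:nmMax
    ng <- 0:G
    idx <- function(m, g) m + 1L + g * (nmMax + 1L)  # column-major state index
    nstate <- (nmMax + 1L) * (G + 1L)

    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    add <- function(from, to, rate) {
        keep <- rate > 0
        ii <<- c(ii, to[keep]); jj <<- c(jj, from[keep])
        xx <<- c(xx, rate[keep])
    }
    grid <- expand.grid(m = nm, g = ng)
    m <- grid$m; g <- grid$g; s <- idx(m, g)
    # initiation: (m, g) -> (m+1, g) at kini*g (truncated at nmMax)
    ok <- m < nmMax
    add(s[ok], idx(m[ok] + 1L, g[ok]), kini * g[ok])
    # decay: (m, g) -> (m-1, g) at kdeg*m
    ok <- m > 0
    add(s[ok], idx(m[ok] - 1L, g[ok]), kdeg * m[ok])
    # switch on: (m, g) -> (m, g+1) at kon*(G - g)
    ok <- g < G
    add(s[ok], idx(m[ok], g[ok] + 1L), kon * (G - g[ok]))
    # switch off: (m, g) -> (m, g-1) at koff*g
    ok <- g > 0
    add(s[ok], idx(m[ok], g[ok] - 1L), koff * g[ok])

    # diagonal holds minus the total outflow of each state
    outflow <- tapply(xx, jj, sum)
    dii <- as.integer(names(outflow))
    ii <- c(ii, dii); jj <- c(jj, dii); xx <- c(xx, -as.numeric(outflow))
    Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(nstate, nstate))
    # stationary: Q p = 0 (Q here is the generator acting on column p),
    # replace one balance equation by the normalization constraint
    A <- rbind(Q[-1, , drop = FALSE], rep(1, nstate))
    b <- c(rep(0, nstate - 1L), 1)
    p <- as.numeric(Matrix::solve(Matrix::crossprod(A),
                                  Matrix::crossprod(A, b)))
    p[p < 0 & p > -1e-12] <- 0
    p <- p / sum(p)

    joint <- matrix(p, nrow = nmMax + 1L, ncol = G + 1L)
    marg <- rowSums(joint)
    if (marg[nmMax + 1L] > 1e-8)
        warning("probability mass at the truncation boundary exceeds 1e-8; ",
                "increase nmMax")
    mu <- sum(nm * marg)
    v <- sum(nm^2 * marg) - mu^2
    list(joint = joint, marginal = marg, mean = mu, variance = v,
         fano = if (mu > 0) v / mu else NA_real_)
}

#' Closed-form stationary moments of the telegraph model
#'
#' Mean \code{ngtot * kon/(kon+koff) * kini/kdeg} and Fano factor
#' \code{1 + kini*koff / ((kon+koff) * (kdeg+kon+koff))} of the stationary
#' mRNA distribution (the Fano factor of a single copy; independent copies
#' share it for the per-copy distribution, and sums of iid copies keep the
#' same Fano factor).
#'
#' @inheritParams gillespieRun
#' @return list with \code{mean} and \code{fano}.
#' @export
telegraphMoments <- function(params) {
    kon <- params@kon; koff <- params@koff
    kini <- params@kini; kdeg <- params@kdeg
    pon <- kon / (kon + koff)
    list(mean = params@ngtot * pon * kini / kdeg,
         fano = 1 + kini * koff / ((kon + koff) * (kdeg + kon + koff)))
}
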