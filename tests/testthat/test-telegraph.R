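test_that("burst descriptors follow their definitions", {
    p <- TelegraphParams(kon = 0.1, koff = 1, kini = 20)
    expect_equal(burstSize(p), 20)
    expect_equal(burstFrequency(p), 1 / (1 / 0.1 + 1 / 1))
    # the parameter pairs used for fixed burst sizes 1, 4, 20
    for (bs in c(1, 4, 20)) {
        q <- TelegraphParams(kon = 0.5, koff = 2, kini = bs * 2)
        expect_equal(burstSize(q), bs)
    }
    expect_error(TelegraphParams(-1, 1, 1), "rates")
})

test_that("the timing table carries the gene elongation times", {
    expect_equal(nascentTiming("brk")@tauElong, 1.35)
    expect_equal(nascentTiming("dad")@tauElong, 2.05)
    expect_equal(nascentTiming("sens")@tauElong, 5.15)
    expect_equal(nascentTiming("salm")@tauElong, 5.30)
    expect_equal(nascentTiming("omb")@tauElong, 3.05)
    expect_equal(nascentTiming("brk")@elongRate, 1100)
    tm <- nascentTiming("brk", probeFraction = 0.5)
    expect_equal(tm@tauProbe, 0.675)
    expect_error(nascentTiming("brk", tauProbe = 2), "tauProbe")
})

test_that("an OFF promoter with kon = 0 never initiates", {
    p <- TelegraphParams(kon = 0, koff = 1, kini = 50)
    expect_warning(tr <- gillespieRun(p, nEvents = 100, seed = 1),
                   "absorbing")
    expect_equal(tr$finalNM, 0)
    expect_true(tr$absorbed)
})

test_that("trajectories respect the reaction bookkeeping", {
    tr <- gillespieRun(TelegraphParams(1, 1, 5), nEvents = 2000, seed = 3)
    d <- tr$trajectory
    expect_true(all(diff(d$time) > 0))
    expect_true(all(d$nm >= 0) && all(d$ng %in% 0:1))
    # initiation only while ON: ng was 1 just before every init event
    ini <- which(d$event == "init")
    prev <- d$ng[pmax(ini - 1, 1)]
    expect_true(all(prev[ini > 1] == 1))
})

test_that("nascent weighting follows the piecewise probe rule", {
    tm <- nascentTiming("brk", tauProbe = 1.35 * 0.5)
    expect_equal(countNascent(c(0.1, 1.0, 10), tm), 1.5)
    expect_equal(countNascent(numeric(0), tm), 0)
    # boundary ages: tauProbe is full weight, tauElong is mature
    expect_equal(countNascent(c(0.675, 1.35), tm), 1.0)
    # a site with two fully transcribed probe cassettes scores 12/6 = 2 units
    expect_identical(countNascent(c(0.8, 1.0), tm), 2.0)
})

test_that("pairing applies the inclusive 2.0 detection cutoff and conserves totals", {
    pr <- pairAlleles(c(3L, 1L), c(1, 1))
    expect_true(pr$detected)
    expect_equal(pr$nascent, 2.0)
    pr2 <- pairAlleles(c(0L, 0L), c(1, 0.5))
    expect_false(pr2$detected)
    set.seed(10)
    m <- rpois(100, 4); n <- runif(100, 0, 3)
    pr3 <- pairAlleles(m, n, seed = 1)
    expect_equal(sum(pr3$mrna), sum(m))
    expect_equal(sum(pr3$nascent), sum(n))
    expect_warning(pairAlleles(c(1L, 2L, 3L), c(1, 1, 1), seed = 2), "odd")
})

test_that("detection fraction is invariant to the pairing permutation", {
    p <- TelegraphParams(0.3, 1, 8)
    tm <- nascentTiming("dad")
    set.seed(21)
    sim <- simulateAlleles(p, 600, window = tm@tauElong)
    nas <- vapply(sim$initAges, countNascent, numeric(1), timing = tm)
    fr <- vapply(1:20, function(i)
        mean(pairAlleles(sim$mature, nas, seed = i)$detected), numeric(1))
    # pair sums change, but the fraction varies only by pairing noise
    expect_lt(diff(range(fr)), 0.1)
    expect_equal(mean(fr), mean(pairAlleles(sim$mature, nas, seed = 99)$detected),
                 tolerance = 0.05)
})

test_that("stationary moments match the closed-form telegraph formulas", {
    for (p in list(TelegraphParams(1, 1, 5),
                   TelegraphParams(0.05, 0.1, 2),
                   TelegraphParams(5, 0.5, 10))) {
        cm <- telegraphMoments(p)
        set.seed(17)
        sim <- simulateAlleles(p, 3000, window = 1)
        m <- mean(sim$mature)
        se <- sd(sim$mature) / sqrt(3000)
        expect_lt(abs(m - cm$mean), 3 * se)
        expect_equal(var(sim$mature) / m, cm$fano, tolerance = 0.12)
    }
})

test_that("the master-equation solver reproduces the closed-form moments", {
    for (p in list(TelegraphParams(1, 1, 5), TelegraphParams(0.08, 0.1, 0.4))) {
        st <- telegraphStationary(p, nmMax = 250)
        cm <- telegraphMoments(p)
        expect_equal(st$mean, cm$mean, tolerance = 1e-6)
        expect_equal(st$fano, cm$fano, tolerance = 1e-4)
    }
    # constitutive limit is exactly Poisson
    st <- telegraphStationary(TelegraphParams(10, 0, 4), nmMax = 250)
    expect_equal(st$marginal[1:150], dpois(0:149, 100), tolerance = 1e-6)
})

test_that("summary statistics are stable when the sampling horizon doubles", {
    p <- TelegraphParams(0.5, 0.5, 4)
    tm <- nascentTiming("dad")
    s1 <- simulatePairs(p, tm, nPairs = 800, tEnd = 400, seed = 5)
    s2 <- simulatePairs(p, tm, nPairs = 800, tEnd = 800, seed = 6)
    mcse <- sqrt(0.25 / 800)
    expect_lt(abs(s1$fractionDetected - s2$fractionDetected), 4 * mcse)
    expect_lt(abs(s1$meanMRNA - s2$meanMRNA) / s1$meanMRNA, 0.1)
})

test_that("sweeps stay inside the model's rate bounds", {
    p <- TelegraphParams(1, 1, 5)
    tm <- nascentTiming("brk")
    expect_error(sweepParameter("kini", c(0.1, 1), p, tm, nPairs = 10),
                 "within")
    expect_error(sweepParameter("kon", c(50), p, tm, nPairs = 10), "within")
})

test_that("rate resolution from burst coordinates inverts the definitions", {
    p <- ratesFromBursts(size = 4, freq = 0.2, ratio = 1)
    expect_equal(burstSize(p), 4)
    expect_equal(burstFrequency(p), 0.2)
    # infeasible corner returns NULL
    expect_null(ratesFromBursts(size = 1000, freq = 5))
})

test_that("detection vanishes without transcription and saturates when strong", {
    tm <- nascentTiming("dad")
    lo <- simulatePairs(TelegraphParams(0.008, 2, 0.5), tm, nPairs = 200,
                        seed = 2)
    expect_lt(lo$fractionDetected, 0.05)
    hi <- simulatePairs(TelegraphParams(5, 0.5, 40), tm, nPairs = 200,
                        seed = 3)
    expect_gt(hi$fractionDetected, 0.95)
})
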