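test_that("bin indices follow the half-open 64-pixel convention", {
    cells <- data.frame(x = c(100, 64, 63.9, 0), y = 0)
    b <- binCells(cells, axis = "border", landmark = 0, binWidth = 64)
    expect_equal(b$bin, c(1, 1, 0, 0))
    # DV axis: distance from the midline, sides tracked
    cells2 <- data.frame(x = 0, y = c(150, 250, 200))
    b2 <- binCells(cells2, axis = "dv", landmark = 200, binWidth = 64)
    expect_equal(b2$bin, c(0, 0, 0))
    expect_equal(b2$side, c("dorsal", "ventral", "ventral"))
    expect_error(binCells(cells, axis = "dv", landmark = NULL), "landmark")
})

test_that("bin summaries compute the defined statistics", {
    s <- summarizeBin(c(2, 2, 2, 2), hasSite = c(TRUE, FALSE, FALSE, FALSE))
    expect_equal(s$medianMRNA, 2)
    expect_equal(s$fano, 0)
    # 4 of 10 mRNA-containing cells have a site
    mrna <- c(rep(1, 10), 0, 0)
    hs <- c(rep(TRUE, 4), rep(FALSE, 8))
    expect_equal(summarizeBin(mrna, hs, mode = "mrnaCells")$fractionSite, 0.4)
    expect_equal(summarizeBin(mrna, hs, mode = "allCells")$fractionSite, 4 / 12)
})

test_that("Poisson counts give a Fano factor of 1", {
    set.seed(123)
    x <- rpois(5000, 10)
    s <- summarizeBin(x, hasSite = rep(FALSE, 5000))
    expect_equal(s$fano, 1, tolerance = 0.1)
})

test_that("the nascent median is suppressed below the small-sample floor", {
    mrna <- rep(5, 100)
    hs <- c(rep(TRUE, 3), rep(FALSE, 97))   # 3% of cells
    s <- summarizeBin(mrna, hs, siteUnits = c(2.5, 3, 4))
    expect_true(is.na(s$medianNascent))
    hs2 <- c(rep(TRUE, 20), rep(FALSE, 80))
    s2 <- summarizeBin(mrna, hs2, siteUnits = rep(c(2.5, 3.5), 10))
    expect_equal(s2$medianNascent, 3)
})

test_that("summaries are invariant to cell order", {
    set.seed(2)
    mrna <- rpois(200, 6)
    hs <- runif(200) < 0.3
    s1 <- summarizeBin(mrna, hs)
    perm <- sample(200)
    s2 <- summarizeBin(mrna[perm], hs[perm])
    expect_equal(s1, s2)
})

test_that("BCa intervals collapse on constant data and match boot's BCa", {
    expect_equal(bootstrapCI(rep(4, 20), mean), c(4, 4))
    set.seed(31)
    x <- rexp(80, 0.5)
    ours <- bootstrapCI(x, mean, nResamples = 4000, seed = 99)
    set.seed(99)
    ref <- boot::boot.ci(boot::boot(x, function(d, i) mean(d[i]), R = 4000),
                         type = "bca")$bca[4:5]
    expect_equal(as.numeric(ours), as.numeric(ref), tolerance = 1e-6)
})

test_that("BCa coverage for the mean of normal samples is near nominal", {
    set.seed(8)
    hits <- vapply(1:120, function(i) {
        x <- rnorm(60)
        ci <- bootstrapCI(x, mean, nResamples = 400)
        ci[1] <= 0 && 0 <= ci[2]
    }, logical(1))
    expect_gte(mean(hits), 0.88)   # 95% nominal, binomial noise at n=120
})

test_that("BCa approaches the percentile interval for a symmetric statistic", {
    set.seed(14)
    x <- rnorm(150, 10, 2)
    ours <- bootstrapCI(x, mean, nResamples = 6000, seed = 5)
    set.seed(5)
    idx <- matrix(sample.int(150, 150 * 6000, replace = TRUE), 6000)
    tb <- apply(idx, 1, function(i) mean(x[i]))
    perc <- quantile(tb, c(0.025, 0.975), names = FALSE)
    expect_equal(as.numeric(ours), perc, tolerance = 0.02)
})

test_that("replicate registration recovers known bin shifts", {
    p <- c(2, 3, 10, 30, 55, 32, 12, 4, 2, 1, 1, 1)
    shift <- function(v, k) if (k > 0) c(v[-(1:k)], rep(1, k)) else
        c(rep(1, -k), v[1:(length(v) + k)])
    expect_equal(registerReplicates(list(p, p)), c(0L, 0L))
    expect_equal(registerReplicates(list(p, shift(p, 3))), c(0L, 3L))
    expect_warning(off <- registerReplicates(list(p, rep(5, 12))), "flat")
    expect_equal(off[2], 0L)
})

test_that("noisy replicate shifts are recovered in >= 95% of seeded trials", {
    # profiles are per-bin mRNA spot sums, so their noise is counting noise
    set.seed(77)
    ok <- vapply(1:100, function(i) {
        shifts <- sample(-2:2, 2, replace = TRUE)
        reps <- lapply(c(0, shifts), function(k)
            rpois(14, dnorm(1:14, 7 + k, 2.2) * 3000))
        off <- registerReplicates(reps)
        # a profile displaced by +k aligns with the reference at offset -k
        all(off[2:3] == -shifts)
    }, logical(1))
    expect_gte(mean(ok), 0.95)
})

test_that("pooling conserves cells across registered bins", {
    r1 <- data.frame(bin = c(0, 0, 1, 2), nMRNA = 1:4)
    r2 <- data.frame(bin = c(0, 1, 1), nMRNA = 5:7)
    pooled <- poolReplicates(list(r1, r2), offsets = c(0L, 1L))
    expect_equal(nrow(pooled), 7)
    expect_equal(sum(pooled$bin == 1), 2)   # r1 bin1 + r2 bin0 shifted
})

test_that("site-fraction regression recovers an exact linear relation", {
    # cells constructed so each count bin has fraction 0.02*count + 0.1
    mrna <- rep(c(5, 10, 15, 20, 25), each = 100)
    frac <- 0.02 * unique(mrna) + 0.1
    hasSite <- unlist(lapply(seq_along(frac), function(i)
        rep(c(TRUE, FALSE), c(frac[i] * 100, 100 - frac[i] * 100))))
    fit <- regressSiteFraction(mrna, hasSite, countBinWidth = 5)
    expect_equal(fit$slope, 0.02, tolerance = 1e-10)
    expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
    expect_equal(fit$ci, c(0.02, 0.02), tolerance = 1e-8)
    expect_equal(fit$df, nrow(fit$bins) - 2)
    expect_error(regressSiteFraction(rep(1, 50), rep(TRUE, 50)),
                 "at least 3")
})
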