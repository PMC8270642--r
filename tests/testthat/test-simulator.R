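test_that("segment breaking conserves sites and handles t = 0", {
    expect_identical(simulateSegmentBreaking(1e4, 0, 1e-9), 10000L)
    ## conservation: surviving run lengths + mutated sites = K, exactly;
    ## the mutation count is recovered by replaying the RNG stream
    K <- 5000; t <- 2e6; mu <- 1e-9
    for (s in 1:10) {
        set.seed(s)
        frag <- simulateSegmentBreaking(K, t, mu)
        set.seed(s)
        nMut <- stats::rbinom(1L, K, 1 - exp(-2 * mu * t))
        expect_identical(sum(frag), as.integer(K - nMut))
        expect_true(all(frag >= 1L))
    }
})

test_that("fragment lengths follow the exponential law of the model", {
    set.seed(123)
    K <- 1e6; mu <- 1e-9; t <- 5e5  # 2 mu t = 1e-3
    frag <- simulateSegmentBreaking(K, t, mu)
    rate <- 2 * mu * t
    ## mean within 3 SE of 1/(2 mu t) = 1000
    se <- (1 / rate) / sqrt(length(frag))
    expect_lt(abs(mean(frag) - 1 / rate), 3 * se)
    ## Kolmogorov-Smirnov against the exponential law, alpha = 0.01
    ks <- suppressWarnings(stats::ks.test(frag, "pexp", rate = rate))
    expect_gt(ks$p.value, 0.01)
})

test_that("steady-state simulation pools reportable fragments reproducibly", {
    sim0 <- simulateSteadyState(0, K = 5000, mu = 1e-9, tMax = 2e7,
                                seed = 1)
    expect_identical(length(sim0$fragments), 0L)

    sim1 <- simulateSteadyState(500, K = 5000, mu = 1e-9, tMax = 2e7,
                                seed = 99)
    sim2 <- simulateSteadyState(500, K = 5000, mu = 1e-9, tMax = 2e7,
                                seed = 99)
    expect_identical(sim1$fragments, sim2$fragments)
    expect_identical(sim1$ages, sim2$ages)
    expect_true(all(sim1$fragments >= 300L))
    expect_true(all(sim1$ages > 0 & sim1$ages <= 2e7))
    expect_identical(sim1$config$seed, 99)

    expect_warning(
        simulateSteadyState(10, K = 5000, mu = 1e-9, tMax = 1e4,
                            seed = 1),
        "steady-state regime")
})

test_that("exponential-age mode suppresses old events", {
    sim <- simulateSteadyState(2000, K = 5000, mu = 1e-9, tMax = 2e7,
                               ageDistribution = "exponential",
                               lambda = 1e-6, seed = 5)
    ## with lambda = 1e-6 almost all ages fall within a few 1/lambda
    expect_lt(stats::quantile(unique(sim$ages), 0.99), 5e6 + 1)
    expect_error(simulateSteadyState(10, K = 5000, mu = 1e-9, tMax = 2e7,
                                     ageDistribution = "exponential"),
                 "lambda")
})

test_that("the exponential mixture sums its analytic components", {
    P <- hgtParams(rho = 1, mu = 1e-9, K = 5000, L1 = 1, L2 = 1)
    rGrid <- exp(seq(log(300), log(3e4), length.out = 40))
    one <- exponentialMixtureMLD(rGrid, P, ages = 1e6)
    expect_equal(one$density, mldConditional(rGrid, 1e6, P))
    set.seed(31)
    mix <- exponentialMixtureMLD(rGrid, P, nComponents = 50, tMax = 1e7)
    expect_identical(ncol(mix$components), 50L)
    expect_true(all(mix$density >= mix$components))  # sum >= each component
    expect_equal(mix$density, rowSums(mix$components))
})

test_that("planted xenologs are recovered exactly by the match finder", {
    planted <- data.frame(K = c(400L, 700L), t = c(0, 0),
                          strand = c("forward", "reverse"))
    pair <- generateGenomePair(20000, 20000, planted, mu = 1e-9,
                               seed = 207)
    m <- findMEMs(pair$seqA, pair$seqB, minLength = 300)
    expect_identical(nrow(m), 2L)
    got <- matchCoords(m)
    truth <- pair$truth[order(match(pair$truth$strand,
                                    c("forward", "reverse"))), ]
    got <- got[order(match(got$strand, c("forward", "reverse"))), ]
    expect_identical(got$ref_start, truth$locus_a)
    expect_identical(got$qry_start, truth$locus_b)
    expect_identical(got$length, truth$K)
    expect_identical(got$strand, truth$strand)
})

test_that("an aged planted event fragments instead of matching whole", {
    ## t chosen so 1 - exp(-mu t) ~ 2e-3 per copy: a 5-kb segment takes
    ## ~20 substitutions and must break into shorter matches
    pair <- generateGenomePair(30000, 30000,
                               data.frame(K = 5000L, t = 2e6,
                                          strand = "forward"),
                               mu = 1e-9, seed = 11)
    m <- findMEMs(pair$seqA, pair$seqB, minLength = 50)
    expect_gt(nrow(m), 1L)
    expect_true(all(m$length < 5000L))
    ## fragments live inside the planted locus
    tr <- pair$truth
    expect_true(all(m$ref_start >= tr$locus_a - 1 &
                    m$ref_start + m$length <= tr$locus_a + tr$K + 1))
})

test_that("empty plants leave no matches and seeds reproduce bytes", {
    p0a <- generateGenomePair(20000, 20000, NULL, seed = 301)
    expect_identical(nrow(p0a$truth), 0L)
    expect_identical(nrow(findMEMs(p0a$seqA, p0a$seqB, minLength = 300)),
                     0L)
    p0b <- generateGenomePair(20000, 20000, NULL, seed = 301)
    expect_identical(p0a$seqA, p0b$seqA)
    expect_identical(p0a$seqB, p0b$seqB)

    expect_error(generateGenomePair(1000, 1000,
                                    data.frame(K = 600L, t = 0)),
                 "half the shorter genome")
})

test_that("fixtures round-trip through FASTA and the truth table", {
    pair <- generateGenomePair(20000, 20000,
                               data.frame(K = 400L, t = 0,
                                          strand = "forward"),
                               seed = 77)
    dir <- tempfile()
    writeFixture(pair, dir)
    A <- readContigs(file.path(dir, "genomeA.fa"), minContigLength = 0)
    B <- readContigs(file.path(dir, "genomeB.fa"), minContigLength = 0)
    truth <- read.delim(file.path(dir, "truth.tsv"))
    m <- findAllPairs(A, B, minLength = 300)
    expect_identical(nrow(m), 1L)
    expect_identical(m$ref_start, truth$locus_a)
    expect_identical(m$length, truth$K)
})
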