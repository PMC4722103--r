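test_that("generated genomes honor length, ORF count, topology and truth", {
    cfg <- SimulationConfig(genomeLength = 3000L, nOrfs = 3L,
                            nReadPairs = 10L, seed = 42L)
    g <- generateGenome(cfg)
    expect_s4_class(g, "VirophageGenome")
    expect_equal(length(genomeSeq(g)), 3000L)
    tf <- truthFeatures(g)
    expect_equal(nrow(tf), 3L)
    expect_true(all(tf$nt_len %% 3L == 0L))
    expect_true(all(tf$nt_len >= 150L))
    expect_true(isCircular(g))
    ## determinism: same config, same seed, identical bases
    g2 <- generateGenome(cfg)
    expect_identical(as.character(genomeSeq(g)), as.character(genomeSeq(g2)))
})

test_that("realized G+C tracks the target at study scale", {
    g <- generateGenome(SimulationConfig(seed = 7L))
    expect_equal(length(genomeSeq(g)), 28788L)
    expect_lt(abs(gcContent(g) - 0.432), 0.005)
})

test_that("impossible ORF packing is an explicit error", {
    expect_error(generateGenome(SimulationConfig(genomeLength = 450L,
                                                 nOrfs = 4L)),
                 "packing")
})

test_that("planted ORFs satisfy the ORF caller's definition exactly", {
    for (seed in c(3L, 9L)) {
        g <- generateGenome(SimulationConfig(genomeLength = 8000L,
                                             nOrfs = 6L, seed = seed))
        tf <- truthFeatures(g)
        orfs <- predictOrfs(g)
        hit <- merge(tf[, c("start", "end", "strand")],
                     orfs[, c("start", "end", "strand")])
        expect_equal(nrow(hit), nrow(tf))
    }
})

test_that("mutateGenome honors rates and provenance", {
    g <- generateGenome(SimulationConfig(genomeLength = 10000L, nOrfs = 5L,
                                         seed = 21L))
    ## zero rates: identity
    m0 <- mutateGenome(g, 0, 0, seed = 1L)
    expect_identical(as.character(genomeSeq(m0)), as.character(genomeSeq(g)))
    ## substitution-only divergence measured through the provenance map
    m <- mutateGenome(g, 0.1, 0, seed = 2L)
    src <- strsplit(as.character(genomeSeq(g)), "")[[1L]]
    der <- strsplit(as.character(genomeSeq(m)), "")[[1L]]
    prov <- m@provenance
    mm <- mean(der[!is.na(prov)] != src[prov[!is.na(prov)]])
    sd3 <- 3 * sqrt(0.1 * 0.9 / 10000)
    expect_lt(abs(mm - 0.1), sd3)
    ## reproducibility under a fixed seed
    m2 <- mutateGenome(g, 0.1, 0, seed = 2L)
    expect_identical(as.character(genomeSeq(m)), as.character(genomeSeq(m2)))
    ## indels change length and are marked NA in the provenance map
    mi <- mutateGenome(g, 0, 0.02, seed = 3L)
    expect_false(length(genomeSeq(mi)) == length(genomeSeq(g)) &&
                 !anyNA(mi@provenance))
    expect_error(mutateGenome(g, 1.5, 0, seed = 1L), "rates")
})

test_that("simulated read sets have the configured geometry and errors", {
    cfg <- SimulationConfig(genomeLength = 5000L, nOrfs = 3L,
                            nReadPairs = 100L, readLength = 100L,
                            insertMean = 300, insertSd = 30,
                            baseErrorRate = 0.01, backgroundFraction = 0,
                            seed = 5L)
    g <- generateGenome(cfg)
    sim <- simulateReads(g, cfg)
    expect_equal(length(sim@r1), 100L)
    expect_equal(length(sim@r2), 100L)
    ## injected error count within 3 sd of the binomial expectation
    nbases <- sum(nchar(as.character(c(sim@r1, sim@r2))))
    nerr <- sum(sim@truth$n_errors)
    expect_lt(abs(nerr - 0.01 * nbases), 3 * sqrt(0.01 * 0.99 * nbases))
    ## circular genomes yield fragments wrapping the origin
    expect_gt(sum(sim@truth$wraps), 0L)
    wrapped <- sim@truth[sim@truth$wraps & sim@truth$mate == 1L, ][1L, ]
    expect_gt(wrapped$frag_end, length(genomeSeq(g)))
})

test_that("background pairs are appended at the configured fraction", {
    cfg <- SimulationConfig(genomeLength = 5000L, nOrfs = 3L,
                            nReadPairs = 120L, backgroundFraction = 0.25,
                            seed = 6L)
    g <- generateGenome(cfg)
    sim <- simulateReads(g, cfg)
    n_bg <- sum(sim@truth$source == "background") / 2L
    expect_equal(n_bg / (n_bg + 120L), 0.25, tolerance = 0.02)
})

test_that("written FASTQ/FASTA are byte-identical under a fixed seed", {
    cfg <- SimulationConfig(genomeLength = 2000L, nOrfs = 2L,
                            nReadPairs = 20L, readLength = 80L,
                            insertMean = 200, backgroundFraction = 0,
                            seed = 9L)
    g <- generateGenome(cfg)
    d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
    p1 <- writeSimulation(simulateReads(g, cfg), g, d1)
    p2 <- writeSimulation(simulateReads(g, cfg), g, d2)
    for (f in c("r1", "r2", "genome")) {
        expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
    }
    ## FASTQ round-trips through a standard reader
    back <- suppressWarnings(readQualityScaledDNAStringSet(p1[["r1"]]))
    expect_equal(length(back), 20L)
})
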