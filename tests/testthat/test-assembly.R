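test_that("single reads and tiling reads assemble to the expected contigs", {
    p <- AssemblyParams()
    ## one read: one contig equal to the read at depth 1
    r1 <- Biostrings::DNAStringSet(c(a = rand_dna(120L)))
    ctg <- denovoAssemble(r1, p)
    expect_length(ctg, 1L)
    expect_identical(as.character(contigSeq(ctg[[1L]])), as.character(r1[[1L]]))
    expect_true(all(contigDepth(ctg[[1L]]) == 1L))
    ## error-free 100-bp reads tiling 2 kb every 50 bp: exact reconstruction
    set.seed(31)
    src <- rand_dna(2000L)
    reads <- Biostrings::DNAStringSet(tile_reads(src, 100L, 50L))
    ctgs <- denovoAssemble(reads, p)
    expect_length(ctgs, 1L)
    got <- as.character(contigSeq(ctgs[[1L]]))
    expect_true(got == src || got == rc(src))
    expect_error(denovoAssemble(Biostrings::DNAStringSet(), p), "non-empty")
})

test_that("greedy assembly equals the exhaustive layout oracle on tiny sets", {
    set.seed(32)
    p <- AssemblyParams(minOverlap = 20L)
    for (i in 1:5) {
        src <- rand_dna(260L)
        reads <- tile_reads(src, 80L, sample(40:55, 1L))[1:5]
        ## random orientations keep the layout unique but exercise strands
        flip <- runif(length(reads)) < 0.5
        reads[flip] <- vapply(reads[flip], rc, "")
        ctgs <- denovoAssemble(Biostrings::DNAStringSet(reads), p)
        expect_length(ctgs, 1L)
        got <- as.character(contigSeq(ctgs[[1L]]))
        ora <- oracle_superstring(unname(reads), min_overlap = 20L)
        expect_true(got == ora || got == rc(ora))
    }
})

test_that("assembly is orientation-invariant", {
    set.seed(33)
    src <- rand_dna(600L)
    reads <- tile_reads(src, 90L, 45L)
    p <- AssemblyParams()
    a <- denovoAssemble(Biostrings::DNAStringSet(reads), p)
    b <- denovoAssemble(Biostrings::DNAStringSet(
        vapply(reads, rc, "")), p)
    sa <- sort(vapply(a, function(x) {
        s <- as.character(contigSeq(x)); min(s, rc(s)) }, ""))
    sb <- sort(vapply(b, function(x) {
        s <- as.character(contigSeq(x)); min(s, rc(s)) }, ""))
    expect_identical(sa, sb)
})

test_that("reference extension reaches the full genome and is a fixed point", {
    set.seed(34)
    p <- AssemblyParams()
    src <- rand_dna(8000L)
    ## 30x error-free coverage
    reads <- tile_reads(src, 200L, 7L)
    seed_ctg <- new("Contig", id = "seed",
                    seq = Biostrings::DNAString(substr(src, 3000L, 4500L)),
                    depth = rep(1L, 1501L), memberReads = character(0),
                    circular = FALSE, terminalRepeatLen = 0L,
                    iterations = 0L)
    ext <- referenceExtend(seed_ctg, Biostrings::DNAStringSet(reads), p)
    got <- as.character(contigSeq(ext))
    expect_true(grepl(src, got, fixed = TRUE) ||
                grepl(src, rc(got), fixed = TRUE))
    expect_gte(iterationsToConverge(ext), 1L)
    ## no overlapping read: the seed is already the fixed point
    lone <- Biostrings::DNAStringSet(c(x = rand_dna(200L)))
    same <- referenceExtend(seed_ctg, lone, p)
    expect_identical(as.character(contigSeq(same)),
                     as.character(contigSeq(seed_ctg)))
    expect_equal(iterationsToConverge(same), 1L)
})

test_that("planted terminal direct repeats are found and collapsed", {
    set.seed(35)
    core <- rand_dna(2000L)
    with_tr <- paste0(core, substr(core, 1L, 189L))
    ctg <- new("Contig", id = "c1", seq = Biostrings::DNAString(with_tr),
               depth = rep(1L, nchar(with_tr)), memberReads = character(0),
               circular = FALSE, terminalRepeatLen = 0L, iterations = 0L)
    out <- detectTerminalRepeat(ctg, AssemblyParams())
    expect_true(isCircular(out))
    expect_equal(terminalRepeatLen(out), 189L)
    expect_equal(length(contigSeq(out)), 2000L)
    expect_identical(as.character(contigSeq(out)), core)
    ## no repeated termini: unchanged
    plain <- new("Contig", id = "c2", seq = Biostrings::DNAString(core),
                 depth = rep(1L, 2000L), memberReads = character(0),
                 circular = FALSE, terminalRepeatLen = 0L, iterations = 0L)
    expect_false(isCircular(detectTerminalRepeat(plain, AssemblyParams())))
})

test_that("full assembly recovers a circular genome as an exact rotation", {
    cfg <- SimulationConfig(genomeLength = 6000L, nOrfs = 4L,
                            nReadPairs = 300L, readLength = 150L,
                            insertMean = 300, baseErrorRate = 0,
                            backgroundFraction = 0, seed = 36L)
    g <- generateGenome(cfg)
    sim <- simulateReads(g, cfg)
    reads <- as(c(sim@r1, sim@r2), "DNAStringSet")
    p <- AssemblyParams()
    seed_ctg <- denovoAssemble(reads[1:40], p)[[1L]]
    ext <- referenceExtend(seed_ctg, reads, p)
    circ <- detectTerminalRepeat(ext, p)
    expect_true(isCircular(circ))
    truth <- as.character(genomeSeq(g))
    expect_equal(length(contigSeq(circ)), nchar(truth))
    got <- as.character(contigSeq(circ))
    doubled <- paste0(truth, truth)
    expect_true(grepl(got, doubled, fixed = TRUE) ||
                grepl(rc(got), doubled, fixed = TRUE))
})
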