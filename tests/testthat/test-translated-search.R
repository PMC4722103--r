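test_that("six-frame translation follows the standard code and conventions", {
    expect_equal(as.character(sixFrameTranslate("ATGAAA"))[["F1"]], "MK")
    ## frame lengths: floor((L - offset) / 3) codons per frame
    set.seed(21)
    for (i in 1:20) {
        L <- sample(3:40, 1L)
        s <- rand_dna(L)
        fr <- as.character(sixFrameTranslate(s))
        for (off in 0:2) {
            expect_equal(nchar(fr[[off + 1L]]), (L - off) %/% 3L)
            expect_equal(nchar(fr[[off + 4L]]), (L - off) %/% 3L)
        }
        ## frame -1 equals frame +1 of the reverse complement
        expect_identical(fr[["R1"]],
                         as.character(sixFrameTranslate(rc(s)))[["F1"]])
    }
    ## N-containing codons render X; stops render *
    fr <- as.character(sixFrameTranslate("ATGANATAA"))
    expect_equal(fr[["F1"]], "MX*")
    ## shorter than a codon: empty frames, no error
    expect_true(all(nchar(as.character(sixFrameTranslate("AT"))) == 0L))
})

test_that("Karlin-Altschul E-values match the closed form and its laws", {
    p <- SearchParams(karlinK = 0.041, karlinLambda = 0.267)
    expect_equal(karlinEvalue(50, 100, 1e6, p),
                 0.041 * 100 * 1e6 * exp(-0.267 * 50))
    ## linear in the database length
    expect_equal(karlinEvalue(50, 100, 2e6, p),
                 2 * karlinEvalue(50, 100, 1e6, p))
    ## strictly decreasing in score
    ev <- karlinEvalue(c(10, 20, 30, 40), 100, 1e6, p)
    expect_true(all(diff(ev) < 0))
    expect_error(karlinEvalue(50, 0, 1e6, p), "positive")
})

test_that("self-match HSP scores the matrix diagonal of its peptide", {
    set.seed(22)
    s <- rand_dna(300L)
    q <- substr(s, 61L, 120L)  # exact 60-nt coding substring
    h <- translatedAlign(q, s, SearchParams(evalueCutoff = 10,
                                            mode = "full"))
    top <- h[h$q_frame == 1L & h$s_frame == 1L, ][1L, ]
    expect_equal(top$identity, 1.0)
    pep <- as.character(sixFrameTranslate(q))[["F1"]]
    diag_score <- sum(vapply(strsplit(pep, "")[[1L]],
                             function(a) blosum62[a, a], 1))
    expect_equal(top$score, diag_score)
    expect_equal(top$s_start, 61L)
    expect_equal(top$s_end, 120L)
})

test_that("best translated score equals the exhaustive frame-by-frame oracle", {
    set.seed(23)
    for (i in 1:15) {
        ## related pairs (mutated substring) and unrelated pairs, <= 100 nt
        s <- rand_dna(sample(60:100, 1L))
        q <- if (i %% 3 == 0) rand_dna(sample(30:90, 1L)) else {
            b <- strsplit(substr(s, 1, sample(45:min(90, nchar(s)), 1L)),
                          "")[[1L]]
            hit <- runif(length(b)) < 0.15
            b[hit] <- sample(c("A", "C", "G", "T"), sum(hit),
                             replace = TRUE)
            paste(b, collapse = "")
        }
        h <- translatedAlign(q, s, SearchParams(evalueCutoff = Inf,
                                                mode = "full"))
        got <- if (nrow(h)) max(h$score) else 0
        expect_equal(got, oracle_translated_best(q, s))
    }
})

test_that("seeded and exhaustive modes agree on clear homologies", {
    set.seed(24)
    s <- rand_dna(3000L)
    q <- substr(s, 1001L, 1250L)
    pf <- SearchParams(evalueCutoff = 1e-5, mode = "full")
    ps <- SearchParams(evalueCutoff = 1e-5, mode = "seeded")
    hf <- translatedAlign(q, s, pf)
    hs <- translatedAlign(q, s, ps)
    expect_equal(max(hs$score), max(hf$score))
})

test_that("recruitment separates true reads from background and is one-hit", {
    cfg <- SimulationConfig(genomeLength = 8000L, nOrfs = 6L,
                            nReadPairs = 120L, backgroundFraction = 0.4,
                            seed = 25L)
    g <- generateGenome(cfg)
    bait <- mutateGenome(g, 0.2, 0, seed = 26L, id = "bait")
    sim <- simulateReads(g, cfg)
    reads <- as(c(sim@r1, sim@r2), "DNAStringSet")
    baits <- Biostrings::DNAStringSet(
        c(bait = as.character(genomeSeq(bait))))
    tab <- recruitReads(reads, baits,
                        SearchParams(evalueCutoff = 1e-5,
                                     bestHitOnly = TRUE))
    expect_lte(max(table(tab$read_id)), 1L)
    truth <- sim@truth
    rec <- unique(tab$read_id)
    true_ids <- truth$read_id[truth$source == "genome"]
    bg_ids <- truth$read_id[truth$source == "background"]
    tpr <- mean(true_ids %in% rec)
    fpr <- mean(bg_ids %in% rec)
    expect_gt(tpr, 0.5)
    expect_lt(fpr, 0.02)
    expect_gt(tpr, 10 * fpr + 0.1)
    ## verbatim read recruits at its true midpoint
    probe <- Biostrings::DNAStringSet(
        c(probe = substr(as.character(genomeSeq(bait)), 2001, 2250)))
    ptab <- recruitReads(probe, baits, SearchParams(evalueCutoff = 1e-5,
                                                    bestHitOnly = TRUE))
    expect_equal(ptab$subject_id, "bait")
    expect_lt(abs(ptab$midpoint - 2125.5), 5)
    ## per-bait counts and share bookkeeping
    cnt <- recruitmentCounts(tab)
    expect_equal(sum(cnt$n_reads), length(rec))
    expect_equal(baitShare(cnt, "bait"), 1)
})

test_that("recruitment is strand-symmetric and monotone in the cutoff", {
    set.seed(27)
    s <- rand_dna(4000L)
    reads <- vapply(1:15, function(i) {
        a <- sample(1000:3000, 1L); substr(s, a, a + 199L)
    }, "")
    names(reads) <- paste0("r", 1:15)
    baits <- Biostrings::DNAStringSet(c(bait = s))
    p <- SearchParams(evalueCutoff = 1e-5, bestHitOnly = TRUE)
    fwd <- recruitReads(Biostrings::DNAStringSet(reads), baits, p)
    rcr <- vapply(reads, rc, "")
    rev <- recruitReads(Biostrings::DNAStringSet(rcr), baits, p)
    expect_equal(fwd$subject_id, rev$subject_id)
    expect_equal(fwd$identity, rev$identity)
    expect_equal(fwd$s_start, rev$s_start)
    ## tightening the cutoff never adds rows
    loose <- recruitReads(Biostrings::DNAStringSet(reads), baits,
                          SearchParams(evalueCutoff = 1e-3))
    tight <- recruitReads(Biostrings::DNAStringSet(reads), baits,
                          SearchParams(evalueCutoff = 1e-12))
    expect_lte(nrow(tight), nrow(loose))
    expect_true(all(tight$evalue <= 1e-12))
})
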