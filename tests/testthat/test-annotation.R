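test_that("gcContent counts bases and ignores ambiguity codes", {
    expect_equal(gcContent("GGCC"), 1.0)
    expect_equal(gcContent("ATAT"), 0.0)
    set.seed(41)
    s <- rand_dna(10000L, gc = 0.37)
    b <- strsplit(s, "")[[1L]]
    expect_equal(gcContent(s), sum(b %in% c("G", "C")) / 10000)
    ## reverse-complement invariance
    expect_equal(gcContent(s), gcContent(rc(s)))
    ## N excluded from the denominator
    expect_equal(gcContent("GGNN"), 1.0)
    expect_error(gcContent("NNN"), "unambiguous")
})

test_that("gcSkew computes (G - C)/(G + C) in sliding windows", {
    s <- paste0(strrep("G", 100), strrep("C", 100))
    sk <- gcSkew(s, window = 100L, step = 100L, circular = FALSE)
    expect_equal(sk$skew, c(1, -1))
})

test_that("ORF arithmetic holds across the published table", {
    tab <- dslv1OrfTable()
    expect_equal(nrow(tab), 28L)
    ## rows 8/9 print misrendered aa counts (off by exactly ten); the
    ## spans of all 28 rows and the aa counts of the other 26 check out
    expect_identical(which(!orfArithmeticConsistent(tab)), c(8L, 9L))
    ## spot rows: forward ORF1, reverse ORF2, marker ORF15
    expect_equal(tab$nt[1L], 786L)
    expect_equal(abs(tab$start[1L] - tab$end[1L]) + 1L, 786L)
    expect_equal(tab$aa[1L], 261L)
    expect_equal(abs(tab$start[2L] - tab$end[2L]) + 1L, 867L)
    expect_equal(tab$aa[2L], 288L)
    expect_true(tab$start[2L] > tab$end[2L])  # reverse-strand convention
    expect_equal(tab$aa[15L], (abs(tab$start[15L] - tab$end[15L]) + 1L) /
                     3L - 1L)
})

test_that("predictOrfs applies the first-ATG / min-length rule", {
    ## single forward ORF with a decoy later ATG in the same interval
    lead <- strrep("T", 30)
    orf <- paste0("ATG", "CAT", paste(rep("GCT", 58), collapse = ""), "TAA")
    s <- paste0(lead, "TAA", orf, strrep("T", 31))
    got <- predictOrfs(s, ORFParams(), circular = FALSE)
    expect_equal(nrow(got), 1L)
    expect_equal(got$start, nchar(lead) + 4L)
    expect_equal(got$nt_len, nchar(orf))
    expect_equal(nchar(got$protein), got$nt_len / 3L - 1L)
    expect_match(got$protein, "^M")
    expect_false(grepl("*", got$protein, fixed = TRUE))
    ## below the length threshold: nothing
    short <- paste0("TAA", "ATG", strrep("GCT", 20), "TAA")
    expect_equal(nrow(predictOrfs(short, ORFParams(), circular = FALSE)), 0L)
})

test_that("reverse-strand and wraparound ORFs are reported correctly", {
    set.seed(42)
    g <- generateGenome(SimulationConfig(genomeLength = 6000L, nOrfs = 5L,
                                         seed = 43L))
    s <- as.character(genomeSeq(g))
    orfs <- predictOrfs(s, ORFParams(), circular = FALSE)
    ## mirror property: calling on the reverse complement flips strands
    mirror <- predictOrfs(rc(s), ORFParams(), circular = FALSE)
    L <- nchar(s)
    remapped <- data.frame(start = L - mirror$start + 1L,
                           end = L - mirror$end + 1L,
                           strand = ifelse(mirror$strand == "+", "-", "+"))
    expect_equal(nrow(merge(orfs[, c("start", "end", "strand")], remapped)),
                 nrow(orfs))
    ## plant an ORF across the origin of a circular sequence
    core <- paste0("ATG", paste(rep("GCA", 58), collapse = ""), "TAA")
    ring <- paste0(substr(core, 101L, nchar(core)), strrep("T", 300),
                   "TAA", substr(core, 1L, 100L))
    worf <- predictOrfs(ring, ORFParams(allowWraparound = TRUE),
                        circular = TRUE)
    wrapped <- worf[worf$strand == "+" & worf$end < worf$start, ]
    expect_equal(nrow(wrapped), 1L)
    expect_equal(wrapped$nt_len, nchar(core))
    ## without wraparound the origin-crossing ORF disappears
    worf2 <- predictOrfs(ring, ORFParams(allowWraparound = FALSE),
                         circular = TRUE)
    expect_equal(nrow(worf2[worf2$strand == "+" &
                            worf2$end < worf2$start, ]), 0L)
})

test_that("translateOrf follows the standard code and rejects junk", {
    expect_equal(translateOrf("ATGAAATAA", 1, 9, circular = FALSE), "MK")
    ## reverse-strand translation equals translating the reverse complement
    s <- paste0("TT", rc("ATGAAACCCTAA"), "GG")
    expect_equal(translateOrf(s, 14, 3, circular = FALSE), "MKP")
    expect_error(translateOrf("ATGTAAAAATAA", 1, 12, circular = FALSE),
                 "internal stop")
    expect_error(translateOrf("ATGAAATAA", 1, 8, circular = FALSE),
                 "divisible")
})

test_that("protein annotation finds best hits at the stated threshold", {
    set.seed(44)
    g <- generateGenome(SimulationConfig(genomeLength = 6000L, nOrfs = 4L,
                                         seed = 45L))
    orfs <- predictOrfs(g)
    planted <- orfs[nchar(orfs$protein) >= 60L, ][1:3, ]
    db <- Biostrings::AAStringSet(setNames(planted$protein,
                                           paste0("db|p", 1:3)))
    ann <- annotateProteins(orfs, db)
    expect_equal(nrow(ann), nrow(orfs))
    ## self-hits: 100% identity over the full length, minimal E
    self <- ann[match(planted$index, ann$orf_index), ]
    expect_true(all(self$percent_identity == 100))
    expect_equal(self$aln_len_aa, nchar(planted$protein))
    expect_true(all(self$evalue < 1e-10))
    ## non-planted ORFs with no homolog are ORFans
    expect_true(any(ann$orfan))
    expect_true(all(is.na(ann$subject_id[ann$orfan])))
    expect_error(annotateProteins(orfs, Biostrings::AAStringSet()),
                 "non-empty")
})

test_that("annotation scores equal the exhaustive pairwise aligner", {
    set.seed(46)
    for (i in 1:6) {
        a <- paste(sample(rownames(blosum62)[1:20], 80L, replace = TRUE),
                   collapse = "")
        b <- if (i %% 2 == 0)
            paste(sample(rownames(blosum62)[1:20], 120L, replace = TRUE),
                  collapse = "")
        else {
            v <- strsplit(a, "")[[1L]]
            hit <- runif(80L) < 0.3
            v[hit] <- sample(rownames(blosum62)[1:20], sum(hit),
                             replace = TRUE)
            paste(v, collapse = "")
        }
        mine <- vmine:::.C_sw_align(a, b, blosum62 + 0.0,
                                    rownames(blosum62), 11, 1)
        expect_equal(mine[1L], oracle_local_score(a, b))
    }
})

test_that("in-silico PCR reproduces planted amplicons and the brute scan", {
    set.seed(47)
    tpl <- rand_dna(3000L)
    fw <- substr(tpl, 501L, 520L)
    rv_site <- substr(tpl, 1181L, 1200L)
    pp <- PrimerPair("pp", fw, rc(rv_site))
    amp <- insilicoPcr(tpl, pp, circular = FALSE)
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$start, 501L)
    expect_equal(amp$length, 700L)
    ## reverse primer absent: no amplicon
    none <- insilicoPcr(tpl, PrimerPair("x", fw, rand_dna(20L)),
                        circular = FALSE)
    expect_equal(nrow(none), 0L)
    ## all site pairs equal an exhaustive sliding-window scan
    f_sites <- oracle_primer_sites(tpl, fw)
    r_sites <- oracle_primer_sites(tpl, rv_site)
    expected <- 0L
    for (a in f_sites) for (b in r_sites)
        if (b >= a + 20L && b + 19L - a + 1L <= 10000L)
            expected <- expected + 1L
    expect_equal(sum(amp$strand == "+"), expected)
    ## mismatch tolerance matches the scan oracle
    fw_mm <- paste0("T", substr(fw, 2L, 20L))
    got_mm <- insilicoPcr(tpl, PrimerPair("mm", fw_mm, rc(rv_site),
                                          maxMismatch = 1L),
                          circular = FALSE)
    expect_equal(nrow(got_mm), 1L)
    ## circular template: the amplicon spans the origin after rotation
    ring <- paste0(substr(tpl, 1001L, 3000L), substr(tpl, 1L, 1000L))
    ramp <- insilicoPcr(ring, pp, circular = TRUE)
    expect_equal(nrow(ramp), 1L)
    expect_equal(ramp$length, 700L)
})

test_that("published primers amplify nothing from an unrelated genome", {
    g <- generateGenome(SimulationConfig(genomeLength = 5000L, nOrfs = 3L,
                                         seed = 48L))
    prim <- virophagePrimers("mcp")
    hits <- vapply(seq_len(nrow(prim)), function(i)
        nrow(insilicoPcr(g, PrimerPair(prim$virophage[i], prim$forward[i],
                                       prim$reverse[i]))), 1L)
    expect_true(all(hits == 0L))
})

test_that("homolog identity declines with divergence into the expected band", {
    set.seed(49)
    g <- generateGenome(SimulationConfig(genomeLength = 8000L, nOrfs = 5L,
                                         seed = 50L))
    tf <- truthFeatures(g)
    big <- tf[which.max(tf$nt_len), ]
    truth <- as.character(genomeSeq(g))
    orig <- vmine:::.translate_span(truth, big$start, big$end, big$strand,
                                    nchar(truth))
    ident_at <- function(q, seed) {
        m <- mutateGenome(g, q, 0, seed = seed)
        ms <- as.character(genomeSeq(m))
        div <- vmine:::.extract_span(ms, big$start, big$end, big$strand,
                                     nchar(ms))
        pep <- as.character(Biostrings::translate(
            Biostrings::DNAString(div), if.fuzzy.codon = "X"))
        a <- vmine:::.C_sw_align(orig, pep, blosum62 + 0.0,
                                 rownames(blosum62), 11, 1)
        a[6L] / a[7L]
    }
    ids <- vapply(c(0.1, 0.2, 0.35), function(q)
        mean(vapply(1:3, function(s) ident_at(q, 100L + s), 1)), 1)
    expect_true(all(diff(ids) < 0))
    expect_gte(ids[3L], 0.33)
    expect_lte(ids[3L], 0.70)
})
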