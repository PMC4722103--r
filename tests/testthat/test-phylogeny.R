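test_that("marker concatenation keeps lengths, order and block round-trip", {
    ## single taxon: concatenated length is the sum of the marker lengths
    m1 <- list(ATPase = Biostrings::AAStringSet(c(t1 = strrep("A", 261))),
               PRO = Biostrings::AAStringSet(c(t1 = strrep("C", 654))),
               MCP = Biostrings::AAStringSet(c(t1 = strrep("D", 575))))
    cm <- concatMarkers(m1)
    expect_equal(nchar(as.character(cm)[["t1"]]), 1490L)
    blocks <- attr(cm, "blocks")
    expect_equal(blocks$marker, c("ATPase", "PRO", "MCP"))
    ## slicing the blocks recovers each marker
    for (i in seq_len(nrow(blocks))) {
        sl <- substr(as.character(cm)[["t1"]], blocks$start[i],
                     blocks$end[i])
        expect_identical(gsub("-", "", sl),
                         as.character(m1[[blocks$marker[i]]][["t1"]]))
    }
    ## identical inputs across two taxa give zero distance downstream
    m2 <- lapply(m1, function(x) {
        y <- c(x, x); names(y) <- c("a", "b"); y
    })
    cm2 <- concatMarkers(m2)
    d <- proteinDistances(cm2)
    expect_equal(d["a", "b"], 0)
    ## missing marker gap-fills; taxon with no marker is dropped with warning
    m3 <- list(ATPase = Biostrings::AAStringSet(c(a = "MKL", b = "MKI")),
               MCP = Biostrings::AAStringSet(c(a = "MAAY")))
    cm3 <- concatMarkers(m3, order = c("ATPase", "MCP"))
    expect_match(as.character(cm3)[["b"]], "-{4}$")
})

test_that("center-star alignment is consistent and near-optimal", {
    ## identical sequences align without gaps
    two <- alignProteins(c(a = "MKLV", b = "MKLV"))
    expect_false(any(grepl("-", as.character(two), fixed = TRUE)))
    set.seed(51)
    pool <- rownames(blosum62)[1:20]
    base <- paste(sample(pool, 60L, replace = TRUE), collapse = "")
    seqs <- vapply(1:4, function(i) {
        v <- strsplit(base, "")[[1L]]
        hit <- runif(60L) < 0.2
        v[hit] <- sample(pool, sum(hit), replace = TRUE)
        if (i %% 2 == 0) v <- v[-sample(60L, 2L)]  # small deletions
        paste(v, collapse = "")
    }, "")
    names(seqs) <- paste0("s", 1:4)
    msa <- alignProteins(seqs)
    rows <- as.character(msa)
    expect_equal(length(unique(nchar(rows))), 1L)
    ## ungap round-trip recovers every input
    expect_identical(gsub("-", "", rows)[names(seqs)], seqs)
    ## induced pairwise identity cannot beat the optimal pairwise aligner
    for (i in 1:3) for (j in (i + 1):4) {
        induced <- sum(vapply(seq_len(nchar(rows[i])), function(p) {
            a <- substr(rows[i], p, p); b <- substr(rows[j], p, p)
            (a != "-") && (b != "-") && a == b
        }, TRUE))
        opt <- pairwiseAlignment(AAString(seqs[i]), AAString(seqs[j]),
                                 type = "global",
                                 substitutionMatrix = blosum62,
                                 gapOpening = 11, gapExtension = 1)
        expect_lte(induced, nmatch(opt) + 2L)
    }
})

test_that("p and Poisson distances follow their definitions", {
    msa <- Biostrings::AAStringSet(c(a = "AAAA", b = "AAAT", c = "A-AT"))
    d <- proteinDistances(msa, "p")
    expect_equal(d["a", "b"], 0.25)
    expect_equal(d["a", "c"], oracle_pdist("AAAA", "A-AT"))
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
    dp <- proteinDistances(msa, "poisson")
    expect_true(all(dp >= d))  # -ln(1 - p) >= p
    bad <- Biostrings::AAStringSet(c(a = "AAAA", b = "CCCC"))
    expect_error(proteinDistances(bad, "poisson"), "Poisson")
})

test_that("neighbor joining recovers additive trees exactly", {
    ## hand-built additive 4-taxon matrix with split ab|cd
    d <- matrix(c(0, 2, 7, 7,
                  2, 0, 7, 7,
                  7, 7, 0, 2,
                  7, 7, 2, 0), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
    tr <- njTree(d)
    expect_s3_class(tr, "phylo")
    ## the ab|cd split is present and branch lengths reproduce the matrix
    ct <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
    expect_equal(unname(ct), unname(d), tolerance = 1e-9)
    ## random additive matrices, 4-6 taxa, topology recovered exactly
    set.seed(52)
    for (i in 1:12) {
        n <- sample(4:6, 1L)
        ref <- ape::rtree(n)
        ref$edge.length <- ref$edge.length + 0.2
        dm <- ape::cophenetic.phylo(ref)
        dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
        mine <- njTree(dm)
        expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                               ape::unroot(ref))), 0)
        ## independent route: canonical NJ from ape agrees on the topology
        expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                               ape::unroot(ape::nj(dm)))), 0)
    }
    ## near-identical pair always joins against distant outgroups
    d2 <- matrix(c(0, .01, 1, .9,
                   .01, 0, .95, 1,
                   1, .95, 0, .8,
                   .9, 1, .8, 0), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
    expect_warning(t2 <- njTree(d2), "triangle")
    part <- ape::prop.part(t2)
    splits <- lapply(part, function(p) sort(t2$tip.label[p]))
    expect_true(list(c("a", "b")) %in% splits ||
                list(c("c", "d")) %in% splits)
    expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
    dd <- d; dd[1, 2] <- 5
    expect_error(njTree(dd), "symmetric")
})

test_that("bootstrap supports are deterministic, bounded and sensible", {
    set.seed(53)
    pool <- rownames(blosum62)[1:20]
    base <- paste(sample(pool, 80L, replace = TRUE), collapse = "")
    mut <- function(s, q) {
        v <- strsplit(s, "")[[1L]]
        hit <- runif(length(v)) < q
        v[hit] <- sample(pool, sum(hit), replace = TRUE)
        paste(v, collapse = "")
    }
    ## two byte-identical taxa vs two distant ones
    msa <- Biostrings::AAStringSet(c(a = base, b = base,
                                     c = mut(base, 0.5),
                                     d = mut(base, 0.6)))
    bt <- bootstrapTree(msa, n = 60L, seed = 4L)
    expect_equal(cladeSupport(bt, c("a", "b")), 100)
    sup <- suppressWarnings(as.numeric(bt$node.label))
    sup <- sup[!is.na(sup)]
    expect_true(all(sup >= 0 & sup <= 100))
    ## seed determinism
    bt2 <- bootstrapTree(msa, n = 60L, seed = 4L)
    expect_identical(ape::write.tree(bt), ape::write.tree(bt2))
    expect_error(bootstrapTree(msa, n = 0L), ">= 1")
})

test_that("diverged-relative clade reaches high support from a common ancestor", {
    ## an ingroup radiating recently from one ancestor vs distant outgroups
    set.seed(54)
    pool <- rownames(blosum62)[1:20]
    anc <- paste(sample(pool, 120L, replace = TRUE), collapse = "")
    mut <- function(s, q) {
        v <- strsplit(s, "")[[1L]]
        hit <- runif(length(v)) < q
        v[hit] <- sample(pool, sum(hit), replace = TRUE)
        paste(v, collapse = "")
    }
    msa <- Biostrings::AAStringSet(c(
        in1 = mut(anc, 0.05), in2 = mut(anc, 0.08), in3 = mut(anc, 0.1),
        out1 = mut(anc, 0.55), out2 = mut(anc, 0.6)))
    bt <- bootstrapTree(msa, n = 100L, seed = 5L)
    expect_gte(cladeSupport(bt, c("in1", "in2", "in3")), 90)
})
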