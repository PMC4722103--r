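test_that("single-read trimming follows the windowed rule", {
    p <- QCParams()
    ## all high quality: untouched
    r <- qcRead(strrep("A", 100), rep(40L, 100), p)
    expect_false(r$rejected)
    expect_equal(nchar(r$bases), 100L)
    ## 49 bp at Q40 fails the >= 50 bp length rule
    expect_true(qcRead(strrep("A", 49), rep(40L, 49), p)$rejected)
    ## good head, bad tail: truncation point equals the brute-force scan
    q <- c(rep(40L, 60), rep(2L, 20))
    r <- qcRead(strrep("A", 80), q, p)
    expect_equal(nchar(r$bases), oracle_qc_keep(q))
    expect_true(all(vapply(seq_len(nchar(r$bases) - 4L), function(i)
        mean(r$quals[i:(i + 4L)]) >= 20, TRUE)))
    ## read shorter than the window: single full-read mean
    expect_equal(qcRead("ACG", c(30L, 30L, 30L),
                        QCParams(minLength = 3L))$rejected, FALSE)
    expect_true(qcRead("ACG", c(10L, 10L, 10L),
                       QCParams(minLength = 3L))$rejected)
})

test_that("trimming matches the brute-force window scan on random reads", {
    set.seed(11)
    p <- QCParams()
    for (i in seq_len(400L)) {
        n <- sample(5:120, 1L)
        q <- sample(2:41, n, replace = TRUE)
        keep <- vmine:::.qc_keep_length(q, p)
        expect_identical(keep, oracle_qc_keep(q))
    }
})

test_that("dataset QC accounts reads and bases per run and is conservative", {
    set.seed(12)
    n <- 200L
    quals <- lapply(seq_len(n), function(i) {
        good <- sample(50:90, 1L)
        c(rep(38L, good), sample(2:41, 100L - good, replace = TRUE))
    })
    seqs <- vapply(seq_len(n), function(i) rand_dna(100L), "")
    reads <- make_qreads(seqs, quals)
    out <- qcDataset(list(runA = reads, runB = reads[1:50]), QCParams())
    st <- out$stats
    expect_equal(st$reads_in, c(200L, 50L))
    expect_true(all(st$reads_out <= st$reads_in))
    expect_true(all(st$bases_out <= st$bases_in))
    ## per-read oracle count
    oracle_out <- sum(vapply(quals, function(q)
        oracle_qc_keep(q) >= 50L, TRUE))
    expect_equal(st$reads_out[1L], oracle_out)
    ## conservation: rejected = in - out
    expect_equal(st$reads_in[1L] - st$reads_out[1L],
                 sum(vapply(quals, function(q) oracle_qc_keep(q) < 50L,
                            TRUE)))
    ## totals are sums over runs
    tot <- qcTotals(st)
    expect_equal(tot$reads_in, sum(st$reads_in))
    ## empty run yields zero stats without error
    empty <- qcDataset(list(z = reads[0]), QCParams())
    expect_equal(empty$stats$reads_in, 0L)
})

test_that("QC is idempotent and monotone in the quality threshold", {
    set.seed(13)
    quals <- lapply(1:100, function(i) sample(2:41, 80L, replace = TRUE))
    seqs <- vapply(1:100, function(i) rand_dna(80L), "")
    reads <- make_qreads(seqs, quals)
    once <- qcDataset(reads, QCParams())
    twice <- qcDataset(once$passed$run1, QCParams())
    expect_identical(as.character(twice$passed$run1),
                     as.character(once$passed$run1))
    expect_equal(twice$stats$reads_out, once$stats$reads_out)
    ## raising the threshold never increases the survivor count
    outs <- vapply(c(10, 20, 30, 38), function(minq)
        qcDataset(reads, QCParams(minMeanQ = minq))$stats$reads_out, 1L)
    expect_true(all(diff(outs) <= 0L))
})
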