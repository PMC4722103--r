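## Independent oracles and small fixture builders used across the suite.
## Every oracle here is written against the definition, not the package
## implementation it checks.

suppressPackageStartupMessages(library(Biostrings))

rand_dna <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

rc <- function(s) as.character(reverseComplement(DNAString(s)))

blosum62 <- local({
    e <- new.env()
    data(BLOSUM62, package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
})

## brute-force windowed QC: scan every window position directly
oracle_qc_keep <- function(q, window = 5L, minq = 20) {
    n <- length(q)
    if (n == 0L) return(0L)
    if (n < window) return(if (mean(q) >= minq) n else 0L)
    for (i in seq_len(n - window + 1L)) {
        if (mean(q[i:(i + window - 1L)]) < minq) return(i - 1L)
    }
    n
}

## exhaustive local protein alignment via the reference implementation in
## Biostrings (independent of the package's own dynamic programming)
oracle_local_score <- function(a, b, gapOpen = 11, gapExtend = 1) {
    score(pairwiseAlignment(AAString(a), AAString(b), type = "local",
                            substitutionMatrix = blosum62,
                            gapOpening = gapOpen,
                            gapExtension = gapExtend))
}

## best translated-search score by brute force: six frames of both
## sequences, reference local aligner per frame pair
oracle_translated_best <- function(qnt, snt) {
    tr <- function(s) {
        s <- DNAString(s); rcs <- reverseComplement(s)
        out <- character(0)
        for (off in 0:2) for (x in list(s, rcs)) {
            ncod <- (length(x) - off) %/% 3L
            if (ncod >= 1L)
                out <- c(out, as.character(
                    translate(subseq(x, off + 1L, off + 3L * ncod),
                              if.fuzzy.codon = "X")))
        }
        out
    }
    best <- 0
    for (qp in tr(qnt)) for (sp in tr(snt)) {
        if (nchar(qp) == 0L || nchar(sp) == 0L) next
        sc <- oracle_local_score(qp, sp)
        if (sc > best) best <- sc
    }
    best
}

## exhaustive greedy-layout oracle for tiny error-free read sets: try all
## permutations and orientations, chaining reads by their best
## suffix-prefix overlap, and return the shortest superstring
oracle_superstring <- function(reads, min_overlap = 10L) {
    n <- length(reads)
    orient <- function(s, o) if (o) rc(s) else s
    ov <- function(a, b) {
        ## longest exact suffix(a)/prefix(b) overlap
        max_ov <- min(nchar(a), nchar(b))
        for (l in rev(seq_len(max_ov))) {
            if (substr(a, nchar(a) - l + 1L, nchar(a)) ==
                substr(b, 1L, l)) return(l)
        }
        0L
    }
    best <- NULL
    perms <- function(v) {
        if (length(v) <= 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
        out
    }
    for (p in perms(seq_len(n))) {
        for (omask in seq_len(2^n) - 1L) {
            os <- as.logical(bitwAnd(omask, 2^(seq_len(n) - 1L)))
            cur <- orient(reads[p[1L]], os[1L])
            ok <- TRUE
            for (t in seq_len(n - 1L)) {
                nxt <- orient(reads[p[t + 1L]], os[t + 1L])
                l <- ov(cur, nxt)
                if (l < min_overlap) { ok <- FALSE; break }
                cur <- paste0(cur, substr(nxt, l + 1L, nchar(nxt)))
            }
            if (ok && (is.null(best) || nchar(cur) < nchar(best)))
                best <- cur
        }
    }
    best
}

## reads tiling a source sequence at fixed stride (error-free)
tile_reads <- function(src, read_len, stride) {
    starts <- seq(1L, nchar(src) - read_len + 1L, by = stride)
    if (max(starts) + read_len - 1L < nchar(src))
        starts <- c(starts, nchar(src) - read_len + 1L)
    r <- substring(src, starts, starts + read_len - 1L)
    names(r) <- sprintf("t%03d", seq_along(r))
    r
}

## p-distance by direct column count
oracle_pdist <- function(a, b) {
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    ok <- av != "-" & bv != "-"
    mean(av[ok] != bv[ok])
}

## brute-force primer scan: all ungapped binding sites with <= mm mismatches
oracle_primer_sites <- function(template, primer, mm = 0L) {
    n <- nchar(template); k <- nchar(primer)
    pv <- strsplit(primer, "")[[1L]]
    hits <- integer(0)
    if (n < k) return(hits)
    for (i in seq_len(n - k + 1L)) {
        w <- strsplit(substr(template, i, i + k - 1L), "")[[1L]]
        if (sum(w != pv) <= mm) hits <- c(hits, i)
    }
    hits
}

## a quality-scaled read set built from plain vectors
make_qreads <- function(seqs, quals) {
    x <- DNAStringSet(seqs)
    if (is.null(names(seqs))) names(x) <- paste0("r", seq_along(seqs))
    QualityScaledDNAStringSet(x, PhredQuality(IRanges::IntegerList(quals)))
}
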