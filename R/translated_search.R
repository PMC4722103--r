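## substitution matrix loaded from Biostrings by name, with its alphabet
.load_matrix <- function(name) {
    e <- new.env()
    data(list = name, package = "Biostrings", envir = e)
    m <- get(name, envir = e)
    storage.mode(m) <- "double"
    m
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code: frames +1/+2/+3 from the sequence itself, -1/-2/-3
#' from its reverse complement.  Trailing partial codons are dropped, stop
#' codons are rendered \code{*}, and codons containing \code{N} translate to
#' \code{X}.
#'
#' @param s a \code{DNAString}, or character coercible to one.
#' @return An \code{AAStringSet} of the six frame peptides, named
#'   \code{F1, F2, F3, R1, R2, R3}; frames shorter than one codon are empty.
#' @examples
#' sixFrameTranslate("ATGAAA")
#' @export
sixFrameTranslate <- function(s) {
    s <- DNAString(as.character(s))
    L <- length(s)
    frames <- vector("list", 6L)
    names(frames) <- c("F1", "F2", "F3", "R1", "R2", "R3")
    rc <- reverseComplement(s)
    for (off in 0:2) {
        frames[[off + 1L]] <- .translate_frame(s, off)
        frames[[off + 4L]] <- .translate_frame(rc, off)
    }
    AAStringSet(unlist(frames))
}

.translate_frame <- function(s, off) {
    L <- length(s)
    ncod <- (L - off) %/% 3L
    if (ncod < 1L) return("")
    as.character(translate(subseq(s, off + 1L, off + 3L * ncod),
                           if.fuzzy.codon = "X"))
}

#' Karlin-Altschul E-value
#'
#' Converts a raw local-alignment score into the expected number of chance
#' hits in a search space of \code{m * n} residues:
#' \deqn{E = K m n e^{-\lambda S}.}
#'
#' @param score raw alignment score(s).
#' @param m query length in aa.
#' @param n effective database length in aa.
#' @param params a [SearchParams-class] carrying \code{karlinK} and
#'   \code{karlinLambda}.
#' @return Numeric E-value(s).
#' @examples
#' karlinEvalue(50, 100, 1e6, SearchParams())
#' @export
karlinEvalue <- function(score, m, n, params = SearchParams()) {
    if (any(m <= 0) || any(n <= 0)) stop("lengths must be positive")
    params@karlinK * m * n * exp(-params@karlinLambda * score)
}

## nt coordinates (original strand, start <= end) of aa positions p1..p2 in
## frame f (1..3 forward, 4..6 reverse) of a sequence of length L
.frame_nt_coords <- function(f, p1, p2, L) {
    if (f <= 3L) {
        off <- f - 1L
        c(start = off + 3L * (p1 - 1L) + 1L, end = off + 3L * p2,
          frame = f)
    } else {
        off <- f - 4L
        c(start = L - off - 3L * p2 + 1L, end = L - off - 3L * (p1 - 1L),
          frame = -(f - 3L))
    }
}

## vectorized version over rows; L may be scalar or per-row
.frame_nt_coords_vec <- function(f, p1, p2, L) {
    fwd <- f <= 3L
    off <- ifelse(fwd, f - 1L, f - 4L)
    start <- ifelse(fwd, off + 3L * (p1 - 1L) + 1L, L - off - 3L * p2 + 1L)
    end <- ifelse(fwd, off + 3L * p2, L - off - 3L * (p1 - 1L))
    data.frame(start = as.integer(start), end = as.integer(end),
               frame = as.integer(ifelse(fwd, f, -(f - 3L))))
}

#' Translated local alignment between two nucleotide sequences
#'
#' tblastx-style search: both sequences are translated in six frames and
#' every frame pair is scanned for the best gapped local alignment in
#' amino-acid space (affine gaps under the configured substitution matrix).
#' Depending on \code{mode}, frame pairs are aligned exhaustively
#' (Smith-Waterman) or via two-hit word seeding with banded extension;
#' \code{"auto"} uses exhaustive alignment for small frame pairs and seeding
#' for large ones.  Scores are converted to E-values with the
#' Karlin-Altschul formula using the search space summed over all 36 frame
#' pairs, and hits with E-value at most \code{evalueCutoff} are returned.
#'
#' @param query,subject nucleotide sequences (character or \code{DNAString}).
#' @param params a [SearchParams-class].
#' @return A data.frame of HSPs sorted by ascending E-value then descending
#'   score, with 1-based inclusive nt coordinates on the original strands
#'   (\code{q_start <= q_end}; the frame sign carries the strand), identity
#'   as a fraction of aligned aa, alignment length in aa, raw score and
#'   E-value.
#' @examples
#' s <- strrep("ATGGCCAAAGAACTGGTCGACCGT", 4)
#' translatedAlign(substr(s, 1, 60), s,
#'                 SearchParams(evalueCutoff = 10, mode = "full"))
#' @export
translatedAlign <- function(query, subject, params = SearchParams()) {
    query <- as.character(query); subject <- as.character(subject)
    if (nchar(query) < 3L || nchar(subject) < 3L)
        return(.empty_hsp_table())
    qf <- as.character(sixFrameTranslate(query))
    sf <- as.character(sixFrameTranslate(subject))
    res <- .batch_search(matrix(qf, nrow = 1L), sf, params)
    if (!nrow(res)) return(.empty_hsp_table())
    .hsps_from_batch(res, query_ids = "query", query_lens = nchar(query),
                     subject_id = "subject", subject_len = nchar(subject),
                     sf_lens = nchar(sf), params = params)
}

## run the C engine; qmat is a reads x 6 character matrix of frame peptides
.batch_search <- function(qmat, sframes, params, minScore = 0) {
    mat <- .load_matrix(params@matrix)
    mode <- match(params@mode, c("auto", "full", "seeded")) - 1L
    .C_translated_batch(qmat, sframes, mat, rownames(mat),
                        params@gapOpen, params@gapExtend, params@wordSize,
                        mode, 16384, 2L, 2L, minScore)
}

.empty_hsp_table <- function() {
    data.frame(query_id = character(0), subject_id = character(0),
               q_start = integer(0), q_end = integer(0),
               s_start = integer(0), s_end = integer(0),
               q_frame = integer(0), s_frame = integer(0),
               score = numeric(0), identity = numeric(0),
               aln_len = integer(0), evalue = numeric(0))
}

## convert batch rows (aa frame coords) into the HSP table, add E-values,
## filter by cutoff and sort
.hsps_from_batch <- function(res, query_ids, query_lens, subject_id,
                             subject_len, sf_lens, params) {
    if (!nrow(res)) return(.empty_hsp_table())
    n_eff <- sum(as.numeric(sf_lens))
    ## search space: query aa length times frame-pair-summed subject length
    ev <- karlinEvalue(res[, "score"], res[, "qlen_aa"] * 6, n_eff, params)
    keep <- ev <= params@evalueCutoff
    if (!any(keep)) return(.empty_hsp_table())
    res <- res[keep, , drop = FALSE]
    ev <- ev[keep]
    qlen_nt <- query_lens[res[, "query"]]
    qc <- .frame_nt_coords_vec(res[, "qframe"], res[, "qstart_aa"],
                               res[, "qend_aa"], qlen_nt)
    sc <- .frame_nt_coords_vec(res[, "sframe"], res[, "sstart_aa"],
                               res[, "send_aa"], subject_len)
    out <- data.frame(
        query_id = query_ids[res[, "query"]],
        subject_id = subject_id,
        q_start = as.integer(qc[, "start"]), q_end = as.integer(qc[, "end"]),
        s_start = as.integer(sc[, "start"]), s_end = as.integer(sc[, "end"]),
        q_frame = as.integer(qc[, "frame"]),
        s_frame = as.integer(sc[, "frame"]),
        score = res[, "score"],
        identity = res[, "matches"] / res[, "aln_cols"],
        aln_len = as.integer(res[, "aln_cols"]),
        evalue = ev)
    out <- out[order(out$evalue, -out$score, out$subject_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Recruit reads against bait genomes by translated homology
#'
#' Searches every read against each bait genome with [translatedAlign()]
#' semantics and returns the recruitment table.  With
#' \code{params@bestHitOnly} a single best hit per read is kept (ties broken
#' by lower E-value, then higher score, then lexicographic subject id),
#' mirroring the "one hit per read" recruitment of the study.
#'
#' @param reads a \code{DNAStringSet} (or \code{QualityScaledDNAStringSet})
#'   of quality-filtered reads.
#' @param baits a named \code{DNAStringSet} of bait genomes.
#' @param params a [SearchParams-class]; the study used cutoff 1e-5 for the
#'   permissive multi-genome scan and 1e-10 with best-hit-only for the
#'   strict bait recruitment.
#' @return A data.frame with one row per retained HSP: \code{read_id,
#'   subject_id, midpoint} (mean of the subject start/end positions, the
#'   x-axis of a fragment recruitment plot), \code{identity, evalue} plus
#'   the full coordinate columns of [translatedAlign()].
#' @seealso [recruitmentCounts()], [baitShare()].
#' @export
recruitReads <- function(reads, baits, params = SearchParams()) {
    if (length(baits) == 0L) stop("baits must be non-empty")
    if (length(reads) == 0L) return(.empty_recruitment_table())
    rs <- as.character(reads)
    ids <- names(rs)
    if (is.null(ids)) ids <- paste0("read", seq_along(rs))
    ## frame peptides for all reads, vectorized per frame
    qmat <- .frame_matrix(rs)
    hits <- vector("list", length(baits))
    bnames <- names(baits)
    if (is.null(bnames)) bnames <- paste0("bait", seq_along(baits))
    for (b in seq_along(baits)) {
        sf <- as.character(sixFrameTranslate(baits[[b]]))
        res <- .batch_search(qmat, sf, params)
        hits[[b]] <- .hsps_from_batch(res, ids, nchar(rs), bnames[b],
                                      nchar(as.character(baits[[b]])),
                                      nchar(sf), params)
    }
    tab <- do.call(rbind, hits)
    if (!nrow(tab)) return(.empty_recruitment_table())
    if (params@bestHitOnly) {
        tab <- tab[order(tab$evalue, -tab$score, tab$subject_id), ,
                   drop = FALSE]
        tab <- tab[!duplicated(tab$query_id), , drop = FALSE]
    }
    out <- data.frame(read_id = tab$query_id, subject_id = tab$subject_id,
                      midpoint = (tab$s_start + tab$s_end) / 2,
                      identity = tab$identity, evalue = tab$evalue,
                      tab[, c("q_start", "q_end", "s_start", "s_end",
                              "q_frame", "s_frame", "score", "aln_len")])
    rownames(out) <- NULL
    out
}

## six-frame peptides of many reads as a reads x 6 character matrix
.frame_matrix <- function(rs) {
    d <- DNAStringSet(rs)
    rc <- reverseComplement(d)
    w <- Biostrings::width(d)
    cols <- vector("list", 6L)
    for (off in 0:2) {
        ncod <- pmax(0L, (w - off) %/% 3L)
        tr <- function(set) {
            keep <- ncod >= 1L
            out <- character(length(set))
            if (any(keep)) {
                sub <- IRanges::narrow(set[keep], start = off + 1L,
                                          end = off + 3L * ncod[keep])
                out[keep] <- as.character(translate(sub,
                                                    if.fuzzy.codon = "X"))
            }
            out
        }
        cols[[off + 1L]] <- tr(d)
        cols[[off + 4L]] <- tr(rc)
    }
    m <- do.call(cbind, cols)
    colnames(m) <- c("F1", "F2", "F3", "R1", "R2", "R3")
    m
}

.empty_recruitment_table <- function() {
    data.frame(read_id = character(0), subject_id = character(0),
               midpoint = numeric(0), identity = numeric(0),
               evalue = numeric(0), q_start = integer(0), q_end = integer(0),
               s_start = integer(0), s_end = integer(0),
               q_frame = integer(0), s_frame = integer(0),
               score = numeric(0), aln_len = integer(0))
}

#' Per-bait recruited-read counts
#'
#' @param table a recruitment table from [recruitReads()].
#' @return data.frame with \code{subject_id, n_reads}, sorted by descending
#'   count (unique reads per bait).
#' @export
recruitmentCounts <- function(table) {
    if (!nrow(table))
        return(data.frame(subject_id = character(0), n_reads = integer(0)))
    u <- unique(table[, c("read_id", "subject_id")])
    agg <- as.data.frame(table(u$subject_id), stringsAsFactors = FALSE)
    names(agg) <- c("subject_id", "n_reads")
    agg <- agg[order(-agg$n_reads, agg$subject_id), , drop = FALSE]
    rownames(agg) <- NULL
    agg
}

#' Share of recruited reads assigned to one bait
#'
#' The bookkeeping behind statements like "1199 of the 3919 recruited reads
#' (30.6%) matched YSLV3": count for one bait divided by the total.
#'
#' @param counts a data.frame with \code{subject_id, n_reads} (from
#'   [recruitmentCounts()] or a bundled count table).
#' @param bait the bait (subject) id.
#' @return The share as a fraction in \[0, 1\].
#' @examples
#' baitShare(dslRecruitmentCounts(), "YSLV3")
#' @export
baitShare <- function(counts, bait) {
    tot <- sum(counts$n_reads)
    if (tot == 0L) stop("no recruited reads")
    sum(counts$n_reads[counts$subject_id == bait]) / tot
}

#' Write a recruitment table as TSV
#'
#' @param table recruitment table from [recruitReads()].
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
writeRecruitmentTable <- function(table, file) {
    write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
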