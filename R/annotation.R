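#' G+C content of a nucleotide sequence
#'
#' (G + C) / (A + C + G + T); ambiguous bases are excluded from the
#' denominator.
#'
#' @param s \code{DNAString}, [VirophageGenome-class], [Contig-class] or
#'   character.
#' @return Fraction in \[0, 1\].
#' @examples
#' gcContent("GGCC")  # 1
#' gcContent("ATAT")  # 0
#' @export
gcContent <- function(s) {
    s <- .as_dna_chr(s)
    b <- strsplit(toupper(s), "")[[1L]]
    n <- sum(b %in% BASES)
    if (n == 0L) stop("sequence contains no unambiguous bases")
    sum(b %in% c("G", "C")) / n
}

#' G+C skew track
#'
#' (G - C) / (G + C) in sliding windows, the inner track of a circular
#' genome map.  Window and step default to 500/100 bp (the plot scale used
#' for a ~29 kb genome; the source tooling does not state its windows).
#'
#' @param s sequence as for [gcContent()].
#' @param window,step window and step size in bp.
#' @param circular wrap windows across the origin.
#' @return data.frame with \code{start, end, skew} (NA where a window has no
#'   G or C).
#' @export
gcSkew <- function(s, window = 500L, step = 100L, circular = TRUE) {
    s <- toupper(.as_dna_chr(s))
    L <- nchar(s)
    if (window > L) window <- L
    starts <- seq.int(1L, if (circular) L else max(1L, L - window + 1L),
                      by = step)
    doubled <- if (circular) paste0(s, s) else s
    wins <- substring(doubled, starts, starts + window - 1L)
    g <- vapply(strsplit(wins, ""), function(b) sum(b == "G"), 1L)
    cc <- vapply(strsplit(wins, ""), function(b) sum(b == "C"), 1L)
    skew <- ifelse(g + cc > 0, (g - cc) / (g + cc), NA_real_)
    data.frame(start = starts, end = (starts + window - 2L) %% L + 1L,
               skew = skew)
}

.as_dna_chr <- function(s) {
    if (is(s, "VirophageGenome")) return(as.character(s@seq))
    if (is(s, "Contig")) return(as.character(s@seq))
    as.character(s)
}

.seq_circular <- function(s, default = FALSE) {
    if (is(s, "VirophageGenome")) return(s@circular)
    if (is(s, "Contig")) return(s@circular)
    default
}

#' Predict open reading frames
#'
#' Rule-based ORF calling as used for the study genome: in each of the six
#' reading frames, every stop-to-stop interval contributes the ORF running
#' from its FIRST start codon (ATG) through the stop codon, reported when
#' the total span is at least \code{minLen} nt (150 by default).
#' Overlapping ORFs in different frames are all reported; ORFs crossing the
#' origin of circular sequences are found when
#' \code{allowWraparound}.  Setting \code{firstAtgOnly = FALSE} expands
#' every ATG into a candidate ORF, with same-frame nested ORFs optionally
#' suppressed.
#'
#' @param g sequence ([VirophageGenome-class], [Contig-class],
#'   \code{DNAString} or character).
#' @param params an [ORFParams-class].
#' @param circular override the sequence's circular flag.
#' @return data.frame of [predictOrfs()] records: \code{index, start, end,
#'   strand, nt_len, protein}; coordinates are 1-based inclusive on the
#'   ORF's own strand (start = first base of ATG, end = last base of the
#'   stop codon, hence start > end on the reverse strand) and records are
#'   numbered in genome order of their leftmost base.  \code{nt_len} counts
#'   the stop codon; the protein excludes it, so its length is
#'   \code{nt_len / 3 - 1}.
#' @examples
#' orfs <- predictOrfs(paste0(strrep("T", 30), "ATG",
#'     paste(rep("GCT", 60), collapse = ""), "TAA", strrep("T", 30)),
#'     ORFParams(), circular = FALSE)
#' orfs[, 1:5]
#' @export
predictOrfs <- function(g, params = ORFParams(), circular = NULL) {
    s <- toupper(.as_dna_chr(g))
    if (is.null(circular)) circular <- .seq_circular(g)
    L <- nchar(s)
    if (L < params@minLen) return(.empty_orf_table())
    wrap <- circular && params@allowWraparound
    scan_s <- if (wrap) paste0(s, s) else s
    fwd <- .scan_orfs(scan_s, params, L, wrap)
    if (nrow(fwd) && wrap)
        fwd$end <- (fwd$end - 1L) %% L + 1L
    rev_scan <- if (wrap) paste0(.rc_chr(s), .rc_chr(s)) else .rc_chr(s)
    rev <- .scan_orfs(rev_scan, params, L, wrap)
    if (nrow(rev)) {
        ## map reverse-scan coordinates back to the original strand
        rev_start <- L - ((rev$start - 1L) %% L)
        rev_end <- L - ((rev$end - 1L) %% L)
        rev$start <- rev_start
        rev$end <- rev_end
        rev$strand <- "-"
    }
    out <- rbind(fwd, rev)
    if (!nrow(out)) return(.empty_orf_table())
    if (wrap) {
        ## the linear scan of a doubled circle can report, for the interval
        ## containing the origin, both a truncated ORF (no upstream context)
        ## and the true origin-crossing ORF sharing its stop: keep the
        ## longest ORF per (strand, stop) locus
        out <- out[order(-out$nt_len), , drop = FALSE]
        out <- out[!duplicated(paste(out$strand, out$end)), , drop = FALSE]
    }
    ## translation and numbering by genome order
    out$protein <- vapply(seq_len(nrow(out)), function(i)
        .translate_span(s, out$start[i], out$end[i], out$strand[i], L), "")
    left <- ifelse(out$strand == "+", out$start, out$end)
    out <- out[order(left, out$nt_len, out$strand), , drop = FALSE]
    out$index <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("index", "start", "end", "strand", "nt_len", "protein")]
}

.empty_orf_table <- function() {
    data.frame(index = integer(0), start = integer(0), end = integer(0),
               strand = character(0), nt_len = integer(0),
               protein = character(0))
}

## forward-strand scan of a (possibly doubled) sequence; reports ORFs whose
## start lies within the first L bases and whose span is <= L
.scan_orfs <- function(s, params, L, doubled) {
    n <- nchar(s)
    out <- list()
    for (off in 0:2) {
        ncod <- (n - off) %/% 3L
        if (ncod < 2L) next
        starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
        codons <- substring(s, starts, starts + 2L)
        is_stop <- codons %in% STOP_CODONS
        is_atg <- codons == params@startCodon
        stop_idx <- which(is_stop)
        ## stop-to-stop intervals: (prev_stop, next_stop]
        bounds <- c(0L, stop_idx)
        for (b in seq_len(length(bounds) - 1L)) {
            lo <- bounds[b] + 1L
            hi <- bounds[b + 1L]          # index of the closing stop codon
            atgs <- which(is_atg[lo:(hi - 1L)])
            if (!length(atgs)) next
            cand <- if (params@firstAtgOnly) atgs[1L] else atgs
            for (a in cand) {
                ai <- lo + a - 1L
                span <- 3L * (hi - ai + 1L)
                if (span < params@minLen) next
                st <- starts[ai]
                if (doubled && st > L) next
                if (doubled && span > L) next
                out[[length(out) + 1L]] <-
                    data.frame(start = st, end = starts[hi] + 2L,
                               strand = "+", nt_len = span)
            }
        }
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(start = integer(0), end = integer(0),
                   strand = character(0), nt_len = integer(0))
    if (nrow(res) && !params@firstAtgOnly && params@suppressNested) {
        ## drop ORFs nested in a longer same-frame ORF (they share a stop)
        res <- res[order(-res$nt_len), , drop = FALSE]
        res <- res[!duplicated(res$end), , drop = FALSE]
    }
    res
}

## translate a strand-aware span (start > end means reverse strand), with
## wraparound on circular sequences; drops the stop codon
.translate_span <- function(s, start, end, strand, L) {
    sub <- .extract_span(s, start, end, strand, L)
    p <- as.character(translate(DNAString(sub), if.fuzzy.codon = "X"))
    substr(p, 1L, nchar(p) - 1L)
}

.extract_span <- function(s, start, end, strand, L) {
    if (strand == "+") {
        if (end >= start) substr(s, start, end)
        else paste0(substr(s, start, L), substr(s, 1L, end))  # wraps origin
    } else {
        sub <- if (start >= end) substr(s, end, start)
            else paste0(substr(s, end, L), substr(s, 1L, start))
        .rc_chr(sub)
    }
}

#' Translate one ORF record
#'
#' Extracts the strand-aware span from the genome (wrapping the origin on
#' circular sequences), translates it under the standard genetic code and
#' drops the stop codon.  An internal stop violates the ORF definition and
#' raises an error.
#'
#' @param g the genome the record refers to.
#' @param start,end 1-based inclusive coordinates on the ORF's own strand
#'   (start > end implies the reverse strand).
#' @param circular override the genome's circular flag.
#' @return The protein string (starts with M, no stop).
#' @examples
#' translateOrf("ATGAAATAA", 1, 9)  # "MK"
#' @export
translateOrf <- function(g, start, end, circular = NULL) {
    s <- toupper(.as_dna_chr(g))
    if (is.null(circular)) circular <- .seq_circular(g)
    L <- nchar(s)
    strand <- if (start <= end) "+" else "-"
    span <- if (circular) (abs(end - start) %% L) + 1L else
        abs(end - start) + 1L
    if (span %% 3L != 0L) stop("ORF span must be divisible by 3")
    p <- .translate_span(s, start, end, strand, L)
    if (grepl("*", p, fixed = TRUE))
        stop("internal stop codon: not a valid ORF")
    p
}

#' Annotate ORF proteins against a local protein database
#'
#' For each ORF protein, finds the best gapped local alignment
#' (Smith-Waterman, exhaustive) against every database protein, converts
#' scores to Karlin-Altschul E-values over the summed database length, and
#' reports the best hit when its E-value is at most
#' \code{params@evalueCutoff} (1e-3, the study's annotation threshold).
#' ORFs without a qualifying hit are flagged as ORFans.
#'
#' @param orfs ORF table from [predictOrfs()] (needs \code{index} and
#'   \code{protein} columns), or a character vector of proteins.
#' @param db a named \code{AAStringSet} protein database.
#' @param params a [SearchParams-class]; \code{mode} is forced to full
#'   dynamic programming.
#' @return data.frame with one row per ORF: \code{orf_index, subject_id,
#'   percent_identity, aln_len_aa, q_start, q_end} (aa positions on the ORF
#'   protein), \code{evalue, orfan}; subject columns are NA for ORFans.
#' @export
annotateProteins <- function(orfs, db,
                             params = SearchParams(evalueCutoff = 1e-3,
                                                   mode = "full")) {
    if (length(db) == 0L) stop("protein database must be non-empty")
    if (is.character(orfs))
        orfs <- data.frame(index = seq_along(orfs), protein = orfs)
    mat <- .load_matrix(params@matrix)
    dbs <- as.character(db)
    dbn <- names(dbs)
    if (is.null(dbn)) dbn <- paste0("prot", seq_along(dbs))
    n_eff <- sum(nchar(dbs))
    rows <- vector("list", nrow(orfs))
    for (i in seq_len(nrow(orfs))) {
        q <- orfs$protein[i]
        best <- NULL
        for (d in seq_along(dbs)) {
            a <- .C_sw_align(q, dbs[d], mat, rownames(mat), params@gapOpen,
                             params@gapExtend)
            ev <- karlinEvalue(a[1L], nchar(q), n_eff, params)
            cand <- list(subject = dbn[d], score = a[1L], ev = ev,
                         qs = a[2L], qe = a[3L], matches = a[6L],
                         cols = a[7L])
            if (is.null(best) || ev < best$ev ||
                (ev == best$ev && (a[1L] > best$score ||
                 (a[1L] == best$score && dbn[d] < best$subject))))
                best <- cand
        }
        hit <- !is.null(best) && best$ev <= params@evalueCutoff
        rows[[i]] <- data.frame(
            orf_index = orfs$index[i],
            subject_id = if (hit) best$subject else NA_character_,
            percent_identity = if (hit)
                100 * best$matches / best$cols else NA_real_,
            aln_len_aa = if (hit) as.integer(best$cols) else NA_integer_,
            q_start = if (hit) as.integer(best$qs) else NA_integer_,
            q_end = if (hit) as.integer(best$qe) else NA_integer_,
            evalue = if (hit) best$ev else NA_real_,
            orfan = !hit)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' In-silico PCR
#'
#' Finds amplicons a primer pair would produce from a template: forward
#' primer sites on either strand and reverse-primer sites (as the reverse
#' complement) downstream on the same amplifiable orientation, allowing up
#' to \code{maxMismatch} mismatches per site and no indels.  The amplicon
#' runs from the first base of the forward primer through the last base of
#' the reverse-primer binding site.  Circular templates are searched across
#' the origin; \code{maxProduct} caps the product length (on a circle every
#' site pair also amplifies the long way around).
#'
#' @param template sequence ([VirophageGenome-class], [Contig-class] or
#'   character/DNAString).
#' @param primers a [PrimerPair-class].
#' @param maxProduct maximum amplicon length in bp.
#' @param circular override the template's circular flag.
#' @return data.frame with \code{template, start, end, strand, length}:
#'   \code{start}/\code{end} are the 1-based outer coordinates of the
#'   amplicon on the forward strand of the template (\code{end} wraps past
#'   the origin as \code{((end - 1) mod L) + 1} with \code{length} keeping
#'   the true product size); \code{strand} is the strand the forward primer
#'   annealed to.
#' @examples
#' tpl <- paste0(strrep("A", 30), "CGACCAAGACTTCCAGCCTC", strrep("G", 50),
#'               "GCAACTCAGTGGGACTTGTG", strrep("A", 30))
#' pp <- PrimerPair("p", "CGACCAAGACTTCCAGCCTC", "CACAAGTCCCACTGAGTTGC")
#' insilicoPcr(tpl, pp, circular = FALSE)
#' @export
insilicoPcr <- function(template, primers, maxProduct = 10000L,
                        circular = NULL) {
    stopifnot(is(primers, "PrimerPair"))
    s <- toupper(.as_dna_chr(template))
    if (is.null(circular)) circular <- .seq_circular(template)
    L <- nchar(s)
    id <- if (is(template, "VirophageGenome") || is(template, "Contig"))
        template@id else "template"
    search_s <- if (circular) paste0(s, s) else s

    hits <- function(primer) {
        m <- matchPattern(DNAString(primer), DNAString(search_s),
                          max.mismatch = primers@maxMismatch,
                          with.indels = FALSE)
        IRanges::start(m)
    }
    out <- list()
    scan_orientation <- function(seq_fwd, seq_rev, strand) {
        f <- hits(seq_fwd)                                   # fwd primer 5' ends
        r <- hits(.rc_chr(seq_rev))                          # rev site starts
        rev_w <- nchar(seq_rev)
        for (fs in f) {
            if (fs > L) next  # canonical copy only
            re <- r[r >= fs + nchar(seq_fwd)]                # non-overlapping
            for (rs in re) {
                len <- rs + rev_w - fs
                if (len > maxProduct || (circular && len > L)) next
                out[[length(out) + 1L]] <<- data.frame(
                    template = id,
                    start = fs, end = (fs + len - 2L) %% L + 1L,
                    strand = strand, length = len)
            }
        }
    }
    scan_orientation(primers@forward, primers@reverse, "+")
    ## forward primer annealing to the minus strand: amplicon on the
    ## reverse-complement template; report coordinates on the plus strand
    s_rc <- .rc_chr(s)
    search_rc <- if (circular) paste0(s_rc, s_rc) else s_rc
    hits_rc <- function(primer) {
        m <- matchPattern(DNAString(primer), DNAString(search_rc),
                          max.mismatch = primers@maxMismatch,
                          with.indels = FALSE)
        IRanges::start(m)
    }
    f <- hits_rc(primers@forward)
    r <- hits_rc(.rc_chr(primers@reverse))
    rev_w <- nchar(primers@reverse)
    for (fs in f) {
        if (fs > L) next
        re <- r[r >= fs + nchar(primers@forward)]
        for (rs in re) {
            len <- rs + rev_w - fs
            if (len > maxProduct || (circular && len > L)) next
            ## map rc coordinates back: rc position p -> plus position L-p+1
            plus_end <- L - fs + 1L            # outer end on plus strand
            plus_start <- plus_end - len + 1L
            out[[length(out) + 1L]] <- data.frame(
                template = id,
                start = (plus_start - 1L) %% L + 1L,
                end = (plus_end - 1L) %% L + 1L,
                strand = "-", length = len)
        }
    }
    if (!length(out))
        return(data.frame(template = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          length = integer(0)))
    res <- unique(do.call(rbind, out))
    res <- res[order(res$start, res$length), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Arithmetic consistency of an ORF coordinate table
#'
#' Checks, for each row of a strand-aware ORF table, that the span
#' \code{|start - end| + 1} is divisible by 3, matches the stated nt length,
#' and that the protein length equals \code{nt/3 - 1} -- the invariants every
#' row of the study's ORF table satisfies.
#'
#' @param tab data.frame with columns \code{start, end} and optionally
#'   \code{nt, aa}.
#' @return Logical vector, one entry per row.
#' @examples
#' all(orfArithmeticConsistent(dslv1OrfTable()))
#' @export
orfArithmeticConsistent <- function(tab) {
    span <- abs(tab$start - tab$end) + 1L
    ok <- span %% 3L == 0L
    if (!is.null(tab$nt)) ok <- ok & span == tab$nt
    if (!is.null(tab$aa)) ok <- ok & tab$aa == span / 3L - 1L
    ok
}

#' Write an ORF table as GFF3 and the proteins as FASTA
#'
#' @param orfs ORF table from [predictOrfs()].
#' @param seqid sequence name for the GFF3 column 1.
#' @param prefix output prefix (writes \code{<prefix>.gff3} and
#'   \code{<prefix>_proteins.faa}).
#' @return Invisibly, the two paths.
#' @export
writeOrfs <- function(orfs, seqid, prefix) {
    gr <- GenomicRanges::GRanges(
        seqnames = seqid,
        ranges = IRanges::IRanges(start = pmin(orfs$start, orfs$end),
                                  end = pmax(orfs$start, orfs$end)),
        strand = orfs$strand, type = "CDS", phase = 0L,
        ID = paste0("orf", orfs$index))
    gff <- paste0(prefix, ".gff3")
    rtracklayer::export(gr, gff, format = "gff3")
    aa <- AAStringSet(orfs$protein)
    names(aa) <- paste0("orf", orfs$index)
    faa <- paste0(prefix, "_proteins.faa")
    writeXStringSet(aa, faa, width = 70L)
    invisible(c(gff = gff, proteins = faa))
}
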