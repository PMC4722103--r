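#' Quality-trim a single read
#'
#' Implements the windowed rule used on the study metagenome: scan 5' to 3'
#' and truncate the read immediately before the first position at which the
#' mean Phred score of the \code{window} bases starting there falls below
#' \code{minMeanQ}; reject the read if the retained prefix is shorter than
#' \code{minLength}.  When the read is shorter than the window, the mean of
#' the whole read is evaluated instead.  Retained reads therefore have every
#' full window mean at or above the threshold, which makes the rule
#' idempotent.
#'
#' @param bases character, the read sequence.
#' @param quals integer vector of Phred scores, one per base.
#' @param params a [QCParams-class].
#' @return A list with \code{bases}, \code{quals} (the retained prefix) and
#'   \code{rejected} (logical).
#' @examples
#' qcRead(strrep("A", 60), c(rep(40L, 50), rep(2L, 10)), QCParams())
#' @export
qcRead <- function(bases, quals, params = QCParams()) {
    if (nchar(bases) != length(quals))
        stop("bases and quals must have equal length")
    keep <- .qc_keep_length(as.integer(quals), params)
    if (keep < params@minLength)
        return(list(bases = "", quals = integer(0), rejected = TRUE))
    list(bases = substr(bases, 1L, keep), quals = quals[seq_len(keep)],
         rejected = FALSE)
}

## retained prefix length under the windowed rule
.qc_keep_length <- function(q, params) {
    n <- length(q)
    w <- params@window
    if (n == 0L) return(0L)
    if (n < w) return(if (mean(q) >= params@minMeanQ) n else 0L)
    cs <- c(0, cumsum(as.numeric(q)))
    wm <- (cs[(w + 1L):(n + 1L)] - cs[seq_len(n - w + 1L)]) / w
    bad <- which(wm < params@minMeanQ)
    if (!length(bad)) n else bad[1L] - 1L
}

#' Quality-filter a read set (or several runs) with accounting
#'
#' Applies [qcRead()] to every read of one or several sequencing runs and
#' tallies reads and bases in and out per run, mirroring the study's
#' run-by-run QC table; totals are sums over runs.
#'
#' @param runs a \code{QualityScaledDNAStringSet}, or a named list of them
#'   (one per run).
#' @param params a [QCParams-class].
#' @return A list with \code{passed} (named list of filtered
#'   \code{QualityScaledDNAStringSet}, input order preserved) and
#'   \code{stats} (data.frame with columns \code{run, reads_in, reads_out,
#'   bases_in, bases_out}).
#' @seealso [qcTotals()] for the Total row.
#' @export
qcDataset <- function(runs, params = QCParams()) {
    if (!is.list(runs)) runs <- list(run1 = runs)
    if (is.null(names(runs)))
        names(runs) <- paste0("run", seq_along(runs))
    passed <- vector("list", length(runs))
    names(passed) <- names(runs)
    stats <- vector("list", length(runs))
    for (k in seq_along(runs)) {
        rs <- runs[[k]]
        n <- length(rs)
        if (n == 0L) {
            passed[[k]] <- rs
            stats[[k]] <- data.frame(run = names(runs)[k], reads_in = 0L,
                                     reads_out = 0L, bases_in = 0L,
                                     bases_out = 0L)
            next
        }
        qlist <- as(quality(rs), "IntegerList")
        keep <- vapply(seq_len(n), function(i)
            .qc_keep_length(qlist[[i]], params), 1L)
        ok <- keep >= params@minLength
        widths <- Biostrings::width(rs)
        trimmed <- IRanges::narrow(rs[ok], start = 1L, end = keep[ok])
        passed[[k]] <- trimmed
        stats[[k]] <- data.frame(run = names(runs)[k],
                                 reads_in = n, reads_out = sum(ok),
                                 bases_in = sum(widths),
                                 bases_out = sum(keep[ok]))
    }
    list(passed = passed, stats = do.call(rbind, stats))
}

#' Total row of a QC accounting table
#'
#' @param stats the \code{stats} data.frame from [qcDataset()], or any
#'   data.frame with the same numeric columns (e.g. the bundled study run
#'   table).
#' @return A one-row data.frame with \code{run = "Total"} and column sums.
#' @examples
#' qcTotals(dslQcRuns())
#' @export
qcTotals <- function(stats) {
    num <- vapply(stats, is.numeric, TRUE)
    tot <- as.data.frame(lapply(stats[num], sum))
    cbind(run = "Total", tot)
}

#' Write a QC accounting table as TSV
#'
#' @param stats data.frame from [qcDataset()].
#' @param file output path.
#' @param total append the Total row?
#' @return Invisibly, \code{file}.
#' @export
writeQCStats <- function(stats, file, total = TRUE) {
    out <- if (total) rbind(stats, qcTotals(stats)) else stats
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
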