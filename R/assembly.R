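## ---- internal consensus machinery ------------------------------------------
## A growing contig is represented as a 4 x L count matrix of base votes plus
## the id set of member reads.  Consensus is per-column majority; ties keep
## the earlier consensus base (deterministic).

.BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.votes_from_seq <- function(s) {
    b <- strsplit(s, "")[[1L]]
    m <- matrix(0L, nrow = 4L, ncol = length(b))
    idx <- .BASE_IDX[b]
    ok <- !is.na(idx)
    m[cbind(idx[ok], which(ok))] <- 1L
    m
}

.consensus <- function(votes, prefer = NULL) {
    w <- ncol(votes)
    if (w == 0L) return(character(0))
    top <- pmax(votes[1L, ], votes[2L, ], votes[3L, ], votes[4L, ])
    first <- max.col(t(votes), ties.method = "first")
    cons <- names(.BASE_IDX)[first]
    if (!is.null(prefer)) {
        pidx <- .BASE_IDX[prefer]
        ok <- !is.na(pidx) & votes[cbind(pidx, seq_len(w))] == top
        cons[ok] <- prefer[ok]
    }
    cons
}

.rc_chr <- function(s) as.character(reverseComplement(DNAString(s)))

## ---- de novo assembly --------------------------------------------------------

#' Greedy de novo overlap-layout-consensus assembly
#'
#' Repeatedly merges the pair of sequences (read or partial contig, either
#' orientation) with the longest qualifying overlap -- at least
#' \code{minOverlap} bp at \code{minIdentityDenovo} identity -- breaking ties
#' by higher identity and then lexicographic id.  Overlaps are located by
#' exact-word seeding and scored gapless (substitution-only error model, see
#' the package vignette); the consensus is the per-column majority of all
#' member reads with per-base depth recorded.  Unmergeable reads are emitted
#' as singleton contigs.  These are the thresholds used for the study's de
#' novo stage (25 bp, 80%).
#'
#' @param reads a named \code{DNAStringSet} (or character vector).
#' @param params an [AssemblyParams-class].
#' @return A list of [Contig-class] objects sorted by descending length.
#' @examples
#' src <- paste(sample(c("A","C","G","T"), 300, TRUE), collapse = "")
#' reads <- Biostrings::DNAStringSet(substring(src, c(1, 81, 161), c(120, 200, 300)))
#' names(reads) <- c("r1", "r2", "r3")
#' length(denovoAssemble(reads, AssemblyParams())) # 1 contig
#' @export
denovoAssemble <- function(reads, params = AssemblyParams()) {
    rs <- as.character(reads)
    if (length(rs) == 0L) stop("reads must be non-empty")
    ids <- names(rs)
    if (is.null(ids)) ids <- paste0("read", seq_along(rs))
    names(rs) <- NULL

    ## active assemblies: consensus string, vote matrix, member ids, entry id;
    ## stable integer keys so the candidate cache survives merges
    items <- lapply(seq_along(rs), function(i)
        list(seq = rs[i], votes = .votes_from_seq(rs[i]),
             members = ids[i], id = ids[i]))
    active <- seq_along(items)
    k <- min(params@wordSize, params@minOverlap)

    ## candidate overlaps of several sequences against one pivot, found by
    ## one seeded mapping call (pivot indexed once); returns a numeric
    ## matrix plus the pair tie-break keys
    cands_onto <- function(pivot_key, other_keys) {
        if (!length(other_keys)) return(NULL)
        m <- .C_map_reads(vapply(items[other_keys], `[[`, "", "seq"),
                          items[[pivot_key]]$seq, k, params@minOverlap,
                          params@minIdentityDenovo, 4L)
        if (!nrow(m)) return(NULL)
        jj <- other_keys[m[, "read"]]
        id_i <- items[[pivot_key]]$id
        id_j <- vapply(items[jj], `[[`, "", "id")
        list(mat = cbind(i = pivot_key, j = jj, orient = m[, "strand"],
                         offset = m[, "offset"], overlap = m[, "overlap"],
                         matches = m[, "matches"],
                         identity = m[, "identity"]),
             key = paste(pmin(id_i, id_j), pmax(id_i, id_j), sep = "\r"))
    }
    bind_cands <- function(a, b) {
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        list(mat = rbind(a$mat, b$mat), key = c(a$key, b$key))
    }
    cand <- NULL
    for (t in seq_along(active)[-1L])
        cand <- bind_cands(cand,
                           cands_onto(active[t], active[seq_len(t - 1L)]))

    while (!is.null(cand) && nrow(cand$mat)) {
        ## longest overlap, then higher identity, then lexicographic ids;
        ## staged argmax avoids a full sort per merge
        sel <- which(cand$mat[, "overlap"] == max(cand$mat[, "overlap"]))
        if (length(sel) > 1L) {
            idy <- cand$mat[sel, "identity"]
            sel <- sel[idy == max(idy)]
        }
        if (length(sel) > 1L) sel <- sel[order(cand$key[sel])[1L]]
        pick <- cand$mat[sel[1L], ]
        i <- pick[["i"]]; j <- pick[["j"]]
        a <- items[[i]]; b <- items[[j]]
        if (pick[["orient"]] < 0) {
            b$seq <- .rc_chr(b$seq)
            b$votes <- b$votes[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(b$votes))),
                               drop = FALSE]
        }
        off <- as.integer(pick[["offset"]])
        la <- nchar(a$seq); lb <- nchar(b$seq)
        lo <- min(1L, off + 1L); hi <- max(la, off + lb)
        width <- hi - lo + 1L
        votes <- matrix(0L, 4L, width)
        a0 <- 1L - lo
        votes[, (a0 + 1L):(a0 + la)] <- a$votes
        b0 <- off + 1L - lo
        votes[, (b0 + 1L):(b0 + lb)] <-
            votes[, (b0 + 1L):(b0 + lb), drop = FALSE] + b$votes
        prefer <- rep(NA_character_, width)
        prefer[(a0 + 1L):(a0 + la)] <- strsplit(a$seq, "")[[1L]]
        cons <- paste(.consensus(votes, prefer), collapse = "")
        merged <- list(seq = cons, votes = votes,
                       members = c(a$members, b$members),
                       id = min(a$id, b$id))
        items[[length(items) + 1L]] <- merged
        new_key <- length(items)
        active <- c(setdiff(active, c(i, j)), new_key)
        keep <- !(cand$mat[, "i"] %in% c(i, j) |
                  cand$mat[, "j"] %in% c(i, j))
        cand <- bind_cands(list(mat = cand$mat[keep, , drop = FALSE],
                                key = cand$key[keep]),
                           cands_onto(new_key, setdiff(active, new_key)))
    }
    contigs <- lapply(seq_along(active), function(t) {
        it <- items[[active[t]]]
        depth <- as.integer(colSums(it$votes))
        new("Contig", id = paste0("contig", t), seq = DNAString(it$seq),
            depth = depth, memberReads = it$members, circular = FALSE,
            terminalRepeatLen = 0L, iterations = 0L)
    })
    contigs[order(-vapply(contigs, function(x) length(x@seq), 1L),
                  vapply(contigs, function(x) x@id, ""))]
}

## ---- iterative reference-guided extension -----------------------------------

#' Iteratively extend a contig against the full read set
#'
#' Each iteration maps every read (both orientations, gapless, seeded) to
#' the current contig requiring at least \code{minOverlap} bp at
#' \code{minIdentityExtend} identity, with overhangs allowed at either end;
#' the consensus is recomputed per column from the mapped reads and the
#' contig grows by majority-supported overhang columns (single-read
#' extensions are only accepted where no deeper support exists).  Iteration
#' stops at a length fixed point, when a terminal direct repeat of at least
#' \code{minTerminalRepeat} bp emerges (the circularity signal -- continuing
#' would wrap around the genome indefinitely), or at
#' \code{maxIterations}.  These are the study's extension thresholds
#' (25 bp, 90%, repeated "until the assembled sequences stop extending").
#'
#' @param seed a [Contig-class] (from [denovoAssemble()]) or coercible
#'   sequence.
#' @param reads \code{DNAStringSet} of all quality-filtered reads.
#' @param params an [AssemblyParams-class].
#' @return The extended [Contig-class] with \code{iterations} recorded.
#' @export
referenceExtend <- function(seed, reads, params = AssemblyParams()) {
    if (!is(seed, "Contig"))
        seed <- new("Contig", id = "seed",
                    seq = DNAString(as.character(seed)),
                    depth = rep(1L, nchar(as.character(seed))),
                    memberReads = character(0), circular = FALSE,
                    terminalRepeatLen = 0L, iterations = 0L)
    rs <- as.character(reads)
    ids <- names(rs)
    if (is.null(ids)) ids <- paste0("read", seq_along(rs))
    k <- min(params@wordSize, params@minOverlap)

    cur <- as.character(seed@seq)
    depth <- seed@depth
    members <- seed@memberReads
    iter <- 0L
    repeat {
        iter <- iter + 1L
        map <- .C_map_reads(rs, cur, k, params@minOverlap,
                            params@minIdentityExtend, 4L)
        if (nrow(map) == 0L) { depth <- depth; break }
        L <- nchar(cur)
        offs <- as.integer(map[, "offset"])
        rlens <- nchar(rs)[map[, "read"]]
        lo <- min(1L, min(offs) + 1L)
        hi <- max(L, max(offs + rlens))
        width <- hi - lo + 1L
        ## C-level pileup: column of read base 1 (0-based) = offset - (lo - 1)
        votes <- .C_pileup(rs[map[, "read"]],
                           as.integer(map[, "strand"]), offs, lo - 1L, width)
        c0 <- 1L - lo  # columns c0+1 .. c0+L are the current contig
        coldepth <- colSums(votes)
        ## overhang acceptance: keep columns with depth >= 2; where a flank
        ## has only single-read support, accept depth 1 (documented knob)
        accept_flank <- function(idx_seq) {
            d <- coldepth[idx_seq]
            if (!length(idx_seq)) return(integer(0))
            if (any(d >= 2L)) {
                keep <- d >= 2L
                ## contiguous run adjacent to the contig only
                run <- cumprod(keep) > 0
                idx_seq[run]
            } else idx_seq[cumprod(d >= 1L) > 0]
        }
        left_idx <- if (c0 >= 1L) accept_flank(rev(seq_len(c0))) else integer(0)
        right_idx <- if (c0 + L < width)
            accept_flank((c0 + L + 1L):width) else integer(0)
        keep_cols <- sort(c(left_idx, (c0 + 1L):(c0 + L), right_idx))
        prefer <- rep(NA_character_, width)
        prefer[(c0 + 1L):(c0 + L)] <- strsplit(cur, "")[[1L]]
        consensus_cols <- .consensus(votes[, keep_cols, drop = FALSE],
                                     prefer[keep_cols])
        newseq <- paste(consensus_cols, collapse = "")
        depth <- pmax(1L, as.integer(coldepth[keep_cols]))
        members <- unique(c(members, ids[map[, "read"]]))
        grown <- nchar(newseq) > nchar(cur)
        cur <- newseq
        tr <- .C_terminal_repeat(cur, params@minTerminalRepeat,
                                 params@repeatMaxMismatch)
        if (tr > 0L || !grown || iter >= params@maxIterations) break
    }
    if (length(depth) != nchar(cur)) depth <- rep(1L, nchar(cur))
    new("Contig", id = seed@id, seq = DNAString(cur), depth = depth,
        memberReads = members, circular = FALSE, terminalRepeatLen = 0L,
        iterations = iter)
}

## ---- circularization ---------------------------------------------------------

#' Detect and collapse a terminal direct repeat
#'
#' A linear assembly of a circular genome carries an identical sequence at
#' both ends.  This finds the longest prefix of the contig equal to one of
#' its suffixes (exact by default; a mismatch-tolerant mode is available via
#' \code{params@repeatMaxMismatch}), and if its length reaches
#' \code{minTerminalRepeat} collapses one copy, marks the contig circular
#' and records the repeat length.  The reported circular length is the
#' original length minus the repeat.
#'
#' @param contig a [Contig-class] (linear).
#' @param params an [AssemblyParams-class].
#' @return The (possibly collapsed) [Contig-class].
#' @examples
#' s <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
#' ctg <- new("Contig", id = "c", seq = Biostrings::DNAString(
#'     paste0(s, substr(s, 1, 189))), depth = rep(1L, 689),
#'     memberReads = character(0), circular = FALSE,
#'     terminalRepeatLen = 0L, iterations = 0L)
#' terminalRepeatLen(detectTerminalRepeat(ctg)) # 189
#' @export
detectTerminalRepeat <- function(contig, params = AssemblyParams()) {
    stopifnot(is(contig, "Contig"))
    if (contig@circular) stop("contig is already circular")
    s <- as.character(contig@seq)
    L <- nchar(s)
    tr <- .C_terminal_repeat(s, params@minTerminalRepeat,
                             params@repeatMaxMismatch)
    if (tr == 0L) return(contig)
    if (tr >= L) stop("degenerate: terminal repeat spans the whole contig")
    keep <- L - tr
    depth <- contig@depth[seq_len(keep)]
    ## depth of the collapsed copy folds onto the retained prefix
    depth[seq_len(tr)] <- depth[seq_len(tr)] +
        contig@depth[(keep + 1L):L]
    new("Contig", id = contig@id, seq = DNAString(substr(s, 1L, keep)),
        depth = pmax(1L, as.integer(depth)), memberReads = contig@memberReads,
        circular = TRUE, terminalRepeatLen = as.integer(tr),
        iterations = contig@iterations)
}

#' Rotate a circular contig to a canonical origin
#'
#' Rotates the sequence so that position 1 is the first base of the start
#' codon of the longest forward-strand ORF (the convention under which the
#' study genome's ORF1 starts at position 1).
#'
#' @param contig a circular [Contig-class].
#' @param orfParams an [ORFParams-class] used to locate ORFs.
#' @return The rotated [Contig-class].
#' @export
rotateCircular <- function(contig, orfParams = ORFParams()) {
    stopifnot(is(contig, "Contig"))
    if (!contig@circular) return(contig)
    orfs <- predictOrfs(contig, orfParams)
    fwd <- orfs[orfs$strand == "+", , drop = FALSE]
    if (!nrow(fwd)) return(contig)
    rot <- fwd$start[which.max(fwd$nt_len)]
    if (rot == 1L) return(contig)
    s <- as.character(contig@seq)
    L <- nchar(s)
    news <- paste0(substr(s, rot, L), substr(s, 1L, rot - 1L))
    newd <- contig@depth[c(rot:L, seq_len(rot - 1L))]
    new("Contig", id = contig@id, seq = DNAString(news), depth = newd,
        memberReads = contig@memberReads, circular = TRUE,
        terminalRepeatLen = contig@terminalRepeatLen,
        iterations = contig@iterations)
}

#' Per-contig assembly report
#'
#' @param contigs list of [Contig-class] objects.
#' @return data.frame with contig id, length, mean depth, circularity,
#'   terminal repeat length and extension iterations (the shape of the
#'   study's contig table).
#' @export
assemblyReport <- function(contigs) {
    if (is(contigs, "Contig")) contigs <- list(contigs)
    do.call(rbind, lapply(contigs, function(x)
        data.frame(contig = x@id, length_bp = length(x@seq),
                   mean_depth = round(mean(x@depth), 2),
                   n_reads = length(x@memberReads),
                   circular = x@circular,
                   terminal_repeat_bp = x@terminalRepeatLen,
                   iterations = x@iterations)))
}

#' Write contigs as FASTA with a depth sidecar TSV
#'
#' @param contigs list of [Contig-class] objects.
#' @param prefix output path prefix (writes \code{<prefix>.fasta} and
#'   \code{<prefix>_depth.tsv}).
#' @return Invisibly, the two paths.
#' @export
writeContigs <- function(contigs, prefix) {
    if (is(contigs, "Contig")) contigs <- list(contigs)
    seqs <- DNAStringSet(vapply(contigs, function(x) as.character(x@seq), ""))
    names(seqs) <- vapply(contigs, function(x) x@id, "")
    fa <- paste0(prefix, ".fasta")
    writeXStringSet(seqs, fa, width = 70L)
    depth <- do.call(rbind, lapply(contigs, function(x)
        data.frame(contig = x@id, pos = seq_along(x@depth),
                   depth = x@depth)))
    tsv <- paste0(prefix, "_depth.tsv")
    write.table(depth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fasta = fa, depth = tsv))
}
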