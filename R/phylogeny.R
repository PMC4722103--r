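#' Concatenate marker proteins across taxa
#'
#' Builds the concatenated marker supermatrix used for virophage phylogeny
#' (fixed marker order ATPase, PRO, MCP by default).  Each marker block is
#' aligned separately with [alignProteins()] and taxa missing a marker are
#' gap-filled over that block's aligned width; block boundaries are recorded
#' so each marker can be sliced back out.  Taxa with no marker at all are
#' excluded with a warning.
#'
#' @param markers named list of \code{AAStringSet}s, one per marker, each
#'   named by taxon.
#' @param order character vector fixing the marker order.
#' @param align align each block (default); with \code{align = FALSE} the
#'   raw sequences are concatenated (all markers must then be present for
#'   every taxon).
#' @return An \code{AAStringSet} (aligned rows when \code{align = TRUE})
#'   with a \code{"blocks"} attribute data.frame (\code{marker, start,
#'   end}).
#' @examples
#' m <- list(ATPase = Biostrings::AAStringSet(c(a = "MKL", b = "MKI")),
#'           MCP = Biostrings::AAStringSet(c(a = "MAAY", b = "MAAW")))
#' concatMarkers(m, order = c("ATPase", "MCP"))
#' @export
concatMarkers <- function(markers, order = c("ATPase", "PRO", "MCP"),
                          align = TRUE) {
    order <- order[order %in% names(markers)]
    if (!length(order)) stop("no requested marker present")
    markers <- markers[order]
    taxa <- unique(unlist(lapply(markers, names)))
    if (is.null(taxa) || !length(taxa)) stop("markers carry no taxon names")
    n_markers <- vapply(taxa, function(t)
        sum(vapply(markers, function(m) t %in% names(m), TRUE)), 1L)
    if (any(n_markers == 0L)) {
        warning("excluding taxa without any marker: ",
                paste(taxa[n_markers == 0L], collapse = ", "))
        taxa <- taxa[n_markers > 0L]
    }
    blocks <- list()
    rows <- setNames(rep("", length(taxa)), taxa)
    pos <- 0L
    for (mk in order) {
        m <- markers[[mk]]
        present <- intersect(taxa, names(m))
        if (!align && length(present) < length(taxa))
            stop("align = FALSE requires every marker for every taxon")
        seqs <- as.character(m[present])
        aln <- if (align && length(seqs) > 1L)
            as.character(alignProteins(seqs)) else seqs
        w <- if (length(aln)) nchar(aln[[1L]]) else 0L
        fill <- strrep("-", w)
        for (t in taxa)
            rows[t] <- paste0(rows[t],
                              if (t %in% present) aln[[t]] else fill)
        blocks[[length(blocks) + 1L]] <-
            data.frame(marker = mk, start = pos + 1L, end = pos + w)
        pos <- pos + w
    }
    out <- AAStringSet(rows)
    attr(out, "blocks") <- do.call(rbind, blocks)
    out
}

#' Center-star progressive multiple alignment
#'
#' Deterministic progressive protein alignment: the center sequence is the
#' one maximizing the summed pairwise global alignment score (BLOSUM62,
#' affine gaps) against all others; every other sequence is aligned to the
#' center and the pairwise alignments are merged under the
#' "once a gap, always a gap" rule.  A self-contained stand-in for a full
#' progressive aligner, adequate for conserved marker proteins.
#'
#' @param seqs \code{AAStringSet} or named character vector (>= 1).
#' @param gapOpen,gapExtend affine gap penalties.
#' @return \code{AAStringSet} of equal-width aligned rows, in input order;
#'   removing the gaps of a row recovers its input.
#' @examples
#' alignProteins(c(a = "MKLV", b = "MKV"))
#' @export
alignProteins <- function(seqs, gapOpen = 11, gapExtend = 1) {
    nm <- names(seqs)           # as.character() drops names of plain vectors
    s <- as.character(seqs)
    if (any(nchar(s) == 0L)) stop("empty sequence")
    if (is.null(nm)) nm <- paste0("seq", seq_along(s))
    names(s) <- nm
    if (length(s) == 1L) return(AAStringSet(s))
    mat <- .load_matrix("BLOSUM62")
    pa <- function(a, b)
        Biostrings::pairwiseAlignment(AAString(a), AAString(b),
                                      type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExtend)
    n <- length(s)
    ## center = max total pairwise score (first index on ties)
    tot <- numeric(n)
    score_cache <- list()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        sc <- Biostrings::score(pa(s[[i]], s[[j]]))
        tot[i] <- tot[i] + sc
        tot[j] <- tot[j] + sc
    }
    c_idx <- which.max(tot)
    others <- setdiff(seq_len(n), c_idx)
    master <- strsplit(s[[c_idx]], "")[[1L]]     # center row, with gaps
    rows <- list(master)
    row_order <- c_idx
    for (o in others) {
        aln <- pa(s[[c_idx]], s[[o]])
        c_aln <- strsplit(as.character(Biostrings::alignedPattern(aln)),
                          "")[[1L]]
        o_aln <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                          "")[[1L]]
        merged <- .merge_star(rows, master, c_aln, o_aln)
        rows <- merged$rows
        master <- merged$master
        row_order <- c(row_order, o)
    }
    out <- vapply(rows, paste, "", collapse = "")
    names(out) <- nm[row_order]
    AAStringSet(out[nm])
}

## merge a new center/other pairwise alignment into the running MSA; master
## and c_aln contain the same center residues, with different gap patterns
.merge_star <- function(rows, master, c_aln, o_aln) {
    mi <- 1L; ci <- 1L
    lm <- length(master); lc <- length(c_aln)
    new_rows <- lapply(rows, function(x) character(0))
    new_master <- character(0)
    new_o <- character(0)
    emit <- function(take_master, take_new) {
        if (take_master) {
            for (r in seq_along(rows))
                new_rows[[r]][length(new_master) + 1L] <<- rows[[r]][mi]
            new_master[length(new_master) + 1L] <<- master[mi]
        } else {
            for (r in seq_along(rows))
                new_rows[[r]][length(new_master) + 1L] <<- "-"
            new_master[length(new_master) + 1L] <<- "-"
        }
        new_o[length(new_master)] <<- if (take_new) o_aln[ci] else "-"
    }
    while (mi <= lm || ci <= lc) {
        a <- if (mi <= lm) master[mi] else NULL
        b <- if (ci <= lc) c_aln[ci] else NULL
        if (!is.null(a) && a == "-") {
            ## extra master gap column from an earlier merge
            emit(TRUE, FALSE); mi <- mi + 1L
        } else if (!is.null(b) && b == "-") {
            ## new-sequence insertion relative to the center
            emit(FALSE, TRUE); ci <- ci + 1L
        } else if (!is.null(a) && !is.null(b)) {
            emit(TRUE, TRUE); mi <- mi + 1L; ci <- ci + 1L
        } else if (!is.null(a)) {
            emit(TRUE, FALSE); mi <- mi + 1L
        } else {
            emit(FALSE, TRUE); ci <- ci + 1L
        }
    }
    rows <- c(lapply(new_rows, identity), list(new_o))
    list(rows = rows, master = new_master)
}

#' Pairwise distances from a protein alignment
#'
#' Pairwise-deletion p-distance (mismatching fraction over columns where
#' both rows are ungapped), optionally Poisson-corrected
#' (\eqn{-\ln(1 - p)}).
#'
#' @param msa \code{AAStringSet} of equal-width aligned rows.
#' @param model \code{"p"} or \code{"poisson"}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @examples
#' proteinDistances(Biostrings::AAStringSet(c(a = "AAAA", b = "AAAT")))
#' @export
proteinDistances <- function(msa, model = c("p", "poisson")) {
    model <- match.arg(model)
    s <- as.character(msa)
    if (length(s) < 2L) stop("need at least two rows")
    if (length(unique(nchar(s))) != 1L) stop("rows must have equal width")
    nm <- names(s)
    if (is.null(nm)) nm <- paste0("t", seq_along(s))
    chars <- lapply(s, function(x) strsplit(x, "")[[1L]])
    n <- length(s)
    d <- matrix(0, n, n, dimnames = list(nm, nm))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        a <- chars[[i]]; b <- chars[[j]]
        ok <- a != "-" & b != "-"
        p <- if (any(ok)) mean(a[ok] != b[ok]) else NA_real_
        if (model == "poisson") {
            if (!is.na(p) && p >= 1)
                stop("p-distance >= 1: Poisson correction undefined")
            p <- -log(1 - p)
        }
        d[i, j] <- d[j, i] <- p
    }
    if (any(is.na(d))) {
        warning("pairs without shared ungapped columns; ",
                "distance set to the maximum observed")
        d[is.na(d)] <- max(d, na.rm = TRUE)
    }
    d
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining on a symmetric distance matrix, with
#' deterministic tie-breaking by taxon order.  Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch.  Triangle
#' inequality violations are reported as a warning, never an error.
#'
#' @param d symmetric numeric matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted \code{ape::phylo} tree.
#' @examples
#' d <- matrix(c(0,2,4,4, 2,0,4,4, 4,4,0,2, 4,4,2,0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' njTree(d)
#' @export
njTree <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (n < 3L) stop("need at least 3 taxa")
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
        stop("distance matrix must be symmetric")
    taxa <- rownames(d)
    if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
    .check_triangle(d, taxa)

    active <- seq_len(n)              # node ids currently joinable
    node_id <- seq_len(n)             # phylo ids of active nodes
    next_internal <- n + 1L
    edges <- matrix(0L, 0L, 2L)
    lens <- numeric(0)
    D <- d
    while (length(active) > 3L) {
        r <- length(active)
        R <- rowSums(D)
        ## Q criterion; scan in fixed order for deterministic ties
        best <- NULL
        for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
            q <- (r - 2) * D[i, j] - R[i] - R[j]
            if (is.null(best) || q < best$q - 1e-12)
                best <- list(q = q, i = i, j = j)
        }
        i <- best$i; j <- best$j
        li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
        lj <- D[i, j] - li
        if (li < 0) { lj <- lj + li; li <- 0 }
        if (lj < 0) { li <- li + lj; lj <- 0 }
        li <- max(0, li); lj <- max(0, lj)
        u <- next_internal; next_internal <- next_internal + 1L
        edges <- rbind(edges, c(u, node_id[i]), c(u, node_id[j]))
        lens <- c(lens, li, lj)
        newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(r), c(i, j))
        D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                   c(newd[keep], 0))
        node_id <- c(node_id[keep], u)
        active <- seq_len(r - 1L)
    }
    ## final star over the last three nodes
    D3 <- D; u <- next_internal
    l1 <- max(0, (D3[1, 2] + D3[1, 3] - D3[2, 3]) / 2)
    l2 <- max(0, (D3[1, 2] + D3[2, 3] - D3[1, 3]) / 2)
    l3 <- max(0, (D3[1, 3] + D3[2, 3] - D3[1, 2]) / 2)
    edges <- rbind(edges, c(u, node_id[1]), c(u, node_id[2]),
                   c(u, node_id[3]))
    lens <- c(lens, l1, l2, l3)
    n_internal <- u - n
    ## phylo convention expects the (virtual) root first among internal
    ## ids; remap so the final star node becomes n+1
    remap <- integer(u)
    remap[seq_len(n)] <- seq_len(n)
    olds <- c(u, setdiff((n + 1L):u, u))
    news <- (n + 1L):u
    remap[olds] <- news
    edges2 <- matrix(remap[edges], ncol = 2L)
    tr <- list(edge = edges2, edge.length = lens, tip.label = taxa,
               Nnode = n_internal)
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    tr
}

.check_triangle <- function(d, taxa) {
    n <- nrow(d)
    if (n > 30L) return(invisible())
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
        if (d[i, j] > d[i, k] + d[k, j] + 1e-9) {
            warning("triangle inequality violated (", taxa[i], ", ",
                    taxa[j], ", ", taxa[k], ")")
            return(invisible())
        }
    }
    invisible()
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement \code{n} times (seed-deterministic), rebuilds a
#' tree per replicate and attaches to each internal node the percentage of
#' replicates containing the corresponding bipartition (the study used 100
#' iterations).
#'
#' @param msa \code{AAStringSet} of aligned rows (>= 4 taxa).
#' @param n bootstrap replicates.
#' @param seed integer seed.
#' @param model distance model passed to [proteinDistances()].
#' @return An \code{ape::phylo} with \code{node.label} holding supports
#'   (0-100; the root label is empty).
#' @export
bootstrapTree <- function(msa, n = 100L, seed = 1L, model = "p") {
    if (n < 1L) stop("n must be >= 1")
    s <- as.character(msa)
    if (length(s) < 4L) stop("need at least 4 taxa")
    w <- nchar(s[[1L]])
    chars <- do.call(rbind, strsplit(s, ""))
    rownames(chars) <- names(s)
    ref <- njTree(proteinDistances(msa, model))
    set.seed(as.integer(seed))
    boots <- vector("list", n)
    for (b in seq_len(n)) {
        cols <- sample.int(w, w, replace = TRUE)
        rep_msa <- AAStringSet(apply(chars[, cols, drop = FALSE], 1L,
                                     paste, collapse = ""))
        boots[[b]] <- suppressWarnings(
            njTree(proteinDistances(rep_msa, model)))
    }
    counts <- ape::prop.clades(ref, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    supports <- round(100 * counts / n)
    supports[1L] <- NA  # root of an unrooted tree carries no bipartition
    ref$node.label <- ifelse(is.na(supports), "", as.character(supports))
    ref
}

#' Bootstrap support of one clade
#'
#' Supports are attached to bipartitions, so on an unrooted tree the clade
#' is located either as a node whose descendant tips equal \code{tips} or
#' as one whose descendants are exactly the complement.
#'
#' @param tree a tree from [bootstrapTree()].
#' @param tips tip labels of the clade of interest.
#' @return Support (0-100), or NA when the tree has no such bipartition.
#' @export
cladeSupport <- function(tree, tips) {
    if (is.null(tree$node.label)) return(NA_real_)
    n <- length(tree$tip.label)
    idx <- match(tips, tree$tip.label)
    if (anyNA(idx)) return(NA_real_)
    comp <- setdiff(seq_len(n), idx)
    for (node in (n + 1L):(n + tree$Nnode)) {
        desc <- .tips_under(tree, node)
        if (setequal(desc, idx) || setequal(desc, comp)) {
            lab <- tree$node.label[node - n]
            return(if (nzchar(lab)) as.numeric(lab) else NA_real_)
        }
    }
    NA_real_
}

.tips_under <- function(tree, node) {
    n <- length(tree$tip.label)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    out <- integer(0)
    for (k in kids)
        out <- c(out, if (k <= n) k else .tips_under(tree, k))
    out
}
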