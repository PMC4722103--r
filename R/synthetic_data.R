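#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement subseq translate QualityScaledDNAStringSet
#'   PhredQuality writeXStringSet readDNAStringSet readAAStringSet
#'   writeQualityScaledXStringSet readQualityScaledDNAStringSet quality
#'   matchPattern vcountPattern
#' @importFrom IRanges IntegerList
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

## letter sampling probabilities for a target G+C fraction
.gc_probs <- function(gc) {
    at <- (1 - gc) / 2
    c(A = at, C = gc / 2, G = gc / 2, T = at)
}

## Expected G+C of a stop-free random codon when letters are drawn with
## per-letter G+C rate g.  Stop codons (TAA/TAG/TGA) are AT-rich, so
## rejecting them raises the realized G+C above g.
.codon_gc_expect <- function(g) {
    p <- .gc_probs(g)
    pstop <- p["T"] * p["A"] * p["A"] + p["T"] * p["A"] * p["G"] +
        p["T"] * p["G"] * p["A"]
    ## expected G+C letter fraction contributed by stop codons
    ## (TAA carries 0, TAG and TGA carry 1 of 3 letters)
    gc_stop_frac <- (p["T"] * p["A"] * p["G"] +
                     p["T"] * p["G"] * p["A"]) / 3
    unname((g - gc_stop_frac) / (1 - pstop))
}

.sample_bases <- function(n, gc) {
    if (n <= 0L) return(character(0))
    sample(BASES, n, replace = TRUE, prob = .gc_probs(gc))
}

## shuffled fixed-composition draw: exactly round(n * gc) G+C letters
.sample_bases_exact <- function(n, gc) {
    if (n <= 0L) return(character(0))
    ngc <- round(n * gc)
    g <- ngc %/% 2L; cc <- ngc - g
    a <- (n - ngc) %/% 2L; t <- n - ngc - a
    sample(c(rep("G", g), rep("C", cc), rep("A", a), rep("T", t)))
}

## n random sense codons, no stops, at the stop-rejection-corrected G+C
.sample_codons <- function(n, gc_body) {
    out <- character(0)
    while (length(out) < n) {
        need <- n - length(out)
        cand <- matrix(.sample_bases(3L * ceiling(need * 1.1 + 10), gc_body),
                       nrow = 3L)
        cod <- apply(cand, 2L, paste, collapse = "")
        out <- c(out, cod[!cod %in% STOP_CODONS])
    }
    out[seq_len(n)]
}

#' Generate a virophage-like genome with planted ORFs
#'
#' Draws an i.i.d. background at the target G+C and plants
#' \code{nOrfs} ORF cassettes (ATG, stop-free codon body, stop codon) on both
#' strands at rejection-sampled non-overlapping positions.  Each cassette is
#' preceded, in its own reading direction, by an in-frame stop codon so that
#' the planted ATG is the first ATG of its stop-to-stop interval -- this
#' guarantees that [predictOrfs()] recovers every planted ORF at its exact
#' coordinates.  Codon bodies are sampled at a G+C rate corrected for
#' stop-codon rejection so the realized composition matches
#' \code{gcTarget}.
#'
#' @param cfg a [SimulationConfig-class].
#' @return A [VirophageGenome-class] whose \code{truthFeatures} records the
#'   planted ORFs in the strand-aware convention of [predictOrfs()]
#'   (start > end on the reverse strand).
#' @examples
#' g <- generateGenome(SimulationConfig(genomeLength = 3000L, nOrfs = 3L,
#'                                      nReadPairs = 10L, seed = 42L))
#' g
#' truthFeatures(g)
#' @export
generateGenome <- function(cfg) {
    stopifnot(is(cfg, "SimulationConfig"))
    validObject(cfg)
    L <- cfg@genomeLength
    if (cfg@nOrfs * 150L > L)
        stop("impossible packing: nOrfs * 150 exceeds genomeLength")
    set.seed(cfg@seed)
    ## exact-composition background keeps the realized G+C tight around the
    ## target; planted codon bodies add the only sampling noise
    genome <- .sample_bases_exact(L, cfg@gcTarget)

    ## ORF lengths shaped like a gene-dense small viral genome
    aa_len <- pmin(900L, pmax(50L, round(exp(rnorm(cfg@nOrfs,
                                                   log(180), 0.6)))))
    ## cassette = guard stop + ATG + body (aa-1 codons) + stop = 3(aa+2) nt
    repeat {
        cass_len <- 3L * (aa_len + 2L)
        if (sum(cass_len) <= floor(0.95 * L) || all(aa_len <= 50L)) break
        aa_len <- pmax(50L, as.integer(floor(aa_len * 0.9)))
    }
    cass_len <- 3L * (aa_len + 2L)

    ## body letter rate solved so the whole-genome expectation hits the
    ## target: the fixed cassette codons (ATG and two stops, 9 nt carrying
    ## 7/3 expected G+C letters) are AT-rich and must be compensated
    n_orf <- cfg@nOrfs
    body_letters <- sum(3L * (aa_len - 1L))
    gc_body <- if (n_orf > 0L && body_letters > 0L) {
        target_body <- (cfg@gcTarget * (body_letters + 9 * n_orf) -
                        n_orf * 7 / 3) / body_letters
        target_body <- min(0.99, max(0.01, target_body))
        uniroot(function(g) .codon_gc_expect(g) - target_body,
                c(1e-6, 1 - 1e-6), tol = 1e-9)$root
    } else cfg@gcTarget

    occupied <- rep(FALSE, L)
    feats <- vector("list", cfg@nOrfs)
    ## place longest cassettes first: rejection sampling then fails far
    ## less often from fragmentation of the remaining free space
    for (i in order(-cass_len)) {
        len <- cass_len[i]
        placed <- FALSE
        for (try in seq_len(5000L)) {
            pos <- sample.int(L - len + 1L, 1L)
            if (any(occupied[pos:(pos + len - 1L)])) next
            strand <- sample(c("+", "-"), 1L)
            body <- .sample_codons(aa_len[i] - 1L, gc_body)
            stopc <- sample(STOP_CODONS, 1L)
            guard <- sample(STOP_CODONS, 1L)
            cassette <- paste0(guard, "ATG", paste(body, collapse = ""),
                               stopc)
            if (strand == "-")
                cassette <- as.character(
                    reverseComplement(DNAString(cassette)))
            genome[pos:(pos + len - 1L)] <- strsplit(cassette, "")[[1L]]
            occupied[pos:(pos + len - 1L)] <- TRUE
            ## ORF coordinates exclude the guard stop
            if (strand == "+") {
                s <- pos + 3L; e <- pos + len - 1L
            } else {
                s <- pos + len - 4L; e <- pos
            }
            feats[[i]] <- data.frame(start = s, end = e, strand = strand,
                                     nt_len = len - 3L)
            placed <- TRUE
            break
        }
        if (!placed)
            stop("could not place ORF ", i,
                 ": genome too densely packed for nOrfs = ", cfg@nOrfs)
    }
    tf <- do.call(rbind, feats)
    if (is.null(tf)) {
        tf <- data.frame(start = integer(0), end = integer(0),
                         strand = character(0), nt_len = integer(0))
    } else {
        tf <- tf[order(pmin(tf$start, tf$end)), , drop = FALSE]
        rownames(tf) <- NULL
    }
    tf <- cbind(index = seq_len(nrow(tf)), tf)
    new("VirophageGenome", id = "synthetic_genome",
        seq = DNAString(paste(genome, collapse = "")),
        circular = cfg@circular, truthFeatures = tf,
        provenance = integer(0))
}

#' Derive a diverged relative of a genome
#'
#' Applies per-site substitutions (uniform over the three alternative bases)
#' and single-base indels, recording a provenance map from every derived base
#' back to its source position (NA for insertions).  Used to create the
#' diverged bait genome that stands in for a related virophage.
#'
#' @param g a [VirophageGenome-class].
#' @param subRate substitutions per site in \[0, 1\].
#' @param indelRate single-base indel events per site (half insertions, half
#'   deletions).
#' @param seed integer seed.
#' @param id identifier of the derived sequence.
#' @return A [VirophageGenome-class] with a populated \code{provenance} slot;
#'   \code{truthFeatures} is dropped (coordinates no longer apply).
#' @examples
#' g <- generateGenome(SimulationConfig(genomeLength = 1200L, nOrfs = 2L,
#'                                      seed = 3L))
#' bait <- mutateGenome(g, subRate = 0.2, indelRate = 0, seed = 4L)
#' @export
mutateGenome <- function(g, subRate, indelRate, seed, id = "mutated") {
    stopifnot(is(g, "VirophageGenome"))
    if (subRate < 0 || subRate > 1 || indelRate < 0 || indelRate > 1)
        stop("rates must lie in [0, 1]")
    set.seed(as.integer(seed))
    src <- strsplit(as.character(g@seq), "")[[1L]]
    L <- length(src)
    out <- src
    prov <- seq_len(L)
    ## substitutions: one draw per site, always to a different base
    hit <- which(runif(L) < subRate)
    if (length(hit)) {
        for (i in hit) {
            alt <- BASES[BASES != out[i]]
            out[i] <- alt[sample.int(3L, 1L)]
        }
    }
    if (indelRate > 0) {
        ev <- runif(L)
        del <- ev < indelRate / 2
        ins <- ev >= indelRate / 2 & ev < indelRate
        pieces <- vector("list", L)
        provp <- vector("list", L)
        ins_bases <- .sample_bases(sum(ins), 0.5)
        j <- 0L
        for (i in seq_len(L)) {
            if (del[i]) next
            if (ins[i]) {
                j <- j + 1L
                pieces[[i]] <- c(out[i], ins_bases[j])
                provp[[i]] <- c(prov[i], NA_integer_)
            } else {
                pieces[[i]] <- out[i]
                provp[[i]] <- prov[i]
            }
        }
        out <- unlist(pieces)
        prov <- unlist(provp)
    }
    new("VirophageGenome", id = id,
        seq = DNAString(paste(out, collapse = "")),
        circular = g@circular,
        truthFeatures = data.frame(index = integer(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   nt_len = integer(0)),
        provenance = as.integer(prov))
}

#' Simulate paired-end reads from a genome
#'
#' Draws fragments with a truncated-normal insert-size distribution (wrapping
#' the origin for circular genomes), emits the 5' \code{readLength} bases of
#' each fragment end as the mates, injects substitution sequencing errors at
#' \code{baseErrorRate}, and assigns per-cycle Gaussian Phred qualities
#' (clipped to \[2, 41\]) around \code{qualityProfile}.  Background read
#' pairs from an unrelated i.i.d. sequence at the same G+C are appended so
#' they make up \code{backgroundFraction} of all pairs.
#'
#' @param g a [VirophageGenome-class].
#' @param cfg a [SimulationConfig-class].
#' @param background logical; append background pairs?
#' @return A [ReadSimulation-class]; \code{truth} records per read the
#'   source, fragment coordinates (possibly wrapping: \code{frag_end} may
#'   exceed the genome length), strand, mate and injected error count.
#' @examples
#' cfg <- SimulationConfig(genomeLength = 2000L, nOrfs = 2L,
#'                         nReadPairs = 50L, readLength = 100L,
#'                         insertMean = 300, seed = 5L)
#' sim <- simulateReads(generateGenome(cfg), cfg)
#' sim
#' @export
simulateReads <- function(g, cfg, background = TRUE) {
    stopifnot(is(g, "VirophageGenome"), is(cfg, "SimulationConfig"))
    validObject(cfg)
    L <- length(g@seq)
    rl <- cfg@readLength
    if (!g@circular && rl > L)
        stop("readLength exceeds the length of a linear genome")
    set.seed(cfg@seed + 1L)
    n_bg <- if (background && cfg@backgroundFraction > 0)
        as.integer(round(cfg@nReadPairs * cfg@backgroundFraction /
                         (1 - cfg@backgroundFraction))) else 0L

    gseq <- as.character(g@seq)
    bg_len <- max(L, 4L * rl)
    bgseq <- paste(.sample_bases(bg_len, cfg@gcTarget), collapse = "")

    sim_one_source <- function(seqchr, n, circular, source, id_prefix) {
        if (n == 0L)
            return(list(r1 = character(0), r2 = character(0),
                        truth = NULL))
        slen <- nchar(seqchr)
        ins <- pmax(rl, pmin(if (circular) slen else slen,
                             round(rnorm(n, cfg@insertMean, cfg@insertSd))))
        start <- if (circular) sample.int(slen, n, replace = TRUE)
            else vapply(ins, function(w) sample.int(slen - w + 1L, 1L), 1L)
        doubled <- if (circular) paste0(seqchr, seqchr) else seqchr
        frag <- substring(doubled, start, start + ins - 1L)
        r1 <- substring(frag, 1L, rl)
        frag_rc <- as.character(reverseComplement(DNAStringSet(frag)))
        r2 <- substring(frag_rc, 1L, rl)
        truth <- data.frame(
            read_id = paste0(id_prefix, seq_len(n)),
            source = source, frag_start = start,
            frag_end = start + ins - 1L,
            strand = "+", mate = 0L, n_errors = 0L,
            wraps = start + ins - 1L > slen)
        list(r1 = r1, r2 = r2, truth = truth)
    }

    gen <- sim_one_source(gseq, cfg@nReadPairs, g@circular, "genome", "gp")
    bg <- sim_one_source(bgseq, n_bg, FALSE, "background", "bp")

    r1 <- c(gen$r1, bg$r1)
    r2 <- c(gen$r2, bg$r2)
    truth <- rbind(gen$truth, bg$truth)
    n_tot <- length(r1)

    inject <- function(reads) {
        nerr <- integer(length(reads))
        if (cfg@baseErrorRate > 0 && length(reads)) {
            for (i in seq_along(reads)) {
                b <- strsplit(reads[i], "")[[1L]]
                hit <- which(runif(length(b)) < cfg@baseErrorRate)
                for (p in hit) {
                    alt <- BASES[BASES != b[p]]
                    b[p] <- alt[sample.int(3L, 1L)]
                }
                nerr[i] <- length(hit)
                if (length(hit)) reads[i] <- paste(b, collapse = "")
            }
        }
        list(reads = reads, nerr = nerr)
    }
    e1 <- inject(r1); e2 <- inject(r2)

    quals <- function(n) {
        if (n == 0L) return(IntegerList())
        q <- matrix(rnorm(n * rl, mean = rep(cfg@qualityProfile, each = n),
                          sd = 3), nrow = n)
        q[] <- pmin(41, pmax(2, round(q)))
        IntegerList(lapply(seq_len(n), function(i) as.integer(q[i, ])))
    }
    ids <- truth$read_id
    mk <- function(reads, mate) {
        x <- DNAStringSet(reads)
        names(x) <- paste0(ids, "/", mate)
        QualityScaledDNAStringSet(x, PhredQuality(quals(length(reads))))
    }
    set.seed(cfg@seed + 2L)
    s1 <- mk(e1$reads, 1L)
    s2 <- mk(e2$reads, 2L)

    t1 <- truth; t1$mate <- 1L; t1$n_errors <- e1$nerr
    t1$read_id <- paste0(ids, "/1")
    t2 <- truth; t2$mate <- 2L; t2$n_errors <- e2$nerr
    t2$read_id <- paste0(ids, "/2")
    new("ReadSimulation", r1 = s1, r2 = s2,
        truth = rbind(t1, t2)[order(rep(seq_len(n_tot), 2L),
                                    rep(1:2, each = n_tot)), ])
}

#' Write simulated data to disk
#'
#' Writes the mates as Sanger FASTQ (Phred+33), the genome as 70-column
#' FASTA, the planted ORFs as GFF3, and the full truth table as JSON.
#'
#' @param sim a [ReadSimulation-class].
#' @param g the [VirophageGenome-class] the reads were simulated from.
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, g, outdir, prefix = "sim") {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        r1 = file.path(outdir, paste0(prefix, "_R1.fastq")),
        r2 = file.path(outdir, paste0(prefix, "_R2.fastq")),
        genome = file.path(outdir, paste0(prefix, "_genome.fasta")),
        gff = file.path(outdir, paste0(prefix, "_truth.gff3")),
        truth = file.path(outdir, paste0(prefix, "_truth.json")))
    writeQualityScaledXStringSet(sim@r1, paths["r1"])
    writeQualityScaledXStringSet(sim@r2, paths["r2"])
    writeGenomeFasta(g, paths["genome"])
    writeTruthGff3(g, paths["gff"])
    jsonlite::write_json(sim@truth, paths["truth"], dataframe = "rows")
    invisible(paths)
}

#' Write a genome as wrapped FASTA
#'
#' @param g a [VirophageGenome-class] or [Contig-class].
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
writeGenomeFasta <- function(g, file) {
    s <- if (is(g, "Contig")) g@seq else g@seq
    x <- DNAStringSet(s)
    names(x) <- g@id
    writeXStringSet(x, file, width = 70L)
    invisible(file)
}

#' Write planted truth features as GFF3
#'
#' @param g a [VirophageGenome-class] with truth features.
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
writeTruthGff3 <- function(g, file) {
    tf <- g@truthFeatures
    gr <- GenomicRanges::GRanges(
        seqnames = g@id,
        ranges = IRanges::IRanges(start = pmin(tf$start, tf$end),
                                  end = pmax(tf$start, tf$end)),
        strand = tf$strand,
        type = "CDS",
        phase = 0L,
        ID = paste0("planted_orf_", tf$index))
    rtracklayer::export(gr, file, format = "gff3")
    invisible(file)
}
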