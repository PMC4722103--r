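#' Run the full virophage discovery workflow
#'
#' Executes the study's stage order on a read set: windowed QC, permissive
#' translated scan against all bait genomes (E <= 1e-5), strict best-hit
#' recruitment against the final bait (E <= 1e-10), greedy de novo assembly
#' of the recruited reads, iterative reference-guided extension of the
#' longest contig against all quality-filtered reads, terminal-direct-repeat
#' circularization, canonical rotation, ORF prediction, protein-homology
#' annotation (E <= 1e-3) and, when the protein database is organized as
#' \code{taxon|marker} entries for the ATPase/PRO/MCP markers, a
#' marker-concatenation bootstrap NJ tree including the assembled genome.
#' The run is seed-deterministic end to end; an empty stage (e.g. zero
#' recruited reads) empties the downstream sections with a warning instead
#' of failing.
#'
#' @param cfg a [PipelineConfig-class].
#' @return A [DiscoveryReport-class].
#' @seealso [makeDemo()] for a self-contained synthetic dataset.
#' @export
runDiscovery <- function(cfg) {
    stopifnot(is(cfg, "PipelineConfig"))
    set.seed(cfg@seed)
    log <- character(0)
    note <- function(...) log <<- c(log, paste0(...))

    ## stage 1: QC
    qc <- qcDataset(cfg@reads, cfg@qc)
    note("qc: ", sum(qc$stats$reads_out), "/", sum(qc$stats$reads_in),
         " reads retained")
    all_reads <- .pool_runs(qc$passed)
    empty <- .empty_report(qc$stats, cfg)
    if (length(all_reads) == 0L) {
        warning("no reads survived QC; downstream sections are empty")
        return(empty)
    }

    ## stage 2: permissive multi-genome scan
    scan_tab <- recruitReads(all_reads, cfg@baits, cfg@scan)
    scan_counts <- recruitmentCounts(scan_tab)
    note("scan: ", length(unique(scan_tab$read_id)), " reads at E<=",
         format(cfg@scan@evalueCutoff))

    ## stage 3: strict best-hit recruitment against the final bait
    bait_id <- names(cfg@baits)[length(cfg@baits)]
    if (is.null(bait_id)) bait_id <- paste0("bait", length(cfg@baits))
    recruited <- .bait_stage(scan_tab, all_reads, cfg, bait_id)
    note("bait: ", length(unique(recruited$read_id)), " reads at E<=",
         format(cfg@bait@evalueCutoff), " vs ", bait_id)
    if (!nrow(recruited)) {
        warning("no reads recruited; downstream sections are empty")
        empty@scanCounts <- scan_counts
        return(empty)
    }

    ## stage 4: de novo assembly of recruited reads
    rec_reads <- all_reads[unique(recruited$read_id)]
    contigs <- denovoAssemble(rec_reads, cfg@assembly)
    ctab <- assemblyReport(contigs)
    note("denovo: ", nrow(ctab), " contigs, ", min(ctab$length_bp), "-",
         max(ctab$length_bp), " bp")

    ## stage 5: iterative extension of the longest contig, circularization
    genome <- referenceExtend(contigs[[1L]], all_reads, cfg@assembly)
    note("extend: ", length(genome@seq), " bp after ",
         genome@iterations, " iterations")
    genome <- detectTerminalRepeat(genome, cfg@assembly)
    if (genome@circular) {
        note("circular: terminal repeat ", genome@terminalRepeatLen,
             " bp, collapsed length ", length(genome@seq))
        genome <- rotateCircular(genome, cfg@orf)
    } else note("no terminal repeat: genome kept linear")

    ## stage 6: annotation
    orfs <- predictOrfs(genome, cfg@orf)
    note("orfs: ", nrow(orfs))
    ann <- if (length(cfg@proteinDb) && nrow(orfs))
        annotateProteins(orfs, cfg@proteinDb, cfg@annotate)
    else .empty_annotation()

    ## stage 7: marker phylogeny
    tree <- NULL
    if (cfg@bootstrapN > 0L && nrow(ann) && any(!ann$orfan)) {
        ms <- .marker_set_from_db(cfg@proteinDb)
        if (!is.null(ms)) {
            ms2 <- .add_assembly_markers(ms, orfs, ann, taxon = "assembly")
            if (!is.null(ms2)) {
                msa <- concatMarkers(ms2)
                if (length(msa) >= 4L) {
                    tree <- bootstrapTree(msa, n = cfg@bootstrapN,
                                          seed = cfg@seed)
                    note("tree: ", length(tree$tip.label), " taxa, ",
                         cfg@bootstrapN, " bootstrap replicates")
                }
            }
        }
    }

    new("DiscoveryReport", qcStats = qc$stats, recruitment = recruited,
        scanCounts = scan_counts, contigTable = ctab, genome = genome,
        orfs = orfs, annotations = ann, tree = tree,
        params = .echo_params(cfg), log = log)
}

.pool_runs <- function(passed) {
    sets <- lapply(names(passed), function(rn) {
        x <- as(passed[[rn]], "DNAStringSet")
        if (length(x))
            names(x) <- paste0(rn, ":", if (is.null(names(x)))
                seq_along(x) else names(x))
        x
    })
    out <- do.call(c, sets)
    out
}

## the strict stage reuses the scan HSPs when its cutoff is nested inside
## the scan cutoff (same scoring parameters), otherwise searches afresh
.bait_stage <- function(scan_tab, all_reads, cfg, bait_id) {
    sp <- cfg@scan; bp <- cfg@bait
    same_scoring <- identical(sp@matrix, bp@matrix) &&
        sp@gapOpen == bp@gapOpen && sp@gapExtend == bp@gapExtend &&
        sp@wordSize == bp@wordSize && sp@mode == bp@mode
    if (same_scoring && bp@evalueCutoff <= sp@evalueCutoff) {
        tab <- scan_tab[scan_tab$subject_id == bait_id &
                        scan_tab$evalue <= bp@evalueCutoff, , drop = FALSE]
        if (bp@bestHitOnly && nrow(tab)) {
            tab <- tab[order(tab$evalue, -tab$score, tab$subject_id), ,
                       drop = FALSE]
            tab <- tab[!duplicated(tab$read_id), , drop = FALSE]
        }
        rownames(tab) <- NULL
        return(tab)
    }
    recruitReads(all_reads, cfg@baits[bait_id], bp)
}

.empty_annotation <- function()
    data.frame(orf_index = integer(0), subject_id = character(0),
               percent_identity = numeric(0), aln_len_aa = integer(0),
               q_start = integer(0), q_end = integer(0),
               evalue = numeric(0), orfan = logical(0))

.empty_report <- function(qcStats, cfg)
    new("DiscoveryReport", qcStats = qcStats,
        recruitment = .empty_recruitment_table(),
        scanCounts = data.frame(subject_id = character(0),
                                n_reads = integer(0)),
        contigTable = data.frame(), genome = NULL,
        orfs = .empty_orf_table(), annotations = .empty_annotation(),
        tree = NULL, params = .echo_params(cfg), log = character(0))

.echo_params <- function(cfg) {
    pl <- function(x) {
        sl <- methods::slotNames(class(x))
        setNames(lapply(sl, function(s) methods::slot(x, s)), sl)
    }
    list(qc = pl(cfg@qc), scan = pl(cfg@scan), bait = pl(cfg@bait),
         annotate = pl(cfg@annotate), assembly = pl(cfg@assembly),
         orf = pl(cfg@orf), bootstrapN = cfg@bootstrapN, seed = cfg@seed)
}

## markers from a database whose entries are named "taxon|marker"
.marker_set_from_db <- function(db) {
    nm <- names(db)
    if (is.null(nm) || !any(grepl("|", nm, fixed = TRUE))) return(NULL)
    parts <- strsplit(nm, "|", fixed = TRUE)
    taxon <- vapply(parts, `[`, "", 1L)
    marker <- vapply(parts, `[`, "", 2L)
    keep <- marker %in% c("ATPase", "PRO", "MCP")
    if (!any(keep)) return(NULL)
    out <- lapply(c("ATPase", "PRO", "MCP"), function(mk) {
        sel <- keep & marker == mk
        x <- db[sel]
        names(x) <- taxon[sel]
        x
    })
    names(out) <- c("ATPase", "PRO", "MCP")
    out[vapply(out, length, 1L) > 0L]
}

## add the assembled genome's ORFs that best-hit each marker
.add_assembly_markers <- function(ms, orfs, ann, taxon = "assembly") {
    added <- FALSE
    for (mk in names(ms)) {
        hits <- ann[!ann$orfan &
                    grepl(paste0("\\|", mk, "$"), ann$subject_id), ,
                    drop = FALSE]
        if (!nrow(hits)) next
        best <- hits[order(hits$evalue), , drop = FALSE][1L, ]
        prot <- orfs$protein[match(best$orf_index, orfs$index)]
        ms[[mk]] <- c(ms[[mk]], setNames(AAStringSet(prot), taxon))
        added <- TRUE
    }
    if (!added) return(NULL)
    ms
}

#' Generate a self-contained synthetic demo dataset
#'
#' Writes a complete small study to \code{outdir}: a circular 20 kb
#' virophage-like genome with 20 planted ORFs, a bait relative diverged at
#' 0.3 substitutions per site, roughly 40x paired 2 x 251 bp read coverage
#' plus 25% background pairs, a \code{taxon|marker} protein database of
#' diverged relatives for annotation and phylogeny, primer sets, the truth
#' files and a JSON configuration echo.  Every stage of [runDiscovery()] is
#' exercised by this dataset.
#'
#' @param outdir output directory.
#' @param seed integer seed; fixed seed, identical bytes.
#' @return Invisibly, a list with \code{cfg} (the [PipelineConfig-class]),
#'   \code{simCfg}, \code{genome} (truth), \code{bait} and the written
#'   \code{paths}.
#' @export
makeDemo <- function(outdir, seed = 1L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    simCfg <- SimulationConfig(genomeLength = 20000L, nOrfs = 20L,
                               subRate = 0.30, indelRate = 0.001,
                               nReadPairs = 1600L, seed = seed)
    genome <- generateGenome(simCfg)
    bait <- mutateGenome(genome, simCfg@subRate, simCfg@indelRate,
                         seed = seed + 10L, id = "bait_relative")
    sim <- simulateReads(genome, simCfg)
    paths <- writeSimulation(sim, genome, outdir, prefix = "demo")
    bait_path <- file.path(outdir, "demo_bait.fasta")
    writeGenomeFasta(bait, bait_path)

    db <- .demo_protein_db(genome, seed = seed + 20L)
    db_path <- file.path(outdir, "demo_proteins.faa")
    writeXStringSet(db, db_path, width = 70L)

    primers <- virophagePrimers("mcp")
    primer_path <- file.path(outdir, "demo_primers.tsv")
    write.table(primers, primer_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    baits <- DNAStringSet(setNames(as.character(bait@seq), bait@id))
    cfg <- PipelineConfig(
        reads = list(run1 = c(sim@r1, sim@r2)),
        baits = baits, proteinDb = db, seed = seed)
    cfg_path <- file.path(outdir, "demo_config.json")
    jsonlite::write_json(
        list(reads = unname(paths[c("r1", "r2")]), baits = bait_path,
             protein_db = db_path, primers = primer_path,
             cutoffs = list(scan = 1e-5, bait = 1e-10, annotate = 1e-3),
             seed = seed),
        cfg_path, auto_unbox = TRUE)
    invisible(list(cfg = cfg, simCfg = simCfg, genome = genome,
                   bait = bait,
                   paths = c(paths, bait = bait_path, db = db_path,
                             primers = primer_path, config = cfg_path)))
}

## protein database of diverged pseudo-relatives: every planted ORF of the
## truth genome, mutated at the protein level per taxon; the three longest
## ORFs double as the ATPase/PRO/MCP markers
.demo_protein_db <- function(genome, seed = 21L,
                             taxa = c(close_relative = 0.35,
                                      relative_b = 0.5,
                                      relative_c = 0.6,
                                      outgroup = 0.7)) {
    set.seed(as.integer(seed))
    tf <- truthFeatures(genome)
    s <- as.character(genomeSeq(genome))
    L <- nchar(s)
    prots <- vapply(seq_len(nrow(tf)), function(i)
        .translate_span(s, tf$start[i], tf$end[i], tf$strand[i], L), "")
    marker_idx <- order(-tf$nt_len)[1:3]
    marker_names <- c("ATPase", "PRO", "MCP")
    aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    entries <- character(0)
    for (t in names(taxa)) {
        q <- taxa[[t]]
        for (i in seq_len(nrow(tf))) {
            p <- strsplit(prots[i], "")[[1L]]
            hit <- which(runif(length(p)) < q)
            for (h in hit) {
                alt <- aa_letters[aa_letters != p[h]]
                p[h] <- alt[sample.int(length(alt), 1L)]
            }
            nm <- if (i %in% marker_idx)
                paste0(t, "|", marker_names[match(i, marker_idx)])
            else paste0(t, "|orf", i)
            entries[nm] <- paste(p, collapse = "")
        }
    }
    AAStringSet(entries)
}

#' Write a discovery report to disk
#'
#' Writes the report as machine-readable JSON plus a short human-readable
#' text summary, and the genome/ORF artifacts alongside.
#'
#' @param report a [DiscoveryReport-class].
#' @param outdir output directory.
#' @return Invisibly, the named vector of written paths.
#' @export
writeReport <- function(report, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(json = file.path(outdir, "report.json"),
               txt = file.path(outdir, "report.txt"))
    genome_stats <- if (!is.null(report@genome)) list(
        length_bp = length(report@genome@seq),
        circular = report@genome@circular,
        terminal_repeat_bp = report@genome@terminalRepeatLen,
        gc_percent = 100 * gcContent(report@genome),
        mean_depth = mean(report@genome@depth)) else NULL
    jsonlite::write_json(list(
        qc = report@qcStats, scan_counts = report@scanCounts,
        n_recruited = length(unique(report@recruitment$read_id)),
        contigs = report@contigTable, genome = genome_stats,
        orfs = report@orfs[, setdiff(names(report@orfs), "protein")],
        annotations = report@annotations,
        tree_newick = if (!is.null(report@tree))
            ape::write.tree(report@tree) else NULL,
        params = report@params, log = report@log),
        paths["json"], auto_unbox = TRUE, digits = NA, null = "null")
    txt <- utils::capture.output(show(report))
    writeLines(c(txt, "", report@log), paths["txt"])
    if (!is.null(report@genome))
        writeContigs(report@genome, file.path(outdir, "genome"))
    if (nrow(report@orfs))
        writeOrfs(report@orfs,
                  if (!is.null(report@genome)) report@genome@id else "genome",
                  file.path(outdir, "orfs"))
    if (!is.null(report@tree))
        ape::write.tree(report@tree, file.path(outdir, "markers.nwk"))
    invisible(paths)
}
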