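#' Simulation settings for the synthetic metagenome generator
#'
#' Bundles every knob of the synthetic study: the virophage-like genome to
#' emulate, the divergence of the bait relative, the sequencing library
#' geometry and error model, and the unrelated background fraction.  Defaults
#' mirror the Dishui Lake virophage DSLV1 (28,788 bp circular genome at 43.2%
#' G+C with 28 ORFs) sequenced as 2 x 251 bp MiSeq pairs from a 430 bp insert
#' library.
#'
#' @slot genomeLength integer, genome size in bp.
#' @slot gcTarget target G+C fraction in \[0, 1\].
#' @slot nOrfs number of ORFs planted in the genome.
#' @slot subRate substitutions per site used when deriving the diverged bait.
#' @slot indelRate single-base indel events per site for the bait.
#' @slot nReadPairs number of read pairs drawn from the genome.
#' @slot readLength read length in bp (2 x 251 geometry by default).
#' @slot insertMean,insertSd fragment (insert) length distribution in bp.
#' @slot baseErrorRate per-base substitution sequencing-error rate.
#' @slot qualityProfile numeric vector of per-cycle mean Phred scores,
#'   length \code{readLength}.
#' @slot backgroundFraction fraction of all read pairs drawn from an
#'   unrelated background sequence of the same G+C.
#' @slot circular logical, whether the genome is circular.
#' @slot seed integer seed; identical configs and seeds give byte-identical
#'   output.
#'
#' @seealso [SimulationConfig()] for the user constructor.
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
    genomeLength = "integer",
    gcTarget = "numeric",
    nOrfs = "integer",
    subRate = "numeric",
    indelRate = "numeric",
    nReadPairs = "integer",
    readLength = "integer",
    insertMean = "numeric",
    insertSd = "numeric",
    baseErrorRate = "numeric",
    qualityProfile = "numeric",
    backgroundFraction = "numeric",
    circular = "logical",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    rates <- c(gcTarget = object@gcTarget, subRate = object@subRate,
               indelRate = object@indelRate,
               baseErrorRate = object@baseErrorRate,
               backgroundFraction = object@backgroundFraction)
    bad <- rates < 0 | rates > 1
    if (any(bad))
        msg <- c(msg, paste0("rates must lie in [0, 1]: ",
                             paste(names(rates)[bad], collapse = ", ")))
    if (object@genomeLength < 3L * 150L)
        msg <- c(msg, "genomeLength must be >= 450 bp (3 x 150)")
    if (object@nOrfs < 0L) msg <- c(msg, "nOrfs must be >= 0")
    if (object@readLength > object@insertMean)
        msg <- c(msg, "readLength must not exceed insertMean")
    if (length(object@qualityProfile) != object@readLength)
        msg <- c(msg, "qualityProfile must have one entry per cycle")
    if (object@nReadPairs < 0L) msg <- c(msg, "nReadPairs must be >= 0")
    if (length(msg)) msg else TRUE
})

#' A (possibly circular) nucleotide sequence with planted-feature truth
#'
#' Wraps a [Biostrings::DNAString] together with its topology and, for
#' simulated genomes, the coordinates of every planted ORF
#' (\code{truthFeatures}) and a provenance map back to the source sequence for
#' mutated derivatives.
#'
#' @slot id sequence identifier.
#' @slot seq a \code{DNAString}.
#' @slot circular logical topology flag.
#' @slot truthFeatures data.frame of planted ORFs with columns
#'   \code{index, start, end, strand, nt_len} in the strand-aware 1-based
#'   inclusive convention of [predictOrfs()].
#' @slot provenance integer vector mapping each base to its position in the
#'   parent sequence (\code{NA} for inserted bases); empty when not derived.
#'
#' @exportClass VirophageGenome
setClass("VirophageGenome", representation(
    id = "character",
    seq = "DNAString",
    circular = "logical",
    truthFeatures = "data.frame",
    provenance = "integer"
))

setValidity("VirophageGenome", function(object) {
    msg <- character()
    if (length(object@seq) == 0L) msg <- c(msg, "sequence must be non-empty")
    tf <- object@truthFeatures
    if (nrow(tf)) {
        span <- abs(tf$start - tf$end) + 1L
        if (any(span %% 3L != 0L))
            msg <- c(msg, "truth ORF spans must be divisible by 3")
        if (any(span < 150L))
            msg <- c(msg, "truth ORF spans must be >= 150 bp")
    }
    if (length(object@provenance) &&
        length(object@provenance) != length(object@seq))
        msg <- c(msg, "provenance map must match sequence length")
    if (length(msg)) msg else TRUE
})

#' Simulated paired-end read set with per-read truth
#'
#' @slot r1,r2 \code{QualityScaledDNAStringSet} mates (Sanger Phred+33).
#' @slot truth data.frame with one row per read: \code{read_id, source,
#'   frag_start, frag_end, strand, mate, n_errors, wraps}.  Coordinates are on
#'   the source sequence; \code{frag_end} may exceed its length for fragments
#'   wrapping the origin of a circular genome.
#' @exportClass ReadSimulation
setClass("ReadSimulation", representation(
    r1 = "QualityScaledDNAStringSet",
    r2 = "QualityScaledDNAStringSet",
    truth = "data.frame"
))

#' Read quality-control parameters
#'
#' The windowed rule used on the study's metagenome: a read is truncated at
#' the first position where the mean Phred score of the \code{window}
#' neighboring bases starting there drops below \code{minMeanQ} (Q20 over 5
#' bases by default), and discarded if the retained prefix is shorter than
#' \code{minLength} (50 bp).
#'
#' @slot window window width in nt.
#' @slot minMeanQ minimum mean Phred score of every full window.
#' @slot minLength minimum retained read length in bp ("more than 50 bp" is
#'   interpreted as >= 50 retained bases; adjust the knob for strict >).
#' @exportClass QCParams
setClass("QCParams", representation(
    window = "integer", minMeanQ = "numeric", minLength = "integer"))

setValidity("QCParams", function(object) {
    msg <- character()
    if (object@window < 1L) msg <- c(msg, "window must be >= 1")
    if (object@minLength < 1L) msg <- c(msg, "minLength must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Translated homology-search parameters
#'
#' Controls the six-frame, tblastx-style search used both for read
#' recruitment and protein annotation: substitution matrix, affine gap
#' penalties, word seeding, the E-value reporting cutoff, and the
#' Karlin-Altschul constants used to convert raw Smith-Waterman scores into
#' E-values (E = K m n exp(-lambda S)).
#'
#' @slot matrix substitution matrix name (a matrix of that name is loaded
#'   from Biostrings, e.g. \code{"BLOSUM62"}).
#' @slot gapOpen,gapExtend affine gap penalties (positive costs).
#' @slot wordSize seed word size in amino acids.
#' @slot evalueCutoff report hits with E-value <= this cutoff.
#' @slot bestHitOnly keep a single best hit per query.
#' @slot karlinK,karlinLambda Karlin-Altschul constants; defaults are the
#'   published gapped BLOSUM62 (open 11 / extend 1) values K = 0.041,
#'   lambda = 0.267.
#' @slot mode \code{"auto"}, \code{"full"} (exhaustive per-frame-pair
#'   dynamic programming) or \code{"seeded"} (two-hit word seeding plus
#'   banded extension).
#' @exportClass SearchParams
setClass("SearchParams", representation(
    matrix = "character",
    gapOpen = "numeric", gapExtend = "numeric",
    wordSize = "integer",
    evalueCutoff = "numeric",
    bestHitOnly = "logical",
    karlinK = "numeric", karlinLambda = "numeric",
    mode = "character"
))

setValidity("SearchParams", function(object) {
    msg <- character()
    if (object@evalueCutoff <= 0) msg <- c(msg, "evalueCutoff must be > 0")
    if (object@gapOpen < 0 || object@gapExtend < 0)
        msg <- c(msg, "gap penalties must be >= 0")
    if (object@wordSize < 1L) msg <- c(msg, "wordSize must be >= 1")
    if (!object@mode %in% c("auto", "full", "seeded"))
        msg <- c(msg, "mode must be one of auto/full/seeded")
    if (length(msg)) msg else TRUE
})

#' Assembly parameters
#'
#' Thresholds of the two assembly stages used in the study: greedy de novo
#' overlap-layout-consensus of the recruited reads (minimum overlap 25 bp at
#' 80% identity) and iterative reference-guided extension against the full
#' read set (25 bp at 90%), plus the terminal-direct-repeat threshold used to
#' call circularity.
#'
#' @slot minOverlap minimum overlap length in bp.
#' @slot minIdentityDenovo minimum overlap identity for de novo merging.
#' @slot minIdentityExtend minimum identity for read-to-contig mapping.
#' @slot maxIterations safety cap on extension iterations.
#' @slot minTerminalRepeat minimum terminal direct repeat length in bp.
#' @slot wordSize exact-match seed length for overlap/mapping candidates.
#' @slot repeatMaxMismatch mismatch fraction tolerated in the terminal
#'   repeat (0 = exact, the default).
#' @exportClass AssemblyParams
setClass("AssemblyParams", representation(
    minOverlap = "integer",
    minIdentityDenovo = "numeric",
    minIdentityExtend = "numeric",
    maxIterations = "integer",
    minTerminalRepeat = "integer",
    wordSize = "integer",
    repeatMaxMismatch = "numeric"
))

setValidity("AssemblyParams", function(object) {
    msg <- character()
    if (object@minOverlap < 1L) msg <- c(msg, "minOverlap must be >= 1")
    ids <- c(object@minIdentityDenovo, object@minIdentityExtend)
    if (any(ids <= 0 | ids > 1))
        msg <- c(msg, "identities must lie in (0, 1]")
    if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
    if (length(msg)) msg else TRUE
})

#' An assembled contig with per-base depth and circularity metadata
#'
#' @slot id contig identifier.
#' @slot seq consensus sequence (\code{DNAString}).
#' @slot depth integer per-base read depth, same length as \code{seq}.
#' @slot memberReads ids of the reads merged into the contig.
#' @slot circular logical; TRUE once a terminal direct repeat was detected
#'   and collapsed.
#' @slot terminalRepeatLen length in bp of the detected terminal direct
#'   repeat (0 if none).
#' @slot iterations reference-extension iterations to convergence.
#' @exportClass Contig
setClass("Contig", representation(
    id = "character",
    seq = "DNAString",
    depth = "integer",
    memberReads = "character",
    circular = "logical",
    terminalRepeatLen = "integer",
    iterations = "integer"
))

setValidity("Contig", function(object) {
    msg <- character()
    if (length(object@depth) != length(object@seq))
        msg <- c(msg, "depth must have one entry per base")
    if (length(object@depth) && any(object@depth < 1L))
        msg <- c(msg, "depth must be >= 1 at every retained position")
    if (object@circular && object@terminalRepeatLen <= 0L)
        msg <- c(msg, "circular contigs must record a terminal repeat length")
    if (length(msg)) msg else TRUE
})

#' ORF-calling parameters
#'
#' The study's rule: an ORF starts at the first ATG of a stop-to-stop
#' interval and must span at least 150 bp including its stop codon.
#'
#' @slot startCodon start codon (ATG).
#' @slot minLen minimum ORF span in nt, stop codon included.
#' @slot allowWraparound report ORFs crossing the origin of circular
#'   genomes.
#' @slot firstAtgOnly one ORF per stop-to-stop interval (first ATG); when
#'   FALSE every ATG opens a candidate ORF.
#' @slot suppressNested drop ORFs fully contained in a longer same-frame ORF
#'   (only reachable with \code{firstAtgOnly = FALSE}).
#' @exportClass ORFParams
setClass("ORFParams", representation(
    startCodon = "character",
    minLen = "integer",
    allowWraparound = "logical",
    firstAtgOnly = "logical",
    suppressNested = "logical"
))

setValidity("ORFParams", function(object) {
    msg <- character()
    if (nchar(object@startCodon) != 3L)
        msg <- c(msg, "startCodon must be a codon")
    if (object@minLen < 6L)
        msg <- c(msg, "minLen must cover at least start and stop codons")
    if (length(msg)) msg else TRUE
})

#' A PCR primer pair for in-silico amplification
#'
#' @slot name primer-pair name.
#' @slot forward,reverse primer sequences written 5' to 3'.
#' @slot maxMismatch mismatches tolerated per primer binding site.
#' @exportClass PrimerPair
setClass("PrimerPair", representation(
    name = "character", forward = "character", reverse = "character",
    maxMismatch = "integer"))

setValidity("PrimerPair", function(object) {
    msg <- character()
    if (nchar(object@forward) < 10L || nchar(object@reverse) < 10L)
        msg <- c(msg, "primers must be >= 10 nt")
    if (object@maxMismatch < 0L) msg <- c(msg, "maxMismatch must be >= 0")
    if (length(msg)) msg else TRUE
})

#' End-to-end discovery pipeline configuration
#'
#' Holds the inputs and the per-stage parameter objects of
#' [runDiscovery()].  Stage E-value cutoffs default to the study's:
#' 1e-5 for the multi-genome scan, 1e-10 (best hit per read) for bait
#' recruitment, and 1e-3 for protein annotation.
#'
#' @slot reads named list of \code{QualityScaledDNAStringSet} runs.
#' @slot baits \code{DNAStringSet} of bait genomes.
#' @slot proteinDb \code{AAStringSet} local virophage protein database.
#' @slot qc a [QCParams-class].
#' @slot scan,bait,annotate [SearchParams-class] for the three stages.
#' @slot assembly an [AssemblyParams-class].
#' @slot orf an [ORFParams-class].
#' @slot bootstrapN bootstrap replicates for the marker tree.
#' @slot seed integer seed for the stochastic stages.
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
    reads = "list",
    baits = "DNAStringSet",
    proteinDb = "AAStringSet",
    qc = "QCParams",
    scan = "SearchParams",
    bait = "SearchParams",
    annotate = "SearchParams",
    assembly = "AssemblyParams",
    orf = "ORFParams",
    bootstrapN = "integer",
    seed = "integer"
))

#' Report of a full discovery run
#'
#' @slot qcStats per-run QC accounting (see [qcDataset()]).
#' @slot recruitment recruitment table of the bait stage.
#' @slot scanCounts per-bait recruited-read counts of the 1e-5 scan.
#' @slot contigTable per-contig summary of the de novo stage.
#' @slot genome the extended (and, when detected, circularized) [Contig-class],
#'   or NULL when nothing was recruited.
#' @slot orfs predicted ORF table of the final genome.
#' @slot annotations protein-homology annotations of the ORFs.
#' @slot tree marker-gene bootstrap tree (\code{ape::phylo}) or NULL.
#' @slot params full parameter echo (list) for the audit trail.
#' @slot log character vector of stage messages.
#' @exportClass DiscoveryReport
setClass("DiscoveryReport", representation(
    qcStats = "data.frame",
    recruitment = "data.frame",
    scanCounts = "data.frame",
    contigTable = "data.frame",
    genome = "ANY",
    orfs = "data.frame",
    annotations = "data.frame",
    tree = "ANY",
    params = "list",
    log = "character"
))
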