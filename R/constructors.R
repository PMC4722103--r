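#' Create a SimulationConfig
#'
#' Defaults emulate the DSLV1 study conditions: a 28,788 bp circular genome
#' at 43.2% G+C with 28 ORFs, a bait relative diverged at 0.35 substitutions
#' per site (which lands recovered amino-acid identities in the 33-70% band
#' observed between DSLV1 and YSLV3), 2 x 251 bp read pairs from a 430 bp
#' insert library with a 0.5% substitution error rate, and 25% unrelated
#' background reads.
#'
#' @param genomeLength genome size in bp.
#' @param gcTarget target G+C fraction.
#' @param nOrfs ORFs to plant.
#' @param subRate bait substitutions per site.
#' @param indelRate bait single-base indel events per site.
#' @param nReadPairs read pairs drawn from the genome.
#' @param readLength read length in bp.
#' @param insertMean,insertSd insert-size distribution in bp.
#' @param baseErrorRate per-base sequencing substitution rate.
#' @param qualityProfile per-cycle mean Phred scores; default declines
#'   smoothly from 38 to 28 over the read.
#' @param backgroundFraction fraction of all pairs from unrelated sequence.
#' @param circular circular genome flag.
#' @param seed integer seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(genomeLength = 3000L, nOrfs = 3L, seed = 7L)
#' cfg
#' @export
SimulationConfig <- function(genomeLength = 28788L, gcTarget = 0.432,
                             nOrfs = 28L, subRate = 0.35, indelRate = 0.001,
                             nReadPairs = 2000L, readLength = 251L,
                             insertMean = 430, insertSd = 43,
                             baseErrorRate = 0.005, qualityProfile = NULL,
                             backgroundFraction = 0.25, circular = TRUE,
                             seed = 1L) {
    if (is.null(qualityProfile)) {
        cyc <- seq_len(readLength)
        qualityProfile <- 38 - 10 * (cyc / readLength)^2
    }
    new("SimulationConfig",
        genomeLength = as.integer(genomeLength), gcTarget = gcTarget,
        nOrfs = as.integer(nOrfs), subRate = subRate, indelRate = indelRate,
        nReadPairs = as.integer(nReadPairs),
        readLength = as.integer(readLength),
        insertMean = insertMean, insertSd = insertSd,
        baseErrorRate = baseErrorRate, qualityProfile = qualityProfile,
        backgroundFraction = backgroundFraction,
        circular = circular, seed = as.integer(seed))
}

#' Create QC parameters
#'
#' @param window window width in nt.
#' @param minMeanQ minimum mean Phred of each window.
#' @param minLength minimum retained read length in bp.
#' @return A [QCParams-class] object.
#' @examples
#' QCParams()
#' @export
QCParams <- function(window = 5L, minMeanQ = 20, minLength = 50L)
    new("QCParams", window = as.integer(window), minMeanQ = minMeanQ,
        minLength = as.integer(minLength))

#' Create translated-search parameters
#'
#' @param matrix substitution matrix name available from Biostrings.
#' @param gapOpen,gapExtend affine gap costs.
#' @param wordSize seed word size in aa.
#' @param evalueCutoff E-value reporting cutoff.
#' @param bestHitOnly keep only the best hit per query.
#' @param karlinK,karlinLambda Karlin-Altschul constants.
#' @param mode "auto", "full" or "seeded" (see [SearchParams-class]).
#' @return A [SearchParams-class] object.
#' @examples
#' SearchParams(evalueCutoff = 1e-10, bestHitOnly = TRUE)
#' @export
SearchParams <- function(matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                         wordSize = 3L, evalueCutoff = 1e-5,
                         bestHitOnly = FALSE, karlinK = 0.041,
                         karlinLambda = 0.267, mode = "auto")
    new("SearchParams", matrix = matrix, gapOpen = gapOpen,
        gapExtend = gapExtend, wordSize = as.integer(wordSize),
        evalueCutoff = evalueCutoff, bestHitOnly = bestHitOnly,
        karlinK = karlinK, karlinLambda = karlinLambda, mode = mode)

#' Create assembly parameters
#'
#' @param minOverlap minimum overlap in bp.
#' @param minIdentityDenovo de novo overlap identity threshold.
#' @param minIdentityExtend extension mapping identity threshold.
#' @param maxIterations extension iteration cap.
#' @param minTerminalRepeat minimum terminal direct repeat (defaults to
#'   \code{minOverlap}).
#' @param wordSize exact seed length for overlap candidates.
#' @param repeatMaxMismatch tolerated mismatch fraction in the terminal
#'   repeat (0 = exact matching).
#' @return An [AssemblyParams-class] object.
#' @examples
#' AssemblyParams()
#' @export
AssemblyParams <- function(minOverlap = 25L, minIdentityDenovo = 0.80,
                           minIdentityExtend = 0.90, maxIterations = 100L,
                           minTerminalRepeat = minOverlap, wordSize = 12L,
                           repeatMaxMismatch = 0)
    new("AssemblyParams", minOverlap = as.integer(minOverlap),
        minIdentityDenovo = minIdentityDenovo,
        minIdentityExtend = minIdentityExtend,
        maxIterations = as.integer(maxIterations),
        minTerminalRepeat = as.integer(minTerminalRepeat),
        wordSize = as.integer(wordSize),
        repeatMaxMismatch = repeatMaxMismatch)

#' Create ORF-calling parameters
#'
#' @param startCodon start codon.
#' @param minLen minimum ORF span in nt (stop included).
#' @param allowWraparound report origin-crossing ORFs on circular genomes.
#' @param firstAtgOnly one ORF (first ATG) per stop-to-stop interval.
#' @param suppressNested drop same-frame nested ORFs.
#' @return An [ORFParams-class] object.
#' @examples
#' ORFParams()
#' @export
ORFParams <- function(startCodon = "ATG", minLen = 150L,
                      allowWraparound = TRUE, firstAtgOnly = TRUE,
                      suppressNested = TRUE)
    new("ORFParams", startCodon = startCodon, minLen = as.integer(minLen),
        allowWraparound = allowWraparound, firstAtgOnly = firstAtgOnly,
        suppressNested = suppressNested)

#' Create a primer pair
#'
#' @param name primer-pair name.
#' @param forward,reverse 5'-to-3' primer sequences.
#' @param maxMismatch mismatches tolerated per binding site.
#' @return A [PrimerPair-class] object.
#' @examples
#' PrimerPair("YSLV3", "CGACCAAGACTTCCAGCCTC", "CACAAGTCCCACTGAGTTGC")
#' @export
PrimerPair <- function(name, forward, reverse, maxMismatch = 0L)
    new("PrimerPair", name = name, forward = toupper(forward),
        reverse = toupper(reverse), maxMismatch = as.integer(maxMismatch))

#' Create a pipeline configuration
#'
#' @param reads named list of \code{QualityScaledDNAStringSet} runs (or a
#'   single set, wrapped automatically).
#' @param baits \code{DNAStringSet} of bait genomes; the LAST bait is used
#'   for the strict recruitment stage (mirroring the YSLV3 bait), all baits
#'   for the permissive scan.
#' @param proteinDb \code{AAStringSet} protein database for annotation.
#' @param qc,scan,bait,annotate,assembly,orf stage parameter objects.
#' @param bootstrapN bootstrap replicates (0 disables the tree stage).
#' @param seed integer seed.
#' @return A [PipelineConfig-class] object.
#' @export
PipelineConfig <- function(reads, baits, proteinDb = Biostrings::AAStringSet(),
                           qc = QCParams(),
                           scan = SearchParams(evalueCutoff = 1e-5),
                           bait = SearchParams(evalueCutoff = 1e-10,
                                               bestHitOnly = TRUE),
                           annotate = SearchParams(evalueCutoff = 1e-3,
                                                   bestHitOnly = TRUE,
                                                   mode = "full"),
                           assembly = AssemblyParams(), orf = ORFParams(),
                           bootstrapN = 100L, seed = 1L) {
    if (!is.list(reads)) reads <- list(run1 = reads)
    if (is.null(names(reads)))
        names(reads) <- paste0("run", seq_along(reads))
    new("PipelineConfig", reads = reads, baits = baits,
        proteinDb = proteinDb, qc = qc, scan = scan, bait = bait,
        annotate = annotate, assembly = assembly, orf = orf,
        bootstrapN = as.integer(bootstrapN), seed = as.integer(seed))
}
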