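#' @name accessors
#' @title Accessors for vmine S4 objects
#'
#' @description Slot accessors for [VirophageGenome-class] and
#' [Contig-class] objects: the underlying sequence, topology, planted truth
#' features, per-base depth, terminal-repeat length and extension iteration
#' count.
#'
#' @param x a \code{VirophageGenome} or \code{Contig}.
#' @return \code{genomeSeq} and \code{contigSeq} return a
#'   \code{DNAString}; \code{isCircular} a logical; \code{truthFeatures} a
#'   data.frame; \code{contigDepth} an integer vector;
#'   \code{terminalRepeatLen} and \code{iterationsToConverge} integers.
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setMethod("genomeSeq", "VirophageGenome", function(x) x@seq)

#' @rdname accessors
#' @importFrom GenomeInfoDb isCircular
#' @export isCircular
#' @export
setMethod("isCircular", "VirophageGenome", function(x) x@circular)
#' @rdname accessors
#' @export
setMethod("isCircular", "Contig", function(x) x@circular)

#' @rdname accessors
#' @export
setGeneric("truthFeatures", function(x) standardGeneric("truthFeatures"))
#' @rdname accessors
#' @export
setMethod("truthFeatures", "VirophageGenome", function(x) x@truthFeatures)

#' @rdname accessors
#' @export
setGeneric("contigSeq", function(x) standardGeneric("contigSeq"))
#' @rdname accessors
#' @export
setMethod("contigSeq", "Contig", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("contigDepth", function(x) standardGeneric("contigDepth"))
#' @rdname accessors
#' @export
setMethod("contigDepth", "Contig", function(x) x@depth)

#' @rdname accessors
#' @export
setGeneric("terminalRepeatLen",
           function(x) standardGeneric("terminalRepeatLen"))
#' @rdname accessors
#' @export
setMethod("terminalRepeatLen", "Contig", function(x) x@terminalRepeatLen)

#' @rdname accessors
#' @export
setGeneric("iterationsToConverge",
           function(x) standardGeneric("iterationsToConverge"))
#' @rdname accessors
#' @export
setMethod("iterationsToConverge", "Contig", function(x) x@iterations)

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@genomeLength, "bp",
        if (object@circular) "circular" else "linear", "genome,",
        sprintf("G+C %.1f%%,", 100 * object@gcTarget),
        object@nOrfs, "ORFs\n")
    cat("  bait divergence: sub", object@subRate, "/ indel",
        object@indelRate, "per site\n")
    cat("  reads: ", object@nReadPairs, " x 2 x ", object@readLength,
        " bp, insert ", object@insertMean, " +/- ", object@insertSd,
        " bp, error ", object@baseErrorRate, "\n", sep = "")
    cat("  background fraction", object@backgroundFraction,
        "| seed", object@seed, "\n")
})

setMethod("show", "VirophageGenome", function(object) {
    cat("VirophageGenome '", object@id, "': ", length(object@seq), " bp, ",
        if (object@circular) "circular" else "linear", sep = "")
    if (nrow(object@truthFeatures))
        cat(",", nrow(object@truthFeatures), "planted ORFs")
    cat("\n")
})

setMethod("show", "ReadSimulation", function(object) {
    cat("ReadSimulation:", length(object@r1), "read pairs (",
        sum(object@truth$source == "background") %/% 2L,
        "background pairs )\n")
})

setMethod("show", "Contig", function(object) {
    cat("Contig '", object@id, "': ", length(object@seq), " bp, ",
        if (object@circular) "circular" else "linear",
        ", mean depth ", round(mean(object@depth), 1), sep = "")
    if (object@terminalRepeatLen > 0L)
        cat(", terminal repeat ", object@terminalRepeatLen, " bp", sep = "")
    if (object@iterations > 0L)
        cat(", ", object@iterations, " extension iterations", sep = "")
    cat("\n")
})

setMethod("show", "DiscoveryReport", function(object) {
    cat("DiscoveryReport\n")
    cat("  QC: ", sum(object@qcStats$reads_out), "/",
        sum(object@qcStats$reads_in), " reads retained over ",
        nrow(object@qcStats), " run(s)\n", sep = "")
    cat("  recruited (bait stage):", nrow(object@recruitment), "reads\n")
    cat("  de novo contigs:", nrow(object@contigTable), "\n")
    if (!is.null(object@genome)) {
        cat("  genome: ")
        show(object@genome)
    } else cat("  genome: none\n")
    cat("  ORFs:", nrow(object@orfs), "| annotated:",
        if (nrow(object@annotations))
            sum(!is.na(object@annotations$subject_id)) else 0L, "\n")
    if (!is.null(object@tree))
        cat("  tree:", length(object@tree$tip.label), "taxa\n")
})
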