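## Accessors for the small published reference tables bundled with the
## package.  These are the printed study tables (coordinates, run accounting,
## recruitment counts, primer sets) used by desk checks and examples.

.extdata <- function(name)
    system.file("extdata", name, package = "vmine", mustWork = TRUE)

#' Published DSLV1 ORF coordinate table
#'
#' The 28 ORFs of the Dishui Lake virophage 1 genome with strand-aware
#' start/end positions (start > end on the reverse strand), nt/aa lengths
#' and the published best protein homolog per ORF (NA for ORFans).
#'
#' @return data.frame, one row per ORF.
#' @examples
#' head(dslv1OrfTable())
#' @export
dslv1OrfTable <- function() {
    read.delim(.extdata("dslv1_orf_table.tsv"), stringsAsFactors = FALSE)
}

#' Published per-run metagenome QC accounting
#'
#' Six MiSeq runs with raw and quality-controlled gigabases and read counts
#' (two QC columns: the windowed pipeline rule, then the NGS QC Toolkit
#' pass); totals are the column sums.
#'
#' @return data.frame, one row per run.
#' @examples
#' qcTotals(dslQcRuns())
#' @export
dslQcRuns <- function() {
    read.delim(.extdata("dsl_qc_runs.tsv"), stringsAsFactors = FALSE)
}

#' Published recruitment counts of the 12-genome scan
#'
#' Reads recruited from the Dishui Lake metagenome at E-value 1e-5:
#' 1199 to YSLV3, 2138 to the other OLV/YSLV genomes, and 582 to the distant
#' virophages (Mavirus, ALM, Sputnik, Zamilon).
#'
#' @return data.frame with \code{subject_id, n_reads, group}.
#' @examples
#' baitShare(dslRecruitmentCounts(), "YSLV3")
#' @export
dslRecruitmentCounts <- function() {
    read.delim(.extdata("dsl_recruitment_counts.tsv"),
               stringsAsFactors = FALSE)
}

#' Published virophage primer sets
#'
#' The eight MCP-gene-specific primer pairs used for lake screening
#' (\code{set = "mcp"}) and the eight DSLV1 verification pairs
#' (\code{set = "verification"}), with theoretical amplicon lengths.
#'
#' @param set which primer table.
#' @return data.frame with name, theoretical amplicon length and the
#'   forward/reverse sequences (5' to 3').
#' @examples
#' virophagePrimers("mcp")
#' @export
virophagePrimers <- function(set = c("mcp", "verification")) {
    set <- match.arg(set)
    f <- if (set == "mcp") "mcp_primers.tsv" else "verification_primers.tsv"
    read.delim(.extdata(f), stringsAsFactors = FALSE)
}

#' Check the headline properties of an assembled virophage genome
#'
#' Computes the three summary statistics reported for a finished genome --
#' length, G+C content, and the number of ORFs under the ATG / >= 150 bp
#' rule -- from a genome provided as a FASTA file or sequence object.  Use it
#' to verify a deposited record (e.g. GenBank KT894027 for DSLV1, which must
#' be fetched separately) or any assembly produced by this package.
#'
#' @param genome path to a FASTA file, or a sequence object accepted by
#'   [gcContent()].
#' @param circular treat the genome as circular when calling ORFs.
#' @param orfParams an [ORFParams-class].
#' @return A list with \code{length_bp}, \code{gc_percent} and
#'   \code{n_orfs}.
#' @export
checkGenomeProperties <- function(genome, circular = TRUE,
                                  orfParams = ORFParams()) {
    if (is.character(genome) && length(genome) == 1L &&
        file.exists(genome)) {
        set <- readDNAStringSet(genome)
        genome <- as.character(set[[1L]])
    }
    s <- .as_dna_chr(genome)
    orfs <- predictOrfs(s, orfParams, circular = circular)
    list(length_bp = nchar(s), gc_percent = 100 * gcContent(s),
         n_orfs = nrow(orfs))
}
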