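#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- mcols mcols<-
#' @importFrom BiocGenerics width start end strand
NULL

GENE_BIOTYPES <- c("germline_coding", "soma_coding", "rRNA", "tRNA", "snRNA",
                   "snoRNA", "ncRNA", "miRNA", "piRNA_21U")
STRUCTURAL_BIOTYPES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "ncRNA")
TRUTH_CLASSES <- c("E", "M", "UP", "NEUTRAL")
GENOTYPES <- c("WT", "egc1", "elli1", "ego1", "mut16", "egc1_mut16",
               "elli1_mut16")

#' AnnotatedGenome: toy chromosomes plus gene annotation
#'
#' Container for a simulated genome: chromosome sequences as a
#' \code{DNAStringSet} and single-exon gene models as a \code{GRanges} whose
#' metadata columns carry \code{gene_id}, \code{biotype}, \code{truth_class}
#' (the hidden simulation truth, \code{NA} for non-germline genes) and
#' \code{base_rate} (relative siRNA production rate of the locus in wild type).
#'
#' @slot chromosomes \code{DNAStringSet} of chromosome sequences.
#' @slot genes \code{GRanges} of gene bodies, one unspliced transcript each.
#' @slot seed integer seed the genome was generated from.
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome",
  representation(chromosomes = "DNAStringSet", genes = "GRanges",
                 seed = "integer"))

setValidity("AnnotatedGenome", function(object) {
  gr <- object@genes
  msg <- character()
  if (length(gr)) {
    mc <- S4Vectors::mcols(gr)
    need <- c("gene_id", "biotype", "truth_class", "base_rate")
    if (!all(need %in% colnames(mc)))
      return(paste("genes must carry mcols:", paste(need, collapse = ", ")))
    if (anyDuplicated(mc$gene_id)) msg <- c(msg, "gene_id values must be unique")
    if (!all(mc$biotype %in% GENE_BIOTYPES))
      msg <- c(msg, "unknown biotype")
    bad_truth <- !is.na(mc$truth_class) & mc$biotype != "germline_coding"
    if (any(bad_truth))
      msg <- c(msg, "truth_class must be NA except on germline_coding genes")
    if (!all(as.character(GenomicRanges::seqnames(gr)) %in%
             names(object@chromosomes)))
      msg <- c(msg, "gene on unknown chromosome")
    else {
      lens <- BiocGenerics::width(object@chromosomes)[
        match(as.character(GenomicRanges::seqnames(gr)),
              names(object@chromosomes))]
      if (any(BiocGenerics::start(gr) < 1L | BiocGenerics::end(gr) > lens))
        msg <- c(msg, "gene outside chromosome bounds")
    }
    if (length(gr) > 1L) {
      hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
      if (length(hits) > length(gr))
        msg <- c(msg, "gene intervals must be pairwise non-overlapping")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' GenotypeModel: per-class siRNA rate multipliers for one genotype
#'
#' Encodes how a genotype reshapes per-region 22G production rates relative to
#' wild type: \code{delta5}/\code{delta3} act on the 5' and 3' windows of
#' E-class genes, \code{deltaM} on M-class genes and \code{deltaUp} on UP-class
#' genes. The gene body is split at \code{fivePrimeFraction} (default 0.8),
#' the 3' remainder standing in for the terminal exon.
#'
#' @exportClass GenotypeModel
setClass("GenotypeModel",
  representation(genotype = "character", delta5 = "numeric",
                 delta3 = "numeric", deltaM = "numeric", deltaUp = "numeric",
                 fivePrimeFraction = "numeric",
                 threePrimeFraction = "numeric"))

setValidity("GenotypeModel", function(object) {
  msg <- character()
  mult <- c(object@delta5, object@delta3, object@deltaM, object@deltaUp)
  if (any(!is.finite(mult)) || any(mult < 0))
    msg <- c(msg, "all rate multipliers must be finite and >= 0")
  if (abs(object@fivePrimeFraction + object@threePrimeFraction - 1) > 1e-9)
    msg <- c(msg, "fivePrimeFraction + threePrimeFraction must equal 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SmallRNAReadSet: small-RNA inserts with optional simulation truth
#'
#' Holds adapter-free insert sequences. For simulated libraries each read
#' carries its template gene (\code{truthGene}) and the 0-based transcript
#' coordinate of the 5'-most template base it covers (\code{truthStart});
#' both are \code{NA} for reads of unknown origin.
#'
#' @exportClass SmallRNAReadSet
setClass("SmallRNAReadSet",
  representation(reads = "DNAStringSet", truthGene = "character",
                 truthStart = "integer", genotype = "character",
                 seed = "integer", adapter3 = "character",
                 adapter5 = "character"))

setValidity("SmallRNAReadSet", function(object) {
  n <- length(object@reads)
  if (length(object@truthGene) != n || length(object@truthStart) != n)
    return("truth vectors must match read count")
  if (n && !all(Biostrings::alphabetFrequency(object@reads,
      baseOnly = TRUE)[, "other"] == 0))
    return("read sequences must be over {A,C,G,T}")
  TRUE
})

#' NormalizationStats: library-level read tallies for RPM denominators
#'
#' \code{totalMappers} counts every read with at least one exact hit;
#' \code{senseRRNA} the (weight-summed) reads attributable to sense rRNA
#' fragments; \code{nonstructuralMappers} the 18-26 nt reads whose hits all
#' avoid structural biotypes (tRNA, snRNA, snoRNA, rRNA, ncRNA). The
#' quantification denominator is totalMappers - senseRRNA; the metagene
#' denominator is nonstructuralMappers.
#'
#' @exportClass NormalizationStats
setClass("NormalizationStats",
  representation(totalMappers = "numeric", senseRRNA = "numeric",
                 nonstructuralMappers = "numeric"))

setValidity("NormalizationStats", function(object) {
  msg <- character()
  if (object@senseRRNA > object@totalMappers + 1e-9)
    msg <- c(msg, "senseRRNA cannot exceed totalMappers")
  if (object@nonstructuralMappers > object@totalMappers + 1e-9)
    msg <- c(msg, "nonstructuralMappers cannot exceed totalMappers")
  if (object@totalMappers - object@senseRRNA <= 0)
    msg <- c(msg, "quantification denominator must be positive")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SirnaAlignments: exact-match hits plus library tallies
#'
#' \code{hits} is a \code{DataFrame} with one row per (read, locus) exact
#' full-length match: read_id, gene_id, offset (0-based from the transcript
#' 5' end of the leftmost covered template base), orientation
#' (sense/antisense), weight (1/n over the read's n hits), width and
#' first_base of the read.
#'
#' @exportClass SirnaAlignments
setClass("SirnaAlignments",
  representation(hits = "DFrame", stats = "NormalizationStats"))

#' GeneCountTable: per-gene weighted antisense 22G counts
#'
#' \code{counts} holds, per gene: biotype, raw weighted antisense count, RPM
#' under the rRNA-subtracted quantification denominator, RPM under the
#' nonstructural metagene denominator, and exclusion flags.
#' \code{coverage} is a per-gene numeric vector of per-base antisense
#' coverage (transcript 5'->3', metagene-RPM scale).
#'
#' @exportClass GeneCountTable
setClass("GeneCountTable",
  representation(counts = "DFrame", coverage = "SimpleList",
                 stats = "NormalizationStats", sample = "character"))

#' ClassAssignment: gene memberships in the E/M/UP class machinery
#'
#' Logical membership columns per gene (EGC-1 target, ELLI-1 target, E-class,
#' M-class, UP-class) with the defining invariant
#' E_class = EGC1_target union ELLI1_target.
#'
#' @exportClass ClassAssignment
setClass("ClassAssignment",
  representation(memberships = "DFrame", provenance = "list"))

setValidity("ClassAssignment", function(object) {
  m <- object@memberships
  need <- c("gene_id", "egc1_target", "elli1_target", "e_class", "m_class",
            "up_class")
  if (!all(need %in% colnames(m)))
    return(paste("memberships must have columns:",
                 paste(need, collapse = ", ")))
  if (!identical(as.logical(m$e_class),
                 as.logical(m$egc1_target | m$elli1_target)))
    return("e_class must equal egc1_target | elli1_target")
  TRUE
})

#' MetageneProfile: binned gene-body coverage averaged over a gene set
#'
#' @exportClass MetageneProfile
setClass("MetageneProfile",
  representation(bins = "numeric", nGenes = "integer", sample = "character"))

setValidity("MetageneProfile", function(object) {
  if (any(object@bins < 0)) "bin values must be >= 0" else TRUE
})
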