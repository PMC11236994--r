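#' Configuration for a simulated annotated genome
#'
#' Defines the gene content of a toy chromosome: germline-expressed coding
#' genes partitioned into hidden truth classes (E, M, UP, NEUTRAL),
#' soma-expressed coding genes, structural RNA loci (rRNA, tRNA, snRNA,
#' snoRNA, ncRNA), miRNA loci and 21U-RNA (piRNA) loci.
#'
#' Defaults describe the demonstration cohort used throughout the package:
#' 120 germline genes (30 E / 30 M / 15 UP / 45 NEUTRAL), a handful of soma
#' and structural loci, 500-1500 nt gene bodies on a 400 kb chromosome.
#'
#' @param nGermlineGenes number of germline coding genes.
#' @param classCounts named integer vector (E, M, UP, NEUTRAL) partitioning
#'   the germline genes; must sum to \code{nGermlineGenes}.
#' @param nSomaGenes number of soma-specific coding genes.
#' @param nStructural named counts for rRNA, tRNA, snRNA, snoRNA, ncRNA loci.
#' @param nMirna,n21u counts of miRNA and 21U-RNA loci.
#' @param geneLengthRange min/max gene length in nt (min must be >= 100 so
#'   100-bin profiles stay meaningful).
#' @param chromLength chromosome length in nt.
#' @param minSpacing minimum intergenic gap in nt (>= 50 keeps antisense
#'   read assignment unambiguous).
#' @param rateSdLog sd (log scale) of the per-gene wild-type siRNA production
#'   rate drawn at genome creation.
#' @param upRateScale factor shrinking the wild-type base rate of UP-class
#'   genes (default 0.1): genes whose siRNAs are amplified in E-granule
#'   mutants start from low wild-type levels.
#' @param seed integer seed.
#' @return A validated list of class \code{genome_config}.
#' @export
genomeConfig <- function(nGermlineGenes = 120L,
                         classCounts = c(E = 30L, M = 30L, UP = 15L,
                                         NEUTRAL = 45L),
                         nSomaGenes = 6L,
                         nStructural = c(rRNA = 2L, tRNA = 2L, snRNA = 1L,
                                         snoRNA = 1L, ncRNA = 1L),
                         nMirna = 2L, n21u = 2L,
                         geneLengthRange = c(500L, 1500L),
                         chromLength = 400000L, minSpacing = 50L,
                         rateSdLog = 0.5, upRateScale = 0.1, seed = 1L) {
  cfg <- list(nGermlineGenes = as.integer(nGermlineGenes),
              classCounts = classCounts, nSomaGenes = as.integer(nSomaGenes),
              nStructural = nStructural, nMirna = as.integer(nMirna),
              n21u = as.integer(n21u),
              geneLengthRange = as.integer(geneLengthRange),
              chromLength = as.integer(chromLength),
              minSpacing = as.integer(minSpacing),
              rateSdLog = rateSdLog, upRateScale = upRateScale,
              seed = as.integer(seed))
  class(cfg) <- "genome_config"
  validateGenomeConfig(cfg)
  cfg
}

validateGenomeConfig <- function(cfg) {
  counts <- c(cfg$nGermlineGenes, cfg$nSomaGenes, cfg$nStructural,
              cfg$nMirna, cfg$n21u)
  if (any(counts < 0)) stop("all gene counts must be >= 0")
  if (!setequal(names(cfg$classCounts), c("E", "M", "UP", "NEUTRAL")))
    stop("classCounts must name E, M, UP, NEUTRAL")
  if (sum(cfg$classCounts) != cfg$nGermlineGenes)
    stop("classCounts must sum to nGermlineGenes")
  if (!setequal(names(cfg$nStructural),
                c("rRNA", "tRNA", "snRNA", "snoRNA", "ncRNA")))
    stop("nStructural must name rRNA, tRNA, snRNA, snoRNA, ncRNA")
  if (cfg$geneLengthRange[1] < 100L)
    stop("minimum gene length must be >= 100 nt")
  if (cfg$geneLengthRange[1] > cfg$geneLengthRange[2])
    stop("geneLengthRange must be non-decreasing")
  n <- sum(counts)
  worst <- n * cfg$geneLengthRange[2] + max(0L, n - 1L) * cfg$minSpacing
  if (worst > cfg$chromLength)
    stop("requested genes cannot fit on the chromosome: need up to ", worst,
         " nt, have ", cfg$chromLength)
  invisible(cfg)
}

#' Generate an annotated toy genome
#'
#' Lays out non-overlapping single-exon genes on one random chromosome with
#' at least \code{minSpacing} nt between neighbours, assigns biotypes and
#' hidden truth classes, and draws a per-gene wild-type siRNA production rate
#' (log-normal). Deterministic for a fixed config (the seed lives in the
#' config).
#'
#' @param config a \code{genome_config} from \code{\link{genomeConfig}}.
#' @return An \linkS4class{AnnotatedGenome}.
#' @export
makeGenome <- function(config) {
  validateGenomeConfig(config)
  set.seed(config$seed)
  chrom <- Biostrings::DNAStringSet(random_dna(config$chromLength))
  names(chrom) <- "chrT"

  biotype <- c(rep("germline_coding", config$nGermlineGenes),
               rep("soma_coding", config$nSomaGenes),
               rep(names(config$nStructural), config$nStructural),
               rep("miRNA", config$nMirna),
               rep("piRNA_21U", config$n21u))
  n <- length(biotype)
  truth <- rep(NA_character_, n)
  truth[seq_len(config$nGermlineGenes)] <-
    sample(rep(names(config$classCounts), config$classCounts))

  gr <- GenomicRanges::GRanges()
  if (n > 0L) {
    len <- sample(seq(config$geneLengthRange[1], config$geneLengthRange[2]),
                  n, replace = TRUE)
    ord <- sample.int(n)
    spare <- config$chromLength - sum(len) -
      max(0L, n - 1L) * config$minSpacing
    if (spare < 0L)
      stop("genes cannot be placed without overlap on this chromosome")
    extra <- as.integer(stats::rmultinom(1, spare, rep(1, n + 1L)))
    gaps <- c(extra[1L], config$minSpacing + extra[seq_len(n - 1L) + 1L])
    starts <- cumsum(gaps) + cumsum(c(0L, len[ord][-n])) + 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rate <- ifelse(biotype %in% c("germline_coding", "soma_coding"),
                   stats::rlnorm(n, meanlog = 0, sdlog = config$rateSdLog), 0)
    ## genes that gain siRNAs in E-granule mutants start near-silent in WT
    rate[!is.na(truth) & truth == "UP"] <-
      rate[!is.na(truth) & truth == "UP"] * config$upRateScale
    gene_id <- sprintf("%s%03d",
                       c(germline_coding = "glg", soma_coding = "som",
                         rRNA = "rrn", tRNA = "trn", snRNA = "snr",
                         snoRNA = "sno", ncRNA = "ncr", miRNA = "mir",
                         piRNA_21U = "piu")[biotype],
                       stats::ave(seq_len(n), biotype, FUN = seq_along))
    gr <- GenomicRanges::GRanges("chrT",
      IRanges::IRanges(start = starts[order(ord)], width = len),
      strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = gene_id, biotype = biotype, truth_class = truth,
      base_rate = rate)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  }
  methods::new("AnnotatedGenome", chromosomes = chrom, genes = gr,
               seed = config$seed)
}

#' Strand-aware transcript sequences
#'
#' Extracts each gene's unspliced transcript (5' to 3'): the chromosome
#' substring for plus-strand genes, its reverse complement for minus-strand
#' genes.
#'
#' @param genome an \linkS4class{AnnotatedGenome}.
#' @return A named \code{DNAStringSet}, one entry per gene.
#' @export
transcriptSeqs <- function(genome) {
  gr <- genes(genome)
  if (!length(gr)) return(Biostrings::DNAStringSet())
  chrom <- chromosomes(genome)
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(gr), function(i) {
    s <- Biostrings::subseq(chrom[[as.character(
      GenomicRanges::seqnames(gr)[i])]],
      start = BiocGenerics::start(gr)[i], end = BiocGenerics::end(gr)[i])
    if (as.character(BiocGenerics::strand(gr)[i]) == "-")
      Biostrings::reverseComplement(s) else s
  }))
  names(seqs) <- S4Vectors::mcols(gr)$gene_id
  seqs
}

#' Write a genome as FASTA + GFF3
#'
#' The GFF3 carries \code{ID}, \code{biotype} and \code{truth_class}
#' attributes per gene. Output is byte-identical for identical genomes.
#'
#' @param genome an \linkS4class{AnnotatedGenome}.
#' @param fastaPath,gffPath output paths.
#' @return Invisibly, the two paths.
#' @export
writeGenome <- function(genome, fastaPath, gffPath) {
  Biostrings::writeXStringSet(chromosomes(genome), fastaPath)
  gr <- genes(genome)
  mc <- S4Vectors::mcols(gr)
  out <- gr
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    source = "eGranuleSeq", type = "gene", ID = mc$gene_id,
    biotype = mc$biotype,
    truth_class = ifelse(is.na(mc$truth_class), "NA", mc$truth_class),
    base_rate = sprintf("%.6g", mc$base_rate))
  rtracklayer::export(out, gffPath, format = "gff3")
  invisible(c(fastaPath, gffPath))
}

#' Read a genome back from FASTA + GFF3
#'
#' Inverse of \code{\link{writeGenome}}; the original seed is not recoverable
#' and is stored as \code{NA}.
#'
#' @param fastaPath,gffPath paths written by \code{\link{writeGenome}}.
#' @return An \linkS4class{AnnotatedGenome}.
#' @export
readAnnotatedGenome <- function(fastaPath, gffPath) {
  chrom <- Biostrings::readDNAStringSet(fastaPath)
  names(chrom) <- sub("\\s.*$", "", names(chrom))
  gr <- rtracklayer::import(gffPath, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = as.character(mc$ID), biotype = as.character(mc$biotype),
    truth_class = ifelse(mc$truth_class == "NA", NA_character_,
                         as.character(mc$truth_class)),
    base_rate = as.numeric(mc$base_rate))
  methods::new("AnnotatedGenome", chromosomes = chrom,
               genes = GenomicRanges::sort(gr, ignore.strand = TRUE),
               seed = NA_integer_)
}
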