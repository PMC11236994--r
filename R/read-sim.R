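DEFAULT_LENGTH_PROBS <- c(`18` = 0.02, `19` = 0.03, `20` = 0.08, `21` = 0.15,
                          `22` = 0.40, `23` = 0.15, `24` = 0.08, `25` = 0.05,
                          `26` = 0.04)
ADAPTER3_DEFAULT <- "TCGTATGCCGTCTTCTGCTTG"
ADAPTER5_DEFAULT <- "GTTCAGAGTTCTACAGTCCGACGATC"

#' Expected read share per gene under a genotype model
#'
#' The relative rate of gene g is base_rate x (f5 x mult5 + f3 x mult3);
#' expected reads are \code{depth x (1 - contamination fractions) x share}.
#' Exposed so rate-conservation and composition contracts can be checked
#' against simulated libraries.
#'
#' @param genome an \linkS4class{AnnotatedGenome}.
#' @param model a \linkS4class{GenotypeModel}.
#' @return A \code{DataFrame} with gene_id, rate and share (rates normalized
#'   over coding genes).
#' @export
expectedReadShare <- function(genome, model) {
  mc <- S4Vectors::mcols(genes(genome))
  mult <- rateMultipliers(genome, model)
  coding <- mc$biotype %in% c("germline_coding", "soma_coding")
  rate <- mc$base_rate * (model@fivePrimeFraction * mult$mult5 +
                          model@threePrimeFraction * mult$mult3)
  rate[!coding] <- 0
  S4Vectors::DataFrame(gene_id = mc$gene_id, rate = rate,
                       share = if (sum(rate) > 0) rate / sum(rate) else rate)
}

#' Simulate a genotype-specific 22G small-RNA library
#'
#' Draws reads antisense to coding transcripts according to the genome's
#' per-gene base rates reshaped by the genotype model: E-class genes emit
#' from their 5' window at rate x delta5 and from the 3'-terminal window at
#' rate x delta3; M- and UP-class genes are scaled gene-wide by deltaM and
#' deltaUp. Read lengths follow a discrete distribution peaked at 22 nt
#' (support 18-26 by default) and the first transcribed base is a G with
#' probability \code{pG}: G starts are realised by drawing template positions
#' whose template base is a C, so every simulated read remains an exact
#' reverse-complement substring of its transcript. Sense rRNA degradation
#' fragments (and optionally sense miRNA / 21U-RNA reads) are mixed in to
#' exercise the normalization subtractions and biotype filters downstream.
#'
#' @param genome an \linkS4class{AnnotatedGenome} with at least one
#'   germline_coding gene.
#' @param model a \linkS4class{GenotypeModel}.
#' @param depth expected total read count (> 0).
#' @param seed integer seed.
#' @param lengthProbs named probability vector over insert lengths.
#' @param pG probability that a read starts with G (default 0.9).
#' @param contamination fraction of reads that are sense rRNA fragments
#'   (default 0.05).
#' @param mirnaFraction,piFraction fractions of sense miRNA and 21U-RNA
#'   reads (defaults 0.01 each; forced to 0 when the genome has no such
#'   locus).
#' @return A \linkS4class{SmallRNAReadSet} with per-read truth.
#' @export
simulateSirnaLibrary <- function(genome, model, depth, seed,
                                 lengthProbs = DEFAULT_LENGTH_PROBS,
                                 pG = 0.9, contamination = 0.05,
                                 mirnaFraction = 0.01, piFraction = 0.01) {
  stopifnot(depth > 0)
  mc <- S4Vectors::mcols(genes(genome))
  if (!any(mc$biotype == "germline_coding"))
    stop("genome contains no germline_coding genes")
  lens <- as.integer(names(lengthProbs))
  stopifnot(abs(sum(lengthProbs) - 1) < 1e-9, all(lens >= 17), all(lens <= 30))

  if (!any(mc$biotype == "rRNA")) contamination <- 0
  if (!any(mc$biotype == "miRNA")) mirnaFraction <- 0
  if (!any(mc$biotype == "piRNA_21U")) piFraction <- 0

  set.seed(seed)
  tx <- transcriptSeqs(genome)
  txchar <- as.character(tx)
  txlen <- nchar(txchar)
  gid <- mc$gene_id

  n <- as.integer(depth)
  category <- sample(c("coding", "rRNA", "miRNA", "piU"), n, replace = TRUE,
                     prob = c(1 - contamination - mirnaFraction - piFraction,
                              contamination, mirnaFraction, piFraction))
  seq_out <- character(n)
  truth_gene <- rep(NA_character_, n)
  truth_start <- rep(NA_integer_, n)

  ## antisense coding reads: multinomial over (gene, window) rate cells
  cod_idx <- which(category == "coding")
  ## template C positions per transcript (a C under the read 5' end gives a
  ## G-starting read); computed once, reused across sampling groups
  cposList <- lapply(txchar, function(s)
    which(strsplit(s, "", fixed = TRUE)[[1]] == "C"))
  if (length(cod_idx)) {
    mult <- rateMultipliers(genome, model)
    coding <- which(mc$biotype %in% c("germline_coding", "soma_coding"))
    b5 <- pmax(1L, as.integer(floor(model@fivePrimeFraction * txlen[coding])))
    w <- c(mc$base_rate[coding] * model@fivePrimeFraction *
             mult$mult5[coding],
           mc$base_rate[coding] * model@threePrimeFraction *
             mult$mult3[coding])
    cell <- sample.int(2L * length(coding), length(cod_idx), replace = TRUE,
                       prob = w)
    gpos <- ((cell - 1L) %% length(coding)) + 1L   # index into coding
    win <- ifelse(cell <= length(coding), 5L, 3L)
    rlen <- sample(lens, length(cod_idx), replace = TRUE, prob = lengthProbs)
    wantG <- stats::runif(length(cod_idx)) < pG
    grp <- split(seq_along(cell),
                 paste(gpos, win, rlen, sep = "."))
    for (sel in grp) {
      gi <- coding[gpos[sel[1]]]
      L <- txlen[gi]; l <- rlen[sel[1]]; b <- b5[gpos[sel[1]]]
      if (win[sel[1]] == 5L) { lo <- 1L; hi <- min(b, L - l + 1L)
      } else { lo <- b + 1L; hi <- L - l + 1L }
      if (hi < lo) { lo <- 1L; hi <- L - l + 1L }  # degenerate window guard
      s <- integer(length(sel))
      ## template base under the read's 5' end must be C for a G start
      cp <- cposList[[gi]]
      cand <- cp[cp >= lo + l - 1L & cp <= hi + l - 1L] - l + 1L
      gsel <- wantG[sel] & length(cand) > 0L
      if (any(gsel))
        s[gsel] <- cand[sample.int(length(cand), sum(gsel), replace = TRUE)]
      if (any(!gsel))
        s[!gsel] <- lo + sample.int(hi - lo + 1L, sum(!gsel),
                                    replace = TRUE) - 1L
      frag <- Biostrings::extractAt(tx[[gi]],
        IRanges::IRanges(start = s, width = l))
      seq_out[cod_idx[sel]] <-
        as.character(Biostrings::reverseComplement(frag))
      truth_gene[cod_idx[sel]] <- gid[gi]
      truth_start[cod_idx[sel]] <- s - 1L
    }
  }

  ## sense-strand fragments from structural / small-RNA loci
  sense_fill <- function(idx, biotype, lenv) {
    loci <- which(mc$biotype == biotype)
    if (!length(idx)) return(invisible(NULL))
    gi <- loci[sample.int(length(loci), length(idx), replace = TRUE)]
    for (g in unique(gi)) {
      sel <- which(gi == g)
      l <- lenv[sel]
      s <- vapply(l, function(li)
        sample.int(txlen[g] - li + 1L, 1L), 1L)
      frag <- Biostrings::extractAt(tx[[g]],
        IRanges::IRanges(start = s, width = l))
      seq_out[idx[sel]] <<- as.character(frag)
      truth_gene[idx[sel]] <<- gid[g]
      truth_start[idx[sel]] <<- s - 1L
    }
  }
  ri <- which(category == "rRNA")
  sense_fill(ri, "rRNA", sample(lens, length(ri), TRUE, prob = lengthProbs))
  mi <- which(category == "miRNA")
  sense_fill(mi, "miRNA", rep(22L, length(mi)))
  pi <- which(category == "piU")
  sense_fill(pi, "piRNA_21U", rep(21L, length(pi)))

  reads <- Biostrings::DNAStringSet(seq_out)
  names(reads) <- sprintf("read%07d", seq_len(n))
  methods::new("SmallRNAReadSet", reads = reads, truthGene = truth_gene,
               truthStart = truth_start, genotype = model@genotype,
               seed = as.integer(seed), adapter3 = ADAPTER3_DEFAULT,
               adapter5 = ADAPTER5_DEFAULT)
}

#' Write a read set to FASTQ, appending the 3' adapter
#'
#' Mimics the sequencing library structure: each record is the insert
#' followed by the ligated 3' adapter, with constant Phred-33 quality.
#'
#' @param readset a \linkS4class{SmallRNAReadSet}.
#' @param path output FASTQ path.
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(readset, path) {
  seqs <- Biostrings::DNAStringSet(paste0(as.character(readSeqs(readset)),
                                          readset@adapter3))
  names(seqs) <- names(readSeqs(readset))
  quals <- Biostrings::BStringSet(strrep("I", BiocGenerics::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read raw reads from FASTQ
#'
#' Returns a \linkS4class{SmallRNAReadSet} with no simulation truth.
#'
#' @param path FASTQ path.
#' @param genotype optional label.
#' @return A \linkS4class{SmallRNAReadSet}.
#' @export
readFastq <- function(path, genotype = "unknown") {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  methods::new("SmallRNAReadSet", reads = seqs,
               truthGene = rep(NA_character_, length(seqs)),
               truthStart = rep(NA_integer_, length(seqs)),
               genotype = genotype, seed = NA_integer_,
               adapter3 = ADAPTER3_DEFAULT, adapter5 = ADAPTER5_DEFAULT)
}
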