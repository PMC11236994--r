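#' Construct a genotype rate model
#'
#' A \linkS4class{GenotypeModel} describes how a genotype rescales per-region
#' 22G production relative to wild type. Presets encode the biology under
#' study:
#' \describe{
#'   \item{WT}{all multipliers 1.}
#'   \item{egc1, elli1}{E-granule loss: the 5' window of E-class genes drops
#'     (\code{delta5}, default 0.1) while the 3'-terminal window persists
#'     (\code{delta3} = 1); a subset of Mutator-derived siRNAs is amplified
#'     (\code{deltaUp}, default 10 on UP-class genes, echoing the more than
#'     tenfold siRNA gains seen at genes like sid-1 and rde-11).}
#'   \item{ego1}{loss of the RdRP itself: both windows of E-class genes drop
#'     (\code{delta5} applied gene-wide).}
#'   \item{mut16}{Mutator-focus loss: M-class genes ablated
#'     (\code{deltaM}, default 0.05); UP-class genes, being Mutator-derived,
#'     are ablated too (\code{deltaUp} = 0.05).}
#'   \item{egc1_mut16, elli1_mut16}{multiplicative composition of the two
#'     parent models (see \code{\link{composeModels}}).}
#' }
#'
#' @param genotype one of WT, egc1, elli1, ego1, mut16, egc1_mut16,
#'   elli1_mut16.
#' @param delta5,delta3,deltaM,deltaUp override the preset multipliers.
#' @param fivePrimeFraction fraction of the gene body counted as the 5'
#'   region (default 0.8; the remaining 0.2 proxies the terminal exon).
#' @return A \linkS4class{GenotypeModel}.
#' @export
genotypeModel <- function(genotype = GENOTYPES, delta5 = NULL, delta3 = NULL,
                          deltaM = NULL, deltaUp = NULL,
                          fivePrimeFraction = 0.8) {
  genotype <- match.arg(genotype)
  preset <- switch(genotype,
    WT          = c(1,    1, 1,    1),
    egc1        = c(0.1,  1, 1,    10),
    elli1       = c(0.1,  1, 1,    10),
    ego1        = c(0.1,  0.1, 1,  1),
    mut16       = c(1,    1, 0.05, 0.05),
    egc1_mut16  = c(0.1,  1, 0.05, 0.5),
    elli1_mut16 = c(0.1,  1, 0.05, 0.5))
  methods::new("GenotypeModel", genotype = genotype,
               delta5 = delta5 %||% preset[1], delta3 = delta3 %||% preset[2],
               deltaM = deltaM %||% preset[3], deltaUp = deltaUp %||% preset[4],
               fivePrimeFraction = fivePrimeFraction,
               threePrimeFraction = 1 - fivePrimeFraction)
}

#' Compose two genotype models multiplicatively
#'
#' Double mutants are modelled as the elementwise product of the parents'
#' rate multipliers (relative to wild type), the standard independence
#' assumption for loss-of-function alleles acting on different granule
#' compartments.
#'
#' @param a,b \linkS4class{GenotypeModel} objects with matching window
#'   fractions.
#' @param genotype label for the composed model.
#' @return A \linkS4class{GenotypeModel}.
#' @export
composeModels <- function(a, b, genotype = paste(a@genotype, b@genotype,
                                                 sep = "_")) {
  stopifnot(methods::is(a, "GenotypeModel"), methods::is(b, "GenotypeModel"))
  if (abs(a@fivePrimeFraction - b@fivePrimeFraction) > 1e-9)
    stop("cannot compose models with different window fractions")
  methods::new("GenotypeModel", genotype = genotype,
               delta5 = a@delta5 * b@delta5, delta3 = a@delta3 * b@delta3,
               deltaM = a@deltaM * b@deltaM, deltaUp = a@deltaUp * b@deltaUp,
               fivePrimeFraction = a@fivePrimeFraction,
               threePrimeFraction = a@threePrimeFraction)
}

#' Per-gene, per-window expected rate multipliers under a model
#'
#' Returns, for each gene of the genome, the multiplier applied to its
#' wild-type base rate in the 5' and 3' windows. E-class genes feel
#' \code{delta5}/\code{delta3}, M-class genes \code{deltaM} in both windows,
#' UP-class genes \code{deltaUp} in both; NEUTRAL, soma and non-coding genes
#' are untouched.
#'
#' @param genome an \linkS4class{AnnotatedGenome}.
#' @param model a \linkS4class{GenotypeModel}.
#' @return A \code{DataFrame} with gene_id, mult5, mult3.
#' @export
rateMultipliers <- function(genome, model) {
  mc <- S4Vectors::mcols(genes(genome))
  tc <- mc$truth_class
  mult5 <- rep(1, length(tc))
  mult3 <- rep(1, length(tc))
  isE <- !is.na(tc) & tc == "E"
  isM <- !is.na(tc) & tc == "M"
  isU <- !is.na(tc) & tc == "UP"
  mult5[isE] <- model@delta5; mult3[isE] <- model@delta3
  mult5[isM] <- model@deltaM; mult3[isM] <- model@deltaM
  mult5[isU] <- model@deltaUp; mult3[isU] <- model@deltaUp
  S4Vectors::DataFrame(gene_id = mc$gene_id, mult5 = mult5, mult3 = mult3)
}

#' Model-implied truth set for a depletion or gain contrast
#'
#' The generator's own answer key for a genotype-vs-wild-type contrast: the
#' expected gene-wide rate ratio is the window-weighted multiplier
#' f5 x mult5 + f3 x mult3 (wild-type multipliers are all 1). Genes whose
#' ratio crosses the fold-change cutoff in the stated direction constitute
#' the set a perfect caller should recover. Restricted to germline coding
#' genes, matching the contrast filters. Note that genes can belong to more
#' than one contrast's truth set (UP-class genes, being Mutator-derived,
#' also deplete when Mutator foci are lost).
#'
#' @param genome an \linkS4class{AnnotatedGenome}.
#' @param model a \linkS4class{GenotypeModel}.
#' @param fcCutoff fold-change cutoff (default 2).
#' @param direction "down" or "up".
#' @return Character vector of gene ids.
#' @export
truthContrastSet <- function(genome, model, fcCutoff = 2,
                             direction = c("down", "up")) {
  direction <- match.arg(direction)
  mc <- S4Vectors::mcols(genes(genome))
  mult <- rateMultipliers(genome, model)
  ratio <- model@fivePrimeFraction * mult$mult5 +
    model@threePrimeFraction * mult$mult3
  germ <- mc$biotype == "germline_coding"
  if (direction == "down") mc$gene_id[germ & ratio <= 1 / fcCutoff]
  else mc$gene_id[germ & ratio >= fcCutoff]
}
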