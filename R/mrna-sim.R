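#' Simulate replicate mRNA count tables for a genotype
#'
#' Negative-binomial counts per coding gene, two replicates. mRNA levels of
#' siRNA-target genes are mostly unchanged in E-granule mutants; a
#' configurable gene set is silenced (default 4-fold down) to emulate the
#' behaviour of RNAi-pathway genes such as sid-1 and rde-11, whose mRNAs
#' collapse when their siRNAs are amplified.
#'
#' @param genome an \linkS4class{AnnotatedGenome}.
#' @param genotype genotype label (stored only; effects come via
#'   \code{silencedGenes}).
#' @param meanDepth expected count per gene at base expression (default 200).
#' @param dispersion NB dispersion (size = 1/dispersion; must be > 0).
#' @param seed integer seed.
#' @param silencedGenes gene ids silenced in this genotype.
#' @param silencingFactor fold reduction applied to silenced genes
#'   (default 4).
#' @param nReplicates number of replicates (default 2).
#' @return Integer matrix genes x replicates with gene_id rownames.
#' @export
simulateMrnaCounts <- function(genome, genotype = "WT", meanDepth = 200,
                               dispersion = 0.05, seed = 1L,
                               silencedGenes = character(),
                               silencingFactor = 4, nReplicates = 2L) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  set.seed(seed)
  mc <- S4Vectors::mcols(genes(genome))
  coding <- mc$biotype %in% c("germline_coding", "soma_coding")
  ids <- mc$gene_id[coding]
  mu <- meanDepth * mc$base_rate[coding]
  mu[ids %in% silencedGenes] <- mu[ids %in% silencedGenes] / silencingFactor
  counts <- matrix(
    stats::rnbinom(length(ids) * nReplicates, mu = rep(mu, nReplicates),
                   size = 1 / dispersion),
    nrow = length(ids), ncol = nReplicates,
    dimnames = list(ids, paste0(genotype, "_rep", seq_len(nReplicates))))
  counts
}

#' Simulate a qPCR Ct table
#'
#' Ct(target) = baseline - log2(level) + noise; the reference gene sits at
#' its own baseline. Three biological x three technical replicates per
#' sample. Noise-free tables invert exactly under \code{\link{ddct}}.
#'
#' @param trueRelativeLevels named numeric vector: per-sample target level
#'   relative to the control sample (all > 0). The first name is taken as
#'   the control unless \code{controlSample} is given.
#' @param noiseSd Ct measurement noise sd (default 0.1).
#' @param seed integer seed.
#' @param targetGene,referenceGene gene labels (default "target", "eft-3").
#' @param controlSample control sample name.
#' @param baselineTarget,baselineRef clean Ct baselines (defaults 22, 15).
#' @return data.frame with columns sample, gene, bio_rep, tech_rep, ct.
#' @export
simulateCtTable <- function(trueRelativeLevels, noiseSd = 0.1, seed = 1L,
                            targetGene = "target", referenceGene = "eft-3",
                            controlSample = names(trueRelativeLevels)[1],
                            baselineTarget = 22, baselineRef = 15) {
  stopifnot(all(trueRelativeLevels > 0), !is.null(names(trueRelativeLevels)))
  set.seed(seed)
  grid <- expand.grid(sample = names(trueRelativeLevels),
                      gene = c(targetGene, referenceGene),
                      bio_rep = 1:3, tech_rep = 1:3,
                      stringsAsFactors = FALSE)
  lv <- trueRelativeLevels[grid$sample]
  clean <- ifelse(grid$gene == targetGene,
                  baselineTarget - log2(lv), baselineRef)
  grid$ct <- clean + stats::rnorm(nrow(grid), 0, noiseSd)
  grid
}
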