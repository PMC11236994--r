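#' Contrast parameters for differential siRNA calling
#'
#' The twofold-change criterion with a wild-type abundance floor: genes need
#' at least \code{wtMinRpm} RPM in the reference (wild-type) library to enter
#' a depletion contrast. For up-contrasts the floor is applied to the mutant
#' library instead (genes gaining siRNAs can start near zero in wild type).
#'
#' @param fcCutoff fold-change cutoff (> 1; default 2).
#' @param wtMinRpm abundance floor in RPM (default 10).
#' @param pseudocount RPM added to numerator and denominator of fold changes
#'   (default 0.1; negligible next to the 10 RPM floor but prevents division
#'   by zero).
#' @param direction "down" (depletion) or "up" (gain).
#' @return A list of class \code{contrast_params}.
#' @export
contrastParams <- function(fcCutoff = 2, wtMinRpm = 10, pseudocount = 0.1,
                           direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (fcCutoff <= 1) stop("fcCutoff must be > 1")
  if (wtMinRpm < 0 || pseudocount < 0)
    stop("wtMinRpm and pseudocount must be >= 0")
  structure(list(fcCutoff = fcCutoff, wtMinRpm = wtMinRpm,
                 pseudocount = pseudocount, direction = direction),
            class = "contrast_params")
}

#' Pseudocounted fold change
#'
#' \code{(mut + eps) / (wt + eps)}, vectorised.
#'
#' @param rpmMut,rpmWt RPM values (>= 0).
#' @param pseudocount eps >= 0.
#' @return Numeric ratio(s).
#' @export
foldChange <- function(rpmMut, rpmWt, pseudocount = 0.1) {
  if (any(rpmMut < 0 | rpmWt < 0)) stop("RPM values must be >= 0")
  if (pseudocount == 0 && any(rpmWt == 0 & rpmMut == 0))
    stop("fold change undefined: both inputs and pseudocount are 0")
  (rpmMut + pseudocount) / (rpmWt + pseudocount)
}

eligible_genes <- function(tab) {
  cc <- geneCounts(tab)
  cc$gene_id[!cc$excluded_biotype & !cc$soma_specific]
}

#' Genes differentially targeted by siRNAs between two libraries
#'
#' Applies the twofold criterion with biotype and soma exclusions: candidate
#' genes must not be miRNA/21U-RNA/structural loci nor soma-specific, must
#' clear the RPM floor (wild type for "down", mutant for "up"), and must
#' change at least \code{fcCutoff}-fold in the stated direction.
#'
#' @param tableMut,tableWt \linkS4class{GeneCountTable}s over the same gene
#'   universe.
#' @param params a \code{\link{contrastParams}} object.
#' @return Character vector of gene ids.
#' @export
depletedGenes <- function(tableMut, tableWt, params = contrastParams()) {
  cm <- geneCounts(tableMut)
  cw <- geneCounts(tableWt)
  if (!identical(cm$gene_id, cw$gene_id))
    stop("count tables have mismatched gene universes")
  ok <- !cw$excluded_biotype & !cw$soma_specific
  fc <- foldChange(cm$rpm, cw$rpm, params$pseudocount)
  if (params$direction == "down") {
    ok <- ok & cw$rpm >= params$wtMinRpm & fc <= 1 / params$fcCutoff
  } else {
    ok <- ok & cm$rpm >= params$wtMinRpm & fc >= params$fcCutoff
  }
  cw$gene_id[ok]
}

#' Consensus targets across two alleles
#'
#' Genes called in both allele-specific contrasts — the allele-overlap rule
#' that defines EGC-1 and ELLI-1 target sets.
#'
#' @param setAllele1,setAllele2 character vectors of gene ids.
#' @return Their intersection.
#' @export
consensusTargets <- function(setAllele1, setAllele2) {
  intersect(setAllele1, setAllele2)
}

#' Assemble E/M/UP class membership from contrast gene sets
#'
#' E-class is the union of the EGC-1 and ELLI-1 target sets; M-class the
#' Mutator-dependent set; UP-class the union of genes gaining siRNAs in
#' either E-granule mutant.
#'
#' @param egc1Targets,elli1Targets,mut16Targets,upEgc1,upElli1 character
#'   vectors of gene ids (post-filter).
#' @param universe optional gene universe (defaults to the union of all
#'   inputs).
#' @return A \linkS4class{ClassAssignment}.
#' @export
defineClasses <- function(egc1Targets, elli1Targets, mut16Targets = character(),
                          upEgc1 = character(), upElli1 = character(),
                          universe = NULL) {
  universe <- universe %||% sort(unique(c(egc1Targets, elli1Targets,
                                          mut16Targets, upEgc1, upElli1)))
  m <- S4Vectors::DataFrame(
    gene_id = universe,
    egc1_target = universe %in% egc1Targets,
    elli1_target = universe %in% elli1Targets,
    m_class = universe %in% mut16Targets,
    up_class = universe %in% upEgc1 | universe %in% upElli1)
  m$e_class <- m$egc1_target | m$elli1_target
  methods::new("ClassAssignment", memberships = m,
               provenance = list(egc1 = egc1Targets, elli1 = elli1Targets,
                                 mut16 = mut16Targets, up_egc1 = upEgc1,
                                 up_elli1 = upElli1))
}

#' Overlap statistics between two gene sets
#'
#' Exact set arithmetic (inclusion-exclusion holds by construction);
#' percentages are not rounded — round at the presentation layer.
#'
#' @param A,B character vectors.
#' @return A list: sizeA, sizeB, intersection, union, pctOfAShared,
#'   pctOfBShared.
#' @export
overlapStats <- function(A, B) {
  A <- unique(A); B <- unique(B)
  i <- length(intersect(A, B))
  list(sizeA = length(A), sizeB = length(B), intersection = i,
       union = length(A) + length(B) - i,
       pctOfAShared = if (length(A)) 100 * i / length(A) else 0,
       pctOfBShared = if (length(B)) 100 * i / length(B) else 0)
}

#' Differentially expressed genes from replicate mRNA counts
#'
#' Library-size normalization (each replicate scaled to the mean library
#' size) followed by a plain fold-change filter on condition means, with a
#' minimum-abundance floor — no dispersion model, mirroring a custom-script
#' two-fold filter.
#'
#' @param countsMut,countsWt numeric matrices (genes x replicates) with
#'   identical rownames.
#' @param fcCutoff fold-change cutoff (default 2).
#' @param minMean minimum normalized mean (in either condition) to call a
#'   gene (default 5).
#' @param pseudocount added to both means in the ratio (default 0.5).
#' @return List with \code{up} and \code{down} gene-id vectors.
#' @export
mrnaDeGenes <- function(countsMut, countsWt, fcCutoff = 2, minMean = 5,
                        pseudocount = 0.5) {
  stopifnot(identical(rownames(countsMut), rownames(countsWt)))
  all_counts <- cbind(countsMut, countsWt)
  libs <- colSums(all_counts)
  if (any(libs == 0)) stop("a replicate has zero total counts")
  sf <- libs / mean(libs)
  norm <- sweep(all_counts, 2, sf, "/")
  nm <- ncol(countsMut)
  meanMut <- rowMeans(norm[, seq_len(nm), drop = FALSE])
  meanWt <- rowMeans(norm[, -seq_len(nm), drop = FALSE])
  fc <- (meanMut + pseudocount) / (meanWt + pseudocount)
  expressed <- pmax(meanMut, meanWt) >= minMean
  list(up = rownames(countsMut)[expressed & fc >= fcCutoff],
       down = rownames(countsMut)[expressed & fc <= 1 / fcCutoff])
}

#' Relative RNA levels by the 2^-ddCt method
#'
#' Technical replicates are averaged per biological replicate; dCt is
#' Ct(target) - Ct(reference) within each sample/replicate; ddCt subtracts
#' the control sample's mean dCt; relative level is 2^-ddCt.
#'
#' @param ctTable data.frame with columns sample, gene, bio_rep, tech_rep,
#'   ct.
#' @param referenceGene internal-control gene (default "eft-3").
#' @param controlSample sample whose level defines 1.0.
#' @return data.frame of per-biological-replicate relative levels plus a
#'   per-sample summary (mean, sd) as attribute \code{"summary"}.
#' @export
ddct <- function(ctTable, referenceGene = "eft-3", controlSample) {
  stopifnot(all(c("sample", "gene", "bio_rep", "tech_rep", "ct") %in%
                colnames(ctTable)))
  if (!any(ctTable$gene == referenceGene))
    stop("reference gene '", referenceGene, "' missing from Ct table")
  if (!controlSample %in% ctTable$sample)
    stop("control sample missing from Ct table")
  avg <- stats::aggregate(ct ~ sample + gene + bio_rep, data = ctTable,
                          FUN = mean)
  targets <- setdiff(unique(avg$gene), referenceGene)
  out <- do.call(rbind, lapply(targets, function(g) {
    tg <- avg[avg$gene == g, ]
    rf <- avg[avg$gene == referenceGene, ]
    mrg <- merge(tg, rf, by = c("sample", "bio_rep"),
                 suffixes = c("_t", "_r"))
    if (nrow(mrg) < nrow(tg))
      stop("reference gene rows missing for some sample/replicate")
    mrg$dct <- mrg$ct_t - mrg$ct_r
    ctrl <- mean(mrg$dct[mrg$sample == controlSample])
    data.frame(gene = g, sample = mrg$sample, bio_rep = mrg$bio_rep,
               rel_level = 2^(-(mrg$dct - ctrl)))
  }))
  summ <- stats::aggregate(rel_level ~ gene + sample, data = out,
                           FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  attr(out, "summary") <- do.call(data.frame, summ)
  out
}
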