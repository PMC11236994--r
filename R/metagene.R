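#' Scale one gene's coverage to a fixed number of bins
#'
#' Bases are partitioned into \code{nBins} contiguous, near-equal intervals;
#' when the length is not divisible the remainder bases are assigned one
#' each to the leading bins (deterministic and symmetric under reversal up
#' to the usual one-base discretisation). The bin value is the mean
#' per-base coverage of the interval. Coverage is already stored 5'->3' in
#' transcript coordinates, so minus-strand genes need no special handling
#' here.
#'
#' @param coverage numeric vector of per-base antisense coverage
#'   (transcript 5'->3').
#' @param nBins number of bins (default 100; transcript must be at least
#'   this long).
#' @return Numeric vector of length \code{nBins}.
#' @export
geneProfile <- function(coverage, nBins = 100L) {
  L <- length(coverage)
  if (L < nBins) stop("transcript shorter than nBins")
  size <- rep(L %/% nBins, nBins)
  rem <- L %% nBins
  if (rem) size[seq_len(rem)] <- size[seq_len(rem)] + 1L
  ends <- cumsum(size)
  cs <- c(0, cumsum(coverage))
  (cs[ends + 1L] - cs[ends - size + 1L]) / size
}

#' Average profiles over a gene set
#'
#' Unweighted arithmetic mean per bin (default), or each gene's profile
#' normalized to its own mean first ("gene-normalized") so every gene
#' contributes equally regardless of expression.
#'
#' @param profiles list (or matrix, genes in rows) of equal-length bin
#'   vectors; at least one gene.
#' @param mode "raw" or "gene-normalized".
#' @param sample label for the result.
#' @return A \linkS4class{MetageneProfile}.
#' @export
metaprofile <- function(profiles, mode = c("raw", "gene-normalized"),
                        sample = "sample") {
  mode <- match.arg(mode)
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (is.null(profiles) || !length(profiles))
    stop("metaprofile of an empty gene set")
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (mode == "gene-normalized") {
    m <- rowMeans(profiles)
    profiles <- profiles / ifelse(m > 0, m, 1)
  }
  methods::new("MetageneProfile", bins = colMeans(profiles),
               nGenes = nrow(profiles), sample = sample)
}

#' Positional depletion call for one gene
#'
#' Splits the profile into a 5' window (first \code{fivePrimeFraction} of
#' bins) and the 3'-terminal remainder, computes pseudocounted
#' mutant/wild-type coverage ratios per window, and labels the gene:
#' \code{five_prime_depleted} when the 5' window drops at least twofold
#' while the 3' window persists (fc5 <= depletedMax, fc3 >= unchangedMin);
#' \code{uniform_depleted} when both windows drop; \code{unchanged} when
#' both persist; otherwise \code{other}. The 0.5 threshold echoes the
#' twofold change criterion; 0.75 is a package choice.
#'
#' @param profileMut,profileWt equal-length bin vectors.
#' @param fivePrimeFraction fraction of bins in the 5' window (default 0.8).
#' @param depletedMax,unchangedMin label thresholds (defaults 0.5, 0.75).
#' @param pseudocount added to both window sums (default 0.01).
#' @param wtFloor minimum wild-type coverage sum required in each window for
#'   the label to be callable (default 0.1).
#' @return List: fc5, fc3, label.
#' @export
positionalBias <- function(profileMut, profileWt, fivePrimeFraction = 0.8,
                           depletedMax = 0.5, unchangedMin = 0.75,
                           pseudocount = 0.01, wtFloor = 0.1) {
  if (length(profileMut) != length(profileWt))
    stop("profiles must have the same number of bins")
  n <- length(profileWt)
  k <- max(1L, min(n - 1L, round(fivePrimeFraction * n)))
  w5 <- seq_len(k)
  wt5 <- sum(profileWt[w5]); wt3 <- sum(profileWt[-w5])
  if (wt5 < wtFloor || wt3 < wtFloor)
    stop("wild-type window coverage below floor; label not callable")
  fc5 <- (sum(profileMut[w5]) + pseudocount) / (wt5 + pseudocount)
  fc3 <- (sum(profileMut[-w5]) + pseudocount) / (wt3 + pseudocount)
  label <- if (fc5 <= depletedMax && fc3 >= unchangedMin) "five_prime_depleted"
    else if (fc5 <= depletedMax && fc3 <= depletedMax) "uniform_depleted"
    else if (fc5 >= unchangedMin && fc3 >= unchangedMin) "unchanged"
    else "other"
  list(fc5 = fc5, fc3 = fc3, label = label)
}

#' Positional bias calls for a gene set between two libraries
#'
#' Convenience wrapper: builds 100-bin profiles from the per-base coverage in
#' two \linkS4class{GeneCountTable}s and calls \code{\link{positionalBias}}
#' per gene. Genes whose wild-type windows are below the floor are labelled
#' \code{not_callable}.
#'
#' @param tableMut,tableWt \linkS4class{GeneCountTable}s.
#' @param geneIds genes to call.
#' @param nBins bins per profile (default 100).
#' @param ... passed to \code{\link{positionalBias}}.
#' @return data.frame with gene_id, fc5, fc3, label.
#' @export
positionalBiasTable <- function(tableMut, tableWt, geneIds, nBins = 100L,
                                ...) {
  covM <- coverageList(tableMut)
  covW <- coverageList(tableWt)
  res <- lapply(geneIds, function(g) {
    pm <- geneProfile(covM[[g]], nBins)
    pw <- geneProfile(covW[[g]], nBins)
    tryCatch(positionalBias(pm, pw, ...),
             error = function(e) list(fc5 = NA_real_, fc3 = NA_real_,
                                      label = "not_callable"))
  })
  data.frame(gene_id = geneIds,
             fc5 = vapply(res, `[[`, 1, "fc5"),
             fc3 = vapply(res, `[[`, 1, "fc3"),
             label = vapply(res, `[[`, "", "label"))
}

#' Metagene profile for a gene set from a count table
#'
#' @param table a \linkS4class{GeneCountTable}.
#' @param geneIds genes to aggregate.
#' @param nBins bins per profile (default 100).
#' @param mode aggregation mode, see \code{\link{metaprofile}}.
#' @return A \linkS4class{MetageneProfile}.
#' @export
metageneProfile <- function(table, geneIds, nBins = 100L,
                            mode = c("raw", "gene-normalized")) {
  cov <- coverageList(table)
  profs <- lapply(geneIds, function(g) geneProfile(cov[[g]], nBins))
  metaprofile(profs, mode = match.arg(mode), sample = table@sample)
}
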