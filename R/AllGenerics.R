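#' Accessors for eGranuleSeq containers
#'
#' Small accessor layer so downstream code never reaches into slots:
#' \code{genes()} / \code{chromosomes()} for \linkS4class{AnnotatedGenome},
#' \code{readSeqs()} / \code{readTruth()} for \linkS4class{SmallRNAReadSet},
#' \code{hits()} / \code{normStats()} for \linkS4class{SirnaAlignments},
#' \code{geneCounts()} / \code{coverageList()} for
#' \linkS4class{GeneCountTable}, \code{memberships()} / \code{classSet()} for
#' \linkS4class{ClassAssignment} and \code{profileBins()} for
#' \linkS4class{MetageneProfile}.
#'
#' @param x an eGranuleSeq object.
#' @param ... unused.
#' @return The corresponding slot content (see Details per class).
#' @name accessors
#' @aliases genes chromosomes readSeqs readTruth hits normStats geneCounts
#'   coverageList memberships classSet profileBins denomQuant denomMeta
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x, ...) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setGeneric("readSeqs", function(x, ...) standardGeneric("readSeqs"))
#' @rdname accessors
#' @export
setGeneric("readTruth", function(x, ...) standardGeneric("readTruth"))
#' @rdname accessors
#' @export
setGeneric("hits", function(x, ...) standardGeneric("hits"))
#' @rdname accessors
#' @export
setGeneric("normStats", function(x, ...) standardGeneric("normStats"))
#' @rdname accessors
#' @export
setGeneric("geneCounts", function(x, ...) standardGeneric("geneCounts"))
#' @rdname accessors
#' @export
setGeneric("coverageList", function(x, ...) standardGeneric("coverageList"))
#' @rdname accessors
#' @export
setGeneric("memberships", function(x, ...) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setGeneric("classSet", function(x, class, ...) standardGeneric("classSet"))
#' @rdname accessors
#' @export
setGeneric("profileBins", function(x, ...) standardGeneric("profileBins"))
#' @rdname accessors
#' @export
setGeneric("denomQuant", function(x, ...) standardGeneric("denomQuant"))
#' @rdname accessors
#' @export
setGeneric("denomMeta", function(x, ...) standardGeneric("denomMeta"))

#' @rdname accessors
setMethod("genes", "AnnotatedGenome", function(x, ...) x@genes)
#' @rdname accessors
setMethod("chromosomes", "AnnotatedGenome", function(x, ...) x@chromosomes)

#' @rdname accessors
setMethod("readSeqs", "SmallRNAReadSet", function(x, ...) x@reads)
#' @rdname accessors
setMethod("readTruth", "SmallRNAReadSet", function(x, ...)
  S4Vectors::DataFrame(read_id = names(x@reads), truth_gene = x@truthGene,
                       truth_start = x@truthStart))

#' @rdname accessors
setMethod("hits", "SirnaAlignments", function(x, ...) x@hits)
#' @rdname accessors
setMethod("normStats", "SirnaAlignments", function(x, ...) x@stats)
#' @rdname accessors
setMethod("normStats", "GeneCountTable", function(x, ...) x@stats)

#' @rdname accessors
setMethod("geneCounts", "GeneCountTable", function(x, ...) x@counts)
#' @rdname accessors
setMethod("coverageList", "GeneCountTable", function(x, ...) x@coverage)

#' @rdname accessors
setMethod("memberships", "ClassAssignment", function(x, ...) x@memberships)
#' @rdname accessors
setMethod("classSet", "ClassAssignment", function(x, class, ...) {
  m <- x@memberships
  col <- match.arg(class, c("egc1_target", "elli1_target", "e_class",
                            "m_class", "up_class"))
  m$gene_id[m[[col]]]
})

#' @rdname accessors
setMethod("profileBins", "MetageneProfile", function(x, ...) x@bins)

#' @rdname accessors
setMethod("denomQuant", "NormalizationStats", function(x, ...)
  x@totalMappers - x@senseRRNA)
#' @rdname accessors
setMethod("denomMeta", "NormalizationStats", function(x, ...)
  x@nonstructuralMappers)
#' @rdname accessors
setMethod("denomQuant", "GeneCountTable", function(x, ...) denomQuant(x@stats))
#' @rdname accessors
setMethod("denomMeta", "GeneCountTable", function(x, ...) denomMeta(x@stats))

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome:", length(object@chromosomes), "chromosome(s),",
      length(object@genes), "gene(s)\n")
  if (length(object@genes)) {
    bt <- table(S4Vectors::mcols(object@genes)$biotype)
    cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
    tc <- table(S4Vectors::mcols(object@genes)$truth_class, useNA = "no")
    if (length(tc))
      cat("  truth classes:",
          paste(names(tc), tc, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "GenotypeModel", function(object) {
  cat(sprintf(
    "GenotypeModel '%s': delta5=%g delta3=%g deltaM=%g deltaUp=%g (5' fraction %g)\n",
    object@genotype, object@delta5, object@delta3, object@deltaM,
    object@deltaUp, object@fivePrimeFraction))
})

setMethod("show", "SmallRNAReadSet", function(object) {
  cat("SmallRNAReadSet:", length(object@reads), "reads, genotype",
      object@genotype, "\n")
  if (length(object@reads)) {
    w <- BiocGenerics::width(object@reads)
    cat("  insert lengths:", min(w), "-", max(w), "nt; 22 nt fraction",
        round(mean(w == 22), 3), "\n")
  }
})

setMethod("show", "NormalizationStats", function(object) {
  cat(sprintf(
    "NormalizationStats: %g mappers, %g sense-rRNA, %g nonstructural (denoms: quant %g, meta %g)\n",
    object@totalMappers, object@senseRRNA, object@nonstructuralMappers,
    denomQuant(object), denomMeta(object)))
})

setMethod("show", "SirnaAlignments", function(object) {
  cat("SirnaAlignments:", nrow(object@hits), "hits\n")
  show(object@stats)
})

setMethod("show", "GeneCountTable", function(object) {
  cat("GeneCountTable (", object@sample, "): ", nrow(object@counts),
      " genes\n", sep = "")
})

setMethod("show", "ClassAssignment", function(object) {
  m <- object@memberships
  cat(sprintf(
    "ClassAssignment: %d genes; E=%d (EGC1 %d, ELLI1 %d), M=%d, UP=%d\n",
    nrow(m), sum(m$e_class), sum(m$egc1_target), sum(m$elli1_target),
    sum(m$m_class), sum(m$up_class)))
})

setMethod("show", "MetageneProfile", function(object) {
  cat("MetageneProfile (", object@sample, "): ", length(object@bins),
      " bins over ", object@nGenes, " genes\n", sep = "")
})
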