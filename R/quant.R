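#' Read-cleaning parameters
#'
#' Adapter sequences and length window for small-RNA read cleaning. The
#' quantification pipeline keeps 17-30 nt inserts; metagene profiling keeps
#' 18-26 nt (use \code{preset = "meta"}).
#'
#' @param adapter3,adapter5 adapter sequences (3' adapter is searched in the
#'   read; 5' adapter carryover is stripped from the read start).
#' @param minLen,maxLen retained insert length window.
#' @param discardUntrimmed drop reads in which no 3' adapter is found.
#' @param preset "quant" (17-30 nt) or "meta" (18-26 nt).
#' @return A list of class \code{cleaning_params}.
#' @export
cleaningParams <- function(adapter3 = ADAPTER3_DEFAULT,
                           adapter5 = ADAPTER5_DEFAULT,
                           minLen = NULL, maxLen = NULL,
                           discardUntrimmed = TRUE,
                           preset = c("quant", "meta")) {
  preset <- match.arg(preset)
  window <- if (preset == "quant") c(17L, 30L) else c(18L, 26L)
  p <- list(adapter3 = adapter3, adapter5 = adapter5,
            minLen = as.integer(minLen %||% window[1]),
            maxLen = as.integer(maxLen %||% window[2]),
            discardUntrimmed = isTRUE(discardUntrimmed))
  if (p$minLen > p$maxLen) stop("minLen must be <= maxLen")
  if (!nzchar(p$adapter3)) stop("adapter3 must be non-empty")
  class(p) <- "cleaning_params"
  p
}

#' Trim adapters and length-filter raw reads
#'
#' The 3' adapter is located as the longest prefix of \code{adapter3}
#' (at least 8 nt) occurring in the read, and the read is truncated at that
#' position; reads without a hit are dropped when \code{discardUntrimmed}.
#' A read that begins with a suffix (>= 8 nt) of the 5' adapter has that
#' carryover removed. Survivors are filtered to \code{[minLen, maxLen]}.
#' Empty input yields empty output.
#'
#' @param raw a \linkS4class{SmallRNAReadSet} of raw (adapter-bearing) reads.
#' @param params a \code{\link{cleaningParams}} object.
#' @return A cleaned \linkS4class{SmallRNAReadSet}.
#' @export
cleanReads <- function(raw, params = cleaningParams()) {
  stopifnot(inherits(params, "cleaning_params"))
  s <- as.character(readSeqs(raw))
  if (!length(s))
    return(methods::new("SmallRNAReadSet",
                        reads = Biostrings::DNAStringSet(),
                        truthGene = character(), truthStart = integer(),
                        genotype = raw@genotype, seed = raw@seed,
                        adapter3 = params$adapter3,
                        adapter5 = params$adapter5))
  cut <- rep(NA_integer_, length(s))
  for (k in seq(min(nchar(params$adapter3), max(nchar(s))), 8L)) {
    todo <- which(is.na(cut))
    if (!length(todo)) break
    pos <- regexpr(substr(params$adapter3, 1L, k), s[todo], fixed = TRUE)
    hit <- pos > 0L
    cut[todo[hit]] <- pos[hit]
  }
  keep <- !is.na(cut) | !params$discardUntrimmed
  ins <- ifelse(is.na(cut), s, substr(s, 1L, cut - 1L))
  ## occasional 5' adapter carryover at the read start
  if (nzchar(params$adapter5)) {
    a5 <- params$adapter5
    for (k in seq(min(nchar(a5), max(nchar(ins))), 8L)) {
      suf <- substr(a5, nchar(a5) - k + 1L, nchar(a5))
      lead <- startsWith(ins, suf)
      if (any(lead)) ins[lead] <- substr(ins[lead], k + 1L, nchar(ins[lead]))
    }
  }
  keep <- keep & nchar(ins) >= params$minLen & nchar(ins) <= params$maxLen
  reads <- Biostrings::DNAStringSet(ins[keep])
  names(reads) <- names(readSeqs(raw))[keep]
  methods::new("SmallRNAReadSet", reads = reads,
               truthGene = raw@truthGene[keep],
               truthStart = raw@truthStart[keep], genotype = raw@genotype,
               seed = raw@seed, adapter3 = params$adapter3,
               adapter5 = params$adapter5)
}

#' Is a read a 22G RNA?
#'
#' Strict: exactly 22 nt with a 5' G. Relaxed (the counting default): 21-23
#' nt with a 5' G, tolerating the length heterogeneity of real libraries.
#'
#' @param reads character vector or \code{DNAStringSet} of insert sequences.
#' @param strict logical; use the strict definition.
#' @return Logical vector.
#' @export
is22G <- function(reads, strict = FALSE) {
  s <- as.character(reads)
  if (any(!nzchar(s))) stop("empty read sequence")
  w <- nchar(s)
  g <- substr(s, 1L, 1L) == "G"
  if (strict) w == 22L & g else w >= 21L & w <= 23L & g
}

#' Map reads to transcripts by exact full-length matching
#'
#' A bespoke exact-match aligner standing in for a short-read mapper at toy
#' scale: a hit is a full-length exact match of the read to either strand of
#' an annotated transcript. Reads matching n loci receive weight 1/n at each
#' (deterministic fractional multi-mapper handling). Orientation is recorded
#' relative to the annotated transcript, and \code{offset} is the 0-based
#' transcript coordinate of the leftmost template base the read covers.
#'
#' Library tallies for normalization are collected on the way: every mapped
#' read counts toward \code{totalMappers}; weight on sense rRNA hits
#' accumulates into \code{senseRRNA}; 18-26 nt reads whose hits all avoid
#' structural biotypes count toward \code{nonstructuralMappers}.
#'
#' @param reads a \linkS4class{SmallRNAReadSet} (cleaned inserts).
#' @param genome an \linkS4class{AnnotatedGenome}.
#' @return A \linkS4class{SirnaAlignments}.
#' @export
mapReads <- function(reads, genome) {
  seqs <- as.character(readSeqs(reads))
  if (length(seqs) &&
      any(grepl("[^ACGT]", seqs)))
    stop("reads contain characters outside {A,C,G,T}")
  tx <- transcriptSeqs(genome)
  mc <- S4Vectors::mcols(genes(genome))
  ntx <- length(tx)
  txlen <- BiocGenerics::width(tx)
  subject <- c(tx, Biostrings::reverseComplement(tx))
  cat_seq <- Biostrings::DNAString(
    paste(as.character(subject), collapse = "N"))
  offs <- cumsum(c(0L, BiocGenerics::width(subject)[-(2L * ntx)] + 1L))

  uniq <- unique(seqs)
  uhits <- vector("list", length(uniq))
  for (w in sort(unique(nchar(uniq)))) {
    idx <- which(nchar(uniq) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq[idx]))
    m <- Biostrings::matchPDict(pd, cat_seq)
    st <- Biostrings::startIndex(m)
    nz <- which(lengths(st) > 0L)
    for (j in nz) {
      sj <- st[[j]]
      subj <- findInterval(sj - 1L, offs)       # 1-based subject index
      within <- sj - offs[subj]                 # 1-based start in subject
      sense <- subj <= ntx
      g <- ifelse(sense, subj, subj - ntx)
      off0 <- ifelse(sense, within - 1L, txlen[g] - (within - 1L) - w)
      uhits[[idx[j]]] <- list(gene = g, off = as.integer(off0),
                              sense = sense)
    }
  }

  uidx <- match(seqs, uniq)
  nh <- vapply(uhits, function(h) if (is.null(h)) 0L else length(h$gene), 1L)
  per_read_hits <- nh[uidx]
  mapped <- per_read_hits > 0L

  rep_reads <- rep(seq_along(seqs), per_read_hits)
  ## expand unique-level hit lists to per-read rows
  gl <- lapply(uhits, function(h) if (is.null(h)) integer() else h$gene)
  ol <- lapply(uhits, function(h) if (is.null(h)) integer() else h$off)
  sl <- lapply(uhits, function(h) if (is.null(h)) logical() else h$sense)
  gene_v <- unlist(gl[uidx], use.names = FALSE)
  off_v <- unlist(ol[uidx], use.names = FALSE)
  sense_v <- unlist(sl[uidx], use.names = FALSE)
  weight_v <- 1 / per_read_hits[rep_reads]
  width_v <- nchar(seqs)[rep_reads]
  first_v <- substr(seqs, 1L, 1L)[rep_reads]

  hits <- S4Vectors::DataFrame(
    read_id = names(readSeqs(reads))[rep_reads],
    gene_id = mc$gene_id[gene_v],
    offset = off_v,
    orientation = ifelse(sense_v, "sense", "antisense"),
    weight = weight_v, width = width_v, first_base = first_v)

  total <- sum(mapped)
  is_rrna_hit <- mc$biotype[gene_v] == "rRNA" & sense_v
  sense_rrna <- sum(weight_v[is_rrna_hit])
  structural <- mc$biotype[gene_v] %in% STRUCTURAL_BIOTYPES
  has_struct <- logical(length(seqs))
  has_struct[rep_reads[structural]] <- TRUE
  widths <- nchar(seqs)
  nonstr <- sum(mapped & widths >= 18L & widths <= 26L & !has_struct)
  stats <- methods::new("NormalizationStats", totalMappers = total,
                        senseRRNA = sense_rrna,
                        nonstructuralMappers = nonstr)
  methods::new("SirnaAlignments", hits = hits, stats = stats)
}

#' Count weighted antisense reads per gene
#'
#' Sums antisense hit weights per gene (sense hits never count toward gene
#' totals), optionally restricted to 22G reads (relaxed definition: 21-23 nt
#' with 5' G). Two RPM columns are computed: \code{rpm} uses the
#' quantification denominator (total mappers minus sense rRNA reads),
#' \code{rpm_meta} the metagene denominator (nonstructural 18-26 nt
#' mappers). miRNA and 21U-RNA loci (and structural loci) are flagged
#' \code{excluded_biotype}; soma-specific coding genes are flagged
#' \code{soma_specific}. Per-base antisense coverage over each transcript
#' (full read span, rpm_meta scale) is retained for metagene profiling.
#'
#' @param aln a \linkS4class{SirnaAlignments}.
#' @param genome the matching \linkS4class{AnnotatedGenome}.
#' @param only22g restrict counting to relaxed 22G reads (default TRUE).
#' @param sample label stored with the table.
#' @return A \linkS4class{GeneCountTable}.
#' @export
countGenes <- function(aln, genome, only22g = TRUE, sample = "sample") {
  h <- hits(aln)
  stats <- normStats(aln)
  if (length(unique(h$read_id)) > stats@totalMappers)
    stop("normalization stats inconsistent with hits")
  mc <- S4Vectors::mcols(genes(genome))
  txlen <- BiocGenerics::width(genes(genome))
  dq <- denomQuant(stats)
  dm <- denomMeta(stats)
  if (dq <= 0) stop("quantification denominator must be positive")

  anti <- h[h$orientation == "antisense", ]
  if (only22g)
    anti <- anti[anti$width >= 21L & anti$width <= 23L &
                   anti$first_base == "G", ]
  gi <- match(anti$gene_id, mc$gene_id)
  raw <- numeric(nrow(mc))
  agg <- tapply(anti$weight, gi, sum)
  raw[as.integer(names(agg))] <- as.numeric(agg)

  rows_by_gene <- split(seq_along(gi), gi)
  cov <- S4Vectors::SimpleList(lapply(seq_len(nrow(mc)), function(i) {
    rows <- rows_by_gene[[as.character(i)]]
    if (is.null(rows)) return(numeric(txlen[i]))
    ir <- IRanges::IRanges(start = anti$offset[rows] + 1L,
                           width = anti$width[rows])
    v <- as.numeric(IRanges::coverage(ir, weight = anti$weight[rows],
                                      width = txlen[i]))
    v * 1e6 / max(dm, 1)
  }))
  names(cov) <- mc$gene_id

  counts <- S4Vectors::DataFrame(
    gene_id = mc$gene_id, biotype = mc$biotype,
    truth_class = mc$truth_class, raw = raw,
    rpm = raw * 1e6 / dq,
    rpm_meta = raw * 1e6 / max(dm, 1),
    excluded_biotype = mc$biotype %in%
      c("miRNA", "piRNA_21U", STRUCTURAL_BIOTYPES),
    soma_specific = mc$biotype == "soma_coding")
  methods::new("GeneCountTable", counts = counts, coverage = cov,
               stats = stats, sample = sample)
}

#' Write a count table as TSV
#'
#' @param table a \linkS4class{GeneCountTable}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeCountsTsv <- function(table, path) {
  df <- as.data.frame(geneCounts(table))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-base antisense coverage as bedGraph-style text
#'
#' One track per sample in transcript coordinates (gene_id as the sequence
#' name, 0-based half-open intervals, rpm_meta-scaled values); adjacent
#' equal-valued bases are merged into one interval.
#'
#' @param table a \linkS4class{GeneCountTable}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeCoverageBedGraph <- function(table, path) {
  cov <- coverageList(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", table@sample), con)
  for (g in names(cov)) {
    r <- S4Vectors::Rle(cov[[g]])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    val <- S4Vectors::runValue(r)
    keep <- val != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.6g", g, starts[keep], ends[keep],
                         val[keep]), con)
  }
  invisible(path)
}
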