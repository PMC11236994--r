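test_that("cleanReads trims adapters, strips carryover and length-filters", {
  p <- cleaningParams()
  insert <- "GACCATTGTACGGATTCGAGCT"            # 22 nt
  mk <- function(seqs) {
    r <- Biostrings::DNAStringSet(seqs)
    names(r) <- sprintf("r%02d", seq_along(seqs))
    methods::new("SmallRNAReadSet", reads = r,
                 truthGene = rep(NA_character_, length(seqs)),
                 truthStart = rep(NA_integer_, length(seqs)),
                 genotype = "unknown", seed = NA_integer_,
                 adapter3 = p$adapter3, adapter5 = p$adapter5)
  }
  raw <- mk(c(
    paste0(insert, p$adapter3),                       # full adapter
    paste0(insert, substr(p$adapter3, 1, 9)),         # partial adapter (>= 8)
    insert,                                           # no adapter: dropped
    paste0(substr(insert, 1, 10), p$adapter3),        # too short after trim
    paste0(substr(p$adapter5, nchar(p$adapter5) - 9, nchar(p$adapter5)),
           insert, p$adapter3)))                      # 5' carryover
  cleaned <- cleanReads(raw, p)
  s <- as.character(readSeqs(cleaned))
  expect_identical(unname(s), c(insert, insert, insert))
  expect_identical(names(readSeqs(cleaned)), c("r01", "r02", "r05"))

  keepAll <- cleanReads(raw, cleaningParams(discardUntrimmed = FALSE))
  expect_true("r03" %in% names(readSeqs(keepAll)))

  meta <- cleaningParams(preset = "meta")
  expect_identical(c(meta$minLen, meta$maxLen), c(18L, 26L))
  empty <- cleanReads(mk(character()), p)
  expect_length(readSeqs(empty), 0)
})

test_that("is22G applies strict and relaxed definitions", {
  reads <- c("GACCATTGTACGGATTCGAGCT",    # 22 nt G
             "AACCATTGTACGGATTCGAGCT",    # 22 nt non-G
             "GACCATTGTACGGATTCGAGC",     # 21 nt G
             "GACCATTGTACGGATTCGAGCTAA")  # 24 nt G
  expect_identical(is22G(reads, strict = TRUE), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(is22G(reads), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(is22G(c("G", "")), "empty")
})

test_that("mapReads records orientation and 0-based offsets correctly", {
  g <- tiny_genome()
  tx <- transcriptSeqs(g)
  t1 <- as.character(tx[[3]])
  gid <- names(tx)[3]
  sense <- substr(t1, 11, 32)
  anti <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(t1, 41, 62))))
  r <- Biostrings::DNAStringSet(c(sense, anti))
  names(r) <- c("s1", "a1")
  rs <- methods::new("SmallRNAReadSet", reads = r,
                     truthGene = rep(NA_character_, 2),
                     truthStart = rep(NA_integer_, 2), genotype = "unknown",
                     seed = NA_integer_, adapter3 = ADAPTER3_DEFAULT,
                     adapter5 = ADAPTER5_DEFAULT)
  h <- hits(mapReads(rs, g))
  hs <- h[h$read_id == "s1", ]
  ha <- h[h$read_id == "a1", ]
  expect_true(any(hs$gene_id == gid & hs$orientation == "sense" &
                    hs$offset == 10L))
  expect_true(any(ha$gene_id == gid & ha$orientation == "antisense" &
                    ha$offset == 40L))
})

test_that("multi-mapping reads receive fractional weights summing to one", {
  ## two identical transcripts: every read maps to both with weight 1/2
  chrom <- Biostrings::DNAStringSet(paste0(
    strrep("A", 10), "GGCATTCGATCCGTAAGGCTTCATCGATGCAA",
    strrep("A", 60), "GGCATTCGATCCGTAAGGCTTCATCGATGCAA", strrep("A", 10)))
  names(chrom) <- "chrT"
  gr <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(start = c(11L, 103L), width = 32L), strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = c("gA", "gB"), biotype = rep("germline_coding", 2),
    truth_class = c("NEUTRAL", "NEUTRAL"), base_rate = c(1, 1))
  g <- methods::new("AnnotatedGenome", chromosomes = chrom, genes = gr,
                    seed = 1L)
  read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GCATTCGATCCGTAAGGCTTCA")))
  r <- Biostrings::DNAStringSet(read)
  names(r) <- "m1"
  rs <- methods::new("SmallRNAReadSet", reads = r,
                     truthGene = NA_character_, truthStart = NA_integer_,
                     genotype = "unknown", seed = NA_integer_,
                     adapter3 = ADAPTER3_DEFAULT, adapter5 = ADAPTER5_DEFAULT)
  aln <- mapReads(rs, g)
  h <- hits(aln)
  expect_equal(nrow(h), 2L)
  expect_setequal(h$gene_id, c("gA", "gB"))
  expect_equal(h$weight, c(0.5, 0.5))
  expect_equal(sum(h$weight), as.numeric(normStats(aln)@totalMappers))
})

test_that("countGenes counts antisense 22G weight and flags exclusions", {
  lib <- tiny_wt_library()
  tab <- lib$table
  cc <- geneCounts(tab)
  h <- hits(lib$aln)
  anti22 <- h[h$orientation == "antisense" & h$width >= 21L &
                h$width <= 23L & h$first_base == "G", ]
  byGene <- tapply(anti22$weight, anti22$gene_id, sum)
  for (gid in names(byGene))
    expect_equal(cc$raw[cc$gene_id == gid], as.numeric(byGene[[gid]]))
  ## sense rRNA fragments never produce gene counts
  expect_true(all(cc$raw[cc$biotype == "rRNA"] == 0))
  expect_true(all(cc$excluded_biotype[cc$biotype %in%
    c("miRNA", "piRNA_21U", "rRNA", "tRNA", "snRNA", "snoRNA", "ncRNA")]))
  expect_true(all(cc$soma_specific == (cc$biotype == "soma_coding")))
  ## RPM columns are raw rescaled by the two denominators
  expect_equal(cc$rpm, cc$raw * 1e6 / denomQuant(tab))
  expect_equal(cc$rpm_meta, cc$raw * 1e6 / denomMeta(tab))
  ## coverage sums: total covered bases = sum(weight x width) on 22G hits
  gi <- match(anti22$gene_id, cc$gene_id)
  for (i in unique(gi)[1:5]) {
    rows <- which(gi == i)
    expect_equal(sum(coverageList(tab)[[i]]) * denomMeta(tab) / 1e6,
                 sum(anti22$weight[rows] * anti22$width[rows]))
  }
})

test_that("count table and coverage serialise to readable text", {
  lib <- tiny_wt_library()
  tsv <- tempfile(fileext = ".tsv")
  writeCountsTsv(lib$table, tsv)
  df <- read.delim(tsv)
  expect_identical(df$gene_id, geneCounts(lib$table)$gene_id)
  expect_equal(df$rpm, geneCounts(lib$table)$rpm)

  bg <- tempfile(fileext = ".bedGraph")
  writeCoverageBedGraph(lib$table, bg)
  lines <- readLines(bg)
  expect_match(lines[1], "^track type=bedGraph")
  body <- read.delim(bg, skip = 1, header = FALSE,
                     col.names = c("gene", "start", "end", "value"))
  expect_true(all(body$end > body$start))
  ## intervals reconstruct the stored coverage for one covered gene
  g1 <- body$gene[1]
  v <- numeric(length(coverageList(lib$table)[[g1]]))
  for (r in which(body$gene == g1))
    v[(body$start[r] + 1):body$end[r]] <- body$value[r]
  expect_equal(v, coverageList(lib$table)[[g1]], tolerance = 1e-5)
})
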