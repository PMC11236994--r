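test_that("genome generation is deterministic and respects the config", {
  cfg <- tiny_genome_config()
  g1 <- makeGenome(cfg)
  g2 <- makeGenome(cfg)
  expect_identical(as.character(chromosomes(g1)),
                   as.character(chromosomes(g2)))
  expect_identical(S4Vectors::mcols(genes(g1)),
                   S4Vectors::mcols(genes(g2)))

  mc <- S4Vectors::mcols(genes(g1))
  expect_equal(sum(mc$biotype == "germline_coding"), 20L)
  expect_equal(as.integer(table(mc$truth_class)[c("E", "M", "NEUTRAL",
                                                  "UP")]),
               c(6L, 6L, 6L, 2L))
  expect_true(all(mc$base_rate[mc$biotype %in%
                                 c("germline_coding", "soma_coding")] > 0))
  expect_true(all(mc$base_rate[!mc$biotype %in%
                                 c("germline_coding", "soma_coding")] == 0))

  ## no overlaps and at least minSpacing between neighbours
  gr <- genes(g1)
  expect_true(all(diff(BiocGenerics::start(gr)) > 0))
  gaps <- BiocGenerics::start(gr)[-1] -
    BiocGenerics::end(gr)[-length(gr)] - 1L
  expect_true(all(gaps >= cfg$minSpacing))
})

test_that("invalid genome configs are rejected with clear messages", {
  expect_error(genomeConfig(nGermlineGenes = 10L,
                            classCounts = c(E = 3L, M = 3L, UP = 2L,
                                            NEUTRAL = 3L)),
               "sum to nGermlineGenes")
  expect_error(genomeConfig(geneLengthRange = c(50L, 200L)), ">= 100")
  expect_error(genomeConfig(chromLength = 1000L), "cannot fit")
})

test_that("transcript sequences are strand-aware", {
  g <- tiny_genome()
  gr <- genes(g)
  tx <- transcriptSeqs(g)
  chrom <- chromosomes(g)[["chrT"]]
  i <- which(as.character(BiocGenerics::strand(gr)) == "+")[1]
  j <- which(as.character(BiocGenerics::strand(gr)) == "-")[1]
  plus <- as.character(Biostrings::subseq(chrom, BiocGenerics::start(gr)[i],
                                          BiocGenerics::end(gr)[i]))
  minus <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(chrom, BiocGenerics::start(gr)[j],
                       BiocGenerics::end(gr)[j])))
  expect_identical(as.character(tx[[i]]), plus)
  expect_identical(as.character(tx[[j]]), minus)
})

test_that("genome FASTA/GFF3 round trip preserves annotation", {
  g <- tiny_genome()
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  writeGenome(g, fa, gff)
  g2 <- readAnnotatedGenome(fa, gff)
  expect_identical(as.character(chromosomes(g2)),
                   as.character(chromosomes(g)))
  m1 <- S4Vectors::mcols(genes(g))
  m2 <- S4Vectors::mcols(genes(g2))
  expect_identical(m2$gene_id, m1$gene_id)
  expect_identical(m2$biotype, m1$biotype)
  expect_identical(m2$truth_class, m1$truth_class)
  expect_equal(m2$base_rate, m1$base_rate, tolerance = 1e-5)
  expect_identical(BiocGenerics::start(genes(g2)),
                   BiocGenerics::start(genes(g)))
  expect_identical(as.character(BiocGenerics::strand(genes(g2))),
                   as.character(BiocGenerics::strand(genes(g))))
})

test_that("simulated reads are exact antisense substrings with recorded truth", {
  lib <- tiny_wt_library()
  g <- lib$genome
  rs <- lib$reads
  tx <- transcriptSeqs(g)
  mc <- S4Vectors::mcols(genes(g))
  seqs <- unname(as.character(readSeqs(rs)))
  tg <- readTruth(rs)$truth_gene
  ts <- readTruth(rs)$truth_start

  coding <- tg %in% mc$gene_id[mc$biotype %in%
                                 c("germline_coding", "soma_coding")]
  idx <- sample(which(coding), 200)
  for (i in idx) {
    t <- tx[[tg[i]]]
    frag <- Biostrings::subseq(t, start = ts[i] + 1L,
                               width = nchar(seqs[i]))
    expect_identical(
      as.character(Biostrings::reverseComplement(frag)), seqs[i])
  }
  ## sense rRNA fragments are forward substrings
  rrna <- which(tg %in% mc$gene_id[mc$biotype == "rRNA"])
  for (i in rrna[seq_len(min(50, length(rrna)))]) {
    frag <- Biostrings::subseq(tx[[tg[i]]], start = ts[i] + 1L,
                               width = nchar(seqs[i]))
    expect_identical(as.character(frag), seqs[i])
  }
})

test_that("read lengths, G starts and contamination match the configured law", {
  lib <- tiny_wt_library()
  rs <- lib$reads
  g <- lib$genome
  mc <- S4Vectors::mcols(genes(g))
  seqs <- as.character(readSeqs(rs))
  tg <- readTruth(rs)$truth_gene
  n <- length(seqs)
  coding <- tg %in% mc$gene_id[mc$biotype %in%
                                 c("germline_coding", "soma_coding")]

  ## length law on coding reads: each probability within 3 sigma
  w <- nchar(seqs[coding])
  nc <- sum(coding)
  for (l in names(DEFAULT_LENGTH_PROBS)) {
    p <- DEFAULT_LENGTH_PROBS[[l]]
    expect_lt(abs(mean(w == as.integer(l)) - p),
              3 * sqrt(p * (1 - p) / nc) + 1e-9)
  }
  ## G-start fraction near pG = 0.9 (some non-G draws start with G by chance,
  ## so the observed fraction can only exceed pG)
  gfrac <- mean(substr(seqs[coding], 1, 1) == "G")
  expect_gte(gfrac, 0.9 - 3 * sqrt(0.9 * 0.1 / nc))
  expect_lte(gfrac, 0.9 + 0.25 * 0.1 + 3 * sqrt(0.9 * 0.1 / nc))

  ## contamination fraction within 3 sigma of 0.05
  rrna <- mean(tg %in% mc$gene_id[mc$biotype == "rRNA"])
  expect_lt(abs(rrna - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("forcing pG = 1 yields only G-starting coding reads", {
  g <- tiny_genome()
  rs <- simulateSirnaLibrary(g, genotypeModel("WT"), depth = 2000,
                             seed = 7L, pG = 1, contamination = 0,
                             mirnaFraction = 0, piFraction = 0)
  expect_true(all(substr(as.character(readSeqs(rs)), 1, 1) == "G"))
})

test_that("genotype models compose multiplicatively and shift read shares", {
  a <- genotypeModel("egc1")
  b <- genotypeModel("mut16")
  ab <- composeModels(a, b)
  expect_equal(ab@delta5, a@delta5 * b@delta5)
  expect_equal(ab@delta3, a@delta3 * b@delta3)
  expect_equal(ab@deltaM, a@deltaM * b@deltaM)
  expect_equal(ab@deltaUp, a@deltaUp * b@deltaUp)
  preset <- genotypeModel("egc1_mut16")
  expect_equal(ab@delta5, preset@delta5)
  expect_equal(ab@deltaM, preset@deltaM)

  g <- tiny_genome()
  mc <- S4Vectors::mcols(genes(g))
  shareWT <- expectedReadShare(g, genotypeModel("WT"))
  shareE <- expectedReadShare(g, a)
  isE <- !is.na(mc$truth_class) & mc$truth_class == "E"
  ## E-class genes lose their 5' window (0.8 x 0.1 + 0.2 x 1 = 0.28 of rate)
  expect_equal(shareE$rate[isE] / shareWT$rate[isE],
               rep(0.28, sum(isE)))
  expect_equal(sum(shareE$share), 1)
})

test_that("model-implied truth sets match the per-class multipliers", {
  g <- tiny_genome()
  mc <- S4Vectors::mcols(genes(g))
  cls <- function(k) mc$gene_id[!is.na(mc$truth_class) & mc$truth_class == k]
  expect_setequal(truthContrastSet(g, genotypeModel("egc1")), cls("E"))
  expect_setequal(truthContrastSet(g, genotypeModel("egc1"),
                                   direction = "up"), cls("UP"))
  ## Mutator loss takes down both M- and UP-class genes
  expect_setequal(truthContrastSet(g, genotypeModel("mut16")),
                  c(cls("M"), cls("UP")))
  expect_length(truthContrastSet(g, genotypeModel("WT")), 0)
})

test_that("FASTQ round trip returns the adapter-bearing reads", {
  g <- tiny_genome()
  rs <- simulateSirnaLibrary(g, genotypeModel("WT"), depth = 500, seed = 3L)
  fq <- tempfile(fileext = ".fq")
  writeFastq(rs, fq)
  back <- readFastq(fq)
  expect_identical(unname(as.character(readSeqs(back))),
                   paste0(unname(as.character(readSeqs(rs))), rs@adapter3))
  cleaned <- cleanReads(back, cleaningParams())
  kept <- names(readSeqs(cleaned))
  orig <- as.character(readSeqs(rs))
  expect_identical(unname(as.character(readSeqs(cleaned))),
                   unname(orig[kept]))
})

test_that("deriveSeed is deterministic, stage-sensitive and in range", {
  expect_identical(deriveSeed(1L, "genome"), deriveSeed(1L, "genome"))
  expect_false(deriveSeed(1L, "reads:WT") == deriveSeed(1L, "reads:egc1_a"))
  seeds <- vapply(c("a", "b", "genome", "reads:WT", "imaging"),
                  function(s) deriveSeed(123456789L, s), 1L)
  expect_true(all(seeds >= 0 & seeds < 2^31 - 1))
})
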