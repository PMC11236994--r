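# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

## A small genome for unit tests: 20 germline genes on a 60 kb chromosome.
tiny_genome_config <- function(seed = 11L) {
  genomeConfig(nGermlineGenes = 20L,
               classCounts = c(E = 6L, M = 6L, UP = 2L, NEUTRAL = 6L),
               nSomaGenes = 2L,
               nStructural = c(rRNA = 1L, tRNA = 1L, snRNA = 1L,
                               snoRNA = 1L, ncRNA = 1L),
               nMirna = 1L, n21u = 1L,
               geneLengthRange = c(300L, 800L),
               chromLength = 60000L, seed = seed)
}

tiny_genome <- function() {
  fixture("tiny_genome", function() makeGenome(tiny_genome_config()))
}

## A mapped-and-counted wild-type library on the tiny genome.
tiny_wt_library <- function() {
  fixture("tiny_wt_library", function() {
    g <- tiny_genome()
    rs <- simulateSirnaLibrary(g, genotypeModel("WT"), depth = 2e4,
                               seed = 101L)
    aln <- mapReads(rs, g)
    list(genome = g, reads = rs, aln = aln,
         table = countGenes(aln, g, sample = "WT"))
  })
}

## The full study-scale pipeline (default panel, default genome, seed 1):
## shared by the class-recovery and positional-signature checks.
study_pipeline <- function() {
  fixture("study_pipeline", function() runPipeline(runConfig(seed = 1L)))
}

## Brute-force exact mapper used as an oracle against mapReads().
naive_map <- function(seqs, tx) {
  gene_ids <- names(tx)
  txc <- as.character(tx)
  rows <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    w <- nchar(s)
    for (g in seq_along(txc)) {
      t <- txc[g]
      L <- nchar(t)
      if (L < w) next
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(t)))
      for (j in seq_len(L - w + 1L)) {
        if (substr(t, j, j + w - 1L) == s)
          rows[[length(rows) + 1L]] <- data.frame(
            read = i, gene_id = gene_ids[g], offset = j - 1L,
            orientation = "sense")
        if (substr(rc, j, j + w - 1L) == s)
          rows[[length(rows) + 1L]] <- data.frame(
            read = i, gene_id = gene_ids[g], offset = L - (j - 1L) - w,
            orientation = "antisense")
      }
    }
  }
  if (!length(rows))
    return(data.frame(read = integer(), gene_id = character(),
                      offset = integer(), orientation = character()))
  do.call(rbind, rows)
}
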