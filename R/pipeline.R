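#' Configuration for an end-to-end simulated study
#'
#' Bundles the genome configuration, the genotype panel (wild type, two
#' alleles each of the E-granule factor mutants, the RdRP mutant, the
#' Mutator mutant and both double mutants), sequencing depths, contrast
#' thresholds and the master seed.
#'
#' @param genome a \code{\link{genomeConfig}}.
#' @param depth reads per library (default 1e5).
#' @param seed master seed (mandatory; fanned out per stage via
#'   \code{\link{deriveSeed}}).
#' @param contrast \code{\link{contrastParams}} for depletion calls.
#' @param upContrast \code{\link{contrastParams}} for gain calls.
#' @param nBins metagene bins (default 100).
#' @param pG,contamination passed to \code{\link{simulateSirnaLibrary}}.
#' @param models named list of \linkS4class{GenotypeModel}s keyed by library
#'   name; the default panel simulates WT once, egc1 and elli1 twice
#'   (allele a/b, same model, independent seeds), and ego1, mut16 and the
#'   doubles once each.
#' @return A list of class \code{run_config}.
#' @export
runConfig <- function(genome = genomeConfig(), depth = 1e5, seed = 1L,
                      contrast = contrastParams(),
                      upContrast = contrastParams(direction = "up"),
                      nBins = 100L, pG = 0.9, contamination = 0.05,
                      models = NULL) {
  if (is.null(models)) {
    models <- list(
      WT = genotypeModel("WT"),
      egc1_a = genotypeModel("egc1"), egc1_b = genotypeModel("egc1"),
      elli1_a = genotypeModel("elli1"), elli1_b = genotypeModel("elli1"),
      ego1 = genotypeModel("ego1"), mut16 = genotypeModel("mut16"),
      egc1_mut16 = genotypeModel("egc1_mut16"),
      elli1_mut16 = genotypeModel("elli1_mut16"))
  }
  structure(list(genome = genome, depth = depth, seed = seed,
                 contrast = contrast, upContrast = upContrast,
                 nBins = as.integer(nBins), pG = pG,
                 contamination = contamination, models = models),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Returns a character vector of violations (empty when valid); never
#' mutates the config.
#'
#' @param config a \code{\link{runConfig}}.
#' @return Character vector of violation messages.
#' @export
validateConfig <- function(config) {
  v <- character()
  if (is.null(config$seed) || is.na(config$seed))
    v <- c(v, "seed: a master seed is mandatory")
  if (!is.null(config$contrast) && config$contrast$fcCutoff <= 1)
    v <- c(v, "contrast$fcCutoff: must be > 1")
  if (is.null(config$depth) || config$depth <= 0)
    v <- c(v, "depth: must be > 0")
  ok <- tryCatch({ validateGenomeConfig(config$genome); TRUE },
                 error = function(e) e$message)
  if (!isTRUE(ok)) v <- c(v, paste0("genome: ", ok))
  need <- c("WT", "egc1_a", "egc1_b", "elli1_a", "elli1_b", "ego1", "mut16",
            "egc1_mut16", "elli1_mut16")
  missing <- setdiff(need, names(config$models))
  if (length(missing))
    v <- c(v, paste0("models: undefined genotype libraries: ",
                     paste(missing, collapse = ", ")))
  bad <- names(config$models)[!vapply(config$models,
    function(m) methods::is(m, "GenotypeModel"), TRUE)]
  if (length(bad))
    v <- c(v, paste0("models: not GenotypeModel objects: ",
                     paste(bad, collapse = ", ")))
  v
}

#' Run the full simulate / quantify / classify / profile pipeline
#'
#' Generates the genome, simulates one library per panel entry, quantifies
#' antisense 22G RNAs, derives the allele-consensus EGC-1/ELLI-1 target
#' sets and the E/M/UP classes, computes overlap statistics, truth-vs-call
#' confusion summaries, class metaprofiles and per-gene positional-bias
#' calls. Deterministic for a fixed config.
#'
#' @param config a \code{\link{runConfig}}; must validate cleanly.
#' @param outDir optional directory for intermediates (count TSVs, class
#'   TSV, report JSON).
#' @param verbose print per-stage progress.
#' @return A list report (also written as JSON when \code{outDir} is given):
#'   set sizes and overlaps, recovery metrics, metaprofiles, positional-bias
#'   tables and provenance.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL,
                        verbose = FALSE) {
  viol <- validateConfig(config)
  if (length(viol))
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  gcfg <- config$genome
  gcfg$seed <- deriveSeed(config$seed, "genome")
  genome <- makeGenome(gcfg)
  say("[genome] %d genes", length(genes(genome)))

  tables <- list()
  for (lib in names(config$models)) {
    rs <- simulateSirnaLibrary(genome, config$models[[lib]], config$depth,
                               seed = deriveSeed(config$seed,
                                                 paste0("reads:", lib)),
                               pG = config$pG,
                               contamination = config$contamination)
    aln <- mapReads(rs, genome)
    tables[[lib]] <- countGenes(aln, genome, sample = lib)
    say("[quant:%s] %d mapped reads", lib,
        as.integer(normStats(aln)@totalMappers))
  }

  down <- config$contrast
  up <- config$upContrast
  dep <- function(lib) depletedGenes(tables[[lib]], tables$WT, down)
  gain <- function(lib) depletedGenes(tables[[lib]], tables$WT, up)
  egc1T <- consensusTargets(dep("egc1_a"), dep("egc1_b"))
  elli1T <- consensusTargets(dep("elli1_a"), dep("elli1_b"))
  mut16T <- dep("mut16")
  ego1T <- dep("ego1")
  upE <- consensusTargets(gain("egc1_a"), gain("egc1_b"))
  upL <- consensusTargets(gain("elli1_a"), gain("elli1_b"))
  upDouble <- union(gain("egc1_mut16"), gain("elli1_mut16"))
  universe <- eligible_genes(tables$WT)
  classes <- defineClasses(egc1T, elli1T, mut16T, upE, upL,
                           universe = universe)
  say("[classify] E=%d M=%d UP=%d", length(classSet(classes, "e_class")),
      length(classSet(classes, "m_class")),
      length(classSet(classes, "up_class")))

  mc <- S4Vectors::mcols(genes(genome))
  truth <- function(cl) mc$gene_id[!is.na(mc$truth_class) &
                                     mc$truth_class == cl]
  recov <- function(called, truthSet) {
    tp <- length(intersect(called, truthSet))
    prec <- if (length(called)) tp / length(called) else NA_real_
    rec <- if (length(truthSet)) tp / length(truthSet) else NA_real_
    list(precision = prec, recall = rec,
         f1 = if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
              else 2 * prec * rec / (prec + rec))
  }

  eT <- truth("E"); mT <- truth("M")
  ## model-implied answer keys: the mut16 truth set includes UP-class genes,
  ## which are Mutator-derived and deplete when Mutator foci are lost
  eKey <- truthContrastSet(genome, config$models$egc1_a, down$fcCutoff)
  mKey <- truthContrastSet(genome, config$models$mut16, down$fcCutoff)
  uKey <- truthContrastSet(genome, config$models$egc1_a, down$fcCutoff,
                           direction = "up")
  profiles <- list()
  for (lib in c("WT", "egc1_a", "elli1_a", "ego1", "mut16", "egc1_mut16")) {
    for (cl in c("E", "M")) {
      ids <- if (cl == "E") eT else mT
      profiles[[paste(lib, cl, sep = ":")]] <-
        profileBins(metageneProfile(tables[[lib]], ids, config$nBins))
    }
  }
  biasTabs <- list(
    egc1_E = positionalBiasTable(tables$egc1_a, tables$WT, eT, config$nBins),
    ego1_E = positionalBiasTable(tables$ego1, tables$WT, eT, config$nBins),
    double_E = positionalBiasTable(tables$egc1_mut16, tables$WT, eT,
                                   config$nBins),
    double_M = positionalBiasTable(tables$egc1_mut16, tables$WT, mT,
                                   config$nBins))

  report <- list(
    provenance = list(seed = config$seed, depth = config$depth,
                      n_genes = length(genes(genome)),
                      elapsed_s = round(as.numeric(Sys.time() - t0,
                                                   units = "secs"), 1)),
    set_sizes = list(
      egc1_targets = length(egc1T), elli1_targets = length(elli1T),
      e_class = length(classSet(classes, "e_class")),
      m_class = length(mut16T), ego1_targets = length(ego1T),
      up_class = length(classSet(classes, "up_class")),
      up_in_double = length(upDouble)),
    overlaps = list(
      egc1_vs_elli1 = overlapStats(egc1T, elli1T),
      e_vs_m = overlapStats(classSet(classes, "e_class"), mut16T),
      up_vs_m = overlapStats(classSet(classes, "up_class"), mut16T),
      e_vs_ego1 = overlapStats(classSet(classes, "e_class"), ego1T)),
    recovery = list(
      e_class = recov(classSet(classes, "e_class"), eKey),
      m_class = recov(mut16T, mKey),
      up_class = recov(classSet(classes, "up_class"), uKey)),
    positional = lapply(biasTabs, function(tb) list(
      frac_five_prime_depleted = mean(tb$label == "five_prime_depleted"),
      frac_uniform_depleted = mean(tb$label == "uniform_depleted"),
      mean_fc5 = mean(tb$fc5, na.rm = TRUE),
      mean_fc3 = mean(tb$fc3, na.rm = TRUE))),
    metaprofiles = profiles)

  result <- list(report = report, classes = classes, tables = tables,
                 genome = genome, bias = biasTabs)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (lib in names(tables))
      writeCountsTsv(tables[[lib]], file.path(outDir,
                                              paste0("counts_", lib, ".tsv")))
    utils::write.table(as.data.frame(memberships(classes)),
                       file.path(outDir, "classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(result)
}
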