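# Orchestration: config-driven end-to-end runs (classify -> three engines ->
# consensus -> validation), per-stage logging and output files, a run
# manifest with input hashes and stage seeds, and the random-gene-background
# companion run.

.pipelineDefaults <- function() {
  list(alpha = 0.05, fold = 2, fraction = 0.70, contrast = "N_vs_TL",
       discovery = list(nMotifs = 4, widths = c(8, 10, 12), maxWidth = 15,
                        nStarts = 12, maxIter = 40, tol = 1e-3,
                        nShuffles = 20),
       tcs = list(universe = "library", subsetSize = 5, nIterations = 200,
                  k = 8, minPromoters = 3, threshold = 0.8),
       affinity = list(cutoffGrid = c(5, 10, 20, 50, 100, 200)),
       consensus = list(minOverlap = 4, threshold = 0.75),
       seeds = list(discovery = 11, tcs = 12, background = 13, null = 14))
}

.mergeConfig <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], override[[nm]])
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

.stage <- function(name, log, expr) {
  res <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  res
}

.logLine <- function(lines, stage, event, ...) {
  kv <- c(...)
  msg <- paste0(stage, "\t", event,
                if (length(kv)) paste0("\t", paste(names(kv), kv, sep = "=",
                                                   collapse = "\t")) else "")
  c(lines, msg)
}

#' Run the full classification-to-validation pipeline
#'
#' Stages, in workflow order: read inputs; classify probes into phenotypes;
#' build the test gene set (symbol-collapsed pro-inflammatory genes by
#' default); run the three motif engines on the test promoters (de novo
#' discovery mapped to library accessions; TCS with the library as motif
#' universe by default, response `log2(TL/NL)`; affinity association over
#' all promoters with specificity `log2(NL/N)`); retain the top fraction per
#' engine; intersect; validate against the curated target lists. Each
#' stage's counts are logged and all outputs are written under `outDir`
#' when given.
#'
#' @param inputs either a bundle directory (as written by [generateBundle()])
#'   or a named list with paths `expression`, `promoters`, `library`,
#'   `targets` — or pre-loaded objects `se`, `promoters`, `library`,
#'   `associations`.
#' @param config named list of parameter overrides; see
#'   `MotifTriad:::.pipelineDefaults()` for the full set (alpha, fold,
#'   fraction, contrast, per-engine settings, named stage seeds).
#' @param outDir optional output directory for TSV/JSON artifacts.
#' @param geneSet which phenotype class drives the motif analysis
#'   (`"pro"` or `"anti"`).
#' @return list of class `PipelineRun` with the classification
#'   (`phenotypes`), engine tables (`discovery`, `tcs`, `affinity`), the
#'   retained sets (`retained`), `consensus`, `validation`, the resolved
#'   `config`, inputs, logs and output paths.
#' @export
runPipeline <- function(inputs, config = list(), outDir = NULL,
                        geneSet = c("pro", "anti")) {
  geneSet <- match.arg(geneSet)
  cfg <- .mergeConfig(.pipelineDefaults(), config)
  log <- character()

  # ---- stage: inputs
  inp <- .stage("inputs", log, {
    if (is.character(inputs) && length(inputs) == 1L) {
      inputs <- list(expression = file.path(inputs, "expression.tsv"),
                     promoters = file.path(inputs, "promoters.fasta"),
                     library = file.path(inputs, "library.transfac"),
                     targets = file.path(inputs, "targets.tsv"))
    }
    need <- c("expression", "promoters", "library", "targets")
    if (all(c("se", "promoters", "library", "associations") %in%
            names(inputs))) {
      inputs
    } else {
      miss <- need[!vapply(need, function(f)
        !is.null(inputs[[f]]) && file.exists(inputs[[f]]), logical(1))]
      if (length(miss))
        stop("missing input file(s) for: ", paste(miss, collapse = ", "))
      list(se = readExpressionMatrix(inputs$expression),
           promoters = readPromoters(inputs$promoters),
           library = readPWMLibrary(inputs$library),
           associations = readTargetList(inputs$targets),
           paths = inputs)
    }
  })
  se <- inp$se; promoters <- inp$promoters
  library <- inp$library; associations <- inp$associations
  log <- .logLine(log, "inputs", "loaded", probes = nrow(se),
                  promoters = length(promoters),
                  matrices = length(library))

  # ---- stage: classify
  pheno <- .stage("classify", log,
    classifyGenes(se, alpha = cfg$alpha, contrast = cfg$contrast))
  log <- .logLine(log, "classify", "done",
                  pro_probes = length(pheno$proProbes),
                  pro_genes = length(pheno$proGenes),
                  anti_probes = length(pheno$antiProbes),
                  anti_genes = length(pheno$antiGenes))

  testGenes <- if (geneSet == "pro") pheno$proGenes else pheno$antiGenes
  promKey <- toupper(names(promoters))
  testProm <- promoters[match(toupper(testGenes), promKey)]
  testProm <- testProm[!is.na(names(testProm))]
  if (length(testProm) < 2L)
    stop("stage 'gene_set' failed: fewer than 2 ", geneSet,
         " genes with promoters")
  g <- collapseToGenes(se)
  gav <- conditionAverages(g, c("N", "NL", "TL"))
  gkey <- toupper(rowData(g)$gene_symbol)
  eps <- .Machine$double.eps
  respAll <- setNames(log2(pmax(gav[, "TL"], eps) /
                           pmax(gav[, "NL"], eps)), gkey)
  specAll <- setNames(log2(pmax(gav[, "NL"], eps) /
                           pmax(gav[, "N"], eps)), gkey)
  response <- respAll[toupper(names(testProm))]
  log <- .logLine(log, "gene_set", "selected", genes = length(testProm))

  # ---- stage: engines
  disc <- .stage("discovery", log,
    discoverMotifs(testProm, nMotifs = cfg$discovery$nMotifs,
                   widths = cfg$discovery$widths,
                   maxWidth = cfg$discovery$maxWidth,
                   seed = cfg$seeds$discovery,
                   nStarts = cfg$discovery$nStarts,
                   maxIter = cfg$discovery$maxIter,
                   tol = cfg$discovery$tol,
                   nShuffles = cfg$discovery$nShuffles))
  discMapped <- mapDiscoveryToLibrary(disc, library,
                                      minOverlap = cfg$consensus$minOverlap,
                                      threshold = cfg$consensus$threshold)
  log <- .logLine(log, "discovery", "done", motifs = length(disc),
                  mapped = sum(!is.na(discMapped$accession)))

  tcsUniverse <- if (identical(cfg$tcs$universe, "library")) library
    else wordUniverse(testProm, k = cfg$tcs$k,
                      minPromoters = cfg$tcs$minPromoters)
  tcsTab <- .stage("tcs", log,
    runTCS(testProm, response, motifUniverse = tcsUniverse,
           subsetSize = min(cfg$tcs$subsetSize, length(tcsUniverse)),
           nIterations = cfg$tcs$nIterations, seed = cfg$seeds$tcs,
           threshold = cfg$tcs$threshold))
  log <- .logLine(log, "tcs", "done", motifs = nrow(tcsTab))

  spec <- specAll[promKey]
  names(spec) <- names(promoters)
  affTab <- .stage("affinity", log,
    associateLibrary(library, promoters, spec,
                     cutoffGrid = cfg$affinity$cutoffGrid))
  log <- .logLine(log, "affinity", "done", matrices = nrow(affTab))

  # ---- stage: consensus
  retained <- list(
    discovery = topFraction(discMapped, cfg$fraction, "lower_better"),
    tcs = topFraction(data.frame(accession = tcsTab$motif,
                                 score = tcsTab$tcs,
                                 stringsAsFactors = FALSE),
                      cfg$fraction, "higher_better"),
    affinity = topFraction(data.frame(accession = affTab$accession,
                                      score = affTab$best_p,
                                      stringsAsFactors = FALSE),
                           cfg$fraction, "lower_better"))
  consensus <- .stage("consensus", log,
    intersectEngines(retained$discovery, retained$tcs, retained$affinity,
                     library = library))
  log <- .logLine(log, "consensus", "done",
                  retained_discovery = nrow(retained$discovery),
                  retained_tcs = nrow(retained$tcs),
                  retained_affinity = nrow(retained$affinity),
                  consensus = nrow(consensus))

  # ---- stage: validation
  validation <- .stage("validate", log,
    validateTargets(se, associations, seed = cfg$seeds$null,
                    fold = cfg$fold))
  log <- .logLine(log, "validate", "done",
                  signature = validation$signature_size,
                  overlap = validation$overlap_count,
                  pattern_pass = validation$pattern_pass_count)

  run <- structure(list(
    phenotypes = pheno, discovery = disc, discoveryMapped = discMapped,
    tcs = tcsTab, affinity = affTab, retained = retained,
    consensus = consensus, validation = validation, config = cfg,
    geneSet = geneSet, testGenes = names(testProm),
    inputs = list(se = se, promoters = promoters, library = library,
                  associations = associations,
                  paths = inp$paths), response = response,
    specificity = spec, log = log), class = "PipelineRun")
  if (!is.null(outDir)) .writeRunOutputs(run, outDir)
  run
}

.writeRunOutputs <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$phenotypes$calls, "phenotype_calls.tsv")
  wt(run$discoveryMapped, "discovery_motifs.tsv")
  wt(run$tcs, "tcs.tsv")
  wt(run$affinity, "affinity.tsv")
  wt(run$consensus, "consensus.tsv")
  for (d in run$discovery)
    writeMotifTable(motifPWM(d), file.path(
      outDir, paste0(accession(motifPWM(d)), ".tsv")))
  writeValidationReport(run$validation, file.path(outDir, "validation.json"))
  writeLines(run$log, file.path(outDir, "run.log"))
  cfg <- run$config
  manifest <- list(config = cfg,
                   gene_set = run$geneSet,
                   n_test_genes = length(run$testGenes),
                   input_md5 = if (!is.null(run$inputs$paths))
                     as.list(tools::md5sum(unlist(run$inputs$paths)))
                   else NULL)
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(outDir)
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat("PipelineRun (", x$geneSet, " gene set, ",
      length(x$testGenes), " genes)\n", sep = "")
  cat("  consensus accessions:",
      if (nrow(x$consensus)) paste(x$consensus$accession, collapse = ", ")
      else "(none)", "\n")
  cat("  validation overlap:", x$validation$overlap_count, "genes\n")
  invisible(x)
}

#' Random-gene background companion run
#'
#' Samples `nRandomGenes` genes (without replacement) from the probes that
#' the classification left unclassified, assigns them uniform random
#' expression responses within the range of the test genes' responses, runs
#' the three engines under the test run's configuration, applies the same
#' top-fraction selection, and builds the test-vs-random contrast table for
#' the test run's consensus motifs.
#'
#' @param run a `PipelineRun` from [runPipeline()].
#' @param nRandomGenes size of the random gene set (default: size of the
#'   test set; must be >= 2).
#' @param seed seed for the gene sampling and the random response (default:
#'   the run config's `background` seed).
#' @return list with `randomGenes`, engine tables, `retained`, and
#'   `contrast` (from [contrastTestVsRandom()]).
#' @export
runRandomBackground <- function(run, nRandomGenes = NULL, seed = NULL) {
  stopifnot(inherits(run, "PipelineRun"))
  cfg <- run$config
  if (is.null(seed)) seed <- cfg$seeds$background
  if (is.null(nRandomGenes)) nRandomGenes <- length(run$testGenes)
  if (nRandomGenes < 2L) stop("nRandomGenes must be >= 2")
  promoters <- run$inputs$promoters
  calls <- run$phenotypes$calls
  unclassified <- toupper(calls$gene_symbol[calls$label == "unclassified"])
  pool <- names(promoters)[toupper(names(promoters)) %in% unclassified]
  if (length(pool) < nRandomGenes)
    stop("unclassified pool (", length(pool),
         ") smaller than nRandomGenes (", nRandomGenes, ")")
  randomGenes <- .withSeed(.deriveSeed(seed, 1L),
                           sort(sample(pool, nRandomGenes)))
  randProm <- promoters[randomGenes]
  resp <- randomResponse(min(run$response), max(run$response),
                         nRandomGenes, seed = .deriveSeed(seed, 2L))
  names(resp) <- randomGenes

  disc <- discoverMotifs(randProm, nMotifs = cfg$discovery$nMotifs,
                         widths = cfg$discovery$widths,
                         maxWidth = cfg$discovery$maxWidth,
                         seed = cfg$seeds$discovery,
                         nStarts = cfg$discovery$nStarts,
                         maxIter = cfg$discovery$maxIter,
                         tol = cfg$discovery$tol,
                         nShuffles = cfg$discovery$nShuffles)
  library <- run$inputs$library
  discMapped <- mapDiscoveryToLibrary(disc, library,
                                      minOverlap = cfg$consensus$minOverlap,
                                      threshold = cfg$consensus$threshold)
  tcsUniverse <- if (identical(cfg$tcs$universe, "library")) library
    else wordUniverse(randProm, k = cfg$tcs$k,
                      minPromoters = cfg$tcs$minPromoters)
  tcsTab <- runTCS(randProm, resp, motifUniverse = tcsUniverse,
                   subsetSize = min(cfg$tcs$subsetSize, length(tcsUniverse)),
                   nIterations = cfg$tcs$nIterations, seed = cfg$seeds$tcs,
                   threshold = cfg$tcs$threshold)
  # affinity specificity for the random contrast: random scores over the
  # same promoter universe, replacing the test genes' condition contrast
  specRand <- randomResponse(min(run$specificity), max(run$specificity),
                             length(promoters),
                             seed = .deriveSeed(seed, 3L))
  names(specRand) <- names(promoters)
  affTab <- associateLibrary(library, promoters, specRand,
                             cutoffGrid = cfg$affinity$cutoffGrid)
  retained <- list(
    discovery = topFraction(discMapped, cfg$fraction, "lower_better"),
    tcs = topFraction(data.frame(accession = tcsTab$motif,
                                 score = tcsTab$tcs,
                                 stringsAsFactors = FALSE),
                      cfg$fraction, "higher_better"),
    affinity = topFraction(data.frame(accession = affTab$accession,
                                      score = affTab$best_p,
                                      stringsAsFactors = FALSE),
                           cfg$fraction, "lower_better"))
  contrast <- contrastTestVsRandom(run$consensus, run$retained, retained)
  list(randomGenes = randomGenes, discovery = disc,
       discoveryMapped = discMapped, tcs = tcsTab, affinity = affTab,
       retained = retained, contrast = contrast)
}
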