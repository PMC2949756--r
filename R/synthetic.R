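# Seeded synthetic-data generators: a three-condition expression matrix with
# planted phenotype classes, background-composition promoters with planted
# PWM instances and masked runs, a matrix library of planted plus
# information-content-matched decoy PWMs, and consistent TF-target lists,
# all tracked in a ground-truth manifest. These stand in for the study-style
# microarray, promoter, TRANSFAC-library and curated-target inputs.

#' Synthetic study configuration
#'
#' Defaults encode the emulated study conditions: two replicates per
#' condition, lognormal multiplicative replicate noise at 5\% CV, four-fold
#' LPS induction of planted classes with four-fold tolerized repression
#' (pro-inflammatory) or 1.5-fold escalation (antibacterial), promoters of
#' 1301 nt (-1000..+300 around the TSS) of uniform base composition, one
#' planted width-10 PWM inserted into 60\% of pro-class promoters, eight
#' IC-matched decoy matrices, and sparse repeat-mask `N` runs.
#'
#' @param nGenes number of genes/probes (default 1000).
#' @param fracPro,fracAnti planted class fractions (default 0.10, 0.02).
#' @param foldInduction N to N+L fold for both planted classes (default 4).
#' @param foldRepression N+L to T+L repression fold for pro genes (default 4).
#' @param foldEscalation N+L to T+L escalation for anti genes (default 1.5).
#' @param replicateCV lognormal replicate coefficient of variation
#'   (default 0.05).
#' @param nReplicates replicates per condition (default 2).
#' @param includeT also simulate the tolerant (T) condition (default FALSE),
#'   for four-condition cross-dataset layouts.
#' @param promoterWindow TSS window (default `c(-1000, 300)`).
#' @param background length-4 promoter base composition (default uniform).
#' @param plantedPWM the planted [PWMotif-class]; a fixed width-10 matrix
#'   with 0.85 consensus probabilities by default.
#' @param plantedClass class whose promoters receive insertions
#'   (default "pro").
#' @param insertionProb per-promoter insertion probability (default 0.6).
#' @param sitesPerPromoter planted sites per selected promoter (default 1).
#' @param nDecoys decoy matrices in the library (default 8).
#' @param maskRunRate per-promoter probability of a masked `N` run
#'   (default 0.1).
#' @param maskRunLength min/max masked-run length (default `c(10, 50)`).
#' @param baselineMeanlog,baselineSdlog lognormal baseline intensity
#'   parameters (default `log(200)`, 1).
#' @param targetFraction fraction of plant-carrying genes listed as curated
#'   targets of the planted TF (default 0.7).
#' @param seed master seed.
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 1000, fracPro = 0.10, fracAnti = 0.02,
                            foldInduction = 4, foldRepression = 4,
                            foldEscalation = 1.5, replicateCV = 0.05,
                            nReplicates = 2, includeT = FALSE,
                            promoterWindow = c(-1000L, 300L),
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                            plantedPWM = NULL, plantedClass = "pro",
                            insertionProb = 0.6, sitesPerPromoter = 1,
                            nDecoys = 8, maskRunRate = 0.1,
                            maskRunLength = c(10L, 50L),
                            baselineMeanlog = log(200), baselineSdlog = 1,
                            targetFraction = 0.7, seed = 1) {
  if (fracPro + fracAnti > 1) stop("class fractions must sum to <= 1")
  if (fracPro < 0 || fracAnti < 0) stop("class fractions must be >= 0")
  if (foldInduction <= 1 || foldRepression <= 1 || foldEscalation <= 1)
    stop("fold changes must be > 1")
  if (replicateCV < 0) stop("replicateCV must be >= 0")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background composition must sum to 1")
  if (is.null(plantedPWM)) plantedPWM <- .defaultPlantedPWM()
  cfg <- list(nGenes = as.integer(nGenes), fracPro = fracPro,
              fracAnti = fracAnti, foldInduction = foldInduction,
              foldRepression = foldRepression,
              foldEscalation = foldEscalation, replicateCV = replicateCV,
              nReplicates = as.integer(nReplicates), includeT = includeT,
              promoterWindow = as.integer(promoterWindow),
              background = background, plantedPWM = plantedPWM,
              plantedClass = plantedClass, insertionProb = insertionProb,
              sitesPerPromoter = as.integer(sitesPerPromoter),
              nDecoys = as.integer(nDecoys), maskRunRate = maskRunRate,
              maskRunLength = as.integer(maskRunLength),
              baselineMeanlog = baselineMeanlog,
              baselineSdlog = baselineSdlog,
              targetFraction = targetFraction, seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  cfg
}

# fixed, fairly informative width-10 planted matrix (0.85 on the consensus)
.defaultPlantedPWM <- function() {
  cons <- c("T", "G", "A", "C", "G", "T", "C", "A", "A", "T")
  p <- matrix(0.05, nrow = 4L, ncol = length(cons),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  p[cbind(match(cons, rownames(p)), seq_along(cons))] <- 0.85
  PWMotif(p, accession = "PL0001", tfName = "PlantedTF1")
}

#' Generate a synthetic three-condition expression matrix
#'
#' Baseline intensities are lognormal; pro-class genes have
#' `NL = foldInduction x N` and `TL = NL / foldRepression`, antibacterial
#' genes have `NL = foldInduction x N` and `TL = foldEscalation x NL`, null
#' genes are flat. Replicates receive multiplicative lognormal noise with
#' the configured CV. Fully deterministic under the config seed.
#'
#' @param config a [syntheticConfig()].
#' @return list with `se` (a `SummarizedExperiment`) and `manifest` (list
#'   with per-gene `classes`, plus the config echo).
#' @export
generateExpression <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  n <- config$nGenes
  genes <- sprintf("GENE%04d", seq_len(n))
  res <- .withSeed(.deriveSeed(config$seed, 1L), {
    nPro <- round(config$fracPro * n)
    nAnti <- round(config$fracAnti * n)
    classes <- rep("null", n)
    planted <- sample.int(n, nPro + nAnti)
    classes[planted[seq_len(nPro)]] <- "pro"
    if (nAnti > 0) classes[planted[nPro + seq_len(nAnti)]] <- "anti"
    base <- stats::rlnorm(n, config$baselineMeanlog, config$baselineSdlog)
    meanN <- base
    meanNL <- ifelse(classes == "null", base, base * config$foldInduction)
    meanTL <- ifelse(classes == "pro", meanNL / config$foldRepression,
              ifelse(classes == "anti", meanNL * config$foldEscalation,
                     base))
    conds <- c("N", "NL", "TL", if (config$includeT) "T")
    means <- cbind(N = meanN, NL = meanNL, TL = meanTL)
    if (config$includeT) means <- cbind(means, T = base)
    sigma <- if (config$replicateCV > 0)
      sqrt(log(1 + config$replicateCV^2)) else 0
    cols <- unlist(lapply(conds, function(cc)
      paste0(cc, "_", seq_len(config$nReplicates))))
    m <- matrix(0, nrow = n, ncol = length(cols),
                dimnames = list(genes, cols))
    for (cc in conds) for (r in seq_len(config$nReplicates)) {
      noise <- if (sigma > 0) exp(stats::rnorm(n, 0, sigma)) else rep(1, n)
      m[, paste0(cc, "_", r)] <- means[, cc] * noise
    }
    list(m = m, classes = classes, conds = conds)
  })
  cond <- sub("_[0-9]+$", "", colnames(res$m))
  se <- SummarizedExperiment(
    assays = list(intensity = res$m),
    rowData = DataFrame(probe_id = genes, gene_symbol = genes,
                        annotated = TRUE, row.names = genes),
    colData = DataFrame(condition = cond,
                        replicate = as.integer(sub("^.*_", "",
                                                   colnames(res$m))),
                        row.names = colnames(res$m)))
  metadata(se)$counts <- list(n_probes = length(genes),
                              n_annotated = length(genes))
  manifest <- list(classes = setNames(res$classes, genes))
  list(se = se, manifest = manifest)
}

# sample one site sequence from the PWM columns
.samplePWMSite <- function(pwm) {
  p <- motifMatrix(pwm)
  paste(vapply(seq_len(ncol(p)), function(j)
    sample(c("A", "C", "G", "T"), 1L, prob = p[, j]), character(1)),
    collapse = "")
}

#' Generate synthetic promoters with planted PWM instances
#'
#' Background sequence is drawn i.i.d. from the configured 0-order
#' composition. Promoters of the planted class receive, with the configured
#' insertion probability, `sitesPerPromoter` sites sampled from the planted
#' PWM at random non-overlapping offsets and strands. Masked `N` runs are
#' then inserted at the configured rate, avoiding planted sites. All
#' insertions are recorded in the manifest.
#'
#' @param config a [syntheticConfig()].
#' @param classes named character vector of per-gene classes (from
#'   [generateExpression()]'s manifest).
#' @return list with `promoters` (named `DNAStringSet` with window/strand
#'   `mcols`) and `plants` (data.frame `gene`, `accession`, `offset`,
#'   `strand`).
#' @export
generatePromoters <- function(config, classes) {
  stopifnot(inherits(config, "SyntheticConfig"))
  len <- config$promoterWindow[2L] - config$promoterWindow[1L] + 1L
  pwm <- config$plantedPWM
  w <- motifWidth(pwm)
  if (len < w) stop("promoter window shorter than the planted matrix width")
  genes <- names(classes)
  res <- .withSeed(.deriveSeed(config$seed, 2L), {
    seqs <- character(length(genes))
    plants <- list()
    classMap <- c(pro = "pro", anti = "anti", null = "null")
    for (i in seq_along(genes)) {
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = config$background)
      occupied <- rep(FALSE, len)
      if (classes[[i]] == config$plantedClass &&
          stats::runif(1) < config$insertionProb) {
        for (k in seq_len(config$sitesPerPromoter)) {
          for (try in 1:50) {
            off <- sample.int(len - w + 1L, 1L)
            if (!any(occupied[off:(off + w - 1L)])) break
            off <- NA_integer_
          }
          if (is.na(off)) next
          strand <- sample(c("+", "-"), 1L)
          site <- .samplePWMSite(pwm)
          if (strand == "-")
            site <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(site)))
          s[off:(off + w - 1L)] <- strsplit(site, "")[[1L]]
          occupied[off:(off + w - 1L)] <- TRUE
          plants[[length(plants) + 1L]] <- data.frame(
            gene = genes[i], accession = accession(pwm), offset = off,
            strand = strand, stringsAsFactors = FALSE)
        }
      }
      if (stats::runif(1) < config$maskRunRate) {
        rl <- sample(config$maskRunLength[1L]:config$maskRunLength[2L], 1L)
        for (try in 1:50) {
          off <- sample.int(len - rl + 1L, 1L)
          if (!any(occupied[off:(off + rl - 1L)])) {
            s[off:(off + rl - 1L)] <- "N"
            break
          }
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    list(seqs = seqs, plants = plants)
  })
  promoters <- Biostrings::DNAStringSet(res$seqs)
  names(promoters) <- genes
  mcols(promoters) <- DataFrame(
    window_start = rep(config$promoterWindow[1L], length(genes)),
    window_end = rep(config$promoterWindow[2L], length(genes)),
    strand = rep("+", length(genes)))
  plants <- if (length(res$plants)) do.call(rbind, res$plants)
    else data.frame(gene = character(), accession = character(),
                    offset = integer(), strand = character(),
                    stringsAsFactors = FALSE)
  list(promoters = promoters, plants = plants)
}

# decoy with exactly matched information content: permute letters within
# each column and shuffle column order of the template
.decoyPWM <- function(template, accession, tfName) {
  p <- motifMatrix(template)
  q <- apply(p, 2L, function(col) col[sample.int(4L)])
  q <- q[, sample.int(ncol(q)), drop = FALSE]
  rownames(q) <- c("A", "C", "G", "T")
  PWMotif(q, accession = accession, tfName = tfName)
}

#' Generate the matrix library and curated-style target lists
#'
#' The library holds the planted PWM plus `nDecoys` decoys built by permuting
#' letters within columns and shuffling column order of the planted matrix —
#' exactly matching its information content so planted vs decoy cannot be
#' told apart by motif strength alone. The target list pairs the planted TF
#' with a random `targetFraction` subset of the genes that actually carry its
#' plants, plus one decoy TF entry with targets drawn from unplanted genes.
#'
#' @param config a [syntheticConfig()].
#' @param plants plant table from [generatePromoters()].
#' @param classes per-gene class vector.
#' @return list with `library` (named list of [PWMotif-class]) and
#'   `associations` (data.frame as from [readTargetList()]).
#' @export
generateLibraryAndTargets <- function(config, plants, classes) {
  stopifnot(inherits(config, "SyntheticConfig"))
  .withSeed(.deriveSeed(config$seed, 3L), {
    planted <- config$plantedPWM
    lib <- list(planted)
    for (d in seq_len(config$nDecoys))
      lib[[d + 1L]] <- .decoyPWM(planted, sprintf("DC%04d", d),
                                 sprintf("DecoyTF%d", d))
    names(lib) <- vapply(lib, accession, character(1))
    carriers <- unique(plants$gene[plants$accession == accession(planted)])
    nTake <- max(1L, round(config$targetFraction * length(carriers)))
    targets <- if (length(carriers)) sort(sample(carriers, nTake))
               else character()
    decoyGenes <- names(classes)[classes == "null"]
    decoyTargets <- sort(sample(decoyGenes, min(10L, length(decoyGenes))))
    assoc <- data.frame(
      accession = c(accession(planted), names(lib)[2L]),
      tf_name = c(tfName(planted), tfName(lib[[2L]])),
      stringsAsFactors = FALSE)
    assoc$targets <- list(targets, decoyTargets)
    list(library = lib, associations = assoc)
  })
}

#' Generate and write a complete synthetic study bundle
#'
#' Runs [generateExpression()], [generatePromoters()] and
#' [generateLibraryAndTargets()], writes `expression.tsv`,
#' `promoters.fasta`, `library.transfac`, `targets.tsv` and `manifest.json`
#' under `dir`, and returns the in-memory objects plus the ground-truth
#' manifest. Output files are byte-identical across runs with the same
#' config (no timestamps; fixed number formatting).
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed); `NULL` skips writing.
#' @return list with `se`, `promoters`, `library`, `associations`,
#'   `manifest`, `paths`.
#' @export
generateBundle <- function(config, dir = NULL) {
  expr <- generateExpression(config)
  classes <- expr$manifest$classes
  prom <- generatePromoters(config, classes)
  libT <- generateLibraryAndTargets(config, prom$plants, classes)
  manifest <- list(
    seed = config$seed,
    classes = as.list(classes),
    plants = prom$plants,
    planted_accession = accession(config$plantedPWM),
    planted_tf = tfName(config$plantedPWM),
    planted_targets = libT$associations$targets[[1L]],
    config = config[setdiff(names(config), "plantedPWM")])
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      expression = file.path(dir, "expression.tsv"),
      promoters = file.path(dir, "promoters.fasta"),
      library = file.path(dir, "library.transfac"),
      targets = file.path(dir, "targets.tsv"),
      manifest = file.path(dir, "manifest.json"))
    writeExpressionMatrix(expr$se, paths$expression)
    writePromoters(prom$promoters, paths$promoters)
    writePWMLibrary(libT$library, paths$library)
    writeTargetList(libT$associations, paths$targets)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE, force = TRUE)
  }
  list(se = expr$se, promoters = prom$promoters, library = libT$library,
       associations = libT$associations, manifest = manifest, paths = paths)
}
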