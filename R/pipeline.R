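#' Descriptive summary of a phenotype table
#'
#' Per-breed-group and overall record counts, minimum, maximum, mean
#' and standard deviation of days open.  The overall mean is computed
#' over all records and therefore equals the record-count-weighted mean
#' of the group means.
#'
#' @param pheno phenotype data.frame (see [buildDesign()]).
#' @return data.frame, one row per breed group plus an `overall` row.
#' @export
summarizePhenotypes <- function(pheno) {
  if (!nrow(pheno)) stop("empty phenotype table")
  one <- function(x, label) data.frame(
    group = label, n = length(x), min = min(x), max = max(x),
    mean = mean(x), sd = stats::sd(x))
  groups <- split(pheno$days_open, pheno$breed_group)
  out <- do.call(rbind, c(
    list(one(pheno$days_open, "overall")),
    lapply(names(groups), function(g) one(groups[[g]], g))))
  rownames(out) <- NULL
  out
}

#' Read and write variance components as YAML
#'
#' @param vc a [VarianceComponents-class].
#' @param path YAML file path.
#' @return `readVarianceComponents` returns a
#'   [VarianceComponents-class]; `writeVarianceComponents` returns
#'   `path` invisibly.
#' @export
writeVarianceComponents <- function(vc, path) {
  x <- list(source = vc@source,
            components = list(hy = vc@varHY, u = vc@varU, pe = vc@varPE,
                              e = vc@varE),
            se = as.list(vc@se),
            h2 = if (all(is.finite(c(vc@varHY, vc@varPE))))
              heritability(vc) else NA,
            converged = vc@converged, iterations = vc@iterations)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeVarianceComponents
#' @export
readVarianceComponents <- function(path) {
  x <- yaml::read_yaml(path)
  se <- unlist(x$se)
  VarianceComponents(varU = x$components$u, varHY = x$components$hy,
                     varPE = x$components$pe, varE = x$components$e,
                     se = se[c("hy", "u", "pe", "e")],
                     source = x$source,
                     converged = isTRUE(x$converged),
                     iterations = if (is.null(x$iterations)) NA_integer_
                       else x$iterations)
}

.fmt <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], 6)
  df
}

.writeTsv <- function(df, path) {
  utils::write.table(.fmt(df), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run the full evaluation pipeline
#'
#' Orchestrates simulate (or load) -> phenotype summary -> genotype QC
#' -> AI-REML variance components -> mixed-model solutions and rankings
#' -> single-step GWAS, writing every stage's output as fixed-format
#' TSV/CSV/YAML into `outDir`.  Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config list describing the run.  Either `simulate` (a
#'   [simConfig()] object) or input paths `phenoPath` (CSV),
#'   `pedPath` (CSV) and optionally `genoPrefix` (012 text + map,
#'   see [readGenotypes012()]).  Optional elements with defaults:
#'   `mode` ("single-step" when genotypes are present, else
#'   "pedigree"), `markerCallrate` 0.90, `maf` 0.05, `animalCallrate`
#'   0.90, `beta` 0.05, `tune` TRUE, `remlTol` 1e-8, `window` 5,
#'   `minWindowPct` 0.25, `thresholdLogP` 7.30..., `gwasIter` 1,
#'   `topFraction` 0.2, `bgReference` "2", `genesBed` (path of a gene
#'   BED file for annotation), `seed`.
#' @param outDir output directory, created if needed.
#' @return invisible list with the in-memory results (`pheno`, `ped`,
#'   `panel`, `vc`, `solutions`, `rankings`, `gwas`, `annotations`).
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  def <- list(mode = NULL, markerCallrate = 0.90, maf = 0.05,
              animalCallrate = 0.90, beta = 0.05, tune = TRUE,
              remlTol = 1e-8, window = 5L, minWindowPct = 0.25,
              thresholdLogP = gwasThreshold(), gwasIter = 1L,
              topFraction = 0.2, bgReference = "2", genesBed = NULL,
              seed = 1L)
  for (k in names(def)) if (is.null(config[[k]])) config[[k]] <- def[[k]]
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  if (!is.null(config$simulate)) {
    sim <- simulateDataset(config$simulate)
    ped <- sim$ped; panel <- sim$panel; pheno <- sim$pheno
    writePedigree(ped, file.path(outDir, "ped.csv"))
    utils::write.csv(.fmt(pheno), file.path(outDir, "pheno.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(panel))
      writeGenotypes012(panel, file.path(outDir, "geno"))
    note("simulate")
  } else {
    ped <- readPedigree(config$pedPath)
    pheno <- utils::read.csv(config$phenoPath)
    panel <- if (!is.null(config$genoPrefix))
      readGenotypes012(config$genoPrefix) else NULL
    note("load")
  }
  if (is.null(config$mode))
    config$mode <- if (is.null(panel)) "pedigree" else "single-step"
  if (config$mode == "pedigree" && !is.null(panel)) {
    warning("mode is 'pedigree'; supplied genotypes are ignored")
    panel <- NULL
  }

  .writeTsv(summarizePhenotypes(pheno),
            file.path(outDir, "descriptives.tsv"))
  note("summarize")

  if (!is.null(panel)) {
    qc <- qcGenotypes(panel, config$markerCallrate, config$maf,
                      config$animalCallrate)
    panel <- qc$panel
    .writeTsv(qc$report, file.path(outDir, "qc_report.tsv"))
    note("qc")
  }

  design <- buildDesign(pheno, ped, bgReference = config$bgReference)
  rels <- buildRelationships(ped, panel, beta = config$beta,
                             tune = config$tune)
  K <- if (config$mode == "single-step") rels@Hinv else rels@Ainv
  vc <- remlEstimate(design, K, tol = config$remlTol,
                     source = if (config$mode == "single-step")
                       "ssGAIREML" else "AIREML")
  writeVarianceComponents(vc, file.path(outDir, "vc.yaml"))
  note("varcomp")

  mme <- assembleMME(design, K, vc)
  sol <- solveMME(mme, mode = config$mode,
                  inbreedingF = inbreeding(ped), relDiag = rels@relDiag,
                  uuCovFor = if (!is.null(panel)) animalIds(panel))
  solTab <- rbind(
    data.frame(id = sol@fixed$level, type = paste0("fixed:", sol@fixed$term),
               estimate = sol@fixed$estimate, pev = NA_real_,
               accuracy = NA_real_),
    data.frame(id = sol@herdYear$level, type = "herd_year",
               estimate = sol@herdYear$estimate, pev = NA_real_,
               accuracy = NA_real_),
    data.frame(id = sol@animals$id,
               type = if (config$mode == "single-step") "gebv" else "ebv",
               estimate = sol@animals$value, pev = sol@animals$pev,
               accuracy = sol@animals$accuracy),
    data.frame(id = sol@pe$id, type = "pe", estimate = sol@pe$estimate,
               pev = NA_real_, accuracy = NA_real_))
  .writeTsv(solTab, file.path(outDir, "solutions.tsv"))
  bgByAnimal <- NULL
  if (!is.null(config$simulate))
    bgByAnimal <- sim$truth$breedGroup
  rankings <- summarizeRankings(sol, ped, breedGroups = bgByAnimal,
                                topFraction = config$topFraction)
  .writeTsv(rankings, file.path(outDir, "rankings.tsv"))
  note("evaluate")

  gwas <- NULL; annotations <- NULL
  if (config$mode == "single-step") {
    gwas <- ssGwas(panel, sol, nIter = config$gwasIter,
                   window = config$window,
                   minWindowPct = config$minWindowPct,
                   thresholdLogP = config$thresholdLogP)
    .writeTsv(as.data.frame(gwas@snp), file.path(outDir, "snp_effects.tsv"))
    .writeTsv(as.data.frame(gwas@windows), file.path(outDir, "windows.tsv"))
    sig <- significantSnps(gwas)
    .writeTsv(sig, file.path(outDir, "significant_snps.tsv"))
    if (!is.null(config$genesBed) && nrow(sig)) {
      genes <- readGeneBed(config$genesBed)
      annotations <- annotateGenes(sig, genes)
      .writeTsv(annotations, file.path(outDir, "gene_annotations.tsv"))
    }
    note("gwas")
  }

  report <- c(
    "# Evaluation run report", "",
    paste("mode:", config$mode), paste("seed:", config$seed),
    paste("records:", nrow(pheno)), paste("animals:", length(ped)),
    paste("genotyped:", if (is.null(panel)) 0 else ncol(panel)),
    paste("equations:", length(mme$RHS)),
    sprintf("h2: %.4f", heritability(vc)),
    sprintf("mean accuracy: %.4f",
            mean(sol@animals$accuracy, na.rm = TRUE)),
    if (!is.null(gwas))
      paste("significant SNPs:", sum(gwas@snp$significant, na.rm = TRUE)),
    "", paste("stages completed:", paste(stages, collapse = " -> ")))
  writeLines(report, file.path(outDir, "report.md"))
  writeLines(c(stages, "report"), file.path(outDir, "MANIFEST"))
  invisible(list(pheno = pheno, ped = ped, panel = panel, vc = vc,
                 solutions = sol, rankings = rankings, gwas = gwas,
                 annotations = annotations))
}

#' Read a gene coordinate BED file
#'
#' Uses `rtracklayer::import` when available (handling the 0-based
#' half-open BED convention); otherwise parses the first four columns
#' directly and converts starts to 1-based.
#'
#' @param path BED file path.
#' @return data.frame `chr`, `start`, `end`, `gene` (1-based inclusive).
#' @export
readGeneBed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(data.frame(chr = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      gene = gr$name, stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chr", "start", "end", "gene"),
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  df$start <- df$start + 1L
  df
}
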