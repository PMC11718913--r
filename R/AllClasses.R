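#' @import methods
#' @importFrom Matrix Matrix sparseMatrix Diagonal bdiag crossprod t diag solve forceSymmetric drop0
#' @importFrom stats rnorm runif rbinom var sd pnorm qnorm setNames complete.cases
#' @importFrom utils read.table write.table head
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowRanges
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors metadata DataFrame
#' @importClassesFrom S4Vectors DFrame
NULL

#' Pedigree with derived inbreeding coefficients
#'
#' An ordered pedigree: each row is one animal with its sire and dam
#' (`NA` when unknown).  On construction the rows are topologically
#' sorted so every parent precedes its offspring, cycles are rejected,
#' and the inbreeding coefficient F of every animal is derived from the
#' numerator relationship matrix.  Founders have F = 0; the diagonal of
#' [buildA()] equals 1 + F.
#'
#' @slot id character vector of unique animal identifiers, parents first.
#' @slot sire,dam integer row index of the parent within `id`
#'   (`NA_integer_` when unknown); always smaller than the row index of
#'   the offspring.
#' @slot F numeric inbreeding coefficient per animal, in `[0, 1)`.
#'
#' @seealso [Pedigree()], [buildA()], [buildAInverse()], [inbreeding()]
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "integer", dam = "integer",
                 F = "numeric"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@F) != n)
    return("id, sire, dam and F must have equal length")
  if (anyDuplicated(object@id))
    return("duplicated animal ids")
  for (p in list(object@sire, object@dam)) {
    known <- !is.na(p)
    if (any(p[known] >= seq_len(n)[known]))
      return("parents must precede offspring")
    if (any(p[known] < 1L))
      return("parent indices out of range")
  }
  if (any(object@F < 0 | object@F >= 1))
    return("inbreeding coefficients must lie in [0, 1)")
  TRUE
})

#' SNP genotype panel
#'
#' Allele-count genotypes (0/1/2, `NA` for missing; mean imputation
#' by [qcGenotypes()] produces fractional dosages in `[0, 2]`) for a
#' set of genotyped animals together with the marker map.  Extends
#' `RangedSummarizedExperiment`: rows are markers (with a `GRanges` of
#' chromosome/position), columns are animals, and the single assay
#' `"calls"` holds the allele counts.  Positions are 1-based and
#' strictly increasing within each chromosome.
#'
#' @seealso [GenotypePanel()], [genotypeCalls()], [qcGenotypes()],
#'   [buildG()]
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  calls <- SummarizedExperiment::assay(object, "calls")
  ok <- is.na(calls) | (calls >= 0 & calls <= 2)
  if (!all(ok))
    return("genotype dosages must lie in [0, 2] or be NA")
  rr <- SummarizedExperiment::rowRanges(object)
  pos <- GenomicRanges::start(rr)
  chr <- as.character(GenomicRanges::seqnames(rr))
  for (cc in unique(chr)) {
    p <- pos[chr == cc]
    if (any(diff(p) <= 0))
      return(sprintf("positions not strictly increasing on chromosome %s", cc))
  }
  TRUE
})

#' Variance components of the repeatability animal model
#'
#' The four variances of the model `y = Xb + Qh + Zu + Wp + e`:
#' herd-year (`varHY`), additive genetic (`varU`), permanent
#' environment (`varPE`) and residual (`varE`), all in squared trait
#' units (days^2 for days open), with their asymptotic standard errors
#' from the inverse average-information matrix.
#'
#' Heritability is defined with the herd-year variance in the
#' denominator: h2 = varU / (varHY + varU + varPE + varE).
#'
#' @slot varU,varHY,varPE,varE numeric variance components (days^2).
#' @slot se named numeric standard errors for the four components.
#' @slot source character, `"AIREML"` (pedigree relationship matrix) or
#'   `"ssGAIREML"` (single-step H matrix).
#' @slot converged logical; `iterations` integer; `loglik` numeric REML
#'   log-likelihood at the final iterate (up to an additive constant).
#'
#' @seealso [VarianceComponents()], [remlEstimate()], [heritability()]
#' @export
setClass("VarianceComponents",
  representation(varU = "numeric", varHY = "numeric", varPE = "numeric",
                 varE = "numeric", se = "numeric", source = "character",
                 converged = "logical", iterations = "integer",
                 loglik = "numeric"))

#' Solutions of the mixed model equations
#'
#' Fixed-effect estimates and random-effect predictions from one solve
#' of the repeatability-model mixed model equations, either with the
#' pedigree A-inverse (EBV) or the single-step H-inverse (GEBV).
#'
#' @slot fixed data.frame with columns `term`, `level`, `estimate`
#'   (days); reference levels carry estimate 0.
#' @slot herdYear data.frame `level`, `estimate` for the random
#'   herd-year effect.
#' @slot animals data.frame `id`, `value` (EBV or GEBV in days), `pev`
#'   (prediction error variance, days^2; NA when the system was solved
#'   iteratively) and `accuracy` in `[0, 1]`.
#' @slot pe data.frame `id`, `estimate`: permanent-environment effect of
#'   each cow with records.
#' @slot mode `"pedigree"` or `"single-step"`.
#' @slot vc the [VarianceComponents-class] used to build the equations.
#' @slot details list of solver diagnostics (method, iterations,
#'   residual norm) and, when requested, the prediction-error covariance
#'   of a subset of animals (`uuCov`, used by the ssGWAS back-solve).
#'
#' @seealso [solveMME()], [predictionAccuracy()], [summarizeRankings()]
#' @export
setClass("SolutionSet",
  representation(fixed = "data.frame", herdYear = "data.frame",
                 animals = "data.frame", pe = "data.frame",
                 mode = "character", vc = "VarianceComponents",
                 details = "list"))

setValidity("SolutionSet", function(object) {
  if (!object@mode %in% c("pedigree", "single-step"))
    return("mode must be 'pedigree' or 'single-step'")
  acc <- object@animals$accuracy
  if (!is.null(acc) && any(!is.na(acc) & (acc < 0 | acc > 1)))
    return("accuracy must lie in [0, 1]")
  TRUE
})

#' Relationship matrices for a single-step evaluation
#'
#' Bundle of the matrices entering the mixed model equations: sparse
#' pedigree A-inverse, the pedigree relationship among genotyped
#' animals (A22) and its inverse, the raw and blended/tuned genomic
#' relationship matrices, and the single-step H-inverse
#' `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]` with the correction confined
#' to the genotyped block.
#'
#' @slot Ainv sparse symmetric pedigree A-inverse (all animals).
#' @slot A22,A22inv,Graw,Gstar dense matrices over the genotyped
#'   animals (zero-dimension matrices when no animal is genotyped).
#' @slot Hinv sparse symmetric single-step inverse; equals `Ainv`
#'   exactly when the genotyped set is empty.
#' @slot genotypedIds character ids of the genotyped animals, a subset
#'   of the pedigree ids.
#' @slot relDiag named diagonal of the relationship matrix the inverse
#'   belongs to (`1 + F` per animal for A; the exact H diagonal in a
#'   single-step set); used to normalize prediction error variances
#'   into accuracies.
#'
#' @seealso [buildRelationships()], [buildHInverse()]
#' @export
setClass("RelationshipSet",
  representation(Ainv = "Matrix", A22 = "matrix", A22inv = "matrix",
                 Graw = "matrix", Gstar = "matrix", Hinv = "Matrix",
                 genotypedIds = "character", relDiag = "numeric"))

#' Back-solved SNP effects and window variances
#'
#' Result of a single-step GWAS: marker effects back-solved from the
#' genomic breeding values of the genotyped animals, their weights,
#' normal-test p-values, and the percentage of total additive genetic
#' variance captured by sliding windows of adjacent SNPs.
#'
#' @slot snp DataFrame, one row per marker: `marker`, `chr`, `pos`,
#'   `freq`, `effect` (days per allele copy), `weight`, `sd`, `logp`
#'   (-log10 p), `significant`.
#' @slot windows DataFrame, one row per within-chromosome window:
#'   `chr`, `start`, `end` (marker indices), `startPos`, `endPos`,
#'   `pctVar`, `flagged` (pctVar >= the minimum percentage).
#' @slot nIter integer number of weight iterations used.
#' @slot totalVar numeric total additive variance of the marker score
#'   `M alpha` across genotyped animals.
#' @slot threshold numeric -log10 p significance threshold.
#'
#' @seealso [backsolveSnpEffects()], [windowVariance()], [snpPvalues()],
#'   [annotateGenes()]
#' @export
setClass("SnpEffectResult",
  representation(snp = "DFrame", windows = "DFrame", nIter = "integer",
                 totalVar = "numeric", threshold = "numeric"))
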