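#' Back-solve SNP effects from genomic breeding values
#'
#' Linear transform of the GEBVs of the genotyped animals onto marker
#' effects: `a = D W' Gw^-1 u / k` where `W` is the allele-count matrix
#' centred by `2 p_j`, `D = diag(d_j)` the marker weights,
#' `k = 2 sum p_j q_j`, and `Gw = W D W' / k` the weighted (unblended)
#' marker-based relationship.  With equal weights this is the classic
#' single-pass decomposition; the reconstruction `W a = u` holds
#' exactly whenever `Gw` is invertible.
#'
#' @param panel quality-controlled [GenotypePanel-class] (no missing
#'   calls).
#' @param uHat named GEBV vector covering the panel animals (days).
#' @param weights positive per-marker weights, default all 1.
#' Because `W` is centred with the observed frequencies, `Gw` always
#' has the constant vector in its null space; it is inverted with a
#' tolerance-based (Moore-Penrose) pseudo-inverse, which equals the
#' ordinary inverse whenever `Gw` is non-singular and otherwise
#' projects out the uninformative mean direction.  If the rank
#' collapses further (e.g. fewer informative markers than animals) a
#' small `ridge` can be added instead; blending with A22 belongs to
#' the evaluation step, not here.
#'
#' @param ridge non-negative value added to the diagonal of `Gw`
#'   before inversion (default 0: pseudo-inverse).
#' @return numeric per-marker effects (days per allele copy), named by
#'   marker.
#' @export
backsolveSnpEffects <- function(panel, uHat, weights = NULL, ridge = 0) {
  W <- .centeredCalls(panel)
  ids <- rownames(W)
  if (!all(ids %in% names(uHat)))
    stop("uHat does not cover all genotyped animals")
  u <- uHat[ids]
  m <- ncol(W)
  d <- if (is.null(weights)) rep(1, m) else weights
  stopifnot(length(d) == m, all(d > 0))
  p <- alleleFreqs(panel)
  k <- 2 * sum(p * (1 - p))
  Gw <- tcrossprod(W * rep(d, each = nrow(W)), W) / k
  Ginv <- .invGw(Gw, ridge)
  a <- d * drop(crossprod(W, Ginv %*% u)) / k
  setNames(a, colnames(W))
}

# Invert the weighted marker relationship.  ridge > 0: plain inverse of
# Gw + ridge I; ridge 0: eigenvalue pseudo-inverse with relative
# tolerance (handles the mean-centring null space, and rank deficiency
# when there are fewer informative markers than animals).
.invGw <- function(Gw, ridge = 0) {
  n <- nrow(Gw)
  if (ridge > 0) return(solve(Gw + diag(ridge, n)))
  ev <- eigen(Gw, symmetric = TRUE)
  tol <- max(ev$values) * n * .Machine$double.eps * 100
  pos <- ev$values > tol
  if (!any(pos))
    stop("weighted marker relationship is zero; no informative markers")
  ev$vectors[, pos, drop = FALSE] %*%
    (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
}

#' Update marker weights from back-solved effects
#'
#' One reweighting pass of the iterative ssGWAS: `d_j` proportional to
#' `a_j^2 2 p_j q_j`, renormalized so the weighted total marker
#' variance `sum d_j 2 p_j q_j` stays equal to `sum 2 p_j q_j` (the
#' weighted mean of the weights is 1).  A single-pass analysis (one
#' iteration) uses equal weights.
#'
#' @param effects per-marker effects from [backsolveSnpEffects()].
#' @param freqs per-marker allele frequencies.
#' @return numeric weights, positive, same length as `effects`.
#' @export
iterateWeights <- function(effects, freqs) {
  pq <- 2 * freqs * (1 - freqs)
  d <- effects^2 * pq
  if (all(d == 0)) {
    warning("all effects are zero; weights reset to 1")
    return(rep(1, length(effects)))
  }
  d <- pmax(d, 1e-12 * max(d))      # keep weights strictly positive
  d * sum(pq) / sum(d * pq)
}

#' Sliding-window share of additive genetic variance
#'
#' For each within-chromosome sliding window of `window` adjacent SNPs,
#' the empirical variance of the window score `W_w a_w` across the
#' genotyped animals, expressed as a percentage of the variance of the
#' full marker score `W a` (covariance-aware, not a sum of squared
#' effects).  Chromosomes with fewer than `window` SNPs are skipped.
#'
#' @param panel quality-controlled [GenotypePanel-class].
#' @param effects per-marker effects aligned with the panel.
#' @param window window size in SNPs, default 5.
#' @param minPct flagging threshold: windows explaining at least this
#'   percentage of the total additive variance are marked, default
#'   0.25.
#' @return data.frame: `chr`, `start`, `end` (marker indices within the
#'   panel), `startPos`, `endPos`, `pctVar`, `flagged`; the total
#'   variance is in `attr(, "totalVar")`.
#' @export
windowVariance <- function(panel, effects, window = 5L, minPct = 0.25) {
  W <- .centeredCalls(panel)
  stopifnot(length(effects) == ncol(W))
  totalVar <- stats::var(drop(W %*% effects))
  map <- markerMap(panel)
  rows <- list()
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    if (length(idx) < window) {
      message("chromosome ", cc, " has fewer than ", window,
              " SNPs; windows skipped")
      next
    }
    for (s in seq_len(length(idx) - window + 1L)) {
      w <- idx[s:(s + window - 1L)]
      vw <- stats::var(drop(W[, w, drop = FALSE] %*% effects[w]))
      pct <- if (totalVar > 0) 100 * vw / totalVar else 0
      rows[[length(rows) + 1L]] <- data.frame(
        chr = cc, start = w[1], end = w[window],
        startPos = map$pos[w[1]], endPos = map$pos[w[window]],
        pctVar = pct)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chr = character(0), start = integer(0),
                      end = integer(0), startPos = integer(0),
                      endPos = integer(0), pctVar = numeric(0))
  out$flagged <- out$pctVar >= minPct
  attr(out, "totalVar") <- totalVar
  out
}

# Sampling standard deviations of back-solved effects: a = T u with
# T = D W' Gw^-1 / k, so Var(a) = T Var(u) T' and Var(u) is the
# prediction-error covariance of the genotyped animals.
snpEffectSds <- function(panel, uuCov, weights = NULL, ridge = 0) {
  W <- .centeredCalls(panel)
  ids <- rownames(W)
  if (is.null(uuCov) || !all(ids %in% rownames(uuCov)))
    stop("prediction-error covariance of the genotyped animals is ",
         "required (solve with uuCovFor = genotyped ids)")
  V <- uuCov[ids, ids]
  m <- ncol(W)
  d <- if (is.null(weights)) rep(1, m) else weights
  p <- alleleFreqs(panel)
  k <- 2 * sum(p * (1 - p))
  Gw <- tcrossprod(W * rep(d, each = nrow(W)), W) / k
  Tm <- (d * t(W)) %*% .invGw(Gw, ridge) / k       # m x n
  setNames(sqrt(pmax(0, rowSums((Tm %*% V) * Tm))), colnames(W))
}

#' Per-SNP significance from the normal test
#'
#' Two-sided p-values `p_j = 2 (1 - Phi(|a_j| / sd_j))` on the
#' back-solved effects, returned as `-log10 p`.  The conventional
#' genome-wide threshold is `-log10(5e-8) = 7.30`.
#'
#' @param effects per-marker effects.
#' @param samplingVar per-marker sampling variances of the effects (or
#'   standard deviations when `sd = TRUE`).
#' @param sd interpret `samplingVar` as standard deviations.
#' @return numeric `-log10 p` per marker; markers with zero sampling
#'   variance get `NA` with a warning.
#' @export
snpPvalues <- function(effects, samplingVar, sd = FALSE) {
  s <- if (sd) samplingVar else sqrt(samplingVar)
  out <- rep(NA_real_, length(effects))
  ok <- is.finite(s) & s > 0
  if (any(!ok))
    warning(sum(!ok), " markers with zero sampling variance flagged NA")
  z <- abs(effects[ok]) / s[ok]
  # -log10(2 (1 - Phi(z))) computed on the log scale for large z
  out[ok] <- -(stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) +
                 log(2)) / log(10)
  names(out) <- names(effects)
  out
}

#' Genome-wide significance threshold
#'
#' `-log10(alpha)` for the conventional genome-wide level
#' `alpha = 5e-8`, i.e. 7.30.
#' @param alpha significance level, default `5e-8`.
#' @return numeric `-log10(alpha)`.
#' @export
gwasThreshold <- function(alpha = 5e-8) -log10(alpha)

#' Annotate SNPs against gene coordinates
#'
#' For each SNP, genes overlapping it ("on target", distance 0) or
#' lying within `nearBp` of it.  The signed distance follows the
#' convention: positive when the SNP lies to the right of the gene end,
#' negative when it lies to the left of the gene start.  Genes farther
#' than `nearBp` but within `searchBp` are reported with classification
#' `"beyond"`.
#'
#' @param snps data.frame with columns `marker`, `chr`, `pos` (1-based).
#' @param genes gene table: a data.frame with columns `chr`, `start`,
#'   `end`, `gene` (1-based inclusive coordinates) or a `GRanges` with
#'   a `name`/`gene` metadata column (as returned by
#'   `rtracklayer::import` on a BED file, which converts the 0-based
#'   half-open BED intervals to 1-based).
#' @param nearBp classification radius in bp, default 37000 (inclusive:
#'   a SNP exactly `nearBp` away is still "within").
#' @param searchBp maximum distance reported at all, default `5e5`.
#' @return data.frame: `marker`, `chr`, `pos`, `gene`, `geneStart`,
#'   `geneEnd`, `size`, `distance` (signed, 0 = on target),
#'   `classification` in `on_target` / `within` / `beyond`.
#' @export
annotateGenes <- function(snps, genes, nearBp = 37000, searchBp = 5e5) {
  if (inherits(genes, "GRanges")) {
    nm <- if (!is.null(genes$gene)) genes$gene else genes$name
    genes <- data.frame(chr = as.character(GenomicRanges::seqnames(genes)),
                        start = GenomicRanges::start(genes),
                        end = GenomicRanges::end(genes),
                        gene = nm, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chr", "start", "end", "gene") %in% names(genes)),
            all(c("marker", "chr", "pos") %in% names(snps)))
  if (any(genes$start > genes$end))
    stop("malformed gene intervals (start > end)")
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$chr == snps$chr[i], , drop = FALSE]
    if (!nrow(g)) next
    pos <- snps$pos[i]
    dist <- ifelse(pos < g$start, -(g$start - pos),
                   ifelse(pos > g$end, pos - g$end, 0))
    keep <- abs(dist) <= searchBp
    g <- g[keep, , drop = FALSE]; dist <- dist[keep]
    if (!nrow(g)) next
    cls <- ifelse(dist == 0, "on_target",
                  ifelse(abs(dist) <= nearBp, "within", "beyond"))
    rows[[length(rows) + 1L]] <- data.frame(
      marker = snps$marker[i], chr = snps$chr[i], pos = pos,
      gene = g$gene, geneStart = g$start, geneEnd = g$end,
      size = g$end - g$start + 1L, distance = dist,
      classification = cls, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(marker = character(0), chr = character(0),
                      pos = integer(0), gene = character(0),
                      geneStart = integer(0), geneEnd = integer(0),
                      size = integer(0), distance = integer(0),
                      classification = character(0))
  rownames(out) <- NULL
  out[order(out$marker, abs(out$distance)), , drop = FALSE]
}

#' Single-step GWAS on back-solved SNP effects
#'
#' Full association pass: back-solves marker effects from the GEBVs of
#' the genotyped animals (optionally iteratively reweighted), computes
#' the sliding-window shares of additive genetic variance, and the
#' per-SNP normal-test significance when the solution set carries the
#' prediction-error covariance of the genotyped animals.
#'
#' @param panel quality-controlled [GenotypePanel-class].
#' @param solutions a single-step [SolutionSet-class]; run [solveMME()]
#'   with `uuCovFor = animalIds(panel)` to enable p-values.
#' @param nIter weight iterations; 1 (default) is the single equal-
#'   weight pass.
#' @param window,minWindowPct window size and flagging threshold.
#' @param thresholdLogP significance threshold on `-log10 p`, default
#'   `gwasThreshold()` = 7.30.
#' @param ridge passed to [backsolveSnpEffects()].
#' @return a [SnpEffectResult-class].
#' @export
ssGwas <- function(panel, solutions, nIter = 1L, window = 5L,
                   minWindowPct = 0.25, thresholdLogP = gwasThreshold(),
                   ridge = 0) {
  gids <- animalIds(panel)
  u <- breedingValues(solutions)
  if (!all(gids %in% names(u)))
    stop("solutions do not cover the genotyped animals")
  m <- nrow(panel)
  weights <- rep(1, m)
  p <- alleleFreqs(panel)
  effects <- backsolveSnpEffects(panel, u, weights, ridge = ridge)
  if (nIter > 1L) for (it in seq_len(nIter - 1L)) {
    weights <- iterateWeights(effects, p)
    effects <- backsolveSnpEffects(panel, u, weights, ridge = ridge)
  }
  win <- windowVariance(panel, effects, window = window,
                        minPct = minWindowPct)
  uuCov <- solutions@details$uuCov
  if (!is.null(uuCov) && all(gids %in% rownames(uuCov))) {
    sds <- snpEffectSds(panel, uuCov, weights, ridge = ridge)
    logp <- snpPvalues(effects, sds, sd = TRUE)
  } else {
    sds <- rep(NA_real_, m); logp <- rep(NA_real_, m)
  }
  map <- markerMap(panel)
  snp <- S4Vectors::DataFrame(
    marker = map$marker, chr = map$chr, pos = map$pos, freq = unname(p),
    effect = unname(effects), weight = weights, sd = unname(sds),
    logp = unname(logp),
    significant = !is.na(logp) & logp > thresholdLogP)
  new("SnpEffectResult", snp = snp, windows = S4Vectors::DataFrame(win),
      nIter = as.integer(nIter),
      totalVar = attr(win, "totalVar"),
      threshold = thresholdLogP)
}

#' @export
setMethod("show", "SnpEffectResult", function(object) {
  cat("SnpEffectResult:", nrow(object@snp), "markers,",
      nrow(object@windows), "windows,", object@nIter, "iteration(s)\n")
  cat("  significant SNPs (-log10 p >", sprintf("%.2f", object@threshold),
      "):", sum(object@snp$significant, na.rm = TRUE), "\n")
  cat("  flagged windows (>= 0.25% additive variance):",
      sum(object@windows$flagged), "\n")
})

#' Significant SNPs of a GWAS result
#' @param result a [SnpEffectResult-class].
#' @return data.frame of markers exceeding the significance threshold.
#' @export
significantSnps <- function(result) {
  as.data.frame(result@snp[which(result@snp$significant), , drop = FALSE])
}
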