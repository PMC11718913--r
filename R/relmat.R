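#' Numerator relationship matrix A
#'
#' Tabular-method recursion over the sorted pedigree:
#' `a_ij = 0.5 (a_j,s(i) + a_j,d(i))` for j < i and
#' `a_ii = 1 + 0.5 a_s(i),d(i)`, unknown parents contributing zero.
#' Dense; intended for desk-scale pedigrees (up to a few thousand
#' animals) and for extracting A22 over the genotyped subset.
#'
#' @param ped a [Pedigree-class].
#' @param ids optional character ids; when given, the returned matrix is
#'   restricted to these animals (in the given order), e.g. A22 for the
#'   genotyped subset.
#' @return dense symmetric matrix with dimnames = animal ids; diagonal
#'   equals `1 + inbreeding(ped)`.
#' @export
buildA <- function(ped, ids = NULL) {
  A <- .tabularA(ped@sire, ped@dam)
  dimnames(A) <- list(ped@id, ped@id)
  if (!is.null(ids)) {
    miss <- setdiff(ids, ped@id)
    if (length(miss))
      stop("ids not in pedigree: ", paste(head(miss, 5), collapse = ", "))
    A <- A[ids, ids, drop = FALSE]
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: for each animal i with
#' Mendelian sampling variance
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (both parents known),
#' `0.75 - 0.25 F_p` (one parent) or `1` (founder), the outer product of
#' `(1, -0.5, -0.5)` over (animal, sire, dam) scaled by `1/d_i` is added
#' into A-inverse.
#'
#' @param ped a [Pedigree-class].
#' @return sparse symmetric `dsCMatrix` with dimnames = animal ids;
#'   satisfies `A %*% Ainv = I`.
#' @export
buildAInverse <- function(ped) {
  n <- length(ped@id)
  si <- ped@sire; di <- ped@dam; F <- ped@F
  ii <- jj <- xx <- vector("list", n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dms <- if (!is.na(s) && !is.na(d)) 0.5 - 0.25 * (F[s] + F[d])
      else if (!is.na(s)) 0.75 - 0.25 * F[s]
      else if (!is.na(d)) 0.75 - 0.25 * F[d]
      else 1
    a <- 1 / dms
    idx <- c(i, s, d); idx <- idx[!is.na(idx)]
    w <- c(1, rep(-0.5, length(idx) - 1L))
    ii[[i]] <- rep(idx, each = length(idx))
    jj[[i]] <- rep(idx, times = length(idx))
    xx[[i]] <- a * as.vector(outer(w, w))
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(ped@id, ped@id))
  Matrix::forceSymmetric(Matrix::drop0(Ainv))
}

#' Genotype quality control
#'
#' Removes animals with call rate below `animalCallrate`, then markers
#' with call rate below `markerCallrate` or minor allele frequency not
#' strictly greater than `maf`, and finally imputes remaining missing
#' calls to the marker mean `2 p_j`.
#'
#' @param panel a [GenotypePanel-class], possibly with missing calls.
#' @param markerCallrate,maf,animalCallrate QC thresholds; markers are
#'   kept when call rate >= `markerCallrate` and MAF > `maf` (strict),
#'   animals when call rate >= `animalCallrate`.
#' @return list with `panel` (the filtered, mean-imputed
#'   [GenotypePanel-class]; imputed dosages are fractional) and `report`
#'   (data.frame of counts before/after and numbers removed per rule).
#' @export
qcGenotypes <- function(panel, markerCallrate = 0.90, maf = 0.05,
                        animalCallrate = 0.90) {
  calls <- genotypeCalls(panel)
  n0 <- nrow(calls); m0 <- ncol(calls)
  aRate <- rowMeans(!is.na(calls))
  keepA <- aRate >= animalCallrate
  calls <- calls[keepA, , drop = FALSE]
  mRate <- colMeans(!is.na(calls))
  p <- colMeans(calls, na.rm = TRUE) / 2
  mafObs <- pmin(p, 1 - p)
  keepM <- mRate >= markerCallrate & mafObs > maf
  keepM[is.na(keepM)] <- FALSE
  if (!any(keepM))
    stop("quality control removed every marker")
  calls <- calls[, keepM, drop = FALSE]
  # mean imputation at 2p computed from the retained calls
  p <- colMeans(calls, na.rm = TRUE) / 2
  nas <- which(is.na(calls), arr.ind = TRUE)
  if (nrow(nas)) calls[nas] <- 2 * p[nas[, 2]]
  map <- markerMap(panel)[keepM, , drop = FALSE]
  report <- data.frame(
    stage = c("animals", "markers"),
    before = c(n0, m0),
    removed = c(n0 - sum(keepA), m0 - sum(keepM)),
    after = c(sum(keepA), sum(keepM)))
  list(panel = GenotypePanel(calls, map), report = report)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / (2 sum p_j (1 - p_j))` where W is the allele-count
#' matrix column-centred by `2 p_j` and the `p_j` are observed
#' frequencies.  Optional marker weights `d_j` give the weighted form
#' `G = W D W' / (2 sum p_j q_j)` used by the iterative ssGWAS.
#'
#' @param panel a [GenotypePanel-class] after [qcGenotypes()].
#' @param weights optional positive per-marker weights.
#' @param freqs optional allele frequencies to centre/scale by; defaults
#'   to the observed [alleleFreqs()].
#' @return dense symmetric matrix over the genotyped animals.
#' @export
buildG <- function(panel, weights = NULL, freqs = NULL) {
  W <- .centeredCalls(panel, freqs)
  p <- if (is.null(freqs)) alleleFreqs(panel) else freqs
  k <- 2 * sum(p * (1 - p))
  if (k <= 0) stop("all markers monomorphic: zero VanRaden denominator")
  if (!is.null(weights)) {
    stopifnot(length(weights) == ncol(W), all(weights > 0))
    G <- tcrossprod(W * rep(weights, each = nrow(W)), W) / k
  } else {
    G <- tcrossprod(W) / k
  }
  (G + t(G)) / 2
}

.centeredCalls <- function(panel, freqs = NULL) {
  calls <- genotypeCalls(panel)
  p <- if (is.null(freqs)) alleleFreqs(panel) else freqs
  sweep(calls, 2, 2 * p)
}

#' Blend and tune the genomic relationship matrix
#'
#' Optionally rescales G so that its mean diagonal and mean off-diagonal
#' match those of A22 (solving `a + b G = G_tuned` for scalars a, b),
#' then blends `G* = (1 - beta) G + beta A22` to guarantee positive
#' definiteness and a common base with the pedigree.
#'
#' @param Graw genomic relationship from [buildG()].
#' @param A22 pedigree relationship among the same animals, same order.
#' @param beta blending weight on A22, default 0.05.
#' @param tune logical: match first moments of G to A22 before blending.
#' @return the blended matrix `G*`.
#' @export
blendG <- function(Graw, A22, beta = 0.05, tune = TRUE) {
  stopifnot(identical(dim(Graw), dim(A22)), beta >= 0, beta <= 1)
  n <- nrow(Graw)
  G <- Graw
  if (tune && n > 1) {
    off <- row(G) != col(G)
    mdG <- mean(diag(G)); moG <- mean(G[off])
    mdA <- mean(diag(A22)); moA <- mean(A22[off])
    b <- if (abs(mdG - moG) > 1e-12) (mdA - moA) / (mdG - moG) else 1
    a <- mdA - b * mdG
    G <- a + b * G
  }
  Gstar <- (1 - beta) * G + beta * A22
  Gstar <- (Gstar + t(Gstar)) / 2
  ev <- min(eigen(Gstar, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop(sprintf("G* not positive definite (min eigenvalue %.2e); increase beta", ev))
  dimnames(Gstar) <- dimnames(Graw)
  Gstar
}

#' Single-step H-inverse
#'
#' `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]`: the inverse pedigree
#' relationship matrix with the genotyped block corrected by the
#' difference between the inverse blended genomic and inverse pedigree
#' relationships of the genotyped animals.  With an empty genotyped set
#' (or `G* = A22`) the result is exactly `A^-1`.
#'
#' @param Ainv sparse A-inverse from [buildAInverse()] with animal-id
#'   dimnames.
#' @param A22inv,GstarInv dense inverses over the genotyped animals
#'   (matching dimnames); pass `NULL` for both when nothing is
#'   genotyped.
#' @return sparse symmetric H-inverse over all pedigree animals.
#' @export
buildHInverse <- function(Ainv, A22inv = NULL, GstarInv = NULL) {
  if (is.null(A22inv) && is.null(GstarInv)) return(Ainv)
  stopifnot(identical(dim(A22inv), dim(GstarInv)))
  gids <- rownames(A22inv)
  idx <- match(gids, rownames(Ainv))
  if (anyNA(idx))
    stop("genotyped ids missing from pedigree: ",
         paste(head(gids[is.na(idx)], 5), collapse = ", "))
  H <- as(Ainv, "generalMatrix")
  H[idx, idx] <- H[idx, idx] + (GstarInv - A22inv)
  Matrix::forceSymmetric(Matrix::drop0(H, tol = 0))
}

#' Build the full relationship set for an evaluation
#'
#' Convenience wrapper producing everything [assembleMME()] needs:
#' sparse A-inverse, and when a genotype panel is supplied (already
#' quality-controlled), A22, the VanRaden G, the blended/tuned `G*` and
#' the single-step H-inverse.
#'
#' @param ped a [Pedigree-class].
#' @param panel optional [GenotypePanel-class] of genotyped animals (all
#'   must appear in the pedigree).
#' @param beta,tune blending parameters passed to [blendG()].
#' @return a [RelationshipSet-class].
#' @export
buildRelationships <- function(ped, panel = NULL, beta = 0.05, tune = TRUE) {
  Ainv <- buildAInverse(ped)
  e <- matrix(numeric(0), 0, 0)
  if (is.null(panel))
    return(new("RelationshipSet", Ainv = Ainv, A22 = e, A22inv = e,
               Graw = e, Gstar = e, Hinv = Ainv,
               genotypedIds = character(0),
               relDiag = setNames(1 + ped@F, animalIds(ped))))
  gids <- animalIds(panel)
  miss <- setdiff(gids, animalIds(ped))
  if (length(miss))
    stop("genotyped animals not in pedigree: ",
         paste(head(miss, 5), collapse = ", "))
  A <- buildA(ped)
  A22 <- A[gids, gids, drop = FALSE]
  Graw <- buildG(panel)
  Gstar <- blendG(Graw, A22, beta = beta, tune = tune)
  A22inv <- solve(A22)
  GstarInv <- solve(Gstar)
  dimnames(A22inv) <- dimnames(GstarInv) <- dimnames(A22)
  Hinv <- buildHInverse(Ainv, A22inv, GstarInv)
  # exact diagonal of H: genotyped block is G*, the rest picks up the
  # A12 A22^-1 (G* - A22) A22^-1 A21 correction
  ids <- animalIds(ped)
  hDiag <- setNames(diag(A), ids)
  hDiag[gids] <- diag(Gstar)
  oth <- setdiff(ids, gids)
  if (length(oth)) {
    B <- A[oth, gids, drop = FALSE] %*% A22inv
    hDiag[oth] <- hDiag[oth] + rowSums((B %*% (Gstar - A22)) * B)
  }
  new("RelationshipSet", Ainv = Ainv, A22 = A22, A22inv = A22inv,
      Graw = Graw, Gstar = Gstar, Hinv = Hinv, genotypedIds = gids,
      relDiag = hDiag)
}

#' @export
setMethod("show", "RelationshipSet", function(object) {
  cat("RelationshipSet:", nrow(object@Ainv), "pedigree animals,",
      length(object@genotypedIds), "genotyped\n")
})
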