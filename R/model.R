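#' Design matrices of the repeatability animal model
#'
#' Builds the sparse incidence matrices of
#' `y = Xb + Qh + Zu + Wp + e`: `X` for the fixed breed-group, parity
#' and year-month effects (intercept plus treatment contrasts, so the
#' reference level of each factor is absorbed), `Q` for the random
#' herd-year effect, `Z` mapping records to animals (columns span the
#' whole pedigree; ancestors without records get all-zero columns) and
#' `W` mapping records to the cows that have records.
#'
#' @param pheno data.frame with columns `cow_id`, `parity`,
#'   `breed_group`, `herd_year`, `year_month`, `days_open`.
#' @param ped a [Pedigree-class]; every `cow_id` must appear in it.
#' @param bgReference reference breed group (default `"2"`, so
#'   breed-group solutions are contrasts against group 2).
#' @return object of class `DesignMatrices`: list with sparse `X`, `Q`,
#'   `Z`, `W`, response `y`, `fixedInfo` (term/level per column of X),
#'   `hyLevels`, `animalIds`, `cowIds`.
#' @export
buildDesign <- function(pheno, ped, bgReference = "2") {
  need <- c("cow_id", "parity", "breed_group", "herd_year", "year_month",
            "days_open")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  ids <- animalIds(ped)
  bad <- setdiff(unique(pheno$cow_id), ids)
  if (length(bad))
    stop("cows not in pedigree: ", paste(head(bad, 5), collapse = ", "))
  nr <- nrow(pheno)
  if (!nr) stop("empty phenotype table")

  fac <- function(x, ref = NULL) {
    f <- factor(as.character(x))
    if (!is.null(ref) && ref %in% levels(f)) stats::relevel(f, ref) else f
  }
  bg <- fac(pheno$breed_group, as.character(bgReference))
  par <- fac(pheno$parity)
  ym <- fac(pheno$year_month)

  dummies <- function(f, term) {
    lev <- levels(f)
    if (length(lev) < 2)
      return(list(m = NULL, info = NULL))
    m <- Matrix::sparseMatrix(i = which(as.integer(f) > 1L),
                              j = as.integer(f)[as.integer(f) > 1L] - 1L,
                              x = 1, dims = c(length(f), length(lev) - 1L))
    list(m = m, info = data.frame(term = term, level = lev[-1]))
  }
  db <- dummies(bg, "breed_group"); dp <- dummies(par, "parity")
  dy <- dummies(ym, "year_month")
  X <- Matrix::Matrix(1, nr, 1, sparse = TRUE)
  info <- data.frame(term = "intercept", level = "(Intercept)")
  for (d in list(db, dp, dy)) if (!is.null(d$m)) {
    X <- cbind(X, d$m); info <- rbind(info, d$info)
  }

  ind <- function(f) Matrix::sparseMatrix(i = seq_along(f),
                                          j = as.integer(f), x = 1,
                                          dims = c(length(f), nlevels(f)))
  hy <- factor(as.character(pheno$herd_year))
  Q <- ind(hy)
  cowF <- factor(pheno$cow_id, levels = unique(pheno$cow_id))
  W <- ind(cowF)
  Z <- Matrix::sparseMatrix(i = seq_len(nr),
                            j = match(as.character(pheno$cow_id), ids),
                            x = 1, dims = c(nr, length(ids)))
  structure(list(X = X, Q = Q, Z = Z, W = W,
                 y = as.numeric(pheno$days_open), fixedInfo = info,
                 hyLevels = levels(hy), animalIds = ids,
                 cowIds = levels(cowF),
                 references = list(breed_group = as.character(bgReference),
                                   parity = levels(par)[1],
                                   year_month = levels(ym)[1])),
            class = "DesignMatrices")
}

#' Assemble Henderson's mixed model equations
#'
#' `LHS = T'T + diag(0, I lam_h, K lam_u, I lam_p)` and `RHS = T'y`
#' with `T = [X Q Z W]`, variance ratios `lam_i = varE / var_i`, and
#' `K` the relationship inverse: the pedigree A-inverse for an EBV run
#' or the single-step H-inverse for a GEBV run.
#'
#' @param design from [buildDesign()].
#' @param relInv sparse A-inverse or H-inverse with animal-id dimnames
#'   covering `design$animalIds`.
#' @param vc a [VarianceComponents-class]; all components must be
#'   strictly positive.
#' @return object of class `MME`: list with sparse symmetric `LHS`,
#'   `RHS`, the block index map `blocks`, and the pieces needed to
#'   interpret solutions.
#' @export
assembleMME <- function(design, relInv, vc) {
  stopifnot(inherits(design, "DesignMatrices"))
  v <- c(hy = vc@varHY, u = vc@varU, pe = vc@varPE, e = vc@varE)
  if (any(v <= 0)) stop("all variance components must be > 0")
  ids <- design$animalIds
  if (!is.null(rownames(relInv))) {
    if (!setequal(rownames(relInv), ids))
      stop("relationship inverse ids do not match the pedigree")
    relInv <- relInv[ids, ids]
  } else if (nrow(relInv) != length(ids))
    stop("relationship inverse has wrong dimension")

  T <- cbind(design$X, design$Q, design$Z, design$W)
  M <- Matrix::crossprod(T)
  nx <- ncol(design$X); nh <- ncol(design$Q)
  nu <- ncol(design$Z); np <- ncol(design$W)
  blocks <- list(fixed = seq_len(nx), hy = nx + seq_len(nh),
                 u = nx + nh + seq_len(nu), pe = nx + nh + nu + seq_len(np))
  lam <- v[["e"]] / v[c("hy", "u", "pe")]
  penalty <- Matrix::bdiag(
    Matrix::Diagonal(nx, 0), Matrix::Diagonal(nh, lam[["hy"]]),
    relInv * lam[["u"]], Matrix::Diagonal(np, lam[["pe"]]))
  M <- M + penalty
  structure(list(LHS = Matrix::forceSymmetric(M),
                 RHS = as.numeric(Matrix::crossprod(T, design$y)),
                 blocks = blocks, design = design, vc = vc),
            class = "MME")
}

# Jacobi-preconditioned conjugate gradient for sparse SPD systems.
pcgSolve <- function(A, b, tol = 1e-10, maxIter = 5000L) {
  x <- numeric(length(b))
  r <- b
  Minv <- 1 / Matrix::diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  for (it in seq_len(maxIter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bn)
      return(list(x = x, iterations = it, resid = sqrt(sum(r^2)) / bn))
    z <- Minv * r
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  stop(sprintf("PCG did not converge in %d iterations (relative residual %.2e)",
               maxIter, sqrt(sum(r^2)) / bn))
}

#' Solve the mixed model equations
#'
#' Direct sparse/dense factorization (default; required when prediction
#' error variances are wanted) or Jacobi-preconditioned conjugate
#' gradients for large systems.
#'
#' @param mme from [assembleMME()].
#' @param method `"direct"` or `"pcg"`.
#' @param tol PCG convergence tolerance on the relative residual.
#' @param maxIter PCG iteration cap.
#' @param computePev logical: return per-animal prediction error
#'   variance and accuracy (direct method only; uses a dense inverse,
#'   feasible up to ~10,000 equations).
#' @param uuCovFor optional character ids: additionally return the
#'   prediction-error covariance block of these animals (needed by the
#'   ssGWAS back-solve).
#' @param mode label recorded in the result: `"pedigree"` when `mme`
#'   was assembled with the A-inverse, `"single-step"` for the
#'   H-inverse.
#' @param inbreedingF optional named inbreeding coefficients used in the
#'   accuracy denominator `(1 + F) varU`; defaults to 0.
#' @param relDiag optional named diagonal of the relationship matrix
#'   behind the equations (see [RelationshipSet-class]); when given it
#'   replaces `1 + F` in the accuracy denominator, which is the
#'   model-consistent normalization for a single-step run.
#' @return a [SolutionSet-class].
#' @export
solveMME <- function(mme, method = c("direct", "pcg"), tol = 1e-10,
                     maxIter = 5000L, computePev = (method[1] == "direct"),
                     uuCovFor = NULL, mode = "pedigree",
                     inbreedingF = NULL, relDiag = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(mme, "MME"))
  A <- mme$LHS; b <- mme$RHS
  n <- length(b)
  details <- list(method = method, nEquations = n)
  pevU <- NULL; uuCov <- NULL
  if (method == "direct") {
    if (isTRUE(computePev) || !is.null(uuCovFor)) {
      if (n > 12000)
        stop("dense inverse for PEV limited to 12000 equations; ",
             "use computePev = FALSE")
      Ad <- as.matrix(A)
      ch <- chol(Ad)
      Ci <- chol2inv(ch)
      sol <- drop(Ci %*% b)
      pevU <- Ci[cbind(mme$blocks$u, mme$blocks$u)] * mme$vc@varE
      if (!is.null(uuCovFor)) {
        gi <- mme$blocks$u[match(uuCovFor, mme$design$animalIds)]
        if (anyNA(gi)) stop("uuCovFor ids not in the pedigree")
        uuCov <- Ci[gi, gi, drop = FALSE] * mme$vc@varE
        dimnames(uuCov) <- list(uuCovFor, uuCovFor)
      }
    } else {
      sol <- as.numeric(Matrix::solve(A, b))
    }
  } else {
    res <- pcgSolve(A, b, tol = tol, maxIter = maxIter)
    sol <- res$x
    details$iterations <- res$iterations
    details$resid <- res$resid
  }
  details$uuCov <- uuCov
  .makeSolutionSet(mme, sol, pevU, mode, inbreedingF, details, relDiag)
}

.makeSolutionSet <- function(mme, sol, pevU, mode, inbreedingF, details,
                             relDiag = NULL) {
  d <- mme$design
  fixed <- cbind(d$fixedInfo, estimate = sol[mme$blocks$fixed])
  refs <- data.frame(term = names(d$references),
                     level = unlist(d$references, use.names = FALSE),
                     estimate = 0)
  fixed <- rbind(fixed, refs)
  herdYear <- data.frame(level = d$hyLevels, estimate = sol[mme$blocks$hy])
  u <- sol[mme$blocks$u]
  if (is.null(inbreedingF)) Fv <- rep(0, length(u))
  else Fv <- ifelse(is.na(inbreedingF[d$animalIds]), 0,
                    inbreedingF[d$animalIds])
  dv <- if (is.null(relDiag)) NULL else unname(relDiag[d$animalIds])
  if (!is.null(pevU)) {
    acc <- predictionAccuracy(pevU, mme$vc, Fv, relDiag = dv)
  } else {
    pevU <- rep(NA_real_, length(u)); acc <- rep(NA_real_, length(u))
  }
  animals <- data.frame(id = d$animalIds, value = u, pev = pevU,
                        accuracy = acc, stringsAsFactors = FALSE)
  pe <- data.frame(id = d$cowIds, estimate = sol[mme$blocks$pe],
                   stringsAsFactors = FALSE)
  new("SolutionSet", fixed = fixed, herdYear = herdYear, animals = animals,
      pe = pe, mode = mode, vc = mme$vc, details = details)
}

#' Theoretical accuracy from prediction error variance
#'
#' `acc_i = sqrt(max(0, 1 - PEV_i / ((1 + F_i) varU)))`.  A PEV equal
#' to the full genetic variance (an animal with no information) gives
#' accuracy 0; PEV 0 gives accuracy 1.  PEVs exceeding `(1 + F) varU`
#' beyond numerical tolerance are clipped to accuracy 0 with a warning.
#'
#' In a single-step run the genomic diagonal of H may exceed the
#' pedigree `1 + F`, so small overshoots of the bound are expected and
#' clipped silently; only overshoots beyond `tolerance` draw a warning.
#'
#' @param pev numeric prediction error variances (days^2).
#' @param vc a [VarianceComponents-class].
#' @param F inbreeding coefficients (default 0).
#' @param relDiag optional relationship-matrix diagonal per animal;
#'   replaces `1 + F` (model-consistent choice for H-based runs).
#' @param tolerance relative overshoot of the denominator tolerated
#'   before warning, default 0.05.
#' @return numeric accuracies in `[0, 1]`.
#' @export
predictionAccuracy <- function(pev, vc, F = 0, relDiag = NULL,
                               tolerance = 0.05) {
  den <- (if (is.null(relDiag)) 1 + F else relDiag) * vc@varU
  ratio <- pev / den
  if (any(ratio > 1 + tolerance, na.rm = TRUE))
    warning("some PEV exceed (1 + F) varU beyond tolerance; ",
            "accuracy clipped to 0")
  sqrt(pmax(0, pmin(1, 1 - ratio)))
}

#' Extract breeding values from a solution set
#'
#' @param object a [SolutionSet-class].
#' @return named numeric vector of EBV/GEBV (days), one per pedigree
#'   animal.
#' @export
setMethod("breedingValues", "SolutionSet", function(object)
  setNames(object@animals$value, object@animals$id))

#' Variance components used by a solution set
#' @param object a [SolutionSet-class].
#' @return the [VarianceComponents-class] the equations were built with.
#' @export
setMethod("varianceComponents", "SolutionSet", function(object) object@vc)

#' @export
setMethod("show", "SolutionSet", function(object) {
  cat("SolutionSet (", object@mode, " model): ",
      nrow(object@animals), " animals, ", nrow(object@pe),
      " cows with records\n", sep = "")
  acc <- object@animals$accuracy
  if (!all(is.na(acc)))
    cat("  mean accuracy:", sprintf("%.3f", mean(acc, na.rm = TRUE)), "\n")
})

#' Ranking summaries by dataset and breed group
#'
#' Reproduces the summary layout of a genetic-evaluation report: mean
#' EBV/GEBV and mean accuracy for the full set of animals, the bulls
#' (animals appearing as sires), the dams (animals appearing as dams)
#' and the top fraction of each, selected by most negative value (for
#' days open a negative breeding value is favourable), optionally split
#' by breed group.
#'
#' @param solutions a [SolutionSet-class].
#' @param ped the [Pedigree-class] of the evaluation (defines the
#'   bull/dam roles).
#' @param breedGroups optional named vector (animal id -> group label)
#'   for per-group means.
#' @param topFraction fraction retained in the "top" subsets, default
#'   0.20.
#' @param direction `"most_negative"` (default; lower is better, as for
#'   days open) or `"most_positive"`.
#' @return data.frame with columns `dataset`, `subset`, `group`, `n`,
#'   `meanValue`, `meanAccuracy`.
#' @export
summarizeRankings <- function(solutions, ped, breedGroups = NULL,
                              topFraction = 0.20,
                              direction = c("most_negative",
                                            "most_positive")) {
  direction <- match.arg(direction)
  an <- solutions@animals
  sires <- unique(sireIds(ped)); dams <- unique(damIds(ped))
  sets <- list(all = an$id,
               bulls = intersect(an$id, sires[!is.na(sires)]),
               dams = intersect(an$id, dams[!is.na(dams)]))
  rows <- list()
  for (ds in names(sets)) {
    sub <- an[an$id %in% sets[[ds]], , drop = FALSE]
    if (!nrow(sub)) {
      warning("empty dataset '", ds, "' omitted")
      next
    }
    ord <- order(sub$value, decreasing = (direction == "most_positive"))
    top <- sub[ord[seq_len(max(1L, ceiling(topFraction * nrow(sub))))], ,
               drop = FALSE]
    for (ss in c("full", "top")) {
      dat <- if (ss == "full") sub else top
      grp <- if (is.null(breedGroups)) rep("all", nrow(dat))
        else as.character(breedGroups[dat$id])
      for (g in sort(unique(grp))) {
        dd <- dat[grp == g, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds, subset = ss, group = g, n = nrow(dd),
          meanValue = mean(dd$value),
          meanAccuracy = mean(dd$accuracy, na.rm = TRUE))
      }
    }
  }
  do.call(rbind, rows)
}

#' One-call genetic evaluation
#'
#' Convenience wrapper: builds the design, the requested relationship
#' inverse (A or H), assembles and solves the equations.
#'
#' @param pheno phenotype data.frame (see [buildDesign()]).
#' @param ped a [Pedigree-class].
#' @param vc a [VarianceComponents-class].
#' @param panel optional quality-controlled [GenotypePanel-class];
#'   required for `mode = "single-step"`.
#' @param mode `"pedigree"` (EBV) or `"single-step"` (GEBV).
#' @param beta,tune passed to [blendG()].
#' @param bgReference passed to [buildDesign()].
#' @param ... passed to [solveMME()].
#' @return a [SolutionSet-class].
#' @export
runEvaluation <- function(pheno, ped, vc, panel = NULL,
                          mode = c("pedigree", "single-step"),
                          beta = 0.05, tune = TRUE, bgReference = "2",
                          ...) {
  mode <- match.arg(mode)
  if (mode == "single-step" && is.null(panel))
    stop("single-step mode requires a genotype panel")
  if (mode == "pedigree" && !is.null(panel))
    warning("genotypes supplied but mode is 'pedigree'; they are ignored")
  design <- buildDesign(pheno, ped, bgReference = bgReference)
  rels <- buildRelationships(ped, if (mode == "single-step") panel,
                             beta = beta, tune = tune)
  K <- if (mode == "single-step") rels@Hinv else rels@Ainv
  mme <- assembleMME(design, K, vc)
  solveMME(mme, mode = mode, inbreedingF = inbreeding(ped),
           relDiag = rels@relDiag, ...)
}
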