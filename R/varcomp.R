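#' Construct a VarianceComponents object
#'
#' @param varU,varHY,varPE,varE variances in days^2; `varHY`/`varPE`
#'   may be `NA` when the corresponding term was excluded from a
#'   reduced model fit.
#' @param se named numeric standard errors (optional).
#' @param source `"AIREML"` or `"ssGAIREML"`.
#' @param converged,iterations,loglik fit diagnostics (optional).
#' @return a [VarianceComponents-class].
#' @examples
#' vc <- VarianceComponents(varU = 18.23, varHY = 30.41, varPE = 51.19,
#'                          varE = 707.87)
#' heritability(vc)
#' @export
VarianceComponents <- function(varU, varHY, varPE, varE,
                               se = c(hy = NA_real_, u = NA_real_,
                                      pe = NA_real_, e = NA_real_),
                               source = "AIREML", converged = NA,
                               iterations = NA_integer_,
                               loglik = NA_real_) {
  new("VarianceComponents", varU = as.numeric(varU),
      varHY = as.numeric(varHY), varPE = as.numeric(varPE),
      varE = as.numeric(varE), se = se, source = source,
      converged = as.logical(converged),
      iterations = as.integer(iterations), loglik = as.numeric(loglik))
}

setValidity("VarianceComponents", function(object) {
  for (s in c("varU", "varE")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      return(paste(s, "must be a finite positive scalar"))
  }
  for (s in c("varHY", "varPE")) {
    v <- slot(object, s)
    if (length(v) != 1 || (!is.na(v) && v <= 0))
      return(paste(s, "must be positive or NA (excluded term)"))
  }
  if (!object@source %in% c("AIREML", "ssGAIREML"))
    return("source must be 'AIREML' or 'ssGAIREML'")
  TRUE
})

#' Heritability and repeatability of the repeatability animal model
#'
#' Heritability uses the full phenotypic denominator including the
#' herd-year variance: `h2 = varU / (varHY + varU + varPE + varE)`.
#' Repeatability is `(varU + varPE)` over the same denominator.
#'
#' @param object a [VarianceComponents-class] with all four components.
#' @return numeric ratio in (0, 1).
#' @examples
#' heritability(VarianceComponents(18.23, 30.41, 51.19, 707.87)) # 0.0226
#' @export
setMethod("heritability", "VarianceComponents", function(object) {
  den <- object@varHY + object@varU + object@varPE + object@varE
  if (!is.finite(den)) stop("heritability needs all four components")
  if (den == 0) stop("zero phenotypic variance")
  object@varU / den
})

#' @rdname heritability-VarianceComponents-method
#' @export
setMethod("repeatability", "VarianceComponents", function(object) {
  den <- object@varHY + object@varU + object@varPE + object@varE
  if (!is.finite(den)) stop("repeatability needs all four components")
  (object@varU + object@varPE) / den
})

#' @export
setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (", object@source, ")\n", sep = "")
  v <- c(hy = object@varHY, u = object@varU, pe = object@varPE,
         e = object@varE)
  lab <- c(hy = "herd-year", u = "additive", pe = "perm. env.",
           e = "residual")
  for (k in names(v))
    cat(sprintf("  %-11s %9.3f  (SE %s)\n", lab[k], v[k],
                ifelse(is.na(object@se[k]), "-",
                       sprintf("%.3f", object@se[k]))))
  if (all(is.finite(v)))
    cat(sprintf("  h2 = %.4f, repeatability = %.4f\n",
                heritability(object), repeatability(object)))
})

#' Average-information REML for the repeatability animal model
#'
#' Estimates the herd-year, additive, permanent-environment and
#' residual variances by AI-REML with EM fallback.  Each iteration
#' factorizes the mixed model equations once; first derivatives come
#' from the EM identities (solutions, quadratic forms and exact traces
#' of the inverse coefficient matrix) and second derivatives from the
#' average-information matrix of the working variates
#' `f_i = Z_i u_i / var_i`, `f_e = e / varE`.  Any AI update proposing
#' a non-positive component falls back to the EM update for that
#' component in that round; a persistently non-positive-definite AI
#' matrix drops to pure EM with a warning.  Components collapsing
#' towards zero are floored at `1e-8` times the phenotypic variance and
#' removed from the convergence test.  Convergence is declared when the
#' largest relative component change drops below `tol`.  Standard
#' errors are `sqrt(diag(AI^-1))` at convergence.
#'
#' Traces are computed by dense factorization of the coefficient
#' matrix, which is exact; system sizes up to roughly 10,000 equations
#' are practical.
#'
#' @param design from [buildDesign()].
#' @param relInv sparse relationship inverse for the additive term
#'   (A-inverse for AIREML, H-inverse for ssGAIREML).
#' @param start optional starting values, named `c(hy=, u=, pe=, e=)`;
#'   default: the phenotypic variance split equally over the included
#'   components.
#' @param include random terms in the model, a subset of
#'   `c("hy", "u", "pe")`; the additive term `"u"` is always required.
#' @param algorithm `"ai"` (average information with EM fallback,
#'   default) or `"em"` (pure EM, slower but monotone in the
#'   likelihood).
#' @param tol relative-change convergence tolerance, default `1e-8`.
#' @param maxIter iteration cap; exceeding it raises an error carrying
#'   the estimate trajectory in `attr(, "trajectory")`.
#' @param source label for the result, `"AIREML"` or `"ssGAIREML"`.
#' @param verbose print the iterate path.
#' @return a [VarianceComponents-class] (excluded terms reported as
#'   `NA`); `attr(, "history")` holds the per-iteration components and
#'   log-likelihood.
#' @export
remlEstimate <- function(design, relInv, start = NULL,
                         include = c("hy", "u", "pe"),
                         algorithm = c("ai", "em"), tol = 1e-8,
                         maxIter = 200L, source = "AIREML",
                         verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(design, "DesignMatrices"))
  include <- match.arg(include, c("hy", "u", "pe"), several.ok = TRUE)
  if (!"u" %in% include) stop("the additive term 'u' cannot be excluded")
  y <- design$y
  n <- length(y)
  X <- design$X
  p <- ncol(X)
  if (n <= p)
    stop("no residual degrees of freedom: ", n, " records for ", p,
         " fixed-effect columns")

  ids <- design$animalIds
  if (!is.null(rownames(relInv)) && !identical(rownames(relInv), ids)) {
    if (!setequal(rownames(relInv), ids))
      stop("relationship inverse ids do not match the pedigree")
    relInv <- relInv[ids, ids]
  }
  Zs <- list(hy = design$Q, u = design$Z, pe = design$W)[include]
  T <- do.call(cbind, c(list(X), unname(Zs)))
  RHS <- as.numeric(Matrix::crossprod(T, y))
  yy <- sum(y * y)

  sizes <- vapply(Zs, ncol, integer(1))
  blocks <- list()
  off <- p
  for (k in include) {
    blocks[[k]] <- off + seq_len(sizes[[k]])
    off <- off + sizes[[k]]
  }
  nEq <- off
  relTrip <- Matrix::summary(as(Matrix::forceSymmetric(relInv),
                                "generalMatrix"))
  uIdx <- blocks$u

  # The permanent-environment equations are diagonal in the coefficient
  # matrix (W'W counts records per cow), so they are absorbed exactly
  # through their Schur complement; the dense factorization then covers
  # only the fixed + herd-year + animal equations.
  TtT <- Matrix::crossprod(T)
  absorb <- "pe" %in% include
  aIdx <- if (absorb) blocks$pe else integer(0)
  rIdx <- if (absorb) seq_len(nEq)[-aIdx] else seq_len(nEq)
  Mrr0 <- as.matrix(TtT[rIdx, rIdx, drop = FALSE])
  if (absorb) {
    Mra <- TtT[rIdx, aIdx, drop = FALSE]
    cntA <- Matrix::diag(TtT)[aIdx]
  }

  varP <- stats::var(y)
  comp <- c(include, "e")
  theta <- if (is.null(start)) {
    setNames(rep(varP / length(comp), length(comp)), comp)
  } else {
    if (!all(comp %in% names(start)))
      stop("start must name components: ", paste(comp, collapse = ", "))
    start[comp]
  }
  floorV <- 1e-6 * varP
  qvec <- c(sizes, e = n - p)
  names(qvec) <- comp

  traj <- matrix(NA_real_, maxIter, length(comp) + 1L,
                 dimnames = list(NULL, c(comp, "loglik")))
  pureEM <- algorithm == "em"
  loglik <- NA_real_
  converged <- FALSE
  # active set: components pinned at the floor are fixed out of the AI
  # update (standard boundary handling); they rejoin when their EM
  # update pulls them clear of the floor
  active <- setNames(rep(TRUE, length(comp)), comp)

  for (iter in seq_len(maxIter)) {
    ve <- theta[["e"]]
    Mr <- Mrr0
    for (k in setdiff(include, c("u", "pe"))) {
      bi <- blocks[[k]]
      Mr[cbind(bi, bi)] <- Mr[cbind(bi, bi)] + ve / theta[[k]]
    }
    lamU <- ve / theta[["u"]]
    ridx <- uIdx[relTrip$i] + (uIdx[relTrip$j] - 1L) * nrow(Mr)
    Mr[ridx] <- Mr[ridx] + relTrip$x * lamU
    if (absorb) {
      b <- cntA + ve / theta[["pe"]]
      MraB <- Mra %*% Matrix::Diagonal(x = 1 / b)
      Mr <- Mr - as.matrix(MraB %*% Matrix::t(Mra))
      rhsR <- RHS[rIdx] - as.numeric(MraB %*% RHS[aIdx])
    } else {
      rhsR <- RHS
    }
    ch <- tryCatch(chol(Mr), error = function(e) NULL)
    if (is.null(ch))
      stop("mixed model equations not positive definite; ",
           "check identifiability of the model")
    Ci <- chol2inv(ch)
    solR <- drop(Ci %*% rhsR)
    sol <- numeric(nEq)
    sol[rIdx] <- solR
    if (absorb)
      sol[aIdx] <- (RHS[aIdx] - as.numeric(Matrix::crossprod(Mra, solR))) / b

    quad <- yy - sum(sol * RHS)
    veEM <- quad / (n - p)
    emNew <- numeric(length(comp)); names(emNew) <- comp
    emNew[["e"]] <- veEM
    for (k in include) {
      bi <- blocks[[k]]
      uk <- sol[bi]
      if (k == "u") {
        uAu <- sum(uk[relTrip$i] * relTrip$x * uk[relTrip$j])
        trKC <- sum(relTrip$x * Ci[ridx]) * ve
        emNew[[k]] <- (uAu + trKC) / qvec[[k]]
      } else if (k == "pe" && absorb) {
        # diag of the pe block of the inverse via the Schur identity
        # C_aa = B^-1 + B^-1 M_ar C_rr M_ra B^-1
        S <- Ci %*% Mra
        trCaa <- sum(1 / b) + sum(Matrix::colSums(Mra * S) / b^2)
        emNew[[k]] <- (sum(uk^2) + ve * trCaa) / qvec[[k]]
      } else {
        emNew[[k]] <- (sum(uk^2) + ve * sum(Ci[cbind(bi, bi)])) / qvec[[k]]
      }
    }
    # REML log-likelihood up to a constant (includes -0.5 log|A| term
    # only through the constant since relInv is fixed)
    logdetM <- 2 * sum(log(diag(ch))) + if (absorb) sum(log(b)) else 0
    loglik <- -0.5 * (n * log(ve) +
                        sum(qvec[include] * log(theta[include])) +
                        logdetM - nEq * log(ve) + quad / ve)

    scores <- qvec * (emNew - theta) / (2 * theta^2)
    active <- active | emNew > 20 * floorV     # reactivation
    active[comp == "e"] <- TRUE
    newTheta <- emNew
    AI <- NULL
    if (!pureEM) {
      ehat <- y - as.numeric(T %*% sol)
      Fm <- matrix(0, n, length(comp))
      for (j in seq_along(include)) {
        k <- include[j]
        Fm[, j] <- as.numeric(Zs[[k]] %*% sol[blocks[[k]]]) / theta[[k]]
      }
      Fm[, length(comp)] <- ehat / ve
      # P f = (f - T M^-1 T' f) / ve, with the absorbed-system solve
      w <- as.matrix(Matrix::crossprod(T, Fm))
      if (absorb) {
        wR <- w[rIdx, , drop = FALSE] -
          as.matrix(MraB %*% w[aIdx, , drop = FALSE])
        zR <- Ci %*% wR
        zA <- (w[aIdx, , drop = FALSE] -
                 as.matrix(Matrix::crossprod(Mra, zR))) / b
        z <- matrix(0, nEq, ncol(w))
        z[rIdx, ] <- zR; z[aIdx, ] <- zA
      } else {
        z <- Ci %*% w
      }
      PF <- (Fm - as.matrix(T %*% z)) / ve
      AI <- 0.5 * crossprod(Fm, PF)
      AI <- (AI + t(AI)) / 2
      dimnames(AI) <- list(comp, comp)
      a <- which(active)
      step <- tryCatch(solve(AI[a, a, drop = FALSE], scores[a]),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        pureEM <- TRUE
        warning("average-information matrix not invertible; ",
                "continuing with EM updates")
      } else {
        # component-wise guarding: a non-positive AI proposal decays
        # the component geometrically towards the boundary instead of
        # shrinking the whole Newton step
        full <- numeric(length(comp))
        full[a] <- step
        prop <- theta + full
        bad <- !is.finite(prop) | prop <= 0
        prop[bad] <- pmin(theta[bad] / 10, emNew[bad])
        newTheta <- prop
        newTheta[!active] <- pmax(emNew[!active], floorV)
      }
    }
    newTheta <- pmax(newTheta, floorV)
    active <- active & newTheta > floorV * 1.01
    active[comp == "e"] <- TRUE
    relChange <- abs(newTheta - theta) / theta
    traj[iter, ] <- c(newTheta, loglik)
    if (verbose)
      cat(sprintf("iter %3d: %s  logL %.4f\n", iter,
                  paste(sprintf("%s=%.4f", comp, newTheta), collapse = " "),
                  loglik))
    theta <- newTheta
    if (max(relChange[active]) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    err <- simpleError(sprintf(
      "AI-REML did not converge in %d iterations (last max rel. change %.2e)",
      maxIter, max(relChange[active])))
    attr(err, "trajectory") <- traj
    stop(err)
  }

  se <- setNames(rep(NA_real_, 4), c("hy", "u", "pe", "e"))
  if (!pureEM && !is.null(AI)) {
    a <- which(active)
    AIi <- tryCatch(solve(AI[a, a, drop = FALSE]), error = function(e) NULL)
    if (!is.null(AIi)) se[comp[a]] <- sqrt(pmax(0, diag(AIi)))
  }
  getv <- function(k) if (k %in% comp) theta[[k]] else NA_real_
  out <- VarianceComponents(varU = theta[["u"]], varHY = getv("hy"),
                            varPE = getv("pe"), varE = theta[["e"]],
                            se = se, source = source,
                            converged = converged, iterations = iter,
                            loglik = loglik)
  attr(out, "history") <- as.data.frame(traj[seq_len(iter), , drop = FALSE])
  out
}

#' Compare pedigree and single-step runs
#'
#' Side-by-side variance components and heritabilities of an AIREML
#' (pedigree) and an ssGAIREML (single-step) analysis of the same data,
#' with dataset-level mean accuracies and the percentage increase in
#' accuracy `100 (acc_ss - acc_ped) / acc_ped`.
#'
#' @param vcPed,vcSS [VarianceComponents-class] from the two runs.
#' @param solPed,solSS matching [SolutionSet-class] objects; they must
#'   cover the same animals.
#' @param ped optional [Pedigree-class]; when given, accuracies are also
#'   reported for the bull and dam datasets and their top 20% subsets.
#' @return list with `components` (data.frame), `accuracy` (data.frame
#'   with columns dataset, pedigree, singleStep, pctIncrease).
#' @export
compareMethods <- function(vcPed, vcSS, solPed, solSS, ped = NULL) {
  if (!identical(solPed@animals$id, solSS@animals$id))
    stop("the two solution sets cover different animals")
  components <- data.frame(
    parameter = c("varU", "varHY", "varPE", "varE", "h2"),
    AIREML = c(vcPed@varU, vcPed@varHY, vcPed@varPE, vcPed@varE,
               heritability(vcPed)),
    ssGAIREML = c(vcSS@varU, vcSS@varHY, vcSS@varPE, vcSS@varE,
                  heritability(vcSS)))
  accRow <- function(name, idsP, idsS = idsP) {
    a <- mean(solPed@animals$accuracy[solPed@animals$id %in% idsP],
              na.rm = TRUE)
    b <- mean(solSS@animals$accuracy[solSS@animals$id %in% idsS],
              na.rm = TRUE)
    data.frame(dataset = name, pedigree = a, singleStep = b,
               pctIncrease = if (a > 0) 100 * (b - a) / a else 0)
  }
  rows <- list(accRow("all", solPed@animals$id))
  if (!is.null(ped)) {
    s <- unique(sireIds(ped)); d <- unique(damIds(ped))
    rows <- c(rows, list(accRow("bulls", s[!is.na(s)]),
                         accRow("dams", d[!is.na(d)])))
  }
  list(components = components, accuracy = do.call(rbind, rows))
}
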