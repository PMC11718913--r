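# Independent oracles, deliberately implemented differently from the
# package internals.

# Numerator relationship matrix by recursive kinship (path counting):
# phi(i,i) = 0.5 (1 + phi(s_i, d_i)), phi(i,j) = 0.5 (phi(i, s_j) +
# phi(i, d_j)) expanding the younger animal; A = 2 phi.
oracleA <- function(ped) {
  ids <- animalIds(ped)
  si <- match(sireIds(ped), ids)
  di <- match(damIds(ped), ids)
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) 0.5 * (1 + phi(si[i], di[i]))
      else 0.5 * (phi(i, si[j]) + phi(i, di[j]))
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- 2 * phi(i, j)
    A[j, i] <- A[i, j]
  }
  A
}

# Dense generalized-least-squares solutions of the repeatability model,
# computed from the explicit phenotypic covariance matrix V.
oracleGLS <- function(pheno, ped, vc) {
  des <- buildDesign(pheno, ped)
  A <- oracleA(ped)
  X <- as.matrix(des$X); Q <- as.matrix(des$Q)
  Z <- as.matrix(des$Z); W <- as.matrix(des$W)
  y <- des$y
  V <- tcrossprod(Q) * vc@varHY + Z %*% A %*% t(Z) * vc@varU +
    tcrossprod(W) * vc@varPE + diag(length(y)) * vc@varE
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  list(fixed = drop(b),
       hy = drop(vc@varHY * t(Q) %*% Vi %*% r),
       u = drop(vc@varU * A %*% t(Z) %*% Vi %*% r),
       pe = drop(vc@varPE * t(W) %*% Vi %*% r))
}

# Dense-V REML log-likelihood (up to the usual constant).
oracleREMLlogLik <- function(pheno, ped, theta) {
  des <- buildDesign(pheno, ped)
  A <- oracleA(ped)
  X <- as.matrix(des$X); Q <- as.matrix(des$Q)
  Z <- as.matrix(des$Z); W <- as.matrix(des$W)
  y <- des$y
  V <- tcrossprod(Q) * theta[["hy"]] + Z %*% A %*% t(Z) * theta[["u"]] +
    tcrossprod(W) * theta[["pe"]] + diag(length(y)) * theta[["e"]]
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XVX)$modulus) +
            drop(t(y) %*% P %*% y))
}
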