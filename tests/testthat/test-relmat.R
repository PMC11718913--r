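test_that("buildA reproduces textbook relationship patterns", {
  ped <- Pedigree(letters[1:5], rep(NA, 5), rep(NA, 5))
  expect_equal(buildA(ped), diag(5), ignore_attr = TRUE)

  A <- buildA(trioPed())
  expect_equal(A["o", "s"], 0.5)
  expect_equal(A["o", "o"], 1)

  A <- buildA(fullSibPed())
  expect_equal(A["a", "b"], 0.5)          # full sibs
  expect_equal(A["x", "x"], 1.25)         # their offspring, F = 0.25
})

test_that("buildA is positive semidefinite on generated pedigrees", {
  for (seed in 1:3) {
    ped <- randomPed(40, seed = seed)
    ev <- eigen(buildA(ped), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("Henderson's A-inverse inverts A exactly", {
  ped <- Pedigree(letters[1:4], rep(NA, 4), rep(NA, 4))
  expect_equal(as.matrix(buildAInverse(ped)), diag(4), ignore_attr = TRUE)

  # non-inbred trio: known 3x3 pattern
  Ainv <- as.matrix(buildAInverse(trioPed()))
  expect_equal(diag(Ainv), c(1.5, 1.5, 2), ignore_attr = TRUE)
  expect_equal(Ainv["s", "o"], -1)
  expect_equal(Ainv["s", "d"], 0.5)

  for (seed in 1:3) {
    ped <- randomPed(50, seed = seed)
    E <- buildA(ped) %*% as.matrix(buildAInverse(ped)) - diag(50)
    expect_lt(max(abs(E)), 1e-8)
  }
})

test_that("A22 extraction is consistent with a pruned pedigree", {
  ped <- randomPed(40, seed = 2)
  gids <- animalIds(ped)[c(35:40, 10)]
  A22 <- buildA(ped, ids = gids)
  # ancestor closure of the genotyped subset
  ids <- animalIds(ped)
  si <- match(sireIds(ped), ids); di <- match(damIds(ped), ids)
  keep <- logical(40)
  stack <- match(gids, ids)
  while (length(stack)) {
    i <- stack[1]; stack <- stack[-1]
    if (!keep[i]) {
      keep[i] <- TRUE
      stack <- c(stack, si[i][!is.na(si[i])], di[i][!is.na(di[i])])
    }
  }
  pruned <- Pedigree(ids[keep],
                     ifelse(is.na(si[keep]), NA, ids[si[keep]]),
                     ifelse(is.na(di[keep]), NA, ids[di[keep]]))
  expect_equal(buildA(pruned, ids = gids), A22, tolerance = 1e-12)
})

test_that("genotype QC applies the call-rate and strict MAF rules", {
  calls <- rbind(a1 = c(0, 1, 2, NA, NA),
                 a2 = c(0, 1, 2, NA, 0),
                 a3 = c(0, 2, 0, 1,  0),
                 a4 = c(0, 1, 1, NA, 0),
                 a5 = c(1, 2, 2, NA, 0),
                 a6 = c(0, 1, 2, 0,  0),
                 a7 = c(0, 1, 0, 0,  0),
                 a8 = c(0, 2, 1, 0,  1),
                 a9 = c(0, 1, 2, 1,  0),
                 a10 = c(0, 1, 1, 0, 1))
  map <- data.frame(chr = 1, pos = seq_len(5) * 100)
  panel <- GenotypePanel(calls, map)

  # animals below the call-rate threshold are removed first
  qcA <- qcGenotypes(panel)
  expect_equal(qcA$report$removed[qcA$report$stage == "animals"], 4)

  # keep all animals to exercise the marker rules on the full matrix
  qc <- qcGenotypes(panel, animalCallrate = 0.5)
  kept <- markerMap(qc$panel)$pos
  expect_false(100 %in% kept)   # MAF 0.05 exactly: removed (strict > 5%)
  expect_false(400 %in% kept)   # 50% missing: call rate below 0.90
  expect_setequal(kept, c(200, 300, 500))
  expect_false(anyNA(genotypeCalls(qc$panel)))
  expect_equal(qc$report$removed[qc$report$stage == "markers"], 2)

  # a clean matrix passes through unchanged
  clean <- GenotypePanel(calls[, c(2, 3)], map[c(2, 3), ])
  qc2 <- qcGenotypes(clean)
  expect_identical(genotypeCalls(qc2$panel), genotypeCalls(clean))
  expect_true(all(qc2$report$removed == 0))

  # imputation fills missing with the marker mean 2p
  pHat <- mean(calls[, 5], na.rm = TRUE) / 2
  imp <- genotypeCalls(qc$panel)[, "snp5"]
  expect_equal(unname(imp["a1"]), 2 * pHat)
  expect_error(qcGenotypes(panel, maf = 0.5), "every marker")
})

test_that("VanRaden G matches hand computation and HWE expectations", {
  # one marker, codes 0 and 2, observed p = 0.5: W = (-1, 1), k = 0.5
  panel <- GenotypePanel(rbind(a = 0, b = 2),
                         data.frame(chr = 1, pos = 1))
  G <- buildG(panel)
  expect_equal(diag(G), c(a = 2, b = 2))
  expect_equal(G["a", "b"], -2)

  # identical twin rows: off-diagonal equals both diagonals
  twin <- GenotypePanel(rbind(t1 = c(0, 1, 2, 1), t2 = c(0, 1, 2, 1),
                              o = c(2, 1, 0, 0)),
                        data.frame(chr = 1, pos = 1:4))
  Gt <- buildG(twin)
  expect_equal(Gt["t1", "t2"], Gt["t1", "t1"])

  # large unrelated panel under HWE: mean diagonal near 1
  cfg <- simConfig(nFounders = 200, nGenerations = 0, nCows = 50,
                   nSnps = 2000, nChromosomes = 4, genotypedFraction = 1,
                   seed = 8)
  ped <- simulatePedigree(cfg)
  big <- simulateGenotypes(ped, cfg)
  expect_equal(mean(diag(buildG(big))), 1, tolerance = 0.05)
})

test_that("blending and tuning produce a positive definite G*", {
  sim <- smallSim(seed = 3)
  qc <- qcGenotypes(sim$panel)$panel
  A22 <- buildA(sim$ped, ids = animalIds(qc))
  Graw <- buildG(qc)
  expect_equal(blendG(Graw, A22, beta = 1, tune = FALSE), A22,
               ignore_attr = TRUE)
  pd <- Graw + diag(0.1, nrow(Graw))
  expect_equal(blendG(pd, A22, beta = 0, tune = FALSE), pd)
  # raw G is singular (centring); a 5% blend restores definiteness
  evRaw <- eigen(Graw, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(evRaw), 1e-8)
  Gstar <- blendG(Graw, A22, beta = 0.05)
  ev <- eigen(Gstar, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 1e-8)
  # tuning matches first moments of A22
  off <- row(Gstar) != col(Gstar)
  expect_equal(mean(diag(Gstar)), mean(diag(A22)), tolerance = 1e-6)
  expect_equal(mean(Gstar[off]), mean(A22[off]), tolerance = 1e-6)
})

test_that("H-inverse equals A-inverse in the degenerate cases", {
  ped <- randomPed(30, seed = 5)
  rel <- buildRelationships(ped)
  expect_identical(rel@Hinv, rel@Ainv)
  expect_equal(rel@relDiag, 1 + inbreeding(ped))

  # G* = A22: the correction cancels exactly
  gids <- animalIds(ped)[25:30]
  A22 <- buildA(ped, ids = gids)
  A22inv <- solve(A22)
  H <- buildHInverse(rel@Ainv, A22inv, A22inv)
  expect_lt(max(abs(H - rel@Ainv)), 1e-12)
})

test_that("H-inverse matches the dense closed-form joint matrix", {
  cfg <- simConfig(nFounders = 6, nGenerations = 1, nCows = 5,
                   maxParities = 2, nSnps = 400, nChromosomes = 2,
                   genotypedFraction = 0.8, seed = 7)
  ped <- simulatePedigree(cfg)
  panel <- simulateGenotypes(ped, cfg)
  rel <- buildRelationships(ped, panel)
  ids <- animalIds(ped)
  g <- rel@genotypedIds
  ng <- match(g, ids); og <- setdiff(seq_along(ids), ng)
  A <- buildA(ped); G <- rel@Gstar
  A22i <- solve(A[ng, ng])
  H <- matrix(0, length(ids), length(ids))
  H[og, og] <- A[og, og] +
    A[og, ng] %*% A22i %*% (G - A[ng, ng]) %*% A22i %*% A[ng, og]
  H[og, ng] <- A[og, ng] %*% A22i %*% G
  H[ng, og] <- t(H[og, ng])
  H[ng, ng] <- G
  expect_lt(max(abs(as.matrix(rel@Hinv) - solve(H))), 1e-8)
  # the exact H diagonal is exposed for accuracy normalization
  expect_equal(unname(rel@relDiag[ids]), diag(H), tolerance = 1e-10)
  expect_error(buildHInverse(rel@Ainv, A22i, solve(G)[1:3, 1:3]))
})
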