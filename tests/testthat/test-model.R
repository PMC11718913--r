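test_that("design matrices have the documented incidence structure", {
  tp <- tinyPheno()
  des <- buildDesign(tp$pheno, tp$ped)
  # each record carries exactly one herd-year, one animal, one cow
  expect_true(all(Matrix::rowSums(des$Q) == 1))
  expect_true(all(Matrix::rowSums(des$Z) == 1))
  expect_true(all(Matrix::rowSums(des$W) == 1))
  # cow c1 has 2 records; so do its Z and W columns
  expect_equal(sum(des$Z[, match("c1", des$animalIds)]), 2)
  expect_equal(Matrix::colSums(des$W)[[1]], 2)
  # ancestors without records have all-zero Z columns
  expect_equal(sum(des$Z[, match("s", des$animalIds)]), 0)
  # 3 breed groups -> 2 free columns after the reference constraint
  expect_equal(sum(des$fixedInfo$term == "breed_group"), 2)
  expect_equal(des$references$breed_group, "2")
  expect_error(buildDesign(transform(tp$pheno, cow_id = "ghost"), tp$ped),
               "not in pedigree")
})

test_that("MME solutions equal dense GLS on a toy system", {
  tp <- tinyPheno()
  vc <- tableTwoVc()
  des <- buildDesign(tp$pheno, tp$ped)
  mme <- assembleMME(des, buildAInverse(tp$ped), vc)
  sol <- solveMME(mme)
  gls <- oracleGLS(tp$pheno, tp$ped, vc)
  expect_equal(unname(breedingValues(sol)), unname(gls$u),
               tolerance = 1e-6)
  expect_equal(sol@herdYear$estimate, unname(gls$hy), tolerance = 1e-6)
  expect_equal(sol@pe$estimate, unname(gls$pe), tolerance = 1e-6)
  expect_equal(sol@fixed$estimate[seq_along(gls$fixed)],
               unname(gls$fixed), tolerance = 1e-6)
})

test_that("fixed-effect solutions reduce to OLS when random effects vanish", {
  tp <- tinyPheno()
  vcTiny <- VarianceComponents(varU = 1e-8, varHY = 1e-8, varPE = 1e-8,
                               varE = 700)
  des <- buildDesign(tp$pheno, tp$ped)
  sol <- solveMME(assembleMME(des, buildAInverse(tp$ped), vcTiny))
  Xd <- as.matrix(des$X)
  ols <- qr.coef(qr(Xd), des$y)
  expect_equal(sol@fixed$estimate[seq_along(ols)], unname(ols),
               tolerance = 1e-4)
  # shrinkage limit: breeding values vanish as varU -> 0
  expect_lt(max(abs(breedingValues(sol))), 1e-3)
})

test_that("direct and PCG solvers agree and are permutation invariant", {
  sim <- smallSim(seed = 2)
  vc <- tableTwoVc()
  des <- buildDesign(sim$pheno, sim$ped)
  mme <- assembleMME(des, buildAInverse(sim$ped), vc)
  solD <- solveMME(mme, method = "direct", computePev = FALSE)
  solP <- solveMME(mme, method = "pcg", tol = 1e-12)
  expect_equal(breedingValues(solD), breedingValues(solP),
               tolerance = 1e-6)
  expect_gt(solP@details$iterations, 1)

  # permuting record order leaves every solution unchanged
  perm <- sample(nrow(sim$pheno))
  desP <- buildDesign(sim$pheno[perm, ], sim$ped)
  solPerm <- solveMME(assembleMME(desP, buildAInverse(sim$ped), vc),
                      computePev = FALSE)
  expect_equal(breedingValues(solD), breedingValues(solPerm),
               tolerance = 1e-8)
})

test_that("PCG solves a hand-checkable SPD system", {
  A <- Matrix::Matrix(c(4, 1, 0, 1, 3, 1, 0, 1, 2), 3, 3, sparse = TRUE)
  b <- c(1, 2, 3)
  res <- ssgblup:::pcgSolve(A, b)
  expect_equal(res$x, solve(as.matrix(A), b), tolerance = 1e-9)
})

test_that("the stationarity conditions hold at the solution", {
  sim <- smallSim(seed = 4)
  vc <- tableTwoVc()
  des <- buildDesign(sim$pheno, sim$ped)
  mme <- assembleMME(des, buildAInverse(sim$ped), vc)
  sol <- solveMME(mme, computePev = FALSE)
  key <- paste(sol@fixed$term, sol@fixed$level)
  solVec <- c(sol@fixed$estimate[match(paste(des$fixedInfo$term,
                                             des$fixedInfo$level), key)],
              sol@herdYear$estimate, sol@animals$value, sol@pe$estimate)
  resid <- as.numeric(mme$LHS %*% solVec) - mme$RHS
  expect_lt(max(abs(resid)) / max(abs(mme$RHS)), 1e-6)
  # fixed-effect normal equations: X' e = 0
  T <- cbind(des$X, des$Q, des$Z, des$W)
  e <- des$y - as.numeric(T %*% solVec)
  expect_lt(max(abs(as.numeric(Matrix::crossprod(des$X, e)))), 1e-6)
})

test_that("an animal without records or descendants gets the parent average", {
  ped <- Pedigree(c("p1", "p2", "k"), c(NA, NA, "p1"), c(NA, NA, "p2"))
  pheno <- data.frame(cow_id = rep(c("p1", "p2"), each = 3),
                      parity = rep(1:3, 2), breed_group = 1,
                      herd_year = rep(c("h1", "h2"), 3),
                      year_month = "m1",
                      days_open = c(80, 90, 100, 110, 120, 100))
  sol <- solveMME(assembleMME(buildDesign(pheno, ped),
                              buildAInverse(ped), tableTwoVc()))
  u <- breedingValues(sol)
  expect_equal(unname(u["k"]), unname((u["p1"] + u["p2"]) / 2),
               tolerance = 1e-8)
})

test_that("theoretical accuracy maps PEV to [0, 1] with the documented limits", {
  vc <- tableTwoVc()
  expect_equal(predictionAccuracy(vc@varU, vc), 0)      # no information
  expect_equal(predictionAccuracy(0, vc), 1)            # perfect
  expect_warning(predictionAccuracy(2 * vc@varU, vc), "clipped")
  acc <- predictionAccuracy(c(5, 10, 15), vc, F = c(0, 0.25, 0))
  expect_true(all(acc >= 0 & acc <= 1))
  # inbreeding enlarges the denominator
  expect_gt(predictionAccuracy(10, vc, F = 0.25),
            predictionAccuracy(10, vc, F = 0))
  # a supplied relationship diagonal replaces 1 + F
  expect_equal(predictionAccuracy(10, vc, relDiag = 1.25),
               predictionAccuracy(10, vc, F = 0.25))
})

test_that("BLUP is unbiased: true breeding value regresses on prediction with slope 1", {
  # informative heritability so the pooled slope estimator is sharp;
  # at h2 = 0.02 predictions are family means and the slope estimate
  # itself is dominated by between-family sampling noise
  tv <- c(hy = 30, u = 200, pe = 50, e = 550)
  vc <- VarianceComponents(varU = 200, varHY = 30, varPE = 50,
                           varE = 550)
  uhat <- utrue <- NULL
  for (seed in 1:10) {
    cfg <- simConfig(nFounders = 60, nGenerations = 2, nCows = 300,
                     maxParities = 3, nHerdYears = 8, nYearMonths = 6,
                     recordBounds = NULL, trueVar = tv, seed = seed)
    ped <- simulatePedigree(cfg)
    ph <- simulatePhenotypes(ped, NULL, cfg)
    sol <- runEvaluation(ph$pheno, ped, vc, mode = "pedigree",
                         computePev = FALSE)
    uhat <- c(uhat, breedingValues(sol))
    utrue <- c(utrue, ph$truth$u[ped@id])
  }
  slope <- coef(lm(utrue ~ uhat))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("ranking summaries respect subsets, ties and directions", {
  sim <- smallSim(seed = 6)
  vc <- tableTwoVc()
  sol <- runEvaluation(sim$pheno, sim$ped, vc, mode = "pedigree")
  full <- summarizeRankings(sol, sim$ped, topFraction = 1.0)
  expect_equal(full$meanValue[full$dataset == "all" & full$subset == "top"],
               full$meanValue[full$dataset == "all" & full$subset == "full"])
  # bulls and dams are disjoint role-based subsets
  r <- summarizeRankings(sol, sim$ped)
  expect_true(all(c("all", "bulls", "dams") %in% r$dataset))
  nb <- r$n[r$dataset == "bulls" & r$subset == "full"]
  expect_lt(nb, r$n[r$dataset == "all" & r$subset == "full"])
  # top subsets are selected by most negative value
  top <- r[r$dataset == "all" & r$subset == "top", ]
  expect_lt(top$meanValue, full$meanValue[1])

  # all-equal values: the top mean equals the overall mean
  solT <- sol
  solT@animals$value <- rep(1.5, nrow(solT@animals))
  rt <- summarizeRankings(solT, sim$ped)
  expect_equal(rt$meanValue[rt$dataset == "all" & rt$subset == "top"], 1.5)
})

test_that("breed-group solutions recover the simulated contrast ordering", {
  cfg <- simConfig(nFounders = 150, nGenerations = 2, nCows = 1500,
                   maxParities = 5, nHerdYears = 50, nYearMonths = 24,
                   recordBounds = NULL, seed = 1)
  ped <- simulatePedigree(cfg)
  ph <- simulatePhenotypes(ped, NULL, cfg)
  sol <- runEvaluation(ph$pheno, ped, tableTwoVc(), mode = "pedigree",
                       computePev = FALSE)
  bg <- sol@fixed[sol@fixed$term == "breed_group", ]
  est <- setNames(bg$estimate, bg$level)
  # group 3 (lowest Holstein fraction) below the group-2 reference,
  # group 1 above: shorter days open for lower Holstein percentage
  expect_lt(est[["3"]], 0)
  expect_gt(est[["1"]], est[["3"]])
})

test_that("runEvaluation warns when genotypes are ignored in pedigree mode", {
  sim <- smallSim(seed = 9)
  expect_warning(
    runEvaluation(sim$pheno, sim$ped, tableTwoVc(), panel = sim$panel,
                  mode = "pedigree", computePev = FALSE),
    "ignored")
  expect_error(
    runEvaluation(sim$pheno, sim$ped, tableTwoVc(), mode = "single-step"),
    "requires a genotype panel")
})
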