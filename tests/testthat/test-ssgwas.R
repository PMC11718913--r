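test_that("back-solved effects match explicit matrix arithmetic", {
  set.seed(42)
  calls <- matrix(sample(0:2, 15, replace = TRUE), 5, 3,
                  dimnames = list(paste0("a", 1:5), NULL))
  panel <- GenotypePanel(calls, data.frame(chr = 1, pos = c(10, 20, 30)))
  u <- setNames(rnorm(5), rownames(calls))
  a <- backsolveSnpEffects(panel, u)
  # independent route: MASS::ginv on the explicitly built matrices
  p <- colMeans(genotypeCalls(panel)) / 2
  W <- sweep(genotypeCalls(panel), 2, 2 * p)
  k <- 2 * sum(p * (1 - p))
  G <- W %*% t(W) / k
  aOracle <- drop(t(W) %*% MASS::ginv(G) %*% u[rownames(W)]) / k
  expect_equal(unname(a), unname(aOracle), tolerance = 1e-8)
})

test_that("marker scores reconstruct breeding values in the marker span", {
  sim <- smallSim(seed = 21, nSnps = 800)
  qc <- qcGenotypes(sim$panel)$panel
  W <- ssgblup:::.centeredCalls(qc)
  set.seed(1)
  u <- setNames(drop(W %*% rnorm(ncol(W), 0, 0.1)), rownames(W))
  a <- backsolveSnpEffects(qc, u)
  expect_lt(max(abs(drop(W %*% a) - u)), 1e-6 * max(abs(u)))
  # zero input gives zero effects
  expect_true(all(backsolveSnpEffects(qc, u * 0) == 0))
})

test_that("back-solve then re-aggregate correlates with the GEBVs", {
  sim <- smallSim(seed = 22, nSnps = 1000)
  qc <- qcGenotypes(sim$panel)$panel
  vc <- tableTwoVc()
  sol <- runEvaluation(sim$pheno, sim$ped, vc, panel = qc,
                       mode = "single-step", computePev = FALSE)
  u <- breedingValues(sol)[animalIds(qc)]
  a <- backsolveSnpEffects(qc, u)
  W <- ssgblup:::.centeredCalls(qc)
  expect_gt(cor(drop(W %*% a), u), 0.99)
})

test_that("weight iteration concentrates on a simulated QTL and conserves variance", {
  qtl <- data.frame(marker = 50, effect = 10)
  sim <- smallSim(seed = 23, nSnps = 400, qtl = qtl,
                  trueVar = c(hy = 30, u = 100, pe = 50, e = 400))
  qc <- qcGenotypes(sim$panel)$panel
  u <- sim$truth$u
  p <- alleleFreqs(qc)
  a1 <- backsolveSnpEffects(qc, u)
  w2 <- iterateWeights(a1, p)
  a2 <- backsolveSnpEffects(qc, u, weights = w2)
  w3 <- iterateWeights(a2, p)
  qi <- which(markerMap(qc)$marker == "snp00050")
  expect_gt(w2[qi], 1)              # QTL marker upweighted after one pass
  expect_lte(rank(-w2)[[qi]], 10)   # among the very largest weights
  # conservation: weighted total marker variance is invariant
  pq <- 2 * p * (1 - p)
  expect_equal(sum(w2 * pq), sum(pq), tolerance = 1e-10)
  expect_equal(sum(w3 * pq), sum(pq), tolerance = 1e-10)
  expect_warning(iterateWeights(rep(0, 10), runif(10, 0.1, 0.5)),
                 "reset")
})

test_that("window variances are local, exhaustive on one chromosome, and flagged", {
  # a single chromosome of exactly window-size SNPs: one window, 100%
  calls <- matrix(sample(0:2, 200, replace = TRUE), 40, 5)
  rownames(calls) <- paste0("a", 1:40)
  panel <- GenotypePanel(calls, data.frame(chr = 1, pos = 1:5 * 1000))
  eff <- rnorm(5)
  w <- windowVariance(panel, eff)
  expect_equal(nrow(w), 1L)
  expect_equal(w$pctVar, 100, tolerance = 1e-10)

  # locality: a single nonzero effect only shows in windows covering it
  sim <- smallSim(seed = 24, nSnps = 300)
  qc <- qcGenotypes(sim$panel)$panel
  eff <- rep(0, nrow(qc)); eff[120] <- 1
  w <- windowVariance(qc, eff)
  covering <- w$start <= 120 & w$end >= 120
  expect_true(all(w$pctVar[covering] > 0))
  expect_true(all(w$pctVar[!covering] == 0))

  # chromosomes shorter than the window are skipped with a note
  tiny <- GenotypePanel(matrix(sample(0:2, 30, replace = TRUE), 10, 3),
                        data.frame(chr = c(1, 1, 2), pos = c(1, 2, 1)))
  expect_message(w2 <- windowVariance(tiny, rep(1, 3), window = 2),
                 "skipped")
  expect_true(all(w2$chr == "1"))
})

test_that("normal-test p-values behave at the boundaries and the threshold", {
  expect_equal(snpPvalues(0, 1), 0)                  # p = 1 -> -log10 = 0
  expect_equal(snpPvalues(5.45, 1), 7.30, tolerance = 0.005)
  expect_warning(out <- snpPvalues(c(1, 1), c(1, 0)), "zero sampling")
  expect_true(is.na(out[2]))
  expect_equal(gwasThreshold(), -log10(5e-8))
  expect_equal(round(gwasThreshold(), 2), 7.30)
})

test_that("significance machinery integrates with the solved model", {
  sim <- smallSim(seed = 25, nSnps = 500)
  qc <- qcGenotypes(sim$panel)$panel
  vc <- tableTwoVc()
  sol <- runEvaluation(sim$pheno, sim$ped, vc, panel = qc,
                       mode = "single-step",
                       uuCovFor = animalIds(qc))
  g <- ssGwas(qc, sol)
  expect_s4_class(g, "SnpEffectResult")
  expect_true(all(g@snp$weight == 1))               # single pass
  expect_false(anyNA(g@snp$logp))
  expect_true(all(g@snp$logp >= 0))
  expect_true(all(g@windows$pctVar >= 0))
  expect_identical(nrow(significantSnps(g)),
                   sum(g@snp$significant))
  # windows never span chromosome boundaries
  map <- markerMap(qc)
  expect_true(all(map$chr[g@windows$start] == map$chr[g@windows$end]))
})

test_that("gene annotation follows the signed-distance conventions", {
  genes <- data.frame(chr = c("1", "1", "2"),
                      start = c(1000, 50000, 500),
                      end = c(2000, 60000, 900),
                      gene = c("GENE_A", "GENE_B", "GENE_C"))
  snps <- data.frame(marker = c("s1", "s2", "s3", "s4"),
                     chr = c("1", "1", "1", "2"),
                     pos = c(1500, 3808, 87000, 100))
  ann <- annotateGenes(snps, genes)
  a1 <- ann[ann$marker == "s1" & ann$gene == "GENE_A", ]
  expect_equal(a1$distance, 0)
  expect_equal(a1$classification, "on_target")
  expect_equal(a1$size, 1001)
  # SNP right of the gene end: positive distance
  a2 <- ann[ann$marker == "s2" & ann$gene == "GENE_A", ]
  expect_equal(a2$distance, 1808)
  expect_equal(a2$classification, "within")
  # SNP left of a gene start: negative distance
  a2b <- ann[ann$marker == "s2" & ann$gene == "GENE_B", ]
  expect_equal(a2b$distance, -(50000 - 3808))
  expect_equal(a2b$classification, "beyond")
  # exactly 37 kb away is still "within" (inclusive boundary)
  a3 <- ann[ann$marker == "s3" & ann$gene == "GENE_B", ]
  expect_equal(a3$distance, 27000)
  expect_equal(a3$classification, "within")
  snpEdge <- data.frame(marker = "e", chr = "1", pos = 2000 + 37000)
  ae <- annotateGenes(snpEdge, genes)
  expect_equal(ae$classification[ae$gene == "GENE_A"], "within")
  # chromosomes partition the search
  expect_false("GENE_C" %in% ann$gene[ann$marker != "s4"])
  expect_error(annotateGenes(snps, transform(genes, start = end + 1)),
               "malformed")
})

test_that("BED gene tables are read with 1-based inclusive coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tGENE_A", "2\t499\t900\tGENE_C"), bed)
  genes <- readGeneBed(bed)
  expect_equal(genes$start, c(1000, 500))
  expect_equal(genes$end, c(2000, 900))
  expect_equal(genes$gene, c("GENE_A", "GENE_C"))
})
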