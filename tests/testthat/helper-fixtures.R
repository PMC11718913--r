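# Small shared fixtures, all generated in code.

# sire x dam -> two full sibs -> their offspring (F = 0.25)
fullSibPed <- function() {
  Pedigree(c("s", "d", "a", "b", "x"),
           c(NA, NA, "s", "s", "a"),
           c(NA, NA, "d", "d", "b"))
}

# unrelated sire and dam with one offspring
trioPed <- function() {
  Pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
}

# small random pedigree with some inbreeding (cousin/sib matings occur
# by chance)
randomPed <- function(n = 50, founders = 10, seed = 1) {
  set.seed(seed)
  id <- sprintf("r%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (founders + 1):n) {
    sire[i] <- id[sample.int(i - 1L, 1)]
    repeat {
      dam[i] <- id[sample.int(i - 1L, 1)]
      if (dam[i] != sire[i]) break
    }
  }
  Pedigree(id, sire, dam)
}

# tiny phenotype set: 3 cows (one with 2 records) in a 5-animal pedigree
tinyPheno <- function() {
  ped <- Pedigree(c("s", "d", "c1", "c2", "c3"),
                  c(NA, NA, "s", "s", NA),
                  c(NA, NA, "d", "d", NA))
  pheno <- data.frame(
    cow_id = c("c1", "c1", "c2", "c3", "c3"),
    parity = c(1, 2, 1, 1, 2),
    breed_group = c(1, 1, 2, 3, 3),
    herd_year = c("h1", "h1", "h2", "h2", "h1"),
    year_month = c("m1", "m2", "m1", "m2", "m1"),
    days_open = c(95, 110, 88, 102, 97))
  list(ped = ped, pheno = pheno)
}

tableTwoVc <- function() {
  VarianceComponents(varU = 18.23, varHY = 30.41, varPE = 51.19,
                     varE = 707.87)
}

# moderately sized simulated dataset shared across model/gwas tests
smallSim <- function(seed = 1, nCows = 120, nSnps = 600,
                     genotypedFraction = 0.6, qtl = NULL,
                     trueVar = c(hy = 30.41, u = 18.23, pe = 51.19,
                                 e = 707.87)) {
  cfg <- simConfig(nFounders = 40, nGenerations = 2, nCows = nCows,
                   maxParities = 3, nHerdYears = 8, nYearMonths = 6,
                   nSnps = nSnps, nChromosomes = 3,
                   genotypedFraction = genotypedFraction,
                   recordBounds = NULL, trueVar = trueVar, qtl = qtl,
                   seed = seed)
  simulateDataset(cfg)
}
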