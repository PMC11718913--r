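#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic-data
#' generator.  The defaults emulate, at roughly 1/20 desk scale, a
#' tropical crossbred dairy population with repeated days-open records:
#' ~1,500 recorded cows in the final generation with 1-5 parities each,
#' 3 breed groups, 50 herd-year and 24 year-month levels, variance
#' components (herd-year 30.41, additive 18.23, permanent environment
#' 51.19, residual 707.87 days^2), records edited to the 35-150 day
#' window, and a 29-autosome SNP panel for a genotyped subset.
#'
#' @param nFounders founder animals (generation 0).
#' @param nGenerations discrete non-overlapping generations after the
#'   founders; the recorded cows are the females of the last one.
#' @param nCows number of cows with records (final-generation females).
#' @param maxParities each cow receives between 1 and `maxParities`
#'   records (uniform), one per parity.
#' @param nHerdYears,nYearMonths numbers of herd-year (random) and
#'   year-month-of-calving (fixed) levels.
#' @param trueVar named numeric: true variances `hy`, `u`, `pe`, `e` in
#'   days^2.
#' @param recordBounds `c(min, max)` in days, or `NULL`: records
#'   outside the bounds are dropped (not truncated in value).
#' @param meanDO overall mean days open (intercept), days.
#' @param bgEffects length-3 fixed breed-group effects, days; the
#'   default `(+0.372, 0, -1.508)` makes the lowest-Holstein-fraction
#'   group genetically favourable (shorter days open).
#' @param parityEffects length-`maxParities` fixed parity effects, days.
#' @param ymSd standard deviation used to draw the fixed year-month
#'   effects, days.
#' @param nSnps,nChromosomes SNP panel size and autosome count.
#' @param mafRange founder minor-allele-frequency range, within
#'   (0, 0.5].
#' @param sireFraction fraction of a generation's offspring count used
#'   as active sires from the previous generation (default 0.05,
#'   emulating artificial-insemination breeding: paternal half-sib
#'   families of roughly twenty daughters); at least 5 sires are always used.
#' @param genotypedFraction fraction of final-generation animals
#'   returned as genotyped, in (0, 1].
#' @param missingRate fraction of genotype calls set to missing.
#' @param qtl optional data.frame with columns `marker` (index into the
#'   panel) and `effect` (days per allele copy) of biallelic QTL added
#'   to the breeding values.
#' @param seed integer seed; every generator stage derives its stream
#'   from it, so equal configs give byte-identical data.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(nFounders = 150, nGenerations = 2, nCows = 1500,
                      maxParities = 5, nHerdYears = 50, nYearMonths = 24,
                      trueVar = c(hy = 30.41, u = 18.23, pe = 51.19,
                                  e = 707.87),
                      recordBounds = c(35, 150), meanDO = 97,
                      bgEffects = c(0.372, 0, -1.508),
                      parityEffects = NULL, ymSd = 2,
                      nSnps = 2500, nChromosomes = 29,
                      mafRange = c(0.05, 0.5), sireFraction = 0.05,
                      genotypedFraction = 0.1,
                      missingRate = 0, qtl = NULL, seed = 1) {
  if (is.null(parityEffects))
    parityEffects <- c(0, 1.8, 0.9, 0, -1.6)[seq_len(maxParities)]
  cfg <- list(nFounders = nFounders, nGenerations = nGenerations,
              nCows = nCows, maxParities = maxParities,
              nHerdYears = nHerdYears, nYearMonths = nYearMonths,
              trueVar = trueVar, recordBounds = recordBounds,
              meanDO = meanDO, bgEffects = bgEffects,
              parityEffects = parityEffects, ymSd = ymSd, nSnps = nSnps,
              nChromosomes = nChromosomes, mafRange = mafRange,
              sireFraction = sireFraction,
              genotypedFraction = genotypedFraction,
              missingRate = missingRate, qtl = qtl, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' @rdname simConfig
#' @param config a `SimConfig` to validate.
#' @export
validateSimConfig <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with(config, {
    if (nFounders < 2) stop("at least two founders are required")
    if (nGenerations < 0) stop("nGenerations must be non-negative")
    if (length(trueVar) != 4 ||
        !all(c("hy", "u", "pe", "e") %in% names(trueVar)))
      stop("trueVar must name the four components hy, u, pe, e")
    if (any(trueVar < 0)) stop("variances must be non-negative")
    if (trueVar["e"] <= 0) stop("residual variance must be positive")
    if (!is.null(recordBounds)) {
      if (length(recordBounds) != 2 || recordBounds[1] >= recordBounds[2])
        stop("recordBounds must be c(min, max) with min < max")
    }
    if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
      stop("mafRange must lie within (0, 0.5]")
    if (genotypedFraction <= 0 || genotypedFraction > 1)
      stop("genotypedFraction must lie in (0, 1]")
    if (sireFraction <= 0 || sireFraction > 1)
      stop("sireFraction must lie in (0, 1]")
    if (maxParities < 1 || maxParities > 5)
      stop("maxParities must be between 1 and 5")
    if (length(bgEffects) != 3) stop("bgEffects must have length 3")
  })
  invisible(config)
}

#' Simulate a generation-discrete random-mating pedigree
#'
#' Founders (half female, half male) are followed by `nGenerations`
#' non-overlapping generations; each offspring draws a random sire and
#' a random dam from the previous generation.  Generation sizes grow
#' geometrically from `nFounders` towards the final generation, which
#' holds the `nCows` future recorded females (90% of its animals)
#' plus young males.  The result carries `generation` and `sex`
#' attributes used by the other generator stages.
#'
#' @param config a [simConfig()] object.
#' @return a [Pedigree-class], parents before offspring.
#' @export
simulatePedigree <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  nF <- config$nFounders; G <- config$nGenerations
  if (G == 0L) {           # founders only
    id <- sprintf("A%05d", seq_len(nF))
    ped <- Pedigree(id, rep(NA, nF), rep(NA, nF))
    attr(ped, "generation") <- setNames(integer(nF), id)
    attr(ped, "sex") <- setNames(rep_len(c("F", "M"), nF), id)
    return(ped)
  }
  nFinal <- ceiling(config$nCows / 0.9)
  sizes <- round(nF * (nFinal / nF)^(seq_len(G) / G))
  sizes[G] <- nFinal
  sizes <- pmax(sizes, 4L)

  id <- sprintf("A%05d", seq_len(nF + sum(sizes)))
  sire <- dam <- rep(NA_character_, length(id))
  sex <- character(length(id))
  gen <- integer(length(id))
  sex[seq_len(nF)] <- rep_len(c("F", "M"), nF)
  if (!any(sex[seq_len(nF)] == "M") || !any(sex[seq_len(nF)] == "F"))
    stop("founder set must contain both sexes")
  offset <- nF
  for (g in seq_len(G)) {
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == "M"]; females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("generation ", g - 1L, " lacks one sex; increase sizes")
    idx <- offset + seq_len(sizes[g])
    # AI breeding: a small team of active sires fathers the generation
    nSires <- min(length(males),
                  max(5L, ceiling(config$sireFraction * sizes[g])))
    males <- males[sample.int(length(males), nSires)]
    sire[idx] <- id[males[sample.int(length(males), sizes[g], replace = TRUE)]]
    dam[idx] <- id[females[sample.int(length(females), sizes[g], replace = TRUE)]]
    gen[idx] <- g
    if (g == G) {
      sx <- c(rep("F", config$nCows), rep("M", sizes[g] - config$nCows))
      if (sizes[g] < config$nCows)
        stop("final generation smaller than nCows")
      sex[idx] <- sample(sx)
    } else {
      sex[idx] <- rep_len(c("F", "M"), sizes[g])
    }
    offset <- offset + sizes[g]
  }
  ped <- Pedigree(id, sire, dam)
  ord <- match(animalIds(ped), id)
  attr(ped, "generation") <- setNames(gen[ord], id[ord])
  attr(ped, "sex") <- setNames(sex[ord], id[ord])
  ped
}

#' Cows with records implied by a simulated pedigree
#'
#' The females of the final generation, in pedigree order.
#' @param ped a pedigree from [simulatePedigree()].
#' @return character vector of cow ids.
#' @export
recordedCows <- function(ped) {
  gen <- attr(ped, "generation"); sex <- attr(ped, "sex")
  if (is.null(gen) || is.null(sex))
    stop("pedigree lacks generation/sex attributes; use simulatePedigree()")
  names(gen)[gen == max(gen) & sex == "F"]
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder alleles are drawn per marker as Bernoulli(p) with p uniform
#' in `mafRange`; every non-founder inherits one allele from each
#' parent at random (markers unlinked).  Markers are spread evenly over
#' `nChromosomes` autosomes with strictly increasing positions.  Only a
#' random `genotypedFraction` of the final generation is returned as
#' genotyped; when QTL are configured, the allele codes of every
#' pedigree animal at the QTL markers are kept in the panel metadata so
#' phenotype simulation can use them.
#'
#' @param ped pedigree from [simulatePedigree()].
#' @param config a [simConfig()] object.
#' @return a [GenotypePanel-class] of the genotyped subset.
#' @export
simulateGenotypes <- function(ped, config) {
  validateSimConfig(config)
  set.seed(config$seed + 1L)
  n <- length(ped); m <- config$nSnps
  p <- runif(m, config$mafRange[1], config$mafRange[2])
  a1 <- matrix(0L, n, m); a2 <- matrix(0L, n, m)
  founder <- is.na(ped@sire) & is.na(ped@dam)
  nf <- sum(founder)
  a1[founder, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  a2[founder, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  for (i in which(!founder)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    pick <- runif(m) < 0.5
    a1[i, ] <- ifelse(pick, a1[s, ], a2[s, ])
    pick <- runif(m) < 0.5
    a2[i, ] <- ifelse(pick, a1[d, ], a2[d, ])
  }
  calls <- a1 + a2
  rownames(calls) <- animalIds(ped)

  # marker map: even split over autosomes, strictly increasing positions
  chr <- sort(rep(seq_len(config$nChromosomes), length.out = m))
  pos <- integer(m)
  for (cc in unique(chr)) {
    ix <- which(chr == cc)
    pos[ix] <- sort(sample.int(1.2e8, length(ix)))
  }
  map <- data.frame(marker = sprintf("snp%05d", seq_len(m)), chr = chr,
                    pos = pos)

  gen <- attr(ped, "generation")
  finals <- names(gen)[gen == max(gen)]
  ng <- max(1L, round(config$genotypedFraction * length(finals)))
  gids <- sort(sample(finals, ng))
  sub <- calls[gids, , drop = FALSE]
  if (config$missingRate > 0) {
    nas <- which(runif(length(sub)) < config$missingRate)
    sub[nas] <- NA_integer_
  }
  panel <- GenotypePanel(sub, map)
  if (!is.null(config$qtl)) {
    qm <- config$qtl$marker
    S4Vectors::metadata(panel)$qtl <- config$qtl
    S4Vectors::metadata(panel)$qtlCodes <-
      calls[, qm, drop = FALSE]
  }
  panel
}

# Recursive Mendelian-sampling draw of breeding values with Var(u) = A * varU:
# founders ~ N(0, varU); offspring u = 0.5 (u_s + u_d) + phi with
# Var(phi) = varU * (0.5 - 0.25 (F_s + F_d)), adjusted for unknown parents.
drawBreedingValues <- function(ped, varU) {
  n <- length(ped)
  if (varU <= 0) return(setNames(numeric(n), ped@id))
  F <- ped@F
  u <- numeric(n)
  si <- ped@sire; di <- ped@dam
  msd <- vapply(seq_len(n), function(i) {
    s <- si[i]; d <- di[i]
    v <- if (!is.na(s) && !is.na(d)) 0.5 - 0.25 * (F[s] + F[d])
      else if (!is.na(s)) 0.75 - 0.25 * F[s]
      else if (!is.na(d)) 0.75 - 0.25 * F[d]
      else 1
    sqrt(varU * v)
  }, numeric(1))
  phi <- rnorm(n, 0, msd)
  for (i in seq_len(n)) {
    pa <- 0
    if (!is.na(si[i])) pa <- pa + 0.5 * u[si[i]]
    if (!is.na(di[i])) pa <- pa + 0.5 * u[di[i]]
    u[i] <- pa + phi[i]
  }
  setNames(u, ped@id)
}

#' Simulate repeated days-open phenotypes
#'
#' Draws all effects of the repeatability animal model
#' `y = Xb + Qh + Zu + Wp + e`: breeding values by the recursive
#' Mendelian-sampling form (so `Var(u) = A * varU` without forming A),
#' optional QTL contributions through centred marker codes, i.i.d.
#' herd-year and permanent-environment effects, fixed breed-group,
#' parity and year-month effects, and i.i.d. residuals.  Each cow
#' receives 1 to `maxParities` records; with `recordBounds` set,
#' records falling outside the window are dropped.
#'
#' @param ped pedigree from [simulatePedigree()].
#' @param panel optional [GenotypePanel-class] from
#'   [simulateGenotypes()]; only consulted for QTL codes.
#' @param config a [simConfig()] object.
#' @return list with `pheno` (data.frame: `cow_id`, `parity`,
#'   `breed_group`, `herd_year`, `year_month`, `days_open`) and `truth`
#'   (list of the drawn breeding values, permanent-environment and
#'   herd-year effects, fixed effects and QTL effects).
#' @export
simulatePhenotypes <- function(ped, panel = NULL, config) {
  validateSimConfig(config)
  set.seed(config$seed + 2L)
  v <- config$trueVar
  ids <- animalIds(ped)
  n <- length(ids)

  u <- drawBreedingValues(ped, v[["u"]])
  qtlTruth <- NULL
  if (!is.null(config$qtl)) {
    if (is.null(panel) || is.null(S4Vectors::metadata(panel)$qtlCodes))
      stop("QTL configured but panel carries no QTL codes; ",
           "run simulateGenotypes() with the same config")
    codes <- S4Vectors::metadata(panel)$qtlCodes
    eff <- config$qtl$effect
    centred <- sweep(codes, 2, colMeans(codes))
    u <- u + drop(centred[ids, , drop = FALSE] %*% eff)
    qtlTruth <- config$qtl
  }

  # breed groups (Holstein-fraction classes) at the study proportions;
  # upgrading moves an animal's fraction away from its dam's, so groups
  # are assigned per animal rather than inherited
  bg <- setNames(sample.int(3L, n, replace = TRUE,
                            prob = c(0.25, 0.46, 0.29)), ids)

  hy <- rnorm(config$nHerdYears, 0, sqrt(v[["hy"]]))
  ym <- rnorm(config$nYearMonths, 0, config$ymSd)

  cows <- recordedCows(ped)
  pe <- setNames(rnorm(length(cows), 0, sqrt(v[["pe"]])), cows)
  nrec <- sample.int(config$maxParities, length(cows), replace = TRUE)

  cow_id <- rep(cows, nrec)
  parity <- unlist(lapply(nrec, seq_len), use.names = FALSE)
  nr <- length(cow_id)
  hyLev <- sample.int(config$nHerdYears, nr, replace = TRUE)
  ymLev <- sample.int(config$nYearMonths, nr, replace = TRUE)
  y <- config$meanDO + config$bgEffects[bg[cow_id]] +
    config$parityEffects[parity] + ym[ymLev] + hy[hyLev] +
    u[cow_id] + pe[cow_id] + rnorm(nr, 0, sqrt(v[["e"]]))

  pheno <- data.frame(cow_id = cow_id, parity = parity,
                      breed_group = bg[cow_id],
                      herd_year = sprintf("HY%04d", hyLev),
                      year_month = sprintf("YM%03d", ymLev),
                      days_open = y, stringsAsFactors = FALSE,
                      row.names = NULL)
  if (!is.null(config$recordBounds)) {
    keep <- y >= config$recordBounds[1] & y <= config$recordBounds[2]
    if (mean(!keep) > 0.5)
      warning(sprintf("record bounds dropped %.0f%% of records",
                      100 * mean(!keep)))
    pheno <- pheno[keep, , drop = FALSE]
  }
  truth <- list(u = u, pe = pe,
                hy = setNames(hy, sprintf("HY%04d", seq_along(hy))),
                fixed = list(mean = config$meanDO, bg = config$bgEffects,
                             parity = config$parityEffects,
                             ym = setNames(ym, sprintf("YM%03d", seq_along(ym)))),
                breedGroup = bg, qtl = qtlTruth)
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete dataset
#'
#' Runs [simulatePedigree()], [simulateGenotypes()] and
#' [simulatePhenotypes()] under one configuration.
#'
#' @param config a [simConfig()] object.
#' @param genotypes logical; set `FALSE` to skip the SNP panel.
#' @return list `ped`, `panel` (or `NULL`), `pheno`, `truth`.
#' @export
simulateDataset <- function(config, genotypes = TRUE) {
  ped <- simulatePedigree(config)
  panel <- if (genotypes) simulateGenotypes(ped, config) else NULL
  ph <- simulatePhenotypes(ped, panel, config)
  list(ped = ped, panel = panel, pheno = ph$pheno, truth = ph$truth)
}
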