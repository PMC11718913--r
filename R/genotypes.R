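#' Construct a GenotypePanel
#'
#' @param calls integer/numeric matrix of allele counts, animals in
#'   rows, markers in columns (0/1/2, `NA` missing).  Row names are
#'   animal ids; column names are marker ids (generated when absent).
#' @param map data.frame with columns `chr` and `pos` (1-based bp),
#'   one row per marker, in the column order of `calls`.  Markers are
#'   reordered by (chr, pos) if necessary.
#' @return A [GenotypePanel-class].
#' @examples
#' calls <- rbind(a1 = c(0, 1, 2), a2 = c(2, 1, 0))
#' gp <- GenotypePanel(calls, data.frame(chr = 1, pos = c(100, 200, 300)))
#' alleleFreqs(gp)
#' @export
GenotypePanel <- function(calls, map) {
  calls <- as.matrix(calls)
  if (nrow(map) != ncol(calls))
    stop("map must have one row per marker column of calls")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("animal", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) {
    colnames(calls) <- if (!is.null(rownames(map)) &&
                           !identical(rownames(map), as.character(seq_len(nrow(map)))))
      rownames(map) else paste0("snp", seq_len(ncol(calls)))
  }
  if (!is.null(map$marker)) colnames(calls) <- as.character(map$marker)
  ord <- order(as.character(map$chr), map$pos)
  calls <- calls[, ord, drop = FALSE]
  map <- map[ord, , drop = FALSE]
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(map$chr),
    ranges = IRanges::IRanges(start = map$pos, width = 1L),
    marker = colnames(calls))
  names(rr) <- colnames(calls)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = t(calls)), rowRanges = rr)
  new("GenotypePanel", se)
}

#' @describeIn GenotypePanel animals-by-markers allele-count matrix.
#' @param object a `GenotypePanel`.
#' @export
setMethod("genotypeCalls", "GenotypePanel", function(object)
  t(SummarizedExperiment::assay(object, "calls")))

#' @describeIn GenotypePanel genotyped animal ids.
#' @export
setMethod("animalIds", "GenotypePanel", function(object) colnames(object))

#' @describeIn GenotypePanel observed alternate-allele frequency per
#'   marker (missing calls ignored).
#' @export
setMethod("alleleFreqs", "GenotypePanel", function(object) {
  calls <- SummarizedExperiment::assay(object, "calls")
  setNames(rowMeans(calls, na.rm = TRUE) / 2, rownames(calls))
})

#' @describeIn GenotypePanel marker map as a data.frame
#'   (`marker`, `chr`, `pos`).
#' @export
setMethod("markerMap", "GenotypePanel", function(object) {
  rr <- SummarizedExperiment::rowRanges(object)
  data.frame(marker = names(rr),
             chr = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             stringsAsFactors = FALSE)
})

#' @export
setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", ncol(object), "animals x", nrow(object), "markers on",
      length(unique(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object))))), "chromosomes\n")
  calls <- SummarizedExperiment::assay(object, "calls")
  miss <- mean(is.na(calls))
  cat("  missing calls:", sprintf("%.2f%%", 100 * miss), "\n")
})

#' Read and write 0/1/2 text genotypes with a marker map
#'
#' The text format is a whitespace-separated table: first column the
#' animal id, then one 0/1/2 column per marker (`NA` for missing), with
#' a header row of marker ids.  The map is a TSV with columns `marker`,
#' `chr`, `pos`.
#'
#' @param prefix path prefix; `<prefix>.geno.txt` and `<prefix>.map.tsv`
#'   are read or written.
#' @return `readGenotypes012` returns a [GenotypePanel-class];
#'   `writeGenotypes012` returns `prefix` invisibly.
#' @export
readGenotypes012 <- function(prefix) {
  g <- utils::read.table(paste0(prefix, ".geno.txt"), header = TRUE,
                         check.names = FALSE)
  map <- utils::read.table(paste0(prefix, ".map.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  calls <- as.matrix(g[, -1, drop = FALSE])
  rownames(calls) <- as.character(g[[1]])
  GenotypePanel(calls, map)
}

#' @rdname readGenotypes012
#' @param panel a [GenotypePanel-class] to write.
#' @export
writeGenotypes012 <- function(panel, prefix) {
  calls <- genotypeCalls(panel)
  df <- data.frame(id = rownames(calls), calls, check.names = FALSE)
  utils::write.table(df, paste0(prefix, ".geno.txt"), sep = " ",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(markerMap(panel), paste0(prefix, ".map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read and write PLINK bed/bim/fam genotypes
#'
#' Minimal codec for the binary PLINK 1 format (SNP-major, magic bytes
#' `0x6c 0x1b 0x01`).  Allele counts refer to the A1 allele in the bim
#' file.  bim positions are 1-based.
#'
#' @param prefix path prefix of `<prefix>.bed/.bim/.fam`.
#' @return `readPlink` returns a [GenotypePanel-class]; `writePlink`
#'   returns `prefix` invisibly.
#' @export
readPlink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + m * ceiling(n / 4))
  if (!identical(as.integer(raw[1:3]), c(108L, 27L, 1L)))
    stop("not a SNP-major PLINK bed file")
  bpm <- ceiling(n / 4)                   # bytes per marker
  body <- raw[-(1:3)]
  # decode 2-bit codes: 00=hom A1 (2), 10=het (1), 11=hom A2 (0), 01=missing
  lut <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) for (k in 0:3) {
    code <- bitwAnd(bitwShiftR(b, 2 * k), 3L)
    lut[b + 1, k + 1] <- c(2L, NA_integer_, 1L, 0L)[code + 1]
  }
  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    bytes <- as.integer(body[((j - 1) * bpm + 1):(j * bpm)])
    vals <- lut[bytes + 1, , drop = FALSE]
    calls[, j] <- as.vector(t(vals))[seq_len(n)]
  }
  rownames(calls) <- fam[[2]]
  colnames(calls) <- bim[[2]]
  GenotypePanel(calls, data.frame(marker = bim[[2]], chr = bim[[1]],
                                  pos = bim[[4]]))
}

#' @rdname readPlink
#' @param panel a [GenotypePanel-class] to write.
#' @export
writePlink <- function(panel, prefix) {
  calls <- genotypeCalls(panel)
  n <- nrow(calls); m <- ncol(calls)
  map <- markerMap(panel)
  utils::write.table(
    data.frame(map$chr, map$marker, 0, map$pos, "A", "B"),
    paste0(prefix, ".bim"), sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(rownames(calls), rownames(calls), 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = " ", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  code <- c(3L, 2L, 0L)                    # counts 0,1,2 -> 2-bit codes
  bpm <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    g <- calls[, j]
    cc <- ifelse(is.na(g), 1L, code[g + 1L])
    cc <- c(cc, rep(0L, bpm * 4 - n))
    idx <- matrix(cc, nrow = 4)
    bytes <- idx[1, ] + bitwShiftL(idx[2, ], 2) +
      bitwShiftL(idx[3, ], 4) + bitwShiftL(idx[4, ], 6)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
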