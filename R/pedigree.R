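#' Construct a Pedigree
#'
#' Builds a [Pedigree-class] from animal/sire/dam identifier triples.
#' Unknown parents are given as `NA`, `""` or `"0"`.  Rows are
#' topologically sorted (parents before offspring, original order kept
#' where possible), cycles raise an error, and inbreeding coefficients
#' are derived from the diagonal of the numerator relationship matrix.
#'
#' @param id character (or coercible) vector of unique animal ids.
#' @param sire,dam parent ids aligned with `id`; unknown as `NA`, `""`
#'   or `"0"`.  A parent id not listed in `id` is added as a founder.
#' @return A [Pedigree-class] object.
#' @examples
#' ped <- Pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' inbreeding(ped)
#' @export
Pedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have equal length")
  unknown <- function(x) is.na(x) | x == "" | x == "0"
  sire[unknown(sire)] <- NA_character_
  dam[unknown(dam)] <- NA_character_
  if (anyDuplicated(id))
    stop("duplicated animal ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  # implicit founders: parents never listed as animals
  extra <- setdiff(c(sire, dam), c(id, NA_character_))
  if (length(extra)) {
    id <- c(extra, id)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
  }
  n <- length(id)
  si <- match(sire, id); di <- match(dam, id)

  # Kahn topological sort, stable in input order
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (!is.na(p)) {
      indeg[i] <- indeg[i] + 1L
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  order_out <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order_out <- c(order_out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- sort(c(avail, k))
    }
  }
  if (length(order_out) != n)
    stop("pedigree contains a cycle (an animal is its own ancestor)")
  id <- id[order_out]
  si <- match(sire[order_out], id); di <- match(dam[order_out], id)

  F <- .inbreedingTabular(si, di)
  new("Pedigree", id = id, sire = si, dam = di, F = F)
}

# Inbreeding from the tabular-method relationship matrix: F = diag(A) - 1.
.inbreedingTabular <- function(si, di) {
  diag(.tabularA(si, di)) - 1
}

# Dense numerator relationship matrix by the tabular method.
.tabularA <- function(si, di) {
  n <- length(si)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      r <- numeric(i - 1L)
      if (!is.na(s)) r <- r + 0.5 * A[s, prev]
      if (!is.na(d)) r <- r + 0.5 * A[d, prev]
      A[i, prev] <- r
      A[prev, i] <- r
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Read a three-column pedigree CSV
#'
#' Expects columns `animal`, `sire`, `dam` (or the first three columns
#' in that order); `0`, empty and `NA` denote unknown parents.
#'
#' @param path file path of the CSV.
#' @return A [Pedigree-class].
#' @export
readPedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  cols <- intersect(c("animal", "sire", "dam"), names(df))
  if (length(cols) == 3) df <- df[cols] else df <- df[, 1:3]
  Pedigree(df[[1]], df[[2]], df[[3]])
}

#' Write a pedigree to CSV
#' @param ped a [Pedigree-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$F <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "0")
  invisible(path)
}

#' @describeIn Pedigree animal identifiers in pedigree (sorted) order.
#' @param object,x a `Pedigree`.
#' @export
setMethod("animalIds", "Pedigree", function(object) object@id)

#' @describeIn Pedigree named vector of inbreeding coefficients.
#' @export
setMethod("inbreeding", "Pedigree", function(object)
  setNames(object@F, object@id))

#' @describeIn Pedigree number of animals.
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

#' Sire and dam ids of a pedigree
#'
#' @param ped a [Pedigree-class].
#' @return character vector of parent ids (`NA` when unknown), aligned
#'   with [animalIds()].
#' @export
sireIds <- function(ped) ped@id[ped@sire]

#' @rdname sireIds
#' @export
damIds <- function(ped) ped@id[ped@dam]

#' @export
setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  founders <- sum(is.na(object@sire) & is.na(object@dam))
  cat("Pedigree with", n, "animals (", founders, "founders )\n")
  cat("  mean F:", format(mean(object@F), digits = 4),
      " max F:", format(max(object@F), digits = 4), "\n")
})

#' Coerce a Pedigree to a data.frame
#'
#' @param x a [Pedigree-class].
#' @param ... ignored.
#' @return data.frame with columns `animal`, `sire`, `dam`, `F`.
#' @export
as.data.frame.Pedigree <- function(x, ...) {
  data.frame(animal = x@id, sire = sireIds(x), dam = damIds(x),
             F = x@F, stringsAsFactors = FALSE)
}
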