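## Genotype enumeration and Hardy-Weinberg population frequencies.
##
## Conventions: loci are labelled A, B, C, ... in order; uppercase is the
## major allele (frequency 1 - MAF), lowercase the minor allele (frequency
## MAF). Enumeration is row-major over loci with the LAST locus varying
## fastest, each locus cycling (major-hom, het, minor-hom), so an order-2
## model reads AABB, AABb, AAbb, AaBB, ...

## Largest supported interaction order (3^10 = 59049 genotypes).
.ORDER_CAP <- 10L

.checkOrder <- function(order) {
  if (length(order) != 1L || !is.numeric(order) || is.na(order) ||
      order != as.integer(order) || order < 1L)
    .epiStop("invalid_argument", "'order' must be a single positive integer")
  order <- as.integer(order)
  if (order > .ORDER_CAP)
    .epiStop("invalid_argument",
             sprintf("'order' must be <= %d (got %d)", .ORDER_CAP, order))
  order
}

.checkMafs <- function(mafs) {
  if (!is.numeric(mafs) || length(mafs) < 1L || anyNA(mafs))
    .epiStop("invalid_argument",
             "'mafs' must be a non-empty numeric vector without NAs")
  if (any(mafs <= 0) || any(mafs > 0.5))
    .epiStop("invalid_argument",
             "every minor allele frequency must lie in (0, 0.5]")
  if (length(mafs) > .ORDER_CAP)
    .epiStop("invalid_argument",
             sprintf("at most %d loci are supported", .ORDER_CAP))
  as.numeric(mafs)
}

#' Enumerate multi-locus genotype combinations
#'
#' Generates the canonical ordered sequence of all \code{3^order} genotype
#' strings for \code{order} biallelic loci. Locus \code{i} uses the
#' \code{i}-th letter of the alphabet, uppercase for the major allele and
#' lowercase for the minor allele. The last locus varies fastest and each
#' locus cycles through homozygous-major, heterozygous, homozygous-minor,
#' matching the row-by-row reading of a two-locus penetrance table.
#'
#' @param order number of interacting loci, an integer in 1..10.
#' @return character vector of length \code{3^order}, e.g.
#'   \code{c("AA", "Aa", "aa")} for \code{order = 1}.
#' @examples
#' enumerateGenotypes(2)
#' @export
enumerateGenotypes <- function(order) {
  order <- .checkOrder(order)
  parts <- vector("list", order)
  for (i in seq_len(order)) {
    states <- c(paste0(LETTERS[i], LETTERS[i]),
                paste0(LETTERS[i], letters[i]),
                paste0(letters[i], letters[i]))
    parts[[i]] <- rep(rep(states, each = 3L^(order - i)),
                      times = 3L^(i - 1L))
  }
  do.call(paste0, parts)
}

## Minor-allele dosage (0/1/2 per locus) for every genotype, in canonical
## order; an n x order integer matrix. Used by the bank-model generator.
.minorCounts <- function(order) {
  counts <- matrix(0L, nrow = 3L^order, ncol = order)
  for (i in seq_len(order)) {
    counts[, i] <- rep(rep(0:2, each = 3L^(order - i)), times = 3L^(i - 1L))
  }
  counts
}

#' Hardy-Weinberg genotype frequencies
#'
#' Computes the population frequency of every multi-locus genotype from the
#' per-locus minor allele frequencies, assuming Hardy-Weinberg equilibrium
#' at each locus and linkage equilibrium (independence) between loci: the
#' frequency of a genotype is the product over loci of \eqn{(1-m)^2}
#' (homozygous major), \eqn{2m(1-m)} (heterozygous) or \eqn{m^2}
#' (homozygous minor), where \eqn{m} is that locus's MAF.
#'
#' @param mafs numeric vector of minor allele frequencies, one per locus,
#'   each in \eqn{(0, 0.5]}.
#' @return named numeric vector of length \code{3^length(mafs)} in canonical
#'   genotype order; entries sum to 1.
#' @examples
#' genotypeFrequencies(0.5)            # AA 0.25, Aa 0.5, aa 0.25
#' sum(genotypeFrequencies(c(0.1, 0.3)))
#' @export
genotypeFrequencies <- function(mafs) {
  mafs <- .checkMafs(mafs)
  perLocus <- lapply(mafs, function(m) c((1 - m)^2, 2 * m * (1 - m), m^2))
  ## kronecker nests the right operand fastest, matching the enumeration
  freqs <- Reduce(kronecker, perLocus)
  names(freqs) <- enumerateGenotypes(length(mafs))
  freqs
}
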