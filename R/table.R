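## Numeric penetrance tables: materialization from a solved model,
## realized prevalence/heritability, and CSV / GAMETES serialization.

#' PenetranceTable: a numeric penetrance table
#'
#' The full mapping of every multi-locus genotype to its penetrance
#' \eqn{P(D|g_i)}, obtained by evaluating a model's expressions at a solved
#' \code{(x, y)}, together with the realized prevalence and heritability.
#'
#' @slot name source model label.
#' @slot order interaction order.
#' @slot mafs per-locus minor allele frequencies.
#' @slot genotypes canonical genotype strings.
#' @slot penetrances numeric penetrances in \eqn{[0, 1]}, parallel to
#'   \code{genotypes}.
#' @slot x,y the solved parameter values.
#' @slot prevalence realized prevalence at construction time.
#' @slot heritability realized heritability at construction time.
#' @export
setClass("PenetranceTable",
         representation(name = "character",
                        order = "integer",
                        mafs = "numeric",
                        genotypes = "character",
                        penetrances = "numeric",
                        x = "numeric",
                        y = "numeric",
                        prevalence = "numeric",
                        heritability = "numeric"))

setValidity("PenetranceTable", function(object) {
  n <- 3L^object@order
  if (length(object@genotypes) != n || length(object@penetrances) != n)
    return(sprintf("expected %d entries", n))
  if (!identical(object@genotypes, enumerateGenotypes(object@order)))
    return("genotypes are not in canonical order")
  if (length(object@mafs) != object@order)
    return("one MAF per locus is required")
  if (any(object@penetrances < 0) || any(object@penetrances > 1))
    return("penetrances must lie in [0, 1]")
  if (abs(max(object@penetrances) - 1) > tolerableError(object@order))
    return("maximum penetrance must equal 1 within the tolerable error")
  TRUE
})

#' @describeIn PenetranceTable source model label
#' @param object a \code{PenetranceTable}
#' @export
setMethod("modelName", "PenetranceTable", function(object) object@name)

#' @describeIn PenetranceTable interaction order
#' @export
setMethod("modelOrder", "PenetranceTable", function(object) object@order)

#' @describeIn PenetranceTable canonical genotype strings
#' @export
setMethod("modelGenotypes", "PenetranceTable",
          function(object) object@genotypes)

#' @describeIn PenetranceTable minor allele frequencies
#' @export
setMethod("mafs", "PenetranceTable", function(object) object@mafs)

#' @describeIn PenetranceTable named numeric penetrances
#' @export
setMethod("penetrances", "PenetranceTable",
          function(object) setNames(object@penetrances, object@genotypes))

#' @describeIn PenetranceTable solved x
#' @export
setMethod("xValue", "PenetranceTable", function(object) object@x)

#' @describeIn PenetranceTable solved y
#' @export
setMethod("yValue", "PenetranceTable", function(object) object@y)

setMethod("show", "PenetranceTable", function(object) {
  cat(sprintf("PenetranceTable '%s': order %d, MAFs (%s)\n",
              object@name, object@order,
              paste(format(object@mafs), collapse = ", ")))
  cat(sprintf("  x = %.12g, y = %.12g\n", object@x, object@y))
  cat(sprintf("  prevalence = %.12g, heritability = %.12g\n",
              object@prevalence, object@heritability))
  k <- min(6L, length(object@genotypes))
  for (i in seq_len(k))
    cat(sprintf("  %s  %.12g\n", object@genotypes[i],
                object@penetrances[i]))
  if (length(object@genotypes) > k) cat("  ...\n")
})

#' Materialize the penetrance table for a solved model
#'
#' Evaluates every model expression at the solved \code{(x, y)}. Tiny
#' numerical excursions outside \eqn{[0, 1]} (within 1e-12) are clamped;
#' larger violations raise an inconsistent-solution error. The realized
#' prevalence and heritability are attached.
#'
#' @param model an \linkS4class{EpistasisModel}.
#' @param mafs minor allele frequencies, one per locus.
#' @param solution a \linkS4class{PenetranceSolution} for this model/MAF
#'   configuration.
#' @return a \linkS4class{PenetranceTable}.
#' @examples
#' m <- bankModel("additive", 1)
#' sol <- solveSystem(buildSystem(m, 0.5, "prevalence", 0.5))
#' buildTable(m, 0.5, sol)
#' @export
buildTable <- function(model, mafs, solution) {
  stopifnot(is(model, "EpistasisModel"),
            is(solution, "PenetranceSolution"))
  mafs <- .checkMafs(mafs)
  if (length(mafs) != model@order)
    .epiStop("invalid_argument",
             sprintf("model order is %d but %d MAFs were given",
                     model@order, length(mafs)))
  env <- list(x = solution@x, y = solution@y)
  pen <- vapply(model@expressions, eval, numeric(1), envir = env)
  if (any(!is.finite(pen)) || any(pen < -1e-12) || any(pen > 1 + 1e-12))
    .epiStop("inconsistent_solution",
             sprintf("penetrances outside [0, 1] beyond rounding tolerance (range %.6g .. %.6g)",
                     min(pen), max(pen)))
  pen <- pmin(pmax(pen, 0), 1)
  freqs <- unname(genotypeFrequencies(mafs))
  P <- sum(freqs * pen)
  h2 <- if (P > 0 && P < 1)
    sum(freqs * (pen - P)^2) / (P * (1 - P)) else NA_real_
  tab <- new("PenetranceTable",
             name = model@name, order = model@order, mafs = mafs,
             genotypes = model@genotypes, penetrances = pen,
             x = solution@x, y = solution@y,
             prevalence = P, heritability = h2)
  validObject(tab)
  tab
}

#' @rdname realizedPrevalence
#' @export
setMethod("realizedPrevalence", "PenetranceTable", function(object) {
  freqs <- unname(genotypeFrequencies(object@mafs))
  sum(freqs * object@penetrances)
})

#' @rdname realizedHeritability
#' @export
setMethod("realizedHeritability", "PenetranceTable", function(object) {
  freqs <- unname(genotypeFrequencies(object@mafs))
  P <- sum(freqs * object@penetrances)
  if (P <= 0 || P >= 1)
    .epiStop("undefined_heritability",
             sprintf("heritability is undefined at prevalence %g", P))
  sum(freqs * (object@penetrances - P)^2) / (P * (1 - P))
})

## 12 significant digits; the documented output precision of both writers.
.fmt12 <- function(v) sprintf("%.12g", v)

#' Write a penetrance table as CSV
#'
#' One line per genotype in canonical order, \code{genotype,penetrance},
#' penetrances printed with 12 significant digits, no header.
#'
#' @param table a \linkS4class{PenetranceTable}.
#' @param path file path or connection (e.g. \code{stdout()}).
#' @export
writeTableCsv <- function(table, path) {
  stopifnot(is(table, "PenetranceTable"))
  lines <- paste0(table@genotypes, ",", .fmt12(table@penetrances))
  tryCatch(writeLines(lines, path),
           error = function(err)
             .epiStop("io", sprintf("cannot write table: %s",
                                    conditionMessage(err))))
  invisible(NULL)
}

## GAMETES-style model file layout (pinned by golden tests):
##   Attribute names:  P0 .. P{k-1}        (tab-separated)
##   Minor allele frequencies: m0 .. m{k-1} (tab-separated)
##   x: / y: / Prevalence: / Heritability: one per line
##   blank line, "Table:", blank line
##   penetrances in rows of 3 (last locus fastest), one blank line between
##   successive 3x3 blocks for order >= 3.
.gametesLines <- function(table) {
  k <- table@order
  header <- c(
    paste(c("Attribute names:", paste0("P", seq_len(k) - 1L)),
          collapse = "\t"),
    paste(c("Minor allele frequencies:", .fmt12(table@mafs)),
          collapse = "\t"),
    paste0("x: ", .fmt12(table@x)),
    paste0("y: ", .fmt12(table@y)),
    paste0("Prevalence: ", .fmt12(table@prevalence)),
    paste0("Heritability: ", .fmt12(table@heritability)),
    "",
    "Table:",
    "")
  rows <- apply(matrix(.fmt12(table@penetrances), ncol = 3L, byrow = TRUE),
                1L, paste, collapse = ", ")
  if (length(rows) > 3L) {
    blocks <- split(rows, (seq_along(rows) - 1L) %/% 3L)
    rows <- unlist(lapply(seq_along(blocks), function(i)
      if (i < length(blocks)) c(blocks[[i]], "") else blocks[[i]]),
      use.names = FALSE)
  }
  c(header, rows)
}

#' Write a penetrance table in GAMETES model-file format
#'
#' Emits a GAMETES-style model file: attribute declarations with their
#' MAFs, the solved \code{x}/\code{y} and the realized prevalence and
#' heritability, followed by the penetrance block in nested 3-column
#' layout (last locus across columns, blank line between 3x3 blocks).
#' The layout is fixed and kept bit-stable under golden tests; numeric
#' values are identical to the CSV writer's. Byte-level compatibility with
#' a specific GAMETES release has not been verified.
#'
#' @param table a \linkS4class{PenetranceTable}.
#' @param path file path or connection (e.g. \code{stdout()}).
#' @export
writeGametes <- function(table, path) {
  stopifnot(is(table, "PenetranceTable"))
  tryCatch(writeLines(.gametesLines(table), path),
           error = function(err)
             .epiStop("io", sprintf("cannot write table: %s",
                                    conditionMessage(err))))
  invisible(NULL)
}
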