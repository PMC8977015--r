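## Symbolic epistasis models: the EpistasisModel class, the model CSV
## dialect, the generalized threshold/additive/multiplicative bank, and
## identification of the maximum-penetrance expression.

#' EpistasisModel: a symbolic penetrance model
#'
#' Maps every multi-locus genotype to a penetrance expression in exactly the
#' two free variables \code{x} (baseline penetrance) and \code{y} (effect
#' size). Expressions are stored as R language objects; allowed syntax is
#' numbers, the variables \code{x} and \code{y}, the operators
#' \code{+ - * / ^} and parentheses.
#'
#' @slot name model label.
#' @slot order number of interacting loci.
#' @slot genotypes character vector of \code{3^order} genotype strings in
#'   canonical order (see \code{\link{enumerateGenotypes}}).
#' @slot expressions list of language objects, parallel to
#'   \code{genotypes}.
#' @export
setClass("EpistasisModel",
         representation(name = "character",
                        order = "integer",
                        genotypes = "character",
                        expressions = "list"))

setValidity("EpistasisModel", function(object) {
  n <- 3L^object@order
  if (length(object@order) != 1L || object@order < 1L)
    return("'order' must be a single positive integer")
  if (length(object@genotypes) != n)
    return(sprintf("expected %d genotypes, found %d", n,
                   length(object@genotypes)))
  if (!identical(object@genotypes, enumerateGenotypes(object@order)))
    return("genotypes are not in canonical enumeration order")
  if (length(object@expressions) != n)
    return("one expression per genotype is required")
  ok <- vapply(object@expressions,
               function(e) is.language(e) ||
                 (is.numeric(e) && length(e) == 1L), logical(1))
  if (!all(ok))
    return("expressions must be language objects or numeric scalars")
  TRUE
})

## Probe grid on which model expressions must evaluate finite and
## nonnegative, and on which expression dominance is established. All bank
## expressions share the factor x, so dominance depends only on y; probing
## several y magnitudes covers weak and strong effect sizes.
.PROBE_X <- c(0.01, 1)
.PROBE_Y <- c(0.1, 1, 10, 100)

## Whitelist walk over an expression AST: only x, y, numbers, arithmetic.
.checkExprSyntax <- function(e, where = "expression") {
  if (is.numeric(e) && length(e) == 1L) return(invisible(TRUE))
  if (is.name(e)) {
    if (!as.character(e) %in% c("x", "y"))
      .epiStop("expression",
               sprintf("%s uses variable '%s'; only x and y are allowed",
                       where, as.character(e)))
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (!op %in% c("+", "-", "*", "/", "^", "("))
      .epiStop("expression",
               sprintf("%s uses operator or function '%s'; only + - * / ^ and parentheses are allowed",
                       where, op))
    for (a in as.list(e)[-1L]) .checkExprSyntax(a, where)
    return(invisible(TRUE))
  }
  .epiStop("expression", sprintf("%s is not a valid penetrance expression",
                                 where))
}

.parsePenetranceExpr <- function(text, where = "expression") {
  e <- tryCatch(str2lang(text),
                error = function(err)
                  .epiStop("expression",
                           sprintf("%s: cannot parse '%s'", where, text)))
  .checkExprSyntax(e, where)
  e
}

.evalExpr <- function(e, x, y) {
  eval(e, list(x = x, y = y))
}

## Probe unique expressions for finiteness/nonnegativity on the grid.
.probeModelExpressions <- function(genotypes, expressions) {
  keys <- vapply(expressions, deparse1, character(1))
  firstIdx <- which(!duplicated(keys))
  for (i in firstIdx) {
    for (xv in .PROBE_X) for (yv in .PROBE_Y) {
      v <- tryCatch(.evalExpr(expressions[[i]], xv, yv),
                    error = function(err) NaN)
      ## overflow past double range (+Inf) at the largest probes is allowed
      ## for high-order models; NaN or negative values never are, and the
      ## moderate probes (y <= 1) must stay finite
      if (is.nan(v) || v < 0 || (yv <= 1 && !is.finite(v)))
        .epiStop("expression",
                 sprintf("expression for genotype %s ('%s') is not finite and nonnegative at x=%g, y=%g",
                         genotypes[i], keys[i], xv, yv))
    }
  }
  invisible(TRUE)
}

#' Construct an epistasis model
#'
#' Builds a validated \linkS4class{EpistasisModel} from genotype strings and
#' penetrance expressions (language objects, numeric scalars, or strings to
#' be parsed). Entries are reordered to canonical genotype order; the
#' interaction order is inferred from the genotype string length.
#'
#' @param name model label.
#' @param genotypes character vector of genotype strings covering the full
#'   enumeration for the inferred order.
#' @param expressions list (or character vector) of penetrance expressions
#'   in \code{x} and \code{y}, parallel to \code{genotypes}.
#' @return an \linkS4class{EpistasisModel}.
#' @examples
#' m <- EpistasisModel("dominant", c("AA", "Aa", "aa"),
#'                     c("x", "x*(1+y)", "x*(1+y)"))
#' modelOrder(m)
#' @export
EpistasisModel <- function(name, genotypes, expressions) {
  if (!is.character(genotypes) || length(genotypes) < 1L)
    .epiStop("malformed_model", "no genotypes supplied")
  if (is.character(expressions)) expressions <- as.list(expressions)
  if (length(expressions) != length(genotypes))
    .epiStop("malformed_model",
             "genotypes and expressions must have equal length")
  expressions <- lapply(seq_along(expressions), function(i) {
    e <- expressions[[i]]
    if (is.character(e))
      e <- .parsePenetranceExpr(e, sprintf("entry %d (%s)", i, genotypes[i]))
    else .checkExprSyntax(e, sprintf("entry %d (%s)", i, genotypes[i]))
    e
  })

  lens <- unique(nchar(genotypes))
  if (length(lens) != 1L || lens %% 2L != 0L)
    .epiStop("malformed_model",
             "genotype strings must share a common even length")
  order <- lens %/% 2L
  canonical <- enumerateGenotypes(order)
  if (anyDuplicated(genotypes))
    .epiStop("malformed_model",
             sprintf("duplicate genotype(s): %s",
                     paste(unique(genotypes[duplicated(genotypes)]),
                           collapse = ", ")))
  missing <- setdiff(canonical, genotypes)
  if (length(missing))
    .epiStop("malformed_model",
             sprintf("missing genotype(s): %s",
                     paste(head(missing, 5L), collapse = ", ")))
  extra <- setdiff(genotypes, canonical)
  if (length(extra))
    .epiStop("malformed_model",
             sprintf("unknown genotype(s): %s",
                     paste(head(extra, 5L), collapse = ", ")))
  idx <- match(canonical, genotypes)
  expressions <- expressions[idx]
  .probeModelExpressions(canonical, expressions)
  new("EpistasisModel", name = as.character(name)[1L], order = order,
      genotypes = canonical, expressions = expressions)
}

#' @describeIn EpistasisModel model label
#' @param object an \code{EpistasisModel}
#' @export
setMethod("modelName", "EpistasisModel", function(object) object@name)

#' @describeIn EpistasisModel interaction order
#' @export
setMethod("modelOrder", "EpistasisModel", function(object) object@order)

#' @describeIn EpistasisModel canonical genotype strings
#' @export
setMethod("modelGenotypes", "EpistasisModel",
          function(object) object@genotypes)

#' @describeIn EpistasisModel list of penetrance expressions
#' @export
setMethod("modelExpressions", "EpistasisModel",
          function(object) object@expressions)

setMethod("show", "EpistasisModel", function(object) {
  cat(sprintf("EpistasisModel '%s': order %d, %d genotypes\n",
              object@name, object@order, length(object@genotypes)))
  k <- min(4L, length(object@genotypes))
  for (i in seq_len(k))
    cat(sprintf("  %s  ->  %s\n", object@genotypes[i],
                deparse1(object@expressions[[i]])))
  if (length(object@genotypes) > k) cat("  ...\n")
})

## ---- model CSV dialect -----------------------------------------------------

#' Read an epistasis model from CSV
#'
#' Parses the two-column model dialect: one row per genotype, no header,
#' column 1 the genotype string, column 2 the penetrance expression in
#' \code{x} and \code{y} (operators \code{+ - * / ^} or \code{**}, numbers,
#' parentheses). Surrounding whitespace is ignored and lines starting with
#' \code{#} are skipped. The row count must be a power of 3 and the
#' genotypes must cover the full enumeration for the inferred order.
#'
#' @param path file path or connection.
#' @param name model label; defaults to the file name without extension.
#' @return an \linkS4class{EpistasisModel} in canonical genotype order.
#' @export
readModelCsv <- function(path, name = NULL) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(err)
                      .epiStop("io", sprintf("cannot read model file: %s",
                                             conditionMessage(err))))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    .epiStop("malformed_model", "model file contains no entries")
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    .epiStop("malformed_model",
             sprintf("line %d does not have exactly two comma-separated fields",
                     bad[1L]))
  genotypes <- trimws(vapply(parts, `[[`, character(1), 1L))
  exprText <- trimws(vapply(parts, `[[`, character(1), 2L))
  n <- length(genotypes)
  if (abs(log(n, 3) - round(log(n, 3))) > 1e-9)
    .epiStop("malformed_model",
             sprintf("row count %d is not a power of 3", n))
  if (is.null(name)) {
    name <- if (is.character(path))
      sub("\\.[^.]*$", "", basename(path)) else "model"
  }
  EpistasisModel(name, genotypes, exprText)
}

#' Write an epistasis model to CSV
#'
#' Emits the model dialect read by \code{\link{readModelCsv}}: one
#' \code{genotype,expression} line per genotype in canonical order, with
#' expressions canonically deparsed (exponentiation printed as \code{^}).
#' Reading the result back reproduces the model exactly.
#'
#' @param model an \linkS4class{EpistasisModel}.
#' @param path file path or connection.
#' @export
writeModelCsv <- function(model, path) {
  stopifnot(is(model, "EpistasisModel"))
  lines <- paste0(model@genotypes, ",",
                  vapply(model@expressions, deparse1, character(1)))
  tryCatch(writeLines(lines, path),
           error = function(err)
             .epiStop("io", sprintf("cannot write model file: %s",
                                    conditionMessage(err))))
  invisible(NULL)
}

## ---- bank models -----------------------------------------------------------

## Canonical expression for penetrance x * (1 + y)^e.
.powerExpr <- function(e) {
  if (e == 0) quote(x)
  else if (e == 1) quote(x * (1 + y))
  else bquote(x * (1 + y)^.(e))
}

#' Generate a bank model (generalized Marchini family)
#'
#' Constructs the generalized threshold, additive or multiplicative
#' epistasis model of a given order. With \eqn{g_i} the minor-allele count
#' (0, 1 or 2) at locus \eqn{i}, the penetrance expressions are
#' \itemize{
#'   \item additive: \eqn{x (1+y)^{\sum_i g_i}}
#'   \item multiplicative: \eqn{x (1+y)^{\prod_i g_i}}
#'   \item threshold: \eqn{x (1+y)} if every locus carries at least one
#'     minor allele, otherwise \eqn{x}.
#' }
#'
#' @param family one of \code{"threshold"}, \code{"additive"},
#'   \code{"multiplicative"}.
#' @param order interaction order (>= 1; >= 2 for realistic use).
#' @return an \linkS4class{EpistasisModel} named
#'   \code{"<family>_<order>"}.
#' @examples
#' bankModel("additive", 2)
#' @export
bankModel <- function(family = c("threshold", "additive", "multiplicative"),
                      order) {
  family <- tryCatch(match.arg(family),
                     error = function(err)
                       .epiStop("invalid_argument",
                                sprintf("unknown model family '%s'",
                                        as.character(family)[1L])))
  order <- .checkOrder(order)
  counts <- .minorCounts(order)
  exps <- switch(family,
                 additive = rowSums(counts),
                 multiplicative = apply(counts, 1L, prod),
                 threshold = as.integer(rowSums(counts >= 1L) == order))
  model <- new("EpistasisModel",
               name = paste0(family, "_", order),
               order = order,
               genotypes = enumerateGenotypes(order),
               expressions = lapply(exps, .powerExpr))
  validObject(model)
  model
}

## ---- maximum-penetrance expression ----------------------------------------

#' Maximum-penetrance expression of a model
#'
#' Identifies the single expression that dominates all others for every
#' \code{x > 0}, \code{y > 0}; it is the one pinned to 1 by the solver's
#' constraint. Dominance is established by evaluation on the documented
#' probe grid (\code{x = 1}, \code{y} in 0.1, 1, 10, 100; all supported
#' expressions are proportional to \code{x}, so dominance only depends on
#' \code{y}). For the bank models this is the all-minor-homozygote entry.
#'
#' @param model an \linkS4class{EpistasisModel}.
#' @return the dominating expression as a language object.
#' @examples
#' maxPenetranceExpression(bankModel("additive", 2))  # x * (1 + y)^4
#' @export
maxPenetranceExpression <- function(model) {
  stopifnot(is(model, "EpistasisModel"))
  keys <- vapply(model@expressions, deparse1, character(1))
  uIdx <- which(!duplicated(keys))
  if (length(uIdx) == 1L) return(model@expressions[[uIdx]])
  vals <- vapply(uIdx, function(i)
    vapply(.PROBE_Y, function(yv)
      .evalExpr(model@expressions[[i]], 1, yv), numeric(1)),
    numeric(length(.PROBE_Y)))
  ## vals: length(.PROBE_Y) x length(uIdx); probe points where any
  ## expression overflows double range are dropped from the comparison
  finiteRows <- apply(is.finite(vals), 1L, all)
  if (!any(finiteRows))
    .epiStop("unsupported_model",
             "expressions are not evaluable on the dominance probe grid")
  vals <- vals[finiteRows, , drop = FALSE]
  colMax <- apply(vals, 1L, max)
  dominant <- which(vapply(seq_along(uIdx), function(j)
    all(vals[, j] >= colMax - 1e-12 * pmax(1, abs(colMax))), logical(1)))
  if (length(dominant) != 1L)
    .epiStop("unsupported_model",
             "no single expression dominates all others on the probe grid; the max-penetrance constraint is ill-posed for this model")
  model@expressions[[uIdx[dominant]]]
}
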