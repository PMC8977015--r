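## Independent brute-force verification solver. Exploits the structure of
## the max-penetrance constraint -- x * u(y) = 1 with u(y) > 0 -- to
## eliminate x in closed form, then locates the root of the resulting
## scalar equation in y by plain bisection. Works on the full, unsimplified
## 3^order genotype enumeration so that it shares no numeric machinery with
## the main solver.

## Decompose a max-penetrance expression of the form x or x * u(y); errors
## for any other shape (the oracle's documented precondition).
.constraintFactor <- function(expr) {
  if (identical(expr, quote(x))) return(quote(1))
  if (is.call(expr) && identical(expr[[1L]], as.name("*"))) {
    a <- expr[[2L]]
    b <- expr[[3L]]
    if (identical(a, quote(x)) && !("x" %in% all.vars(b))) return(b)
    if (identical(b, quote(x)) && !("x" %in% all.vars(a))) return(a)
  }
  .epiStop("unsupported_model",
           sprintf("the oracle requires a max-penetrance expression of the form x * u(y); got '%s'",
                   deparse1(expr)))
}

#' Brute-force verification solve
#'
#' An independent oracle for \code{\link{solveSystem}}: substitutes
#' \code{x = 1 / u(y)} (from the constraint \code{x * u(y) = 1}) into the
#' main equation evaluated over the full genotype enumeration, brackets a
#' sign change of the resulting scalar function of \code{y}, and bisects.
#' For a fixed prevalence the function is monotone and the bracket is found
#' by geometric expansion (upper bound doubling from 10 up to \code{2^40});
#' for a fixed heritability, which need not be monotone, a logarithmic grid
#' of 10^4 points is scanned for all sign changes and the smallest
#' admissible root is returned, matching the main solver's root-selection
#' policy. Failure to bracket is reported as an unsolvable configuration
#' (evidence, not proof, of infeasibility).
#'
#' @param model an \linkS4class{EpistasisModel} whose maximum penetrance
#'   expression has the form \code{x * u(y)} with \code{u > 0}.
#' @param mafs minor allele frequencies, one per locus.
#' @param fixedParameter \code{"prevalence"} or \code{"heritability"}.
#' @param fixedValue the fixed target, strictly in (0, 1).
#' @return a \linkS4class{PenetranceSolution}.
#' @examples
#' oracleSolve(bankModel("additive", 1), 0.5, "prevalence", 0.5)
#' @export
oracleSolve <- function(model, mafs,
                        fixedParameter = c("prevalence", "heritability"),
                        fixedValue) {
  stopifnot(is(model, "EpistasisModel"))
  fixedParameter <- match.arg(fixedParameter)
  mafs <- .checkMafs(mafs)
  if (length(mafs) != model@order)
    .epiStop("invalid_argument",
             sprintf("model order is %d but %d MAFs were given",
                     model@order, length(mafs)))
  if (fixedValue <= 0 || fixedValue > 1 ||
      (fixedParameter == "heritability" && fixedValue >= 1))
    .epiStop("invalid_argument",
             "fixedValue must lie strictly in (0, 1); a fixed prevalence may equal 1")

  uExpr <- .constraintFactor(maxPenetranceExpression(model))
  freqs <- unname(genotypeFrequencies(mafs))
  exprs <- model@expressions

  evalAll <- function(x, y) {
    env <- list(x = x, y = y)
    vapply(exprs, eval, numeric(1), envir = env)
  }
  gFun <- function(y) {
    u <- eval(uExpr, list(y = y))
    if (!is.finite(u) || u <= 0) return(NA_real_)
    x <- 1 / u
    pen <- evalAll(x, y)
    if (any(!is.finite(pen))) return(NA_real_)
    P <- sum(freqs * pen)
    val <- if (fixedParameter == "prevalence") P
           else sum(freqs * (pen - P)^2) / (P * (1 - P))
    val - fixedValue
  }

  if (!("y" %in% all.vars(uExpr)) &&
      !any(vapply(exprs, function(e) "y" %in% all.vars(e), logical(1)))) {
    g0 <- gFun(0)
    if (is.finite(g0) && abs(g0) <= 1e-8) {
      x <- 1 / eval(uExpr, list(y = 0))
      return(new("PenetranceSolution", x = x, y = 0, residual = abs(g0),
                 attempts = 1L))
    }
    .epiStop("unsolvable",
             "degenerate model (y absent) cannot meet the fixed target")
  }

  bisect <- function(a, b, ga) {
    for (it in 1:500) {
      if ((b - a) <= 1e-15 * max(1, abs(a))) break
      m <- sqrt(a * b)
      gm <- gFun(m)
      if (!is.finite(gm)) { b <- m; next }
      if (gm == 0) { a <- m; b <- m; break }
      if (sign(gm) == sign(ga)) { a <- m; ga <- gm } else b <- m
    }
    (a + b) / 2
  }

  a <- 1e-12
  ga <- gFun(a)
  if (!is.finite(ga))
    .epiStop("unsolvable", "main equation not evaluable near y = 0")

  if (fixedParameter == "prevalence") {
    ## monotone decreasing in y: expand the upper bound geometrically
    b <- 10
    gb <- gFun(b)
    while (!is.finite(gb) && b > a * 4) {
      b <- b / 4
      gb <- gFun(b)
    }
    while ((!is.finite(gb) || sign(gb) == sign(ga)) && b < 2^40) {
      bNext <- b * 2
      gNext <- gFun(bNext)
      if (!is.finite(gNext)) break
      b <- bNext
      gb <- gNext
    }
    if (!is.finite(gb) || sign(gb) == sign(ga))
      .epiStop("unsolvable",
               "no sign change found up to the y expansion cap; the configuration appears infeasible")
    root <- bisect(a, b, ga)
  } else {
    ## possibly non-monotone: scan a log grid for the smallest sign change
    yhi <- NA_real_
    for (ycand in 2^seq(40, -3)) {
      if (is.finite(gFun(ycand))) { yhi <- ycand; break }
    }
    if (!is.finite(yhi))
      .epiStop("unsolvable", "main equation not evaluable for any y > 0")
    grid <- 10^seq(log10(a), log10(yhi), length.out = 10000L)
    gPrev <- ga
    yPrev <- a
    root <- NA_real_
    for (yv in grid[-1L]) {
      gv <- gFun(yv)
      if (!is.finite(gv)) break
      if (sign(gv) != sign(gPrev)) {
        root <- bisect(yPrev, yv, gPrev)
        break
      }
      yPrev <- yv
      gPrev <- gv
    }
    if (!is.finite(root))
      .epiStop("unsolvable",
               "no sign change found on the heritability scan grid; the configuration appears infeasible")
  }

  x <- 1 / eval(uExpr, list(y = root))
  resid <- abs(gFun(root))
  new("PenetranceSolution", x = x, y = root, residual = resid,
      attempts = 1L)
}
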