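## Constrained solver: build the two-equation nonlinear system for a fixed
## prevalence or heritability, solve for (x, y) with the maximum penetrance
## pinned to 1, and check the solution against the order-dependent
## tolerable-error heuristic.
##
## Strategy: the constraint max_i f_i(x, y) = 1 defines x implicitly as a
## function of y (solved by Newton; exact in one step when the constraint is
## linear in x, as in all bank models). Substituting reduces the main
## equation to a scalar function F(y); its roots are located by a sign-change
## scan over a logarithmic y-grid and polished by bracket-safeguarded Newton
## using analytic derivatives obtained symbolically with stats::D and the
## implicit-function rule dx/dy = -c_y / c_x.

#' EquationSystem: the constrained system for one target parameter
#'
#' Holds the algebraically simplified main equation (identical penetrance
#' expressions grouped, their Hardy-Weinberg genotype frequencies summed
#' into one weight per distinct expression), the max-penetrance constraint
#' \eqn{\max_i f_i(x,y) = 1}, and symbolic partial derivatives of every
#' component.
#'
#' @slot fixedParameter \code{"prevalence"} or \code{"heritability"}.
#' @slot fixedValue the fixed target, in (0, 1).
#' @slot mafs per-locus minor allele frequencies.
#' @slot order interaction order.
#' @slot modelName label of the source model.
#' @slot termExprs distinct penetrance expressions (language objects).
#' @slot termKeys canonical deparsed form of each term.
#' @slot termWeights summed genotype frequencies per term (sum to 1).
#' @slot termDx,termDy symbolic partials of each term.
#' @slot constraint the max-penetrance expression (pinned to 1).
#' @slot constraintDx,constraintDy its symbolic partials.
#' @export
setClass("EquationSystem",
         representation(fixedParameter = "character",
                        fixedValue = "numeric",
                        mafs = "numeric",
                        order = "integer",
                        modelName = "character",
                        termExprs = "list",
                        termKeys = "character",
                        termWeights = "numeric",
                        termDx = "list",
                        termDy = "list",
                        constraint = "language",
                        constraintDx = "ANY",
                        constraintDy = "ANY"))

setValidity("EquationSystem", function(object) {
  if (!object@fixedParameter %in% c("prevalence", "heritability"))
    return("fixedParameter must be 'prevalence' or 'heritability'")
  if (object@fixedValue <= 0 || object@fixedValue > 1 ||
      (object@fixedParameter == "heritability" && object@fixedValue >= 1))
    return("fixedValue must lie in (0, 1) (prevalence may equal 1)")
  if (abs(sum(object@termWeights) - 1) > 1e-9)
    return("term weights must sum to 1")
  TRUE
})

setMethod("show", "EquationSystem", function(object) {
  lhs <- paste(sprintf("%.6g*%s", object@termWeights, object@termKeys),
               collapse = " + ")
  cat(sprintf("EquationSystem (model '%s', order %d, fixed %s = %g)\n",
              object@modelName, object@order, object@fixedParameter,
              object@fixedValue))
  if (object@fixedParameter == "prevalence") {
    cat(sprintf("  main:       %s = %g\n", lhs, object@fixedValue))
  } else {
    cat(sprintf("  main:       sum_i w_i (f_i - P)^2 / (P (1 - P)) = %g, P = %s\n",
                object@fixedValue, lhs))
  }
  cat(sprintf("  constraint: %s = 1\n", deparse1(object@constraint)))
})

#' @describeIn EquationSystem which parameter is fixed
#' @param object an \code{EquationSystem}
#' @export
setMethod("fixedParameter", "EquationSystem",
          function(object) object@fixedParameter)

#' @describeIn EquationSystem the fixed target value
#' @export
setMethod("fixedValue", "EquationSystem", function(object) object@fixedValue)

#' @describeIn EquationSystem minor allele frequencies
#' @export
setMethod("mafs", "EquationSystem", function(object) object@mafs)

#' @describeIn EquationSystem interaction order
#' @export
setMethod("modelOrder", "EquationSystem", function(object) object@order)

#' PenetranceSolution: a solved (x, y) pair
#'
#' @slot x baseline penetrance parameter, > 0.
#' @slot y effect-size parameter.
#' @slot residual absolute deviation of the fixed parameter recomputed at
#'   (x, y) from its requested value.
#' @slot attempts index in the tolerance-relaxation schedule at which the
#'   solution was accepted (1 = strictest tolerance, no relaxation needed).
#' @export
setClass("PenetranceSolution",
         representation(x = "numeric", y = "numeric",
                        residual = "numeric", attempts = "integer"))

setValidity("PenetranceSolution", function(object) {
  if (length(object@x) != 1L || !is.finite(object@x) || object@x <= 0)
    return("x must be a single finite positive number")
  if (length(object@y) != 1L || !is.finite(object@y))
    return("y must be a single finite number")
  if (object@residual < 0) return("residual must be nonnegative")
  TRUE
})

#' @describeIn PenetranceSolution value of x
#' @param object a \code{PenetranceSolution}
#' @export
setMethod("xValue", "PenetranceSolution", function(object) object@x)

#' @describeIn PenetranceSolution value of y
#' @export
setMethod("yValue", "PenetranceSolution", function(object) object@y)

#' @describeIn PenetranceSolution residual of the fixed parameter
#' @export
setMethod("residualError", "PenetranceSolution",
          function(object) object@residual)

#' @describeIn PenetranceSolution relaxation attempts used
#' @export
setMethod("attemptsUsed", "PenetranceSolution",
          function(object) object@attempts)

setMethod("show", "PenetranceSolution", function(object) {
  cat(sprintf("PenetranceSolution: x = %.15g, y = %.15g (residual %.3g, attempt %d)\n",
              object@x, object@y, object@residual, object@attempts))
})

## ---- heuristics ------------------------------------------------------------

#' Heuristic solver timeout
#'
#' Maximum solving time, in seconds, assumed from the interaction order:
#' \code{60 * (order + 1)^2}.
#'
#' @param order interaction order (>= 1).
#' @return timeout in seconds.
#' @examples
#' heuristicTimeout(2)  # 540
#' @export
heuristicTimeout <- function(order) {
  order <- .checkOrder(order)
  60 * (order + 1)^2
}

#' Order-dependent tolerable error
#'
#' The residual cap above which a solution is flagged invalid:
#' \code{min(10^order * E0, Emax)}. The base error \code{E0} scales with the
#' order because the system grows more ill-conditioned; \code{Emax} bounds
#' the guaranteed maximum deviation.
#'
#' @param order interaction order (>= 1).
#' @param E0 base error (default 1e-16).
#' @param Emax maximum allowed error (default 1e-8).
#' @return the tolerable residual.
#' @examples
#' tolerableError(2)  # 1e-14
#' tolerableError(8)  # 1e-8 (cap reached)
#' @export
tolerableError <- function(order, E0 = 1e-16, Emax = 1e-8) {
  order <- .checkOrder(order)
  if (E0 > Emax)
    .epiStop("invalid_argument", "E0 must not exceed Emax")
  min(10^order * E0, Emax)
}

#' Solver configuration
#'
#' @param check verify the solution residual after solving (default TRUE).
#' @param timeout \code{"auto"} (heuristic \code{60*(order+1)^2} seconds),
#'   \code{"none"}, or a positive number of seconds.
#' @param E0,Emax base and maximum tolerable error (see
#'   \code{\link{tolerableError}}).
#' @param relaxSchedule decreasing-strictness convergence tolerances tried
#'   in turn; the attempt index at which a root is accepted is reported in
#'   the solution. The last entry equals \code{Emax}.
#' @return a \code{"epistable_solver_config"} list.
#' @export
solverConfig <- function(check = TRUE, timeout = "auto",
                         E0 = 1e-16, Emax = 1e-8,
                         relaxSchedule = c(1e-15, 1e-12, 1e-10, 1e-8)) {
  if (is.character(timeout)) {
    if (!timeout %in% c("auto", "none"))
      .epiStop("invalid_argument",
               "'timeout' must be \"auto\", \"none\" or a positive number of seconds")
  } else if (!is.numeric(timeout) || length(timeout) != 1L || timeout <= 0) {
    .epiStop("invalid_argument",
             "'timeout' must be \"auto\", \"none\" or a positive number of seconds")
  }
  if (E0 > Emax)
    .epiStop("invalid_argument", "E0 must not exceed Emax")
  if (any(diff(relaxSchedule) < 0))
    .epiStop("invalid_argument", "relaxSchedule must be nondecreasing")
  structure(list(check = isTRUE(check), timeout = timeout,
                 E0 = E0, Emax = Emax,
                 relaxSchedule = as.numeric(relaxSchedule)),
            class = "epistable_solver_config")
}

## ---- system construction ---------------------------------------------------

#' Build the constrained equation system
#'
#' Assembles the system for one fixed target parameter. For a fixed
#' prevalence the main equation is
#' \eqn{\sum_i f_i(x,y) P(g_i) = P(D)}; for a fixed heritability it is
#' \eqn{\sum_i (f_i(x,y) - P(D))^2 P(g_i) / (P(D)(1-P(D))) = h^2} with
#' \eqn{P(D)} itself expanded as \eqn{\sum_i f_i(x,y) P(g_i)}. In both
#' cases the constraint \eqn{\max_i f_i(x,y) = 1} pins the maximum
#' penetrance, which maximizes the free parameter. The system is
#' algebraically simplified before solving by grouping identical
#' expressions and summing their genotype frequencies.
#'
#' @param model an \linkS4class{EpistasisModel}.
#' @param mafs minor allele frequencies, one per locus (length must equal
#'   the model order).
#' @param fixedParameter \code{"prevalence"} or \code{"heritability"}.
#' @param fixedValue the fixed target, strictly in (0, 1).
#' @return an \linkS4class{EquationSystem}.
#' @examples
#' sys <- buildSystem(bankModel("additive", 2), c(0.25, 0.25),
#'                    "heritability", 0.1)
#' sys
#' @export
buildSystem <- function(model, mafs,
                        fixedParameter = c("prevalence", "heritability"),
                        fixedValue) {
  stopifnot(is(model, "EpistasisModel"))
  fixedParameter <- match.arg(fixedParameter)
  mafs <- .checkMafs(mafs)
  if (length(mafs) != model@order)
    .epiStop("invalid_argument",
             sprintf("model order is %d but %d MAFs were given",
                     model@order, length(mafs)))
  if (!is.numeric(fixedValue) || length(fixedValue) != 1L ||
      !is.finite(fixedValue) || fixedValue <= 0 || fixedValue > 1 ||
      (fixedParameter == "heritability" && fixedValue >= 1))
    .epiStop("invalid_argument",
             "fixedValue must lie strictly in (0, 1); a fixed prevalence may equal 1")

  freqs <- genotypeFrequencies(mafs)
  keys <- vapply(model@expressions, deparse1, character(1))
  weights <- as.numeric(tapply(freqs, keys, sum))
  keyLevels <- names(tapply(freqs, keys, sum))
  firstIdx <- match(keyLevels, keys)
  exprs <- model@expressions[firstIdx]

  constraint <- maxPenetranceExpression(model)
  sys <- new("EquationSystem",
             fixedParameter = fixedParameter,
             fixedValue = as.numeric(fixedValue),
             mafs = mafs,
             order = model@order,
             modelName = model@name,
             termExprs = exprs,
             termKeys = keyLevels,
             termWeights = weights,
             termDx = lapply(exprs, D, name = "x"),
             termDy = lapply(exprs, D, name = "y"),
             constraint = constraint,
             constraintDx = D(constraint, "x"),
             constraintDy = D(constraint, "y"))
  validObject(sys)
  sys
}

## ---- numeric evaluation of the system --------------------------------------

.termValues <- function(sys, x, y) {
  env <- list(x = x, y = y)
  vapply(sys@termExprs, eval, numeric(1), envir = env)
}

## Main-equation value (the recomputed fixed parameter) at (x, y).
.mainValue <- function(sys, x, y, pen = NULL) {
  if (is.null(pen)) pen <- .termValues(sys, x, y)
  w <- sys@termWeights
  P <- sum(w * pen)
  if (sys@fixedParameter == "prevalence") return(P)
  V <- sum(w * (pen - P)^2)
  V / (P * (1 - P))
}

## Value plus analytic gradient wrt (x, y); returns list(value, gx, gy, pen).
.mainValueGrad <- function(sys, x, y) {
  env <- list(x = x, y = y)
  pen <- vapply(sys@termExprs, eval, numeric(1), envir = env)
  dpx <- vapply(sys@termDx, eval, numeric(1), envir = env)
  dpy <- vapply(sys@termDy, eval, numeric(1), envir = env)
  w <- sys@termWeights
  P <- sum(w * pen)
  dPx <- sum(w * dpx)
  dPy <- sum(w * dpy)
  if (sys@fixedParameter == "prevalence")
    return(list(value = P, gx = dPx, gy = dPy, pen = pen))
  V <- sum(w * (pen - P)^2)
  dVx <- sum(w * 2 * (pen - P) * (dpx - dPx))
  dVy <- sum(w * 2 * (pen - P) * (dpy - dPy))
  Dn <- P * (1 - P)
  dDnx <- (1 - 2 * P) * dPx
  dDny <- (1 - 2 * P) * dPy
  list(value = V / Dn,
       gx = (dVx * Dn - V * dDnx) / Dn^2,
       gy = (dVy * Dn - V * dDny) / Dn^2,
       pen = pen)
}

## Solve the constraint c(x, y) = 1 for x at fixed y by Newton iteration
## (one exact step when the constraint is linear in x). Returns NA when the
## constraint cannot be satisfied in double range at this y.
.solveConstraintX <- function(sys, y, x0 = 1) {
  x <- if (is.finite(x0) && x0 > 0) x0 else 1
  env <- list(x = x, y = y)
  for (it in 1:100) {
    env$x <- x
    cv <- eval(sys@constraint, env)
    ## overflow at the current iterate: retreat x and retry
    if (!is.finite(cv)) {
      if (x <= 1e-300) return(NA_real_)
      x <- x * 1e-30
      next
    }
    cx <- eval(sys@constraintDx, env)
    if (!is.finite(cx) || cx == 0) return(NA_real_)
    xn <- x - (cv - 1) / cx
    if (!is.finite(xn)) return(NA_real_)
    if (xn <= 0) xn <- x / 2
    if (abs(xn - x) <= 4 * .Machine$double.eps * abs(x)) {
      x <- xn
      break
    }
    x <- xn
  }
  env$x <- x
  cv <- eval(sys@constraint, env)
  if (!is.finite(cv) || abs(cv - 1) > 1e-9 || x <= 0) return(NA_real_)
  x
}

## Reduced scalar function F(y) = main(x(y), y) - fixedValue, with
## derivative via the implicit-function rule. Returns ok = FALSE outside
## the numerically representable region.
.reducedEval <- function(sys, y, x0 = 1, grad = TRUE) {
  x <- .solveConstraintX(sys, y, x0)
  if (!is.finite(x)) return(list(ok = FALSE))
  if (grad) {
    mv <- .mainValueGrad(sys, x, y)
    env <- list(x = x, y = y)
    cx <- eval(sys@constraintDx, env)
    cy <- eval(sys@constraintDy, env)
    xprime <- if (is.finite(cx) && cx != 0 && is.finite(cy)) -cy / cx else NA
    dF <- mv$gx * xprime + mv$gy
  } else {
    mv <- list(value = .mainValue(sys, x, y), pen = .termValues(sys, x, y))
    dF <- NA_real_
  }
  if (!is.finite(mv$value)) return(list(ok = FALSE))
  list(ok = TRUE, x = x, y = y, F = mv$value - sys@fixedValue,
       dF = dF, pen = mv$pen)
}

.checkDeadline <- function(deadline, budget) {
  if (is.finite(budget) && Sys.time() > deadline)
    .epiStop("timeout",
             sprintf("solver exceeded its time budget of %g seconds", budget))
  invisible(TRUE)
}

## Bracket-safeguarded Newton refinement of a root of F(y) in [ya, yb].
.refineRoot <- function(sys, ya, yb, Fa, Fb, xa, deadline, budget) {
  y <- exp((log(ya) + log(yb)) / 2)
  x0 <- xa
  best <- NULL
  for (it in 1:120) {
    .checkDeadline(deadline, budget)
    ev <- .reducedEval(sys, y, x0)
    if (!ev$ok) {
      ## non-evaluable interior point: shrink toward the lower end
      yb <- y
      y <- exp((log(ya) + log(yb)) / 2)
      next
    }
    x0 <- ev$x
    if (is.null(best) || abs(ev$F) < abs(best$F)) best <- ev
    if (abs(ev$F) <= 1e-17) break
    if (sign(ev$F) == sign(Fa)) {
      ya <- y; Fa <- ev$F
    } else {
      yb <- y; Fb <- ev$F
    }
    yn <- if (is.finite(ev$dF) && ev$dF != 0) y - ev$F / ev$dF else NA_real_
    if (!is.finite(yn) || yn <= ya || yn >= yb)
      yn <- exp((log(ya) + log(yb)) / 2)
    if ((yb - ya) <= 8 * .Machine$double.eps * max(1, yb) ||
        abs(yn - y) <= 2 * .Machine$double.eps * max(1, abs(y))) {
      y <- yn
      ev <- .reducedEval(sys, y, x0)
      if (ev$ok && (is.null(best) || abs(ev$F) < abs(best$F))) best <- ev
      break
    }
    y <- yn
  }
  best
}

## Locate all sign-change roots of the reduced equation on a log grid.
.scanRoots <- function(sys, deadline, budget, npts = 400) {
  ## find the largest y at which the reduced system is evaluable
  yhi <- NA_real_
  for (ycand in 10^seq(12, -8, by = -0.5)) {
    ev <- .reducedEval(sys, ycand, grad = FALSE)
    if (ev$ok) { yhi <- ycand; break }
  }
  if (!is.finite(yhi)) return(list())
  ylo <- min(1e-9, yhi / 10)
  ys <- 10^seq(log10(ylo), log10(yhi), length.out = npts)
  Fs <- rep(NA_real_, npts)
  xs <- rep(NA_real_, npts)
  x0 <- 1
  for (i in seq_len(npts)) {
    if (i %% 50L == 0L) .checkDeadline(deadline, budget)
    ev <- .reducedEval(sys, ys[i], x0, grad = FALSE)
    if (ev$ok) {
      Fs[i] <- ev$F
      xs[i] <- ev$x
      x0 <- ev$x
    }
  }
  roots <- list()
  lastGood <- NA_integer_
  for (i in seq_len(npts)) {
    if (!is.finite(Fs[i])) next
    if (Fs[i] == 0) {
      ev <- .reducedEval(sys, ys[i], xs[i])
      if (ev$ok) roots[[length(roots) + 1L]] <- ev
    } else if (is.finite(lastGood) && sign(Fs[lastGood]) != sign(Fs[i])) {
      r <- .refineRoot(sys, ys[lastGood], ys[i], Fs[lastGood], Fs[i],
                       xs[lastGood], deadline, budget)
      if (!is.null(r)) roots[[length(roots) + 1L]] <- r
    }
    lastGood <- i
  }
  roots
}

## ---- solve & check ---------------------------------------------------------

#' Solve the constrained system
#'
#' Finds \code{(x, y)} with \code{x > 0} satisfying the max-penetrance
#' constraint exactly (to machine precision) and the main equation within a
#' convergence tolerance taken from the relaxation schedule: the strictest
#' tolerance is tried first and only relaxed if no root meets it. Among
#' admissible roots (all penetrances within \eqn{[0, 1 + E_{tol}]}) the one
#' with the smallest residual is selected, ties broken by smallest
#' \code{y}. If \code{y} does not occur in the system, the canonical
#' \code{y = 0} is reported.
#'
#' @param system an \linkS4class{EquationSystem}.
#' @param config a \code{\link{solverConfig}}.
#' @return a \linkS4class{PenetranceSolution}.
#' @examples
#' sys <- buildSystem(bankModel("additive", 1), 0.5, "prevalence", 0.5)
#' solveSystem(sys)  # y = sqrt(2), x = 3 - 2*sqrt(2)
#' @export
solveSystem <- function(system, config = solverConfig()) {
  stopifnot(is(system, "EquationSystem"),
            inherits(config, "epistable_solver_config"))
  budget <- if (identical(config$timeout, "none")) Inf
            else if (identical(config$timeout, "auto"))
              heuristicTimeout(system@order)
            else as.numeric(config$timeout)
  deadline <- Sys.time() + budget
  etol <- tolerableError(system@order, config$E0, config$Emax)

  usesY <- any(vapply(system@termExprs,
                      function(e) "y" %in% all.vars(e), logical(1))) ||
    "y" %in% all.vars(system@constraint)

  if (!usesY) {
    ## degenerate system: one unknown; constraint fixes x, then the main
    ## equation either holds or the configuration is infeasible
    x <- .solveConstraintX(system, 0)
    if (!is.finite(x))
      .epiStop("unsolvable",
               "constraint cannot be satisfied for any x > 0")
    resid <- abs(.mainValue(system, x, 0) - system@fixedValue)
    if (resid > etol)
      .epiStop("unsolvable",
               sprintf("degenerate system (y absent): fixed %s deviates by %.3g from its target",
                       system@fixedParameter, resid))
    return(new("PenetranceSolution", x = x, y = 0, residual = resid,
               attempts = 1L))
  }

  roots <- .scanRoots(system, deadline, budget)
  if (length(roots) == 0L)
    .epiStop("unsolvable",
             sprintf("no admissible real root: the main equation has no sign change for %s = %g over the searchable y range",
                     system@fixedParameter, system@fixedValue))

  ## dedupe and filter to admissible roots
  ys <- vapply(roots, `[[`, numeric(1), "y")
  keep <- !duplicated(round(log10(pmax(ys, 1e-300)), 7))
  roots <- roots[keep]
  admissible <- Filter(function(r) {
    is.finite(r$x) && r$x > 0 &&
      all(r$pen >= -1e-12) && all(r$pen <= 1 + etol)
  }, roots)
  if (length(admissible) == 0L)
    .epiStop("unsolvable",
             "roots were found but none yields penetrances within [0, 1]")

  resids <- vapply(admissible, function(r) abs(r$F), numeric(1))
  yvals <- vapply(admissible, `[[`, numeric(1), "y")
  bestIdx <- order(resids, yvals)[1L]
  best <- admissible[[bestIdx]]
  bestResid <- abs(best$F)

  ## tolerance-relaxation: accept at the first schedule entry the residual
  ## satisfies; beyond the last entry the configuration is unsolved
  attempt <- which(bestResid <= config$relaxSchedule)[1L]
  if (is.na(attempt))
    .epiStop("unsolvable",
             sprintf("best root has residual %.3g, above the maximum tolerance %.3g",
                     bestResid, config$relaxSchedule[length(config$relaxSchedule)]))

  sol <- new("PenetranceSolution", x = best$x, y = best$y,
             residual = bestResid, attempts = as.integer(attempt))
  if (isTRUE(config$check)) checkSolution(system, sol)
  sol
}

#' Check a solution against the tolerable-error heuristic
#'
#' Recomputes the fixed parameter by substituting \code{(x, y)} into the
#' main equation and returns the absolute deviation from the requested
#' value. When the deviation exceeds \code{\link{tolerableError}} for the
#' system's order the solution is considered invalid and a warning is
#' raised (never an error).
#'
#' @param system an \linkS4class{EquationSystem}.
#' @param solution a \linkS4class{PenetranceSolution}.
#' @param E0,Emax tolerable-error parameters.
#' @return the residual, invisibly a plain number.
#' @export
checkSolution <- function(system, solution, E0 = 1e-16, Emax = 1e-8) {
  stopifnot(is(system, "EquationSystem"),
            is(solution, "PenetranceSolution"))
  resid <- abs(.mainValue(system, solution@x, solution@y) -
                 system@fixedValue)
  etol <- tolerableError(system@order, E0, Emax)
  if (!is.finite(resid) || resid > etol)
    .epiWarn("invalid_solution",
             sprintf("solution residual %.3g exceeds the tolerable error %.3g for order %d; the solution is considered invalid",
                     resid, etol, system@order))
  resid
}
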