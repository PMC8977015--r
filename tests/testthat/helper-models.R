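# Shared fixtures and helpers, all built in code.

# Closed-form order-1 additive solution for maf = 0.5, fixed prevalence 0.5:
# eliminating x through x = (1+y)^-2 turns the main equation into the
# quadratic t^2 - 2t - 1 = 0 in t = 1 + y, whence y = sqrt(2) and
# x = (1 + sqrt(2))^-2 = 3 - 2*sqrt(2).
closedForm1 <- list(
  y = sqrt(2),
  x = 3 - 2 * sqrt(2),
  penetrances = c(AA = 3 - 2 * sqrt(2), Aa = sqrt(2) - 1, aa = 1),
  prevalence = 0.5,
  heritability = {
    p <- c(3 - 2 * sqrt(2), sqrt(2) - 1, 1)
    w <- c(0.25, 0.5, 0.25)
    sum(w * (p - 0.5)^2) / 0.25
  })

# A flat model whose every entry is x (degenerate: y absent).
flatModel <- function(order = 2) {
  g <- enumerateGenotypes(order)
  EpistasisModel("flat", g, rep("x", length(g)))
}

# Table-2 layout of the order-2 additive model, written as CSV text.
additive2Lines <- function() {
  m <- bankModel("additive", 2)
  paste0(modelGenotypes(m), ",",
         vapply(modelExpressions(m), deparse1, character(1)))
}

# Realized value of the fixed parameter, recomputed from a table.
realizedFixed <- function(tab, fixedParameter) {
  if (fixedParameter == "prevalence") realizedPrevalence(tab)
  else realizedHeritability(tab)
}

# Try to solve one configuration; returns NULL for expected failures
# (infeasible configuration or timeout), the built table otherwise.
trySolve <- function(family, order, maf, fixedParameter, fixedValue,
                     config = solverConfig()) {
  model <- bankModel(family, order)
  sys <- buildSystem(model, rep(maf, order), fixedParameter, fixedValue)
  sol <- tryCatch(suppressWarnings(solveSystem(sys, config)),
                  epistable_unsolvable = function(e) NULL,
                  epistable_timeout = function(e) NULL)
  if (is.null(sol)) return(NULL)
  list(solution = sol, table = buildTable(model, rep(maf, order), sol),
       system = sys, model = model)
}
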