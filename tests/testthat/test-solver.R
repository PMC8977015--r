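test_that("system construction weights expressions by genotype frequency", {
  m <- bankModel("additive", 1)
  sys <- buildSystem(m, 0.5, "prevalence", 0.5)
  expect_identical(fixedParameter(sys), "prevalence")
  expect_identical(fixedValue(sys), 0.5)
  # weights of x, x(1+y), x(1+y)^2 are the HWE frequencies 1/4, 1/2, 1/4
  expect_equal(sum(sys@termWeights), 1, tolerance = 1e-15)
  w <- setNames(sys@termWeights, sys@termKeys)
  expect_equal(unname(w[["x"]]), 0.25)
  expect_equal(unname(w[["x * (1 + y)"]]), 0.5)
  expect_equal(unname(w[["x * (1 + y)^2"]]), 0.25)
  expect_identical(deparse1(sys@constraint), "x * (1 + y)^2")

  # the order-2 additive system references all nine Table-style expressions,
  # grouped into the five distinct powers
  sys2 <- buildSystem(bankModel("additive", 2), c(0.25, 0.25),
                      "prevalence", 0.3)
  expect_length(sys2@termKeys, 5L)
  expect_setequal(sys2@termKeys,
                  unique(vapply(modelExpressions(bankModel("additive", 2)),
                                deparse1, character(1))))

  expect_error(buildSystem(m, c(0.5, 0.5), "prevalence", 0.5),
               class = "epistable_invalid_argument")
  expect_error(buildSystem(m, 0.5, "prevalence", 0),
               class = "epistable_invalid_argument")
  expect_error(buildSystem(m, 0.5, "heritability", 1),
               class = "epistable_invalid_argument")
})

test_that("simplified system equals the raw weighted sum at random probes", {
  set.seed(42)
  for (fam in c("additive", "multiplicative")) {
    m <- bankModel(fam, 3)
    mafsv <- runif(3, 0.05, 0.5)
    freqs <- unname(genotypeFrequencies(mafsv))
    sys <- buildSystem(m, mafsv, "heritability", 0.2)
    for (probe in 1:20) {
      xv <- runif(1, 1e-6, 1)
      yv <- runif(1, 0.01, 10)
      pen <- vapply(modelExpressions(m), function(e)
        eval(e, list(x = xv, y = yv)), numeric(1))
      P <- sum(freqs * pen)
      raw <- sum(freqs * (pen - P)^2) / (P * (1 - P))
      simplified <- epistable:::.mainValue(sys, xv, yv)
      expect_equal(simplified, raw, tolerance = 1e-12)
    }
  }
})

test_that("timeout and tolerable-error heuristics follow their formulas", {
  expect_identical(heuristicTimeout(1), 240)
  expect_identical(heuristicTimeout(2), 540)
  expect_identical(heuristicTimeout(8), 4860)
  expect_equal(tolerableError(2), 1e-14)
  expect_equal(tolerableError(8), 1e-8)
  expect_equal(tolerableError(9), 1e-8)  # stays capped
  expect_error(tolerableError(2, E0 = 1e-6, Emax = 1e-8),
               class = "epistable_invalid_argument")
})

test_that("the closed-form order-1 configuration is solved exactly", {
  sys <- buildSystem(bankModel("additive", 1), 0.5, "prevalence", 0.5)
  sol <- solveSystem(sys)
  expect_equal(yValue(sol), closedForm1$y, tolerance = 1e-12)
  expect_equal(xValue(sol), closedForm1$x, tolerance = 1e-12)
  expect_lt(residualError(sol), 1e-14)
  expect_identical(attemptsUsed(sol), 1L)
})

test_that("degenerate systems without y are handled canonically", {
  m <- flatModel(2)
  # prevalence 1 forces x = 1; y is absent and reported as 0
  sys1 <- buildSystem(m, c(0.3, 0.3), "prevalence", 1)
  sol <- solveSystem(sys1)
  expect_equal(xValue(sol), 1)
  expect_identical(yValue(sol), 0)
  # any other prevalence contradicts the constraint x = 1
  sys2 <- buildSystem(m, c(0.3, 0.3), "prevalence", 0.5)
  expect_error(solveSystem(sys2), class = "epistable_unsolvable")
})

test_that("infeasible prevalence targets raise unsolvable, not wrong answers", {
  # threshold order 4, MAF 0.4: the prevalence cannot drop below the
  # frequency of all-carrier genotypes (~0.168), so 0.1 is unreachable
  sys <- buildSystem(bankModel("threshold", 4), rep(0.4, 4),
                     "prevalence", 0.1)
  expect_error(solveSystem(sys), class = "epistable_unsolvable")
})

test_that("solution checking warns above the tolerable error", {
  sys <- buildSystem(bankModel("additive", 1), 0.5, "prevalence", 0.5)
  sol <- solveSystem(sys)
  expect_silent(resid <- checkSolution(sys, sol))
  expect_lt(resid, 1e-14)
  # corrupt y by 1e-3: the residual must exceed tolerable_error(1) = 1e-15
  bad <- new("PenetranceSolution", x = xValue(sol),
             y = yValue(sol) + 1e-3, residual = 0, attempts = 1L)
  expect_warning(residBad <- checkSolution(sys, bad),
                 class = "epistable_invalid_solution")
  expect_gt(residBad, tolerableError(1))
})

test_that("accepted solutions satisfy the pinned-max constraint", {
  for (fam in c("threshold", "additive", "multiplicative")) {
    for (val in c(0.2, 0.6)) {
      res <- trySolve(fam, 3, 0.25, "heritability", val)
      expect_false(is.null(res))
      maxPen <- max(penetrances(res$table))
      expect_lt(abs(maxPen - 1), tolerableError(3))
      # the constraint expression itself evaluates to 1 at (x, y)
      cval <- eval(maxPenetranceExpression(res$model),
                   list(x = xValue(res$solution), y = yValue(res$solution)))
      expect_equal(cval, 1, tolerance = 1e-12)
    }
  }
})

test_that("solving is deterministic and reports relaxation attempts", {
  sys <- buildSystem(bankModel("multiplicative", 3), rep(0.2, 3),
                     "heritability", 0.4)
  s1 <- solveSystem(sys)
  s2 <- solveSystem(sys)
  expect_identical(xValue(s1), xValue(s2))
  expect_identical(yValue(s1), yValue(s2))
  expect_gte(attemptsUsed(s1), 1L)
  expect_lte(attemptsUsed(s1), 4L)
})

test_that("maximized heritability is monotone in the fixed prevalence", {
  # with the maximum penetrance pinned at 1, a lower target prevalence
  # forces a more concentrated table, hence a larger heritability
  # MAF 0.1 keeps the whole prevalence grid feasible (the threshold
  # model's floor, the all-carrier frequency, is ~0.036 there)
  for (fam in c("threshold", "additive")) {
    h2 <- vapply(c(0.15, 0.3, 0.5, 0.7, 0.9), function(p) {
      res <- trySolve(fam, 2, 0.1, "prevalence", p)
      realizedHeritability(res$table)
    }, numeric(1))
    expect_true(all(diff(h2) < 0))
  }
})

test_that("a tiny explicit timeout raises a timeout error", {
  sys <- buildSystem(bankModel("additive", 5), rep(0.2, 5),
                     "heritability", 0.3)
  expect_error(solveSystem(sys, solverConfig(timeout = 1e-9)),
               class = "epistable_timeout")
})
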