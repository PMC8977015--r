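test_that("model CSV parsing accepts the two-column dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# a comment", additive2Lines()), path)
  m <- readModelCsv(path)
  expect_s4_class(m, "EpistasisModel")
  expect_identical(modelOrder(m), 2L)
  expect_identical(modelGenotypes(m), enumerateGenotypes(2))
  expect_identical(deparse1(modelExpressions(m)[[9]]), "x * (1 + y)^4")

  # entries given out of order are restored to canonical order
  writeLines(rev(additive2Lines()), path)
  m2 <- readModelCsv(path)
  expect_identical(modelGenotypes(m2), enumerateGenotypes(2))
  expect_identical(deparse1(modelExpressions(m2)[[1]]), "x")

  # ** is accepted for exponentiation and printed back as ^
  writeLines(c("AA,x", "Aa,x*(1+y)", "aa,x*(1+y)**2"), path)
  m3 <- readModelCsv(path)
  expect_identical(deparse1(modelExpressions(m3)[[3]]), "x * (1 + y)^2")
})

test_that("malformed models are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(character(0), path)
  expect_error(readModelCsv(path), class = "epistable_malformed_model")

  lines <- additive2Lines()
  writeLines(lines[-5], path)  # AaBb missing -> 8 rows, not a power of 3
  expect_error(readModelCsv(path), class = "epistable_malformed_model")

  # full power-of-3 count but one genotype duplicated / one missing
  writeLines(c(lines[-5], lines[1]), path)
  err <- tryCatch(readModelCsv(path), error = identity)
  expect_s3_class(err, "epistable_malformed_model")
  expect_match(conditionMessage(err), "AABB|AaBb")

  writeLines(c("AA,x", "Aa,x*(1+z)", "aa,x"), path)
  expect_error(readModelCsv(path), class = "epistable_expression")

  writeLines(c("AA,x", "Aa,sin(x)", "aa,x"), path)
  expect_error(readModelCsv(path), class = "epistable_expression")
})

test_that("write/parse round-trips reproduce bank models exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  for (fam in c("threshold", "additive", "multiplicative")) {
    for (ord in 2:5) {
      m <- bankModel(fam, ord)
      writeModelCsv(m, path)
      m2 <- readModelCsv(path, name = modelName(m))
      expect_identical(modelGenotypes(m2), modelGenotypes(m))
      expect_identical(vapply(modelExpressions(m2), deparse1, character(1)),
                       vapply(modelExpressions(m), deparse1, character(1)))
    }
  }
  # an order-8 model writes 3^8 lines
  writeModelCsv(bankModel("additive", 8), path)
  expect_length(readLines(path), 6561L)
})

test_that("bundled model files match the generator", {
  for (fam in c("threshold", "additive", "multiplicative")) {
    for (ord in 2:4) {
      path <- system.file("extdata", sprintf("%s_%d.csv", fam, ord),
                          package = "epistable")
      expect_true(nzchar(path))
      m <- readModelCsv(path)
      expect_identical(
        vapply(modelExpressions(m), deparse1, character(1)),
        vapply(modelExpressions(bankModel(fam, ord)), deparse1,
               character(1)))
    }
  }
})

test_that("bank families implement the minor-allele-count rules", {
  # additive order 2 reproduces the classic two-locus table
  add2 <- bankModel("additive", 2)
  expected <- c("x", "x * (1 + y)", "x * (1 + y)^2",
                "x * (1 + y)", "x * (1 + y)^2", "x * (1 + y)^3",
                "x * (1 + y)^2", "x * (1 + y)^3", "x * (1 + y)^4")
  expect_identical(vapply(modelExpressions(add2), deparse1, character(1)),
                   expected)

  # multiplicative: exponent is the product of per-locus minor counts
  mul2 <- bankModel("multiplicative", 2)
  g <- modelGenotypes(mul2)
  expect_identical(deparse1(modelExpressions(mul2)[[which(g == "aabb")]]),
                   "x * (1 + y)^4")
  expect_identical(deparse1(modelExpressions(mul2)[[which(g == "Aabb")]]),
                   "x * (1 + y)^2")
  expect_identical(deparse1(modelExpressions(mul2)[[which(g == "AAbb")]]),
                   "x")

  # threshold: x*(1+y) iff every locus carries a minor allele
  thr3 <- bankModel("threshold", 3)
  g3 <- modelGenotypes(thr3)
  expect_identical(deparse1(modelExpressions(thr3)[[which(g3 == "AaBbCc")]]),
                   "x * (1 + y)")
  expect_identical(deparse1(modelExpressions(thr3)[[which(g3 == "AABbCc")]]),
                   "x")

  expect_error(bankModel("dominant", 2),
               class = "epistable_invalid_argument")
})

test_that("distinct-expression counts match brute-force enumeration", {
  nDistinct <- function(m)
    length(unique(vapply(modelExpressions(m), deparse1, character(1))))
  for (ord in 2:4) {
    expect_identical(nDistinct(bankModel("threshold", ord)), 2L)
    expect_identical(nDistinct(bankModel("additive", ord)), 2L * ord + 1L)
    counts <- expand.grid(rep(list(0:2), ord))
    nProducts <- length(unique(apply(counts, 1, prod)))
    expect_identical(nDistinct(bankModel("multiplicative", ord)), nProducts)
  }
})

test_that("bank expressions are nondecreasing in minor-allele count and the all-minor corner dominates", {
  yProbes <- c(0.2, 1, 5)
  for (fam in c("threshold", "additive", "multiplicative")) {
    m <- bankModel(fam, 3)
    g <- modelGenotypes(m)
    vals <- sapply(yProbes, function(yv)
      vapply(modelExpressions(m), function(e)
        eval(e, list(x = 1, y = yv)), numeric(1)))
    # adding a minor allele at locus 3 never decreases the penetrance
    het <- match(sub("CC$", "Cc", g[grepl("CC$", g)]), g)
    hom <- match(sub("CC$", "cc", g[grepl("CC$", g)]), g)
    ref <- which(grepl("CC$", g))
    expect_true(all(vals[het, ] >= vals[ref, ]))
    expect_true(all(vals[hom, ] >= vals[het, ]))
    # the maximum expression is the all-minor corner
    expect_identical(deparse1(maxPenetranceExpression(m)),
                     deparse1(modelExpressions(m)[[length(g)]]))
  }
})

test_that("maximum-penetrance expression handles trivial and ill-posed models", {
  flat <- flatModel(2)
  expect_identical(deparse1(maxPenetranceExpression(flat)), "x")
  expect_identical(deparse1(maxPenetranceExpression(bankModel("additive", 2))),
                   "x * (1 + y)^4")
  expect_identical(deparse1(maxPenetranceExpression(bankModel("threshold", 5))),
                   "x * (1 + y)")
  # two expressions that cross in y: no single dominator
  g <- enumerateGenotypes(1)
  crossing <- EpistasisModel("crossing", g, c("x", "x*y", "x/y"))
  expect_error(maxPenetranceExpression(crossing),
               class = "epistable_unsupported_model")
})
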