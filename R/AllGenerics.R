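#' @import methods
#' @importFrom stats D setNames
#' @importFrom utils head
NULL

## ---- condition helpers -----------------------------------------------------

## All package errors carry class "epistable_<kind>" plus "epistable_error" so
## callers (and the CLI) can dispatch on the failure kind.
.epiStop <- function(kind, msg) {
  stop(errorCondition(msg,
                      class = c(paste0("epistable_", kind),
                                "epistable_error", "error", "condition")))
}

.epiWarn <- function(kind, msg) {
  warning(warningCondition(msg,
                           class = c(paste0("epistable_", kind),
                                     "epistable_warning", "warning",
                                     "condition")))
}

## ---- generics --------------------------------------------------------------

#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))

#' @export
setGeneric("modelOrder", function(object) standardGeneric("modelOrder"))

#' @export
setGeneric("modelGenotypes", function(object) standardGeneric("modelGenotypes"))

#' @export
setGeneric("modelExpressions",
           function(object) standardGeneric("modelExpressions"))

#' @export
setGeneric("mafs", function(object) standardGeneric("mafs"))

#' @export
setGeneric("fixedParameter",
           function(object) standardGeneric("fixedParameter"))

#' @export
setGeneric("fixedValue", function(object) standardGeneric("fixedValue"))

#' @export
setGeneric("xValue", function(object) standardGeneric("xValue"))

#' @export
setGeneric("yValue", function(object) standardGeneric("yValue"))

#' @export
setGeneric("residualError", function(object) standardGeneric("residualError"))

#' @export
setGeneric("attemptsUsed", function(object) standardGeneric("attemptsUsed"))

#' @export
setGeneric("penetrances", function(object) standardGeneric("penetrances"))

#' Realized prevalence of a penetrance table
#'
#' Recomputes the population prevalence \eqn{P(D) = \sum_i P(D|g_i) P(g_i)}
#' from the numeric table entries and the Hardy-Weinberg genotype
#' frequencies implied by the table's minor allele frequencies.
#'
#' @param object a \linkS4class{PenetranceTable}.
#' @return the prevalence, a probability in \eqn{[0, 1]}.
#' @export
setGeneric("realizedPrevalence",
           function(object) standardGeneric("realizedPrevalence"))

#' Realized (broad-sense) heritability of a penetrance table
#'
#' Recomputes
#' \eqn{h^2 = \sum_i (P(D|g_i) - P(D))^2 P(g_i) / (P(D)(1 - P(D)))}
#' from the numeric table entries.
#'
#' @param object a \linkS4class{PenetranceTable}.
#' @return the heritability, a ratio in \eqn{[0, 1]} whenever all
#'   penetrances lie in \eqn{[0, 1]}.
#' @export
setGeneric("realizedHeritability",
           function(object) standardGeneric("realizedHeritability"))
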