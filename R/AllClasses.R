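## Central S4 classes: ItemBank, ResponseMatrix, QuadratureGrid, CATConfig,
## ThetaEstimate, CATRecord.

#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData rowData<-
#' @importFrom S4Vectors DataFrame
#' @importFrom stats dnorm plogis qlogis rnorm runif cor sd var optim
#'   rbinom quantile pchisq logLik coef pnorm qnorm cor.test uniroot
#' @importFrom utils read.csv write.csv head
NULL

.SOURCE_SCALES <- c("IAT", "GPIUS", "GAS", "CIAT")
.DOMAINS <- c("salience", "tolerance", "mood modification", "relapse",
              "withdrawal", "negative outcomes", "benefits")
.N_CATEGORIES <- 5L

#' ItemBank: a calibrated pool of graded-response-model items
#'
#' An \code{ItemBank} holds one row per item with its provenance (source
#' scale, content domain, abbreviated label), a discrimination parameter
#' \code{a} (logit slope, unitless, positive) and four strictly ordered
#' threshold parameters \code{b1 < b2 < b3 < b4} on the latent-trait (theta)
#' scale. All items are scored in five ordered categories (1--5).
#'
#' @slot items data.frame with columns \code{item_id}, \code{source_scale},
#'   \code{domain}, \code{label}, \code{a}, \code{b1}, \code{b2}, \code{b3},
#'   \code{b4}.
#' @slot nCategories integer, fixed at 5.
#' @export
setClass("ItemBank",
  representation(items = "data.frame", nCategories = "integer"),
  prototype(nCategories = .N_CATEGORIES))

setValidity("ItemBank", function(object) {
  it <- object@items
  req <- c("item_id", "source_scale", "domain", "label",
           "a", "b1", "b2", "b3", "b4")
  miss <- setdiff(req, names(it))
  if (length(miss) > 0)
    return(paste("missing item columns:", paste(miss, collapse = ", ")))
  if (nrow(it) == 0)
    return("empty bank: an ItemBank must contain at least one item")
  if (anyDuplicated(it$item_id))
    return(paste("duplicated item_id:",
                 paste(unique(it$item_id[duplicated(it$item_id)]),
                       collapse = ", ")))
  if (object@nCategories != .N_CATEGORIES)
    return("nCategories must be 5")
  bad <- it$item_id[!(it$source_scale %in% .SOURCE_SCALES)]
  if (length(bad) > 0)
    return(paste0("unknown source_scale for item(s): ",
                  paste(bad, collapse = ", "),
                  " (allowed: ", paste(.SOURCE_SCALES, collapse = ", "), ")"))
  bad <- it$item_id[!(it$domain %in% .DOMAINS)]
  if (length(bad) > 0)
    return(paste0("unknown domain for item(s): ",
                  paste(bad, collapse = ", "),
                  " (allowed: ", paste(.DOMAINS, collapse = ", "), ")"))
  num <- c("a", "b1", "b2", "b3", "b4")
  for (cl in num)
    if (!is.numeric(it[[cl]]) || anyNA(it[[cl]]) || any(!is.finite(it[[cl]])))
      return(paste("column", cl, "must be finite numeric"))
  bad <- it$item_id[it$a <= 0]
  if (length(bad) > 0)
    return(paste("non-positive discrimination (a <= 0) for item(s):",
                 paste(bad, collapse = ", ")))
  b <- as.matrix(it[, c("b1", "b2", "b3", "b4")])
  unordered <- it$item_id[apply(b, 1L, function(x) any(diff(x) <= 0))]
  if (length(unordered) > 0)
    return(paste("thresholds not strictly ordered (b1 < b2 < b3 < b4)",
                 "for item(s):", paste(unordered, collapse = ", ")))
  TRUE
})

#' ResponseMatrix: persons x items ordinal responses
#'
#' Five-category ordinal scores (file coding 1--5) for a set of persons on a
#' set of items, stored as a \linkS4class{SummarizedExperiment} with items as
#' rows and persons as columns. Person-level covariates (e.g. \code{gender},
#' \code{age_group}, \code{region}, diagnosis labels, simulation truth such
#' as \code{true_theta}) live in \code{colData}.
#'
#' @export
setClass("ResponseMatrix", contains = "SummarizedExperiment")

setValidity("ResponseMatrix", function(object) {
  if (!("scores" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'scores' is required")
  s <- SummarizedExperiment::assay(object, "scores")
  if (anyNA(s))
    return("missing responses are not supported: assay 'scores' contains NA")
  if (!all(s == round(s)) || any(s < 1) || any(s > .N_CATEGORIES))
    return("scores must be integers in 1..5")
  if (is.null(rownames(object)))
    return("items (rows) must be named by item_id")
  if (anyDuplicated(rownames(object)))
    return("duplicated item ids in rows")
  TRUE
})

#' QuadratureGrid: nodes and prior weights for posterior integration
#'
#' Equally spaced theta nodes with standard-normal prior masses renormalized
#' to sum to one; used for EAP scoring and marginal maximum likelihood.
#'
#' @slot nodes numeric, strictly increasing theta values.
#' @slot weights numeric, non-negative, summing to 1.
#' @export
setClass("QuadratureGrid",
  representation(nodes = "numeric", weights = "numeric"))

setValidity("QuadratureGrid", function(object) {
  if (length(object@nodes) < 2L) return("need at least 2 nodes")
  if (length(object@nodes) != length(object@weights))
    return("nodes and weights must have equal length")
  if (any(diff(object@nodes) <= 0)) return("nodes must be strictly increasing")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-10)
    return("weights must sum to 1 (within 1e-10)")
  TRUE
})

#' CATConfig: settings for one adaptive administration
#'
#' The estimator is EAP and the selection rule is maximum information (MIC);
#' configurable pieces are the stopping rule (\code{"none"} for full-bank
#' administration, or a positive SE threshold), the initial item (random or a
#' fixed item id), the quadrature grid, an optional maximum test length, and
#' the random seed.
#'
#' @export
setClass("CATConfig",
  representation(stoppingRule = "character", seThreshold = "numeric",
                 initialItem = "character", maxItems = "numeric",
                 grid = "QuadratureGrid", seed = "integer"))

setValidity("CATConfig", function(object) {
  if (!(object@stoppingRule %in% c("none", "se_threshold")))
    return("stoppingRule must be 'none' or 'se_threshold'")
  if (object@stoppingRule == "se_threshold" &&
      (length(object@seThreshold) != 1L || !is.finite(object@seThreshold) ||
       object@seThreshold <= 0))
    return("seThreshold must be a single positive number")
  if (length(object@maxItems) != 1L || object@maxItems < 1)
    return("maxItems must be >= 1")
  TRUE
})

#' ThetaEstimate: a scored latent-trait value
#'
#' @slot theta numeric, EAP estimate (posterior mean).
#' @slot se numeric, standard error = posterior standard deviation.
#' @slot nItemsUsed integer, number of administered items.
#' @slot trace character, administered item ids in administration order.
#' @export
setClass("ThetaEstimate",
  representation(theta = "numeric", se = "numeric",
                 nItemsUsed = "integer", trace = "character"))

setValidity("ThetaEstimate", function(object) {
  if (object@se <= 0) return("se must be positive")
  if (object@nItemsUsed != length(object@trace))
    return("nItemsUsed must equal length(trace)")
  TRUE
})

#' CATRecord: the full log of one adaptive administration
#'
#' @slot estimate final \linkS4class{ThetaEstimate}.
#' @slot steps data.frame with one row per administered item: \code{item_id},
#'   \code{response}, \code{theta}, \code{se} (interim values after the EAP
#'   update for that step).
#' @slot stopReason one of \code{"se_reached"}, \code{"bank_exhausted"},
#'   \code{"none_rule_complete"}, \code{"max_items"}.
#' @export
setClass("CATRecord",
  representation(estimate = "ThetaEstimate", steps = "data.frame",
                 stopReason = "character"))

setValidity("CATRecord", function(object) {
  if (!(object@stopReason %in%
        c("se_reached", "bank_exhausted", "none_rule_complete", "max_items")))
    return("unknown stopReason")
  if (nrow(object@steps) != object@estimate@nItemsUsed)
    return("steps must have one row per administered item")
  TRUE
})
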