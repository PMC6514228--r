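#' Construct a ResponseMatrix
#'
#' @param scores persons x items matrix of integer scores 1..5, with column
#'   names giving item ids. Row names (person ids) are optional; defaults
#'   \code{P1..Pn} are assigned.
#' @param personData optional data.frame of person covariates (one row per
#'   person): e.g. \code{gender}, \code{age_group}, \code{region}, diagnosis
#'   labels, or simulation truth (\code{true_theta}).
#' @return A \linkS4class{ResponseMatrix} (items as rows, persons as columns).
#' @export
ResponseMatrix <- function(scores, personData = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (is.null(colnames(scores)))
    stop("scores must have column names giving item ids")
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("P", seq_len(nrow(scores)))
  if (is.null(personData))
    personData <- data.frame(row.names = rownames(scores))
  cd <- S4Vectors::DataFrame(personData, row.names = rownames(scores))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scores = t(scores)), colData = cd)
  new("ResponseMatrix", se)
}

#' Accessors for ResponseMatrix
#'
#' \code{scoreMatrix} returns the persons x items integer score matrix (file
#' coding 1..5); \code{personData} the person covariates as a data.frame;
#' \code{nPersons} the number of persons; \code{itemIds} the item ids.
#'
#' @param x a \linkS4class{ResponseMatrix}.
#' @aliases scoreMatrix personData nPersons
#' @name responseMatrix-accessors
NULL

#' @rdname responseMatrix-accessors
#' @export
setMethod("scoreMatrix", "ResponseMatrix", function(x)
  t(SummarizedExperiment::assay(x, "scores")))

#' @rdname responseMatrix-accessors
#' @export
setMethod("personData", "ResponseMatrix", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname responseMatrix-accessors
#' @export
setMethod("nPersons", "ResponseMatrix", function(x) ncol(x))

#' @rdname responseMatrix-accessors
#' @export
setMethod("itemIds", "ResponseMatrix", function(x) rownames(x))

setMethod("show", "ResponseMatrix", function(object) {
  cat("ResponseMatrix:", ncol(object), "persons x", nrow(object),
      "items (scores 1-5)\n")
  cov <- names(SummarizedExperiment::colData(object))
  if (length(cov) > 0)
    cat("  person covariates:", paste(cov, collapse = ", "), "\n")
})

#' Read/write the response-matrix CSV dialect
#'
#' The CSV has a \code{person_id} column, optional covariate columns
#' (any column not named like an item), and one integer column (scores 1..5)
#' per item. Missing values are rejected.
#'
#' @param path CSV file path.
#' @param itemCols optional character vector naming the item columns; by
#'   default every column other than \code{person_id} whose values are all
#'   integers in 1..5 is treated as an item.
#' @return A \linkS4class{ResponseMatrix}.
#' @export
readResponseMatrix <- function(path, itemCols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                check.names = FALSE)
  if (!("person_id" %in% names(d))) stop("missing person_id column")
  if (is.null(itemCols)) {
    isItem <- vapply(names(d), function(nm) {
      v <- d[[nm]]
      nm != "person_id" && is.numeric(v) && !anyNA(v) &&
        all(v == round(v)) && all(v >= 1 & v <= 5)
    }, logical(1))
    itemCols <- names(d)[isItem]
  }
  if (length(itemCols) == 0) stop("no item columns found")
  sc <- as.matrix(d[, itemCols, drop = FALSE])
  rownames(sc) <- as.character(d$person_id)
  covCols <- setdiff(names(d), c("person_id", itemCols))
  pd <- d[, covCols, drop = FALSE]
  rownames(pd) <- as.character(d$person_id)
  ResponseMatrix(sc, personData = pd)
}

#' @param x a \linkS4class{ResponseMatrix}.
#' @rdname readResponseMatrix
#' @export
writeResponseMatrix <- function(x, path) {
  stopifnot(is(x, "ResponseMatrix"))
  out <- data.frame(person_id = colnames(x), personData(x),
                    scoreMatrix(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}
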