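#' @rdname itemBank-accessors
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname itemBank-accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname itemBank-accessors
#' @export
setGeneric("discrimination", function(x) standardGeneric("discrimination"))

#' @rdname itemBank-accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname itemBank-accessors
#' @export
setGeneric("itemParameters", function(x) standardGeneric("itemParameters"))

#' @rdname bankSummary
#' @export
setGeneric("bankSummary", function(bank) standardGeneric("bankSummary"))

#' @rdname responseMatrix-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname responseMatrix-accessors
#' @export
setGeneric("personData", function(x) standardGeneric("personData"))

#' @rdname responseMatrix-accessors
#' @export
setGeneric("nPersons", function(x) standardGeneric("nPersons"))
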