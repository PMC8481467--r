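NULL

#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @export
setGeneric("kinshipMatrix", function(x) standardGeneric("kinshipMatrix"))

#' @export
setGeneric("kinshipConvention", function(x) standardGeneric("kinshipConvention"))

#' @export
setGeneric("geneGroups", function(x) standardGeneric("geneGroups"))

#' @export
setGeneric("geneGroups<-", function(x, value) standardGeneric("geneGroups<-"))

#' @export
setGeneric("testInteraction", function(null, model, ...)
    standardGeneric("testInteraction"))

#' @export
setGeneric("testJoint", function(null, model, ...)
    standardGeneric("testJoint"))
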