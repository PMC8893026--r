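#' @name OtuExperiment-accessors
#' @title Accessors for OtuExperiment
#' @description \code{otuCounts} returns the count matrix oriented samples x
#'   OTUs (the orientation all statistical functions in this package take);
#'   \code{sampleData} the per-sample covariate table as a \code{data.frame};
#'   \code{otuTree} the attached phylogeny (or \code{NULL}); \code{sampleIds}
#'   and \code{otuIds} the identifier vectors.
#' @param x an [OtuExperiment-class] object.
#' @param value replacement value.
#' @return see Description.
NULL

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("otuTree", function(x) standardGeneric("otuTree"))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("otuTree<-", function(x, value) standardGeneric("otuTree<-"))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname OtuExperiment-accessors
setMethod("otuCounts", "OtuExperiment", function(x)
  t(SummarizedExperiment::assay(x, "counts")))

#' @rdname OtuExperiment-accessors
setMethod("sampleData", "OtuExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname OtuExperiment-accessors
setMethod("otuTree", "OtuExperiment", function(x) x@tree)

#' @rdname OtuExperiment-accessors
setMethod("otuTree<-", "OtuExperiment", function(x, value) {
  x@tree <- value
  methods::validObject(x)
  x
})

#' @rdname OtuExperiment-accessors
setMethod("sampleIds", "OtuExperiment", function(x) colnames(x))

#' @rdname OtuExperiment-accessors
setMethod("otuIds", "OtuExperiment", function(x) rownames(x))

#' @importMethodsFrom SummarizedExperiment show
setMethod("show", "OtuExperiment", function(object) {
  m <- SummarizedExperiment::assay(object, "counts")
  cat("OtuExperiment:", ncol(m), "samples x", nrow(m), "OTUs\n")
  cat("  reads/sample: ", paste(range(colSums(m)), collapse = "-"),
      "; tree: ", if (is.null(object@tree)) "none" else
        paste0(length(object@tree$tip.label), " tips"), "\n", sep = "")
  md <- SummarizedExperiment::colData(object)
  if (ncol(md)) cat("  metadata:", paste(colnames(md), collapse = ", "), "\n")
})
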