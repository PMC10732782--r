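#' Accessors for PhosphoSiteTable and EmbeddingSet
#'
#' `siteRecords()` returns the site data.frame, `proteinSeqs()` the
#' underlying `AAStringSet`, `rejectedRecords()` the rejection log of a
#' [PhosphoSiteTable-class].  `embeddingDim()` and `embeddingMatrix()`
#' access an [EmbeddingSet-class].
#'
#' @param x a `PhosphoSiteTable` or `EmbeddingSet`.
#' @param protein_id protein identifier (for `embeddingMatrix`).
#' @return `siteRecords`, `rejectedRecords`: a `data.frame`;
#'   `proteinSeqs`: an `AAStringSet`; `embeddingDim`: an integer;
#'   `embeddingMatrix`: a numeric matrix.
#' @name site-accessors
#' @aliases siteRecords proteinSeqs rejectedRecords embeddingDim embeddingMatrix
NULL

#' @rdname site-accessors
#' @export
setGeneric("siteRecords", function(x) standardGeneric("siteRecords"))
#' @rdname site-accessors
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))
#' @rdname site-accessors
#' @export
setGeneric("rejectedRecords", function(x) standardGeneric("rejectedRecords"))
#' @rdname site-accessors
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
#' @rdname site-accessors
#' @export
setGeneric("embeddingMatrix", function(x, protein_id) standardGeneric("embeddingMatrix"))

#' @rdname site-accessors
#' @export
setMethod("siteRecords", "PhosphoSiteTable", function(x) x@sites)
#' @rdname site-accessors
#' @export
setMethod("proteinSeqs", "PhosphoSiteTable", function(x) x@proteins)
#' @rdname site-accessors
#' @export
setMethod("rejectedRecords", "PhosphoSiteTable", function(x) x@rejected)
#' @rdname site-accessors
#' @export
setMethod("embeddingDim", "EmbeddingSet", function(x) x@dim)
#' @rdname site-accessors
#' @export
setMethod("embeddingMatrix", "EmbeddingSet", function(x, protein_id) {
  m <- x@matrices[[protein_id]]
  if (is.null(m)) stop("no embedding matrix for protein '", protein_id, "'")
  m
})

setMethod("show", "PhosphoSiteTable", function(object) {
  s <- object@sites
  cat("PhosphoSiteTable with", nrow(s), "sites on",
      length(object@proteins), "proteins\n")
  if (nrow(s)) {
    tab <- table(factor(s$label, levels = c("positive", "negative",
                                            "inferred_positive")),
                 factor(s$residue, levels = PHOSPHO_RESIDUES))
    print(tab)
  }
  if (nrow(object@rejected))
    cat(nrow(object@rejected), "rejected records (see rejectedRecords())\n")
  invisible(object)
})

setMethod("show", "EmbeddingSet", function(object) {
  cat("EmbeddingSet:", length(object@matrices), "proteins, dim =",
      object@dim, "\n")
  invisible(object)
})

setMethod("show", "StackModel", function(object) {
  cat("StackModel (two gradient-boosted bases + logistic meta-learner)\n")
  cat("  feature width:", object@featureDim, "\n")
  cat("  training classes: ", object@classCounts[1], " positive / ",
      object@classCounts[2], " negative\n", sep = "")
  cat("  meta coefficients:",
      paste(sprintf("%.3f", object@metaCoef), collapse = ", "), "\n")
  invisible(object)
})
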