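#' @import methods
#' @importFrom Biostrings AAStringSet width
NULL

#' PhosphoSiteTable: phosphosite records tied to their protein sequences
#'
#' The central data container of the package: an ordered table of candidate
#' phosphorylation sites (serine, threonine or tyrosine residues) together
#' with the protein sequences they live on.  Each site carries a 1-based
#' residue position, the residue letter, a label (`"positive"`,
#' `"negative"` or `"inferred_positive"`) and a free-text evidence source.
#'
#' Objects are normally built by [crossReference()] from raw evidence rows,
#' which also enforces the invariants: every site's protein is present, the
#' residue letter matches the sequence at that position, and no
#' (protein, position) pair occurs twice.  Records that fail are kept in a
#' rejection log rather than silently fixed.
#'
#' @slot sites `data.frame` with columns `protein_id`, `position`,
#'   `residue`, `label`, `source`.
#' @slot proteins [Biostrings::AAStringSet] of canonical-alphabet sequences,
#'   named by protein id.
#' @slot rejected `data.frame` rejection log with columns `protein_id`,
#'   `position`, `reason`.
#'
#' @seealso [crossReference()], [deriveNegatives()], [stratifiedSplit()]
#' @export
setClass("PhosphoSiteTable",
  slots = c(sites = "data.frame", proteins = "AAStringSet",
            rejected = "data.frame"),
  prototype = prototype(sites = empty_sites(),
                        proteins = Biostrings::AAStringSet(),
                        rejected = empty_rejections()))

setValidity("PhosphoSiteTable", function(object) {
  msgs <- character()
  s <- object@sites
  need <- c("protein_id", "position", "residue", "label", "source")
  if (!all(need %in% names(s)))
    msgs <- c(msgs, paste("sites must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(site_key(s$protein_id, s$position)))
      msgs <- c(msgs, "duplicate (protein_id, position) pairs in sites")
    if (nrow(s) && !all(s$protein_id %in% names(object@proteins)))
      msgs <- c(msgs, "some sites refer to proteins absent from 'proteins'")
    if (nrow(s) && !all(s$residue %in% PHOSPHO_RESIDUES))
      msgs <- c(msgs, "site residues must be S, T or Y")
    if (nrow(s) && !all(s$label %in% c("positive", "negative", "inferred_positive")))
      msgs <- c(msgs, "labels must be positive, negative or inferred_positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' EmbeddingSet: per-residue embedding matrices keyed by protein
#'
#' Holds one L x D numeric matrix per protein (row i is the embedding of
#' residue i, 1-based) plus the shared embedding dimension D.  Produced by
#' [embedProteins()] (deterministic synthetic backend or pre-computed files)
#' or [makeEmbeddings()] for class-separable fixtures.
#'
#' @slot matrices named `list` of numeric matrices, one per protein.
#' @slot dim single integer, the embedding dimension D common to all
#'   matrices.
#'
#' @seealso [embedProteins()], [assembleFeatures()], [proteinAverage()]
#' @export
setClass("EmbeddingSet",
  slots = c(matrices = "list", dim = "integer"),
  prototype = prototype(matrices = list(), dim = 0L))

setValidity("EmbeddingSet", function(object) {
  msgs <- character()
  if (length(object@matrices)) {
    if (is.null(names(object@matrices)) || any(names(object@matrices) == ""))
      msgs <- c(msgs, "matrices must be named by protein_id")
    widths <- vapply(object@matrices, ncol, integer(1))
    if (any(widths != object@dim))
      msgs <- c(msgs, "all matrices must have 'dim' columns")
    finite <- vapply(object@matrices, function(m) all(is.finite(m)), logical(1))
    if (!all(finite))
      msgs <- c(msgs, "all embedding entries must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' StackModel: fitted two-base stacking classifier
#'
#' The trained stacking ensemble: two gradient-boosted tree base classifiers
#' (one with equal class weights, one with balanced class weights) and a
#' logistic meta-learner that consumes exactly their two positive-class
#' probabilities, in fixed order (equal first, balanced second).  Built by
#' [fitStack()]; applied with [predictProba()].
#'
#' @slot baseEqual fitted xgboost booster, equal class weights.
#' @slot baseBalanced fitted xgboost booster, balanced class weights.
#' @slot metaCoef numeric length-3 vector: intercept and coefficients for
#'   (p_equal, p_balanced) in the logistic meta-learner.
#' @slot config the `stackConfig()` list used for training.
#' @slot featureDim integer, training feature width (checked at predict time).
#' @slot classCounts integer length-2 vector (positives, negatives) seen in
#'   training.
#'
#' @seealso [fitStack()], [predictProba()], [saveStackModel()]
#' @export
setClass("StackModel",
  slots = c(baseEqual = "ANY", baseBalanced = "ANY", metaCoef = "numeric",
            config = "list", featureDim = "integer", classCounts = "integer"))

setValidity("StackModel", function(object) {
  msgs <- character()
  if (length(object@metaCoef) != 3L)
    msgs <- c(msgs, "metaCoef must have length 3 (intercept, p_equal, p_balanced)")
  if (length(object@featureDim) != 1L || object@featureDim < 1L)
    msgs <- c(msgs, "featureDim must be a single positive integer")
  if (length(msgs)) msgs else TRUE
})
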