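#' @name accessors
#' @title Accessors for EQTLDataset and SurgeFit objects
#'
#' @description Slot access for the package's S4 containers. Matrix accessors
#' on `EQTLDataset` return the samples-in-rows orientation used throughout
#' the model equations (N samples by T tests / L covariates), i.e. the
#' transpose of the underlying tests-by-samples assays.
#'
#' @param x an `EQTLDataset` or `SurgeFit`.
#' @return
#' * `exprMatrix`, `dosageMatrix`: N x T numeric matrix.
#' * `covariateMatrix`: N x L numeric matrix (0 columns when no covariates).
#' * `individualOf`: factor of length N mapping samples to individuals.
#' * `testMeta`: `DataFrame` of per-test metadata (gene, variant, ...).
#' * `contextLoadings`: N x K' posterior-mean context loadings.
#' * `contextEffects`: K' x T posterior-mean context-specific eQTL effects.
#' * `sharedEffects`: length-T posterior-mean shared eQTL effects.
#' * `contextPve`, `contextPsmve`: per-retained-context variance fractions.
#' * `elboTrace`: ELBO value per coordinate-ascent iteration.
NULL

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname accessors
#' @export
setGeneric("covariateMatrix", function(x) standardGeneric("covariateMatrix"))

#' @rdname accessors
#' @export
setGeneric("individualOf", function(x) standardGeneric("individualOf"))

#' @rdname accessors
#' @export
setGeneric("testMeta", function(x) standardGeneric("testMeta"))

#' @rdname accessors
#' @export
setGeneric("contextLoadings", function(x) standardGeneric("contextLoadings"))

#' @rdname accessors
#' @export
setGeneric("contextEffects", function(x) standardGeneric("contextEffects"))

#' @rdname accessors
#' @export
setGeneric("sharedEffects", function(x) standardGeneric("sharedEffects"))

#' @rdname accessors
#' @export
setGeneric("contextPve", function(x) standardGeneric("contextPve"))

#' @rdname accessors
#' @export
setGeneric("contextPsmve", function(x) standardGeneric("contextPsmve"))

#' @rdname accessors
#' @export
setGeneric("elboTrace", function(x) standardGeneric("elboTrace"))
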