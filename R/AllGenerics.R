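#' Abundance matrix accessor
#'
#' Returns the abundance assay. By default the Bioconductor orientation
#' (proteins as rows, participants as columns); set
#' \code{participantsAsRows = TRUE} for the machine-learning orientation.
#'
#' @param x a \linkS4class{ProteoCohort}
#' @param participantsAsRows logical; transpose to participants-by-proteins.
#' @return numeric matrix.
#' @export
setGeneric("abundance", function(x, participantsAsRows = FALSE)
  standardGeneric("abundance"))

#' @rdname abundance
#' @export
setMethod("abundance", "ProteoCohort", function(x, participantsAsRows = FALSE) {
  a <- assay(x, "abundance")
  if (participantsAsRows) t(a) else a
})

#' Ternary label matrix accessor
#'
#' @param x a \linkS4class{ProteoCohort}
#' @return participant-by-6 integer matrix (1 = positive, 0 = negative,
#'   \code{NA} = missing), columns ordered as \code{conditionNames()}.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "ProteoCohort", function(x) {
  cd <- colData(x)
  m <- vapply(.labelCols(), function(lc) as.integer(cd[[lc]]),
              integer(nrow(cd)))
  dimnames(m) <- list(colnames(x), conditionNames())
  m
})

#' Phenotype table accessor
#'
#' @param x a \linkS4class{ProteoCohort}
#' @return \code{data.frame} of phenotypes, one row per participant.
#' @export
setGeneric("phenoTable", function(x) standardGeneric("phenoTable"))

#' @rdname phenoTable
#' @export
setMethod("phenoTable", "ProteoCohort", function(x) {
  cd <- as.data.frame(colData(x))
  cd[, intersect(.phenoCols(), colnames(cd)), drop = FALSE]
})

#' Site id accessor
#' @param x a \linkS4class{ProteoCohort}
#' @return character vector of site ids, one per participant.
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname siteIds
#' @export
setMethod("siteIds", "ProteoCohort", function(x)
  as.character(colData(x)$site))

#' Ground truth accessor for simulated cohorts
#' @param x a \linkS4class{ProteoCohort}
#' @return the attached \link{GroundTruth}, or \code{NULL}.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "ProteoCohort", function(x)
  metadata(x)$groundTruth)

#' Participant and protein ids
#' @param x a \linkS4class{ProteoCohort}
#' @return character vector.
#' @export
participantIds <- function(x) colnames(x)

#' @rdname participantIds
#' @export
proteinIds <- function(x) rownames(x)
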