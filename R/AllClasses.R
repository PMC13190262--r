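#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Condition panel
#'
#' The six dementia-associated conditions modelled by the toolkit, in their
#' fixed order: cognitively unimpaired controls, Alzheimer's disease (AD),
#' Parkinson's disease (PD), frontotemporal dementia (FTD), amyotrophic
#' lateral sclerosis (ALS), and previous stroke or transient ischemic attack.
#' The order is immutable across all label matrices, losses and reports.
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' conditionNames()
conditionNames <- function() {
  c("control", "AD", "PD", "FTD", "ALS", "stroke_TIA")
}

.labelCols <- function() paste0("label_", conditionNames())

.phenoCols <- function() {
  c("site", "age", "sex", "mmse", "cdr", "apoe_e2", "apoe_e4", "cdr_followup")
}

#' Cohort container for multi-condition proteomic diagnosis
#'
#' \code{ProteoCohort} extends \linkS4class{SummarizedExperiment}. The single
#' assay \code{"abundance"} holds protein abundances in relative fluorescence
#' units with proteins as rows and participants as columns; missing
#' measurements are \code{NA}. \code{colData} carries the phenotypes
#' (\code{site}, \code{age}, \code{sex}, \code{mmse}, \code{cdr},
#' \code{apoe_e2}, \code{apoe_e4}, \code{cdr_followup}) and one ternary label
#' column per condition (\code{label_control} ... \code{label_stroke_TIA};
#' 1 = positive, 0 = negative, \code{NA} = missing). Simulated cohorts store
#' their \link{GroundTruth} in \code{metadata(x)$groundTruth}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{ProteoCohort}} (constructor), \code{\link{labelMatrix}},
#'   \code{\link{simulateCohort}}, \code{\link{readCohort}}
#' @exportClass ProteoCohort
setClass("ProteoCohort", contains = "SummarizedExperiment")

.validProteoCohort <- function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  cd <- colData(object)
  need <- c("site", "age", "sex", .labelCols())
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing colData columns: ", paste(miss, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "protein ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "participant ids (colnames) must be present and unique")
  for (lc in intersect(.labelCols(), colnames(cd))) {
    v <- cd[[lc]]
    if (!all(v %in% c(0L, 1L, NA)))
      msg <- c(msg, paste0(lc, " must contain only 0, 1 or NA"))
  }
  if ("mmse" %in% colnames(cd)) {
    m <- cd$mmse
    if (any(!is.na(m) & (m < 0 | m > 30)))
      msg <- c(msg, "mmse must lie in [0, 30] when present")
  }
  if (length(msg)) msg else TRUE
}

setValidity("ProteoCohort", .validProteoCohort)

#' Construct a ProteoCohort
#'
#' @param abundance numeric matrix of protein abundances (relative
#'   fluorescence units). Participants as rows and proteins as columns, the
#'   layout of the on-disk tables; it is transposed into the
#'   features-by-samples orientation internally. \code{NA} entries are
#'   allowed.
#' @param phenotypes \code{data.frame} with one row per participant
#'   (rownames = participant ids) and at least columns \code{site},
#'   \code{age}, \code{sex}; optionally \code{mmse}, \code{cdr},
#'   \code{apoe_e2}, \code{apoe_e4} and \code{cdr_followup} (comma-separated
#'   follow-up CDR stages).
#' @param labels participant-by-6 matrix (or data.frame) of ternary labels in
#'   \{1, 0, NA\}; columns must be \code{conditionNames()}.
#' @param groundTruth optional \link{GroundTruth} for simulated cohorts.
#'
#' @return A \linkS4class{ProteoCohort}.
#' @export
ProteoCohort <- function(abundance, phenotypes, labels, groundTruth = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    stop("abundance must have participant ids as rownames")
  ids <- rownames(abundance)
  if (!setequal(ids, rownames(phenotypes)) || !setequal(ids, rownames(labels))) {
    bad <- unique(c(
      setdiff(ids, rownames(phenotypes)), setdiff(rownames(phenotypes), ids),
      setdiff(ids, rownames(labels)), setdiff(rownames(labels), ids)))
    stop("participant ids do not align across tables; offending ids: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  labels <- as.matrix(labels)[ids, conditionNames(), drop = FALSE]
  storage.mode(labels) <- "integer"
  phenotypes <- as.data.frame(phenotypes)[ids, , drop = FALSE]
  for (col in setdiff(.phenoCols(), colnames(phenotypes))) {
    phenotypes[[col]] <- if (col == "cdr_followup") NA_character_ else NA_real_
  }
  cd <- DataFrame(phenotypes, check.names = FALSE)
  for (i in seq_along(conditionNames()))
    cd[[.labelCols()[i]]] <- labels[, i]
  se <- SummarizedExperiment(
    assays = list(abundance = t(abundance)),
    colData = cd)
  obj <- new("ProteoCohort", se)
  if (!is.null(groundTruth)) metadata(obj)$groundTruth <- groundTruth
  obj
}

#' @describeIn ProteoCohort-class compact display
#' @param object a \code{ProteoCohort}
#' @export
setMethod("show", "ProteoCohort", function(object) {
  cat("ProteoCohort:", ncol(object), "participants x", nrow(object), "proteins\n")
  cat("  sites:", length(unique(colData(object)$site)), "\n")
  lm <- labelMatrix(object)
  pos <- colSums(lm == 1L, na.rm = TRUE)
  obs <- colSums(!is.na(lm))
  cat("  labels (positive/observed):\n")
  for (i in seq_along(conditionNames()))
    cat(sprintf("    %-10s %5d / %5d\n", conditionNames()[i], pos[i], obs[i]))
  na_frac <- mean(is.na(assay(object, "abundance")))
  cat(sprintf("  missing abundance entries: %.2f%%\n", 100 * na_frac))
  if (!is.null(metadata(object)$groundTruth))
    cat("  simulated cohort with attached ground truth\n")
  invisible(NULL)
})

#' Train/validation/test split plan
#'
#' Holds the rotations of a site-stratified k-fold plan or a
#' leave-one-site-out plan. Each rotation is a list with character id
#' vectors \code{train}, \code{validation} and \code{test}; the three sets
#' are disjoint within a rotation.
#'
#' @slot scheme \code{"stratified-kfold"} or \code{"leave-one-site-out"}.
#' @slot folds list of rotations.
#' @slot seed integer seed the plan was built with.
#' @seealso \code{\link{makeStratifiedKFold}}, \code{\link{makeLeaveOneSiteOut}}
#' @exportClass SplitPlan
setClass("SplitPlan", representation(
  scheme = "character", folds = "list", seed = "integer"))

setValidity("SplitPlan", function(object) {
  msg <- character()
  if (!object@scheme %in% c("stratified-kfold", "leave-one-site-out"))
    msg <- c(msg, "scheme must be 'stratified-kfold' or 'leave-one-site-out'")
  for (i in seq_along(object@folds)) {
    f <- object@folds[[i]]
    if (!all(c("train", "validation", "test") %in% names(f))) {
      msg <- c(msg, sprintf("rotation %d lacks train/validation/test", i))
      next
    }
    all_ids <- c(f$train, f$validation, f$test)
    if (anyDuplicated(all_ids))
      msg <- c(msg, sprintf("rotation %d has overlapping splits", i))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SplitPlan-class compact display
#' @param object a \code{SplitPlan}
#' @export
setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan (", object@scheme, "), ", length(object@folds),
      " rotations, seed ", object@seed, "\n", sep = "")
  sizes <- vapply(object@folds, function(f)
    c(length(f$train), length(f$validation), length(f$test)), numeric(3))
  cat("  train/val/test sizes: ",
      paste(apply(sizes, 2, paste, collapse = "/")[seq_len(min(5, ncol(sizes)))],
            collapse = ", "),
      if (ncol(sizes) > 5) ", ..." else "", "\n", sep = "")
  invisible(NULL)
})
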