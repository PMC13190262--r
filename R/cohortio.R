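#' @importFrom data.table fread fwrite as.data.table
NULL

# TSV dialect: UTF-8, "." decimal, empty cell = missing (bit-exact across locales)
.LABEL_TOKENS <- c(positive = 1L, negative = 0L)

#' Write a cohort to delimited text
#'
#' Writes \code{abundance.tsv}, \code{phenotypes.tsv} and \code{labels.tsv}
#' (TSV, header row, first column \code{participant_id}, empty cell =
#' missing; labels written as \code{positive}/\code{negative}/empty). A
#' simulated cohort additionally gets a \code{groundtruth.json} sidecar with
#' the planted protein sets, their fold changes and the generating
#' configuration.
#'
#' @param cohort a \linkS4class{ProteoCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- abundance(cohort, participantsAsRows = TRUE)
  ab <- data.frame(participant_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fwrite(ab, file.path(dir, "abundance.tsv"), sep = "\t", na = "", quote = FALSE)

  ph <- phenoTable(cohort)
  ph <- cbind(participant_id = rownames(ph), ph)
  fwrite(ph, file.path(dir, "phenotypes.tsv"), sep = "\t", na = "", quote = FALSE)

  lm <- labelMatrix(cohort)
  tok <- matrix(names(.LABEL_TOKENS)[match(lm, .LABEL_TOKENS)],
                nrow(lm), ncol(lm), dimnames = dimnames(lm))
  lab <- data.frame(participant_id = rownames(lm), tok,
                    check.names = FALSE, stringsAsFactors = FALSE)
  fwrite(lab, file.path(dir, "labels.tsv"), sep = "\t", na = "", quote = FALSE)

  gt <- groundTruth(cohort)
  if (!is.null(gt)) {
    nn <- which(gt$effect != 1, arr.ind = TRUE)
    sidecar <- list(
      planted = gt$planted,
      effects = data.frame(
        protein = rownames(gt$effect)[nn[, 1]],
        condition = colnames(gt$effect)[nn[, 2]],
        fold_change = gt$effect[nn]),
      config = unclass(gt$config))
    jsonlite::write_json(sidecar, file.path(dir, "groundtruth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

.numify <- function(dt, file) {
  for (j in seq_along(dt)) {
    v <- dt[[j]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad))
        stop("parse error in ", file, ": non-numeric value '", v[bad[1]],
             "' at row ", bad[1], ", column ", names(dt)[j], call. = FALSE)
      num[v == ""] <- NA_real_
      dt[[j]] <- num
    }
  }
  dt
}

#' Read a cohort from delimited text
#'
#' Inverse of \code{\link{writeCohort}}: values round-trip to numeric
#' precision and missing entries stay missing. Unknown label tokens and
#' non-numeric abundance cells raise parse errors naming the offending
#' cell; misaligned participant ids raise an alignment error listing them.
#'
#' @param dir directory holding \code{abundance.tsv}, \code{phenotypes.tsv}
#'   and \code{labels.tsv}.
#' @return a \linkS4class{ProteoCohort}.
#' @export
readCohort <- function(dir) {
  abf <- file.path(dir, "abundance.tsv")
  ab <- fread(abf, sep = "\t", na.strings = "", colClasses = list(
    character = "participant_id"), data.table = FALSE)
  ids <- ab$participant_id
  ab$participant_id <- NULL
  ab <- .numify(ab, "abundance.tsv")
  X <- as.matrix(ab)
  rownames(X) <- ids

  ph <- fread(file.path(dir, "phenotypes.tsv"), sep = "\t", na.strings = "",
              colClasses = list(character = c("participant_id", "site", "sex")),
              data.table = FALSE)
  rownames(ph) <- ph$participant_id
  ph$participant_id <- NULL

  lab <- fread(file.path(dir, "labels.tsv"), sep = "\t", na.strings = "",
               colClasses = "character", data.table = FALSE)
  rownames(lab) <- lab$participant_id
  lab$participant_id <- NULL
  lm <- as.matrix(lab)
  known <- lm %in% names(.LABEL_TOKENS) | is.na(lm)
  if (!all(known)) {
    bad <- which(!known)[1]
    stop("parse error in labels.tsv: unknown label state token '",
         lm[bad], "'", call. = FALSE)
  }
  lmat <- matrix(.LABEL_TOKENS[lm], nrow(lm), ncol(lm), dimnames = dimnames(lm))
  ProteoCohort(X, ph, lmat)
}

#' Derive cognition-based diagnostic classes
#'
#' Maps participants without a primary diagnosis onto coarse cognitive
#' classes from MMSE and CDR: good cognition (MMSE >= 26 or CDR 0) is
#' \code{control}; 20 <= MMSE <= 25 or CDR 0.5 is \code{MCI-SCI}; poor
#' cognition (MMSE < \code{dementia_mmse_cutoff} or CDR >= 1) is
#' \code{ComputedDementia}; neither scale valid is \code{Unknown}. When MMSE
#' and CDR disagree the clinician-assigned CDR stage wins by default.
#'
#' @param phenotypes \code{data.frame} with columns \code{mmse} and
#'   \code{cdr} (either may be \code{NA}).
#' @param dementia_mmse_cutoff MMSE bound (exclusive) for the poor-cognition
#'   rule; default 19.
#' @param cdr_precedence logical; CDR decides when both scales are present.
#' @return factor with levels \code{control}, \code{MCI-SCI},
#'   \code{ComputedDementia}, \code{Unknown}.
#' @export
#' @examples
#' ph <- data.frame(mmse = c(28, 23, NA, 12), cdr = c(NA, NA, NA, NA))
#' deriveCognitiveLabels(ph)
deriveCognitiveLabels <- function(phenotypes, dementia_mmse_cutoff = 19,
                                  cdr_precedence = TRUE) {
  mmse <- phenotypes$mmse
  cdr <- phenotypes$cdr
  lev <- c("control", "MCI-SCI", "ComputedDementia", "Unknown")

  byCdr <- rep(NA_character_, length(cdr))
  byCdr[!is.na(cdr) & cdr == 0] <- "control"
  byCdr[!is.na(cdr) & cdr == 0.5] <- "MCI-SCI"
  byCdr[!is.na(cdr) & cdr >= 1] <- "ComputedDementia"

  byMmse <- rep(NA_character_, length(mmse))
  byMmse[!is.na(mmse) & mmse >= 26] <- "control"
  byMmse[!is.na(mmse) & mmse >= 20 & mmse <= 25] <- "MCI-SCI"
  byMmse[!is.na(mmse) & mmse < dementia_mmse_cutoff] <- "ComputedDementia"

  first <- if (cdr_precedence) byCdr else byMmse
  second <- if (cdr_precedence) byMmse else byCdr
  out <- ifelse(!is.na(first), first, second)
  out[is.na(out)] <- "Unknown"
  factor(out, levels = lev)
}

#' Site-stratified k-fold split plan
#'
#' Participants from each site are shuffled and split into \code{k}
#' near-equal folds, so every fold contains members of every site large
#' enough. Each of the \code{k} rotations uses one fold as test, the next as
#' validation and the remaining \code{k - 2} as training (a 9-1-1 usage at
#' \code{k = 10}); every fold serves as the test split exactly once. Sites
#' with fewer than \code{k} members are distributed round-robin after
#' shuffling (with a warning), keeping folds as site-complete as possible.
#'
#' @param cohort a \linkS4class{ProteoCohort}.
#' @param k number of folds (>= 3).
#' @param seed integer seed.
#' @return a \linkS4class{SplitPlan}.
#' @export
makeStratifiedKFold <- function(cohort, k = 10, seed = 1L) {
  k <- .assertCount(k, "k", 3)
  ids <- participantIds(cohort)
  site <- siteIds(cohort)
  .withSeed(seed, {
    fold <- integer(length(ids))
    small <- character()
    for (si in seq_along(unique(site))) {
      s <- unique(site)[si]
      idx <- which(site == s)
      if (length(idx) < k) small <- c(small, s)
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold across sites to balance overall fold sizes
      fold[idx] <- ((seq_along(idx) - 1 + (si - 1)) %% k) + 1
    }
    if (length(small))
      warning("sites with fewer than k participants distributed round-robin: ",
              paste(small, collapse = ", "))
    folds <- lapply(seq_len(k), function(r) {
      test_f <- r
      val_f <- (r %% k) + 1
      list(train = ids[!fold %in% c(test_f, val_f)],
           validation = ids[fold == val_f],
           test = ids[fold == test_f])
    })
    methods::new("SplitPlan", scheme = "stratified-kfold", folds = folds,
                 seed = as.integer(seed))
  })
}

#' Leave-one-site-out split plan
#'
#' Each requested test site supplies one rotation: its participants form the
#' test split; the remaining participants are split site-stratified into
#' training and validation at \code{1 - val_fraction} / \code{val_fraction}.
#'
#' @param cohort a \linkS4class{ProteoCohort}.
#' @param test_sites site id(s) to hold out; default all sites.
#' @param val_fraction validation share of the non-test participants.
#' @param seed integer seed.
#' @return a \linkS4class{SplitPlan}.
#' @export
makeLeaveOneSiteOut <- function(cohort, test_sites = NULL, val_fraction = 1 / 9,
                                seed = 1L) {
  ids <- participantIds(cohort)
  site <- siteIds(cohort)
  allSites <- unique(site)
  if (is.null(test_sites)) test_sites <- allSites
  unknown <- setdiff(test_sites, allSites)
  if (length(unknown))
    stop("unknown site id(s): ", paste(unknown, collapse = ", "))
  .assertFraction(val_fraction, "val_fraction")
  .withSeed(seed, {
    folds <- lapply(test_sites, function(ts) {
      test <- ids[site == ts]
      rest <- which(site != ts)
      val <- integer()
      for (s in setdiff(allSites, ts)) {
        idx <- rest[site[rest] == s]
        idx <- idx[sample.int(length(idx))]
        nv <- round(length(idx) * val_fraction)
        val <- c(val, idx[seq_len(nv)])
      }
      list(train = ids[setdiff(rest, val)], validation = ids[val], test = test)
    })
    methods::new("SplitPlan", scheme = "leave-one-site-out", folds = folds,
                 seed = as.integer(seed))
  })
}

#' Serialize / restore a split plan as JSON
#'
#' @param plan a \linkS4class{SplitPlan}.
#' @param path path to \code{splits.json}.
#' @return \code{writeSplitPlan}: \code{path} invisibly;
#'   \code{readSplitPlan}: a \linkS4class{SplitPlan}.
#' @export
writeSplitPlan <- function(plan, path) {
  jsonlite::write_json(list(scheme = plan@scheme, seed = plan@seed,
                            folds = plan@folds),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(nrow_or_len(x$folds)), function(i) fold_i(x$folds, i))
  methods::new("SplitPlan", scheme = x$scheme, folds = folds,
               seed = as.integer(x$seed))
}

nrow_or_len <- function(f) if (is.data.frame(f)) nrow(f) else length(f)

fold_i <- function(f, i) {
  fi <- if (is.data.frame(f)) lapply(f, function(col) col[[i]]) else f[[i]]
  lapply(fi[c("train", "validation", "test")], as.character)
}
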