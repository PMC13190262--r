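#' Simulation configuration for synthetic multi-site proteomic cohorts
#'
#' Builds the parameter set for \code{\link{simulateCohort}}. Defaults emulate
#' a mid-sized multi-site aptamer-proteomics consortium: several thousand
#' participants spread unevenly over ten contributing sites, multiplicative
#' per-site batch effects, imbalanced condition prevalences, per-condition
#' label missingness, and per-condition planted protein effects expressed as
#' multiplicative fold changes on the raw abundance scale.
#'
#' All condition/site/covariate effects act additively on the natural-log
#' scale (multiplicatively on the raw relative-fluorescence scale), matching
#' the fold-change semantics of the association filter.
#'
#' @param n_participants,n_proteins,n_sites cohort dimensions.
#' @param prevalence named fraction per condition (marginal probability of a
#'   positive true status), names \code{conditionNames()}.
#' @param planted_per_condition number of proteins carrying a true effect for
#'   each condition; the six planted sets are disjoint, so
#'   \code{n_proteins >= 6 * planted_per_condition} is required.
#' @param fold_change_range range of multiplicative effect magnitudes for
#'   planted proteins; each planted effect is \code{U(range)} or its
#'   reciprocal with equal probability.
#' @param site_shift_sd,site_scale_sd log-scale sd of per-site per-protein
#'   additive shifts and of log multiplicative scale factors.
#' @param label_missing_rate fraction of observed true statuses blanked per
#'   condition (single value recycled or named vector of 6).
#' @param copathology_correlation latent-liability correlation between the
#'   five disease conditions (control is anti-correlated with disease).
#' @param age_effect_sd,sex_effect_sd log-scale sd of per-protein age (per
#'   decade) and sex effects.
#' @param measurement_noise_sd log-scale sd of technical noise added on top
#'   of per-protein biological variation.
#' @param missing_value_rate fraction of abundance cells set missing
#'   completely at random.
#' @param seed integer RNG seed; cohorts are bit-identical given the seed.
#'
#' @return a \code{SimulationConfig} (validated list).
#' @export
#' @examples
#' cfg <- simulationConfig(n_participants = 200, n_proteins = 120,
#'                         planted_per_condition = 10, seed = 7)
simulationConfig <- function(
    n_participants = 4000,
    n_proteins = 2000,
    n_sites = 10,
    prevalence = c(control = 0.30, AD = 0.15, PD = 0.12, FTD = 0.05,
                   ALS = 0.05, stroke_TIA = 0.08),
    planted_per_condition = 40,
    fold_change_range = c(1.5, 3),
    site_shift_sd = 0.3,
    site_scale_sd = 0.1,
    label_missing_rate = 0.15,
    copathology_correlation = 0.1,
    age_effect_sd = 0.05,
    sex_effect_sd = 0.05,
    measurement_noise_sd = 0.3,
    missing_value_rate = 0.02,
    seed = 1L) {
  n_participants <- .assertCount(n_participants, "n_participants", 10)
  n_proteins <- .assertCount(n_proteins, "n_proteins", 6)
  n_sites <- .assertCount(n_sites, "n_sites", 1)
  if (length(prevalence) != 6)
    stop("configuration error: 'prevalence' must have 6 entries")
  if (is.null(names(prevalence))) names(prevalence) <- conditionNames()
  prevalence <- prevalence[conditionNames()]
  .assertFraction(prevalence, "prevalence", allow_zero = FALSE)
  planted_per_condition <- .assertCount(planted_per_condition,
                                        "planted_per_condition", 0)
  if (n_proteins < 6 * planted_per_condition)
    stop("configuration error: 'n_proteins' must be >= 6 * planted_per_condition")
  if (length(fold_change_range) != 2 || fold_change_range[1] <= 0 ||
      diff(fold_change_range) < 0)
    stop("configuration error: 'fold_change_range' must be an increasing pair of positive ratios")
  if (length(label_missing_rate) == 1)
    label_missing_rate <- stats::setNames(rep(label_missing_rate, 6), conditionNames())
  label_missing_rate <- label_missing_rate[conditionNames()]
  .assertFraction(label_missing_rate, "label_missing_rate")
  .assertFraction(copathology_correlation, "copathology_correlation")
  .assertFraction(missing_value_rate, "missing_value_rate")
  for (nm in c("site_shift_sd", "site_scale_sd", "age_effect_sd",
               "sex_effect_sd", "measurement_noise_sd")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      stop("configuration error: '", nm, "' must be a nonnegative sd")
  }
  structure(list(
    n_participants = n_participants, n_proteins = n_proteins,
    n_sites = n_sites, prevalence = prevalence,
    planted_per_condition = planted_per_condition,
    fold_change_range = fold_change_range,
    site_shift_sd = site_shift_sd, site_scale_sd = site_scale_sd,
    label_missing_rate = label_missing_rate,
    copathology_correlation = copathology_correlation,
    age_effect_sd = age_effect_sd, sex_effect_sd = sex_effect_sd,
    measurement_noise_sd = measurement_noise_sd,
    missing_value_rate = missing_value_rate,
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Ground truth of a simulated cohort
#'
#' Returned (attached to the cohort) by \code{\link{simulateCohort}}.
#' A list of class \code{GroundTruth} with elements:
#' \describe{
#'   \item{effect}{protein-by-6 matrix of multiplicative fold changes
#'     (1 = null). Every planted protein has an effect different from 1 for
#'     exactly one condition; null proteins are 1 everywhere.}
#'   \item{planted}{list of planted protein ids per condition (disjoint).}
#'   \item{site_shift, site_scale}{site-by-protein additive log shifts and
#'     multiplicative log-scale factors.}
#'   \item{liability, status}{participant-by-6 latent liabilities and true
#'     condition statuses (before label missingness).}
#'   \item{config}{the generating \code{SimulationConfig}.}
#' }
#' @name GroundTruth
NULL

#' Simulate a multi-site proteomic cohort with planted ground truth
#'
#' Draws a log-normal abundance matrix with multiplicative condition, site,
#' age and sex effects plus technical noise; condition statuses come from
#' thresholded correlated latent liabilities, so co-pathology (multiple
#' positives) occurs at a configurable rate. Observed ternary labels blank a
#' per-condition fraction of statuses; abundance cells are additionally set
#' missing completely at random. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{ProteoCohort} with the \link{GroundTruth} attached
#'   in its metadata.
#' @export
#' @examples
#' co <- simulateCohort(simulationConfig(n_participants = 150,
#'                                       n_proteins = 60,
#'                                       planted_per_condition = 5,
#'                                       seed = 42))
#' co
simulateCohort <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simulationConfig, config)
  n <- config$n_participants
  p <- config$n_proteins
  S <- config$n_sites
  conds <- conditionNames()

  .withSeed(config$seed, {
    pid <- sprintf("P%05d", seq_len(n))
    prot <- sprintf("prot_%04d", seq_len(p))
    site_names <- sprintf("S%02d", seq_len(S))

    # uneven site sizes
    w <- stats::runif(S, 0.5, 2)
    site <- sample(site_names, n, replace = TRUE, prob = w / sum(w))

    age <- pmin(pmax(round(stats::rnorm(n, 70, 8)), 40), 95)
    sex <- sample(c("F", "M"), n, replace = TRUE)

    # latent liabilities: diseases share 'copathology_correlation'; control
    # is anti-correlated with disease so co-occurrence is directional
    rho <- config$copathology_correlation
    Sig <- matrix(rho, 6, 6)
    Sig[1, ] <- Sig[, 1] <- -rho
    diag(Sig) <- 1
    L <- matrix(stats::rnorm(n * 6), n, 6) %*% chol(Sig)
    thr <- stats::qnorm(1 - config$prevalence)
    status <- sweep(L, 2, thr, ">")
    dimnames(L) <- dimnames(status) <- list(pid, conds)

    # planted effects: disjoint sets, fold change U(range) up or down
    k <- config$planted_per_condition
    effect <- matrix(1, p, 6, dimnames = list(prot, conds))
    planted <- stats::setNames(vector("list", 6), conds)
    if (k > 0) {
      sel <- sample.int(p, 6 * k)
      for (i in seq_len(6)) {
        idx <- sel[((i - 1) * k + 1):(i * k)]
        fc <- stats::runif(k, config$fold_change_range[1], config$fold_change_range[2])
        dn <- stats::runif(k) < 0.5
        fc[dn] <- 1 / fc[dn]
        effect[idx, i] <- fc
        planted[[i]] <- prot[idx]
      }
    } else planted <- lapply(planted, function(x) character())

    mu <- stats::rnorm(p, 7, 1)              # baseline log-RFU per protein
    sigma_bio <- stats::runif(p, 0.2, 0.5)   # biological log-sd per protein
    site_shift <- matrix(stats::rnorm(S * p, 0, config$site_shift_sd), S, p,
                         dimnames = list(site_names, prot))
    site_scale <- matrix(exp(stats::rnorm(S * p, 0, config$site_scale_sd)), S, p,
                         dimnames = list(site_names, prot))
    a_age <- stats::rnorm(p, 0, config$age_effect_sd)
    b_sex <- stats::rnorm(p, 0, config$sex_effect_sd)

    signal <- (status + 0) %*% t(log(effect))          # n x p
    dev <- signal +
      outer((age - 70) / 10, a_age) +
      outer(as.numeric(sex == "M"), b_sex) +
      matrix(stats::rnorm(n * p, 0, 1), n, p) %*% diag(sigma_bio) +
      matrix(stats::rnorm(n * p, 0, config$measurement_noise_sd), n, p)
    si <- match(site, site_names)
    logX <- matrix(mu, n, p, byrow = TRUE) +
      site_shift[si, , drop = FALSE] +
      site_scale[si, , drop = FALSE] * dev
    X <- exp(logX)
    dimnames(X) <- list(pid, prot)

    # cognition consistent with dementia-driving statuses
    dementia <- status[, "AD"] | status[, "FTD"]
    mmse <- round(29 - 5 * dementia - 3 * dementia * stats::runif(n) +
                    stats::rnorm(n, 0, 1.2))
    mmse <- pmin(pmax(mmse, 0), 30)
    cdr <- ifelse(status[, "control"], 0,
                  ifelse(dementia,
                         sample(c(0.5, 1, 2), n, replace = TRUE,
                                prob = c(0.5, 0.35, 0.15)),
                         sample(c(0, 0.5), n, replace = TRUE,
                                prob = c(0.8, 0.2))))
    mmse[stats::runif(n) < 0.2] <- NA
    cdr[stats::runif(n) < 0.3] <- NA

    apoe_e4 <- stats::rbinom(n, 2, ifelse(status[, "AD"], 0.35, 0.15))
    apoe_e2 <- stats::rbinom(n, 2, 0.07)

    labels <- status + 0L
    for (i in seq_len(6)) {
      miss <- stats::runif(n) < config$label_missing_rate[i]
      labels[miss, i] <- NA_integer_
    }

    if (config$missing_value_rate > 0) {
      nmiss <- stats::rbinom(1, n * p, config$missing_value_rate)
      X[sample.int(n * p, nmiss)] <- NA_real_
    }

    pheno <- data.frame(
      site = site, age = age, sex = sex, mmse = mmse, cdr = cdr,
      apoe_e2 = apoe_e2, apoe_e4 = apoe_e4,
      cdr_followup = NA_character_,
      row.names = pid, stringsAsFactors = FALSE)

    gt <- structure(list(
      effect = effect, planted = planted,
      site_shift = site_shift, site_scale = site_scale,
      liability = L, status = status, config = config),
      class = "GroundTruth")

    ProteoCohort(X, pheno, labels, groundTruth = gt)
  })
}

#' Derive a longitudinal progression task from a simulated cohort
#'
#' Flags a subset of baseline-CDR-0 participants as clinically progressive.
#' Progression probability follows a logistic link on the cohort's planted
#' AD-signal proteins (the first \code{n_signal} planted AD proteins, each
#' oriented so that the pathological direction increases risk; slope
#' \code{signal_strength} on the standardized mean signal, intercept solved
#' so the marginal rate equals \code{progression_fraction}). Follow-up CDR
#' sequences are emitted consistent with the flags: stable participants stay
#' at 0, progressors step up to 0.5 or 1, and a small fraction receive a
#' non-monotone sequence and are marked ineligible — participants whose CDR
#' decreases at a later visit are excluded from the task.
#'
#' @param cohort a simulated \linkS4class{ProteoCohort} with ground truth.
#' @param progression_fraction target marginal progression rate among
#'   eligible baseline-CDR-0 participants.
#' @param signal_strength logistic slope on the standardized protein signal.
#' @param n_signal number of planted AD proteins driving progression.
#' @param nonmonotone_fraction fraction of CDR-0 participants given a
#'   decreasing follow-up sequence (hence excluded).
#' @param seed integer seed.
#'
#' @return list with \code{cohort} (follow-up CDR sequences filled in) and
#'   \code{labels}, a \code{data.frame} with columns \code{participant},
#'   \code{eligible} and \code{progressor} (NA when ineligible).
#' @export
makeProgressionLabels <- function(cohort, progression_fraction = 0.13,
                                  signal_strength = 2, n_signal = 10,
                                  nonmonotone_fraction = 0.02, seed = 1L) {
  gt <- groundTruth(cohort)
  if (is.null(gt)) stop("cohort has no attached ground truth")
  .assertFraction(progression_fraction, "progression_fraction")
  ph <- phenoTable(cohort)
  base0 <- !is.na(ph$cdr) & ph$cdr == 0
  if (!any(base0)) stop("empty selection: no baseline-CDR-0 participants")
  ids <- participantIds(cohort)[base0]

  sig_prot <- utils::head(gt$planted$AD, n_signal)
  if (length(sig_prot) == 0) stop("cohort has no planted AD proteins")
  Xs <- t(abundance(cohort))[ids, sig_prot, drop = FALSE]
  Xs <- log(Xs)
  # orient each protein so its pathological direction increases risk
  orient <- sign(log(gt$effect[sig_prot, "AD"]))
  Z <- scale(Xs)
  Z[is.na(Z)] <- 0
  s <- as.numeric(Z %*% orient) / length(sig_prot)
  s <- as.numeric(scale(s))

  .withSeed(seed, {
    if (progression_fraction == 0) {
      prob <- rep(0, length(ids))
    } else {
      f <- function(b0) mean(stats::plogis(b0 + signal_strength * s)) -
        progression_fraction
      b0 <- stats::uniroot(f, c(-30, 30))$root
      prob <- stats::plogis(b0 + signal_strength * s)
    }
    prog <- stats::rbinom(length(ids), 1, prob)
    nonmono <- stats::runif(length(ids)) < nonmonotone_fraction

    fu <- character(length(ids))
    fu[prog == 0] <- "0,0"
    fu[prog == 1] <- sample(c("0.5,0.5", "0.5,1"), sum(prog == 1), replace = TRUE)
    fu[nonmono] <- "1,0"

    cd <- colData(cohort)
    fuAll <- as.character(cd$cdr_followup)
    fuAll[match(ids, participantIds(cohort))] <- fu
    cd$cdr_followup <- fuAll
    SummarizedExperiment::colData(cohort) <- cd

    labels <- data.frame(
      participant = ids,
      eligible = !nonmono,
      progressor = ifelse(nonmono, NA_integer_, prog),
      stringsAsFactors = FALSE)
    list(cohort = cohort, labels = labels)
  })
}

#' Progression-task eligibility
#'
#' Participants eligible for the progression task: baseline CDR of 0 with a
#' non-decreasing CDR sequence over all recorded follow-up visits (a
#' participant whose CDR later decreases, e.g. 0, 1, 0, is excluded).
#'
#' @param cohort a \linkS4class{ProteoCohort} with \code{cdr_followup} filled.
#' @return logical vector over participants.
#' @export
progressionEligible <- function(cohort) {
  ph <- phenoTable(cohort)
  base0 <- !is.na(ph$cdr) & ph$cdr == 0
  fu <- as.character(ph$cdr_followup)
  ok <- vapply(seq_along(fu), function(i) {
    if (!base0[i] || is.na(fu[i]) || fu[i] == "") return(FALSE)
    seqv <- c(ph$cdr[i], as.numeric(strsplit(fu[i], ",")[[1]]))
    !is.unsorted(seqv)
  }, logical(1))
  stats::setNames(ok, participantIds(cohort))
}
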