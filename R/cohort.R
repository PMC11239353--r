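# Synthetic cohort generator.
#
# Each subject's windowed signal is composed as
#     x(t) = a * m_age * S(t) + b * I(t) + c * eps(t)
# where S is the stimulus-evoked component, drawn once per window from the
# window state's covariance and SHARED across all subjects; I is a
# subject-specific intrinsic component; eps is white noise; m_age is an
# optional per-age SNR multiplier.  A behavioral-group effect is then
# injected per subject by blending every ROI toward the subject's global
# mean signal with a weight solved exactly (on the model covariance) so
# that the expected mean ToM<->Pain edge correlation equals the group's
# coupling target.

#' Default stimulus-evoked state covariances
#'
#' In a window of a given state, the active network's regions co-activate
#' strongly (within-network correlation `active`) while the other network is
#' less coherent (`inactive`); between-network stimulus correlation is zero
#' (the behavioral-group coupling is injected separately per subject).
#'
#' @param networks per-ROI network tags.
#' @param active,inactive within-network correlations for the engaged and
#'   non-engaged network.
#' @return named list with unit-diagonal PSD matrices `ToM` and `Pain`.
#' @export
defaultStateCovariances <- function(networks = defaultRoiSet()@network,
                                    active = 0.9, inactive = 0.7) {
  list(
    ToM  = blockCorrelation(networks, list(ToM = active, Pain = inactive)),
    Pain = blockCorrelation(networks, list(ToM = inactive, Pain = active)))
}

#' Default intrinsic covariance
#'
#' Moderate, state-independent within-network coupling of the
#' subject-specific intrinsic component.
#'
#' @inheritParams defaultStateCovariances
#' @param within within-network intrinsic correlation.
#' @return unit-diagonal PSD matrix.
#' @export
defaultIntrinsicCovariance <- function(networks = defaultRoiSet()@network,
                                       within = 0.4) {
  blockCorrelation(networks, list(ToM = within, Pain = within))
}

#' Cohort generation configuration
#'
#' Defaults reproduce the study cohort: 155 subjects (122 children, 33
#' adults), children split 84 pass / 23 inconsistent / 15 fail, 10 event
#' windows over 168 time points at TR 2 s, and group coupling targets
#' pass 0.8 / inconsistent 0.5 / fail 0.2.  Adults carry the placeholder
#' group `"pass"` and are excluded from performance prediction by default.
#'
#' @param nSubjects total number of subjects.
#' @param groupSizes named counts for pass/inconsistent/fail among
#'   non-adult subjects; must sum to the non-adult total.
#' @param ageGroups named counts per age group; the label `"adult"` marks
#'   adults.
#' @param mixWeights numeric `c(a, b, c)` weights of the stimulus-evoked,
#'   intrinsic and noise components.
#' @param stateCovariances list of unit-diagonal PSD matrices `ToM`, `Pain`.
#' @param intrinsicCovariance unit-diagonal PSD matrix.
#' @param groupCoupling named targets for the mean ToM<->Pain edge
#'   correlation per behavioral group.
#' @param ageSnr named per-age multipliers on the stimulus weight `a`
#'   (children are given a mildly lower stimulus SNR by default).
#' @param roiSet a [RoiSet-class].
#' @param windows window schedule data.frame (see [defaultWindows()]).
#' @param trSeconds sampling interval in seconds.
#' @param seed integer master seed; the cohort is a pure function of the
#'   full configuration including this seed.
#' @return validated configuration list of class `"CohortConfig"`.
#' @export
#' @examples
#' cfg <- cohortConfig(nSubjects = 12,
#'                     groupSizes = c(pass = 4, inconsistent = 3, fail = 3),
#'                     ageGroups = c(child = 10, adult = 2))
cohortConfig <- function(nSubjects = 155L,
                         groupSizes = c(pass = 84L, inconsistent = 23L,
                                        fail = 15L),
                         ageGroups = c(child = 122L, adult = 33L),
                         mixWeights = c(a = 1.0, b = 0.6, c = 0.4),
                         stateCovariances = defaultStateCovariances(
                           roiSet@network),
                         intrinsicCovariance = defaultIntrinsicCovariance(
                           roiSet@network),
                         groupCoupling = c(pass = 0.8, inconsistent = 0.5,
                                           fail = 0.2),
                         ageSnr = c(child = 0.85, adult = 1.0),
                         roiSet = defaultRoiSet(),
                         windows = defaultWindows(),
                         trSeconds = 2,
                         seed = 1L) {
  cfg <- list(nSubjects = as.integer(nSubjects), groupSizes = groupSizes,
              ageGroups = ageGroups, mixWeights = mixWeights,
              stateCovariances = stateCovariances,
              intrinsicCovariance = intrinsicCovariance,
              groupCoupling = groupCoupling, ageSnr = ageSnr,
              roiSet = roiSet, windows = validateWindows(windows),
              trSeconds = trSeconds, seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
}

validateCohortConfig <- function(cfg) {
  if (sum(cfg$ageGroups) != cfg$nSubjects)
    stop("config error: age group counts must sum to nSubjects",
         call. = FALSE)
  nChild <- sum(cfg$ageGroups[setdiff(names(cfg$ageGroups), "adult")])
  if (sum(cfg$groupSizes) != nChild)
    stop("config error: group sizes (", sum(cfg$groupSizes),
         ") must sum to the number of non-adult subjects (", nChild, ")",
         call. = FALSE)
  if (!all(c("pass", "inconsistent", "fail") %in% names(cfg$groupSizes)))
    stop("config error: groupSizes needs pass/inconsistent/fail",
         call. = FALSE)
  if (any(cfg$mixWeights < 0) || length(cfg$mixWeights) != 3L)
    stop("config error: mixWeights must be three nonnegative numbers",
         call. = FALSE)
  n <- length(cfg$roiSet@names)
  for (nm in c("ToM", "Pain")) {
    m <- cfg$stateCovariances[[nm]]
    if (is.null(m) || nrow(m) != n)
      stop("covariance error: state covariance '", nm, "' must be ", n, " x ",
           n, call. = FALSE)
    if (max(abs(diag(m) - 1)) > 1e-8)
      stop("covariance error: state covariance '", nm,
           "' must have unit diagonal", call. = FALSE)
    assertPSD(m, paste0("state covariance '", nm, "'"))
  }
  if (nrow(cfg$intrinsicCovariance) != n)
    stop("covariance error: intrinsic covariance must be ", n, " x ", n,
         call. = FALSE)
  assertPSD(cfg$intrinsicCovariance, "intrinsic covariance")
  if (!all(names(cfg$groupSizes) %in% names(cfg$groupCoupling)))
    stop("config error: groupCoupling must cover all behavioral groups",
         call. = FALSE)
  cfg
}

# Mean ToM<->Pain entry of a correlation matrix.
meanBetweenNetwork <- function(corMat, networks) {
  it <- networks == "ToM"
  mean(corMat[it, !it])
}

# Model covariance of the composed (pre-blending) signal for one age
# multiplier, averaged over the two window states.
composedCovariance <- function(cfg, ageMult = 1) {
  a <- cfg$mixWeights[[1]] * ageMult
  b <- cfg$mixWeights[[2]]
  cc <- cfg$mixWeights[[3]]
  sBar <- (cfg$stateCovariances$ToM + cfg$stateCovariances$Pain) / 2
  a^2 * sBar + b^2 * cfg$intrinsicCovariance +
    cc^2 * diag(nrow(sBar))
}

# Solve the global-mean blending weight w so that the expected mean
# between-network correlation of x' = (I + w/(N*sd_v) J) x equals `target`.
solveCouplingWeight <- function(cfg, target, ageMult = 1) {
  cBar <- composedCovariance(cfg, ageMult)
  n <- nrow(cBar)
  networks <- cfg$roiSet@network
  sdv <- sqrt(sum(cBar)) / n
  if (sdv == 0) stop("degenerate configuration: zero-variance signal",
                     call. = FALSE)
  betweenAt <- function(w) {
    A <- diag(n) + (w / (n * sdv)) * matrix(1, n, n)
    cp <- A %*% cBar %*% base::t(A)
    d <- 1 / sqrt(diag(cp))
    meanBetweenNetwork(d * base::t(d * cp), networks)
  }
  base0 <- betweenAt(0)
  if (target < base0 - 1e-10)
    stop("config error: coupling target ", target,
         " is below the baseline between-network correlation ",
         format(base0, digits = 3), " and cannot be reached by blending",
         call. = FALSE)
  if (abs(target - base0) < 1e-10) return(0)
  if (target >= 1)
    stop("config error: coupling target must be < 1", call. = FALSE)
  uniroot(function(w) betweenAt(w) - target, lower = 0, upper = 200,
          tol = 1e-10)$root
}

#' Generate a synthetic cohort of ROI BOLD time-series with labels
#'
#' See [cohortConfig()] for the generative model.  The cohort is a pure
#' function of the configuration: the same config (and seed) always
#' produces a bitwise-identical cohort.
#'
#' @param config a configuration from [cohortConfig()].
#' @return a [Cohort-class].
#' @export
#' @examples
#' cfg <- cohortConfig(nSubjects = 6,
#'                     groupSizes = c(pass = 2, inconsistent = 2, fail = 2),
#'                     ageGroups = c(child = 6, adult = 0), seed = 7)
#' coh <- generateCohort(cfg)
#' length(coh)
generateCohort <- function(config) {
  cfg <- validateCohortConfig(config)
  set.seed(substreamSeed(cfg$seed, "cohort"))
  rs <- cfg$roiSet
  n <- length(rs@names)
  w <- cfg$windows
  lens <- w$end - w$start + 1L
  a <- cfg$mixWeights[[1]]; b <- cfg$mixWeights[[2]]; cc <- cfg$mixWeights[[3]]

  cholS <- lapply(cfg$stateCovariances, chol)
  cholI <- chol(cfg$intrinsicCovariance)

  # shared stimulus-evoked component, one draw per window
  sharedS <- lapply(seq_len(nrow(w)), function(i) {
    matrix(rnorm(lens[i] * n), lens[i], n) %*% cholS[[w$state[i]]]
  })

  # subject roster: age groups in declared order, behavioral groups
  # randomly permuted among non-adults
  ageLabels <- rep(names(cfg$ageGroups), cfg$ageGroups)
  isAdult <- ageLabels == "adult"
  childGroups <- sample(rep(names(cfg$groupSizes), cfg$groupSizes))
  groups <- character(length(ageLabels))
  groups[!isAdult] <- childGroups
  groups[isAdult] <- "pass"          # placeholder; adults are untested
  nCorrectRange <- list(pass = 5:6, inconsistent = 3:4, fail = 0:2)
  nCorrect <- ifelse(isAdult, NA_integer_,
                     vapply(groups, function(g)
                       sample(nCorrectRange[[g]], 1L), integer(1L)))

  # blending weights per (group, age) pair, solved on the model covariance
  wKey <- paste(groups, ageLabels)
  blendW <- vapply(unique(wKey), function(k) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    solveCouplingWeight(cfg, cfg$groupCoupling[[parts[1]]],
                        cfg$ageSnr[[parts[2]]])
  }, numeric(1L))

  ids <- sprintf("sub-%03d", seq_along(ageLabels))
  subjects <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    m <- cfg$ageSnr[[ageLabels[s]]]
    blocks <- vector("list", nrow(w))
    for (i in seq_len(nrow(w))) {
      intr <- matrix(rnorm(lens[i] * n), lens[i], n) %*% cholI
      eps <- matrix(rnorm(lens[i] * n), lens[i], n)
      blocks[[i]] <- a * m * sharedS[[i]] + b * intr + cc * eps
    }
    x <- do.call(rbind, blocks)
    # per-subject group-coupling injection: blend toward the global mean
    wS <- blendW[[wKey[s]]]
    if (wS != 0) {
      cBar <- composedCovariance(cfg, m)
      sdv <- sqrt(sum(cBar)) / n
      x <- x + (wS / (n * sdv)) * rowSums(x)
    }
    colnames(x) <- rs@names
    subjects[[s]] <- new("BoldTimeSeries", subjectId = ids[s], data = x,
                         windows = w, roiSet = rs,
                         trSeconds = cfg$trSeconds)
  }

  meta <- data.frame(subject_id = ids, age_group = ageLabels,
                     group = groups, n_correct = nCorrect,
                     stringsAsFactors = FALSE)
  new("Cohort", subjects = subjects, meta = meta, roiSet = rs, windows = w,
      config = unclass(cfg))
}
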