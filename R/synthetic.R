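#' Specify a synthetic two-group cohort
#'
#' Builds a [SyntheticSpec-class] describing a resting-state-like cohort:
#' two groups of subjects, each subject a T x N multivariate time series
#' whose population covariance has positive community-block structure,
#' an optional additive "planted" group effect on a chosen edge set, and
#' behavioral scores linearly coupled to the subject's generating
#' connectivity. Defaults mirror a typical two-group resting-state study:
#' 36 + 38 subjects, 230 retained volumes at TR = 2 s, 246 ROIs.
#'
#' Subject-level heterogeneity is controlled by `subjectStrengthSd`: each
#' subject s receives a connectivity strength factor g_s in (0, 1)
#' (logit-normal, median 0.75) and covariance
#' `Sigma_s = g_s * Sigma + (1 - g_s) * diag(Sigma)`, which is always
#' positive-definite and leaves ROI variances untouched. The behavioral
#' score couples to the subject's realized mean covariance on the effect
#' edges, so brain-behavior recovery is testable within a group.
#'
#' @param nRois number of ROIs (default 246; use ~20 for fast tests).
#' @param nVolumes retained time points (default 230).
#' @param trSeconds repetition time in seconds (default 2).
#' @param nGroupA,nGroupB group sizes (defaults 36 patient-like, 38
#'   control-like).
#' @param blockSizes integer partition of ROIs into community blocks;
#'   default six near-equal blocks.
#' @param withinBlockCov,betweenBlockCov covariance inside / between
#'   blocks (defaults 0.6 and 0.15).
#' @param effectEdges two-column matrix of ROI index pairs carrying the
#'   planted group-A effect (default none).
#' @param effectDelta additive covariance increment on `effectEdges` for
#'   group A (default 0).
#' @param arCoeff lag-1 autocorrelation of the series (default 0.3).
#' @param noiseSd ROI-specific noise SD; the covariance diagonal is
#'   `1 + noiseSd^2` (default 0.4).
#' @param subjectStrengthSd logit-scale SD of the per-subject strength
#'   factor (default 0.5; 0 disables heterogeneity).
#' @param behaviorCoupling slope of the score-connectivity coupling
#'   (default 0).
#' @param behaviorNoiseSd residual SD of the coupled score (default 1).
#' @param seed master seed; the cohort is a pure function of (spec, seed).
#' @return a validated [SyntheticSpec-class].
#' @examples
#' sp <- syntheticSpec(nRois = 20, nGroupA = 8, nGroupB = 8, seed = 1)
#' sp
#' @export
syntheticSpec <- function(nRois = 246L, nVolumes = 230L, trSeconds = 2,
                          nGroupA = 36L, nGroupB = 38L,
                          blockSizes = defaultBlockSizes(nRois),
                          withinBlockCov = 0.6, betweenBlockCov = 0.15,
                          effectEdges = matrix(integer(), 0L, 2L),
                          effectDelta = 0, arCoeff = 0.3, noiseSd = 0.4,
                          subjectStrengthSd = 0.5, behaviorCoupling = 0,
                          behaviorNoiseSd = 1, seed = 1L) {
    effectEdges <- matrix(as.integer(effectEdges), ncol = 2L)
    new("SyntheticSpec", nRois = as.integer(nRois),
        nVolumes = as.integer(nVolumes), trSeconds = as.numeric(trSeconds),
        nGroupA = as.integer(nGroupA), nGroupB = as.integer(nGroupB),
        blockSizes = as.integer(blockSizes),
        withinBlockCov = withinBlockCov, betweenBlockCov = betweenBlockCov,
        effectEdges = effectEdges, effectDelta = effectDelta,
        arCoeff = arCoeff, noiseSd = noiseSd,
        subjectStrengthSd = subjectStrengthSd,
        behaviorCoupling = behaviorCoupling,
        behaviorNoiseSd = behaviorNoiseSd, seed = as.integer(seed))
}

#' Default community-block partition
#'
#' Splits `nRois` into `nBlocks` near-equal blocks standing in for
#' functional systems (the first block can be read as a "DMN-like"
#' community when planting effects).
#'
#' @param nRois number of ROIs.
#' @param nBlocks number of blocks (default 6, or fewer for tiny atlases).
#' @return integer vector summing to `nRois`.
#' @export
defaultBlockSizes <- function(nRois, nBlocks = min(6L, max(1L, nRois %/% 5L))) {
    base <- nRois %/% nBlocks
    sizes <- rep(base, nBlocks)
    extra <- nRois - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sizes
}

#' Population covariance matrix of one group
#'
#' Assembles the N x N covariance implied by a [SyntheticSpec-class]:
#' `betweenBlockCov` everywhere, `withinBlockCov` inside each community
#' block, diagonal `1 + noiseSd^2`, and (for group "A") `effectDelta`
#' added symmetrically on the effect edges. The result is checked for
#' positive-definiteness; a non-PD matrix is repaired by the nearest-PD
#' projection and the maximal entry change reported, with a hard error if
#' the repair moves any entry by more than `repairTol`.
#'
#' @param spec a [SyntheticSpec-class].
#' @param group "A" or "B".
#' @param repairTol largest tolerated entry change during nearest-PD
#'   repair (default 0.05).
#' @return symmetric positive-definite N x N covariance matrix.
#' @examples
#' sp <- syntheticSpec(nRois = 20, blockSizes = c(10, 10))
#' Sigma <- buildPopulationCov(sp, "B")
#' Sigma[1, 2]   # within-block level
#' @export
buildPopulationCov <- function(spec, group = c("A", "B"),
                               repairTol = 0.05) {
    group <- match.arg(group)
    n <- spec@nRois
    Sigma <- matrix(spec@betweenBlockCov, n, n)
    stop_ <- cumsum(spec@blockSizes)
    start <- c(1L, head(stop_, -1L) + 1L)
    for (b in seq_along(spec@blockSizes)) {
        idx <- start[b]:stop_[b]
        Sigma[idx, idx] <- spec@withinBlockCov
    }
    if (group == "A" && nrow(spec@effectEdges)) {
        for (e in seq_len(nrow(spec@effectEdges))) {
            i <- spec@effectEdges[e, 1L]; j <- spec@effectEdges[e, 2L]
            Sigma[i, j] <- Sigma[i, j] + spec@effectDelta
            Sigma[j, i] <- Sigma[i, j]
        }
    }
    diag(Sigma) <- 1 + spec@noiseSd^2
    ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) {
        repaired <- as.matrix(Matrix::nearPD(Sigma, corr = FALSE,
                                             keepDiag = TRUE)$mat)
        shift <- max(abs(repaired - Sigma))
        message(sprintf(
            "population covariance not PD (min eigenvalue %.3g); nearest-PD repair moved entries by at most %.3g",
            ev, shift))
        if (shift > repairTol)
            stop(sprintf(
                "covariance for group %s is not positive-definite and repair exceeds tolerance (within=%.3g, between=%.3g, delta=%.3g)",
                group, spec@withinBlockCov, spec@betweenBlockCov,
                spec@effectDelta))
        Sigma <- repaired
        ev2 <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
        if (ev2 <= 0)
            stop("covariance remains non-PD after repair")
    }
    dimnames(Sigma) <- NULL
    Sigma
}

#' Sample an autocorrelated multivariate time series
#'
#' Draws T multivariate-normal innovation vectors with covariance `cov`
#' and passes them through a lag-1 autoregression
#' `x_t = arCoeff * x_(t-1) + e_t` (so the cross-sectional correlation
#' structure of `cov` is preserved while each ROI signal carries BOLD-like
#' temporal smoothness).
#'
#' @param cov positive-definite N x N innovation covariance.
#' @param nVolumes number of time points T (must be at least 20: shorter
#'   series cannot support filtering or correlation estimation).
#' @param arCoeff lag-1 autoregressive coefficient in [0, 1).
#' @param seed RNG seed; identical inputs give bit-identical output.
#' @param trSeconds sampling interval for the returned object.
#' @param subjectID subject identifier.
#' @param roiLabels optional ROI labels.
#' @return a [RoiTimeSeries-class].
#' @export
sampleTimeSeries <- function(cov, nVolumes, arCoeff = 0, seed = 1L,
                             trSeconds = 2, subjectID = "subj",
                             roiLabels = NULL) {
    if (nVolumes < 20L)
        stop("nVolumes must be at least 20 (too short for filtering and correlation)")
    if (arCoeff < 0 || arCoeff >= 1)
        stop("arCoeff must lie in [0, 1)")
    set.seed(as.integer(seed))
    innov <- MASS::mvrnorm(n = nVolumes, mu = rep(0, nrow(cov)), Sigma = cov)
    x <- innov
    if (arCoeff > 0) {
        for (t in 2:nVolumes) x[t, ] <- arCoeff * x[t - 1L, ] + innov[t, ]
    }
    roiTimeSeries(x, trSeconds = trSeconds, subjectID = subjectID,
                  roiLabels = roiLabels)
}

#' Generate random-walk head motion traces
#'
#' Simulates rigid-body motion as six independent Gaussian random walks
#' starting at zero: per-step SD `amplitude` mm for the three
#' translations and `amplitude / 50` radians for the three rotations (so
#' translation and rotation contribute comparably to framewise
#' displacement at a 50 mm head radius).
#'
#' @param nVolumes number of frames.
#' @param amplitude per-step standard deviation in mm (>= 0).
#' @param seed RNG seed.
#' @param subjectID subject identifier.
#' @return a [MotionParams-class].
#' @export
generateMotion <- function(nVolumes, amplitude = 0.02, seed = 1L,
                           subjectID = "subj") {
    if (amplitude < 0) stop("amplitude must be nonnegative")
    set.seed(as.integer(seed))
    steps <- matrix(stats::rnorm(nVolumes * 6L), nVolumes, 6L)
    steps <- sweep(steps, 2L, c(rep(amplitude, 3L), rep(amplitude / 50, 3L)),
                   `*`)
    steps[1L, ] <- 0
    motionParams(apply(steps, 2L, cumsum), subjectID = subjectID)
}

#' Generate a full synthetic cohort
#'
#' Draws the complete bundle the pipeline consumes: a cohort table
#' (group, matched covariates, behavioral scores), one
#' [RoiTimeSeries-class] and one [MotionParams-class] per subject. Group
#' A subjects are sampled from the effect-carrying covariance, group B
#' from the base covariance. The `coupled` score of every subject equals
#' `behaviorCoupling * mean(Sigma_s[effectEdges])` plus Gaussian noise
#' with SD `behaviorNoiseSd` (mean over all off-diagonal entries when no
#' effect edges are declared); the named clinical scores are drawn from
#' group-specific normal distributions typical of insomnia-patient versus
#' control questionnaire summaries, with ESS and disease duration missing
#' for the control-like group.
#'
#' @param spec a [SyntheticSpec-class].
#' @param motionAmplitude per-step motion SD in mm (default 0.02).
#' @return a [Cohort-class].
#' @examples
#' sp <- syntheticSpec(nRois = 20, nVolumes = 60, nGroupA = 4,
#'                     nGroupB = 4, seed = 7)
#' coh <- generateCohort(sp)
#' coh
#' @export
generateCohort <- function(spec, motionAmplitude = 0.02) {
    validObject(spec)
    nA <- spec@nGroupA; nB <- spec@nGroupB; nSubj <- nA + nB
    ids <- sprintf("S%03d", seq_len(nSubj))
    group <- rep(c("A", "B"), c(nA, nB))

    sigmaA <- buildPopulationCov(spec, "A")
    sigmaB <- buildPopulationCov(spec, "B")

    # covariates: identical distributions in both groups (matched design)
    set.seed(deriveSeed(spec@seed, 1L))
    age <- round(stats::rnorm(nSubj, 38, 9.5), 1)
    sex <- ifelse(stats::rbinom(nSubj, 1L, 1 / 3) == 1L, "M", "F")
    education <- pmax(6, pmin(22, round(stats::rnorm(nSubj, 11, 3.5))))

    # subject connectivity strength, logit-normal with median 0.75
    strength <- stats::plogis(stats::rnorm(nSubj, stats::qlogis(0.75),
                                           spec@subjectStrengthSd))
    if (spec@subjectStrengthSd == 0) strength <- rep(0.75, nSubj)

    # clinical questionnaire scores (patient-like vs control-like levels)
    scoreMeans <- list(
        A = c(PSQI = 11.75, ISI = 17.28, SAS = 53.97, SDS = 52.92,
              ESS = 11.00, duration = 28.61),
        B = c(PSQI = 1.68, ISI = 1.39, SAS = 42.45, SDS = 39.55,
              ESS = NA, duration = NA))
    scoreSds <- list(
        A = c(PSQI = 3.78, ISI = 6.70, SAS = 10.12, SDS = 9.25,
              ESS = 4.63, duration = 43.58),
        B = c(PSQI = 1.90, ISI = 2.40, SAS = 6.39, SDS = 10.58,
              ESS = NA, duration = NA))
    scores <- matrix(NA_real_, nSubj, 6L,
                     dimnames = list(NULL, names(scoreMeans$A)))
    for (s in seq_len(nSubj)) {
        g <- group[s]
        mu <- scoreMeans[[g]]; sd <- scoreSds[[g]]
        ok <- !is.na(mu)
        scores[s, ok] <- pmax(0, stats::rnorm(sum(ok), mu[ok], sd[ok]))
    }

    # per-subject covariance, behavioral coupling, series and motion
    labels <- defaultRoiLabels(spec@nRois)
    tsSeeds <- subjectSeeds(spec@seed, nSubj, 2L)
    moSeeds <- subjectSeeds(spec@seed, nSubj, 3L)
    coupled <- numeric(nSubj)
    ts <- vector("list", nSubj); mo <- vector("list", nSubj)
    couplingNoise <- stats::rnorm(nSubj, 0, spec@behaviorNoiseSd)
    for (s in seq_len(nSubj)) {
        base <- if (group[s] == "A") sigmaA else sigmaB
        gS <- strength[s]
        sigmaS <- gS * base + (1 - gS) * diag(diag(base))
        if (nrow(spec@effectEdges)) {
            effCov <- mean(sigmaS[spec@effectEdges])
        } else {
            effCov <- mean(sigmaS[upper.tri(sigmaS)])
        }
        coupled[s] <- spec@behaviorCoupling * effCov + couplingNoise[s]
        ts[[s]] <- sampleTimeSeries(sigmaS, spec@nVolumes, spec@arCoeff,
                                    seed = tsSeeds[s],
                                    trSeconds = spec@trSeconds,
                                    subjectID = ids[s], roiLabels = labels)
        mo[[s]] <- generateMotion(spec@nVolumes, motionAmplitude,
                                  seed = moSeeds[s], subjectID = ids[s])
    }
    names(ts) <- ids; names(mo) <- ids

    tab <- data.frame(subject_id = ids, group = group, age = age,
                      sex = sex, education = education,
                      scores, coupled = coupled,
                      stringsAsFactors = FALSE)
    new("Cohort", table = tab, timeSeries = ts, motion = mo, spec = spec)
}

#' Cohort table accessor
#'
#' @param cohort a [Cohort-class].
#' @return the per-subject data.frame (demographics, scores).
#' @export
cohortTable <- function(cohort) cohort@table

#' Per-subject time series accessor
#'
#' @param cohort a [Cohort-class].
#' @return named list of [RoiTimeSeries-class] objects.
#' @export
cohortTimeSeries <- function(cohort) cohort@timeSeries

#' Per-subject motion accessor
#'
#' @param cohort a [Cohort-class].
#' @return named list of [MotionParams-class] objects.
#' @export
cohortMotion <- function(cohort) cohort@motion
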