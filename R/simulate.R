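#' @include AllClasses.R cohort.R parcellation.R seedmaps.R
NULL

#' Construct a planted coupling effect
#'
#' @param seedName seed network the effect attaches to.
#' @param targetNetwork parcellation network whose time course the seed
#'   couples to.
#' @param beta0 baseline coupling.
#' @param betaLin coupling change per centered-age year.
#' @param betaQuad coupling change per centered-age year squared.
#' @param betaSex additive male-minus-female coupling offset.
#' @param betaSexLin,betaSexQuad sex-by-age interaction coefficients.
#' @return an [EffectSpec].
#' @export
effectSpec <- function(seedName, targetNetwork, beta0 = 0, betaLin = 0,
                       betaQuad = 0, betaSex = 0, betaSexLin = 0,
                       betaSexQuad = 0) {
  new("EffectSpec", seedName = seedName, targetNetwork = targetNetwork,
      beta0 = beta0, betaLin = betaLin, betaQuad = betaQuad,
      betaSex = betaSex, betaSexLin = betaSexLin,
      betaSexQuad = betaSexQuad)
}

#' Default planted-effect scenario
#'
#' The package's reference scenario of seed-to-network coupling effects:
#' the empathy network couples to dorsal attention with a linearly
#' increasing weight, to ventral attention with a linearly decreasing
#' weight, to somatomotor with a convex (U-shaped) quadratic, to control
#' with a sex-by-age linear interaction (men increasing, women decreasing)
#' and to visual with a sex-by-age quadratic interaction (men U-shaped,
#' women inverted-U); the ToM network couples to ventral attention with a
#' concave (inverted-U) quadratic; the moral network carries no age or sex
#' effect anywhere. Effect sizes were chosen so the planted shapes are
#' recoverable from runs of a few hundred volumes while total squared
#' coupling stays well below 1 at the age extremes.
#'
#' @return list of [EffectSpec] objects.
#' @export
socialScenario <- function() {
  list(
    effectSpec("empathy", "DorsAttn", beta0 = 0.10, betaLin =  0.007),
    effectSpec("empathy", "VentAttn", beta0 = 0.22, betaLin = -0.007),
    effectSpec("empathy", "SomMot",   beta0 = 0.00, betaQuad =  4e-4),
    effectSpec("ToM",     "VentAttn", beta0 = 0.30, betaQuad = -4e-4),
    effectSpec("empathy", "Control",  beta0 = 0.10, betaSexLin = 0.018),
    effectSpec("empathy", "Visual",   beta0 = 0.06, betaSexQuad = 5e-4))
}

#' Evaluate a planted coupling weight
#'
#' The coupling between an effect's seed and target network for a subject of
#' the given age and sex, before any variance clipping. Sex is coded +1/2
#' (male) / -1/2 (female), so `betaSex` is the male-minus-female difference.
#'
#' @param effect an [EffectSpec].
#' @param age age in years (vectorized).
#' @param sex `"male"` or `"female"` (vectorized).
#' @param ageCenter centering constant (years), normally the cohort mean age.
#' @return numeric coupling weight(s).
#' @export
plantedCoupling <- function(effect, age, sex, ageCenter) {
  a <- age - ageCenter
  s <- ifelse(sex == "male", 0.5, -0.5)
  effect@beta0 + effect@betaLin * a + effect@betaQuad * a^2 +
    s * (effect@betaSex + effect@betaSexLin * a + effect@betaSexQuad * a^2)
}

# Stationary unit-variance AR(1) series.
.arSeries <- function(t, phi) {
  x <- numeric(t)
  x[1] <- stats::rnorm(1)
  if (t > 1) {
    innov <- stats::rnorm(t - 1) * sqrt(1 - phi^2)
    for (i in 2:t) x[i] <- phi * x[i - 1] + innov[i - 1]
  }
  x
}

# Smooth low-amplitude random walk for one motion parameter.
.motionWalk <- function(t, step) {
  w <- cumsum(stats::rnorm(t, sd = step))
  if (t >= 5) {
    sm <- stats::filter(w, rep(1 / 5, 5), sides = 2)
    w <- ifelse(is.na(sm), w, as.numeric(sm))
  }
  w
}

#' Simulate a cohort of surface-sampled BOLD runs
#'
#' Generates, per subject, `k` unit-variance AR(1) network time courses
#' \eqn{c_k(t)}, one latent time course per seed
#' \deqn{u_i(t) = \sqrt{1 - \sum_k w_{ik}^2}\,\xi_i(t) + \sum_k w_{ik} c_k(t)}
#' with age/sex-dependent couplings \eqn{w_{ik}} from the planted effects
#' (rows clipped so \eqn{\sum_k w_{ik}^2 \le 0.95}, with a warning), and the
#' vertex signal
#' \deqn{x(t, v) = \sum_k M_k(v) c_k(t) + \sum_i Z_i(v) u_i(t) +
#'   \mathrm{noise\_sd}\,\epsilon(t, v)}
#' where \eqn{M_k} is the network indicator and \eqn{Z_i} the seed map,
#' plus a constant baseline and two designated tissue (white-matter / CSF)
#' signals broadcast across vertices so downstream nuisance regression has
#' something to remove. Motion traces are smooth low-amplitude random
#' walks. The latent courses and planted couplings are kept in each run's
#' `generative` slot for testing and truth comparisons.
#'
#' @param surface a [CorticalSurface].
#' @param parcellation a [Parcellation] over the surface.
#' @param seedMaps a [SeedMapSet] over the surface.
#' @param cohort a [Cohort].
#' @param effects list of [EffectSpec]; defaults to [socialScenario()].
#' @param tPoints volumes per run (>= 20).
#' @param tr repetition time in seconds.
#' @param noiseSd vertex-level white-noise standard deviation (>= 0).
#' @param ar1 AR(1) coefficient of all latent courses, in \[0, 1).
#' @param baseline constant signal offset (keeps the global mean positive
#'   for grand-mean scaling).
#' @param tissueWeight amplitude of the broadcast tissue signals.
#' @param seed integer RNG seed; output is byte-identical for a fixed seed
#'   and configuration.
#' @return named list of [BoldRun] objects, one per cohort subject.
#' @export
simulateBold <- function(surface, parcellation, seedMaps, cohort,
                         effects = socialScenario(), tPoints = 200L,
                         tr = 0.645, noiseSd = 0.5, ar1 = 0.3,
                         baseline = 100, tissueWeight = 0.2, seed = 1L) {
  if (tPoints < 20L) stop("tPoints must be >= 20", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)", call. = FALSE)
  v <- nVertices(surface)
  stopifnot(length(parcelLabels(parcellation)) == v,
            ncol(seedWeights(seedMaps)) == v)
  nets <- networkNames(parcellation)
  k <- length(nets)
  sn <- seedNames(seedMaps)
  for (e in effects) {
    if (!e@seedName %in% sn)
      stop("effect seed '", e@seedName, "' not among the seed maps",
           call. = FALSE)
    if (!e@targetNetwork %in% nets)
      stop("effect target '", e@targetNetwork,
           "' not among the parcellation networks", call. = FALSE)
  }
  labels <- parcelLabels(parcellation)
  m <- vapply(seq_len(k), function(i) as.numeric(labels == i),
              numeric(v))                      # V x K indicators
  z <- seedWeights(seedMaps)                   # S x V
  s <- nrow(z)
  tab <- cohortTable(cohort)
  ageCenter <- mean(tab$age)
  set.seed(seed)
  nClipped <- 0L
  runs <- vector("list", nrow(tab))
  for (j in seq_len(nrow(tab))) {
    w <- matrix(0, nrow = s, ncol = k)
    for (e in effects) {
      w[match(e@seedName, sn), match(e@targetNetwork, nets)] <-
        w[match(e@seedName, sn), match(e@targetNetwork, nets)] +
        plantedCoupling(e, tab$age[j], tab$sex[j], ageCenter)
    }
    ss <- rowSums(w^2)
    if (any(ss > 0.95)) {
      nClipped <- nClipped + 1L
      over <- ss > 0.95
      w[over, ] <- w[over, , drop = FALSE] * sqrt(0.95 / ss[over])
      ss <- rowSums(w^2)
    }
    cmat <- vapply(seq_len(k), function(i) .arSeries(tPoints, ar1),
                   numeric(tPoints))           # T x K
    xi <- vapply(seq_len(s), function(i) .arSeries(tPoints, ar1),
                 numeric(tPoints))             # T x S
    u <- sweep(xi, 2L, sqrt(1 - ss), "*") + cmat %*% t(w)
    tissue <- cbind(wm = .arSeries(tPoints, ar1),
                    csf = .arSeries(tPoints, ar1))
    data <- cmat %*% t(m) + u %*% z + baseline +
      tissueWeight * (tissue[, 1] + tissue[, 2])
    if (noiseSd > 0)
      data <- data + matrix(stats::rnorm(tPoints * v, sd = noiseSd),
                            nrow = tPoints)
    motion <- cbind(
      vapply(1:3, function(i) .motionWalk(tPoints, 0.01), numeric(tPoints)),
      vapply(1:3, function(i) .motionWalk(tPoints, 5e-4), numeric(tPoints)))
    colnames(motion) <- c(paste0("trans_", c("x", "y", "z")),
                          paste0("rot_", c("x", "y", "z")))
    runs[[j]] <- new("BoldRun", subjectId = tab$subject_id[j], data = data,
                     tr = tr, motion = motion, tissue = tissue,
                     generative = list(networkCourses = cmat,
                                       seedCourses = u, coupling = w,
                                       ageCenter = ageCenter),
                     provenance = "simulated")
  }
  if (nClipped > 0L)
    warning(nClipped, " subject(s) had total squared coupling > 0.95 ",
            "and were clipped", call. = FALSE)
  names(runs) <- tab$subject_id
  runs
}
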