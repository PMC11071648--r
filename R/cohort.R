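#' @include AllClasses.R
NULL

# Mean of a normal(mu, sd) truncated to [a, b]; asymptotic tail forms keep
# it finite when the untruncated mass in [a, b] underflows.
.truncNormMean <- function(mu, sd, a, b) {
  za <- (a - mu) / sd; zb <- (b - mu) / sd
  mass <- stats::pnorm(zb) - stats::pnorm(za)
  if (mass > 1e-12)
    return(mu + sd * (stats::dnorm(za) - stats::dnorm(zb)) / mass)
  if (za > 0) a + sd / za else b + sd / zb
}

# Location parameter whose truncated mean equals the target.
.truncNormLocation <- function(target, sd, a, b) {
  stats::uniroot(function(mu) .truncNormMean(mu, sd, a, b) - target,
                 lower = a - 8 * sd, upper = b + 8 * sd,
                 tol = 1e-10)$root
}

#' Generate a synthetic study cohort
#'
#' Draws ages from a truncated normal on `[ageMin, ageMax]` whose location
#' is moment-matched (via the closed-form truncated-normal mean and a root
#' search) so the expected sample mean equals `targetMeanAge`. Sex is
#' assigned to exactly `nMale` randomly chosen subjects. Defaults reproduce
#' the reference cohort: 316 subjects, 112 male, ages 8-83 with mean
#' 44.38 y and age scale 19.72 y.
#'
#' @param n cohort size.
#' @param nMale number of male subjects (0 <= nMale <= n).
#' @param ageMin,ageMax truncation bounds in years.
#' @param targetMeanAge desired expected mean age (years); must lie strictly
#'   inside the age bounds.
#' @param ageSd scale of the underlying normal (years).
#' @param seed integer RNG seed.
#' @return a [Cohort].
#' @examples
#' co <- makeCohort(seed = 1)
#' nrow(cohortTable(co))
#' @export
makeCohort <- function(n = 316L, nMale = 112L, ageMin = 8, ageMax = 83,
                       targetMeanAge = 44.38, ageSd = 19.72, seed = 1L) {
  if (nMale < 0L || nMale > n)
    stop("nMale must lie in 0..n", call. = FALSE)
  if (ageMin >= ageMax) stop("ageMin must be below ageMax", call. = FALSE)
  if (targetMeanAge <= ageMin || targetMeanAge >= ageMax)
    stop("target mean age must lie strictly inside [ageMin, ageMax]",
         call. = FALSE)
  mu <- .truncNormLocation(targetMeanAge, ageSd, ageMin, ageMax)
  set.seed(seed)
  pa <- stats::pnorm(ageMin, mu, ageSd)
  pb <- stats::pnorm(ageMax, mu, ageSd)
  ages <- stats::qnorm(stats::runif(n, pa, pb), mu, ageSd)
  sex <- sample(c(rep("male", nMale), rep("female", n - nMale)))
  tab <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = ages, sex = sex, stringsAsFactors = FALSE)
  new("Cohort", table = tab)
}
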