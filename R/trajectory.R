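#' @include AllClasses.R
NULL

# Basis factory: returns eval(ac, s) -> design matrix plus a parameter
# count. `ac` is centered age; `s` the +/- 0.5 sex code (NULL when sex is
# not in the model).
.makeBasis <- function(acData, basis, sexInMu, df = 4L) {
  if (basis == "poly2") {
    evalFun <- function(ac, s = NULL) {
      x <- cbind(1, ac, ac^2)
      colnames(x) <- c("b0", "age", "age2")
      if (sexInMu) {
        if (is.null(s)) s <- rep(0, length(ac))
        x <- cbind(x, sex = s, sex_age = s * ac, sex_age2 = s * ac^2)
      }
      x
    }
  } else {                                   # natural cubic spline basis
    nsObj <- splines::ns(acData, df = df)
    evalFun <- function(ac, s = NULL) {
      x <- cbind(1, stats::predict(nsObj, ac))
      colnames(x) <- c("b0", paste0("ns", seq_len(ncol(x) - 1L)))
      if (sexInMu) {
        if (is.null(s)) s <- rep(0, length(ac))
        x <- cbind(x, sex = s)
      }
      x
    }
  }
  list(eval = evalFun, npar = ncol(evalFun(acData[1])))
}

# Gaussian location-scale ML by backfitting: weighted least squares for the
# location, Fisher scoring (with step halving) for the log-scale.
.fitGaussianLS <- function(bmu, bs, y, maxIter = 200L, tol = 1e-8) {
  n <- length(y)
  b <- qr.solve(bmu, y)
  e <- y - drop(bmu %*% b)
  g <- c(log(stats::sd(e)), numeric(ncol(bs) - 1L))
  loglik <- function(b, g) {
    sigma <- exp(drop(bs %*% g))
    sum(stats::dnorm(y, drop(bmu %*% b), sigma, log = TRUE))
  }
  ll <- loglik(b, g)
  info <- 2 * crossprod(bs)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    sigma <- exp(drop(bs %*% g))
    if (any(sigma < 1e-10))
      stop("scale underflow during location-scale fitting", call. = FALSE)
    w <- 1 / sigma^2
    bw <- bmu * sqrt(w)
    b <- qr.solve(bw, y * sqrt(w))
    e <- y - drop(bmu %*% b)
    score <- drop(crossprod(bs, e^2 / sigma^2 - 1))
    delta <- solve(info, score)
    step <- 1
    llNew <- loglik(b, g + delta)
    while (llNew < loglik(b, g) && step > 1e-8) {
      step <- step / 2
      llNew <- loglik(b, g + step * delta)
    }
    g <- g + step * delta
    if (abs(llNew - ll) < tol * (abs(ll) + 1)) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  if (!converged)
    stop("location-scale fit did not converge in ", maxIter,
         " iterations (last log-likelihood ", signif(ll, 8), ")",
         call. = FALSE)
  sigma <- exp(drop(bs %*% g))
  list(b = b, g = g, logLik = ll,
       muVcov = solve(crossprod(bmu * (1 / sigma))),
       converged = TRUE)
}

# Box-Cox Cole-Green log-likelihood; the scale model is on the outcome sd
# (log tau linear in the basis, sigma = tau / mu), so nu = 1 reduces
# exactly to the Gaussian location-scale model. The truncation normalizer
# at y = 0 is omitted (negligible for sigma * nu well below 1).
.bccgNegLL <- function(par, bmu, bs, y, nuFixed) {
  pmu <- ncol(bmu); ps <- ncol(bs)
  b <- par[seq_len(pmu)]
  g <- par[pmu + seq_len(ps)]
  nu <- if (is.null(nuFixed)) par[pmu + ps + 1L] else nuFixed
  mu <- drop(bmu %*% b)
  if (any(mu <= 0)) return(1e10)
  sigma <- exp(drop(bs %*% g)) / mu
  z <- if (abs(nu) < 1e-8) log(y / mu) / sigma
       else ((y / mu)^nu - 1) / (nu * sigma)
  ll <- sum(stats::dnorm(z, log = TRUE) + (nu - 1) * log(y) -
              nu * log(mu) - log(sigma))
  if (!is.finite(ll)) 1e10 else -ll
}

.bccgQuantile <- function(p, mu, sigma, nu) {
  z <- stats::qnorm(p)
  if (abs(nu) < 1e-8) return(mu * exp(sigma * z))
  base <- 1 + nu * sigma * z
  ifelse(base > 0, mu * base^(1 / nu), 0)
}

#' Fit a normative percentile trajectory
#'
#' Distributional regression of a connectivity measure on age: the location
#' \eqn{\mu(age)} and log scale \eqn{\log\sigma(age)} (and a Box-Cox power
#' for the skewed family) are each linear in the chosen basis and fitted by
#' maximum likelihood — backfitting between weighted least squares for
#' \eqn{\mu} and Fisher scoring for \eqn{\sigma} until the relative
#' log-likelihood change falls below `tol`. Percentile curves are the
#' fitted distribution's quantiles on an age grid spanning the observed
#' ages; because all curves are quantiles of one distribution per age they
#' are strictly ordered and cannot cross. With `sexInMu` the location model
#' additionally carries sex and sex-by-age terms and per-sex curves are
#' produced.
#'
#' @param age,y numeric vectors (>= 30 observations, non-constant age).
#' @param sex optional `"male"`/`"female"` vector (required for `sexInMu`).
#' @param family `"gaussian_ls"` (Gaussian location-scale, default) or
#'   `"box_cox_cole_green"` (LMS; requires positive `y`).
#' @param basis `"poly2"` (quadratic polynomial, default) or `"pspline"`
#'   (natural cubic spline with degrees of freedom selected on a BIC grid).
#' @param percentiles percent levels of the fitted curves.
#' @param sexInMu enter sex into the location model.
#' @param nu fixed Box-Cox power for the BCCG family (`NULL` = estimate).
#' @param gridPoints age-grid resolution.
#' @param maxIter,tol backfitting controls.
#' @return a [TrajectoryFit].
#' @examples
#' set.seed(1)
#' age <- runif(200, 8, 83)
#' y <- 2 + 0.1 * (age - mean(age)) + rnorm(200)
#' fit <- fitTrajectory(age, y)
#' trajectoryCurves(fit)[, 1:3]
#' @export
fitTrajectory <- function(age, y, sex = NULL,
                          family = c("gaussian_ls", "box_cox_cole_green"),
                          basis = c("poly2", "pspline"),
                          percentiles = c(10, 25, 50, 75, 90),
                          sexInMu = FALSE, nu = NULL, gridPoints = 100L,
                          maxIter = 200L, tol = 1e-8) {
  family <- match.arg(family)
  basis <- match.arg(basis)
  if (length(age) != length(y)) stop("age and y lengths differ", call. = FALSE)
  if (length(y) < 30L)
    stop("trajectory fitting needs at least 30 observations", call. = FALSE)
  if (stats::var(age) == 0) stop("age is constant", call. = FALSE)
  if (sexInMu && is.null(sex))
    stop("sexInMu requires a sex vector", call. = FALSE)
  percentiles <- sort(unique(percentiles))
  ageCenter <- mean(age)
  ac <- age - ageCenter
  s <- if (!is.null(sex)) ifelse(sex == "male", 0.5, -0.5) else NULL

  buildFit <- function(bspec) {
    bmu <- bspec$eval(ac, if (sexInMu) s else NULL)
    bs <- cbind(1, ac, ac^2)
    if (family == "gaussian_ls") {
      fit <- .fitGaussianLS(bmu, bs, y, maxIter = maxIter, tol = tol)
      npar <- ncol(bmu) + ncol(bs)
      list(fit = fit, bmu = bmu, bs = bs,
           bic = -2 * fit$logLik + npar * log(length(y)))
    } else {
      if (any(y <= 0))
        stop("the Box-Cox Cole-Green family requires positive outcomes",
             call. = FALSE)
      init <- .fitGaussianLS(bmu, bs, y, maxIter = maxIter, tol = tol)
      par0 <- c(init$b, init$g, if (is.null(nu)) 1)
      # simplex search first (the surface is badly scaled in the
      # polynomial coefficients), then a scaled quasi-Newton polish
      opt <- stats::optim(par0, .bccgNegLL, bmu = bmu, bs = bs, y = y,
                          nuFixed = nu, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12))
      opt <- stats::optim(opt$par, .bccgNegLL, bmu = bmu, bs = bs, y = y,
                          nuFixed = nu, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-14,
                                         parscale = pmax(abs(opt$par),
                                                         1e-5)))
      pmu <- ncol(bmu); ps <- ncol(bs)
      fit <- list(b = opt$par[seq_len(pmu)],
                  g = opt$par[pmu + seq_len(ps)],
                  nu = if (is.null(nu)) opt$par[pmu + ps + 1L] else nu,
                  logLik = -opt$value, muVcov = init$muVcov,
                  converged = opt$convergence == 0)
      if (!fit$converged)
        stop("BCCG optimization did not converge (code ",
             opt$convergence, ")", call. = FALSE)
      npar <- pmu + ps + as.integer(is.null(nu))
      list(fit = fit, bmu = bmu, bs = bs,
           bic = -2 * fit$logLik + npar * log(length(y)))
    }
  }

  if (basis == "poly2") {
    bspec <- .makeBasis(ac, "poly2", sexInMu)
    best <- buildFit(bspec)
  } else {
    cand <- lapply(4:8, function(df) {
      bs <- .makeBasis(ac, "pspline", sexInMu, df = df)
      c(list(bspec = bs), buildFit(bs))
    })
    best <- cand[[which.min(vapply(cand, `[[`, 1, "bic"))]]
    bspec <- best$bspec
  }
  fit <- best$fit

  grid <- seq(min(age), max(age), length.out = gridPoints)
  gc <- grid - ageCenter
  bsGrid <- cbind(1, gc, gc^2)
  curveSet <- function(sexCode) {
    bmuGrid <- bspec$eval(gc, if (sexInMu) rep(sexCode, length(gc)) else NULL)
    muG <- drop(bmuGrid %*% fit$b)
    if (family == "gaussian_ls") {
      sigG <- exp(drop(bsGrid %*% fit$g))
      t(vapply(percentiles / 100,
               function(p) stats::qnorm(p, muG, sigG), muG))
    } else {
      sigG <- exp(drop(bsGrid %*% fit$g)) / muG
      t(vapply(percentiles / 100,
               function(p) .bccgQuantile(p, muG, sigG, fit$nu), muG))
    }
  }
  curves <- curveSet(0)
  sexCurves <- if (sexInMu)
    list(male = curveSet(0.5), female = curveSet(-0.5)) else list()

  dat <- data.frame(age = age, y = y)
  if (!is.null(sex)) dat$sex <- sex
  new("TrajectoryFit", family = family, basis = basis,
      muCoefficients = as.numeric(fit$b),
      sigmaCoefficients = as.numeric(fit$g),
      nuCoefficients = if (family == "box_cox_cole_green")
        as.numeric(fit$nu) else numeric(0),
      percentiles = percentiles, ageGrid = grid, curves = curves,
      sexCurves = sexCurves, logLik = fit$logLik, bic = best$bic,
      converged = isTRUE(fit$converged), ageCenter = ageCenter,
      muVcov = as.matrix(fit$muVcov), data = dat)
}

#' Empirical coverage below each percentile curve
#'
#' Percentage of observations falling strictly below each fitted percentile
#' curve (interpolated at the observation ages); for a well-calibrated fit
#' the coverage matches the nominal percent level.
#'
#' @param fit a [TrajectoryFit].
#' @param age,y observations to evaluate (default: the fitted data).
#' @param sex optional sex vector for per-sex curve evaluation.
#' @return named numeric vector of percentages, one per percentile.
#' @export
trajectoryCoverage <- function(fit, age = fit@data$age, y = fit@data$y,
                               sex = NULL) {
  below <- vapply(seq_along(fit@percentiles), function(i) {
    curveAt <- function(curves)
      stats::approx(fit@ageGrid, curves[i, ], xout = age, rule = 2)$y
    thr <- if (is.null(sex)) curveAt(fit@curves) else {
      m <- curveAt(fit@sexCurves$male)
      f <- curveAt(fit@sexCurves$female)
      ifelse(sex == "male", m, f)
    }
    100 * mean(y < thr)
  }, 1)
  names(below) <- paste0("p", fit@percentiles)
  below
}

#' Classify the shape of a fitted trajectory
#'
#' Refits the location model at polynomial degrees 0 (constant), 1
#' (linear) and 2 (quadratic) under the Gaussian location-scale likelihood
#' with a quadratic scale model, picks the degree by BIC, and gates the
#' winning coefficient with a two-sided Wald test at `alpha` before
#' labeling: a gated quadratic winner is `convex_U` (positive quadratic
#' coefficient) or `concave_inverted_U`; a gated linear winner is
#' `linear_increasing` or `linear_decreasing`; everything else is `flat`
#' (a quadratic winner whose Wald gate fails falls back to the linear
#' decision).
#'
#' @param fit a converged [TrajectoryFit].
#' @param alpha Wald gate level.
#' @return one of `"linear_increasing"`, `"linear_decreasing"`,
#'   `"convex_U"`, `"concave_inverted_U"`, `"flat"`.
#' @export
classifyShape <- function(fit, alpha = 0.05) {
  if (!fit@converged) stop("fit did not converge", call. = FALSE)
  y <- fit@data$y
  ac <- fit@data$age - mean(fit@data$age)
  bs <- cbind(1, ac, ac^2)
  fits <- lapply(0:2, function(d) {
    bmu <- switch(d + 1L, cbind(rep(1, length(ac))), cbind(1, ac),
                  cbind(1, ac, ac^2))
    f <- .fitGaussianLS(bmu, bs, y)
    list(fit = f,
         bic = -2 * f$logLik + (ncol(bmu) + ncol(bs)) * log(length(y)))
  })
  zcrit <- stats::qnorm(1 - alpha / 2)
  wald <- function(f, j) f$b[j] / sqrt(f$muVcov[j, j])
  best <- which.min(vapply(fits, `[[`, 1, "bic"))
  if (best == 3L) {
    zq <- wald(fits[[3]]$fit, 3L)
    if (abs(zq) > zcrit)
      return(if (zq > 0) "convex_U" else "concave_inverted_U")
    best <- 2L                                # fall back to the linear call
  }
  if (best == 2L) {
    zl <- wald(fits[[2]]$fit, 2L)
    if (abs(zl) > zcrit)
      return(if (zl > 0) "linear_increasing" else "linear_decreasing")
  }
  "flat"
}
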