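#' @include AllClasses.R
NULL

# Rebuild a run with new data/motion/tissue, trimming any generative latent
# matrices that track the time axis, and append a provenance step.
.updateRun <- function(run, data = run@data, motion = run@motion,
                       tissue = run@tissue, keepRows = NULL, step) {
  gen <- run@generative
  if (!is.null(keepRows) && length(gen)) {
    tOld <- nrow(run@data)
    gen <- lapply(gen, function(g) {
      if (is.matrix(g) && nrow(g) == tOld) g[keepRows, , drop = FALSE] else g
    })
  }
  new("BoldRun", subjectId = run@subjectId, data = data, tr = run@tr,
      motion = motion, tissue = tissue, generative = gen,
      provenance = c(run@provenance, step))
}

#' Discard initial volumes
#'
#' Drops the first `nDiscard` timepoints of data, motion and tissue traces;
#' the default removes the conventional eight pre-steady-state volumes.
#'
#' @param run a [BoldRun].
#' @param nDiscard non-negative integer, strictly below the run length.
#' @return the shortened [BoldRun].
#' @export
discardVolumes <- function(run, nDiscard = 8L) {
  t <- nrow(run@data)
  if (nDiscard < 0L) stop("nDiscard must be >= 0", call. = FALSE)
  if (nDiscard >= t)
    stop("nDiscard (", nDiscard, ") must be below the run length (", t, ")",
         call. = FALSE)
  if (nDiscard == 0L) return(run)
  keep <- (nDiscard + 1L):t
  .updateRun(run, data = run@data[keep, , drop = FALSE],
             motion = run@motion[keep, , drop = FALSE],
             tissue = run@tissue[keep, , drop = FALSE], keepRows = keep,
             step = sprintf("discard(%d)", nDiscard))
}

#' Grand-mean intensity scaling
#'
#' Multiplies the run so its global (all timepoints, all vertices) mean
#' intensity equals `target`; the conventional target is 10,000.
#'
#' @param run a [BoldRun].
#' @param target positive target global mean.
#' @return the rescaled [BoldRun].
#' @export
grandMeanScale <- function(run, target = 10000) {
  if (target <= 0) stop("target must be positive", call. = FALSE)
  gm <- mean(run@data)
  if (!is.finite(gm) || abs(gm) < .Machine$double.eps * 100 ||
      mean(abs(run@data)) == 0)
    stop("degenerate input: global mean is zero", call. = FALSE)
  .updateRun(run, data = run@data * (target / gm),
             step = sprintf("grand_mean(%g)", target))
}

#' Friston 24-parameter motion expansion
#'
#' Expands six rigid-body motion parameters into the 24-column confound
#' block: the parameters, their one-volume lags, and the squares of both,
#' in that column order. The lagged blocks are zero-padded in their first
#' row.
#'
#' @param motion numeric matrix (T x 6).
#' @return numeric matrix (T x 24) with columns `mot1..mot24`.
#' @export
friston24 <- function(motion) {
  if (!is.matrix(motion) || ncol(motion) != 6L)
    stop("motion must be a T x 6 matrix", call. = FALSE)
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  colnames(out) <- paste0("mot", 1:24)
  out
}

#' Assemble a temporal nuisance design
#'
#' Intercept plus, optionally, the run's designated white-matter/CSF mean
#' signals and the Friston-24 motion expansion.
#'
#' @param run a [BoldRun].
#' @param friston include the 24-parameter motion block.
#' @param tissue include the wm/csf mean-signal columns.
#' @return a [NuisanceDesign].
#' @export
nuisanceDesign <- function(run, friston = TRUE, tissue = TRUE) {
  t <- nrow(run@data)
  x <- matrix(1, nrow = t, ncol = 1L, dimnames = list(NULL, "intercept"))
  if (tissue) {
    tis <- run@tissue
    colnames(tis) <- c("wm_mean", "csf_mean")
    x <- cbind(x, tis)
  }
  if (friston) x <- cbind(x, friston24(run@motion))
  new("NuisanceDesign", design = x)
}

# Least-squares residualization with a pseudo-inverse fallback for
# rank-deficient designs (singular values below 1e-10 * max dropped).
.residualize <- function(y, x) {
  sv <- svd(x)
  keep <- sv$d > 1e-10 * sv$d[1]
  fitted <- sv$u[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) %*% y)
  y - fitted
}

#' Nuisance regression
#'
#' Replaces every vertex time series by its residual after least-squares
#' projection onto the nuisance design; residuals are orthogonal to every
#' design column, and re-applying the same design is a no-op.
#'
#' @param run a [BoldRun].
#' @param design a [NuisanceDesign] whose row count matches the run length.
#' @return the residualized [BoldRun].
#' @export
nuisanceRegress <- function(run, design) {
  x <- designMatrix(design)
  if (nrow(x) != nrow(run@data))
    stop("design has ", nrow(x), " rows but the run has ", nrow(run@data),
         call. = FALSE)
  .updateRun(run, data = .residualize(run@data, x),
             step = sprintf("nuisance(%d cols)", ncol(x)))
}

#' Linear and quadratic detrending
#'
#' Removes, per vertex, the least-squares fit on \{1, t, t^2\} with the time
#' index centered and scaled to \[-1, 1\] for conditioning.
#'
#' @param run a [BoldRun] with at least 3 timepoints.
#' @return the detrended [BoldRun].
#' @export
detrendRun <- function(run) {
  t <- nrow(run@data)
  if (t < 3L) stop("detrending needs at least 3 timepoints", call. = FALSE)
  tt <- seq(-1, 1, length.out = t)
  x <- cbind(1, tt, tt^2)
  .updateRun(run, data = .residualize(run@data, x), step = "detrend")
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain masking: the run is Fourier transformed along time,
#' bins outside `[lowHz, highHz]` are zeroed (symmetrically, so the filter
#' is zero-phase by construction) and the signal inverse-transformed. The
#' default 0.01-0.1 Hz band is the conventional resting-state range. The
#' DC bin is kept only when `lowHz == 0`.
#'
#' @param run a [BoldRun].
#' @param lowHz,highHz band edges in Hz; `0 <= lowHz < highHz <= 1/(2 TR)`.
#' @return the filtered [BoldRun].
#' @export
bandpassFilter <- function(run, lowHz = 0.01, highHz = 0.1) {
  nyq <- 1 / (2 * run@tr)
  if (lowHz < 0 || lowHz >= highHz)
    stop("need 0 <= lowHz < highHz", call. = FALSE)
  if (highHz > nyq + 1e-12)
    stop("highHz (", highHz, ") exceeds the Nyquist frequency (",
         signif(nyq, 6), ")", call. = FALSE)
  t <- nrow(run@data)
  freq <- (seq_len(t) - 1) / (t * run@tr)
  folded <- pmin(freq, 1 / run@tr - freq)
  keep <- folded >= lowHz - 1e-12 & folded <= highHz + 1e-12
  xf <- stats::mvfft(run@data)
  xf[!keep, ] <- 0
  .updateRun(run, data = Re(stats::mvfft(xf, inverse = TRUE)) / t,
             step = sprintf("bandpass(%g-%g Hz)", lowHz, highHz))
}

#' Run the default preprocessing chain
#'
#' Applies the surface-domain preprocessing stages in a configurable order;
#' the default follows the conventional enumeration: volume discard,
#' grand-mean scaling, nuisance regression (Friston-24 + tissue), band-pass
#' filtering, then polynomial detrending. Every step is recorded in the
#' run's provenance.
#'
#' @param run a [BoldRun].
#' @param nDiscard,grandMeanTarget,band scalar step parameters
#'   (`band = c(low, high)` in Hz).
#' @param friston,tissue nuisance design content switches.
#' @param order character vector over
#'   `c("discard", "scale", "nuisance", "bandpass", "detrend")`; steps run
#'   in the given order and omitted steps are skipped.
#' @return the preprocessed [BoldRun].
#' @export
preprocessRun <- function(run, nDiscard = 8L, grandMeanTarget = 10000,
                          band = c(0.01, 0.1), friston = TRUE, tissue = TRUE,
                          order = c("discard", "scale", "nuisance",
                                    "bandpass", "detrend")) {
  known <- c("discard", "scale", "nuisance", "bandpass", "detrend")
  if (!all(order %in% known))
    stop("unknown preprocessing step(s): ",
         paste(setdiff(order, known), collapse = ", "), call. = FALSE)
  for (step in order) {
    run <- switch(step,
      discard  = discardVolumes(run, nDiscard),
      scale    = grandMeanScale(run, grandMeanTarget),
      nuisance = nuisanceRegress(run, nuisanceDesign(run, friston, tissue)),
      bandpass = bandpassFilter(run, band[1], band[2]),
      detrend  = detrendRun(run))
  }
  run
}
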