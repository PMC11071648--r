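#' @include trajectory.R
NULL

#' Plot a fitted percentile trajectory
#'
#' Percentile fan over age with the fitted observations, in the style of
#' normative growth-curve panels (five percentile lines by default).
#'
#' @param fit a [TrajectoryFit].
#' @param sex optionally `"male"` or `"female"` to plot per-sex curves.
#' @param pointAlpha transparency of the observation points.
#' @return a ggplot object.
#' @export
plotTrajectory <- function(fit, sex = NULL, pointAlpha = 0.3) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotTrajectory needs the ggplot2 package", call. = FALSE)
  curves <- trajectoryCurves(fit, sex = sex)
  long <- data.frame(
    age = rep(fit@ageGrid, each = nrow(curves)),
    percentile = factor(rep(paste0("p", fit@percentiles), ncol(curves)),
                        levels = paste0("p", rev(fit@percentiles))),
    value = as.numeric(curves))
  dat <- fit@data
  if (!is.null(sex) && "sex" %in% names(dat)) dat <- dat[dat$sex == sex, ]
  ggplot2::ggplot(long, ggplot2::aes(x = age)) +
    ggplot2::geom_point(data = dat,
                        ggplot2::aes(y = y), alpha = pointAlpha,
                        size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = value, linetype = percentile)) +
    ggplot2::labs(x = "age (years)", y = "iFC",
                  linetype = "percentile") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("age", "y", "value", "percentile"))
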