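#' @export
print.sel_fit <- function(x, digits = 4, ...) {
  cat("Codend selection curve fit:", x$model$name, "\n")
  if (!x$converged) {
    cat("  NOT CONVERGED (", x$n_starts, "starts attempted )\n")
    return(invisible(x))
  }
  print(round(x$par, digits))
  cat(sprintf("  nll %.4f | AIC %.4f | deviance %.3f on %d dof (p = %.3f)\n",
              x$nll, x$aic, x$deviance, x$dof, x$p_value))
  if (isTRUE(x$boundary)) {
    cat("  warning: boundary fit (retention flat over the observed range)\n")
  }
  invisible(x)
}

#' @export
coef.sel_fit <- function(object, ...) object$par

#' @export
logLik.sel_fit <- function(object, ...) {
  structure(-object$nll, df = object$model$k,
            nobs = count_measured(object$data), class = "logLik")
}

#' Summarise a fitted selection curve
#'
#' Reports the natural-scale parameters and, for contact models, the
#' overall L50/SR implied by the mixture curve. When the mixture floor
#' `1 - C` sits at or above 0.5 (0.25) the overall L50 (SR) is never
#' reached and is reported as `NA`: only the contact-conditional `L50c`
#' and `SRc` are then meaningful.
#'
#' @param object a `"sel_fit"` object.
#' @param ... unused.
#' @return An object of class `"summary.sel_fit"`.
#' @export
summary.sel_fit <- function(object, ...) {
  out <- list(fit = object,
              overall = if (object$converged) {
                overall_l50_sr(object$model, object$par)
              } else c(L50_overall = NA_real_, SR_overall = NA_real_),
              dispersion = if (object$converged && !is.na(object$dof)) {
                object$deviance / object$dof
              } else NA_real_)
  class(out) <- "summary.sel_fit"
  out
}

#' @export
print.summary.sel_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (x$fit$converged && x$fit$model$contact) {
    ov <- x$overall
    cat("  overall L50:",
        if (is.na(ov[1])) "not reached (floor 1 - C >= 0.5)"
        else round(ov[1], digits),
        "| overall SR:",
        if (is.na(ov[2])) "not reached (floor 1 - C >= 0.25)"
        else round(ov[2], digits), "\n")
  }
  if (!is.na(x$dispersion)) {
    cat("  dispersion (deviance/dof):", round(x$dispersion, 3), "\n")
  }
  invisible(x)
}

#' Predict retention probabilities from a fitted selection curve
#'
#' @param object a `"sel_fit"` object.
#' @param length lengths (cm) at which to evaluate the curve; defaults to a
#'   0.1-cm grid over the observed length range extended by 2 cm each side.
#' @param ... unused.
#' @return data.frame with columns `length` and `retention`.
#' @export
predict.sel_fit <- function(object, length = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit",
                              call. = FALSE)
  if (is.null(length)) length <- default_length_grid(object$data)
  data.frame(length = length,
             retention = retention(object$model, object$par, length))
}

# shared 0.1-cm grid convention: observed range widened by 2 cm
default_length_grid <- function(data) {
  lens <- data$counts$length
  seq(min(lens) - 2, max(lens) + 2, by = 0.1)
}

#' Deviance residuals of a fitted selection curve
#'
#' Signed square-root contributions of each occupied length class to the
#' pooled deviance (raised counts pooled over hauls).
#'
#' @param object a `"sel_fit"` object.
#' @param ... unused.
#' @return data.frame with `length`, `observed` (raised retention
#'   proportion), `fitted`, and `residual`.
#' @export
residuals.sel_fit <- function(object, ...) {
  pooled <- pooled_raised(object$data)
  NR <- pooled$raised_codend
  NE <- pooled$raised_cover
  N <- NR + NE
  keep <- N > 0
  pooled <- pooled[keep, ]
  NR <- NR[keep]; NE <- NE[keep]; N <- N[keep]
  eps <- 1e-12
  r <- pmin(pmax(retention(object$model, object$par, pooled$length), eps),
            1 - eps)
  obs <- NR / N
  term <- ifelse(NR > 0, NR * log(NR / (N * r)), 0) +
    ifelse(NE > 0, NE * log(NE / (N * (1 - r))), 0)
  data.frame(length = pooled$length, observed = obs, fitted = r,
             residual = sign(obs - r) * sqrt(pmax(2 * term, 0)))
}

#' Plot a fitted selection curve over the experimental retention ratios
#'
#' @param x a `"sel_fit"` object.
#' @param ci optional `"sel_boot_ci"` object (from [efron_ci()]) whose
#'   curve band is drawn as dashed lines.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sel_fit <- function(x, ci = NULL, ...) {
  pooled <- pooled_raised(x$data)
  N <- pooled$raised_codend + pooled$raised_cover
  keep <- N > 0
  obs <- pooled$raised_codend[keep] / N[keep]
  pr <- predict(x)
  graphics::plot(pr$length, pr$retention, type = "l", ylim = c(0, 1),
                 xlab = "Length (cm)", ylab = "Retention probability",
                 main = paste("Selection curve:", x$model$name), ...)
  graphics::points(pooled$length[keep], obs, pch = 5)
  if (!is.null(ci)) {
    graphics::lines(ci$curve$length, ci$curve$lower, lty = 2)
    graphics::lines(ci$curve$length, ci$curve$upper, lty = 2)
  }
  invisible(x)
}

#' Parametric resampling of a fitted selection curve
#'
#' Holds each haul-by-length-class number of measured fish fixed and
#' redraws the codend/cover split from the fitted curve: a measured fish
#' of length l in haul j lands in the codend sample with probability
#' `r(l) qR / (r(l) qR + (1 - r(l)) qE)`.
#'
#' @param object a converged `"sel_fit"` object.
#' @param nsim number of datasets.
#' @param seed integer seed (required for reproducibility).
#' @param ... unused.
#' @return A list of [catch_data] objects of length `nsim`.
#' @export
simulate.sel_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit",
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  counts <- object$data$counts
  hauls <- object$data$hauls
  qR <- hauls$q_codend[match(counts$haul_id, hauls$haul_id)]
  qE <- hauls$q_cover[match(counts$haul_id, hauls$haul_id)]
  r <- retention(object$model, object$par, counts$length)
  p_codend <- r * qR / (r * qR + (1 - r) * qE)
  n <- counts$n_codend + counts$n_cover
  replicate(nsim, {
    new_counts <- counts
    new_counts$n_codend <- stats::rbinom(length(n), n, p_codend)
    new_counts$n_cover <- n - new_counts$n_codend
    catch_data(new_counts, hauls)
  }, simplify = FALSE)
}
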