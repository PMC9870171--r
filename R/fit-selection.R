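#' Pooled covered-codend negative log-likelihood
#'
#' The estimation objective for haul-pooled covered-codend data:
#' \deqn{-\sum_j \sum_l \left\{ \frac{nR_{jl}}{qR_j} \ln r(l) +
#'   \frac{nE_{jl}}{qE_j} \ln(1 - r(l)) \right\}}
#' where `nR`/`nE` are fish measured in the codend and cover, `qR`/`qE` the
#' compartment subsampling ratios, and `r(l)` the retention curve evaluated
#' with `params`. Terms with a zero raised count contribute zero, and `r` is
#' clipped to `[1e-12, 1 - 1e-12]` so that a curve pinned at 0 or 1 against
#' opposing counts yields a large finite (or `Inf`) objective rather than an
#' error. Binomial coefficients are omitted: they do not depend on the
#' parameters, so likelihood ratios, MLEs and AIC rankings are unchanged.
#'
#' @param data a [catch_data] object.
#' @param spec model name or [sel_model()] object.
#' @param params named natural-scale parameter vector.
#' @return The scalar objective value (lower is better).
#' @export
neg_log_likelihood <- function(data, spec, params) {
  spec <- sel_model(spec)
  validate_params(spec, params)
  make_nll(data, spec)(params)
}

# closure over pooled raised counts; r does not vary by haul, so the
# double sum over hauls collapses onto per-class raised totals
make_nll <- function(data, spec) {
  pooled <- pooled_raised(data)
  lens <- pooled$length
  NR <- pooled$raised_codend
  NE <- pooled$raised_cover
  eps <- 1e-12
  function(params) {
    r <- pmin(pmax(retention(spec, params, lens), eps), 1 - eps)
    -(sum(NR[NR > 0] * log(r[NR > 0])) +
        sum(NE[NE > 0] * log(1 - r[NE > 0])))
  }
}

# unconstrained optimiser scale: (L50, log SR, log 1/delta, logit C)
theta_from_params <- function(spec, params) {
  th <- c(params[["L50"]], log(params[["SR"]]))
  if (spec$family == "richard") th <- c(th, log(params[["inv_delta"]]))
  if (spec$contact) th <- c(th, stats::qlogis(params[["C"]]))
  th
}

params_from_theta <- function(spec, theta) {
  p <- c(L50 = theta[1], SR = exp(theta[2]))
  i <- 3
  if (spec$family == "richard") {
    p <- c(p, inv_delta = exp(theta[i])); i <- i + 1
  }
  if (spec$contact) p <- c(p, C = stats::plogis(theta[i]))
  p
}

# multi-start grid: L50 across the observed length distribution, coarse
# SR / C / (1/delta) levels; mixture likelihoods are multimodal
default_starts <- function(data, spec) {
  pooled <- pooled_raised(data)
  w <- pooled$raised_codend + pooled$raised_cover
  lens <- rep(pooled$length, times = pmax(1, round(w / max(w) * 100)))
  l50s <- unique(stats::quantile(lens, c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 names = FALSE, type = 1))
  srs <- c(2, 4, 8)
  grid <- expand.grid(L50 = l50s, SR = srs, KEEP.OUT.ATTRS = FALSE)
  starts <- lapply(seq_len(nrow(grid)),
                   function(i) c(L50 = grid$L50[i], SR = grid$SR[i]))
  if (spec$family == "richard") {
    starts <- unlist(lapply(starts, function(s) {
      lapply(c(0.5, 1, 2), function(d) c(s, inv_delta = d))
    }), recursive = FALSE)
  }
  if (spec$contact) {
    starts <- unlist(lapply(starts, function(s) {
      lapply(c(0.3, 0.6, 0.9), function(C) c(s, C = C))
    }), recursive = FALSE)
  }
  starts
}

#' Fit a codend selection curve by maximum likelihood
#'
#' Maximises the haul-pooled covered-codend likelihood (see
#' [neg_log_likelihood()]) for one model family, using a bounded
#' quasi-Newton search on unconstrained transformed parameters (log SR,
#' log 1/delta, logit C) from a deterministic multi-start grid, and keeping
#' the best optimum. Goodness of fit is assessed by the deviance of the
#' pooled raised counts against the fitted curve, referred to a chi-square
#' with (occupied length classes - k) degrees of freedom; overdispersion
#' (deviance/dof) is reported but never corrected for.
#'
#' @param data a [catch_data] object.
#' @param model one of [sel_models()] (default `"logit"`).
#' @param treatment optional gear label; fit only that treatment's hauls.
#' @param start optional list of named natural-scale start vectors (or one
#'   vector), replacing the default multi-start grid.
#' @param control passed to [stats::nlminb()]; the default demands a
#'   1e-9-scale objective tolerance.
#' @return An object of class `"sel_fit"` with components `model`, `par`
#'   (natural scale), `nll`, `aic`, `deviance`, `dof`, `p_value`,
#'   `converged`, `boundary`, `n_starts`, and the data fitted. Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `logLik`, `residuals`,
#'   `simulate`.
#' @examples
#' sim <- simulate_catch(catch_sim_config(n_hauls = 4, fish_per_haul = 500,
#'                                        seed = 7))
#' fit <- fit_selection(sim$data, "logit")
#' coef(fit)
#' @export
fit_selection <- function(data, model = "logit", treatment = NULL,
                          start = NULL, control = list(rel.tol = 1e-10)) {
  spec <- sel_model(model)
  data <- subset_treatment(data, treatment)
  pooled <- pooled_raised(data)
  nll <- make_nll(data, spec)
  obj <- function(theta) {
    v <- nll(params_from_theta(spec, theta))
    if (!is.finite(v)) 1e300 else v
  }
  starts <- if (is.null(start)) {
    default_starts(data, spec)
  } else if (is.list(start)) start else list(start)

  best <- NULL
  n_ok <- 0L
  for (s in starts) {
    th0 <- tryCatch(theta_from_params(spec, s), error = function(e) NULL)
    if (is.null(th0) || any(!is.finite(th0))) next
    opt <- tryCatch(stats::nlminb(th0, obj, control = control),
                    error = function(e) NULL)
    if (is.null(opt) || any(!is.finite(opt$par))) next
    if (opt$convergence == 0) n_ok <- n_ok + 1L
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }

  if (is.null(best)) {
    fit <- structure(list(model = spec, par = NULL, nll = Inf, aic = Inf,
                          deviance = NA_real_, dof = NA_integer_,
                          p_value = NA_real_, converged = FALSE,
                          boundary = NA, n_starts = length(starts),
                          data = data, call = match.call()),
                     class = "sel_fit")
    return(fit)
  }

  par <- params_from_theta(spec, best$par)
  converged <- n_ok > 0 && is.finite(best$objective)
  # boundary diagnosis: fitted curve flat against the occupied classes
  occ <- pooled$length[pooled$raised_codend + pooled$raised_cover > 0]
  rhat <- retention(spec, par, occ)
  boundary <- all(rhat < 0.05) || all(rhat > 0.95)

  fit <- structure(list(model = spec, par = par, nll = best$objective,
                        aic = 2 * spec$k + 2 * best$objective,
                        deviance = NA_real_, dof = NA_integer_,
                        p_value = NA_real_, converged = converged,
                        boundary = boundary, n_starts = length(starts),
                        data = data, call = match.call()),
                   class = "sel_fit")
  gof <- goodness_of_fit(fit)
  fit$deviance <- gof$deviance
  fit$dof <- gof$dof
  fit$p_value <- gof$p_value
  fit
}

#' Deviance goodness of fit for a fitted selection curve
#'
#' Deviance of the haul-pooled raised counts per length class against the
#' fitted retention curve (twice the saturated-minus-model log-likelihood,
#' with the saturated model at the observed raised proportion per class),
#' with degrees of freedom equal to the number of occupied length classes
#' minus the number of model parameters, and an upper-tail chi-square
#' p-value. A p-value above 0.05 is conventionally read as an adequate fit;
#' below, residuals should be inspected since small haul numbers commonly
#' produce overdispersion rather than structural misfit.
#'
#' @param fit a `"sel_fit"` object.
#' @return List with `deviance`, `dof` (NA if not assessable), `p_value`,
#'   and `dispersion` (deviance/dof).
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "sel_fit"))
  if (!fit$converged || is.null(fit$par)) {
    return(list(deviance = NA_real_, dof = NA_integer_, p_value = NA_real_,
                dispersion = NA_real_))
  }
  pooled <- pooled_raised(fit$data)
  NR <- pooled$raised_codend
  NE <- pooled$raised_cover
  N <- NR + NE
  occ <- N > 0
  eps <- 1e-12
  r <- pmin(pmax(retention(fit$model, fit$par, pooled$length), eps), 1 - eps)
  dev_terms <- numeric(length(N))
  i <- occ & NR > 0
  dev_terms[i] <- dev_terms[i] + NR[i] * log(NR[i] / (N[i] * r[i]))
  i <- occ & NE > 0
  dev_terms[i] <- dev_terms[i] + NE[i] * log(NE[i] / (N[i] * (1 - r[i])))
  deviance <- 2 * sum(dev_terms)
  dof <- sum(occ) - fit$model$k
  if (dof <= 0) {
    return(list(deviance = deviance, dof = NA_integer_, p_value = NA_real_,
                dispersion = NA_real_))
  }
  list(deviance = deviance, dof = dof,
       p_value = stats::pchisq(deviance, dof, lower.tail = FALSE),
       dispersion = deviance / dof)
}

#' Fit several selection models and rank them by AIC
#'
#' Fits each requested family with [fit_selection()] and ranks the
#' converged fits by AIC (`2k + 2 * negative log-likelihood`); the
#' lowest-AIC model is the selected one.
#'
#' @inheritParams fit_selection
#' @param models character vector of model names (default: all eight).
#' @return An object of class `"sel_fit_list"`: a named list of `sel_fit`
#'   objects with an `aic_table` attribute. Use [select_model()] to extract
#'   the best fit.
#' @export
fit_selection_all <- function(data, models = sel_models(), treatment = NULL,
                              control = list(rel.tol = 1e-10)) {
  fits <- lapply(models, function(m) {
    fit_selection(data, model = m, treatment = treatment, control = control)
  })
  names(fits) <- models
  structure(fits, class = "sel_fit_list")
}

#' Select the best fit by lowest AIC
#'
#' @param fits a `"sel_fit_list"` (or plain list of `sel_fit` objects).
#' @return The converged fit with the lowest AIC; errors if none converged.
#' @export
select_model <- function(fits) {
  fits <- Filter(function(f) inherits(f, "sel_fit") && f$converged, fits)
  if (!length(fits)) stop("no converged fits to select from", call. = FALSE)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  fits[[which.min(aics)]]
}

#' AIC ranking table for a set of fitted selection models
#'
#' @param fits a `"sel_fit_list"`.
#' @return data.frame with one row per model: `model`, `k`, `nll`, `aic`,
#'   `delta_aic`, `deviance`, `dof`, `p_value`, `converged`, sorted by AIC.
#' @export
aic_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(model = f$model$name, k = f$model$k, nll = f$nll, aic = f$aic,
               deviance = f$deviance, dof = f$dof, p_value = f$p_value,
               converged = f$converged)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - min(tab$aic[tab$converged], na.rm = TRUE)
  rownames(tab) <- NULL
  tab[c("model", "k", "nll", "aic", "delta_aic", "deviance", "dof",
        "p_value", "converged")]
}

#' @export
print.sel_fit_list <- function(x, digits = 4, ...) {
  cat("Selection model comparison (", length(x), " fits)\n", sep = "")
  print(aic_table(x), digits = digits)
  invisible(x)
}
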