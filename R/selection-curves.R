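#' Codend selection-curve families
#'
#' Eight retention-probability models are available: the four classical
#' sigmoid families, which assume every fish entering the codend contacts
#' the meshes in a way that gives it a length-dependent chance of escape,
#'
#' * `"logit"`, `"probit"`, `"gompertz"` -- two parameters (L50, SR),
#' * `"richard"` -- three parameters (L50, SR, 1/delta asymmetry),
#'
#' and their contact-probability mixtures `"clogit"`, `"cprobit"`,
#' `"cgompertz"`, `"crichard"`, which add a length-independent contact
#' probability `C` in (0, 1]:
#' `r(l) = 1 - C + C * base(l)`. Fish that never make selective contact
#' with the meshes are retained, so the mixture curve has a floor of
#' `1 - C`; for contact variants (L50, SR) are the contact-conditional
#' `L50c`, `SRc` of the base curve.
#'
#' All base curves are parameterised directly by L50 (length at 50%
#' retention, cm) and SR (selection range = L75 - L25, cm), so that
#' `base(L50) = 0.5` and the 0.25/0.75 quantiles are exactly SR apart. The
#' Richards family is the exponentiated logistic
#' `plogis(a + b*l)^(1/delta)` with (a, b) solved from the quantile
#' function `X(p) = log(p^delta / (1 - p^delta))`; at `1/delta = 1` it
#' reduces to the logistic.
#'
#' @param model a model name (one of the eight above, case-insensitive).
#' @return `sel_model()` returns a list with elements `name`, `family`,
#'   `contact` (logical), `k` (number of parameters) and `par_names`.
#' @examples
#' m <- sel_model("clogit")
#' retention(m, c(L50 = 22, SR = 4, C = 0.6), 18:30)
#' @export
sel_model <- function(model) {
  if (is.list(model) && !is.null(model$family)) return(model)
  name <- tolower(model)
  families <- c("logit", "probit", "gompertz", "richard")
  all_names <- c(families, paste0("c", families))
  if (!name %in% all_names) {
    stop("unknown selection model: ", model, " (expected one of ",
         paste(all_names, collapse = ", "), ")", call. = FALSE)
  }
  contact <- name %in% paste0("c", families)
  family <- if (contact) substr(name, 2, nchar(name)) else name
  par_names <- c("L50", "SR",
                 if (family == "richard") "inv_delta",
                 if (contact) "C")
  list(name = name, family = family, contact = contact,
       k = length(par_names), par_names = par_names)
}

#' All eight selection model names
#' @return Character vector of the eight model names.
#' @export
sel_models <- function() {
  c("logit", "probit", "gompertz", "richard",
    "clogit", "cprobit", "cgompertz", "crichard")
}

validate_params <- function(spec, params) {
  spec <- sel_model(spec)
  miss <- setdiff(spec$par_names, names(params))
  if (length(miss)) {
    stop("parameter error: missing parameter(s) ",
         paste(miss, collapse = ", "), " for model ", spec$name,
         call. = FALSE)
  }
  if (!is.finite(params[["SR"]]) || params[["SR"]] <= 0) {
    stop("parameter error: SR must be > 0", call. = FALSE)
  }
  if (spec$family == "richard" &&
      (!is.finite(params[["inv_delta"]]) || params[["inv_delta"]] <= 0)) {
    stop("parameter error: 1/delta must be > 0", call. = FALSE)
  }
  if (spec$contact) {
    C <- params[["C"]]
    if (!is.finite(C) || C <= 0 || C > 1) {
      stop("parameter error: C must lie in (0, 1]", call. = FALSE)
    }
  }
  invisible(params)
}

# Richards quantile function X(p) = log(p^delta / (1 - p^delta)),
# delta = 1 / inv_delta
richard_X <- function(p, inv_delta) {
  delta <- 1 / inv_delta
  delta * log(p) - log1p(-p^delta)
}

base_retention <- function(family, params, l) {
  L50 <- params[["L50"]]
  SR <- params[["SR"]]
  switch(family,
    logit = stats::plogis((l - L50) * (2 * log(3) / SR)),
    probit = stats::pnorm((l - L50) / (SR / (2 * stats::qnorm(0.75)))),
    gompertz = {
      s <- SR / (log(-log(0.25)) - log(-log(0.75)))
      m <- L50 + s * log(log(2))
      exp(-exp(-(l - m) / s))
    },
    richard = {
      inv_delta <- params[["inv_delta"]]
      b <- (richard_X(0.75, inv_delta) - richard_X(0.25, inv_delta)) / SR
      a <- richard_X(0.5, inv_delta) - b * L50
      stats::plogis(a + b * l)^inv_delta
    },
    stop("unknown family: ", family, call. = FALSE))
}

base_quantile <- function(family, params, p) {
  L50 <- params[["L50"]]
  SR <- params[["SR"]]
  switch(family,
    logit = L50 + stats::qlogis(p) / (2 * log(3) / SR),
    probit = L50 + stats::qnorm(p) * (SR / (2 * stats::qnorm(0.75))),
    gompertz = {
      s <- SR / (log(-log(0.25)) - log(-log(0.75)))
      m <- L50 + s * log(log(2))
      m - s * log(-log(p))
    },
    richard = {
      inv_delta <- params[["inv_delta"]]
      b <- (richard_X(0.75, inv_delta) - richard_X(0.25, inv_delta)) / SR
      a <- richard_X(0.5, inv_delta) - b * L50
      (richard_X(p, inv_delta) - a) / b
    })
}

#' Retention probability at length
#'
#' Evaluates a selection curve: the probability that a fish of length `l`
#' entering the codend is retained (does not escape into the cover).
#' Contact variants return `1 - C + C * base(l)`.
#'
#' @param spec model name or [sel_model()] object.
#' @param params named parameter vector (`L50`, `SR`, and `inv_delta` /
#'   `C` where the model uses them).
#' @param l numeric vector of lengths (cm).
#' @return Vector of retention probabilities in \[0, 1\].
#' @export
retention <- function(spec, params, l) {
  spec <- sel_model(spec)
  validate_params(spec, params)
  base <- base_retention(spec$family, params, l)
  if (spec$contact) 1 - params[["C"]] + params[["C"]] * base else base
}

#' Length at a given retention probability
#'
#' Inverse of [retention()]. For classical families,
#' `quantile_length(spec, params, 0.5)` is L50 and the 0.75/0.25 quantiles
#' differ by SR. For a contact model the curve never drops below `1 - C`,
#' so probabilities at or below that floor are unattainable and raise an
#' error -- this is the situation in which an overall L50 or SR "is not
#' reached" and only the contact-conditional values can be reported.
#'
#' @inheritParams retention
#' @param p retention probability, strictly between the curve's infimum
#'   (`1 - C` for contact variants, 0 otherwise) and 1.
#' @return Length (cm) at which the curve crosses `p`.
#' @export
quantile_length <- function(spec, params, p) {
  spec <- sel_model(spec)
  validate_params(spec, params)
  if (any(p >= 1) || any(p <= 0)) {
    stop("domain error: p must lie strictly in (0, 1)", call. = FALSE)
  }
  if (spec$contact) {
    C <- params[["C"]]
    pb <- (p - (1 - C)) / C
    if (any(pb <= 0)) {
      stop("domain error: retention ", paste(p[pb <= 0], collapse = ", "),
           " is not reached; the curve's floor is 1 - C = ", 1 - C,
           call. = FALSE)
    }
    p <- pb
  }
  base_quantile(spec$family, params, p)
}

# overall L50/SR of a (possibly contact) curve; NA where unreachable
overall_l50_sr <- function(spec, params) {
  spec <- sel_model(spec)
  floor_ <- if (spec$contact) 1 - params[["C"]] else 0
  l50 <- if (floor_ < 0.5) quantile_length(spec, params, 0.5) else NA_real_
  sr <- if (floor_ < 0.25) {
    quantile_length(spec, params, 0.75) - quantile_length(spec, params, 0.25)
  } else NA_real_
  c(L50_overall = l50, SR_overall = sr)
}
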