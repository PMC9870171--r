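#' Double bootstrap of a fitted selection curve
#'
#' Each replicate resamples the hauls with replacement (outer stage,
#' between-haul variation) and then, within every selected haul, resamples
#' its measured fish with replacement separately per compartment while
#' keeping the subsampling ratios fixed (inner stage, within-haul
#' variation); the model is then refitted. Inner resampling acts on
#' measured fish (later raised by 1/q), so subsampling noise propagates
#' into the intervals. Refits start from the point estimate and fall back
#' to the full multi-start grid; a replicate that still fails is redrawn
#' (up to 10 times) so the population size stays exactly `n_boot`.
#'
#' @param fit a converged `"sel_fit"` object.
#' @param n_boot number of bootstrap replicates (the reference analysis
#'   uses 1000).
#' @param seed integer seed; the whole population is reproducible from it.
#' @param grid length grid (cm) on which replicate curves are stored;
#'   default 0.1-cm steps over the observed range widened by 2 cm.
#' @return An object of class `"sel_boot"`: list with `params` (n_boot x k
#'   matrix), `curves` (n_boot x length(grid) matrix), `grid`, `fit`,
#'   `n_boot`, `seed`, and `failures` (replicate ids that needed redraws).
#' @seealso [efron_ci()], [delta_curve()]
#' @export
boot_selection <- function(fit, n_boot = 1000, seed, grid = NULL) {
  stopifnot(inherits(fit, "sel_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit",
                           call. = FALSE)
  if (missing(seed)) stop("a seed is required for the bootstrap",
                          call. = FALSE)
  data <- fit$data
  if (is.null(grid)) grid <- default_length_grid(data)
  spec <- fit$model
  k <- spec$k
  params <- matrix(NA_real_, n_boot, k,
                   dimnames = list(NULL, spec$par_names))
  curves <- matrix(NA_real_, n_boot, length(grid))
  failures <- integer(0)
  set.seed(seed)
  m <- nrow(data$hauls)
  if (n_boot > 0 && m < 1) stop("bootstrap needs at least one haul",
                                call. = FALSE)
  i <- 1L
  while (i <= n_boot) {
    ok <- FALSE
    for (attempt in seq_len(10L)) {
      bdata <- resample_dataset(data)
      bfit <- fit_selection(bdata, spec, start = fit$par)
      if (!bfit$converged) bfit <- fit_selection(bdata, spec)
      if (bfit$converged) {
        params[i, ] <- bfit$par[spec$par_names]
        curves[i, ] <- retention(spec, bfit$par, grid)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("bootstrap replicate ", i, " failed to converge after 10 redraws",
           call. = FALSE)
    }
    if (attempt > 1L) failures <- c(failures, i)
    i <- i + 1L
  }
  if (length(failures) > 0.05 * n_boot) {
    warning("more than 5% of bootstrap replicates needed redraws",
            call. = FALSE)
  }
  structure(list(params = params, curves = curves, grid = grid, fit = fit,
                 n_boot = n_boot, seed = seed, failures = failures),
            class = "sel_boot")
}

# one double-bootstrap dataset: outer hauls, inner fish-per-compartment
resample_dataset <- function(data) {
  m <- nrow(data$hauls)
  pick <- sample.int(m, m, replace = TRUE)
  classes <- sort(unique(data$counts$length))
  counts_list <- vector("list", m)
  hauls <- data$hauls[pick, , drop = FALSE]
  hauls$haul_id <- paste0("b", seq_len(m))
  for (j in seq_len(m)) {
    h <- data$hauls$haul_id[pick[j]]
    cc <- data$counts[data$counts$haul_id == h, , drop = FALSE]
    cc <- cc[match(classes, cc$length), ]
    nR <- resample_counts(cc$n_codend)
    nE <- resample_counts(cc$n_cover)
    counts_list[[j]] <- data.frame(haul_id = paste0("b", j),
                                   length = classes,
                                   n_codend = nR, n_cover = nE)
  }
  rownames(hauls) <- NULL
  # counts are complete and ordered by construction; skip revalidation
  structure(list(counts = do.call(rbind, counts_list), hauls = hauls),
            class = "catch_data")
}

# resample n = sum(x) fish with replacement from the empirical length
# distribution x over the classes
resample_counts <- function(x) {
  n <- sum(x)
  if (n == 0) return(integer(length(x)))
  as.integer(stats::rmultinom(1, n, x / n))
}

#' @export
print.sel_boot <- function(x, ...) {
  cat("Double-bootstrap population:", x$n_boot, "replicates of",
      x$fit$model$name, "( seed", x$seed, ")\n")
  cat("  grid:", length(x$grid), "points,", min(x$grid), "-", max(x$grid),
      "cm;", length(x$failures), "replicate(s) redrawn\n")
  invisible(x)
}

#' Efron percentile confidence intervals from a bootstrap population
#'
#' Takes the empirical `(1 - level)/2` and `(1 + level)/2` percentiles of
#' the bootstrap population, per length-grid point for the retention curve
#' and per parameter, with no bias correction or studentisation.
#'
#' @param pop a `"sel_boot"` object.
#' @param level confidence level (default 0.95).
#' @return An object of class `"sel_boot_ci"`: list with `curve`
#'   (data.frame `length`, `estimate`, `lower`, `upper`), `params`
#'   (data.frame `parameter`, `estimate`, `lower`, `upper`) and `level`.
#' @export
efron_ci <- function(pop, level = 0.95) {
  stopifnot(inherits(pop, "sel_boot"))
  if (pop$n_boot < 1) stop("empty bootstrap population", call. = FALSE)
  probs <- c((1 - level) / 2, (1 + level) / 2)
  cb <- apply(pop$curves, 2, boot_percentile, probs = probs)
  pb <- apply(pop$params, 2, boot_percentile, probs = probs)
  fit <- pop$fit
  curve <- data.frame(length = pop$grid,
                      estimate = retention(fit$model, fit$par, pop$grid),
                      lower = cb[1, ], upper = cb[2, ])
  params <- data.frame(parameter = colnames(pop$params),
                       estimate = as.numeric(fit$par[colnames(pop$params)]),
                       lower = pb[1, ], upper = pb[2, ])
  rownames(params) <- NULL
  structure(list(curve = curve, params = params, level = level),
            class = "sel_boot_ci")
}

#' @export
print.sel_boot_ci <- function(x, digits = 3, ...) {
  cat(sprintf("Efron percentile intervals (level %.2f)\n", x$level))
  tab <- x$params
  tab$estimate <- round(tab$estimate, digits)
  tab$lower <- round(tab$lower, digits)
  tab$upper <- round(tab$upper, digits)
  print(tab)
  invisible(x)
}

# Efron percentile: k-th order statistic with k = ceiling(n * p), guarded
# against floating-point excess in n * p
boot_percentile <- function(x, probs) {
  s <- sort(x)
  n <- length(x)
  k <- pmin(n, pmax(1L, as.integer(ceiling(n * probs - 1e-9))))
  s[k]
}

#' Delta selectivity curve between two gears
#'
#' Pointwise difference `delta(l) = r_e(l) - r_c(l)` between an
#' experimental and a control gear's retention curves, with confidence
#' intervals built by pairing replicate i of the experimental bootstrap
#' population with replicate i of the control population (valid because
#' the two populations were generated independently) and taking Efron
#' percentiles of the paired differences. A length is flagged significant
#' where the interval excludes 0. Pairing differences this way gives
#' intervals that can be no wider than the two marginal intervals
#' combined, which is what lends the comparison its power.
#'
#' @param pop_e bootstrap population (`"sel_boot"`) of the experimental
#'   gear.
#' @param pop_c bootstrap population of the control gear; must share the
#'   length grid and replicate count of `pop_e`.
#' @param level confidence level (default 0.95).
#' @return An object of class `"sel_delta"`: list with `curve` (data.frame
#'   `length`, `delta` from the two point fits, `lower`, `upper`,
#'   `significant`), `significant_ranges` (data.frame `from`, `to` in cm),
#'   and `level`.
#' @export
delta_curve <- function(pop_e, pop_c, level = 0.95) {
  stopifnot(inherits(pop_e, "sel_boot"), inherits(pop_c, "sel_boot"))
  if (pop_e$n_boot != pop_c$n_boot) {
    stop("bootstrap populations have unequal replicate counts",
         call. = FALSE)
  }
  if (length(pop_e$grid) != length(pop_c$grid) ||
      any(abs(pop_e$grid - pop_c$grid) > 1e-9)) {
    stop("bootstrap populations are on different length grids",
         call. = FALSE)
  }
  if (pop_e$n_boot < 1) stop("empty bootstrap population", call. = FALSE)
  grid <- pop_e$grid
  diffs <- pop_e$curves - pop_c$curves
  probs <- c((1 - level) / 2, (1 + level) / 2)
  qs <- apply(diffs, 2, boot_percentile, probs = probs)
  delta <- retention(pop_e$fit$model, pop_e$fit$par, grid) -
    retention(pop_c$fit$model, pop_c$fit$par, grid)
  sig <- qs[1, ] > 0 | qs[2, ] < 0
  curve <- data.frame(length = grid, delta = delta, lower = qs[1, ],
                      upper = qs[2, ], significant = sig)
  structure(list(curve = curve, significant_ranges = sig_ranges(grid, sig),
                 level = level),
            class = "sel_delta")
}

# maximal runs of consecutive significant grid points, as cm intervals
sig_ranges <- function(grid, sig) {
  if (!any(sig)) {
    return(data.frame(from = numeric(0), to = numeric(0)))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(from = grid[starts[keep]], to = grid[ends[keep]])
}

#' @export
print.sel_delta <- function(x, digits = 3, ...) {
  cat(sprintf("Delta selectivity curve (level %.2f), %d grid points\n",
              x$level, nrow(x$curve)))
  if (nrow(x$significant_ranges) == 0) {
    cat("  no lengths with a significant retention difference\n")
  } else {
    cat("  significant retention differences over:\n")
    for (i in seq_len(nrow(x$significant_ranges))) {
      cat(sprintf("    %.1f - %.1f cm\n", x$significant_ranges$from[i],
                  x$significant_ranges$to[i]))
    }
  }
  invisible(x)
}

#' Plot a delta selectivity curve with its confidence band
#'
#' @param x a `"sel_delta"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sel_delta <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$length, cv$delta, type = "l",
                 ylim = range(c(cv$lower, cv$upper, 0)),
                 xlab = "Length (cm)", ylab = expression(Delta * r(l)),
                 main = "Delta selectivity curve", ...)
  graphics::lines(cv$length, cv$lower, lty = 2, col = "grey40")
  graphics::lines(cv$length, cv$upper, lty = 2, col = "grey40")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
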