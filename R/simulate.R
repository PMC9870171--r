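#' Configuration for a synthetic covered-codend catch experiment
#'
#' Defines the ground truth of a simulated sea trial. The defaults emulate
#' the study population and design: a unimodal redfish length distribution
#' (discretised normal, mean 22.7 cm, SD 3.5 cm, truncated to 13-40 cm and
#' binned at 1 cm), a logistic selection curve with L50 = 20 cm and
#' SR = 4 cm, and 10 hauls of (on average) 2000 fish entering the codend.
#' Between-haul variation enters as Gaussian jitter on the haul L50, and
#' compartment subsampling as binomial thinning of the true counts by
#' ratios drawn from `q_codend` / `q_cover`.
#'
#' @param model selection model name ([sel_models()]).
#' @param params named true parameter vector for `model`.
#' @param n_hauls number of hauls.
#' @param fish_per_haul mean number of fish entering the codend per haul.
#' @param fish_dispersion NULL for exactly `fish_per_haul` fish per haul,
#'   or a negative-binomial size parameter for overdispersed entry counts.
#' @param length_mean,length_sd,length_range parameters of the discretised
#'   truncated-normal length distribution (cm).
#' @param haul_l50_sd SD of between-haul L50 jitter (cm; 0 disables it).
#' @param q_codend,q_cover subsampling ratio per compartment: a scalar in
#'   (0, 1] used for every haul, or a length-2 range from which each
#'   haul's ratio is drawn uniformly.
#' @param seed master integer seed; fans out to per-haul substreams.
#' @return A list of class `"catch_sim_config"`.
#' @export
catch_sim_config <- function(model = "logit", params = c(L50 = 20, SR = 4),
                             n_hauls = 10, fish_per_haul = 2000,
                             fish_dispersion = NULL, length_mean = 22.7,
                             length_sd = 3.5, length_range = c(13, 40),
                             haul_l50_sd = 0, q_codend = 1, q_cover = 1,
                             seed = 1) {
  spec <- sel_model(model)
  validate_params(spec, params)
  stopifnot(n_hauls >= 1, fish_per_haul > 0, length_sd > 0,
            length_range[1] < length_range[2], haul_l50_sd >= 0)
  for (q in list(q_codend, q_cover)) {
    if (!length(q) %in% 1:2 || any(q <= 0) || any(q > 1)) {
      stop("subsampling ratios must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(model = spec, params = params, n_hauls = n_hauls,
                 fish_per_haul = fish_per_haul,
                 fish_dispersion = fish_dispersion,
                 length_mean = length_mean, length_sd = length_sd,
                 length_range = length_range, haul_l50_sd = haul_l50_sd,
                 q_codend = q_codend, q_cover = q_cover, seed = seed),
            class = "catch_sim_config")
}

draw_q <- function(q) if (length(q) == 2) stats::runif(1, q[1], q[2]) else q

#' Simulate a covered-codend catch dataset with known truth
#'
#' Per haul: the haul L50 is the true L50 plus Gaussian jitter; fish
#' lengths are drawn from the discretised truncated-normal distribution;
#' each fish is retained in the codend or escapes into the cover according
#' to the haul's selection curve. For contact models the two-stage
#' mechanism is simulated explicitly: each fish makes selective mesh
#' contact with probability C, non-contacted fish are retained (they never
#' reach the meshes in a way that permits escape -- this is what puts the
#' floor 1 - C under the retention curve), and contacted fish are retained
#' with the base-curve probability. Finally each compartment's true count
#' is thinned binomially by its subsampling ratio to give the measured
#' counts.
#'
#' @param config a [catch_sim_config()].
#' @return List with `data` (a [catch_data]; measured counts) and `truth`
#'   (list: `model`, `params`, `haul_l50` per haul, `true_counts`
#'   data.frame of unthinned codend/cover counts, and the `config`).
#' @export
simulate_catch <- function(config) {
  stopifnot(inherits(config, "catch_sim_config"))
  spec <- config$model
  classes <- seq(ceiling(config$length_range[1]),
                 floor(config$length_range[2]))
  pl <- stats::dnorm(classes, config$length_mean, config$length_sd)
  pl <- pl / sum(pl)

  set.seed(config$seed)
  haul_seeds <- sample.int(.Machine$integer.max - 1, config$n_hauls)

  counts_list <- vector("list", config$n_hauls)
  hauls_list <- vector("list", config$n_hauls)
  haul_l50 <- numeric(config$n_hauls)
  for (j in seq_len(config$n_hauls)) {
    set.seed(haul_seeds[j])
    id <- paste0("h", j)
    n_fish <- if (is.null(config$fish_dispersion)) {
      round(config$fish_per_haul)
    } else {
      stats::rnbinom(1, size = config$fish_dispersion,
                     mu = config$fish_per_haul)
    }
    pj <- config$params
    pj[["L50"]] <- pj[["L50"]] + stats::rnorm(1, 0, config$haul_l50_sd)
    haul_l50[j] <- pj[["L50"]]
    n_l <- as.integer(stats::rmultinom(1, n_fish, pl))
    base <- base_retention(spec$family, pj, classes)
    if (spec$contact) {
      n_contact <- stats::rbinom(length(classes), n_l, pj[["C"]])
      retained <- (n_l - n_contact) +
        stats::rbinom(length(classes), n_contact, base)
    } else {
      retained <- stats::rbinom(length(classes), n_l, base)
    }
    escaped <- n_l - retained
    qR <- draw_q(config$q_codend)
    qE <- draw_q(config$q_cover)
    counts_list[[j]] <- data.frame(haul_id = id, length = classes,
                                   n_codend_true = retained,
                                   n_cover_true = escaped,
                                   n_codend = stats::rbinom(length(classes),
                                                            retained, qR),
                                   n_cover = stats::rbinom(length(classes),
                                                           escaped, qE))
    hauls_list[[j]] <- data.frame(haul_id = id, treatment = "simulated",
                                  q_codend = qR, q_cover = qE)
  }
  all_counts <- do.call(rbind, counts_list)
  data <- catch_data(all_counts[c("haul_id", "length", "n_codend",
                                  "n_cover")],
                     do.call(rbind, hauls_list))
  list(data = data,
       truth = list(model = spec, params = config$params,
                    haul_l50 = haul_l50,
                    true_counts = all_counts[c("haul_id", "length",
                                               "n_codend_true",
                                               "n_cover_true")],
                    config = config))
}

#' Configuration for a synthetic depth trace
#'
#' Ground truth for a 1-Hz depth record of an oscillating codend:
#' `depth(t) = base_depth + drift * t + amplitude * sin(2 pi t / period) +
#' Gaussian noise`. The defaults emulate the at-sea shaking regime: a
#' 0.125-m half-amplitude (peak-to-peak 25 cm, amplitude ratio about 0.25
#' against the 99.6-cm panel), a 9.2-s period, and centimetre-scale sensor
#' noise at 300 m fishing depth.
#'
#' @param amplitude sine half-amplitude (m).
#' @param period oscillation period (s); must exceed 2 sampling intervals.
#' @param depth_drift linear depth drift (m s^-1).
#' @param noise_sd Gaussian noise SD (m).
#' @param duration record length (s); at least 3 periods.
#' @param base_depth mean depth at t = 0 (m).
#' @param seed integer seed.
#' @return A list of class `"motion_sim_config"`.
#' @export
motion_sim_config <- function(amplitude = 0.125, period = 9.2,
                              depth_drift = 0, noise_sd = 0.01,
                              duration = 600, base_depth = 300, seed = 1) {
  stopifnot(amplitude >= 0, noise_sd >= 0)
  if (period <= 2) stop("period must exceed 2 sampling intervals (2 s)",
                        call. = FALSE)
  if (duration < 3 * period) stop("duration must cover at least 3 periods",
                                  call. = FALSE)
  structure(list(amplitude = amplitude, period = period,
                 depth_drift = depth_drift, noise_sd = noise_sd,
                 duration = duration, base_depth = base_depth, seed = seed),
            class = "motion_sim_config")
}

#' Simulate a 1-Hz depth trace with known truth
#'
#' @param config a [motion_sim_config()].
#' @return List with `series` (a [sensor_series] with column `depth`) and
#'   `truth` (the config, holding amplitude, period and drift).
#' @export
simulate_depth <- function(config) {
  stopifnot(inherits(config, "motion_sim_config"))
  set.seed(config$seed)
  t <- seq(0, config$duration, by = 1)
  depth <- config$base_depth + config$depth_drift * t +
    config$amplitude * sin(2 * pi * t / config$period) +
    stats::rnorm(length(t), 0, config$noise_sd)
  list(series = sensor_series(t, depth = depth), truth = config)
}
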