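# Small fixtures built in code.

# a minimal valid two-haul dataset spanning retained and escaped fish
tiny_catch <- function() {
  counts <- data.frame(
    haul_id = rep(c("a", "b"), each = 5),
    length = rep(16:20, 2),
    n_codend = c(1, 3, 8, 15, 20, 2, 4, 9, 14, 18),
    n_cover = c(19, 15, 10, 5, 2, 17, 13, 9, 4, 1))
  hauls <- data.frame(haul_id = c("a", "b"), treatment = "test",
                      q_codend = c(1, 0.5), q_cover = c(0.8, 1))
  catch_data(counts, hauls)
}

# the printed sea-trials operations table (per-haul measurement counts,
# subsampling ratios and metadata); per-length-class data are unpublished,
# so for container-level bookkeeping each haul's totals are placed in two
# synthetic length bins -- only totals and metadata are ever consumed
operations_catch <- function() {
  ops <- utils::read.csv(system.file("extdata",
                                     "sea_trials_operations.csv",
                                     package = "codendsel"))
  counts <- rbind(
    data.frame(haul_id = ops$haul_id, length = 18, n_codend = 0,
               n_cover = ops$n_cover),
    data.frame(haul_id = ops$haul_id, length = 25, n_codend = ops$n_codend,
               n_cover = 0))
  hauls <- data.frame(haul_id = ops$haul_id, treatment = ops$codend,
                      q_codend = ops$q_codend, q_cover = ops$q_cover,
                      duration_min = ops$duration_min,
                      depth_m = ops$max_depth_m, speed_kt = ops$speed_kt,
                      date = ops$date)
  catch_data(counts, hauls)
}

# independent brute-force objective: explicit double loop over hauls and
# classes, no shared code with the package implementation; applies the
# same retention clipping contract (r in [1e-12, 1 - 1e-12])
brute_force_nll <- function(data, r_fun) {
  total <- 0
  for (j in seq_len(nrow(data$hauls))) {
    h <- data$hauls[j, ]
    cc <- data$counts[data$counts$haul_id == h$haul_id, ]
    for (i in seq_len(nrow(cc))) {
      r <- min(max(r_fun(cc$length[i]), 1e-12), 1 - 1e-12)
      if (cc$n_codend[i] > 0) {
        total <- total + cc$n_codend[i] / h$q_codend * log(r)
      }
      if (cc$n_cover[i] > 0) {
        total <- total + cc$n_cover[i] / h$q_cover * log(1 - r)
      }
    }
  }
  -total
}

# random small covered-codend dataset for oracle checks
random_tiny_dataset <- function() {
  m <- sample(1:3, 1)
  classes <- sort(sample(12:40, sample(3:8, 1)))
  counts <- do.call(rbind, lapply(seq_len(m), function(j) {
    data.frame(haul_id = paste0("h", j), length = classes,
               n_codend = rpois(length(classes), 5),
               n_cover = rpois(length(classes), 5))
  }))
  hauls <- data.frame(haul_id = paste0("h", seq_len(m)),
                      treatment = "x",
                      q_codend = runif(m, 0.1, 1),
                      q_cover = runif(m, 0.1, 1))
  if (sum(counts$n_codend) + sum(counts$n_cover) == 0) {
    counts$n_codend[1] <- 1
  }
  catch_data(counts, hauls)
}

random_params <- function(spec) {
  spec <- sel_model(spec)
  p <- c(L50 = runif(1, 15, 30), SR = runif(1, 1, 8))
  if (spec$family == "richard") p <- c(p, inv_delta = runif(1, 0.3, 3))
  if (spec$contact) p <- c(p, C = runif(1, 0.2, 1))
  p
}
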