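#' Covered-codend catch-at-length data
#'
#' Container for a covered-codend size-selectivity experiment: per haul, the
#' number of fish measured per 1-cm length class in the test codend and in the
#' small-mesh cover, together with the compartment subsampling ratios and haul
#' metadata. Length classes are 1-cm bins labelled by their integer midpoint
#' (fish lengths are recorded to the nearest centimetre); the binning
#' convention is fixed package-wide. Subsampling ratios apply at the
#' haul-by-compartment level: a ratio `q` means a fraction `q` of that
#' compartment's catch was measured, so measured counts are raised by `1/q`
#' in the likelihood.
#'
#' @param counts data.frame with columns `haul_id`, `length` (integer cm bin
#'   midpoint), `n_codend`, `n_cover` (non-negative integer counts of fish
#'   measured). Classes absent for a haul are zero-filled across the union of
#'   classes observed in the dataset.
#' @param hauls data.frame with one row per haul: `haul_id`, `treatment`
#'   (gear label, e.g. `"shaking"`, `"T90"`), `q_codend`, `q_cover`
#'   (subsampling ratios in (0, 1]) and optional numeric metadata columns
#'   such as `duration_min`, `depth_m`, `speed_kt`, plus `date`.
#'
#' @return An object of class `"catch_data"`: a list with elements `counts`
#'   (zero-filled, ordered by haul then length) and `hauls`.
#' @seealso [read_catch_table()], [count_measured()], [summarize_meta()],
#'   [fit_selection()]
#' @export
catch_data <- function(counts, hauls) {
  counts <- as.data.frame(counts)
  hauls <- as.data.frame(hauls)
  need_counts <- c("haul_id", "length", "n_codend", "n_cover")
  need_hauls <- c("haul_id", "treatment", "q_codend", "q_cover")
  miss <- setdiff(need_counts, names(counts))
  if (length(miss)) {
    stop("schema error: counts is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(need_hauls, names(hauls))
  if (length(miss)) {
    stop("schema error: hauls is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(hauls$haul_id)) {
    stop("validation error: duplicated haul_id in hauls table", call. = FALSE)
  }
  if (!all(counts$haul_id %in% hauls$haul_id)) {
    stop("validation error: counts reference unknown haul_id", call. = FALSE)
  }
  for (qc in c("q_codend", "q_cover")) {
    q <- hauls[[qc]]
    if (!is.numeric(q) || anyNA(q) || any(q <= 0) || any(q > 1)) {
      stop("validation error: ", qc, " must lie in (0, 1]", call. = FALSE)
    }
  }
  for (nc in c("n_codend", "n_cover")) {
    n <- counts[[nc]]
    if (!is.numeric(n) || anyNA(n) || any(n < 0) ||
        any(abs(n - round(n)) > 1e-8)) {
      stop("validation error: ", nc,
           " must be non-negative integer counts", call. = FALSE)
    }
    counts[[nc]] <- as.integer(round(n))
  }
  l <- counts$length
  if (!is.numeric(l) || anyNA(l) || any(abs(l - round(l)) > 1e-8)) {
    stop("validation error: length must be integer 1-cm bin midpoints",
         call. = FALSE)
  }
  counts$length <- as.integer(round(l))
  if (anyDuplicated(counts[c("haul_id", "length")])) {
    stop("validation error: duplicated haul_id x length row", call. = FALSE)
  }
  if (sum(counts$n_codend) + sum(counts$n_cover) == 0) {
    stop("validation error: dataset holds no measured fish", call. = FALSE)
  }

  # zero-fill every haul across the union of observed classes
  classes <- sort(unique(counts$length))
  full <- expand.grid(length = classes, haul_id = hauls$haul_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full <- merge(full, counts, by = c("haul_id", "length"), all.x = TRUE,
                sort = FALSE)
  full$n_codend[is.na(full$n_codend)] <- 0L
  full$n_cover[is.na(full$n_cover)] <- 0L
  full <- full[order(match(full$haul_id, hauls$haul_id), full$length), ]
  rownames(full) <- NULL

  structure(list(counts = full, hauls = hauls), class = "catch_data")
}

#' @export
print.catch_data <- function(x, ...) {
  tr <- table(x$hauls$treatment)
  cat("Covered-codend catch data:", nrow(x$hauls), "haul(s),",
      length(unique(x$counts$length)), "length classes (",
      min(x$counts$length), "-", max(x$counts$length), "cm )\n")
  for (t in names(tr)) {
    cat(sprintf("  %-12s %d haul(s), %d fish measured\n", t, tr[[t]],
                count_measured(x, t)))
  }
  invisible(x)
}

# canonical long-format column names
.catch_cols <- c(haul_id = "haul_id", treatment = "treatment",
                 length = "length_cm", n_codend = "n_codend",
                 n_cover = "n_cover", q_codend = "q_codend",
                 q_cover = "q_cover")
.meta_cols <- c("duration_min", "depth_m", "speed_kt", "date")

#' Read a covered-codend catch table
#'
#' Reads a long-format CSV with one row per haul-by-length-class and builds a
#' validated [catch_data] object. The default schema expects columns
#' `haul_id, treatment, length_cm, n_codend, n_cover, q_codend, q_cover`;
#' optional metadata columns (`duration_min`, `depth_m`, `speed_kt`, `date`)
#' are carried into the haul table.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector remapping canonical names to
#'   the file's column names, e.g. `c(length = "len", n_codend = "nR")`.
#' @return A [catch_data] object.
#' @export
read_catch_table <- function(path, schema = NULL) {
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("schema error: cannot read catch table: ",
                             conditionMessage(e), call. = FALSE))
  cols <- .catch_cols
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), names(cols))
    if (length(bad)) {
      stop("schema error: unknown schema key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cols[names(schema)] <- schema
  }
  miss <- cols[!cols %in% names(raw)]
  if (length(miss) || nrow(raw) == 0) {
    stop("schema error: catch table is missing column(s): ",
         paste(miss, collapse = ", "),
         if (nrow(raw) == 0) " (file has no data rows)", call. = FALSE)
  }
  counts <- data.frame(haul_id = raw[[cols[["haul_id"]]]],
                       length = raw[[cols[["length"]]]],
                       n_codend = raw[[cols[["n_codend"]]]],
                       n_cover = raw[[cols[["n_cover"]]]])
  haul_cols <- c("treatment", "q_codend", "q_cover")
  hauls <- unique(data.frame(
    haul_id = raw[[cols[["haul_id"]]]],
    treatment = raw[[cols[["treatment"]]]],
    q_codend = raw[[cols[["q_codend"]]]],
    q_cover = raw[[cols[["q_cover"]]]]))
  if (anyDuplicated(hauls$haul_id)) {
    stop("validation error: haul-level fields (treatment, q) differ across ",
         "rows of one haul", call. = FALSE)
  }
  for (mc in intersect(.meta_cols, names(raw))) {
    m <- unique(raw[, c(cols[["haul_id"]], mc)])
    names(m) <- c("haul_id", mc)
    if (anyDuplicated(m$haul_id)) {
      stop("validation error: metadata column ", mc,
           " differs across rows of one haul", call. = FALSE)
    }
    hauls <- merge(hauls, m, by = "haul_id", sort = FALSE)
  }
  rownames(hauls) <- NULL
  catch_data(counts, hauls)
}

#' Write a covered-codend catch table
#'
#' Inverse of [read_catch_table()]: writes the long-format CSV dialect the
#' reader consumes, so that a write/read round trip reproduces counts and
#' subsampling ratios exactly.
#'
#' @param x a [catch_data] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catch_table <- function(x, path) {
  stopifnot(inherits(x, "catch_data"))
  long <- merge(x$counts, x$hauls, by = "haul_id", sort = FALSE)
  long <- long[order(match(long$haul_id, x$hauls$haul_id), long$length), ]
  out <- data.frame(haul_id = long$haul_id, treatment = long$treatment,
                    length_cm = long$length, n_codend = long$n_codend,
                    n_cover = long$n_cover, q_codend = long$q_codend,
                    q_cover = long$q_cover)
  for (mc in intersect(.meta_cols, names(long))) out[[mc]] <- long[[mc]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# restrict a catch_data to one treatment (internal)
subset_treatment <- function(x, treatment) {
  stopifnot(inherits(x, "catch_data"))
  if (is.null(treatment)) return(x)
  keep <- x$hauls$treatment %in% treatment
  if (!any(keep)) {
    stop("unknown treatment label: ", paste(treatment, collapse = ", "),
         call. = FALSE)
  }
  hauls <- x$hauls[keep, , drop = FALSE]
  counts <- x$counts[x$counts$haul_id %in% hauls$haul_id, , drop = FALSE]
  catch_data(counts, hauls)
}

#' Total number of fish measured
#'
#' Sum of codend and cover counts over all hauls and length classes,
#' unraised (i.e. as measured, not divided by the subsampling ratios).
#'
#' @param x a [catch_data] object.
#' @param treatment optional gear label; default sums over all hauls.
#' @return Integer total.
#' @export
count_measured <- function(x, treatment = NULL) {
  x <- subset_treatment(x, treatment)
  sum(x$counts$n_codend) + sum(x$counts$n_cover)
}

#' Summarise a haul metadata field
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and maximum
#' of a numeric per-haul field such as towing duration or haul velocity.
#'
#' @param x a [catch_data] object.
#' @param field name of a numeric column of the haul table.
#' @param treatment optional gear label restricting the hauls summarised.
#' @return Named list with `mean`, `sd` (NA for a single haul), `min`,
#'   `max`, `n`.
#' @export
summarize_meta <- function(x, field, treatment = NULL) {
  x <- subset_treatment(x, treatment)
  if (!field %in% names(x$hauls)) {
    stop("unknown haul metadata field: ", field, call. = FALSE)
  }
  v <- x$hauls[[field]]
  if (!is.numeric(v)) {
    stop("metadata field ", field, " is not numeric", call. = FALSE)
  }
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       min = min(v), max = max(v), n = length(v))
}

# pooled raised counts per length class (internal): sum_j n_jl / q_j
pooled_raised <- function(x) {
  q_codend <- x$hauls$q_codend[match(x$counts$haul_id, x$hauls$haul_id)]
  q_cover <- x$hauls$q_cover[match(x$counts$haul_id, x$hauls$haul_id)]
  rR <- x$counts$n_codend / q_codend
  rE <- x$counts$n_cover / q_cover
  lens <- sort(unique(x$counts$length))
  data.frame(
    length = lens,
    raised_codend = as.numeric(tapply(rR, factor(x$counts$length, lens), sum)),
    raised_cover = as.numeric(tapply(rE, factor(x$counts$length, lens), sum)))
}
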