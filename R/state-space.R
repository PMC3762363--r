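#' Zone legend
#'
#' An ordered set of region-of-interest labels. Zone codes are the integers
#' `1:length(labels)`, matching the convention of numbering arena regions from
#' 1 to Z; all file I/O uses these 1-based codes.
#'
#' @param labels Character vector of unique zone names, length >= 2.
#' @return A character vector of class `"zone_legend"`; codes are implicit as
#'   positions `1:Z`.
#' @examples
#' zone_legend(c("open field", "water", "feeder", "nest"))
#' @export
zone_legend <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) abort_validation("a zone legend needs at least 2 zones")
  if (anyDuplicated(labels)) abort_validation("zone labels must be unique")
  structure(labels, class = "zone_legend")
}

default_legend <- function(n_zones) {
  zone_legend(paste0("zone", seq_len(n_zones)))
}

#' @export
print.zone_legend <- function(x, ...) {
  cat(sprintf("Zone legend (%d zones):\n", length(x)))
  for (i in seq_along(x)) cat(sprintf("  %2d  %s\n", i, x[i]))
  invisible(x)
}

#' Discretized multi-animal occupancy series
#'
#' A time series of joint zone occupancy: one row per time bin, one column per
#' animal, entries the integer zone code (1..Z) of that animal in that bin.
#' Missing values are rejected: tracking gaps are outside the data model and
#' must be resolved upstream.
#'
#' @param states Integer matrix (T x N) of zone codes in `1:n_zones`.
#' @param bin_duration Duration of one time bin, in seconds (> 0).
#' @param n_zones Number of zones Z (>= 2). Defaults to the legend length, or
#'   the maximum observed code.
#' @param animal_ids Optional character vector of N animal identifiers.
#' @param legend Optional [zone_legend()].
#' @return An object of class `"config_series"`.
#' @examples
#' s <- config_series(cbind(c(1, 1, 2), c(2, 2, 2)), bin_duration = 0.24,
#'                    n_zones = 3)
#' s
#' @export
config_series <- function(states, bin_duration = 1, n_zones = NULL,
                          animal_ids = NULL, legend = NULL) {
  states <- as.matrix(states)
  if (!nrow(states)) abort_validation("series must have at least one time bin")
  if (anyNA(states)) abort_validation("series contains missing values; tracking gaps are not supported")
  if (any(states != round(states))) abort_validation("zone codes must be integers")
  storage.mode(states) <- "integer"
  if (is.null(n_zones)) n_zones <- if (!is.null(legend)) length(legend) else max(states)
  n_zones <- as.integer(n_zones)
  if (n_zones < 2L) abort_validation("n_zones must be >= 2")
  if (any(states < 1L) || any(states > n_zones)) {
    bad <- which(states < 1L | states > n_zones, arr.ind = TRUE)[1L, ]
    abort_validation(sprintf("zone code out of range 1..%d at bin %d, animal %d",
                             n_zones, bad[["row"]], bad[["col"]]))
  }
  if (!is.null(legend) && length(legend) != n_zones)
    abort_validation("legend length does not match n_zones")
  if (is.null(animal_ids)) animal_ids <- colnames(states) %||% paste0("m", seq_len(ncol(states)))
  if (length(animal_ids) != ncol(states))
    abort_validation("animal_ids length does not match number of animals")
  if (!(bin_duration > 0)) abort_validation("bin_duration must be > 0")
  colnames(states) <- animal_ids
  structure(list(states = states, bin_duration = as.numeric(bin_duration),
                 n_zones = n_zones, animal_ids = as.character(animal_ids),
                 legend = legend),
            class = "config_series")
}

#' @export
print.config_series <- function(x, ...) {
  cat(sprintf("Occupancy series: %d bins x %d animals, %d zones, bin %.4g s (%.3g h total)\n",
              nrow(x$states), length(x$animal_ids), x$n_zones, x$bin_duration,
              nrow(x$states) * x$bin_duration / 3600))
  cat("  animals:", paste(x$animal_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.config_series <- function(x) dim(x$states)

n_animals <- function(x) UseMethod("n_animals")
#' @export
n_animals.config_series <- function(x) ncol(x$states)

#' Read an occupancy series from delimited text
#'
#' Expects a header row of animal ids, one row per time bin, integer zone
#' codes, comma- or tab-separated (auto-detected). An optional leading column
#' named `time` (seconds) is used to infer the bin duration.
#'
#' @param path Path to the file.
#' @param legend Optional [zone_legend()]; codes are validated against it.
#' @param n_zones Number of zones if no legend is given; defaults to the
#'   maximum observed code.
#' @param bin_duration Bin duration in seconds; overrides any `time` column.
#' @return A [config_series()].
#' @seealso [write_series()]
#' @export
read_series <- function(path, legend = NULL, n_zones = NULL, bin_duration = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort_parse("series file needs a header and at least one data row")
  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  header <- trimws(strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]])
  fields <- strsplit(lines[-1L], sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    abort_parse(sprintf("line %d has %d fields, expected %d", bad + 1L,
                        nf[bad], length(header)))
  }
  m <- matrix(trimws(unlist(fields)), nrow = length(fields), byrow = TRUE)
  has_time <- tolower(header[1L]) %in% c("time", "t", "seconds", "time_s")
  times <- NULL
  if (has_time) {
    times <- suppressWarnings(as.numeric(m[, 1L]))
    if (anyNA(times)) abort_parse("non-numeric value in time column")
    m <- m[, -1L, drop = FALSE]
    header <- header[-1L]
  }
  codes <- suppressWarnings(as.integer(m))
  if (anyNA(codes) || any(codes != suppressWarnings(as.numeric(m)))) {
    bad <- which(is.na(suppressWarnings(as.integer(m))), arr.ind = TRUE)
    row <- if (length(bad)) bad[1L] else 1L
    abort_parse(sprintf("non-integer zone code at data line %d", ((row - 1L) %% nrow(m)) + 1L))
  }
  states <- matrix(codes, nrow = nrow(m))
  if (is.null(bin_duration)) {
    bin_duration <- if (!is.null(times) && length(times) > 1L) stats::median(diff(times)) else 1
  }
  config_series(states, bin_duration = bin_duration,
                n_zones = n_zones %||% (if (!is.null(legend)) length(legend) else NULL),
                animal_ids = header, legend = legend)
}

#' Write an occupancy series to delimited text
#'
#' @param series A [config_series()].
#' @param path Output path.
#' @param sep Field separator, `","` or `"\t"`.
#' @param time_column Write a leading `time` column in seconds?
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, sep = ",", time_column = FALSE) {
  stopifnot(inherits(series, "config_series"))
  m <- series$states
  header <- series$animal_ids
  body <- apply(m, 1L, paste, collapse = sep)
  if (time_column) {
    t0 <- (seq_len(nrow(m)) - 1L) * series$bin_duration
    header <- c("time", header)
    body <- paste(format(t0, trim = TRUE, scientific = FALSE), body, sep = sep)
  }
  writeLines(c(paste(header, collapse = sep), body), path)
  invisible(path)
}

#' Read/write a zone legend file
#'
#' Two-column delimited text: integer code, zone label. Codes must be
#' contiguous from 1.
#'
#' @param path File path.
#' @return [read_legend()] returns a [zone_legend()]; [write_legend()] returns
#'   `path` invisibly.
#' @export
read_legend <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) < 2L)) abort_parse("legend rows must be 'code,label'")
  codes <- as.integer(vapply(parts, `[[`, "", 1L))
  labels <- trimws(vapply(parts, function(p) paste(p[-1L], collapse = sep), ""))
  if (anyNA(codes) || !identical(sort(codes), seq_along(codes)))
    abort_parse("legend codes must be contiguous integers starting at 1")
  zone_legend(labels[order(codes)])
}

#' @rdname read_legend
#' @param legend A [zone_legend()].
#' @export
write_legend <- function(legend, path) {
  writeLines(paste(seq_along(legend), unclass(legend), sep = ","), path)
  invisible(path)
}

#' Rebin an occupancy series to a coarser time resolution
#'
#' Each output bin holds, per animal, the modal zone among its constituent
#' frames; a tie is broken by the zone occupied earliest within the bin. The
#' mode is robust to single-frame tracking noise, which is the reason for
#' working at a coarser bin (e.g. 240 ms) than the raw acquisition rate
#' (e.g. 40 ms). Trailing frames that do not fill a whole bin are dropped.
#'
#' @param series A [config_series()].
#' @param target_bin Target bin duration in seconds; must be an integer
#'   multiple of `series$bin_duration`.
#' @return A [config_series()] with `floor(T / factor)` bins.
#' @examples
#' s <- config_series(matrix(c(1, 1, 2, 2, 2, 1), ncol = 1), bin_duration = 0.04)
#' rebin(s, 0.12)$states
#' @export
rebin <- function(series, target_bin) {
  stopifnot(inherits(series, "config_series"))
  factor <- target_bin / series$bin_duration
  if (abs(factor - round(factor)) > 1e-8 || factor < 1)
    abort_argument("target_bin must be a positive integer multiple of the current bin duration")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(series)
  t_out <- nrow(series$states) %/% factor
  if (t_out < 1L) abort_argument("series too short for the requested bin")
  keep <- seq_len(t_out * factor)
  out <- matrix(0L, t_out, ncol(series$states))
  for (a in seq_len(ncol(series$states))) {
    m <- matrix(series$states[keep, a], nrow = factor)  # frames x bins
    out[, a] <- modal_zone_by_column(m, series$n_zones)
  }
  config_series(out, bin_duration = series$bin_duration * factor,
                n_zones = series$n_zones, animal_ids = series$animal_ids,
                legend = series$legend)
}

# Column-wise mode of a frames-x-bins matrix of zone codes; ties broken by the
# earliest frame (within the bin) among the tied zones.
modal_zone_by_column <- function(m, n_zones) {
  nb <- ncol(m)
  counts <- matrix(0L, n_zones, nb)
  first <- matrix(nrow(m) + 1L, n_zones, nb)  # first frame where each zone occurs
  for (z in seq_len(n_zones)) {
    hit <- m == z
    counts[z, ] <- colSums(hit)
    any_hit <- counts[z, ] > 0L
    if (any(any_hit)) {
      pos <- apply(hit[, any_hit, drop = FALSE], 2L, which.max)
      first[z, any_hit] <- pos
    }
  }
  best <- matrix(counts == rep(apply(counts, 2L, max), each = n_zones), n_zones, nb)
  tie_first <- ifelse(best, first, Inf)
  apply(tie_first, 2L, which.min)
}

#' Empirical joint-configuration distribution
#'
#' Counts each joint configuration (the vector of all animals' zones in one
#' bin) and normalizes by the number of bins.
#'
#' @param series A [config_series()].
#' @return A [joint_distribution()] with `sample_count` equal to the number of
#'   bins.
#' @export
empirical_distribution <- function(series) {
  stopifnot(inherits(series, "config_series"))
  N <- n_animals(series); Z <- series$n_zones
  K <- check_enumerable(Z, N, "empirical_distribution")
  idx <- config_linear_index(series$states, Z)
  counts <- tabulate(idx, nbins = K)
  joint_distribution(array(counts / nrow(series$states), dim = rep(Z, N)),
                     sample_count = nrow(series$states),
                     animal_ids = series$animal_ids, legend = series$legend)
}

#' Per-zone occupancy histogram of one animal
#'
#' The fraction of time an animal spends in each zone (its single-animal
#' marginal).
#'
#' @param series A [config_series()].
#' @param animal Animal index in `1:N`.
#' @return Numeric vector of length Z summing to 1, named by zone label.
#' @export
occupancy_histogram <- function(series, animal) {
  stopifnot(inherits(series, "config_series"))
  animal <- check_animal(animal, n_animals(series))
  h <- tabulate(series$states[, animal], nbins = series$n_zones) / nrow(series$states)
  names(h) <- if (!is.null(series$legend)) unclass(series$legend) else paste0("zone", seq_len(series$n_zones))
  h
}

check_animal <- function(animal, N) {
  if (length(animal) != 1L || is.na(animal) || animal < 1 || animal > N ||
      animal != round(animal))
    abort_argument(sprintf("animal must be a single index in 1..%d", N))
  as.integer(animal)
}

#' Continuous dwell times of one animal, per zone
#'
#' Run-length encodes the animal's zone sequence: every maximal run of
#' consecutive bins in the same zone contributes one visit of duration
#' `run length * bin_duration` seconds. The summed durations over all zones
#' equal the total session duration exactly.
#'
#' @param series A [config_series()].
#' @param animal Animal index.
#' @return A list of length Z; element z is the numeric vector of visit
#'   durations (seconds) in zone z.
#' @export
dwell_times <- function(series, animal) {
  stopifnot(inherits(series, "config_series"))
  animal <- check_animal(animal, n_animals(series))
  r <- rle(as.integer(series$states[, animal]))
  out <- vector("list", series$n_zones)
  for (z in seq_len(series$n_zones)) {
    out[[z]] <- r$lengths[r$values == z] * series$bin_duration
  }
  names(out) <- if (!is.null(series$legend)) unclass(series$legend) else paste0("zone", seq_len(series$n_zones))
  out
}

#' Rank-frequency view of a joint distribution
#'
#' Configurations ranked from the most to the least prevalent, plus the count
#' of occupied (nonzero-probability) configurations. Comparing the empirical
#' curve with that of the independent model exposes how correlations contract
#' the set of allowed group configurations.
#'
#' @param dist A [joint_distribution()].
#' @return A list with `probability` (non-increasing numeric vector) and
#'   `occupied` (number of states with p > 0).
#' @export
rank_frequency <- function(dist) {
  stopifnot(inherits(dist, "joint_dist"))
  p <- sort(as.vector(dist), decreasing = TRUE)
  list(probability = p, occupied = sum(p > 0))
}

#' Expected number of distinct configurations in a finite sample
#'
#' For a model distribution with state probabilities \eqn{p_s}, the expected
#' number of distinct states seen in n independent draws is
#' \eqn{\sum_s (1 - (1 - p_s)^n)}. Also returns a Monte-Carlo estimate
#' (mean and sd over replicates), which is the quantity "how many states would
#' typically occur in an experiment of this length".
#'
#' @param dist A [joint_distribution()].
#' @param n Number of draws.
#' @param seed Integer seed for the Monte-Carlo replicates.
#' @param reps Number of Monte-Carlo replicates.
#' @return List with `expected` (closed form), `mc_mean`, `mc_sd`.
#' @export
expected_distinct_states <- function(dist, n, seed = 1L, reps = 20L) {
  stopifnot(inherits(dist, "joint_dist"))
  if (n < 1 || reps < 1) abort_argument("n and reps must be >= 1")
  p <- as.vector(dist)
  expected <- sum(1 - (1 - p[p > 0])^n)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  draws <- vapply(seq_len(reps), function(r) {
    length(unique(sample.int(length(p), n, replace = TRUE, prob = p)))
  }, numeric(1))
  list(expected = expected, mc_mean = mean(draws), mc_sd = stats::sd(draws))
}

# Seed hygiene: run under a given seed, then restore the caller's RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
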