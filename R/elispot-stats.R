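#' ELISPOT positivity statistics
#'
#' @description
#' An ELISPOT stimulus condition is called positive only when all four
#' criteria hold against its matched no-peptide control:
#'
#' 1. mean spot-forming cells (SFC) of the test wells at least
#'    `min_sfc` (default 50, inclusive);
#' 2. two-tailed Student's t test (pooled variance) p-value below
#'    `p_max` (default 0.05, strict);
#' 3. stimulation index (SI = mean test / mean control) above `si_min`
#'    (default 2, strict);
#' 4. Poisson background tail below `poisson_max` (default 0.05,
#'    strict): the probability that a Poisson background with rate
#'    equal to the control mean would produce at least the (rounded)
#'    test mean.
#'
#' Replicate well counts are non-negative SFC on a shared
#' cells-per-well basis; the module never rescales counts.
#'
#' @param test_counts,control_counts Numeric vectors of replicate well
#'   SFC counts.
#' @name elispotStats
NULL

.checkCounts <- function(x, what, min_n = 1L) {
  if (length(x) < min_n)
    stop(what, " needs at least ", min_n, " replicate well(s)")
  if (anyNA(x) || any(x < 0))
    stop(what, " counts must be non-negative and non-missing")
  as.numeric(x)
}

#' @describeIn elispotStats ratio of mean test to mean control SFC;
#'   `Inf` when the control mean is zero but the test mean is positive,
#'   `NaN` when both means are zero.
#' @return `stimulationIndex()`: a single numeric.
#' @export
#' @examples
#' stimulationIndex(c(100, 110, 105), c(10, 12, 11))
stimulationIndex <- function(test_counts, control_counts) {
  test_counts <- .checkCounts(test_counts, "test")
  control_counts <- .checkCounts(control_counts, "control")
  mean(test_counts) / mean(control_counts)
}

#' @describeIn elispotStats two-tailed p-value from a pooled-variance
#'   (classic Student) two-sample t statistic with `n1 + n2 - 2`
#'   degrees of freedom. Degenerate zero-variance data follow the limit
#'   convention p = 1 for equal means and p = 0 for unequal means.
#' @return `twoSampleT()`: a p-value in `[0, 1]`.
#' @export
twoSampleT <- function(test_counts, control_counts) {
  x <- .checkCounts(test_counts, "test", min_n = 2L)
  y <- .checkCounts(control_counts, "control", min_n = 2L)
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), df = n1 + n2 - 2)
}

#' @describeIn elispotStats upper-tail probability `P(X >= k)` for
#'   `X ~ Poisson(lambda)` with `lambda = mean(control)` and
#'   `k = round(mean(test))`; a zero background rate gives probability
#'   0 for `k > 0` and 1 for `k = 0`.
#' @return `poissonTail()`: a probability in `[0, 1]`.
#' @export
poissonTail <- function(test_counts, control_counts) {
  test_counts <- .checkCounts(test_counts, "test")
  control_counts <- .checkCounts(control_counts, "control")
  lambda <- mean(control_counts)
  k <- round(mean(test_counts))
  if (lambda == 0) return(if (k > 0) 0 else 1)
  ppois(k - 1, lambda, lower.tail = FALSE)
}

#' @describeIn elispotStats apply all four criteria to one condition.
#' @param stimulus_id Identifier recorded in the returned call.
#' @param min_sfc,p_max,si_min,poisson_max Criterion thresholds (see
#'   Description for defaults and strictness).
#' @return `callPositive()`: a one-row `data.frame` with columns
#'   `stimulus_id, mean_sfc, si, si_infinite, p_value, poisson_tail,
#'   crit_count, crit_p, crit_si, crit_poisson, positive`, where
#'   `positive` is the conjunction of the four criterion booleans.
#' @export
#' @examples
#' callPositive(c(120, 118, 122), c(10, 12, 11))$positive  # TRUE
#' callPositive(c(45, 48, 44), c(2, 3, 2))$positive        # FALSE
callPositive <- function(test_counts, control_counts,
                         stimulus_id = NA_character_, min_sfc = 50,
                         p_max = 0.05, si_min = 2, poisson_max = 0.05) {
  mean_sfc <- mean(.checkCounts(test_counts, "test"))
  si <- stimulationIndex(test_counts, control_counts)
  p <- twoSampleT(test_counts, control_counts)
  pois <- poissonTail(test_counts, control_counts)
  si_infinite <- is.infinite(si)
  crit_count <- mean_sfc >= min_sfc
  # zero-background control: SI is flagged infinite and the criterion
  # passes iff any test signal exists
  crit_si <- if (mean(control_counts) == 0) mean_sfc > 0 else si > si_min
  crit_p <- p < p_max
  crit_poisson <- pois < poisson_max
  data.frame(stimulus_id = as.character(stimulus_id),
             mean_sfc = mean_sfc, si = si, si_infinite = si_infinite,
             p_value = p, poisson_tail = pois, crit_count = crit_count,
             crit_p = crit_p, crit_si = crit_si,
             crit_poisson = crit_poisson,
             positive = crit_count && crit_p && crit_si && crit_poisson,
             stringsAsFactors = FALSE)
}

#' Call positivity for every stimulus on a plate
#'
#' Applies [callPositive()] to each non-control stimulus of each arm in
#' a long-format plate table, against that arm's control wells.
#'
#' @param plate `data.frame` with columns `stimulus_id, arm, tissue,
#'   well_index, sfc` (see [readPlate()]); `tissue` may be absent.
#' @param control_id Stimulus id of the no-peptide control wells
#'   (default `"control"`); each arm present must include control
#'   wells.
#' @param ... Criterion thresholds passed to [callPositive()].
#' @return `data.frame` of calls, one row per (stimulus, arm), with an
#'   `arm` column prepended to the [callPositive()] columns.
#' @export
callPlate <- function(plate, control_id = "control", ...) {
  stopifnot(is.data.frame(plate),
            all(c("stimulus_id", "arm", "sfc") %in% names(plate)))
  out <- list()
  for (arm in unique(plate$arm)) {
    sub <- plate[plate$arm == arm, , drop = FALSE]
    ctrl <- sub$sfc[sub$stimulus_id == control_id]
    if (!length(ctrl))
      stop("no '", control_id, "' wells for arm ", arm)
    for (stim in setdiff(unique(sub$stimulus_id), control_id)) {
      call <- callPositive(sub$sfc[sub$stimulus_id == stim], ctrl,
                           stimulus_id = stim, ...)
      out[[length(out) + 1L]] <- cbind(arm = arm, call,
                                       stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(arm = character(0), stimulus_id = character(0),
                      mean_sfc = numeric(0), si = numeric(0),
                      si_infinite = logical(0), p_value = numeric(0),
                      poisson_tail = numeric(0), crit_count = logical(0),
                      crit_p = logical(0), crit_si = logical(0),
                      crit_poisson = logical(0), positive = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and write ELISPOT plate tables and calls
#'
#' Plates are tab-delimited with columns `stimulus_id, arm, tissue,
#' well_index, sfc` (one row per well); calls use the [callPlate()]
#' column layout.
#'
#' @param x Object to write.
#' @param file Path.
#' @return Readers return a `data.frame`; writers return `file`
#'   invisibly.
#' @export
readPlate <- function(file) read.delim(file, stringsAsFactors = FALSE)

#' @rdname readPlate
#' @export
writePlate <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname readPlate
#' @export
writeCalls <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
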