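#' @title Quantification of tolerance events
#' @description
#' Colony counts become tolerance percentages through three corrections:
#' internal-standard normalisation of the lesion arm against the lesion-free
#' control arm, inversion of the HDGR/TLS confusion introduced by ~5%
#' marker conversion at the B/D heteroduplex, and (for clustered-UV
#' constructs) removal of the Poisson zero class of lesion-free molecules.
#' @name quantify
NULL

# Wilson score interval; tolerates non-integer "counts" from corrections
.wilson <- function(x, n, conf = 0.95) {
  if (n <= 0) return(c(NA_real_, NA_real_))
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Normalised tolerance partition from colony counts
#'
#' Each class percentage is the ratio of lesion-arm colonies to the
#' lesion-arm internal standard, divided by the same ratio for the
#' lesion-free control arm, times 100; total survival is the sum over
#' surviving classes. Class confidence intervals are Wilson score intervals
#' on the lesion-arm multinomial, scaled by the normalisation ratio.
#'
#' @param lesion_counts Named numeric vector with elements `HDGR`, `TLS`
#'   and `chromatid_loss` (lesion-arm colony counts per class).
#' @param control_count Lesion-free control colony count (> 0).
#' @param std_lesion,std_free Internal-standard colony counts for the lesion
#'   and control electroporations (> 0).
#' @param conf Confidence level for the Wilson intervals.
#' @return Data frame with rows `HDGR`, `TLS`, `chromatid_loss`, `survival`
#'   and columns `class`, `percent`, `ci_low`, `ci_high`, `denominator`.
#' @examples
#' tolerance_partition(c(HDGR = 400, TLS = 10, chromatid_loss = 50),
#'                     control_count = 500, std_lesion = 100, std_free = 100)
#' @export
tolerance_partition <- function(lesion_counts, control_count,
                                std_lesion, std_free, conf = 0.95) {
  need <- c("HDGR", "TLS", "chromatid_loss")
  if (!all(need %in% names(lesion_counts)))
    stop("lesion_counts must name HDGR, TLS and chromatid_loss")
  lesion_counts <- lesion_counts[need]
  if (any(lesion_counts < 0)) stop("counts must be non-negative")
  if (control_count <= 0 || std_lesion <= 0 || std_free <= 0)
    stop("control and internal-standard counts must be positive")
  norm <- (1 / std_lesion) / (control_count / std_free)
  total <- sum(lesion_counts)
  pct <- 100 * lesion_counts * norm
  ci <- t(vapply(lesion_counts, function(x) .wilson(x, total, conf),
                 numeric(2)))
  # Wilson bounds are on the within-arm fraction; rescale to percentages
  ci <- ci * total * norm * 100
  out <- data.frame(
    class = c(need, "survival"),
    percent = c(unname(pct), sum(pct)),
    ci_low = c(ci[, 1], NA_real_),
    ci_high = c(ci[, 2], NA_real_),
    denominator = rep(total, 4L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$class
  out
}

#' Tolerance partition straight from a simulated colony table
#'
#' Convenience wrapper: pools sectored and pure-blue colonies into HDGR,
#' pale-blue into TLS and white into chromatid loss, optionally applies the
#' marker-conversion correction, and normalises with the table's control and
#' internal-standard counts.
#'
#' @param table One-row `colony_table` from [simulate_experiment()] or
#'   [read_colony_table()].
#' @param conversion Marker-conversion rate to correct for; `NULL` skips the
#'   correction.
#' @inheritParams tolerance_partition
#' @return See [tolerance_partition()].
#' @export
partition_from_table <- function(table, conversion = NULL, conf = 0.95) {
  stopifnot(is.data.frame(table), nrow(table) == 1L)
  counts <- c(HDGR = table$n_sectored + table$n_pure_blue,
              TLS = table$n_pale_blue,
              chromatid_loss = table$n_white)
  if (!is.null(conversion) && conversion > 0)
    counts <- marker_conversion_correct(counts, conversion)
  tolerance_partition(counts, table$n_control,
                      table$internal_standard_lesion,
                      table$internal_standard_free, conf = conf)
}

#' Correct class counts for B/D marker conversion
#'
#' Conversion of the B/D heteroduplex region relabels an HDGR daughter
#' (C+B) as TLS-like (C+D) and vice versa, each with probability `c`, so
#' observed counts are the true counts mixed through the 2x2 confusion
#' matrix `[[1-c, c], [c, 1-c]]`. This inverts that matrix; chromatid-loss
#' counts are untouched (conversion of an undamaged daughter leaves the
#' colony white). Corrected counts that come out negative are clipped to
#' zero with a warning.
#'
#' @param class_counts Named numeric vector containing at least `HDGR` and
#'   `TLS`; other elements pass through unchanged.
#' @param c Per-daughter conversion probability, `0 <= c < 0.5`.
#' @return Corrected counts (same names, possibly non-integer).
#' @examples
#' marker_conversion_correct(c(HDGR = 95, TLS = 7, chromatid_loss = 10), 0.05)
#' @export
marker_conversion_correct <- function(class_counts, c) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c >= 0.5)
    stop("conversion rate must satisfy 0 <= c < 0.5")
  if (!all(c("HDGR", "TLS") %in% names(class_counts)))
    stop("class_counts must name HDGR and TLS")
  M <- matrix(c(1 - c, c, c, 1 - c), 2, 2)
  corrected <- solve(M, c(class_counts[["HDGR"]], class_counts[["TLS"]]))
  if (any(corrected < 0)) {
    warning("negative corrected count clipped to 0")
    corrected <- pmax(corrected, 0)
  }
  out <- class_counts
  out[["HDGR"]] <- corrected[1]
  out[["TLS"]] <- corrected[2]
  out
}

#' Forward marker-conversion confusion (for round-trip checks)
#'
#' Applies the confusion matrix that [marker_conversion_correct()] inverts.
#'
#' @inheritParams marker_conversion_correct
#' @return Confused counts.
#' @export
marker_conversion_forward <- function(class_counts, c) {
  if (c < 0 || c >= 0.5) stop("conversion rate must satisfy 0 <= c < 0.5")
  out <- class_counts
  h <- class_counts[["HDGR"]]; t <- class_counts[["TLS"]]
  out[["HDGR"]] <- (1 - c) * h + c * t
  out[["TLS"]] <- c * h + (1 - c) * t
  out
}

#' Poisson zero-class percentage
#'
#' Percentage of randomly damaged molecules carrying no lesion when the
#' per-molecule lesion count is Poisson with mean `lambda`:
#' `100 * exp(-lambda)`. At the clustered-UV calibration `lambda = 2.56`
#' this is 7.73%.
#'
#' @param lambda Mean lesions per strand (>= 0).
#' @return Percentage in `[0, 100]`.
#' @examples
#' poisson_zero_fraction(2.56)
#' @export
poisson_zero_fraction <- function(lambda) {
  if (!is.numeric(lambda) || any(lambda < 0))
    stop("lambda must be non-negative")
  100 * exp(-lambda)
}

#' Correct clustered-lesion survival for the lesion-free zero class
#'
#' Survival measured with randomly irradiated constructs is a mixture of the
#' truly multi-lesion molecules and a zero class of lesion-free molecules
#' (fraction `f0`) whose survival equals the single-/no-lesion reference
#' `S_single`. Inverts `S_obs = f0 * S_single + (1 - f0) * S_clustered`.
#'
#' @param S_obs Observed survival fraction in `[0, 1]`.
#' @param f0 Zero-class fraction, `0 <= f0 < 1`.
#' @param S_single Survival of the zero-class (lesion-free) molecules.
#' @return Corrected survival, clipped to `[0, 1]` with a warning if the
#'   inversion leaves that range.
#' @examples
#' clustered_survival_correct(0.12, 0.0773, 1)
#' @export
clustered_survival_correct <- function(S_obs, f0, S_single) {
  if (f0 < 0 || f0 >= 1) stop("f0 must satisfy 0 <= f0 < 1")
  if (S_obs < 0 || S_obs > 1 || S_single < 0 || S_single > 1)
    stop("survival values must lie in [0, 1]")
  s <- (S_obs - f0 * S_single) / (1 - f0)
  if (s < 0 || s > 1) {
    warning("corrected survival outside [0, 1]; clipped")
    s <- min(1, max(0, s))
  }
  s
}
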