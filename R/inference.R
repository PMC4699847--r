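#' @title Estimators over colony data
#' @description
#' Maximum-likelihood event fractions with Wilson intervals, estimation of
#' the B/D marker-conversion rate from lesion-free control colonies, a
#' closed-form inversion of the survival model for the endogenous
#' opposite-strand lesion burden, and a deterministic grid calibration of
#' model parameters against target percentages.
#' @name inference
NULL

#' Event-class fractions among surviving colonies
#'
#' Multinomial maximum-likelihood fractions (class count / survivors) with
#' Wilson confidence intervals, plus the same classes expressed relative to
#' the lesion-free control (tolerance percentages).
#'
#' @param table One-row `colony_table`.
#' @param conf Confidence level.
#' @return Data frame with columns `class`, `count`, `fraction`, `ci_low`,
#'   `ci_high`, `tolerance_percent`.
#' @examples
#' tab <- simulate_experiment(default_params("recA", "TT64"), 2000, seed = 1)
#' estimate_event_fractions(tab)
#' @export
estimate_event_fractions <- function(table, conf = 0.95) {
  stopifnot(is.data.frame(table), nrow(table) == 1L)
  counts <- c(HDGR = table$n_sectored + table$n_pure_blue,
              TLS = table$n_pale_blue,
              chromatid_loss = table$n_white)
  survivors <- sum(counts)
  if (survivors <= 0) stop("no surviving colonies in the table")
  ci <- t(vapply(counts, function(x) .wilson(x, survivors, conf), numeric(2)))
  norm <- (1 / table$internal_standard_lesion) /
    (table$n_control / table$internal_standard_free)
  data.frame(class = names(counts), count = unname(counts),
             fraction = unname(counts) / survivors,
             ci_low = ci[, 1], ci_high = ci[, 2],
             tolerance_percent = 100 * unname(counts) * norm,
             stringsAsFactors = FALSE)
}

#' Estimate the B/D marker-conversion rate from control colonies
#'
#' In lesion-free control colonies every daughter's B/D information should
#' match its A/C strand of origin (A with B, C with D). A decoded daughter
#' combining A with D, or C with B, has undergone conversion of the B/D
#' heteroduplex. The estimate is the discordant fraction of decoded daughter
#' genotypes, with a Wilson interval.
#'
#' @param decoded Character vector of decoded daughter genotype labels from
#'   lesion-free colonies (e.g. from [decode_colonies()] output split on
#'   `"|"`), or a data frame with a `genotype` column.
#' @param conf Confidence level.
#' @return List with `estimate`, `ci_low`, `ci_high`, `n` (all fractions).
#' @export
estimate_conversion_rate <- function(decoded, conf = 0.95) {
  if (is.data.frame(decoded)) decoded <- decoded$genotype
  decoded <- decoded[!is.na(decoded)]
  if (length(decoded) == 0L) stop("no decoded genotypes supplied")
  has_a <- .has_marker(decoded, "A")
  has_b <- .has_marker(decoded, "B")
  has_c <- .has_marker(decoded, "C")
  has_d <- .has_marker(decoded, "D")
  discordant <- (has_a & has_d) | (has_c & has_b)
  n <- length(decoded)
  ci <- .wilson(sum(discordant), n, conf)
  list(estimate = mean(discordant), ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Invert the survival model for the opposite-strand lesion burden
#'
#' Solves `S = r + (1 - r) * exp(-lambda * (1 - r))` for `lambda`:
#' `lambda = -log((S - r) / (1 - r)) / (1 - r)`. Admissible only for
#' `r <= S_rel <= 1` (with `r < 1`).
#'
#' @param S_rel Relative survival (fraction of the lesion-free control).
#' @param r Per-gap resolution probability `h + t`.
#' @return Estimated mean opposite-strand lesion burden (lambda >= 0).
#' @examples
#' estimate_opposite_burden(0.503, 0.06)  # ~0.8
#' @export
estimate_opposite_burden <- function(S_rel, r) {
  if (S_rel > 1) stop("relative survival cannot exceed 1")
  if (r >= 1) return(0)
  if (S_rel < r)
    stop("no admissible burden: survival below per-gap resolution")
  if (S_rel == r) return(Inf)
  -log((S_rel - r) / (1 - r)) / (1 - r)
}

#' Calibrate model parameters against target percentages
#'
#' Deterministic grid search over `h`, `t` and `lambda_opp` minimising the
#' worst tolerance-scaled residual between the closed-form class
#' percentages and the supplied targets (minimax objective, ties broken by
#' the L2 norm and then by grid order).
#'
#' @param targets Data frame with columns `class` (one of `survival`,
#'   `HDGR`, `TLS`, `chromatid_loss`), `percent` and `tolerance`
#'   (percentage points).
#' @param h_grid,t_grid,lambda_grid Candidate grids.
#' @return List with `params` (named vector `h`, `t`, `lambda_opp`),
#'   `residuals` (per-target, percentage points), `converged` (all scaled
#'   residuals within tolerance).
#' @examples
#' calibrate_params(data.frame(class = c("survival", "HDGR"),
#'                             percent = c(50, 5), tolerance = c(10, 5)))
#' @export
calibrate_params <- function(targets,
                             h_grid = seq(0, 1, by = 0.005),
                             t_grid = seq(0, 0.2, by = 0.005),
                             lambda_grid = seq(0, 2, by = 0.05)) {
  need <- c("class", "percent", "tolerance")
  if (!is.data.frame(targets) || !all(need %in% names(targets)))
    stop("targets must be a data frame with class, percent and tolerance")
  ok_classes <- c("survival", "HDGR", "TLS", "chromatid_loss")
  if (!all(targets$class %in% ok_classes))
    stop("unknown target class")
  if (any(targets$tolerance <= 0)) stop("tolerances must be positive")
  grid <- expand.grid(h = h_grid, t = t_grid, lambda = lambda_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$h + grid$t <= 1, , drop = FALSE]
  r <- grid$h + grid$t
  loss <- (1 - r) * exp(-grid$lambda * (1 - r))
  pred <- cbind(survival = 100 * (r + loss), HDGR = 100 * grid$h,
                TLS = 100 * grid$t, chromatid_loss = 100 * loss)
  resid <- vapply(seq_len(nrow(targets)), function(j)
    abs(pred[, targets$class[j]] - targets$percent[j]), numeric(nrow(grid)))
  scaled <- sweep(resid, 2, targets$tolerance, "/")
  worst <- apply(scaled, 1, max)
  best <- which(worst == min(worst))
  if (length(best) > 1L) {
    l2 <- rowSums(scaled[best, , drop = FALSE]^2)
    best <- best[which.min(l2)]
  } else best <- best[1L]
  list(params = c(h = grid$h[best], t = grid$t[best],
                  lambda_opp = grid$lambda[best]),
       residuals = stats::setNames(resid[best, ], targets$class),
       converged = worst[best] <= 1)
}
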