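#' @title Stochastic model of single-lesion damage tolerance
#' @description
#' One integration event places a heteroduplex with a single
#' replication-blocking lesion on the bottom strand into a replicating
#' chromosome. Replication re-primes downstream of the lesion, leaving a
#' daughter-strand gap. The model resolves the introduced gap by
#' homology-directed gap repair (HDGR) with per-gap probability `h`, by
#' translesion synthesis (TLS) with probability `t`, and otherwise leaves it
#' unrepaired, killing the daughter cell that inherited the damaged
#' chromatid. The sister daughter, replicated from the undamaged strand,
#' carries a Poisson-distributed number of gaps from endogenous (and, in
#' clustered-UV mode, introduced) lesions on the opposite strand; it
#' survives only if every one of those gaps is resolved (each independently
#' with probability `h + t`). A colony forms if either daughter survives,
#' and its colour phenotype follows from the marker alleles the surviving
#' daughters transmit.
#' @name ddt_simulator
NULL

#' Per-genotype model parameters
#'
#' @param strain Strain label (e.g. `"parental"`, `"recA"`).
#' @param lesion Lesion kind: `"TT64"`, `"CPD"`, `"G-AAF"` or `"none"`.
#' @param h Per-gap HDGR resolution probability, in `[0, 1]`.
#' @param t Per-gap TLS resolution probability, in `[0, 1]`; `h + t <= 1`.
#' @param lambda_opp Mean number of endogenous replication-blocking lesions
#'   on the strand opposite the introduced lesion, per integration.
#' @param lambda_uv Mean number of additional clustered UV lesions on the
#'   opposite strand (0 outside clustered mode; 2.56 gives the 7.73%
#'   lesion-free zero class).
#' @param conversion Probability that the B/D heteroduplex region of a
#'   daughter is converted to the opposite strand's information before
#'   replication (~0.05 in the assay).
#' @return Object of class `genotype_params`.
#' @examples
#' genotype_params("recA", "TT64", h = 0.05, t = 0.01)
#' @export
genotype_params <- function(strain, lesion = "TT64", h, t,
                            lambda_opp = 0.8, lambda_uv = 0,
                            conversion = 0.05) {
  for (p in list(h = h, t = t, conversion = conversion)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("h, t and conversion must be probabilities in [0, 1]")
  }
  if (h + t > 1) stop("h + t must not exceed 1")
  if (!is.numeric(lambda_opp) || lambda_opp < 0 ||
      !is.numeric(lambda_uv) || lambda_uv < 0)
    stop("lesion means must be non-negative")
  structure(list(strain = strain, lesion = lesion, h = h, t = t,
                 lambda_opp = lambda_opp, lambda_uv = lambda_uv,
                 conversion = conversion),
            class = "genotype_params")
}

#' @export
print.genotype_params <- function(x, ...) {
  cat(sprintf(
    "<genotype_params %s/%s> h=%.3f t=%.3f lambda_opp=%.2f lambda_uv=%.2f c=%.2f\n",
    x$strain, x$lesion, x$h, x$t, x$lambda_opp, x$lambda_uv, x$conversion))
  invisible(x)
}

#' Calibrated parameter table for the published strains
#'
#' Per-gap resolution probabilities calibrated so that the emergent class
#' frequencies of the simulator reproduce the published partitioning of
#' tolerance events: parental strains resolve >80% of gaps by HDGR with rare
#' TLS (more frequent at G-AAF), recA-null strains retain only a small
#' residual RecA-independent exchange activity, recF impairment halves HDGR
#' (and four-fold increases G-AAF TLS), recB loss trims HDGR by about 20%,
#' and sulA behaves as the parental strain. The endogenous opposite-strand
#' burden is 0.8 lesions per integration throughout and marker conversion
#' 5% per daughter.
#'
#' @param strain,lesion Optional filters; when both are given a single
#'   [genotype_params()] object is returned.
#' @return A data frame (or a `genotype_params` when both filters are given).
#' @examples
#' default_params("recA", "TT64")
#' @export
default_params <- function(strain = NULL, lesion = NULL) {
  tab <- data.frame(
    strain = c("parental", "parental", "parental",
               "recA", "recA", "recA",
               "recF", "recF", "recF",
               "recB", "sulA"),
    lesion = c("TT64", "CPD", "G-AAF",
               "TT64", "CPD", "G-AAF",
               "TT64", "CPD", "G-AAF",
               "TT64", "TT64"),
    h = c(0.895, 0.895, 0.88,
          0.05, 0.05, 0.05,
          0.46, 0.46, 0.42,
          0.72, 0.895),
    t = c(0.002, 0.002, 0.02,
          0.01, 0.01, 0.01,
          0.002, 0.002, 0.08,
          0.002, 0.002),
    lambda_opp = 0.8,
    lambda_uv = 0,
    conversion = 0.05,
    stringsAsFactors = FALSE
  )
  if (is.null(strain) && is.null(lesion)) return(tab)
  sel <- tab
  if (!is.null(strain)) sel <- sel[sel$strain == strain, , drop = FALSE]
  if (!is.null(lesion)) sel <- sel[sel$lesion == lesion, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no calibrated parameters for that strain/lesion")
  if (!is.null(strain) && !is.null(lesion)) {
    r <- sel[1L, ]
    return(genotype_params(r$strain, r$lesion, r$h, r$t, r$lambda_opp,
                           r$lambda_uv, r$conversion))
  }
  sel
}

.flip_bd <- function(labels) {
  # marker-conversion of the B/D heteroduplex unit swaps B and D information
  swap <- c("C+B" = "C+D", "C+D" = "C+B", "A+B" = "A+D", "A+D" = "A+B",
            "A+B+E" = "A+D+E", "A+D+E" = "A+B+E",
            "C+B+F" = "C+D+F", "C+D+F" = "C+B+F")
  out <- unname(swap[labels])
  out[is.na(out)] <- labels[is.na(out)]
  out
}

.labels_for <- function(six_markers) {
  if (six_markers)
    c(undamaged = "A+B+E", hdgr = "C+B+F", tls = "C+D+F")
  else
    c(undamaged = "A+B", hdgr = "C+B", tls = "C+D")
}

#' Simulate a batch of single-lesion integration events
#'
#' Vectorised engine behind [simulate_experiment()]. Each row of the result
#' is one integration: the fate of the introduced gap, the opposite-strand
#' gap count, daughter viabilities, transmitted marker genotypes (after
#' marker conversion) and the resulting colony phenotype. A lesion-free
#' integration (`lesion = "none"`) produces a colony with probability one:
#' normalisation to the lesion-free control absorbs attrition shared by the
#' two arms, so the control arm carries no death in the model.
#'
#' @param params A [genotype_params()] object.
#' @param n Number of integrations.
#' @param seed Optional integer seed (sets the session RNG).
#' @param lesion Lesion kind; defaults to `params$lesion`.
#' @param six_markers Use the six-marker (E/F-bearing) genotype labels.
#' @return Data frame with columns `colony_id`, `resolution`, `n_opp`,
#'   `n_opp_resolved`, `d1_viable`, `d2_viable`, `d1_genotype`,
#'   `d2_genotype`, `phenotype`.
#' @examples
#' head(simulate_colonies(default_params("recA", "TT64"), 10, seed = 1))
#' @export
simulate_colonies <- function(params, n, seed = NULL,
                              lesion = params$lesion, six_markers = FALSE) {
  stopifnot(inherits(params, "genotype_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  labs <- .labels_for(six_markers)
  r <- params$h + params$t

  if (identical(lesion, "none")) {
    d1_lab <- rep(labs[["tls"]], n)   # intact bottom strand: C+D information
    d2_lab <- rep(labs[["undamaged"]], n)
    flip1 <- stats::runif(n) < params$conversion
    flip2 <- stats::runif(n) < params$conversion
    d1_lab[flip1] <- .flip_bd(d1_lab[flip1])
    d2_lab[flip2] <- .flip_bd(d2_lab[flip2])
    return(data.frame(
      colony_id = seq_len(n), resolution = "intact",
      n_opp = 0L, n_opp_resolved = 0L,
      d1_viable = TRUE, d2_viable = TRUE,
      d1_genotype = d1_lab, d2_genotype = d2_lab,
      phenotype = ifelse(.has_marker(d1_lab, "B"), "sectored-blue-white",
                         "pale-blue"),
      stringsAsFactors = FALSE))
  }

  u <- stats::runif(n)
  resolution <- ifelse(u < params$h, "HDGR",
                       ifelse(u < r, "TLS", "unresolved"))
  d1_viable <- resolution != "unresolved"
  lambda <- params$lambda_opp + params$lambda_uv
  n_opp <- stats::rpois(n, lambda)
  n_res <- stats::rbinom(n, n_opp, r)
  d2_viable <- n_res == n_opp

  d1_lab <- rep(NA_character_, n)
  d1_lab[resolution == "HDGR"] <- labs[["hdgr"]]
  d1_lab[resolution == "TLS"] <- labs[["tls"]]
  d2_lab <- ifelse(d2_viable, labs[["undamaged"]], NA_character_)
  flip1 <- d1_viable & stats::runif(n) < params$conversion
  flip2 <- d2_viable & stats::runif(n) < params$conversion
  d1_lab[flip1] <- .flip_bd(d1_lab[flip1])
  d2_lab[flip2] <- .flip_bd(d2_lab[flip2])

  d1_blue <- d1_viable & .has_marker(ifelse(is.na(d1_lab), "(none)", d1_lab), "B")
  d1_pale <- d1_viable & !d1_blue
  phenotype <- rep("dead", n)
  phenotype[!d1_viable & d2_viable] <- "white"
  phenotype[d1_pale] <- "pale-blue"
  phenotype[d1_blue & d2_viable] <- "sectored-blue-white"
  phenotype[d1_blue & !d2_viable] <- "pure-blue"

  data.frame(colony_id = seq_len(n), resolution = resolution,
             n_opp = n_opp, n_opp_resolved = n_res,
             d1_viable = d1_viable, d2_viable = d2_viable,
             d1_genotype = d1_lab, d2_genotype = d2_lab,
             phenotype = phenotype, stringsAsFactors = FALSE)
}

#' Simulate a single integration event
#'
#' Single-event counterpart of [simulate_colonies()], additionally exposing
#' the per-lesion resolutions of the opposite-strand gaps. Uses the current
#' session RNG state.
#'
#' @param params A [genotype_params()] object.
#' @param lesion Lesion kind; defaults to `params$lesion`.
#' @return List of class `cell_outcome` with fields `resolution`, `n_opp`,
#'   `opp_resolved` (logical vector), `d1_viable`, `d2_viable`,
#'   `d1_genotype`, `d2_genotype`, `phenotype`.
#' @examples
#' set.seed(1)
#' simulate_integration(default_params("parental", "TT64"))
#' @export
simulate_integration <- function(params, lesion = params$lesion) {
  stopifnot(inherits(params, "genotype_params"))
  r <- params$h + params$t
  labs <- .labels_for(FALSE)
  if (identical(lesion, "none")) {
    row <- simulate_colonies(params, 1L, lesion = "none")
    opp_resolved <- logical(0)
  } else {
    u <- stats::runif(1)
    resolution <- if (u < params$h) "HDGR" else if (u < r) "TLS" else "unresolved"
    n_opp <- stats::rpois(1, params$lambda_opp + params$lambda_uv)
    opp_resolved <- stats::runif(n_opp) < r
    d1_viable <- resolution != "unresolved"
    d2_viable <- all(opp_resolved)
    d1_lab <- if (resolution == "HDGR") labs[["hdgr"]] else
      if (resolution == "TLS") labs[["tls"]] else NA_character_
    d2_lab <- if (d2_viable) labs[["undamaged"]] else NA_character_
    if (d1_viable && stats::runif(1) < params$conversion)
      d1_lab <- .flip_bd(d1_lab)
    if (d2_viable && stats::runif(1) < params$conversion)
      d2_lab <- .flip_bd(d2_lab)
    d1_blue <- d1_viable && .has_marker(d1_lab, "B")
    phenotype <- if (!d1_viable && !d2_viable) "dead"
      else if (!d1_viable) "white"
      else if (!d1_blue) "pale-blue"
      else if (d2_viable) "sectored-blue-white"
      else "pure-blue"
    row <- data.frame(resolution = resolution, n_opp = n_opp,
                      d1_viable = d1_viable, d2_viable = d2_viable,
                      d1_genotype = d1_lab, d2_genotype = d2_lab,
                      phenotype = phenotype, stringsAsFactors = FALSE)
  }
  structure(list(resolution = row$resolution[1], n_opp = row$n_opp[1],
                 opp_resolved = opp_resolved,
                 d1_viable = row$d1_viable[1], d2_viable = row$d2_viable[1],
                 d1_genotype = row$d1_genotype[1],
                 d2_genotype = row$d2_genotype[1],
                 phenotype = row$phenotype[1]),
            class = "cell_outcome")
}

#' Simulate a full integration experiment
#'
#' Runs `n_integrations` lesion-arm integrations plus a lesion-free control
#' arm and internal-standard transformations, and aggregates the result into
#' a one-row colony table with the standard column set. Per-colony detail is
#' attached as the `"colonies"` attribute.
#'
#' @param params A [genotype_params()] object.
#' @param n_integrations Number of lesion-arm integrations (>= 1).
#' @param seed Integer seed; recorded in the output.
#' @param construct Construct name (metadata column).
#' @param orientation `"leading"` or `"lagging"` (metadata).
#' @param n_control Control-arm integrations (default `n_integrations`).
#' @param std_mean Expected internal-standard colony count per arm; both
#'   arms draw from the same Poisson mean.
#' @return A one-row `data.frame` of class `colony_table`.
#' @examples
#' simulate_experiment(default_params("recA", "TT64"), 1000, seed = 1)
#' @export
simulate_experiment <- function(params, n_integrations, seed,
                                construct = NULL,
                                orientation = "leading",
                                n_control = n_integrations,
                                std_mean = 10000) {
  stopifnot(inherits(params, "genotype_params"))
  if (n_integrations < 1L) stop("n_integrations must be >= 1")
  if (is.null(construct))
    construct <- if (identical(params$lesion, "G-AAF")) "pLL1_7" else "pLL1_2c"
  set.seed(seed)
  colonies <- simulate_colonies(params, n_integrations)
  std <- stats::rpois(2L, std_mean)
  counts <- table(factor(colonies$phenotype,
                         levels = c("sectored-blue-white", "pale-blue",
                                    "white", "pure-blue", "dead")))
  out <- data.frame(
    construct = construct, strain = params$strain, lesion = params$lesion,
    orientation = orientation, n_integrations = n_integrations,
    n_sectored = as.integer(counts[["sectored-blue-white"]]),
    n_pale_blue = as.integer(counts[["pale-blue"]]),
    n_white = as.integer(counts[["white"]]),
    n_pure_blue = as.integer(counts[["pure-blue"]]),
    n_dead = as.integer(counts[["dead"]]),
    n_control = as.integer(n_control),
    internal_standard_lesion = std[1L],
    internal_standard_free = std[2L],
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  class(out) <- c("colony_table", "data.frame")
  attr(out, "colonies") <- colonies
  out
}

#' Closed-form outcome probabilities of the lesion-tolerance model
#'
#' With per-gap resolution probability `r = h + t` and opposite-strand mean
#' `lambda = lambda_opp + lambda_uv`, the sister daughter survives with
#' probability `exp(-lambda * (1 - r))` (every Poisson gap resolved), so
#' relative survival is `S = r + (1 - r) * exp(-lambda * (1 - r))`. HDGR and
#' TLS tolerance equal `h` and `t`, and chromatid loss
#' `(1 - r) * exp(-lambda * (1 - r))`, all as fractions of integrations
#' (the lesion-free control is 1).
#'
#' @param params A [genotype_params()] object.
#' @return Named list: `survival`, `hdgr`, `tls`, `chromatid_loss`.
#' @examples
#' survival_closed_form(default_params("recA", "TT64"))
#' @export
survival_closed_form <- function(params) {
  stopifnot(inherits(params, "genotype_params"))
  r <- params$h + params$t
  lambda <- params$lambda_opp + params$lambda_uv
  loss <- (1 - r) * exp(-lambda * (1 - r))
  list(survival = r + loss, hdgr = params$h, tls = params$t,
       chromatid_loss = loss)
}
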