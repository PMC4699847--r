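test_that("degenerate parameters produce the expected deterministic fates", {
  # perfect gap repair, no opposite-strand burden: every colony sectored
  p1 <- genotype_params("toy", "TT64", h = 1, t = 0, lambda_opp = 0,
                        conversion = 0)
  col <- simulate_colonies(p1, 200, seed = 1)
  expect_true(all(col$phenotype == "sectored-blue-white"))
  expect_true(all(col$d1_viable & col$d2_viable))
  expect_true(all(col$d1_genotype == "C+B"))

  # no resolution at all: pure chromatid loss
  p2 <- genotype_params("toy", "TT64", h = 0, t = 0, lambda_opp = 0,
                        conversion = 0)
  col2 <- simulate_colonies(p2, 200, seed = 2)
  expect_true(all(col2$phenotype == "white"))
  expect_true(all(!col2$d1_viable & col2$d2_viable))

  # heavy opposite-strand burden kills everything
  p3 <- genotype_params("toy", "TT64", h = 0, t = 0, lambda_opp = 30,
                        conversion = 0)
  col3 <- simulate_colonies(p3, 500, seed = 3)
  expect_gt(mean(col3$phenotype == "dead"), 0.99)
})

test_that("simulation is reproducible under a fixed seed", {
  p <- default_params("recA", "TT64")
  a <- simulate_experiment(p, 1000, seed = 99)
  b <- simulate_experiment(p, 1000, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "colonies"), attr(b, "colonies"))
  c <- simulate_experiment(p, 1000, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("phenotype class counts always sum to the number of integrations", {
  for (row in seq_len(nrow(default_params()))) {
    d <- default_params()[row, ]
    p <- genotype_params(d$strain, d$lesion, d$h, d$t, d$lambda_opp,
                         d$lambda_uv, d$conversion)
    tab <- simulate_experiment(p, 500, seed = row)
    expect_equal(tab$n_sectored + tab$n_pale_blue + tab$n_white +
                   tab$n_pure_blue + tab$n_dead, 500L)
  }
})

test_that("cell outcome invariants hold for single integrations", {
  p <- default_params("recF", "TT64")
  set.seed(5)
  for (i in 1:200) {
    out <- simulate_integration(p)
    expect_s3_class(out, "cell_outcome")
    expect_identical(out$d1_viable, out$resolution != "unresolved")
    expect_identical(out$d2_viable, all(out$opp_resolved))
    expect_length(out$opp_resolved, out$n_opp)
    expect_identical(out$phenotype == "dead",
                     !out$d1_viable && !out$d2_viable)
    if (!out$d1_viable) expect_true(is.na(out$d1_genotype))
  }
})

test_that("Monte-Carlo class frequencies match the closed form within 3 SE", {
  set.seed(77)
  grid <- data.frame(h = runif(8, 0, 0.9), t = runif(8, 0, 0.08),
                     lambda = runif(8, 0, 2))
  grid$t <- pmin(grid$t, 1 - grid$h)
  n <- 4000
  for (i in seq_len(nrow(grid))) {
    p <- genotype_params("grid", "TT64", grid$h[i], grid$t[i],
                         grid$lambda[i], conversion = 0)
    cf <- survival_closed_form(p)
    col <- simulate_colonies(p, n, seed = 1000 + i)
    obs <- c(survival = mean(col$phenotype != "dead"),
             hdgr = mean(col$phenotype %in% c("sectored-blue-white",
                                              "pure-blue")),
             tls = mean(col$phenotype == "pale-blue"),
             chromatid_loss = mean(col$phenotype == "white"))
    for (cls in names(obs)) {
      se <- sqrt(cf[[cls]] * (1 - cf[[cls]]) / n)
      expect_lt(abs(obs[[cls]] - cf[[cls]]), 3 * se + 1e-9,
                label = sprintf("param set %d class %s", i, cls))
    }
  }
})

test_that("closed-form survival is monotone in h, t and lambda_opp", {
  hs <- seq(0, 0.95, by = 0.05)
  S_h <- vapply(hs, function(h) survival_closed_form(
    genotype_params("m", "TT64", h, 0.01, 0.8))$survival, 1)
  expect_true(all(diff(S_h) >= -1e-12))
  ts <- seq(0, 0.2, by = 0.01)
  S_t <- vapply(ts, function(t) survival_closed_form(
    genotype_params("m", "TT64", 0.3, t, 0.8))$survival, 1)
  expect_true(all(diff(S_t) >= -1e-12))
  ls <- seq(0, 3, by = 0.1)
  S_l <- vapply(ls, function(l) survival_closed_form(
    genotype_params("m", "TT64", 0.3, 0.01, l))$survival, 1)
  expect_true(all(diff(S_l) <= 1e-12))
})

test_that("without conversion, decoding reproduces transmitted alleles", {
  con <- build_reference_construct("pLL1_2c")
  p <- genotype_params("parental", "TT64", 0.6, 0.2, 0.8, conversion = 0)
  col <- simulate_colonies(p, 150, seed = 21)
  alive <- col[col$phenotype != "dead", ]
  mol <- decode_colonies(con, alive)
  expect_false(any(mol$discordant))
  for (i in seq_len(nrow(alive))) {
    transmitted <- c(if (alive$d1_viable[i]) alive$d1_genotype[i],
                     if (alive$d2_viable[i]) alive$d2_genotype[i])
    expect_identical(strsplit(mol$decoded[i], "|", fixed = TRUE)[[1]],
                     transmitted)
  }
})

test_that("clustered-UV mode reflects the Poisson lesion load", {
  p <- genotype_params("recA", "TT64", 0.05, 0.01, lambda_opp = 0.8,
                       lambda_uv = 2.56)
  col <- simulate_colonies(p, 4000, seed = 31)
  expect_gt(mean(col$n_opp), 3)  # 0.8 + 2.56 endogenous + clustered
  cf <- survival_closed_form(p)
  expect_lt(abs(mean(col$phenotype != "dead") - cf$survival),
            3 * sqrt(cf$survival * (1 - cf$survival) / 4000))
})

test_that("lesion-free integrations always yield colonies", {
  p <- default_params("parental", "TT64")
  col <- simulate_colonies(p, 300, seed = 4, lesion = "none")
  expect_true(all(col$d1_viable & col$d2_viable))
  expect_true(all(col$n_opp == 0L))
  # conversion shows up as blue sectors among control colonies
  expect_gt(mean(col$d1_genotype == "C+B"), 0)
  expect_lt(mean(col$d1_genotype == "C+B"), 0.15)
})

test_that("parameter validation rejects impossible inputs", {
  expect_error(genotype_params("x", "TT64", h = 0.7, t = 0.5), "h \\+ t")
  expect_error(genotype_params("x", "TT64", h = -0.1, t = 0), "probabilities")
  expect_error(genotype_params("x", "TT64", h = 0.1, t = 0,
                               lambda_opp = -1), "non-negative")
})
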