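test_that("find_sites locates lesion-context restriction motifs", {
  expect_equal(find_sites("GCAAGTTAACACG", "HincII"), 5L)
  expect_equal(find_sites("ATCACCGGCGCCACA", "NarI"), 7L)
  expect_equal(find_sites("AAAA", "PvuII"), integer(0))
  expect_error(find_sites("ACGU", "PvuII"), "invalid characters")
  # overlapping matches are all reported
  expect_equal(find_sites("AATATTATATT", enzyme("x", "ATATT", 2L)), c(2L, 7L))
})

test_that("find_sites agrees with a brute-force motif scan", {
  set.seed(101)
  enzymes <- restriction_enzymes()
  for (i in 1:40) {
    seq <- random_dna(sample(50:400, 1))
    e <- enzymes[[sample(length(enzymes), 1)]]
    expect_identical(find_sites(seq, e), brute_force_sites(seq, e$motif),
                     info = sprintf("iter %d enzyme %s", i, e$name))
  }
})

test_that("digest fragment arithmetic and conservation hold", {
  # one PvuII site engineered to cut after base 40 of a 100-mer
  set.seed(7)
  repeat {
    base <- random_dna(100)
    substr(base, 38, 43) <- "CAGCTG"
    if (length(find_sites(base, "PvuII")) == 1L) break
  }
  pat <- digest(base, list("PvuII"))
  expect_equal(sort(pat$fragment_lengths), c(40L, 60L))

  none <- digest(random_dna(80), list("SspI", "PvuII"))
  expect_equal(none$fragment_lengths, 80L)

  # conservation invariant on random sequences and enzyme subsets
  set.seed(11)
  for (i in 1:30) {
    seq <- random_dna(sample(100:1500, 1))
    enz <- sample(restriction_enzymes(), sample(1:3, 1))
    pat <- digest(seq, enz)
    expect_equal(sum(pat$fragment_lengths), nchar(seq))
    expect_equal(pat$total_length, nchar(seq))
  }
})

test_that("daughter digest patterns distinguish the event classes", {
  con <- build_reference_construct("pLL1_2c")
  pats <- lapply(c("undamaged", "hdgr", "tls"), function(ev) {
    amp <- pcr_amplify(daughter_sequence(con, event_genotype(con, ev)),
                       con$primers[["fwd"]], con$primers[["rev"]])
    digest(amp, con$enzymes)$fragment_lengths
  })
  expect_false(identical(pats[[1]], pats[[2]]))
  expect_false(identical(pats[[1]], pats[[3]]))
  expect_false(identical(pats[[2]], pats[[3]]))
})

test_that("in-silico PCR yields the published product lengths and errors", {
  lengths <- c(pLL1_2c = 506L, pLL1_7 = 506L, pLL4_5 = 1100L,
               pLL9_2c = 2283L)
  for (layout in names(lengths)) {
    con <- build_reference_construct(layout)
    for (ev in c("undamaged", "hdgr")) {
      amp <- pcr_amplify(daughter_sequence(con, event_genotype(con, ev)),
                         con$primers[["fwd"]], con$primers[["rev"]])
      expect_equal(nchar(amp), unname(lengths[layout]),
                   info = paste(layout, ev))
    }
  }
  con <- build_reference_construct("pLL1_2c")
  template <- daughter_sequence(con, event_genotype(con, "undamaged"))
  expect_error(pcr_amplify(template, "ACGTACGTACGTACGTACGT",
                           con$primers[["rev"]]), "no binding site")
  # a primer binding twice is ambiguous
  dup <- paste0(template, template)
  expect_error(pcr_amplify(dup, con$primers[["fwd"]], con$primers[["rev"]]),
               "more than once")
  # divergent orientation: swap the primers
  expect_error(pcr_amplify(template, con$primers[["rev"]],
                           con$primers[["fwd"]]), "divergent|no binding")
})

test_that("decoding inverts the digest of every allele combination", {
  for (layout in c("pLL1_2c", "pLL1_7", "pLL4_5", "pLL9_2c")) {
    con <- build_reference_construct(layout)
    for (g in all_marker_genotypes(con)) {
      amp <- pcr_amplify(daughter_sequence(con, g),
                         con$primers[["fwd"]], con$primers[["rev"]])
      dec <- decode_genotype(digest(amp, con$enzymes), con)
      expect_identical(dec$genotype[names(g)], g,
                       info = paste(layout, genotype_label(con, g)))
    }
  }
})

test_that("corrupt digest patterns are rejected", {
  con <- build_reference_construct("pLL1_2c")
  fake <- structure(list(fragment_lengths = c(1L, 505L), total_length = 506L),
                    class = "digest_pattern")
  expect_error(decode_genotype(fake, con), "no genotype")
})

test_that("colony classification follows the marker logic", {
  expect_equal(classify_colony("sectored-blue-white", c("C+B", "A+B"))$class,
               "HDGR")
  expect_equal(classify_colony("white", "A+B")$class, "CHROMATID_LOSS")
  expect_equal(classify_colony("pale-blue", c("C+D", "A+B"))$class, "TLS")
  # converted undamaged daughter still signals chromatid loss
  expect_equal(classify_colony("white", "A+D")$class, "CHROMATID_LOSS")
  # pure blue colonies (only the HDGR daughter survived) count as HDGR
  expect_equal(classify_colony("pure-blue", "C+B")$class, "HDGR")
  expect_equal(classify_colony("dead")$class, "DEAD")
  # phenotype-only calls
  expect_equal(classify_colony("sectored-blue-white")$class, "HDGR")
  expect_false(classify_colony("sectored-blue-white")$discordant)
  # phenotype/genotype contradiction is flagged, not silently classified
  disc <- classify_colony("white", "C+B")
  expect_equal(disc$class, "HDGR")
  expect_true(disc$discordant)
})

test_that("six-marker genotypes classify by their informative loci", {
  expect_equal(classify_colony("sectored-blue-white",
                               c("C+B+F", "A+B+E"))$class, "HDGR")
  expect_equal(classify_colony("white", "A+B+E")$class, "CHROMATID_LOSS")
})
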