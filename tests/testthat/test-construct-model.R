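test_that("reference layouts reproduce the published assay geometry", {
  expect_geom <- function(layout, amplicon, n_markers, fwd, rev, enzymes) {
    con <- build_reference_construct(layout)
    expect_equal(con$expected_amplicon_length, amplicon)
    expect_length(con$markers, n_markers)
    expect_identical(unname(con$primers[["fwd"]]), fwd)
    expect_identical(unname(con$primers[["rev"]]), rev)
    expect_setequal(con$enzymes, enzymes)
    amp <- pcr_amplify(daughter_sequence(con, event_genotype(con, "undamaged")),
                       con$primers[["fwd"]], con$primers[["rev"]])
    expect_equal(nchar(amp), amplicon)
    expect_length(validate_construct(con), 0)
  }
  expect_geom("pLL1_2c", 506L, 4L, "TAAATGTGAGCGAGTAACAACC",
              "CTTGGGCTGCAGGTCGACT", c("SspI", "PvuII"))
  expect_geom("pLL1_7", 506L, 4L, "TAAATGTGAGCGAGTAACAACC",
              "CTTGGGCTGCAGGTCGACT", c("EcoRI", "PvuII"))
  expect_geom("pLL4_5", 1100L, 4L, "TCGGGTTTTCGACGTTCAGA",
              "CTTGGGCTGCAGGTCGACT", c("SspI", "NheI"))
  expect_geom("pLL9_2c", 2283L, 6L, "TAAATGTGAGCGAGTAACAACC",
              "GCGCTAATGCTCTGTTACAGG", c("BglII", "SspI"))
  expect_error(build_reference_construct("pLL_nonexistent"))
})

test_that("lesion context oligos match the lesion chemistry", {
  uv <- build_reference_construct("pLL1_2c")
  expect_identical(uv$lesion$context_oligo, "GCAAGTTAACACG")
  expect_equal(find_sites(uv$lesion$context_oligo, "HincII"), 5L)
  aaf <- build_reference_construct("pLL1_7")
  expect_identical(aaf$lesion$context_oligo, "ATCACCGGCGCCACA")
  expect_equal(find_sites(aaf$lesion$context_oligo, "NarI"), 7L)
  # the G-AAF context carries the NarI motif exactly once
  expect_length(brute_force_sites(aaf$lesion$context_oligo, "GGCGCC"), 1)
  # lesion kinds are tied to their layouts
  expect_error(build_reference_construct("pLL1_2c", lesion_kind = "G-AAF"))
  expect_error(build_reference_construct("pLL1_7", lesion_kind = "CPD"))
})

test_that("marker layout distances follow the construct designs", {
  con <- build_reference_construct("pLL1_2c")
  pos <- vapply(con$markers, function(m) m$position, 1L)
  # C sits upstream of the lesion by roughly 100 bp
  expect_true(abs((con$lesion$position - pos[["C"]]) - 100) < 30)
  far <- build_reference_construct("pLL4_5")
  pos4 <- vapply(far$markers, function(m) m$position, 1L)
  expect_true((far$lesion$position - pos4[["C"]]) > 700)
  six <- build_reference_construct("pLL9_2c")
  pos9 <- vapply(six$markers, function(m) m$position, 1L)
  expect_true((pos9[["E"]] - six$lesion$position) > 1400)
  expect_true(pos9[["F"]] > pos9[["E"]])
})

test_that("validate_construct pinpoints broken invariants", {
  con <- build_reference_construct("pLL1_2c")
  bad <- con
  bad$markers$B$bottom_allele <- bad$markers$B$top_allele
  v <- validate_construct(bad)
  expect_true(any(grepl("marker B", v)))

  out <- con
  out$markers$A$position <- 5L  # upstream of the forward primer
  v2 <- validate_construct(out)
  expect_true(any(grepl("marker A.*amplicon", v2)))

  tampered <- con
  substr(tampered$bottom_strand, 30, 30) <-  # flank base: constant region
    chartr("ACGT", "CGTA", substr(tampered$bottom_strand, 30, 30))
  expect_true(any(grepl("reverse-complementary", validate_construct(tampered))))
})

test_that("strands are reverse-complementary base-by-base away from markers", {
  for (layout in c("pLL1_2c", "pLL9_2c")) {
    con <- build_reference_construct(layout)
    top <- con$top_strand
    bot_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(con$bottom_strand)))
    # walk the shared constant segments of the two assemblies
    cur_t <- 1L; cur_b <- 1L
    for (i in seq_along(con$segments)) {
      w <- nchar(con$segments[i])
      expect_identical(substr(top, cur_t, cur_t + w - 1L),
                       substr(bot_rc, cur_b, cur_b + w - 1L))
      cur_t <- cur_t + w; cur_b <- cur_b + w
      if (i <= length(con$markers)) {
        cur_t <- cur_t + nchar(con$markers[[i]]$top_allele)
        cur_b <- cur_b + nchar(con$markers[[i]]$bottom_allele)
      }
    }
  }
})

test_that("FASTA and sidecar round-trip preserves the fixture", {
  con <- build_reference_construct("pLL1_2c")
  fa <- tempfile(fileext = ".fasta")
  yml <- tempfile(fileext = ".yaml")
  write_construct_fasta(con, fa, config_path = yml)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_setequal(names(seqs),
                  c("top_strand", "bottom_strand", "daughter_undamaged",
                    "daughter_hdgr", "daughter_tls"))
  expect_identical(as.character(seqs[["top_strand"]]), con$top_strand)
  expect_identical(as.character(seqs[["daughter_hdgr"]]),
                   daughter_sequence(con, event_genotype(con, "hdgr")))
  desc <- yaml::read_yaml(yml)
  expect_equal(desc$amplicon_length, 506)
  expect_identical(desc$primers$fwd_seq, "TAAATGTGAGCGAGTAACAACC")
  expect_length(desc$markers, 4)
  unlink(c(fa, yml))
})
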