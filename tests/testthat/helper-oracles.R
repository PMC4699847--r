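# independent oracles and small fixture builders used across test files

# brute-force IUPAC motif scan, independent of the matching engine used by
# find_sites()
brute_force_sites <- function(seq, motif) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  k <- length(m)
  hits <- integer(0)
  for (i in seq_len(max(0L, length(s) - k + 1L))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(s[i + j - 1L] %in% iupac[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# minimal one-row colony table for estimator tests
fake_colony_table <- function(n_sectored, n_pale_blue, n_white,
                              n_pure_blue = 0L, n_dead = 0L,
                              n_control = 1000L, std_lesion = 1000L,
                              std_free = 1000L) {
  n <- n_sectored + n_pale_blue + n_white + n_pure_blue + n_dead
  tab <- data.frame(construct = "pLL1_2c", strain = "test", lesion = "TT64",
                    orientation = "leading", n_integrations = n,
                    n_sectored = n_sectored, n_pale_blue = n_pale_blue,
                    n_white = n_white, n_pure_blue = n_pure_blue,
                    n_dead = n_dead, n_control = n_control,
                    internal_standard_lesion = std_lesion,
                    internal_standard_free = std_free, seed = 1L,
                    stringsAsFactors = FALSE)
  class(tab) <- c("colony_table", "data.frame")
  tab
}

all_marker_genotypes <- function(construct) {
  nm <- names(construct$markers)
  grid <- expand.grid(rep(list(c("top", "bottom")), length(nm)),
                      stringsAsFactors = FALSE)
  names(grid) <- nm
  lapply(seq_len(nrow(grid)), function(i) {
    g <- as.character(grid[i, ]); names(g) <- nm; g
  })
}
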