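#' Restriction enzyme descriptions
#'
#' An enzyme is modelled as a blunt double-strand cutter: a recognition motif
#' (IUPAC codes allowed) and a cut offset within the motif. The offset is the
#' number of bases of the motif left on the upstream fragment, so a site
#' starting at position `s` cuts the molecule after base `s + cut_offset - 1`.
#' Overhang chemistry is irrelevant to fragment lengths on a gel and is not
#' modelled.
#'
#' @param name Enzyme name.
#' @param motif Recognition motif, IUPAC string of length >= 4.
#' @param cut_offset Integer cut offset, between 0 and `nchar(motif)`.
#' @return An object of class `ddt_enzyme`.
#' @examples
#' enzyme("HincII", "GTYRAC", 3)
#' @export
enzyme <- function(name, motif, cut_offset) {
  motif <- toupper(as.character(motif))
  if (nchar(motif) < 4L)
    stop("enzyme motif must be at least 4 bases long")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", motif))
    stop("enzyme motif must be an IUPAC DNA string")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(motif))
    stop("cut_offset must lie within the motif")
  structure(list(name = name, motif = motif, cut_offset = cut_offset),
            class = "ddt_enzyme")
}

#' @export
print.ddt_enzyme <- function(x, ...) {
  cat(sprintf("%s: %s (cuts after base %d)\n", x$name, x$motif, x$cut_offset))
  invisible(x)
}

#' Enzymes used by the marker-decoding assay
#'
#' The set of restriction enzymes referenced by the reference construct
#' layouts: the diagnostic enzymes used to read marker genotypes from digest
#' patterns (SspI, PvuII, EcoRI, NheI, BglII) and the two enzymes whose sites
#' carry the lesion context oligonucleotides (HincII for the UV photoproducts,
#' NarI for the G-AAF adduct).
#'
#' @return A named list of [enzyme()] objects.
#' @examples
#' restriction_enzymes()$SspI
#' @export
restriction_enzymes <- function() {
  list(
    SspI   = enzyme("SspI",   "AATATT", 3L),
    PvuII  = enzyme("PvuII",  "CAGCTG", 3L),
    EcoRI  = enzyme("EcoRI",  "GAATTC", 1L),
    NheI   = enzyme("NheI",   "GCTAGC", 1L),
    BglII  = enzyme("BglII",  "AGATCT", 1L),
    HincII = enzyme("HincII", "GTYRAC", 3L),
    NarI   = enzyme("NarI",   "GGCGCC", 2L)
  )
}

.as_enzyme <- function(x) {
  if (inherits(x, "ddt_enzyme")) return(x)
  if (is.character(x) && length(x) == 1L) {
    enz <- restriction_enzymes()
    if (!x %in% names(enz)) stop("unknown enzyme: ", x)
    return(enz[[x]])
  }
  stop("expected an enzyme object or enzyme name")
}

.check_dna <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("sequence must be a single non-empty string")
  if (grepl("[^ACGT]", seq))
    stop("invalid characters in sequence (A/C/G/T only)")
  seq
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Find restriction sites on one strand
#'
#' Scans the given strand for all (possibly overlapping) matches of the
#' enzyme's recognition motif, honouring IUPAC degeneracy in the motif. Only
#' the supplied strand is scanned; [digest()] takes care of
#' reverse-complement motifs.
#'
#' @param seq DNA sequence (A/C/G/T) as a single string.
#' @param enz An [enzyme()] object or the name of a bundled enzyme.
#' @return Integer vector of 1-based match start positions (possibly empty).
#' @examples
#' find_sites("GCAAGTTAACACG", "HincII")  # 5
#' find_sites("ATCACCGGCGCCACA", "NarI")  # 7
#' @export
find_sites <- function(seq, enz) {
  seq <- .check_dna(seq)
  enz <- .as_enzyme(enz)
  hits <- Biostrings::matchPattern(enz$motif, Biostrings::DNAString(seq),
                                   fixed = "subject")
  as.integer(Biostrings::start(hits))
}

#' Digest a linear molecule and report the fragment-length pattern
#'
#' Cut positions are collected from every enzyme's motif and its reverse
#' complement (so sites on either strand of the duplex are honoured); a site
#' starting at `s` contributes a cut after base `s + cut_offset - 1`
#' (`s + motif_length - cut_offset - 1` for a reverse-orientation site of a
#' non-palindromic motif). Fragments are the intervals between successive
#' cuts on the linear molecule, so fragment lengths always sum to the input
#' length.
#'
#' @param seq DNA sequence of the (linear) molecule, given as its top strand.
#' @param enzymes List of [enzyme()] objects or enzyme names.
#' @return A list of class `digest_pattern` with elements `fragment_lengths`
#'   (sorted integer multiset) and `total_length`.
#' @examples
#' digest(strrep("A", 100), list("SspI"))  # uncut: one fragment of 100
#' @export
digest <- function(seq, enzymes) {
  seq <- .check_dna(seq)
  if (inherits(enzymes, "ddt_enzyme")) enzymes <- list(enzymes)
  cuts <- integer(0)
  for (e in enzymes) {
    e <- .as_enzyme(e)
    fwd <- find_sites(seq, e)
    cuts <- c(cuts, fwd + e$cut_offset - 1L)
    # non-palindromic motifs: scan the reverse-complement orientation
    # explicitly; for palindromes this would only duplicate positions
    rc_full <- .iupac_revcomp(e$motif)
    if (!identical(rc_full, e$motif)) {
      rev_hits <- Biostrings::matchPattern(rc_full, Biostrings::DNAString(seq),
                                           fixed = "subject")
      cuts <- c(cuts, as.integer(Biostrings::start(rev_hits)) +
                  (nchar(e$motif) - e$cut_offset) - 1L)
    }
  }
  n <- nchar(seq)
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  frags <- diff(c(0L, cuts, n))
  structure(list(fragment_lengths = sort(as.integer(frags)),
                 total_length = as.integer(n)),
            class = "digest_pattern")
}

.iupac_revcomp <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(motif, "")[[1]]]), collapse = "")
}

#' @export
print.digest_pattern <- function(x, ...) {
  cat(sprintf("digest of %d bp: fragments %s\n", x$total_length,
              paste(x$fragment_lengths, collapse = " + ")))
  invisible(x)
}

#' In-silico PCR amplification
#'
#' Locates the forward primer on the supplied strand and the reverse primer
#' on the opposite strand (i.e. the reverse complement of the reverse primer
#' on the supplied strand), requires each to bind exactly once in convergent
#' orientation, and returns the primer-inclusive product.
#'
#' @param template Template sequence: the top strand of a daughter duplex
#'   (its complement is implied).
#' @param fwd,rev Primer sequences, 5'->3'.
#' @return The amplicon sequence (character).
#' @examples
#' pcr_amplify("AAACCCGGGTTTAAACGCGCGTATATC", "AAACCC", "GATATA")
#' @export
pcr_amplify <- function(template, fwd, rev) {
  template <- .check_dna(template)
  fwd <- .check_dna(fwd)
  rev <- .check_dna(rev)
  f_hits <- .fixed_matches(template, fwd)
  r_hits <- .fixed_matches(template, .revcomp(rev))
  if (length(f_hits) == 0L || length(r_hits) == 0L) {
    # diagnose divergent orientation for a clearer error
    if (length(.fixed_matches(template, rev)) > 0L ||
        length(.fixed_matches(template, .revcomp(fwd))) > 0L)
      stop("primers bind in divergent orientation; no product")
    stop("primer has no binding site on the template")
  }
  if (length(f_hits) > 1L || length(r_hits) > 1L)
    stop("primer binds the template more than once; ambiguous product")
  start <- f_hits
  end <- r_hits + nchar(rev) - 1L
  if (end <= start)
    stop("primers bind in divergent orientation; no product")
  substr(template, start, end)
}

.fixed_matches <- function(seq, pattern) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                   fixed = TRUE)
  as.integer(Biostrings::start(hits))
}
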