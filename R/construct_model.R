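#' @title Heteroduplex marker constructs
#' @description
#' The assay integrates a heteroduplex vector carrying a single
#' replication-blocking lesion into the *E. coli* chromosome. The two strands
#' differ at short genetic marker loci: the undamaged strand carries markers
#' A (a stop codon) and B (a loop that restores the lacZ reading frame), the
#' damaged strand carries markers C (100 bp upstream of the lesion) and D (a
#' +2 frameshift at the lesion site); two layouts move A/C 800 bp upstream or
#' add a second marker pair E/F 1.6 kb downstream. Each marker's two alleles
#' differ such that exactly one allele carries a diagnostic restriction site,
#' so the allele combination transmitted to a daughter chromosome can be read
#' from the fragment pattern of a digested PCR product spanning the loci.
#'
#' The published assay never discloses full vector sequences; only amplicon
#' lengths, primer sequences, lesion context oligonucleotides and diagnostic
#' enzymes are stated. Construct sequences here are therefore synthetic:
#' generated from a fixed deterministic stream and then constrained so that
#' primer sites are unique, amplicon lengths equal the published values, and
#' each diagnostic motif occurs only inside the allele that is supposed to
#' carry it.
#' @name construct_model
NULL

# deterministic base stream (Lehmer generator) so fixture sequences are
# reproducible without touching the session RNG
.lcg_dna <- function(n, seed) {
  state <- seed %% 2147483647
  if (state <= 0) state <- state + 2147483646
  out <- character(n)
  alphabet <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- alphabet[(state %% 4) + 1]
  }
  paste(out, collapse = "")
}

.PRIMERS <- c(
  VP56  = "TAAATGTGAGCGAGTAACAACC",
  VP215 = "CTTGGGCTGCAGGTCGACT",
  VP210 = "TCGGGTTTTCGACGTTCAGA",
  GM1   = "GCGCTAATGCTCTGTTACAGG"
)

.UV_CONTEXT  <- "GCAAGTTAACACG"     # HincII site; TT(6-4) / CPD lesions
.AAF_CONTEXT <- "ATCACCGGCGCCACA"   # NarI site; G-AAF adduct

# single point change inside a motif that does not recreate any bundled site
.point_mutate <- function(motif) {
  b <- substr(motif, 3, 3)
  substr(motif, 3, 3) <- if (b == "A") "T" else "A"
  motif
}

# allele pairs shared by all layouts; rs1/rs2 are the two diagnostic enzymes.
# Alleles are written in top-strand orientation; `variant` names the strand
# whose transmitted daughter displays the marker (and its diagnostic site).
.allele_set <- function(rs1, rs2) {
  m1 <- .as_enzyme(rs1)$motif
  m2 <- .as_enzyme(rs2)$motif
  list(
    A = list(kind = "stop-codon", variant = "top", enzyme = rs1,
             top = paste0("TAA", m1), bottom = "CTTGCATGG"),
    C = list(kind = "point-mismatch", variant = "bottom", enzyme = rs2,
             top = .point_mutate(m2), bottom = m2),
    B = list(kind = "+4-loop", variant = "top", enzyme = rs2,
             top = paste0("T", m2, "A"), bottom = "TGCA"),
    D = list(kind = "+2-frameshift", variant = "bottom", enzyme = rs1,
             top = "AGCA", bottom = m1),
    E = list(kind = "point-mismatch", variant = "top", enzyme = rs2,
             top = m2, bottom = .point_mutate(m2)),
    F = list(kind = "point-mismatch", variant = "bottom", enzyme = rs1,
             top = .point_mutate(m1), bottom = m1)
  )
}

# layout geometry: spacer lengths between primer sites, marker slots and the
# lesion context; the last spacer is solved so the undamaged-daughter
# amplicon hits the published length exactly
.layout_defs <- function() {
  list(
    pLL1_2c = list(fwd = "VP56", rev = "VP215", amplicon = 506L,
                   rs1 = "SspI", rs2 = "PvuII", lesion_default = "TT64",
                   markers = c("A", "C", "B", "D"),
                   spacers = c(55L, 120L, 85L, 8L), seed = 11L),
    pLL1_7  = list(fwd = "VP56", rev = "VP215", amplicon = 506L,
                   rs1 = "EcoRI", rs2 = "PvuII", lesion_default = "G-AAF",
                   markers = c("A", "C", "B", "D"),
                   spacers = c(55L, 120L, 85L, 8L), seed = 17L),
    pLL4_5  = list(fwd = "VP210", rev = "VP215", amplicon = 1100L,
                   rs1 = "SspI", rs2 = "NheI", lesion_default = "TT64",
                   markers = c("A", "C", "B", "D"),
                   spacers = c(130L, 40L, 790L, 8L), seed = 45L),
    pLL9_2c = list(fwd = "VP56", rev = "GM1", amplicon = 2283L,
                   rs1 = "SspI", rs2 = "BglII", lesion_default = "TT64",
                   markers = c("A", "C", "B", "D", "E", "F"),
                   spacers = c(55L, 120L, 85L, 8L, 1589L, 40L), seed = 92L)
  )
}

.LEFT_FLANK <- 150L
.RIGHT_FLANK <- 120L

.fixture_cache <- new.env(parent = emptyenv())

#' Build one of the reference construct layouts
#'
#' Reproduces the geometry and decodability of the four published vector
#' layouts: `pLL1_2c` and `pLL1_7` (506 bp amplicon with primers VP56/VP215,
#' four markers; UV and G-AAF lesions respectively), `pLL4_5` (1100 bp,
#' VP210/VP215, markers A/C moved ~800 bp upstream of the lesion) and
#' `pLL9_2c` (2283 bp, VP56/GM1, six markers with E/F ~1.6 kb downstream of
#' the lesion).
#'
#' @param layout One of `"pLL1_2c"`, `"pLL1_7"`, `"pLL4_5"`, `"pLL9_2c"`.
#' @param lesion_kind Lesion carried on the bottom (damaged) strand:
#'   `"TT64"`, `"CPD"` or `"none"` for the UV layouts, `"G-AAF"` or `"none"`
#'   for `pLL1_7`. Defaults to the layout's published lesion.
#' @param orientation `"leading"` or `"lagging"`; carried as metadata only.
#' @return An object of class `ddt_construct`.
#' @examples
#' con <- build_reference_construct("pLL1_2c")
#' con$expected_amplicon_length  # 506
#' @export
build_reference_construct <- function(layout = c("pLL1_2c", "pLL1_7",
                                                 "pLL4_5", "pLL9_2c"),
                                      lesion_kind = NULL,
                                      orientation = c("leading", "lagging")) {
  layout <- match.arg(layout)
  orientation <- match.arg(orientation)
  def <- .layout_defs()[[layout]]
  if (is.null(lesion_kind)) lesion_kind <- def$lesion_default
  ok <- if (layout == "pLL1_7") c("G-AAF", "none") else c("TT64", "CPD", "none")
  if (!lesion_kind %in% ok)
    stop(sprintf("layout %s does not support lesion kind '%s'",
                 layout, lesion_kind))
  key <- paste(layout, lesion_kind, orientation, sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])

  alleles <- .allele_set(def$rs1, def$rs2)[def$markers]
  ctx <- if (layout == "pLL1_7") .AAF_CONTEXT else .UV_CONTEXT
  ctx_rc <- .revcomp(ctx)  # context oligo reads 5'->3' on the bottom strand

  fwd_seq <- .PRIMERS[[def$fwd]]
  rev_seq <- .PRIMERS[[def$rev]]
  rev_rc <- .revcomp(rev_seq)

  # assemble constant segments; seg[i] precedes marker i, the last segment
  # follows the final marker. The lesion context is glued to the start of
  # the segment that follows marker D.
  n_mark <- length(def$markers)
  top_allele_len <- sum(vapply(alleles, function(a) nchar(a$top), 1L))
  d_index <- match("D", def$markers)
  inner <- nchar(fwd_seq) + sum(def$spacers) + top_allele_len + nchar(ctx_rc)
  last_spacer <- def$amplicon - inner - nchar(rev_rc)
  if (last_spacer < 10L) stop("layout geometry infeasible")

  seed <- def$seed * 7919L + nchar(ctx)
  rand_block <- function(n, salt) .lcg_dna(n, seed + salt * 131L)

  segments <- character(n_mark + 1L)
  segments[1L] <- paste0(rand_block(.LEFT_FLANK, 1L), fwd_seq,
                         rand_block(def$spacers[1L], 2L))
  for (i in seq_len(n_mark - 1L)) {
    seg <- rand_block(def$spacers[i + 1L], 10L + i)
    # the lesion context oligo is an extra constant piece right after marker D
    if (i == d_index) seg <- paste0(ctx_rc, seg)
    segments[i + 1L] <- seg
  }
  tail_seg <- rand_block(last_spacer, 99L)
  if (d_index == n_mark) tail_seg <- paste0(ctx_rc, tail_seg)
  segments[n_mark + 1L] <- paste0(tail_seg, rev_rc,
                                  rand_block(.RIGHT_FLANK, 100L))

  markers <- lapply(seq_len(n_mark), function(i) {
    a <- alleles[[i]]
    list(name = def$markers[i], kind = a$kind, variant = a$variant,
         diagnostic_enzyme = a$enzyme, top_allele = a$top,
         bottom_allele = a$bottom, position = NA_integer_)
  })
  names(markers) <- def$markers

  construct <- structure(list(
    name = layout, layout = layout,
    segments = segments, markers = markers,
    primers = c(fwd = fwd_seq, rev = rev_seq),
    primer_names = c(fwd = def$fwd, rev = def$rev),
    enzymes = c(def$rs1, def$rs2),
    lesion = list(kind = lesion_kind, strand = orientation,
                  position = NA_integer_,
                  context_oligo = if (lesion_kind == "none") ctx else ctx),
    expected_amplicon_length = def$amplicon
  ), class = "ddt_construct")

  construct <- .scrub_construct(construct)
  construct <- .finalize_positions(construct)
  stopifnot(nchar(pcr_amplify(daughter_sequence(construct,
                                                event_genotype(construct, "undamaged")),
                              fwd_seq, rev_seq)) == def$amplicon)
  .fixture_cache[[key]] <- construct
  construct
}

# all 2^L allele combinations of a construct
.all_genotypes <- function(construct) {
  nm <- names(construct$markers)
  grid <- expand.grid(rep(list(c("top", "bottom")), length(nm)),
                      stringsAsFactors = FALSE)
  names(grid) <- nm
  lapply(seq_len(nrow(grid)), function(i) {
    g <- as.character(grid[i, ])
    names(g) <- nm
    g
  })
}

# spans (start, end) of each allele within a given daughter assembly
.daughter_spans <- function(construct, genotype) {
  pos <- 1L
  spans <- list()
  for (i in seq_along(construct$markers)) {
    m <- construct$markers[[i]]
    pos <- pos + nchar(construct$segments[i])
    allele <- if (genotype[[m$name]] == "top") m$top_allele else m$bottom_allele
    spans[[m$name]] <- c(pos, pos + nchar(allele) - 1L)
    pos <- pos + nchar(allele)
  }
  spans
}

#' Daughter chromosome sequence for a marker allele combination
#'
#' Splices the chosen allele (top- or bottom-strand derived) of every marker
#' locus into the constant backbone and returns the resulting homoduplex
#' daughter sequence in top-strand orientation.
#'
#' @param construct A `ddt_construct`.
#' @param genotype Named character vector over the construct's marker names
#'   with values `"top"` or `"bottom"`.
#' @return Character sequence.
#' @examples
#' con <- build_reference_construct("pLL1_2c")
#' nchar(daughter_sequence(con, event_genotype(con, "hdgr")))
#' @export
daughter_sequence <- function(construct, genotype) {
  stopifnot(inherits(construct, "ddt_construct"))
  nm <- names(construct$markers)
  if (!all(nm %in% names(genotype)))
    stop("genotype must name every marker locus")
  if (!all(genotype[nm] %in% c("top", "bottom")))
    stop("genotype values must be 'top' or 'bottom'")
  pieces <- character(2L * length(nm) + 1L)
  for (i in seq_along(nm)) {
    m <- construct$markers[[i]]
    pieces[2L * i - 1L] <- construct$segments[i]
    pieces[2L * i] <- if (genotype[[m$name]] == "top") m$top_allele else
      m$bottom_allele
  }
  pieces[2L * length(nm) + 1L] <- construct$segments[length(nm) + 1L]
  paste(pieces, collapse = "")
}

#' Genotypes transmitted by each tolerance outcome
#'
#' * `undamaged`: the daughter replicated from the undamaged strand (top
#'   alleles everywhere; markers A+B).
#' * `tls`: the damaged strand replicated across the lesion (bottom alleles
#'   everywhere; markers C+D).
#' * `hdgr`: the damaged-strand daughter whose gap was filled from the sister
#'   chromatid, so the loci opposite the lesion (B/D region) carry the
#'   undamaged-strand information (markers C+B).
#'
#' @param construct A `ddt_construct`.
#' @param event `"undamaged"`, `"hdgr"` or `"tls"`.
#' @return Named character vector usable with [daughter_sequence()].
#' @export
event_genotype <- function(construct, event = c("undamaged", "hdgr", "tls")) {
  event <- match.arg(event)
  nm <- names(construct$markers)
  g <- switch(event,
              undamaged = rep("top", length(nm)),
              tls = rep("bottom", length(nm)),
              hdgr = ifelse(nm %in% c("B", "D"), "top", "bottom"))
  names(g) <- nm
  g
}

#' Human-readable marker label of a genotype
#'
#' Lists the markers whose variant allele is present, ordered by locus
#' position, joined by `+` (e.g. `"A+B"`, `"C+B"`, `"C+D"`).
#'
#' @param construct A `ddt_construct`.
#' @param genotype Named top/bottom vector as used by [daughter_sequence()].
#' @return Character label; `"(none)"` if no variant allele is present.
#' @export
genotype_label <- function(construct, genotype) {
  nm <- names(construct$markers)
  present <- vapply(construct$markers,
                    function(m) genotype[[m$name]] == m$variant, TRUE)
  if (!any(present)) return("(none)")
  ord <- order(vapply(construct$markers, function(m) m$position, 1L))
  lab <- nm[ord][present[ord]]
  paste(lab, collapse = "+")
}

#' Genotype from a marker label
#'
#' Inverse of [genotype_label()]: markers listed in the label take their
#' variant allele, all others the opposite allele.
#'
#' @inheritParams genotype_label
#' @param label Label such as `"C+B"`.
#' @return Named top/bottom genotype vector.
#' @export
label_genotype <- function(construct, label) {
  nm <- names(construct$markers)
  present <- if (identical(label, "(none)")) character(0) else
    strsplit(label, "+", fixed = TRUE)[[1]]
  if (!all(present %in% nm))
    stop("label names unknown markers: ",
         paste(setdiff(present, nm), collapse = ", "))
  g <- vapply(construct$markers, function(m) {
    if (m$name %in% present) m$variant else
      setdiff(c("top", "bottom"), m$variant)
  }, "")
  names(g) <- nm
  g
}

# remove accidental diagnostic motifs and stray primer sites from constant
# segments, across every possible daughter assembly; deterministic
.scrub_construct <- function(construct) {
  motifs <- vapply(construct$enzymes, function(e) .as_enzyme(e)$motif, "")
  fwd <- construct$primers[["fwd"]]
  rev <- construct$primers[["rev"]]
  genotypes <- .all_genotypes(construct)
  for (iter in seq_len(500L)) {
    fix <- NULL
    for (g in genotypes) {
      seq <- daughter_sequence(construct, g)
      spans <- .daughter_spans(construct, g)
      allowed <- lapply(names(construct$markers), function(nm) {
        m <- construct$markers[[nm]]
        if (g[[nm]] == m$variant) spans[[nm]] else NULL
      })
      allowed <- Filter(Negate(is.null), allowed)
      # diagnostic motifs outside variant-allele spans are forbidden
      for (mo in motifs) {
        for (p in find_sites(seq, enzyme("tmp", mo, 0L))) {
          inside <- any(vapply(allowed, function(sp)
            p >= sp[1] && (p + nchar(mo) - 1L) <= sp[2], TRUE))
          if (!inside) { fix <- list(g = g, pos = p, len = nchar(mo)); break }
        }
        if (!is.null(fix)) break
      }
      if (is.null(fix)) {
        # primer sites: fwd and revcomp(rev) exactly once, wrong-orientation
        # bindings never
        f_pos <- .fixed_matches(seq, fwd)
        r_pos <- .fixed_matches(seq, .revcomp(rev))
        bad <- c(if (length(f_pos) > 1L) f_pos[-1L],
                 if (length(r_pos) > 1L) r_pos[-1L],
                 .fixed_matches(seq, rev), .fixed_matches(seq, .revcomp(fwd)))
        if (length(bad) > 0L)
          fix <- list(g = g, pos = bad[1L], len = nchar(fwd))
      }
      if (!is.null(fix)) break
    }
    if (is.null(fix)) return(construct)
    construct <- .mutate_constant(construct, fix$g, fix$pos, fix$len)
  }
  stop("could not scrub construct backbone")
}

# mutate one constant-segment base inside the offending window
.mutate_constant <- function(construct, genotype, pos, len) {
  # map daughter coordinates to (segment, offset) pairs
  cursor <- 1L
  nseg <- length(construct$segments)
  for (i in seq_len(nseg)) {
    seg_len <- nchar(construct$segments[i])
    for (off in seq_len(seg_len)) {
      coord <- cursor + off - 1L
      if (coord >= pos && coord <= pos + len - 1L) {
        # avoid touching the designed primer slots and lesion context
        seg <- construct$segments[i]
        b <- substr(seg, off, off)
        if (!.in_reserved(construct, i, off)) {
          nb <- c(A = "C", C = "G", G = "T", T = "A")[[b]]
          substr(seg, off, off) <- nb
          construct$segments[i] <- seg
          return(construct)
        }
      }
    }
    cursor <- cursor + seg_len
    if (i <= length(construct$markers)) {
      m <- construct$markers[[i]]
      allele <- if (genotype[[m$name]] == "top") m$top_allele else
        m$bottom_allele
      cursor <- cursor + nchar(allele)
    }
  }
  stop("offending site overlaps only reserved bases; cannot scrub")
}

# reserved backbone bases: primer slots and the lesion context oligo
.in_reserved <- function(construct, seg_index, offset) {
  seg <- construct$segments[seg_index]
  fwd <- construct$primers[["fwd"]]
  rev_rc <- .revcomp(construct$primers[["rev"]])
  ctx_rc <- .revcomp(construct$lesion$context_oligo)
  windows <- list()
  if (seg_index == 1L)
    windows <- c(windows, list(c(.LEFT_FLANK + 1L, .LEFT_FLANK + nchar(fwd))))
  if (seg_index == length(construct$segments)) {
    s <- .fixed_matches(seg, rev_rc)
    if (length(s)) windows <- c(windows, list(c(s[1L], s[1L] + nchar(rev_rc) - 1L)))
  }
  s <- .fixed_matches(seg, ctx_rc)
  if (length(s)) windows <- c(windows, list(c(s[1L], s[1L] + nchar(ctx_rc) - 1L)))
  any(vapply(windows, function(w) offset >= w[1] && offset <= w[2], TRUE))
}

.finalize_positions <- function(construct) {
  g_top <- event_genotype(construct, "undamaged")
  spans <- .daughter_spans(construct, g_top)
  for (nm in names(construct$markers))
    construct$markers[[nm]]$position <- spans[[nm]][1L]
  top <- daughter_sequence(construct, g_top)
  bottom_assembly <- daughter_sequence(construct, event_genotype(construct, "tls"))
  construct$top_strand <- top
  construct$bottom_strand <- .revcomp(bottom_assembly)
  ctx_rc <- .revcomp(construct$lesion$context_oligo)
  ctx_pos <- .fixed_matches(top, ctx_rc)
  # the lesion sits on the bottom strand inside the context oligo; record the
  # top-strand coordinate of the context midpoint
  construct$lesion$position <- if (length(ctx_pos))
    ctx_pos[1L] + nchar(ctx_rc) %/% 2L else NA_integer_
  f <- .fixed_matches(top, construct$primers[["fwd"]])
  r <- .fixed_matches(top, .revcomp(construct$primers[["rev"]]))
  construct$amplicon_span <- c(f[1L], r[1L] + nchar(construct$primers[["rev"]]) - 1L)
  construct
}

#' Validate a construct against its design invariants
#'
#' Checks, for every marker locus, that the two alleles differ and that
#' exactly one of them carries the diagnostic enzyme's recognition motif;
#' that all marker loci fall inside the primer-delimited amplicon; that the
#' two strands are reverse-complementary away from marker loci; and that the
#' lesion context oligo matches the lesion kind (HincII context for UV
#' photoproducts, NarI context for G-AAF).
#'
#' @param construct A `ddt_construct`.
#' @return Character vector of violations; empty when the construct is valid.
#' @examples
#' validate_construct(build_reference_construct("pLL1_2c"))
#' @export
validate_construct <- function(construct) {
  stopifnot(inherits(construct, "ddt_construct"))
  bad <- character(0)
  for (m in construct$markers) {
    if (identical(m$top_allele, m$bottom_allele))
      bad <- c(bad, sprintf("marker %s: top and bottom alleles are identical",
                            m$name))
    motif <- .as_enzyme(m$diagnostic_enzyme)$motif
    n_top <- length(find_sites(m$top_allele, m$diagnostic_enzyme))
    n_bot <- length(find_sites(m$bottom_allele, m$diagnostic_enzyme))
    if ((n_top > 0) + (n_bot > 0) != 1L)
      bad <- c(bad, sprintf(
        "marker %s: diagnostic motif %s must occur in exactly one allele",
        m$name, motif))
    span <- c(m$position, m$position + nchar(m$top_allele) - 1L)
    if (!is.na(m$position) && !is.null(construct$amplicon_span) &&
        (span[1] < construct$amplicon_span[1] ||
         span[2] > construct$amplicon_span[2]))
      bad <- c(bad, sprintf("marker %s: locus lies outside the amplicon",
                            m$name))
  }
  # strand symmetry: constant segments must agree base-by-base between the
  # top strand and the reverse complement of the bottom strand
  top <- daughter_sequence(construct, event_genotype(construct, "undamaged"))
  bot <- .revcomp(construct$bottom_strand)
  spans_top <- .daughter_spans(construct, event_genotype(construct, "undamaged"))
  spans_bot <- .daughter_spans(construct, event_genotype(construct, "tls"))
  cur_t <- 1L; cur_b <- 1L
  nm <- names(construct$markers)
  for (i in seq_along(construct$segments)) {
    seg_len <- nchar(construct$segments[i])
    t_piece <- substr(top, cur_t, cur_t + seg_len - 1L)
    b_piece <- substr(bot, cur_b, cur_b + seg_len - 1L)
    if (!identical(t_piece, b_piece))
      bad <- c(bad, sprintf(
        "segment %d: strands are not reverse-complementary outside marker loci", i))
    cur_t <- cur_t + seg_len
    cur_b <- cur_b + seg_len
    if (i <= length(nm)) {
      m <- construct$markers[[i]]
      cur_t <- cur_t + nchar(m$top_allele)
      cur_b <- cur_b + nchar(m$bottom_allele)
    }
  }
  ctx <- construct$lesion$context_oligo
  kind <- construct$lesion$kind
  if (kind %in% c("TT64", "CPD")) {
    if (!identical(ctx, .UV_CONTEXT) ||
        length(find_sites(ctx, "HincII")) == 0L)
      bad <- c(bad, "lesion: UV lesion context must be the HincII 13-mer")
  } else if (kind == "G-AAF") {
    if (!identical(ctx, .AAF_CONTEXT) ||
        length(find_sites(ctx, "NarI")) == 0L)
      bad <- c(bad, "lesion: G-AAF context must be the NarI 15-mer")
  }
  bad
}

#' @export
print.ddt_construct <- function(x, ...) {
  cat(sprintf("<ddt_construct %s> %d markers (%s), lesion %s, amplicon %d bp (%s/%s)\n",
              x$name, length(x$markers),
              paste(names(x$markers), collapse = ""),
              x$lesion$kind, x$expected_amplicon_length,
              x$primer_names[["fwd"]], x$primer_names[["rev"]]))
  invisible(x)
}

#' Write construct strands and daughter duplexes as FASTA
#'
#' Writes the top and bottom parental strands plus the three daughter
#' homoduplexes (undamaged A+B, HDGR C+B, TLS C+D) to a FASTA file, and an
#' optional YAML sidecar describing markers, primers and lesion.
#'
#' @param construct A `ddt_construct`.
#' @param path Output FASTA path.
#' @param config_path Optional path for the YAML construct description.
#' @return Invisibly, the FASTA path.
#' @export
write_construct_fasta <- function(construct, path, config_path = NULL) {
  seqs <- c(
    top_strand = construct$top_strand,
    bottom_strand = construct$bottom_strand,
    daughter_undamaged = daughter_sequence(construct,
                                           event_genotype(construct, "undamaged")),
    daughter_hdgr = daughter_sequence(construct,
                                      event_genotype(construct, "hdgr")),
    daughter_tls = daughter_sequence(construct,
                                     event_genotype(construct, "tls"))
  )
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  if (!is.null(config_path)) {
    desc <- list(
      name = construct$name,
      amplicon_length = construct$expected_amplicon_length,
      primers = list(fwd = unname(construct$primer_names[["fwd"]]),
                     fwd_seq = unname(construct$primers[["fwd"]]),
                     rev = unname(construct$primer_names[["rev"]]),
                     rev_seq = unname(construct$primers[["rev"]])),
      enzymes = as.list(construct$enzymes),
      lesion = construct$lesion[c("kind", "strand", "position")],
      markers = lapply(construct$markers, function(m)
        m[c("name", "kind", "variant", "diagnostic_enzyme", "position",
            "top_allele", "bottom_allele")])
    )
    yaml::write_yaml(desc, config_path)
  }
  invisible(path)
}
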