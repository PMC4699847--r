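#' @title Molecular readout: digest-pattern decoding and colony classification
#' @description
#' A colony's sectors are genotyped by amplifying the marker-bearing region
#' of each daughter chromosome, digesting the product with the layout's two
#' diagnostic enzymes, and inverting the fragment pattern to a marker-allele
#' assignment. The event class then follows the marker logic of the assay:
#' C+B marks homology-directed gap repair (blue sectors), C+D marks
#' translesion synthesis (pale blue), and colonies carrying only
#' undamaged-strand markers (A+B) mark damaged-chromatid loss (pure white).
#' @name molecular_readout
NULL

.decode_cache <- new.env(parent = emptyenv())

# forward-simulate the digest pattern of every allele combination and build
# the (injective) pattern -> genotype lookup table
.decode_map <- function(construct, enzymes = construct$enzymes) {
  key <- paste(construct$name, construct$lesion$kind,
               paste(sort(unlist(lapply(enzymes, function(e) .as_enzyme(e)$name))),
                     collapse = ","), sep = "|")
  cached <- .decode_cache[[key]]
  if (!is.null(cached)) return(cached)
  genotypes <- .all_genotypes(construct)
  keys <- character(length(genotypes))
  for (i in seq_along(genotypes)) {
    seq <- daughter_sequence(construct, genotypes[[i]])
    amp <- pcr_amplify(seq, construct$primers[["fwd"]],
                       construct$primers[["rev"]])
    pat <- digest(amp, enzymes)
    keys[i] <- .pattern_key(pat)
  }
  if (anyDuplicated(keys))
    stop("layout not decodable: distinct allele combinations share a digest pattern")
  map <- list(keys = keys, genotypes = genotypes, enzymes = enzymes)
  .decode_cache[[key]] <- map
  map
}

.pattern_key <- function(pattern) {
  paste(sort(as.integer(pattern$fragment_lengths)), collapse = ";")
}

#' Decode a digest pattern to a marker-allele assignment
#'
#' Forward-simulates the digest pattern of every allele combination of the
#' layout (at most 2^6) and returns the unique combination whose predicted
#' pattern equals the observed one. Errors if the pattern matches no
#' combination (corrupt input) or if the layout is not decodable (two
#' combinations share a pattern).
#'
#' @param pattern A `digest_pattern` from [digest()].
#' @param construct The `ddt_construct` the pattern was produced from.
#' @param enzymes Enzymes used for the digest; defaults to the layout's
#'   diagnostic pair.
#' @return List with `genotype` (named top/bottom vector) and `label`
#'   (e.g. `"C+B"`).
#' @examples
#' con <- build_reference_construct("pLL1_2c")
#' amp <- pcr_amplify(daughter_sequence(con, event_genotype(con, "hdgr")),
#'                    con$primers[["fwd"]], con$primers[["rev"]])
#' decode_genotype(digest(amp, con$enzymes), con)$label  # "C+B"
#' @export
decode_genotype <- function(pattern, construct, enzymes = construct$enzymes) {
  stopifnot(inherits(pattern, "digest_pattern"),
            inherits(construct, "ddt_construct"))
  map <- .decode_map(construct, enzymes)
  hit <- match(.pattern_key(pattern), map$keys)
  if (is.na(hit))
    stop("no genotype matches the observed digest pattern")
  g <- map$genotypes[[hit]]
  list(genotype = g, label = genotype_label(construct, g))
}

# digest-pipeline genotyping of daughter sequences, cached by genotype label
.decode_label <- function(construct, labels) {
  uniq <- unique(labels)
  decoded <- vapply(uniq, function(lab) {
    g <- label_genotype(construct, lab)
    amp <- pcr_amplify(daughter_sequence(construct, g),
                       construct$primers[["fwd"]], construct$primers[["rev"]])
    decode_genotype(digest(amp, construct$enzymes), construct)$label
  }, "")
  decoded[match(labels, uniq)]
}

.has_marker <- function(label, marker) {
  label != "(none)" & vapply(strsplit(label, "+", fixed = TRUE),
                             function(x) marker %in% x, TRUE)
}

#' Classify a colony into a damage-tolerance event class
#'
#' Phenotype-only calls map sectored blue/white and pure blue colonies to
#' HDGR, pale blue to TLS and pure white to damaged-chromatid loss. When
#' decoded sector genotypes are supplied they take precedence: any sector
#' carrying C+B marks HDGR, C+D marks TLS, and colonies whose sectors carry
#' no damaged-strand upstream marker (no C) mark chromatid loss. A
#' phenotype/genotype contradiction (e.g. a white colony decoding C+B) is
#' flagged as discordant rather than silently classified.
#'
#' @param phenotype One of `"sectored-blue-white"`, `"pale-blue"`, `"white"`,
#'   `"pure-blue"`, `"dead"`.
#' @param genotypes Optional character vector of decoded sector labels
#'   (e.g. `c("C+B", "A+B")`).
#' @return List with `class` (one of `"HDGR"`, `"TLS"`, `"CHROMATID_LOSS"`,
#'   `"DEAD"`) and `discordant` (logical).
#' @examples
#' classify_colony("sectored-blue-white", c("C+B", "A+B"))
#' classify_colony("white", "A+B")
#' @export
classify_colony <- function(phenotype, genotypes = NULL) {
  phenotype <- match.arg(phenotype, c("sectored-blue-white", "pale-blue",
                                      "white", "pure-blue", "dead"))
  if (phenotype == "dead")
    return(list(class = "DEAD", discordant = FALSE))
  pheno_class <- switch(phenotype,
                        "sectored-blue-white" = "HDGR",
                        "pure-blue" = "HDGR",
                        "pale-blue" = "TLS",
                        "white" = "CHROMATID_LOSS")
  if (is.null(genotypes) || length(genotypes) == 0L)
    return(list(class = pheno_class, discordant = FALSE))
  has_c <- .has_marker(genotypes, "C")
  has_b <- .has_marker(genotypes, "B")
  has_d <- .has_marker(genotypes, "D")
  geno_class <- if (any(has_c & has_b)) "HDGR"
    else if (any(has_c & has_d)) "TLS"
    else if (!any(has_c)) "CHROMATID_LOSS"
    else "TLS"  # C without B or D: damaged-strand derived, bypass-like
  discordant <- !identical(geno_class, pheno_class)
  list(class = geno_class, discordant = discordant)
}

#' Genotype simulated colonies through the digest pipeline
#'
#' Runs the full molecular readout (PCR of each viable daughter, digestion
#' with the layout's diagnostic enzymes, pattern decoding, event
#' classification) over a table of simulated colonies, and optionally writes
#' the per-colony TSV report (colony id, phenotype, fragment lengths,
#' decoded alleles, event class).
#'
#' @param construct A `ddt_construct`.
#' @param colonies Per-colony data frame from [simulate_colonies()].
#' @param path Optional TSV output path.
#' @return Data frame with one row per colony: `colony_id`, `phenotype`,
#'   `fragments` (semicolon-joined, sectors separated by `|`),
#'   `decoded` (decoded sector labels joined by `|`), `event_class`,
#'   `discordant`.
#' @export
decode_colonies <- function(construct, colonies, path = NULL) {
  stopifnot(is.data.frame(colonies))
  frag_cache <- new.env(parent = emptyenv())
  frag_of <- function(lab) {
    if (is.null(frag_cache[[lab]])) {
      g <- label_genotype(construct, lab)
      amp <- pcr_amplify(daughter_sequence(construct, g),
                         construct$primers[["fwd"]], construct$primers[["rev"]])
      pat <- digest(amp, construct$enzymes)
      frag_cache[[lab]] <- list(
        fragments = paste(pat$fragment_lengths, collapse = ";"),
        decoded = decode_genotype(pat, construct)$label)
    }
    frag_cache[[lab]]
  }
  n <- nrow(colonies)
  fragments <- character(n); decoded <- character(n)
  event_class <- character(n); discordant <- logical(n)
  for (i in seq_len(n)) {
    labs <- c(if (isTRUE(colonies$d1_viable[i])) colonies$d1_genotype[i],
              if (isTRUE(colonies$d2_viable[i])) colonies$d2_genotype[i])
    if (length(labs) == 0L) {
      fragments[i] <- ""; decoded[i] <- ""
      event_class[i] <- "DEAD"; discordant[i] <- FALSE
      next
    }
    res <- lapply(labs, frag_of)
    fragments[i] <- paste(vapply(res, `[[`, "", "fragments"), collapse = "|")
    dec <- vapply(res, `[[`, "", "decoded")
    decoded[i] <- paste(dec, collapse = "|")
    cl <- classify_colony(colonies$phenotype[i], dec)
    event_class[i] <- cl$class
    discordant[i] <- cl$discordant
  }
  out <- data.frame(colony_id = colonies$colony_id,
                    phenotype = colonies$phenotype,
                    fragments = fragments, decoded = decoded,
                    event_class = event_class, discordant = discordant,
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
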