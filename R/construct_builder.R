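# The expression construct fuses a periplasmic carrier (DsbC with an
# internal His6 tag) to the peptide through a TEV recognition site, so that
# cleavage after ENLYFQ releases the native peptide with no extra residue.
# The exact carrier sequence is vector-specific configuration; when only a
# carrier mass is known the module works at the mass level.

# Average mass of the DsbC-His6 carrier plus TEV-site remainder, defined so
# that fusion mass = carrier mass + peptide mass (the junction water and the
# ENLYFQ remainder are folded into the constant).
DEFAULT_CARRIER_MASS <- 27787

#' Describe a fusion carrier
#'
#' @param name Carrier name.
#' @param sequence Optional carrier protein sequence (should contain its
#'   internal His6 tag, `HHHHHH`). When given, fusion masses are computed
#'   from residue masses.
#' @param mass Average carrier mass in Da used when no sequence is given;
#'   defined to already account for the fusion junction, so that
#'   `fusion = mass + peptide mass`. Default 27,787 Da.
#' @param dna Optional carrier CDS (DNA), used for GenBank annotation.
#' @param notes Free-text notes.
#' @return A `carrier_spec` list.
#' @export
carrier_spec <- function(name = "DsbC-His6", sequence = NULL,
                         mass = DEFAULT_CARRIER_MASS, dna = NULL,
                         notes = NULL) {
  if (is.null(sequence) && (is.null(mass) || mass <= 0)) {
    stop("carrier needs a sequence or a positive mass")
  }
  if (!is.null(sequence)) assert_peptide(sequence)
  if (!is.null(dna)) {
    assert_dna(dna)
    if (!is.null(sequence) && translate_dna(dna) != sequence) {
      stop("carrier dna does not translate to the carrier sequence")
    }
  }
  structure(list(name = name, sequence = sequence, mass = mass, dna = dna,
                 notes = notes), class = "carrier_spec")
}

#' A small synthetic stand-in carrier
#'
#' A made-up 66-residue carrier (not the real DsbC sequence, which is
#' vector-specific) ending in the internal His6 tag, with a matching CDS.
#' Useful for examples and for exercising sequence-level construct assembly.
#'
#' @return A `carrier_spec` with sequence, consistent mass and DNA.
#' @export
synthetic_carrier <- function() {
  seq <- paste0("MKKIWLALAGLVLAFSASAAQYEDGKQYTTLEKPVAGAPQVLEFFSFFCPH",
                "CYQFEEVLHHHHHH")
  tab <- read_codon_table()
  dna <- back_translate_initial(seq, tab)
  carrier_spec(name = "synthetic-carrier", sequence = seq,
               mass = peptide_mass(seq, "average"), dna = dna,
               notes = "synthetic stand-in, not the production carrier")
}

#' Fusion mass from a peptide mass and a carrier
#'
#' With a sequence-bearing carrier the mass is computed from the residue
#' masses of the joined chain (carrier + ENLYFQ + peptide). With a mass-only
#' carrier the convention is `carrier mass + peptide mass`: the carrier
#' constant is defined as already accounting for the junction chemistry.
#'
#' @param peptide_mass Average peptide mass in Da (> 0).
#' @param carrier A `carrier_spec`.
#' @param peptide Optional peptide sequence; required for the
#'   sequence-carrier path.
#' @return Fusion average mass in Da.
#' @export
fusion_mass <- function(peptide_mass, carrier, peptide = NULL) {
  if (peptide_mass <= 0) stop("peptide mass must be positive")
  if (!is.null(carrier$sequence)) {
    if (is.null(peptide)) {
      stop("sequence-carrier path needs the peptide sequence")
    }
    chain <- paste0(carrier$sequence, TEV_SITE_AA, peptide)
    # the numeric `peptide_mass` argument does not shadow the function here:
    # R skips non-function bindings when resolving a call
    return(peptide_mass(chain, "average"))
  }
  carrier$mass + peptide_mass
}

#' Build and annotate the full fusion construct
#'
#' @param peptide A single-row `peptide_library` data frame (or a peptide
#'   sequence string).
#' @param gene Optional `gene_design` for the peptide (needed for DNA-level
#'   annotation; its CDS must encode the TEV site + peptide).
#' @param carrier A `carrier_spec`.
#' @return A `construct_record`: fusion sequence (when available), fusion
#'   average mass, peptide mass, mass fraction, annotated protein features
#'   (0-based half-open coordinates) and, when carrier DNA is available, the
#'   full construct DNA with DNA-level features.
#' @export
build_fusion <- function(peptide, gene = NULL, carrier = carrier_spec()) {
  if (is.data.frame(peptide)) {
    stopifnot(nrow(peptide) == 1L)
    pep_id <- peptide$id
    pep <- peptide$sequence
  } else {
    pep_id <- "peptide"
    pep <- peptide
  }
  assert_peptide(pep)
  if (!is.null(gene)) {
    tr <- translate_dna(substr(gene$cds, 1L, nchar(gene$cds) - 6L))
    if (tr != paste0(TEV_SITE_AA, pep)) {
      stop("gene design does not encode the TEV site + peptide")
    }
  }
  pep_mass <- peptide_mass(pep, "average")
  fus_mass <- fusion_mass(pep_mass, carrier, peptide = pep)
  fusion_seq <- NULL
  features <- NULL
  dna <- NULL
  dna_features <- NULL
  if (!is.null(carrier$sequence)) {
    nc <- nchar(carrier$sequence)
    np <- nchar(pep)
    fusion_seq <- paste0(carrier$sequence, TEV_SITE_AA, pep)
    his <- gregexpr("HHHHHH", carrier$sequence, fixed = TRUE)[[1]]
    his_start <- if (his[1L] == -1L) NA_integer_ else
      his[length(his)] - 1L  # last occurrence, 0-based
    features <- data.frame(
      feature = c("carrier", "his6_tag", "tev_site", "peptide"),
      start = c(0L, his_start, nc, nc + 6L),
      end = c(nc, if (is.na(his_start)) NA_integer_ else his_start + 6L,
              nc + 6L, nc + 6L + np),
      stringsAsFactors = FALSE
    )
    if (!is.null(carrier$dna) && !is.null(gene)) {
      dna <- paste0(carrier$dna, gene$cds)
      ncd <- nchar(carrier$dna)
      dna_features <- data.frame(
        feature = c("carrier", "his6_tag", "tev_site", "peptide", "stop"),
        start = c(0L, if (is.na(his_start)) NA_integer_ else 3L * his_start,
                  ncd, ncd + 18L, nchar(dna) - 6L),
        end = c(ncd, if (is.na(his_start)) NA_integer_ else
                  3L * (his_start + 6L),
                ncd + 18L, ncd + 18L + 3L * nchar(pep), nchar(dna)),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(
    peptide_id = pep_id, peptide = pep, carrier = carrier,
    fusion_sequence = fusion_seq,
    fusion_mass = fus_mass, peptide_mass = pep_mass,
    mass_fraction = pep_mass / fus_mass,
    features = features, dna = dna, dna_features = dna_features
  ), class = "construct_record")
}

#' Peptide released by TEV cleavage of a construct
#'
#' Cleavage occurs between the Q of ENLYFQ and the first residue of the
#' peptide, so the C-terminal fragment is the native peptide.
#'
#' @param construct A `construct_record` with a fusion sequence.
#' @return The released peptide sequence.
#' @export
cleave_fusion <- function(construct) {
  if (is.null(construct$fusion_sequence)) {
    stop("mass-only construct: nothing to cleave at sequence level")
  }
  f <- construct$features
  pep_row <- f[f$feature == "peptide", ]
  substr(construct$fusion_sequence, pep_row$start + 1L, pep_row$end)
}

## ---- GenBank flat-file output --------------------------------------------

#' Write a construct as a GenBank flat file
#'
#' Emits the construct DNA with its five features (carrier, His6 tag, TEV
#' site, peptide, stop) as an annotated GenBank record that round-trips
#' through [read_genbank_features()] (and standard GenBank parsers).
#'
#' @param construct A `construct_record` built with carrier DNA and a gene.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
annotate_genbank <- function(construct, path) {
  if (is.null(construct$dna)) {
    stop("construct has no DNA; build it with a carrier that has `dna` ",
         "and with a gene design")
  }
  dna <- tolower(construct$dna)
  L <- nchar(dna)
  feats <- construct$dna_features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "LOCUS       %-16s %5d bp    DNA     linear   SYN %s",
    substr(construct$peptide_id, 1, 16), L,
    format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  fusion construct for %s.",
                     construct$peptide_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (k in seq_len(nrow(feats))) {
    if (is.na(feats$start[k])) next
    writeLines(sprintf("     misc_feature    %d..%d",
                       feats$start[k] + 1L, feats$end[k]), con)
    writeLines(sprintf("                     /label=\"%s\"",
                       feats$feature[k]), con)
  }
  writeLines("ORIGIN", con)
  for (i in seq(1L, L, by = 60L)) {
    chunk <- substr(dna, i, min(i + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read the feature table and sequence back from a GenBank flat file
#'
#' Minimal reader for simple single-record GenBank files such as those
#' written by [annotate_genbank()]: `misc_feature` locations with `/label=`
#' qualifiers plus the ORIGIN sequence.
#'
#' @param path GenBank file path.
#' @return List with `length`, `features` (data frame `feature`, `start`,
#'   `end`; 0-based half-open) and `sequence` (upper case).
#' @export
read_genbank_features <- function(path) {
  lines <- readLines(path)
  loc_len <- as.integer(sub(".*?(\\d+) bp.*", "\\1", lines[grepl("^LOCUS", lines)][1]))
  feat_rows <- grep("^     misc_feature", lines)
  features <- do.call(rbind, lapply(feat_rows, function(i) {
    loc <- sub("^     misc_feature\\s+", "", lines[i])
    se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
    lab <- sub('.*?/label="(.*)".*', "\\1", lines[i + 1L])
    data.frame(feature = lab, start = se[1L] - 1L, end = se[2L],
               stringsAsFactors = FALSE)
  }))
  origin <- grep("^ORIGIN", lines)
  seq_lines <- lines[(origin + 1L):(grep("^//", lines)[1L] - 1L)]
  sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  list(length = loc_len, features = features, sequence = sequence)
}
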