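# Domain model of the metagenomic control material (MCM): a defined mixture
# of bacterial genomic DNAs at known genome copy concentrations, split into
# Gram-negative and Gram-positive subgroups.

MEMBER_FIELDS <- c("name", "genus", "family", "order", "subgroup",
                   "genome_length", "rrn_copies", "gc_fraction",
                   "true_copies_per_ul")

SUBGROUPS <- c("gram_negative", "gram_positive")

#' Construct a community member
#'
#' One species of the control material, with the quantities the analysis
#' needs: genome length `g` (bp), 16S rRNA (rrn) gene copies per genome `r`,
#' GC fraction, and the true abundance in genome copies per microlitre.
#'
#' @param name Species label (unique within a community).
#' @param genus,family,order Taxonomic labels used for LCA assignment.
#' @param subgroup `"gram_negative"` or `"gram_positive"`.
#' @param genome_length Genome size in base pairs (> 0).
#' @param rrn_copies Integer 16S gene copies per genome (>= 1).
#' @param gc_fraction GC content as a fraction in (0, 1).
#' @param true_copies_per_ul True genome copies per microlitre (> 0).
#' @return A one-row `data.frame` with the member fields.
#' @export
community_member <- function(name, genus, family, order, subgroup,
                             genome_length, rrn_copies, gc_fraction,
                             true_copies_per_ul) {
  m <- data.frame(name = name, genus = genus, family = family, order = order,
                  subgroup = subgroup, genome_length = as.numeric(genome_length),
                  rrn_copies = as.integer(rrn_copies),
                  gc_fraction = as.numeric(gc_fraction),
                  true_copies_per_ul = as.numeric(true_copies_per_ul),
                  stringsAsFactors = FALSE)
  validate_members(m)
  m
}

validate_members <- function(members) {
  for (f in MEMBER_FIELDS) {
    if (!f %in% names(members)) {
      stop("community schema error: missing field '", f, "'", call. = FALSE)
    }
    bad <- is.na(members[[f]])
    if (any(bad)) {
      stop("community schema error: field '", f, "' is missing or invalid for member ",
           which(bad)[1], call. = FALSE)
    }
  }
  if (anyDuplicated(members$name)) {
    stop("community schema error: duplicate species name '",
         members$name[duplicated(members$name)][1], "'", call. = FALSE)
  }
  if (!all(members$subgroup %in% SUBGROUPS)) {
    stop("community schema error: field 'subgroup' must be one of ",
         paste(SUBGROUPS, collapse = ", "), call. = FALSE)
  }
  checks <- list(
    genome_length = members$genome_length > 0,
    rrn_copies = members$rrn_copies >= 1,
    gc_fraction = members$gc_fraction > 0 & members$gc_fraction < 1,
    true_copies_per_ul = members$true_copies_per_ul > 0
  )
  for (f in names(checks)) {
    if (!all(checks[[f]])) {
      stop("community schema error: field '", f, "' violates its invariant for member '",
           members$name[!checks[[f]]][1], "'", call. = FALSE)
    }
  }
  invisible(members)
}

#' Construct a community definition
#'
#' @param members A `data.frame` of community members (see
#'   [community_member()]), at least two rows, unique species names.
#' @param name Community name.
#' @param version Version tag.
#' @return An object of class `community_definition`: a list with elements
#'   `name`, `version` and `members`.
#' @export
community_definition <- function(members, name = "community", version = "1") {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  members$rrn_copies <- as.integer(members$rrn_copies)
  validate_members(members)
  if (nrow(members) < 2) {
    stop("a community needs at least 2 members", call. = FALSE)
  }
  structure(list(name = name, version = as.character(version),
                 members = members[, MEMBER_FIELDS]),
            class = "community_definition")
}

#' @export
print.community_definition <- function(x, ...) {
  cat(sprintf("<community_definition> %s (v%s): %d species (%d gram-negative, %d gram-positive)\n",
              x$name, x$version, nrow(x$members),
              sum(x$members$subgroup == "gram_negative"),
              sum(x$members$subgroup == "gram_positive")))
  print(x$members, row.names = FALSE)
  invisible(x)
}

#' Load a community definition from JSON or TSV
#'
#' JSON schema: `{name, version, members: [{name, genus, family, order,
#' subgroup, genome_length, rrn_copies, gc_fraction, true_copies_per_ul}]}`.
#' A TSV file with the same columns (tab-delimited, header required) is also
#' accepted; its community name defaults to the file name.
#'
#' @param path Path to a `.json` or `.tsv`/`.txt` file.
#' @return A [community_definition()].
#' @export
load_community <- function(path) {
  if (!file.exists(path)) stop("community file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::fromJSON(path)
    if (is.null(spec$members)) {
      stop("community schema error: missing field 'members'", call. = FALSE)
    }
    community_definition(spec$members,
                         name = if (is.null(spec$name)) basename(path) else spec$name,
                         version = if (is.null(spec$version)) "1" else spec$version)
  } else {
    community_definition(read_tsv(path), name = basename(path))
  }
}

#' Write a community definition to JSON
#'
#' @param community A [community_definition()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_community <- function(community, path) {
  jsonlite::write_json(list(name = community$name, version = community$version,
                            members = community$members),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The bundled MCM-like community
#'
#' Ten pathogenic species, five per Gram subgroup, with genome sizes
#' (1.85-6.26 Mb), rrn copy numbers (4-8), GC fractions (33%-67%) and
#' abundances spanning more than two orders of magnitude (~100 to >50,000
#' genome copies/uL), mirroring the published control material. Per-species
#' values are representative ("MCM-like"), not authoritative.
#'
#' @param genome_scale Optional uniform scaling factor applied to genome
#'   lengths (default 1). Relative abundances are invariant to uniform
#'   genome scaling because WGS read sampling weights and the genome-size
#'   normalisation both use the scaled lengths; a scale of e.g. 0.01 gives
#'   desk-sized genomes for simulation studies.
#' @return A [community_definition()].
#' @export
mcm_community <- function(genome_scale = 1) {
  stopifnot(genome_scale > 0)
  comm <- load_community(system.file("extdata", "mcm_default.json",
                                     package = "mcmbench", mustWork = TRUE))
  if (genome_scale != 1) {
    comm$members$genome_length <- round(comm$members$genome_length * genome_scale)
    comm$name <- sprintf("%s (genomes x%g)", comm$name, genome_scale)
  }
  comm
}

#' Convert DNA mass to genome copies
#'
#' `copies = mass_ng * 1e-9 * N_A / (genome_length * M_bp)` with Avogadro's
#' number `N_A` and the standard average double-stranded base-pair molar
#' mass `M_bp` = 650 g/mol/bp. This is the conversion behind the
#' fluorometry-to-copy-number axis when comparing fluorometric and dPCR
#' quantification.
#'
#' @param mass_ng DNA mass in nanograms (>= 0).
#' @param genome_length Genome length in base pairs (> 0).
#' @return Genome copies (numeric).
#' @export
mass_to_copies <- function(mass_ng, genome_length) {
  if (any(genome_length <= 0)) stop("genome_length must be > 0", call. = FALSE)
  if (any(mass_ng < 0)) stop("mass_ng must be >= 0", call. = FALSE)
  mass_ng * 1e-9 * AVOGADRO / (genome_length * BP_MOLAR_MASS)
}

#' Convert genome copies to DNA mass
#'
#' Inverse of [mass_to_copies()].
#'
#' @param copies Genome copies (>= 0).
#' @param genome_length Genome length in base pairs (> 0).
#' @return DNA mass in nanograms.
#' @export
copies_to_mass <- function(copies, genome_length) {
  if (any(genome_length <= 0)) stop("genome_length must be > 0", call. = FALSE)
  if (any(copies < 0)) stop("copies must be >= 0", call. = FALSE)
  copies * genome_length * BP_MOLAR_MASS / AVOGADRO * 1e9
}
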