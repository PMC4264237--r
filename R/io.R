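# External-format interfaces: FASTA (80-column wrap), FASTQ (Phred+33),
# TSV truth/taxonomy tables. Sequence I/O goes through Biostrings.

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line wrap width (default 80).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path Input path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Data frame with `id`, `bases`, `quals`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$id
  q <- Biostrings::PhredQuality(reads$quals)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path Input path.
#' @return Data frame with `id`, `bases`, `quals`, `pairing` (`"unpaired"`;
#'   adjust downstream for paired files).
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropped metadata columns on plain FASTQ input
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), bases = as.character(x),
             quals = as.character(Biostrings::quality(x)),
             pairing = "unpaired", stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read set as paired/unpaired FASTQ files
#'
#' Emits `<prefix>_1.fastq`, `<prefix>_2.fastq` and
#' `<prefix>_unpaired.fastq` according to each read's `pairing` field
#' (files for empty streams are still written, so pair files stay
#' synchronised).
#'
#' @param reads Data frame with `id`, `bases`, `quals`, `pairing`.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_read_streams <- function(reads, prefix) {
  paths <- c(pair_1 = paste0(prefix, "_1.fastq"),
             pair_2 = paste0(prefix, "_2.fastq"),
             unpaired = paste0(prefix, "_unpaired.fastq"))
  for (stream in names(paths)) {
    write_fastq(reads[reads$pairing == stream, , drop = FALSE], paths[stream])
  }
  invisible(paths)
}

#' Write a taxonomy table to TSV
#' @param taxonomy Data frame with `node_id`, `parent_id`, `rank`, `name`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) write_tsv(taxonomy, path)

#' Read a taxonomy TSV
#' @param path Input path.
#' @return Data frame with `node_id`, `parent_id`, `rank`, `name`.
#' @export
read_taxonomy <- function(path) read_tsv(path)
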