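#' Transcript catalog: identifiers and lengths
#'
#' @param ids unique transcript identifiers.
#' @param lengths transcript lengths in base pairs (`>= 1`).
#' @return a tibble of class `jointde_catalog` with columns `transcript`,
#'   `length`.
#' @export
transcript_catalog <- function(ids, lengths) {
  ids <- as.character(ids)
  lengths <- as.integer(lengths)
  if (anyDuplicated(ids)) abort("transcript ids must be unique")
  if (length(ids) != length(lengths)) abort("ids and lengths differ in length")
  if (anyNA(lengths) || any(lengths < 1)) abort("lengths must be >= 1")
  structure(tibble(transcript = ids, length = lengths),
            class = c("jointde_catalog", class(tibble())))
}

#' Build a transcript catalog from a transcriptome FASTA
#'
#' @param path FASTA file of transcript sequences.
#' @return a [transcript_catalog()].
#' @export
read_fasta_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))  # first word of the FASTA header
  transcript_catalog(ids, Biostrings::width(seqs))
}

#' Read transcriptome SAM alignments into an alignment table
#'
#' Parses a SAM file of reads aligned to the transcriptome (multi-mapping as
#' multiple records per read name) and attaches the uniform-position
#' alignment density `f = 1 / max(len - read_length + 1, 1)`, where `len` is
#' the target transcript length. Unmapped records are dropped and their count
#' reported. The transcript universe is taken from the catalog, so
#' transcripts without any aligned read keep their index.
#'
#' @param path SAM file; must carry `@SQ` header lines.
#' @param catalog a [transcript_catalog()] covering every reference sequence
#'   that receives an alignment.
#' @param read_length read length `L` in bases used by the density model.
#' @return a [alignments()] table with `transcript_ids` in catalog order.
#' @export
read_sam <- function(path, catalog, read_length) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  stopifnot(inherits(catalog, "jointde_catalog"))
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname"))
  )[[1]]
  unmapped <- bitwAnd(rec$flag, 4L) != 0L
  n_drop <- sum(unmapped)
  if (n_drop > 0)
    inform(sprintf("read_sam: dropped %d unmapped record(s)", n_drop))
  qname <- rec$qname[!unmapped]
  rname <- as.character(rec$rname[!unmapped])
  if (length(qname) == 0) abort("no usable (mapped) reads in SAM file")
  missing <- setdiff(unique(rname), catalog$transcript)
  if (length(missing) > 0)
    abort(paste0("alignment target(s) absent from catalog: ",
                 paste(head(missing, 5), collapse = ", ")))
  len <- catalog$length[match(rname, catalog$transcript)]
  dens <- 1 / pmax(len - read_length + 1, 1)
  alignments(tibble(read = qname, transcript = rname, dens = dens),
             transcript_ids = catalog$transcript)
}
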