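#' Alignment table: read-to-transcript alignment densities for one sample
#'
#' The central data container: one row per reported alignment, columns
#' `read` (read identifier), `transcript` (transcript identifier) and `dens`
#' (the alignment density of that read against that transcript, strictly
#' positive). Multi-mapping reads contribute several rows. The ordered
#' transcript universe is carried in the `transcript_ids` attribute so that
#' two samples of one analysis index the same `K` transcripts even when some
#' receive no reads.
#'
#' Duplicate `(read, transcript)` records are collapsed to the maximum
#' density, which is deterministic and order independent.
#'
#' @param df data frame with columns `read`, `transcript`, `dens`.
#' @param transcript_ids ordered character vector of all transcript ids;
#'   defaults to the transcripts present in `df`, in order of appearance.
#' @return a tibble of class `jointde_align`.
#' @examples
#' alignments(data.frame(read = c("r1", "r1", "r2"),
#'                       transcript = c("tA", "tB", "tA"),
#'                       dens = c(0.5, 0.5, 1)))
#' @export
alignments <- function(df, transcript_ids = NULL) {
  need <- c("read", "transcript", "dens")
  if (!all(need %in% names(df)))
    abort("`df` must have columns read, transcript, dens")
  df <- as_tibble(df[need])
  df$read <- as.character(df$read)
  df$transcript <- as.character(df$transcript)
  df$dens <- as.double(df$dens)
  if (nrow(df) == 0) abort("alignment table has no entries")
  if (any(!is.finite(df$dens)) || any(df$dens <= 0))
    abort("alignment densities must be strictly positive and finite")
  if (is.null(transcript_ids)) {
    transcript_ids <- unique(df$transcript)
  } else {
    transcript_ids <- as.character(transcript_ids)
    unknown <- setdiff(df$transcript, transcript_ids)
    if (length(unknown) > 0)
      abort(paste0("unknown transcript id(s): ",
                   paste(head(unknown, 5), collapse = ", ")))
  }
  if (anyDuplicated(transcript_ids)) abort("transcript ids must be unique")
  # collapse duplicate (read, transcript) records to the max density
  if (anyDuplicated(df[c("read", "transcript")])) {
    df <- df |>
      group_by(.data$read, .data$transcript) |>
      summarise(dens = max(.data$dens), .groups = "drop")
  }
  # stable read order: first appearance
  df <- df[order(match(df$read, unique(df$read))), ]
  structure(df, transcript_ids = transcript_ids,
            class = c("jointde_align", class(df)))
}

#' @export
print.jointde_align <- function(x, ...) {
  cat("<jointde_align> ", length(unique(x$read)), " reads, ",
      length(attr(x, "transcript_ids")), " transcripts, ",
      nrow(x), " alignments\n", sep = "")
  NextMethod()
}

#' Transcript ids of an alignment table
#' @param x a `jointde_align` object.
#' @return character vector of transcript ids, in index order.
#' @export
transcript_ids <- function(x) attr(x, "transcript_ids")

# internal compressed representation handed to the C++ samplers:
# 0-based CSR over reads, transcripts as 0-based column indices
as_align_csr <- function(x) {
  ids <- transcript_ids(x)
  reads <- unique(x$read)
  ri <- match(x$read, reads)
  o <- order(ri)
  ri <- ri[o]
  ti <- match(x$transcript, ids)[o]
  ptr <- c(0L, cumsum(tabulate(ri, nbins = length(reads))))
  list(ptr = as.integer(ptr), idx = as.integer(ti - 1L),
       f = as.double(x$dens[o]), read_ids = reads, K = length(ids))
}

check_matched_pair <- function(x, y) {
  if (!inherits(x, "jointde_align") || !inherits(y, "jointde_align"))
    abort("both samples must be `jointde_align` objects (see alignments())")
  if (!identical(transcript_ids(x), transcript_ids(y)))
    abort("the two samples must share an identical ordered transcript universe")
  invisible(TRUE)
}

#' Read the native sparse alignment-probability format
#'
#' One read per line: `read_id m t_1 d_1 ... t_m d_m`, with `m` the number of
#' candidate transcripts and `d_k > 0` the alignment density of the read
#' against transcript `t_k`. Whitespace separated; lines starting with `#`
#' are ignored.
#'
#' @param path path to a `.prob` file.
#' @param transcript_ids optional ordered transcript universe; transcripts in
#'   the file but not in this list raise an error.
#' @return a [alignments()] table.
#' @export
read_prob <- function(path, transcript_ids = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- lapply(which(keep), function(ln) {
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(tok) < 4)
      abort(sprintf("line %d: expected `read m t1 d1 ...`", ln))
    m <- suppressWarnings(as.integer(tok[2]))
    if (is.na(m) || m < 1)
      abort(sprintf("line %d: invalid alignment count `%s`", ln, tok[2]))
    if (length(tok) != 2 + 2 * m)
      abort(sprintf("line %d: expected %d fields, found %d",
                    ln, 2 + 2 * m, length(tok)))
    dens <- suppressWarnings(as.double(tok[2 + 2 * seq_len(m)]))
    if (anyNA(dens))
      abort(sprintf("line %d: non-numeric density", ln))
    if (any(dens <= 0) || any(!is.finite(dens)))
      abort(sprintf("line %d: densities must be strictly positive and finite", ln))
    tibble(read = tok[1], transcript = tok[1 + 2 * seq_len(m)], dens = dens)
  })
  if (length(rows) == 0) abort(paste0("no alignment records in ", path))
  alignments(bind_rows(rows), transcript_ids = transcript_ids)
}

#' Write an alignment table in the native probability format
#'
#' Inverse of [read_prob()]: `read_prob(write_prob(x, f))` restores `x`.
#'
#' @param x a [alignments()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prob <- function(x, path) {
  stopifnot(inherits(x, "jointde_align"))
  csr <- as_align_csr(x)
  ids <- transcript_ids(x)
  n <- length(csr$read_ids)
  lines <- vapply(seq_len(n), function(i) {
    j <- (csr$ptr[i] + 1):csr$ptr[i + 1]
    paste(csr$read_ids[i], length(j),
          paste(ids[csr$idx[j] + 1], format(csr$f[j], digits = 17),
                collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-transcript results table as TSV
#'
#' Tab-separated with header, one row per transcript in catalog order.
#'
#' @param summary data frame of per-transcript results (e.g. from
#'   [tidy()] on a fit).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
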