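#' Partition transcripts into read-sharing clusters
#'
#' Builds the bipartite graph of reads and transcripts (edges = reported
#' alignments, both samples pooled) and takes connected components, projected
#' to transcripts. Reads only ever align within one component, so MCMC
#' inference decomposes exactly across clusters. Transcripts with no aligned
#' read in either sample form singleton clusters.
#'
#' Cluster ids are deterministic: ordered by decreasing total read count
#' (ties by the smallest transcript index), mirroring a
#' largest-first scheduling of per-cluster chains.
#'
#' @param x,y matched [alignments()] tables.
#' @return an object of class `jointde_clusters`: list with `assignment`
#'   (tibble `transcript`, `cluster`) and `info` (tibble `cluster`,
#'   `n_transcripts`, `n_reads_x`, `n_reads_y`).
#' @examples
#' a <- alignments(data.frame(read = c("r1", "r1", "r2"),
#'                            transcript = c("t1", "t2", "t3"),
#'                            dens = 1), transcript_ids = paste0("t", 1:3))
#' build_clusters(a, a)$assignment
#' @export
build_clusters <- function(x, y) {
  check_matched_pair(x, y)
  ids <- transcript_ids(x)
  K <- length(ids)
  edges <- rbind(
    data.frame(read = paste0("x:", x$read), transcript = x$transcript),
    data.frame(read = paste0("y:", y$read), transcript = y$transcript))
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("T:", edges$transcript), to = edges$read),
    directed = FALSE,
    vertices = data.frame(name = c(paste0("T:", ids),
                                   unique(edges$read))))
  comp <- igraph::components(g)$membership[paste0("T:", ids)]
  # reads per raw component
  rx <- tabulate(comp[match(x$transcript, ids)][!duplicated(x$read)],
                 nbins = max(comp))
  ry <- tabulate(comp[match(y$transcript, ids)][!duplicated(y$read)],
                 nbins = max(comp))
  first_member <- vapply(seq_len(max(comp)), function(cc)
    min(which(comp == cc)), integer(1))
  o <- order(-(rx + ry), first_member)
  relabel <- integer(max(comp))
  relabel[o] <- seq_along(o)
  cluster <- relabel[comp]
  info <- tibble(
    cluster = seq_along(o),
    n_transcripts = as.integer(tabulate(cluster, nbins = length(o))),
    n_reads_x = as.integer(rx[o]),
    n_reads_y = as.integer(ry[o]))
  structure(list(assignment = tibble(transcript = ids,
                                     cluster = as.integer(cluster)),
                 info = info),
            class = "jointde_clusters")
}

#' @export
print.jointde_clusters <- function(x, ...) {
  cat("<jointde_clusters>", nrow(x$info), "cluster(s) over",
      nrow(x$assignment), "transcripts\n")
  print(x$info)
  invisible(x)
}

#' @export
tidy.jointde_clusters <- function(x, ...) x$assignment

# subset one sample's csr to a transcript cluster (members: global indices);
# returns a csr over the cluster-local transcript indexing (possibly 0 reads)
subset_csr <- function(csr, members) {
  keep_entry <- (csr$idx + 1L) %in% members
  if (!any(keep_entry)) {
    return(list(ptr = 0L, idx = integer(0), f = double(0),
                read_ids = character(0), K = length(members)))
  }
  n <- length(csr$ptr) - 1L
  read_of_entry <- rep.int(seq_len(n), diff(csr$ptr))
  keep_reads <- unique(read_of_entry[keep_entry])
  # components guarantee a read's whole candidate set is inside one cluster
  sel <- read_of_entry %in% keep_reads
  ri <- match(read_of_entry[sel], keep_reads)
  local <- match(csr$idx[sel] + 1L, members) - 1L
  ptr <- c(0L, cumsum(tabulate(ri, nbins = length(keep_reads))))
  list(ptr = as.integer(ptr), idx = as.integer(local),
       f = csr$f[sel], read_ids = csr$read_ids[keep_reads],
       K = length(members))
}
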