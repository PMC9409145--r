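# GROMOS-style (Daura neighbor-counting) conformational clustering.

#' All-vs-all Kabsch RMSD matrix over trajectory frames
#'
#' Entry (i, j) is the superposition-minimized RMSD between frames i and j
#' computed on the atom selection. Returned in nanometres, the unit cluster
#' cutoffs are conventionally quoted in.
#'
#' @param traj an \code{md_trajectory} (>= 2 frames).
#' @param selection atom indices the RMSD is computed on (e.g. backbone).
#' @return symmetric matrix (nm) with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(traj, selection) {
  if (!length(selection)) stop("empty selection")
  nf <- n_frames(traj)
  if (nf < 2) stop("need >= 2 frames")
  sel <- lapply(traj$frames, function(f) f[selection, , drop = FALSE])
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    r <- kabsch_superpose(sel[[i]], sel[[j]])$rmsd / 10  # A -> nm
    M[i, j] <- r; M[j, i] <- r
  }
  M
}

#' GROMOS clustering of a pairwise RMSD matrix
#'
#' Greedy neighbor-counting scheme: the frame with the most neighbors within
#' the cutoff becomes a cluster centroid; it and its neighbors form a cluster
#' and are removed; repeat until all frames are assigned. Ties are broken by
#' the lowest frame index, making the partition deterministic. Clusters are
#' numbered in decreasing size (ties again by centroid frame index).
#'
#' @param matrix square symmetric RMSD matrix (nm).
#' @param cutoff_nm neighbor cutoff in nm (default 0.2).
#' @return object of class \code{cluster_result}: \code{cutoff_nm},
#'   \code{assignments} (frame -> cluster id), \code{centroids} (frame
#'   indices), \code{sizes}.
#' @export
gromos_cluster <- function(matrix, cutoff_nm = 0.2) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("RMSD matrix must be square")
  if (max(abs(matrix - t(matrix))) > 1e-9)
    stop("RMSD matrix must be symmetric")
  nf <- nrow(matrix)
  remaining <- seq_len(nf)
  assignments <- integer(nf)
  centroids <- integer(0); sizes <- integer(0)
  cl <- 0L
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(matrix[i, remaining] <= cutoff_nm), integer(1))
    pick <- remaining[which.max(counts)]  # which.max takes the first maximum
    members <- remaining[matrix[pick, remaining] <= cutoff_nm]
    cl <- cl + 1L
    assignments[members] <- cl
    centroids <- c(centroids, pick)
    sizes <- c(sizes, length(members))
    remaining <- setdiff(remaining, members)
  }
  # renumber clusters by decreasing size, ties by centroid frame index
  ord <- order(-sizes, centroids)
  remap <- integer(cl); remap[ord] <- seq_len(cl)
  structure(list(cutoff_nm = cutoff_nm,
                 assignments = remap[assignments],
                 centroids = centroids[ord],
                 sizes = sizes[ord]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters at %.2f nm; sizes: %s\n",
              length(x$sizes), x$cutoff_nm,
              paste(head(x$sizes, 10), collapse = ", ")))
  invisible(x)
}

#' Cluster a trajectory and extract the top centroid structure
#'
#' Convenience wrapper: pairwise RMSD on a selection, GROMOS clustering, and
#' the centroid frame of the largest cluster as an \code{md_structure} (the
#' conformer carried into downstream clash analysis).
#'
#' @param traj an \code{md_trajectory}.
#' @param selection atom indices for the cluster RMSD.
#' @param cutoff_nm cutoff in nm (default 0.2).
#' @return list with \code{clusters} (a \code{cluster_result}) and
#'   \code{centroid} (an \code{md_structure}).
#' @export
cluster_trajectory <- function(traj, selection, cutoff_nm = 0.2) {
  M <- pairwise_rmsd_matrix(traj, selection)
  cr <- gromos_cluster(M, cutoff_nm)
  list(clusters = cr, centroid = get_frame(traj, cr$centroids[1]))
}

#' Write cluster assignments as a delimited table
#' @param result a \code{cluster_result}.
#' @param path output path (tab-separated: frame, cluster_id).
#' @return invisibly, the path.
#' @export
write_cluster_table <- function(result, path) {
  write.table(data.frame(frame = seq_along(result$assignments),
                         cluster_id = result$assignments),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
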