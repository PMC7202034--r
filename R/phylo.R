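# Neighbor-joining point estimates and column-resampling bootstrap support.
# The agglomeration itself is ape's NJ (exact on additive metrics); the
# contract layer adds validation, negative-branch clamping and support
# annotation.

#' Neighbor-joining tree from a distance matrix
#'
#' @param d Symmetric, nonnegative distance matrix with zero diagonal
#'   (matrix or `dist`), at least 3 taxa. Additive input distances are
#'   reproduced exactly by path lengths in the result.
#' @param clamp_negative Clamp negative NJ branch lengths to zero (flagged via
#'   the `clamped` attribute).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix", call. = FALSE)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("non-symmetric distance matrix", call. = FALSE)
  if (any(d < -1e-12) || any(abs(diag(d)) > 1e-12))
    stop("distances must be nonnegative with zero diagonal", call. = FALSE)
  tr <- ape::nj(as.dist(d))
  clamped <- FALSE
  if (clamp_negative && any(tr$edge.length < 0)) {
    tr$edge.length[tr$edge.length < 0] <- 0
    clamped <- TRUE
  }
  attr(tr, "clamped") <- clamped
  tr
}

#' Default tree distance: Kimura two-parameter on the nucleotide columns
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @return Distance matrix.
#' @export
k80_distance <- function(aln) {
  m <- do.call(rbind, strsplit(tolower(unlist(aln)), ""))
  rownames(m) <- names(aln)
  as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                          pairwise.deletion = TRUE))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate (replicate seeds derived from the master seed by index, so
#' support is independent of taxon input order), and annotates each internal
#' edge of the point-estimate tree with the percentage of replicates
#' containing that bipartition.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param dist_fun Function mapping such an alignment to a distance matrix;
#'   defaults to [k80_distance()].
#' @param n_reps Number of bootstrap replicates (the analysis default is
#'   1000; tests scale down).
#' @param seed Master seed for the replicate resampling.
#' @return The point-estimate `phylo` tree with `node.label` holding support
#'   percentages (root label empty) and attribute `boot_trees`.
#' @export
bootstrap_support <- function(aln, dist_fun = k80_distance, n_reps = 1000,
                              seed = 1L) {
  stopifnot(n_reps >= 1)
  len <- unique(nchar(aln))
  if (length(len) != 1) stop("alignment rows must have equal length",
                             call. = FALSE)
  if (len < 1) stop("alignment must have at least 1 column", call. = FALSE)
  point <- nj_tree(dist_fun(aln))
  chars <- do.call(rbind, strsplit(unlist(aln), ""))
  rownames(chars) <- names(aln)
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed((seed + r) %% .Machine$integer.max)
    cols <- sample.int(len, len, replace = TRUE)
    rep_aln <- stats::setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                                     collapse = ""), names(aln))
    trees[[r]] <- nj_tree(dist_fun(rep_aln))
  }
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  point$node.label <- as.character(support)
  point$node.label[1] <- ""  # root of the unrooted representation
  attr(point, "boot_trees") <- trees
  point
}
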