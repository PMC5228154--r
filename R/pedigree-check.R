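# Pedigree verification from genotypes: IBS distances, complete-linkage
# clustering, classical MDS, and nearest-neighbour Z-score outlier detection.

#' Pairwise identity-by-state distance matrix
#'
#' For each sample pair, distance = 1 - (mean shared alleles over markers
#' called in both samples) / 2, so identical genotype vectors are at 0 and
#' opposite homozygotes at every marker are at 1. Pairs are compared over
#' their pairwise-complete marker set; a pair with fewer than `min_overlap`
#' shared calls is an error.
#'
#' @param genotypes Samples x markers matrix coded 0/1/2 with `NA` missing.
#' @param min_overlap Minimum shared non-missing markers per pair.
#' @return Symmetric distance matrix (class `ibs_dist`, zero diagonal).
#' @export
ibs_distance <- function(genotypes, min_overlap = 50) {
  n <- nrow(genotypes)
  if (is.null(n) || n < 2) stop_config("need at least two samples")
  g <- genotypes
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0L
  O <- obs %*% t(obs)                      # shared non-missing counts
  if (any(O[upper.tri(O)] < min(min_overlap, ncol(g)))) {
    stop_config("some sample pair shares fewer than %d called markers",
                min(min_overlap, ncol(g)))
  }
  # shared alleles between genotypes a,b (0/1/2) = 2 - |a - b|
  # sum over complete pairs: 2*O - sum|a-b|; with masked entries zeroed,
  # sum|a-b| over complete pairs needs the mask-aware expansion below.
  S <- g0 %*% t(g0)                        # sum a*b
  sq <- (g0 * g0) %*% t(obs)               # sum a^2 over pairs complete in b
  absdiff_sq <- sq + t(sq) - 2 * S         # sum (a-b)^2 over complete pairs
  # |a-b| in {0,1,2}; (a-b)^2 in {0,1,4}; correct the |diff| = 2 pairs
  m2 <- (g0 == 2L) + 0                     # masked entries are never 2
  m0 <- ((g == 0L) & obs) + 0              # observed hom-ref only
  two_count <- m2 %*% t(m0) + m0 %*% t(m2)
  absdiff <- absdiff_sq - 2 * two_count    # 4 -> 2 per opposite-hom marker
  shared <- 2 * O - absdiff
  D <- 1 - shared / (2 * O)
  diag(D) <- 0
  dimnames(D) <- list(rownames(genotypes), rownames(genotypes))
  structure(D, class = c("ibs_dist", "matrix"))
}

#' Complete-linkage clustering of an IBS matrix
#'
#' Agglomerative clustering with the maximum inter-cluster distance
#' criterion, cut at `n_clusters`. With full-sib families, cutting at the
#' family-group count reproduces the pedigree structure, with families that
#' share a sire merging into one cluster.
#'
#' @param ibs An `ibs_dist` matrix.
#' @param n_clusters Number of clusters to cut at.
#' @return Named integer vector of cluster labels.
#' @export
complete_linkage_cluster <- function(ibs, n_clusters) {
  n <- nrow(ibs)
  if (n_clusters > n) stop_config("more clusters requested than samples")
  hc <- stats::hclust(stats::as.dist(ibs), method = "complete")
  stats::cutree(hc, k = n_clusters)
}

#' Classical multidimensional scaling of an IBS matrix
#'
#' Double-centering plus top eigenvectors (classical/Torgerson scaling) of
#' the pairwise IBS distances, as used to visualise family structure.
#'
#' @param ibs An `ibs_dist` matrix.
#' @param dims Output dimensionality.
#' @return Samples x dims coordinate matrix.
#' @export
classical_mds <- function(ibs, dims = 2) {
  if (dims >= nrow(ibs)) stop_config("dims must be smaller than sample count")
  stats::cmdscale(stats::as.dist(ibs), k = dims)
}

#' Nearest-neighbour Z-score outlier detection
#'
#' Scores each sample by its distance to its nearest neighbour, standardises
#' those distances across samples, and flags samples whose standard score
#' exceeds `z_cut` — samples genetically far from everything else
#' (contaminated, mislabelled, or from outside the pedigree).
#'
#' @param ibs An `ibs_dist` matrix (needs at least 3 samples).
#' @param z_cut Z threshold; default 4.
#' @return data.frame `sample_id`, `nn_dist`, `z`, `flagged`.
#' @export
detect_outliers <- function(ibs, z_cut = 4) {
  n <- nrow(ibs)
  if (n < 3) stop_config("need at least 3 samples for outlier detection")
  D <- unclass(ibs)
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  z <- (nn - mean(nn)) / stats::sd(nn)
  data.frame(sample_id = rownames(ibs), nn_dist = nn, z = z,
             flagged = z > z_cut, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pedigree check report
#'
#' Runs the full genotype-based pedigree verification: IBS distances,
#' complete-linkage clusters, 2-D MDS coordinates and outlier flags.
#'
#' @param genotypes Samples x markers matrix.
#' @param n_clusters Cluster count for the tree cut.
#' @param z_cut Outlier Z threshold.
#' @param min_overlap Minimum pairwise-complete markers.
#' @return List `ibs`, `clusters`, `mds`, `outliers`.
#' @export
pedigree_check <- function(genotypes, n_clusters = 3, z_cut = 4,
                           min_overlap = 50) {
  ibs <- ibs_distance(genotypes, min_overlap)
  list(
    ibs = ibs,
    clusters = complete_linkage_cluster(ibs, n_clusters),
    mds = classical_mds(ibs, 2),
    outliers = detect_outliers(ibs, z_cut)
  )
}
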