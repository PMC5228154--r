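# Two-point linkage engine for outbred full-sib families: marker filtering,
# recombination-fraction and LOD estimation, linkage-group formation,
# duplicate collapsing, ordering, Kosambi distances and sex-dimorphism tests.

# ---- transmissions -------------------------------------------------------

# Transmitted-allele matrix for one parent of one family: offspring x
# markers, entries 0/1 (allele transmitted by `g_par`) or NA when the
# parent is homozygous/missing or the transmission is ambiguous
# (both parents heterozygous and the offspring heterozygous).
transmission_matrix <- function(g_off, g_par, g_other, other_hom_only = FALSE) {
  n <- nrow(g_off)
  m <- ncol(g_off)
  t_mat <- matrix(NA_integer_, n, m,
                  dimnames = list(rownames(g_off), colnames(g_off)))
  het <- !is.na(g_par) & g_par == 1L
  if (!any(het)) return(t_mat)
  oth <- g_other
  for (j in which(het)) {
    g <- g_off[, j]
    o <- oth[j]
    if (is.na(o)) next
    t_mat[, j] <- if (o == 0L) {
      ifelse(is.na(g) | g == 2L, NA_integer_, g)
    } else if (o == 2L) {
      ifelse(is.na(g) | g == 0L, NA_integer_, g - 1L)
    } else if (other_hom_only) {
      # double-het markers dropped entirely: resolving them conditions on
      # agreement between the two parents' transmissions, which biases
      # sex-specific recombination estimates toward each other
      NA_integer_
    } else {
      ifelse(is.na(g), NA_integer_,
             ifelse(g == 0L, 0L, ifelse(g == 2L, 1L, NA_integer_)))
    }
  }
  t_mat
}

# All transmission matrices of a dataset: one per family x parent role.
# Returns a list of entries with family_id, role ("dam"/"sire"), sex, T.
build_transmissions <- function(genotypes, pedigree, markers = NULL,
                                other_hom_only = FALSE) {
  if (is.null(markers)) markers <- colnames(genotypes)
  fams <- unique(pedigree$family_id[!pedigree$is_parent])
  out <- list()
  for (fam in fams) {
    off <- pedigree$id[!pedigree$is_parent & pedigree$family_id == fam]
    sire <- unique(pedigree$sire_id[pedigree$family_id == fam &
                                      !pedigree$is_parent])
    dam <- unique(pedigree$dam_id[pedigree$family_id == fam &
                                    !pedigree$is_parent])
    g_off <- genotypes[off, markers, drop = FALSE]
    g_s <- genotypes[sire, markers]
    g_d <- genotypes[dam, markers]
    out[[paste(fam, "dam", sep = ":")]] <- list(
      family_id = fam, role = "dam", sex = "female",
      T = transmission_matrix(g_off, g_d, g_s, other_hom_only))
    out[[paste(fam, "sire", sep = ":")]] <- list(
      family_id = fam, role = "sire", sex = "male",
      T = transmission_matrix(g_off, g_s, g_d, other_hom_only))
  }
  out
}

# ---- pairwise counts -----------------------------------------------------

# Pairwise recombinant/meiosis count matrices from transmission lists.
# Phase within each parent is unknown, so the per-parent recombinant count
# is min(discordant, concordant); LOD uses the pooled MLE r-hat. With
# `fold = FALSE` the transmissions are assumed phase-aligned already (see
# align_and_clean) and discordance is counted directly — the folded count
# is biased low at moderate r when per-parent meiosis counts are small.
two_point_matrices <- function(transmissions, m, fold = TRUE) {
  zero <- matrix(0, m, m)
  acc <- list(R_f = zero, N_f = zero, R_m = zero, N_m = zero,
              R = zero, N = zero)
  for (tr in transmissions) {
    A <- tr$T
    obs <- !is.na(A)
    A[!obs] <- 0L
    storage.mode(A) <- "double"
    obs <- obs + 0
    N <- crossprod(obs)                  # both observed
    S11 <- crossprod(A)                  # both transmitted allele 1
    S1o <- crossprod(A, obs)             # first is 1, second observed
    D <- S1o + t(S1o) - 2 * S11          # discordant transmissions
    Rp <- if (fold) pmin(D, N - D) else D   # phase maximised per parent
    if (tr$sex == "female") {
      acc$R_f <- acc$R_f + Rp
      acc$N_f <- acc$N_f + N
    } else {
      acc$R_m <- acc$R_m + Rp
      acc$N_m <- acc$N_m + N
    }
    acc$R <- acc$R + Rp
    acc$N <- acc$N + N
  }
  rhat <- ifelse(acc$N > 0, acc$R / acc$N, NA_real_)
  # LOD of linkage at the pooled MLE vs independence (r = 0.5)
  t1 <- ifelse(acc$R > 0, acc$R * log10(rhat), 0)
  t2 <- ifelse(acc$N - acc$R > 0, (acc$N - acc$R) * log10(1 - rhat), 0)
  lod <- ifelse(acc$N > 0, t1 + t2 + acc$N * log10(2), 0)
  acc$rhat <- rhat
  acc$rhat_f <- ifelse(acc$N_f > 0, acc$R_f / acc$N_f, NA_real_)
  acc$rhat_m <- ifelse(acc$N_m > 0, acc$R_m / acc$N_m, NA_real_)
  acc$lod <- lod
  acc
}

#' Two-point linkage estimate for one marker pair
#'
#' Estimates female, male and pooled recombination fractions and the LOD
#' score for a marker pair from full-sib families. A meiosis is informative
#' when the transmitting parent is heterozygous and the transmitted allele
#' can be resolved; linkage phase is a per-parent nuisance maximised over
#' (the recombinant count is the smaller of the two phase readings). The
#' pooled estimate caps at 0.5 by construction; a pair with no informative
#' meioses is returned with `NA` estimates and LOD 0.
#'
#' @param m1,m2 Marker names.
#' @param genotypes Individuals x markers matrix (parents included).
#' @param pedigree Pedigree data.frame (`id`, `family_id`, `sire_id`,
#'   `dam_id`, `is_parent`).
#' @return List `r_female`, `r_male`, `r_pooled`, `lod`,
#'   `n_informative_meioses`.
#' @export
estimate_two_point <- function(m1, m2, genotypes, pedigree) {
  tr <- build_transmissions(genotypes, pedigree, markers = c(m1, m2))
  tp <- two_point_matrices(tr, 2L)
  list(r_female = tp$rhat_f[1, 2], r_male = tp$rhat_m[1, 2],
       r_pooled = tp$rhat[1, 2], lod = tp$lod[1, 2],
       n_informative_meioses = tp$N[1, 2])
}

# ---- marker filtering ----------------------------------------------------

#' Segregation distortion chi-square test
#'
#' Pearson chi-square of observed offspring genotype counts against the
#' Mendelian expectation of the cross: 1:1 for a backcross-type
#' AB x AA marker (two classes), 1:2:1 for an intercross AB x AB marker.
#'
#' @param observed_counts Integer vector of genotype-class counts (length 2
#'   for 1:1, length 3 for 1:2:1).
#' @param cross_type `"1:1"` or `"1:2:1"`.
#' @return List `chi2`, `df`, `p`.
#' @export
segregation_chi2 <- function(observed_counts, cross_type = c("1:1", "1:2:1")) {
  cross_type <- match.arg(cross_type)
  n <- sum(observed_counts)
  if (n == 0) stop_config("no observations for segregation test")
  probs <- if (cross_type == "1:1") c(1, 1) / 2 else c(1, 2, 1) / 4
  if (length(observed_counts) != length(probs)) {
    stop_config("expected %d genotype classes for a %s cross",
                length(probs), cross_type)
  }
  e <- n * probs
  chi2 <- sum((observed_counts - e)^2 / e)
  df <- length(probs) - 1
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Filter markers for linkage mapping
#'
#' Applies the per-family quality criteria: a family's data for a marker is
#' usable when the family has at most `max_missing` missing offspring calls
#' and a minor-allele count of at least `min_minor` among offspring alleles;
#' a family is informative when additionally at least one parent is
#' heterozygous. A marker is retained when informative in at least
#' `min_inform_fams` families and shows no significant segregation
#' distortion (smallest per-family Pearson p below `distortion_p` discards
#' it).
#'
#' @param genotypes Individuals x markers matrix (parents included).
#' @param pedigree Pedigree data.frame.
#' @param max_missing Maximum missing offspring calls per family.
#' @param min_minor Minimum per-family minor-allele count.
#' @param min_inform_fams Minimum informative families.
#' @param distortion_p Segregation-distortion significance cut.
#' @return data.frame `marker_id`, `n_informative_families`,
#'   `distortion_chi2` (largest), `distortion_p` (smallest), `retained`.
#' @export
filter_markers <- function(genotypes, pedigree, max_missing = 12,
                           min_minor = 6, min_inform_fams = 2,
                           distortion_p = 0.005) {
  fams <- unique(pedigree$family_id[!pedigree$is_parent])
  if (length(fams) == 0) stop_config("pedigree has no offspring")
  mk <- colnames(genotypes)
  n_inf <- integer(length(mk))
  worst_chi2 <- numeric(length(mk))
  worst_p <- rep(1, length(mk))

  for (fam in fams) {
    off <- pedigree$id[!pedigree$is_parent & pedigree$family_id == fam]
    sire <- unique(pedigree$sire_id[pedigree$family_id == fam &
                                      !pedigree$is_parent])
    dam <- unique(pedigree$dam_id[pedigree$family_id == fam &
                                    !pedigree$is_parent])
    if (!all(c(sire, dam) %in% rownames(genotypes))) {
      stop_config("unknown parent for family %s", fam)
    }
    g <- genotypes[off, , drop = FALSE]
    miss <- colSums(is.na(g))
    called <- colSums(!is.na(g))
    alt <- colSums(g, na.rm = TRUE)
    minor <- pmin(alt, 2 * called - alt)
    g_s <- genotypes[sire, ]
    g_d <- genotypes[dam, ]
    seg <- (!is.na(g_s) & g_s == 1L) | (!is.na(g_d) & g_d == 1L)
    usable <- miss <= max_missing & minor >= min_minor
    inform <- usable & seg
    n_inf <- n_inf + inform

    # segregation distortion within informative families
    both_het <- inform & !is.na(g_s) & g_s == 1L & !is.na(g_d) & g_d == 1L
    one_het <- inform & !both_het
    for (j in which(one_het)) {
      cnt <- table(factor(g[, j], levels = 0:2))
      # backcross: het vs hom offspring segregate 1:1
      obs <- c(cnt[["1"]], sum(cnt) - cnt[["1"]])
      ans <- segregation_chi2(obs, "1:1")
      if (ans$p < worst_p[j]) {
        worst_p[j] <- ans$p
        worst_chi2[j] <- ans$chi2
      }
    }
    for (j in which(both_het)) {
      cnt <- table(factor(g[, j], levels = 0:2))
      ans <- segregation_chi2(as.integer(cnt), "1:2:1")
      if (ans$p < worst_p[j]) {
        worst_p[j] <- ans$p
        worst_chi2[j] <- ans$chi2
      }
    }
  }
  data.frame(
    marker_id = mk,
    n_informative_families = n_inf,
    distortion_chi2 = worst_chi2,
    distortion_p = worst_p,
    retained = n_inf >= min_inform_fams & worst_p >= distortion_p,
    stringsAsFactors = FALSE
  )
}

# ---- linkage groups ------------------------------------------------------

#' Assign markers to linkage groups
#'
#' Forms linkage groups as the connected components of the marker graph
#' whose edges are pairs with LOD at or above `lod_limit`; components
#' smaller than `min_size` are left unassigned (`NA`). Groups are numbered
#' by decreasing size.
#'
#' @param lod Symmetric LOD matrix with marker dimnames.
#' @param lod_limit LOD threshold for an edge.
#' @param min_size Minimum markers per linkage group.
#' @return Named integer vector of LG ids (`NA` = unassigned).
#' @export
separate_chromosomes <- function(lod, lod_limit = 35, min_size = 10) {
  m <- nrow(lod)
  adj <- lod >= lod_limit
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  keep <- which(sizes >= min_size)
  lg <- rep(NA_integer_, m)
  if (length(keep) > 0) {
    rank <- order(sizes[keep], decreasing = TRUE)
    for (k in seq_along(rank)) {
      lg[comp$membership == keep[rank[k]]] <- k
    }
  }
  names(lg) <- rownames(lod)
  lg
}

#' Join singular markers to established linkage groups
#'
#' A singleton joins the linkage group with its best pairwise LOD when that
#' best LOD reaches `lod_limit` and exceeds the second-best group's LOD by
#' at least `lod_diff`.
#'
#' @param lg Assignment vector from [separate_chromosomes()].
#' @param lod LOD matrix over the same markers.
#' @param lod_limit Minimum best-group LOD.
#' @param lod_diff Minimum margin over the second-best group.
#' @return Updated assignment vector.
#' @export
join_singles <- function(lg, lod, lod_limit = 10, lod_diff = 3) {
  lgs <- sort(unique(lg[!is.na(lg)]))
  if (length(lgs) == 0) return(lg)
  for (i in which(is.na(lg))) {
    best <- vapply(lgs, function(k) max(lod[i, which(lg == k)]), numeric(1))
    o <- order(best, decreasing = TRUE)
    top <- best[o[1]]
    second <- if (length(best) > 1) best[o[2]] else -Inf
    if (top >= lod_limit && top - second >= lod_diff) {
      lg[i] <- lgs[o[1]]
    }
  }
  lg
}

# ---- duplicates ----------------------------------------------------------

#' Collapse duplicate and stacked markers
#'
#' Clusters markers of one linkage group whose offspring genotype patterns
#' are identical wherever both are called, allowing a per-pair missing
#' fraction of at most `missing_tol`; clusters are the transitive closure of
#' that relation. The member with the most informative meioses represents
#' its cluster (ties broken by marker id).
#'
#' @param members Marker names of the linkage group.
#' @param genotypes Offspring x markers matrix.
#' @param informativeness Named vector of informative-meiosis counts.
#' @param missing_tol Maximum fraction of offspring with a one-sided missing
#'   call for a pair still considered comparable.
#' @return data.frame `marker_id`, `cluster`, `representative`.
#' @export
collapse_duplicates <- function(members, genotypes, informativeness,
                                missing_tol = 0.05) {
  g <- genotypes[, members, drop = FALSE]
  n <- nrow(g)
  m <- length(members)
  obs <- (!is.na(g)) + 0
  eq <- matrix(0, m, m)
  for (v in 0:2) {
    iv <- (g == v & !is.na(g)) + 0
    eq <- eq + crossprod(iv)
  }
  both <- crossprod(obs)
  conflicts <- both - eq
  onesided <- (crossprod(obs, 1 - obs) + crossprod(1 - obs, obs))
  dup <- conflicts == 0 & onesided / n <= missing_tol
  diag(dup) <- TRUE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(dup, mode = "max"))
  cluster <- comp$membership
  rep_of <- vapply(seq_len(comp$no), function(k) {
    ids <- members[cluster == k]
    inf <- informativeness[ids]
    ids[order(-inf, ids)][1]
  }, character(1))
  data.frame(marker_id = members, cluster = cluster,
             representative = rep_of[cluster], stringsAsFactors = FALSE)
}

# ---- ordering ------------------------------------------------------------

# Path length objective: sum of Kosambi distances over adjacent pairs,
# with r capped just below 0.5 to keep distances finite.
path_length <- function(ord, dmat) {
  sum(dmat[cbind(ord[-length(ord)], ord[-1])])
}

# Greedy chain construction from a seed edge, extending whichever end has
# the closer unplaced marker.
greedy_chain <- function(seed, dmat) {
  m <- nrow(dmat)
  placed <- logical(m)
  path <- seed
  placed[seed] <- TRUE
  while (!all(placed)) {
    left <- path[1]
    right <- path[length(path)]
    open <- which(!placed)
    dl <- dmat[left, open]
    dr <- dmat[right, open]
    if (min(dl) <= min(dr)) {
      nxt <- open[which.min(dl)]
      path <- c(nxt, path)
    } else {
      nxt <- open[which.min(dr)]
      path <- c(path, nxt)
    }
    placed[nxt] <- TRUE
  }
  path
}

# One full 2-opt pass; returns improved order (possibly unchanged).
two_opt <- function(ord, dmat, max_sweeps = 30) {
  n <- length(ord)
  if (n < 4) return(ord)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in 2:(n - 1)) {
      a <- ord[i - 1]
      b <- ord[i]
      js <- (i + 1):n
      c_ <- ord[js]
      d_ <- c(ord[js[-length(js)] + 1], NA)
      cur <- dmat[a, b] + ifelse(is.na(d_), 0, dmat[cbind(c_, d_)])
      new <- dmat[a, c_] + ifelse(is.na(d_), 0, dmat[cbind(b, d_)])
      gain <- cur - new
      j <- which.max(gain)
      if (gain[j] > 1e-12) {
        ord[i:js[j]] <- rev(ord[i:js[j]])
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ord
}

# Spectral seriation: order by the Fiedler vector of the LOD-weighted graph
# Laplacian. LOD decays monotonically with map distance, so the similarity
# matrix has Robinson structure and the second eigenvector recovers the
# global gradient.
spectral_order <- function(lodm) {
  W <- lodm
  W[W < 0] <- 0
  diag(W) <- 0
  L <- diag(rowSums(W)) - W
  ev <- try(eigen(L, symmetric = TRUE), silent = TRUE)
  if (inherits(ev, "try-error")) return(NULL)
  order(ev$vectors[, ncol(W) - 1])
}

# Weighted 1-D least-squares refinement of marker positions. Only mid-range
# pairs (r in [rmin, rmax]) inform positions: closer pairs cannot resolve
# left/right at the genotyping-error floor (they are the stacked markers),
# farther pairs are saturated. Each sweep re-places every marker at the
# inverse-variance-weighted mean of neighbour-implied coordinates, then
# re-sorts.
wls_refine <- function(ord_idx, dmat, rmat, nmat, iters = 25,
                       rmin = 0.05, rmax = 0.4) {
  m <- length(ord_idx)
  if (m < 4) return(ord_idx)
  r <- rmat[ord_idx, ord_idx]
  n <- nmat[ord_idx, ord_idx]
  d <- dmat[ord_idx, ord_idx]
  use <- r >= rmin & r <= rmax & n > 20
  diag(use) <- FALSE
  var_d <- (100 / (1 - 4 * pmin(r, 0.49)^2))^2 *
    pmax(r * (1 - r), 1e-4) / pmax(n, 1)
  w <- ifelse(use, 1 / var_d, 0)
  x <- c(0, cumsum(d[cbind(seq_len(m - 1), 2:m)]))
  for (it in seq_len(iters)) {
    xn <- x
    for (j in seq_len(m)) {
      wj <- w[-j, j]
      if (sum(wj) == 0) next
      s <- sign(x[j] - x[-j])
      s[s == 0] <- 1
      xn[j] <- sum((x[-j] + s * d[-j, j]) * wj) / sum(wj)
    }
    x <- xn
    o <- order(x)
    if (!identical(o, seq_len(m))) {
      x <- x[o]
      r <- r[o, o]
      n <- n[o, o]
      d <- d[o, o]
      w <- w[o, o]
      ord_idx <- ord_idx[o]
    }
  }
  ord_idx
}

#' Order the representative markers of a linkage group
#'
#' Multi-start seriation: one start orders markers by spectral seriation of
#' the LOD graph; the remaining starts grow greedy chains from high-LOD seed
#' pairs, extending whichever end has the nearest unplaced marker, polished
#' by 2-opt segment reversal on the summed adjacent Kosambi distance. Every
#' start is then refined by an iterative 1-D weighted-least-squares placement
#' that positions each marker from its mid-range neighbours (pairs closer
#' than the genotyping-error floor carry no left/right information and are
#' excluded). The start with the smallest weighted stress wins.
#' Deterministic for fixed `seed`.
#'
#' @param reps Marker names to order (>= 2).
#' @param rhat,lod Pairwise recombination-fraction and LOD matrices over
#'   (at least) `reps`.
#' @param nmat Optional informative-meiosis count matrix (defaults to a
#'   constant when absent).
#' @param n_starts Number of seriation starts.
#' @param seed Integer seed for start selection.
#' @param rmin,rmax Recombination-fraction window of pairs that inform the
#'   least-squares placement.
#' @return Character vector: `reps` in map order.
#' @export
order_markers <- function(reps, rhat, lod, nmat = NULL, n_starts = 10,
                          seed = 1L, rmin = 0.05, rmax = 0.4) {
  if (length(reps) < 2) return(reps)
  r <- rhat[reps, reps, drop = FALSE]
  r[is.na(r)] <- 0.499
  dmat <- kosambi(pmin(r, 0.499))
  diag(dmat) <- 0
  l <- lod[reps, reps, drop = FALSE]
  nm <- if (is.null(nmat)) {
    matrix(100, length(reps), length(reps))
  } else {
    nmat[reps, reps, drop = FALSE]
  }
  nm[is.na(nm)] <- 0
  m <- length(reps)
  if (m < 4) {
    # tiny groups: exhaustive over the distinct paths
    perms <- all_permutations(m)
    lens <- vapply(seq_len(nrow(perms)), function(i) {
      path_length(perms[i, ], dmat)
    }, numeric(1))
    return(reps[perms[which.min(lens), ]])
  }
  diag(l) <- -Inf
  edges <- arrayInd(order(l, decreasing = TRUE), dim(l))
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  starts <- list(seq_len(m))   # the incoming arrangement is a candidate
  sp <- spectral_order(l)
  if (!is.null(sp)) starts[[length(starts) + 1]] <- sp
  n_seed <- min(max(n_starts - length(starts), 0), nrow(edges))
  for (k in seq_len(n_seed)) {
    starts[[length(starts) + 1]] <-
      two_opt(greedy_chain(as.integer(edges[k, ]), dmat), dmat)
  }
  with_seed(seed, {
    cands <- unique(lapply(starts, function(s) {
      ord <- wls_refine(s, dmat, r, nm, rmin = rmin, rmax = rmax)
      # canonical orientation so a reversed duplicate collapses
      if (ord[1] > ord[length(ord)]) rev(ord) else ord
    }))
    if (length(cands) == 1) {
      best <- 1L
    } else {
      # consensus: most refined starts converge to the same basin; pick
      # the candidate agreeing best with the others (mean |Kendall tau|
      # medoid), tie-broken by the shorter adjacent-distance path
      rank_of <- lapply(cands, order)
      agree <- vapply(seq_along(cands), function(a) {
        mean(vapply(seq_along(cands)[-a], function(b) {
          abs(stats::cor(rank_of[[a]], rank_of[[b]], method = "kendall"))
        }, numeric(1)))
      }, numeric(1))
      lens <- vapply(cands, path_length, numeric(1), dmat = dmat)
      best <- order(-agree, lens)[1]
    }
    reps[cands[[best]]]
  })
}

all_permutations <- function(m) {
  if (m == 1) return(matrix(1L))
  sub <- all_permutations(m - 1)
  do.call(rbind, lapply(seq_len(m), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Cluster stacked markers along a provisional order
#'
#' Markers closer than the apparent-recombination floor (`stack_r`) cannot
#' be separated by the data — they stack at one genetic position. Walking
#' the provisional order, each marker joins the current stack while its
#' recombination fraction with the stack's last member is at most
#' `stack_r`; otherwise it opens a new stack. The member with the most
#' informative meioses represents each stack.
#'
#' @param ord Marker names in provisional order.
#' @param rhat Pairwise recombination-fraction matrix.
#' @param informativeness Named informative-meiosis counts.
#' @param stack_r Recombination-fraction floor under which markers stack.
#' @return data.frame `marker_id`, `stack`, `representative`.
#' @export
cluster_stacked <- function(ord, rhat, informativeness, stack_r = 0.05) {
  k <- length(ord)
  stack <- integer(k)
  stack[1] <- 1L
  anchor <- 1L
  for (i in seq_len(k - 1)) {
    r <- rhat[ord[anchor], ord[i + 1]]
    if (!is.na(r) && r <= stack_r) {
      stack[i + 1] <- stack[i]
    } else {
      stack[i + 1] <- stack[i] + 1L
      anchor <- i + 1L
    }
  }
  rep_of <- vapply(seq_len(max(stack)), function(s) {
    ids <- ord[stack == s]
    ids[order(-informativeness[ids], ids)][1]
  }, character(1))
  data.frame(marker_id = ord, stack = stack,
             representative = rep_of[stack], stringsAsFactors = FALSE)
}

#' Reinsert collapsed duplicates into an ordered map
#'
#' Places every clustered marker at its representative's position in the
#' final order; duplicates share their representative's genetic position.
#'
#' @param ordered_reps Representatives in map order.
#' @param clusters data.frame from [collapse_duplicates()].
#' @return data.frame `marker_id`, `representative`, `order_index` (shared
#'   within a cluster).
#' @export
reinsert_duplicates <- function(ordered_reps, clusters) {
  idx <- match(clusters$representative, ordered_reps)
  if (anyNA(idx)) stop_config("cluster with unplaced representative")
  out <- clusters[order(idx, clusters$marker_id),
                  c("marker_id", "representative")]
  out$order_index <- match(out$representative, ordered_reps)
  rownames(out) <- NULL
  out
}

# ---- distances and sex dimorphism ---------------------------------------

# Multipoint least-squares map positions along a fixed order. Pairs inside
# a distance window contribute their Haldane-transformed recombination
# estimates (across many small intervals the count-location crossover
# process composes without interference, so the additive long-range
# distance is -50 log(1 - 2r); it agrees with the Kosambi scale in the
# small-interval limit where the final adjacent positions are read off).
# Positions x and a common apparent-distance offset c — the inflation a
# constant genotyping-error rate adds to every pairwise estimate — solve
# d_ij ~ (x_j - x_i) + c by weighted least squares. Weights and the pair
# window are re-derived from the fitted distances over a few iterations:
# weighting or selecting on the observed r-hat itself would correlate with
# its noise and shrink the map. Returns NULL when too few pairs inform the
# fit (small groups fall back to chain counting).
ls_map_positions <- function(ord, rhat, nmat, rmin = 0.03, rmax = 0.35,
                             d_window = c(3, 30), n_iter = 4) {
  n <- length(ord)
  if (n < 3) return(NULL)
  r <- rhat[ord, ord]
  N <- nmat[ord, ord]
  cand <- which(upper.tri(r) & !is.na(r) & r <= 0.45 & N > 20,
                arr.ind = TRUE)
  if (nrow(cand) < n) return(NULL)
  rr <- pmin(r[cand], 0.45)
  d_all <- -50 * log(1 - 2 * rr)
  ii_all <- cand[, 1]
  jj_all <- cand[, 2]
  sel <- rr >= rmin & rr <= rmax
  w_all <- rep(1, nrow(cand))
  x <- NULL
  offset <- 0
  for (it in seq_len(n_iter)) {
    if (sum(sel) < n) break
    ii <- ii_all[sel]
    jj <- jj_all[sel]
    p <- sum(sel)
    # free coordinates for all n markers plus the offset; the translation
    # gauge is fixed by a tiny ridge on the coordinates
    A <- matrix(0, p, n + 1)
    A[cbind(seq_len(p), ii)] <- -1
    A[cbind(seq_len(p), jj)] <- 1
    A[, n + 1] <- 1
    w <- w_all[sel]
    M <- crossprod(A * sqrt(w))
    lam <- 1e-6 * mean(diag(M)[seq_len(n)])
    diag(M)[seq_len(n)] <- diag(M)[seq_len(n)] + lam
    rhs <- crossprod(A, w * d_all[sel])
    fit <- try(solve(M, rhs), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    offset <- fit[n + 1]
    if (is.na(offset) || offset < 0) offset <- 0
    xr <- fit[seq_len(n)]
    # markers that contribute no selected pair sit at the ridge origin;
    # re-place them by interpolation along the order
    has_pair <- tabulate(c(ii, jj), nbins = n) > 0
    if (sum(has_pair) < 2) return(NULL)
    if (!all(has_pair)) {
      known <- which(has_pair)
      xr <- stats::approx(known, xr[known], xout = seq_len(n), rule = 2)$y
    }
    # coordinate orientation is arbitrary; align with the marker order,
    # then enforce monotone positions by isotonic regression
    if (stats::cor(xr, seq_len(n)) < 0) xr <- -xr
    x <- stats::isoreg(seq_len(n), xr)$yf
    x <- x - x[1]
    # model-based weights and window for the next pass
    dfit <- abs(x[jj_all] - x[ii_all]) + offset
    rfit <- pmin(0.5 * (1 - exp(-2 * pmax(dfit, 0.1) / 100)), 0.45)
    w_all <- 1 / ((100 / (1 - 2 * rfit))^2 *
                    pmax(rfit * (1 - rfit), 1e-4) / pmax(N[cand], 1))
    sel <- dfit >= d_window[1] & dfit <= d_window[2]
  }
  if (is.null(x)) return(NULL)
  list(x = x, offset = offset)
}

# Phase-align one parent's transmissions along an ordered marker chain and
# blank singleton double-crossover calls (a transmitted allele disagreeing
# with both flanking observed transmissions, which agree) — the standard
# genotyping-error filter in dense maps, where genuine double crossovers
# inside two adjacent intervals are vanishingly rare.
align_and_clean <- function(T_ord, clean_singletons = TRUE) {
  inf_cols <- which(colSums(!is.na(T_ord)) > 0)
  if (length(inf_cols) < 2) return(T_ord)
  A <- T_ord[, inf_cols, drop = FALSE]
  k <- ncol(A)
  # relative phase by majority: flip marker j+1 when most informative
  # meioses look recombinant in interval (j, j+1)
  flips <- logical(k)
  for (j in seq_len(k - 1)) {
    a <- A[, j]
    b <- A[, j + 1]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok) && sum(a[ok] != b[ok]) > sum(ok) / 2) {
      flips[j + 1] <- TRUE
    }
  }
  cum <- cumsum(flips) %% 2L == 1L
  A[, cum] <- 1L - A[, cum, drop = FALSE]
  if (clean_singletons) {
    has_na <- !stats::complete.cases(A)
    for (i in seq_len(nrow(A))) {
      v <- A[i, ]
      idx <- if (has_na[i]) which(!is.na(v)) else seq_len(k)
      if (length(idx) < 3) next
      x <- v[idx]
      mid <- 2:(length(idx) - 1)
      sing <- x[mid] != x[mid - 1] & x[mid] != x[mid + 1] &
        x[mid - 1] == x[mid + 1]
      if (any(sing)) A[i, idx[mid][sing]] <- NA_integer_
    }
  }
  T_ord[, inf_cols] <- A
  T_ord
}

# Per-interval recombinant (R) and informative-meiosis (N) tallies by sex
# along an ordered chain, from phase-aligned, error-filtered transmissions.
interval_counts <- function(ordered_reps, transmissions,
                            clean_singletons = TRUE) {
  k <- length(ordered_reps)
  out <- list(R_f = numeric(k - 1), N_f = numeric(k - 1),
              R_m = numeric(k - 1), N_m = numeric(k - 1))
  for (tr in transmissions) {
    A <- align_and_clean(tr$T[, ordered_reps, drop = FALSE], clean_singletons)
    a <- A[, -k, drop = FALSE]
    b <- A[, -1, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    rec <- colSums(ok & a != b, na.rm = TRUE)
    n <- colSums(ok)
    # per-interval phase safeguard: flips, if any survive, read as 1 - r
    rec <- pmin(rec, n - rec)
    if (tr$sex == "female") {
      out$R_f <- out$R_f + rec
      out$N_f <- out$N_f + n
    } else {
      out$R_m <- out$R_m + rec
      out$N_m <- out$N_m + n
    }
  }
  out
}

# Sex-specific chain lengths along an ordered group from clean
# transmissions (other parent homozygous, so every offspring call resolves).
# Each parent's informative markers form a nearly complete chain; spans
# between consecutive informative markers give span-level recombination
# fractions (Haldane-composed across the span), summed to a chain length
# and rescaled by the chain's coverage of the pooled map. Returns lengths
# and pooled recombinant tallies per sex.
sex_chain_lengths <- function(ord, transmissions, transmissions_clean,
                              x_avg) {
  n <- length(ord)
  acc <- list(
    female = list(ii = integer(0), jj = integer(0), d = numeric(0),
                  N = numeric(0), rec = 0, nm = 0),
    male = list(ii = integer(0), jj = integer(0), d = numeric(0),
                N = numeric(0), rec = 0, nm = 0)
  )
  for (idx in seq_along(transmissions)) {
    tr <- transmissions[[idx]]
    # spans are counted raw on the clean (other-parent-homozygous) markers,
    # whose resolution carries no selection bias; the constant inflation a
    # genotyping-error rate adds to every span is absorbed by the offset of
    # the least-squares fit below
    A <- align_and_clean(tr$T[, ord, drop = FALSE], clean_singletons = FALSE)
    clean_mask <- !is.na(transmissions_clean[[idx]]$T[, ord, drop = FALSE])
    A[!clean_mask] <- NA_integer_
    inf_cols <- which(colSums(!is.na(A)) > 0)
    if (length(inf_cols) < 2) next
    B <- A[, inf_cols, drop = FALSE]
    a <- B[, -ncol(B), drop = FALSE]
    b <- B[, -1, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    D <- colSums(ok & a != b, na.rm = TRUE)
    N <- colSums(ok)
    D <- pmin(D, N - D)
    use <- which(N >= 20)
    if (length(use) == 0) next
    r_raw <- pmin(D[use] / N[use], 0.45)
    s <- acc[[tr$sex]]
    s$ii <- c(s$ii, inf_cols[use])
    s$jj <- c(s$jj, inf_cols[use + 1])
    s$d <- c(s$d, -50 * log(1 - 2 * r_raw))
    s$N <- c(s$N, N[use])
    # per-meiosis recombinant classification for the sex-dimorphism test:
    # a meiosis is recombinant when its error-filtered clean chain shows at
    # least one transition
    Bc <- B
    for (i in seq_len(nrow(Bc))) {
      v <- Bc[i, ]
      idx2 <- which(!is.na(v))
      if (length(idx2) < 3) next
      x2 <- v[idx2]
      mid <- 2:(length(idx2) - 1)
      sing <- x2[mid] != x2[mid - 1] & x2[mid] != x2[mid + 1] &
        x2[mid - 1] == x2[mid + 1]
      if (any(sing)) Bc[i, idx2[mid][sing]] <- NA_integer_
    }
    a2 <- Bc[, -ncol(Bc), drop = FALSE]
    b2 <- Bc[, -1, drop = FALSE]
    trans <- rowSums(!is.na(a2) & !is.na(b2) & a2 != b2, na.rm = TRUE)
    counted <- rowSums(!is.na(Bc)) >= 2
    s$rec <- s$rec + sum(trans[counted] > 0)
    s$nm <- s$nm + sum(counted)
    acc[[tr$sex]] <- s
  }
  span_total <- max(x_avg) - min(x_avg)
  lapply(acc, function(s) {
    len <- NA_real_
    if (length(s$d) >= 5 && span_total > 0) {
      beta <- template_scale(x_avg[s$jj] - x_avg[s$ii], s$d, s$N)
      if (!is.na(beta)) len <- beta * span_total
    }
    list(length = len, rec = s$rec, n = s$nm)
  })
}

# Scale of one sex's map relative to the pooled sex-average template:
# weighted regression of observed span distances on the template gaps,
# d ~ beta * gap + c, where the intercept absorbs the constant inflation
# genotyping error adds to every span. Weights are re-derived from fitted
# values (weighting on the observed distances themselves would shrink).
template_scale <- function(gap, d, N, n_iter = 3) {
  keep <- gap > 0.5
  if (sum(keep) < 5) return(NA_real_)
  gap <- gap[keep]
  d <- d[keep]
  N <- N[keep]
  w <- rep(1, length(d))
  beta <- NA_real_
  for (it in seq_len(n_iter)) {
    mg <- sum(w * gap) / sum(w)
    md <- sum(w * d) / sum(w)
    beta <- sum(w * (gap - mg) * (d - md)) / sum(w * (gap - mg)^2)
    cc <- md - beta * mg
    if (cc < 0) {
      # no intercept: pure proportionality
      beta <- sum(w * gap * d) / sum(w * gap^2)
      cc <- 0
    }
    dfit <- pmax(beta * gap + cc, 0.5)
    rfit <- pmin(0.5 * (1 - exp(-2 * dfit / 100)), 0.45)
    w <- 1 / ((100 / (1 - 2 * rfit))^2 *
                pmax(rfit * (1 - rfit), 1e-4) / pmax(N, 1))
  }
  if (!is.finite(beta) || beta < 0) NA_real_ else beta
}

#' Genetic distances along an ordered linkage group
#'
#' Computes female, male and sex-average adjacent recombination fractions
#' between consecutive representatives and accumulates Kosambi distances
#' from the start of the group. Recombinants are counted on phase-aligned
#' transmission chains with singleton double-crossover calls treated as
#' genotyping error (see Details); the sex-average uses the
#' meiosis-count-weighted recombinant fraction. An adjacent pair with no
#' informative meioses in a sex contributes a zero-length gap in that sex,
#' with a warning.
#'
#' @param ordered_reps Representatives in map order.
#' @param transmissions Transmission list from the fitted families (one
#'   entry per family x parent, matrices with marker colnames).
#' @param clean_singletons Filter singleton double-crossover calls?
#' @return data.frame `marker_id`, `cM_avg`, `cM_female`, `cM_male`, with
#'   the per-interval tallies in `attr(, "intervals")`.
#' @export
compute_map_distances <- function(ordered_reps, transmissions,
                                  clean_singletons = TRUE) {
  ic <- interval_counts(ordered_reps, transmissions, clean_singletons)
  rf <- ic$R_f / ic$N_f
  rm_ <- ic$R_m / ic$N_m
  ra <- (ic$R_f + ic$R_m) / (ic$N_f + ic$N_m)
  if (anyNA(rf) || anyNA(rm_)) {
    warning("adjacent pair without informative meioses in one sex; zero gap used")
    rf[is.na(rf)] <- 0
    rm_[is.na(rm_)] <- 0
    ra[is.na(ra)] <- 0
  }
  out <- data.frame(
    marker_id = ordered_reps,
    cM_avg = c(0, cumsum(kosambi(pmin(ra, 0.499)))),
    cM_female = c(0, cumsum(kosambi(pmin(rf, 0.499)))),
    cM_male = c(0, cumsum(kosambi(pmin(rm_, 0.499)))),
    stringsAsFactors = FALSE
  )
  attr(out, "intervals") <- ic
  out
}

#' Sex-dimorphism G-test per linkage group
#'
#' For each linkage group, pools recombinant and non-recombinant
#' adjacent-interval meioses by parental sex into a 2x2 table and computes
#' the likelihood-ratio statistic G = 2 sum O log(O/E) with one degree of
#' freedom, plus the female:male map-length ratio.
#'
#' @param map A `genetic_map` (or its `lg_tables` component).
#' @return data.frame per LG: recombinant counts, `G`, `p`, `length_female`,
#'   `length_male`, `fm_ratio` (NA when the male length is zero).
#' @export
sex_difference_gtest <- function(map) {
  tabs <- if (inherits(map, "genetic_map")) map$lg_tables else map
  out <- lapply(names(tabs), function(lg) {
    t2 <- tabs[[lg]]
    obs <- matrix(c(t2$rec_f, t2$nonrec_f, t2$rec_m, t2$nonrec_m), 2,
                  dimnames = list(c("rec", "nonrec"), c("female", "male")))
    g_stat <- 0
    p <- 1
    if (all(rowSums(obs) > 0) && all(colSums(obs) > 0)) {
      e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
      nz <- obs > 0
      g_stat <- 2 * sum(obs[nz] * log(obs[nz] / e[nz]))
      p <- stats::pchisq(g_stat, df = 1, lower.tail = FALSE)
    }
    data.frame(lg = lg, rec_f = t2$rec_f, nonrec_f = t2$nonrec_f,
               rec_m = t2$rec_m, nonrec_m = t2$nonrec_m,
               G = g_stat, p = p,
               length_female = t2$length_female,
               length_male = t2$length_male,
               fm_ratio = if (t2$length_male > 0) {
                 t2$length_female / t2$length_male
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# ---- the fit -------------------------------------------------------------

#' Build a genetic linkage map from full-sib family genotypes
#'
#' The package's central fit: filters markers, estimates all two-point
#' recombination fractions and LOD scores, forms linkage groups, joins
#' singletons, collapses duplicate/stacked markers, orders representatives
#' in two rounds of multi-start seriation, reinserts duplicates and computes
#' sex-average and sex-specific Kosambi distances.
#'
#' @param genotypes Individuals x markers matrix (parents included), coded
#'   0/1/2 with `NA` missing.
#' @param pedigree Pedigree data.frame (`id`, `family_id`, `sire_id`,
#'   `dam_id`, `sex`, `is_parent`).
#' @param lod_limit,min_lg_size Linkage-group formation parameters.
#' @param join_lod,join_diff Singleton-joining parameters.
#' @param max_missing,min_minor,min_inform_fams,distortion_p Marker-filter
#'   parameters.
#' @param missing_tol Duplicate-collapse missing tolerance.
#' @param stack_r Recombination floor under which ordered markers are
#'   treated as one stacked position (about the apparent-recombination rate
#'   a one-percent genotyping-error rate induces).
#' @param n_starts Ordering starts per round.
#' @param seed Integer seed for ordering.
#' @return Object of class `genetic_map`: list with `map` (per-marker
#'   data.frame: `marker_id`, `lg`, `order_index`, `cM_avg`, `cM_female`,
#'   `cM_male`, `unique_pos_id`, `representative`), `summary` (per-LG
#'   table), `gtest`, `filter`, `lg_assignment`, and `call`.
#' @export
build_linkage_map <- function(genotypes, pedigree,
                              lod_limit = 35, min_lg_size = 10,
                              join_lod = 10, join_diff = 3,
                              max_missing = 12, min_minor = 6,
                              min_inform_fams = 2, distortion_p = 0.005,
                              missing_tol = 0.05, stack_r = 0.05,
                              n_starts = 10, seed = 17L) {
  cl <- match.call()
  flt <- filter_markers(genotypes, pedigree, max_missing, min_minor,
                        min_inform_fams, distortion_p)
  retained <- flt$marker_id[flt$retained]
  if (length(retained) < 2) stop_config("fewer than 2 markers retained")

  tr <- build_transmissions(genotypes, pedigree, markers = retained)
  tr_clean <- build_transmissions(genotypes, pedigree, markers = retained,
                                  other_hom_only = TRUE)
  tp <- two_point_matrices(tr, length(retained))
  for (nm in names(tp)) {
    dimnames(tp[[nm]]) <- list(retained, retained)
  }

  lg <- separate_chromosomes(tp$lod, lod_limit, min_lg_size)
  lg <- join_singles(lg, tp$lod, join_lod, join_diff)

  inform <- stats::setNames(colSums(do.call(rbind, lapply(tr, function(x) {
    colSums(!is.na(x$T))
  }))), retained)
  off <- pedigree$id[!pedigree$is_parent]
  g_off <- genotypes[off, retained, drop = FALSE]

  lgs <- sort(unique(lg[!is.na(lg)]))
  map_rows <- list()
  lg_tables <- list()
  summary_rows <- list()
  for (k in lgs) {
    members <- names(lg)[!is.na(lg) & lg == k]
    clusters <- collapse_duplicates(members, g_off, inform, missing_tol)
    reps <- unique(clusters$representative)
    # round 1: order exact-duplicate representatives, then cluster stacked
    # markers (inseparable at the apparent-recombination floor)
    ord1 <- order_markers(reps, tp$rhat, tp$lod, tp$N, n_starts,
                          seed = child_seed(seed, 10 * k + 1))
    stacks <- cluster_stacked(ord1, tp$rhat, inform, stack_r)
    stack_reps <- unique(stacks$representative)
    # round 2: re-order the stack representatives after duplicate filtering
    ord2 <- if (length(stack_reps) >= 2) {
      order_markers(stack_reps, tp$rhat, tp$lod, tp$N, n_starts,
                    seed = child_seed(seed, 10 * k + 2),
                    rmin = 0.03, rmax = 0.4)
    } else {
      stack_reps
    }
    # chain duplicate -> exact representative -> stack representative
    chain <- clusters
    chain$representative <-
      stacks$representative[match(chain$representative, stacks$marker_id)]
    full <- reinsert_duplicates(ord2, chain)
    # sex-average positions: multipoint least squares with an error-floor
    # offset; chain counting is the small-group fallback
    ls_a <- ls_map_positions(ord2, tp$rhat, tp$N)
    dist <- suppressWarnings(compute_map_distances(ord2, tr))
    if (!is.null(ls_a)) dist$cM_avg <- ls_a$x
    # sex-specific lengths from clean-transmission chain counting (other
    # parent homozygous, so no resolution bias); positions scale the
    # sex-average map, mirroring the simulated uniform sex dimorphism
    sx <- sex_chain_lengths(ord2, tr, tr_clean, dist$cM_avg)
    span_a <- max(dist$cM_avg)
    scale_f <- if (!is.na(sx$female$length) && span_a > 0) {
      sx$female$length / span_a
    } else {
      1
    }
    scale_m <- if (!is.na(sx$male$length) && span_a > 0) {
      sx$male$length / span_a
    } else {
      1
    }
    dist$cM_female <- dist$cM_avg * scale_f
    dist$cM_male <- dist$cM_avg * scale_m
    di <- match(full$representative, dist$marker_id)
    full$lg <- k
    full$cM_avg <- dist$cM_avg[di]
    full$cM_female <- dist$cM_female[di]
    full$cM_male <- dist$cM_male[di]
    full$unique_pos_id <- as.integer(factor(full$cM_avg,
                                            levels = unique(dist$cM_avg)))
    map_rows[[as.character(k)]] <- full

    # clean recombinant tallies for the sex-dimorphism G-test
    lg_tables[[as.character(k)]] <- list(
      rec_f = sx$female$rec, nonrec_f = sx$female$n - sx$female$rec,
      rec_m = sx$male$rec, nonrec_m = sx$male$n - sx$male$rec,
      length_female = max(dist$cM_female),
      length_male = max(dist$cM_male)
    )
    n_unique <- length(unique(dist$cM_avg))
    summary_rows[[as.character(k)]] <- data.frame(
      lg = k, n_markers = nrow(full), n_unique = n_unique,
      length_avg = max(dist$cM_avg),
      length_female = max(dist$cM_female),
      length_male = max(dist$cM_male),
      interval_avg = max(dist$cM_avg) / n_unique,
      stringsAsFactors = FALSE
    )
  }
  map_df <- do.call(rbind, map_rows)
  rownames(map_df) <- NULL
  summary_df <- do.call(rbind, summary_rows)
  rownames(summary_df) <- NULL
  obj <- structure(
    list(map = map_df, summary = summary_df, lg_tables = lg_tables,
         filter = flt, lg_assignment = lg, call = cl),
    class = "genetic_map"
  )
  obj$gtest <- sex_difference_gtest(obj)
  obj
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic linkage map: %d linkage group%s, %s markers (%s unique positions)\n",
              nrow(x$summary), if (nrow(x$summary) == 1) "" else "s",
              format(nrow(x$map), big.mark = ","),
              format(sum(x$summary$n_unique), big.mark = ",")))
  cat(sprintf("  sex-average length %.1f cM; female %.1f cM; male %.1f cM (F:M %.2f)\n",
              sum(x$summary$length_avg), sum(x$summary$length_female),
              sum(x$summary$length_male),
              sum(x$summary$length_female) / sum(x$summary$length_male)))
  invisible(x)
}

#' @export
summary.genetic_map <- function(object, ...) {
  s <- object$summary
  s$fm_ratio <- object$gtest$fm_ratio[match(s$lg, object$gtest$lg)]
  s$g_p <- object$gtest$p[match(s$lg, object$gtest$lg)]
  class(s) <- c("summary.genetic_map", "data.frame")
  s
}

#' @export
print.summary.genetic_map <- function(x, ...) {
  cat("Per-linkage-group map summary\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.genetic_map <- function(x, sex = c("avg", "female", "male"), ...) {
  sex <- match.arg(sex)
  col <- paste0("cM_", sex)
  graphics::plot(x$map$lg + stats::runif(nrow(x$map), -0.3, 0.3),
                 x$map[[col]],
                 pch = 16, cex = 0.3, col = "steelblue",
                 xlab = "Linkage group", ylab = sprintf("Position (cM, %s)", sex),
                 main = "Genetic linkage map", ...)
  invisible(x)
}
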