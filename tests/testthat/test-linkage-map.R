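test_that("segregation chi-square matches the closed form", {
  expect_equal(segregation_chi2(c(30, 30), "1:1")$chi2, 0)
  expect_equal(segregation_chi2(c(30, 30), "1:1")$p, 1)
  expect_equal(segregation_chi2(c(25, 50, 25), "1:2:1")$chi2, 0)
  ans <- segregation_chi2(c(40, 20), "1:1")
  expect_equal(ans$chi2, (40 - 30)^2 / 30 + (20 - 30)^2 / 30)
  expect_equal(ans$chi2, 6.667, tolerance = 1e-3)
  expect_equal(ans$p, pchisq(20 / 3, 1, lower.tail = FALSE))
  expect_equal(round(ans$p, 4), 0.0098)
  ans2 <- segregation_chi2(c(90, 30), "1:1")
  expect_equal(ans2$chi2, 30)
  expect_lt(ans2$p, 0.005)
  expect_error(segregation_chi2(c(0, 0), "1:1"), "no observations")
  expect_error(segregation_chi2(c(10, 10, 10), "1:1"), "classes")
})

test_that("marker filter applies missing, minor-count and distortion rules", {
  cfg <- true_map_config(1, 50, 40, genotyping_error_rate = 0,
                         missing_rate = 0, seed = 71)
  sim <- simulate_families(cfg, default_pedigree_spec(c(60, 60, 60, 60)),
                           seed = 72)
  g <- sim$genotypes
  ped <- sim$pedigree
  base <- filter_markers(g, ped, max_missing = 12, min_minor = 6)
  # plant 13 missing calls in one family at the first retained marker
  mk <- base$marker_id[base$retained][1]
  off1 <- ped$id[!ped$is_parent & ped$family_id == "F01"]
  g2 <- g
  g2[off1[1:13], mk] <- NA
  f2 <- filter_markers(g2, ped, max_missing = 12, min_minor = 6)
  expect_equal(f2$n_informative_families[f2$marker_id == mk],
               base$n_informative_families[base$marker_id == mk] - 1L)
  # requiring more informative families than exist drops everything
  f3 <- filter_markers(g, ped, min_inform_fams = 5)
  expect_false(any(f3$retained))
  # a heavily distorted marker is eliminated
  g4 <- g
  # force 90:30-style distortion in every family by rewriting offspring
  for (fam in unique(ped$family_id[!ped$is_parent])) {
    off <- ped$id[!ped$is_parent & ped$family_id == fam]
    g4[off, mk] <- rep(c(1L, 0L), c(55, 5))
  }
  g4["S01", mk] <- 1L
  g4["D01", mk] <- 0L
  f4 <- filter_markers(g4, ped)
  expect_false(f4$retained[f4$marker_id == mk])
  expect_lt(f4$distortion_p[f4$marker_id == mk], 0.005)
  expect_error(filter_markers(g[-(1:2), ], ped), "unknown parent|subscript")
})

test_that("two-point estimates match counts, the grid oracle and the LOD closed form", {
  # fully linked pair, 100 meioses: LOD = 100 log10(2)
  d <- make_pair_data(rep(0:1, 50), rep(0:1, 50))
  tp <- estimate_two_point("mA", "mB", d$genotypes, d$pedigree)
  expect_equal(tp$r_pooled, 0)
  expect_equal(tp$n_informative_meioses, 100)
  expect_equal(tp$lod, 100 * log10(2), tolerance = 1e-12)

  # known recombinant count
  pair <- simulate_pair(0.1, 480, seed = 73)
  d2 <- make_pair_data(pair$t1, pair$t2)
  tp2 <- estimate_two_point("mA", "mB", d2$genotypes, d2$pedigree)
  r_count <- min(pair$n_rec, 480 - pair$n_rec) / 480
  expect_equal(tp2$r_pooled, r_count, tolerance = 1e-12)
  expect_equal(tp2$r_female, r_count, tolerance = 1e-12)
  expect_true(is.na(tp2$r_male))
  # brute-force likelihood grid oracle (phase chosen by the data)
  grid <- seq(1e-4, 0.5, by = 1e-4)
  R <- min(pair$n_rec, 480 - pair$n_rec)
  ll <- R * log10(grid) + (480 - R) * log10(1 - grid)
  expect_equal(tp2$r_pooled, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(tp2$lod, max(ll) - 480 * log10(0.5), tolerance = 1e-3)

  # independent markers: r-hat near 0.5, LOD near 0
  pair3 <- simulate_pair(0.5, 2000, seed = 74)
  d3 <- make_pair_data(pair3$t1, pair3$t2)
  tp3 <- estimate_two_point("mA", "mB", d3$genotypes, d3$pedigree)
  expect_gt(tp3$r_pooled, 0.45)
  expect_lt(tp3$lod, 1)
})

test_that("linkage groups form by LOD components with a size floor", {
  # two blocks of tightly linked markers, no cross-linkage
  lod <- matrix(0, 25, 25,
                dimnames = list(sprintf("m%02d", 1:25), sprintf("m%02d", 1:25)))
  lod[1:12, 1:12] <- 50
  lod[13:24, 13:24] <- 50
  diag(lod) <- 0
  lg <- separate_chromosomes(lod, lod_limit = 35, min_size = 10)
  expect_equal(length(unique(na.omit(lg))), 2L)
  expect_true(all(lg[1:12] == lg[1]))
  expect_true(all(lg[13:24] == lg[13]))
  expect_true(is.na(lg[25]))
  # a component smaller than min_size stays unassigned
  lod9 <- matrix(50, 9, 9, dimnames = list(sprintf("x%d", 1:9),
                                           sprintf("x%d", 1:9)))
  diag(lod9) <- 0
  expect_true(all(is.na(separate_chromosomes(lod9, 35, 10))))
  # threshold above every edge gives no groups
  expect_true(all(is.na(separate_chromosomes(lod, lod_limit = 100))))
})

test_that("singleton joining honours both LOD cuts", {
  lod <- matrix(0, 12, 12,
                dimnames = list(sprintf("m%02d", 1:12), sprintf("m%02d", 1:12)))
  lod[1:5, 1:5] <- 40
  lod[6:10, 6:10] <- 40
  diag(lod) <- 0
  lg <- separate_chromosomes(lod, lod_limit = 35, min_size = 3)
  # marker 11: best 12 vs second 8 -> joined; marker 12: best 12, second 10 -> not
  lod["m11", 1:5] <- lod[1:5, "m11"] <- 12
  lod["m11", 6:10] <- lod[6:10, "m11"] <- 8
  lod["m12", 1:5] <- lod[1:5, "m12"] <- 12
  lod["m12", 6:10] <- lod[6:10, "m12"] <- 10
  lg2 <- join_singles(lg, lod, lod_limit = 10, lod_diff = 3)
  expect_equal(lg2[["m11"]], lg2[["m01"]])
  expect_true(is.na(lg2[["m12"]]))
})

test_that("duplicate collapsing matches pairwise comparison plus closure", {
  g <- matrix(c(
    0L, 0L, 1L, 2L, 1L, 0L,
    0L, 0L, 1L, 2L, 1L, 0L,
    0L, NA, 1L, 2L, 1L, 0L,
    0L, 1L, 0L, 2L, 1L, 0L,
    2L, 2L, 0L, 1L, 0L, 2L
  ), nrow = 6)
  colnames(g) <- sprintf("d%d", 1:5)
  rownames(g) <- sprintf("o%d", 1:6)
  inform <- stats::setNames(c(10, 9, 8, 7, 6), colnames(g))
  cl <- collapse_duplicates(colnames(g), g, inform, missing_tol = 0.2)
  # d1 == d2; d3 identical up to one missing entry; d4 conflicts at row 2
  expect_equal(cl$representative[cl$marker_id == "d1"],
               cl$representative[cl$marker_id == "d2"])
  expect_equal(cl$representative[cl$marker_id == "d3"],
               cl$representative[cl$marker_id == "d1"])
  expect_false(cl$representative[cl$marker_id == "d4"] ==
                 cl$representative[cl$marker_id == "d1"])
  # representative carries the most informative meioses
  expect_equal(unique(cl$representative[cl$marker_id %in% c("d1", "d2", "d3")]),
               "d1")
  # with a tight missing tolerance the one-sided missing pair splits
  cl2 <- collapse_duplicates(colnames(g), g, inform, missing_tol = 0.05)
  expect_false(cl2$representative[cl2$marker_id == "d3"] ==
                 cl2$representative[cl2$marker_id == "d1"])
})

test_that("marker ordering recovers small configurations exactly", {
  # 3 markers with additive r-hat: order must be A-B-C (or its reverse)
  r <- matrix(c(0, 0.05, 0.10,
                0.05, 0, 0.05,
                0.10, 0.05, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  lod <- 10 * (1 - r)
  dimnames(lod) <- dimnames(r)
  ord <- order_markers(c("A", "B", "C"), r, lod, seed = 75)
  expect_true(identical(ord, c("A", "B", "C")) ||
                identical(ord, c("C", "B", "A")))
  expect_identical(order_markers("A", r, lod), "A")
})

test_that("duplicate reinsertion restores counts and shared positions", {
  clusters <- data.frame(
    marker_id = sprintf("m%02d", 1:40),
    cluster = rep(1:10, each = 4),
    representative = rep(sprintf("m%02d", seq(1, 40, by = 4)), each = 4),
    stringsAsFactors = FALSE
  )
  reps <- sprintf("m%02d", seq(1, 40, by = 4))
  full <- reinsert_duplicates(reps, clusters)
  expect_equal(nrow(full), 40L)
  expect_equal(length(unique(full$order_index)), 10L)
  expect_true(all(table(full$order_index) == 4))
  expect_error(reinsert_duplicates(reps[-1], clusters), "unplaced")
})

test_that("map distances accumulate Kosambi over adjacent fractions", {
  # uniform r = 0.0196 over 51 markers: total ~ 50 x kosambi(0.0196)
  n_mk <- 51
  n_off <- 4000
  withr::with_seed(76, {
    t_mat <- matrix(0L, n_off, n_mk)
    t_mat[, 1] <- rbinom(n_off, 1, 0.5)
    for (j in 2:n_mk) {
      rec <- rbinom(n_off, 1, 0.0196)
      t_mat[, j] <- (t_mat[, j - 1] + rec) %% 2L
    }
  })
  colnames(t_mat) <- sprintf("m%02d", 1:n_mk)
  tr <- list(list(family_id = "F1", role = "dam", sex = "female", T = t_mat),
             list(family_id = "F1", role = "sire", sex = "male",
                  T = t_mat[0, , drop = FALSE]))
  dist <- suppressWarnings(
    compute_map_distances(colnames(t_mat), tr, clean_singletons = FALSE))
  expect_equal(max(dist$cM_female), 50 * kosambi(0.0196), tolerance = 0.15)
  expect_true(all(diff(dist$cM_female) >= 0))
  # all-zero recombination gives length zero
  t0 <- matrix(0L, 50, 5, dimnames = list(NULL, sprintf("z%d", 1:5)))
  tr0 <- list(list(family_id = "F1", role = "dam", sex = "female", T = t0))
  d0 <- suppressWarnings(compute_map_distances(colnames(t0), tr0))
  expect_equal(max(d0$cM_female), 0)
})

test_that("G statistic matches the direct likelihood-ratio formula", {
  tabs <- list(lg1 = list(rec_f = 80, nonrec_f = 920, rec_m = 50,
                          nonrec_m = 950, length_female = 10,
                          length_male = 7))
  out <- sex_difference_gtest(tabs)
  obs <- matrix(c(80, 920, 50, 950), 2)
  e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  g_direct <- 2 * sum(obs * log(obs / e))
  expect_equal(out$G, g_direct, tolerance = 1e-9)
  expect_equal(out$p, pchisq(g_direct, 1, lower.tail = FALSE))
  expect_equal(out$fm_ratio, 10 / 7)
  # identical sexes: G = 0, ratio 1
  tabs0 <- list(lg1 = list(rec_f = 50, nonrec_f = 950, rec_m = 50,
                           nonrec_m = 950, length_female = 7,
                           length_male = 7))
  out0 <- sex_difference_gtest(tabs0)
  expect_equal(out0$G, 0, tolerance = 1e-12)
  expect_equal(out0$fm_ratio, 1)
  # random tables against the oracle
  withr::with_seed(77, {
    for (i in 1:20) {
      tt <- list(x = list(rec_f = sample(10:100, 1),
                          nonrec_f = sample(500:1000, 1),
                          rec_m = sample(10:100, 1),
                          nonrec_m = sample(500:1000, 1),
                          length_female = 1, length_male = 1))
      o <- sex_difference_gtest(tt)
      obs <- matrix(c(tt$x$rec_f, tt$x$nonrec_f, tt$x$rec_m, tt$x$nonrec_m), 2)
      e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
      expect_equal(o$G, 2 * sum(obs * log(obs / e)), tolerance = 1e-9)
    }
  })
})

test_that("stacked-marker clustering walks the order with an anchor", {
  r <- matrix(0.5, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  r["a", "b"] <- r["b", "a"] <- 0.01
  r["a", "c"] <- r["c", "a"] <- 0.04
  r["c", "d"] <- r["d", "c"] <- 0.2
  r["d", "e"] <- r["e", "d"] <- 0.01
  inform <- stats::setNames(c(5, 9, 7, 3, 8), letters[1:5])
  st <- cluster_stacked(letters[1:5], r, inform, stack_r = 0.05)
  # a,b,c stack together (both within 0.05 of anchor a); d opens a new stack
  expect_equal(st$stack, c(1L, 1L, 1L, 2L, 2L))
  # representative is the most informative member
  expect_equal(unique(st$representative[st$stack == 1]), "b")
})
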