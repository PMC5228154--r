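test_that("simulated genome hits requested composition and is reproducible", {
  g <- simulate_genome(50, 1e6, genic_fraction = 0.3, repeat_fraction = 0.1,
                       seed = 1)
  tot <- sum(g$scaffolds$length)
  expect_equal(tot, 1e6)
  genic_frac <- sibmap:::interval_bases(g$genic_intervals) / tot
  rep_frac <- sibmap:::interval_bases(g$repeat_intervals) / tot
  expect_gt(genic_frac, 0.28)
  expect_lt(genic_frac, 0.32)
  expect_gt(rep_frac, 0.08)
  expect_lt(rep_frac, 0.12)
  # intervals lie within scaffolds and genic intervals do not overlap
  for (s in g$scaffolds$scaffold_id) {
    m <- g$genic_intervals[[s]]
    if (nrow(m) == 0) next
    L <- g$scaffolds$length[g$scaffolds$scaffold_id == s]
    expect_true(all(m[, "start"] >= 1 & m[, "end"] <= L))
    expect_true(all(m[, "start"] <= m[, "end"]))
    if (nrow(m) > 1) expect_true(all(m[-1, "start"] > m[-nrow(m), "end"]))
  }
  g2 <- simulate_genome(50, 1e6, genic_fraction = 0.3, repeat_fraction = 0.1,
                        seed = 1)
  expect_identical(g, g2)

  g0 <- simulate_genome(1, 1e4, genic_fraction = 0, repeat_fraction = 0,
                        seed = 7)
  expect_equal(nrow(g0$scaffolds), 1L)
  expect_equal(nrow(g0$genic_intervals[[1]]), 0L)
  expect_error(simulate_genome(0, 1e4), "positive")
})

test_that("variant pool density, composition flags and determinism hold", {
  g <- simulate_genome(20, 1e6, seed = 3)
  pool <- simulate_variant_pool(g, density_per_kb = 1, seed = 4)
  # Poisson +-3 sigma around 1000 expected, minus the MAF floor cull
  expect_gt(nrow(pool), 1000 - 3 * sqrt(1000) - 100)
  expect_lt(nrow(pool), 1000 * 1.1 + 3 * sqrt(1000))
  # every SNP clears the discovery floor in some population or pooled
  fm <- as.matrix(pool[, grep("^freq_", names(pool))])
  maf <- pmin(fm, 1 - fm)
  pooled <- rowMeans(fm)
  expect_true(all(apply(maf, 1, max) >= 0.05 |
                    pmin(pooled, 1 - pooled) >= 0.05))
  # tri-allelic fraction within binomial 99% bounds of the 3% default
  n_tri <- sum(grepl(",", pool$alt, fixed = TRUE))
  bounds <- qbinom(c(0.005, 0.995), nrow(pool), 0.03)
  expect_gte(n_tri, bounds[1])
  expect_lte(n_tri, bounds[2])
  # planted close neighbours exist for the adjacency filter to act on
  byscf <- split(pool$pos, pool$scaffold_id)
  gaps <- unlist(lapply(byscf, function(p) diff(sort(p))))
  expect_gt(sum(gaps <= 35), 0)
  expect_identical(pool, simulate_variant_pool(g, density_per_kb = 1, seed = 4))
  expect_error(simulate_variant_pool(g, populations = list()), "population")
})

test_that("conversion-score simulator matches its calibration", {
  sc <- simulate_pconvert(data.frame(snp_id = sprintf("s%d", 1:50000)),
                          seed = 5)
  all_scores <- c(sc$pconvert_fwd, sc$pconvert_rev)
  expect_true(all(all_scores >= 0 & all_scores <= 1))
  # retained probes (best of the pair over the default threshold)
  best <- pmax(sc$pconvert_fwd, sc$pconvert_rev)
  kept <- best[best >= 0.6]
  expect_gt(mean(kept), 0.69)
  expect_lt(mean(kept), 0.73)
  expect_gt(mean(kept > 0.65), 0.95)
  expect_identical(sc, simulate_pconvert(sc["snp_id"], seed = 5))
})

test_that("family simulator is Mendelian at zero noise and recovers r", {
  cfg <- true_map_config(1, 50, marker_positions = list(c(0, 0, 50)),
                         genotyping_error_rate = 0, missing_rate = 0,
                         female_scale = 1)
  sim <- simulate_families(cfg, default_pedigree_spec(c(40, 40, 40, 40)),
                           seed = 8)
  # exhaustive Mendelian consistency of every offspring against its parents
  ped <- sim$pedigree
  for (fam in unique(ped$family_id[!ped$is_parent])) {
    off <- ped$id[!ped$is_parent & ped$family_id == fam]
    gs <- sim$genotypes[unique(ped$sire_id[ped$family_id == fam &
                                             !ped$is_parent]), ]
    gd <- sim$genotypes[unique(ped$dam_id[ped$family_id == fam &
                                            !ped$is_parent]), ]
    for (o in off) {
      go <- sim$genotypes[o, ]
      expect_true(all(go >= (gs == 2) + (gd == 2)))
      expect_true(all(go <= (gs >= 1) + (gd >= 1)))
    }
  }
  # markers at identical position never recombine
  or <- sim$truth$origins
  for (fam in names(or)) {
    expect_true(all(or[[fam]]$dam[, 1] == or[[fam]]$dam[, 2]))
    expect_true(all(or[[fam]]$sire[, 1] == or[[fam]]$sire[, 2]))
  }
})

test_that("recombinant fraction converges to the inverse Kosambi of the gap", {
  # 50 cM apart: inverse Kosambi = 0.3808; >= 5000 meioses
  cfg <- true_map_config(1, 50, marker_positions = list(c(0, 50)),
                         genotyping_error_rate = 0, missing_rate = 0,
                         female_scale = 1)
  spec <- data.frame(family_id = sprintf("F%02d", 1:2),
                     sire_id = c("S1", "S2"), dam_id = c("D1", "D2"),
                     n_offspring = c(1300, 1300))
  sim <- simulate_families(cfg, spec, seed = 9)
  r_true <- kosambi_inverse(50)
  expect_equal(r_true, 0.3808, tolerance = 1e-4)
  n_rec <- 0
  n_tot <- 0
  for (fam in names(sim$truth$origins)) {
    for (role in c("dam", "sire")) {
      o <- sim$truth$origins[[fam]][[role]]
      n_rec <- n_rec + sum(o[, 1] != o[, 2])
      n_tot <- n_tot + nrow(o)
    }
  }
  bounds <- qbinom(c(0.005, 0.995), n_tot, r_true)
  expect_gte(n_rec, bounds[1])
  expect_lte(n_rec, bounds[2])
})

test_that("female meioses recombine more than male under the 1.4 scale", {
  cfg <- true_map_config(1, 30, marker_positions = list(c(0, 30)),
                         genotyping_error_rate = 0, missing_rate = 0,
                         female_scale = 1.4)
  spec <- data.frame(family_id = "F1", sire_id = "S1", dam_id = "D1",
                     n_offspring = 5000)
  sim <- simulate_families(cfg, spec, seed = 10)
  o <- sim$truth$origins$F1
  rec_f <- sum(o$dam[, 1] != o$dam[, 2])
  rec_m <- sum(o$sire[, 1] != o$sire[, 2])
  pt <- prop.test(c(rec_f, rec_m), c(5000, 5000), alternative = "greater")
  expect_lt(pt$p.value, 0.01)
})

test_that("family simulation is deterministic and honours noise rates", {
  cfg <- true_map_config(2, c(60, 70), 30, genotyping_error_rate = 0.05,
                         missing_rate = 0.1, seed = 11)
  s1 <- simulate_families(cfg, default_pedigree_spec(c(50, 50, 50, 50)),
                          seed = 12)
  s2 <- simulate_families(cfg, default_pedigree_spec(c(50, 50, 50, 50)),
                          seed = 12)
  expect_identical(s1$genotypes, s2$genotypes)
  off <- s1$pedigree$id[!s1$pedigree$is_parent]
  miss <- mean(is.na(s1$genotypes[off, ]))
  n <- length(off) * ncol(s1$genotypes)
  expect_gt(miss, qbinom(0.005, n, 0.1) / n)
  expect_lt(miss, qbinom(0.995, n, 0.1) / n)
  expect_error(simulate_families(true_map_config(1, 10,
                                                 marker_positions = list(numeric(0)))),
               "marker")
})
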