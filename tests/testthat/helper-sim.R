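# Shared fixtures, built in code at test time.

# A two-marker single-family dataset with fully controlled transmissions:
# dam heterozygous at both markers, sire homozygous reference, so every
# dam meiosis is informative and resolvable.
make_pair_data <- function(t1, t2) {
  n <- length(t1)
  geno <- rbind(
    D = c(1L, 1L),
    S = c(0L, 0L),
    matrix(as.integer(c(t1, t2)), ncol = 2)
  )
  rownames(geno) <- c("D", "S", sprintf("O%03d", seq_len(n)))
  colnames(geno) <- c("mA", "mB")
  ped <- data.frame(
    id = rownames(geno),
    family_id = c(NA, NA, rep("F1", n)),
    sire_id = c(NA, NA, rep("S", n)),
    dam_id = c(NA, NA, rep("D", n)),
    sex = c("F", "M", rep("F", n)),
    is_parent = c(TRUE, TRUE, rep(FALSE, n)),
    stringsAsFactors = FALSE
  )
  list(genotypes = geno, pedigree = ped)
}

# Simulate recombinant/non-recombinant dam transmissions at a given r.
simulate_pair <- function(r, n, seed) {
  withr::with_seed(seed, {
    t1 <- stats::rbinom(n, 1, 0.5)
    rec <- stats::rbinom(n, 1, r)
    t2 <- (t1 + rec) %% 2
    list(t1 = t1, t2 = t2, n_rec = sum(rec))
  })
}

# A small candidate pool planted on a toy genome, for filter tests.
make_toy_pool <- function(seed = 42) {
  genome <- simulate_genome(5, 2e5, genic_fraction = 0.3,
                            repeat_fraction = 0.05, seed = seed)
  pool <- simulate_variant_pool(genome, density_per_kb = 1.5, seed = seed + 1)
  list(genome = genome, pool = pool)
}
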