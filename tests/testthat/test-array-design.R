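test_that("flank extraction matches direct slicing and flags edges", {
  g <- simulate_genome(1, 5000, seed = 41)
  sid <- g$scaffolds$scaffold_id[1]
  for (pos in c(36, 100, 2500, 5000 - 35)) {
    fl <- extract_flank(g, sid, pos)
    expect_equal(nchar(fl), 71)
    expect_identical(fl, substring(g$sequence[[sid]], pos - 35, pos + 35))
    expect_identical(substring(fl, 36, 36),
                     substring(g$sequence[[sid]], pos, pos))
  }
  expect_error(extract_flank(g, sid, 10), "edge")
  expect_error(extract_flank(g, sid, 4999), "edge")
  expect_error(extract_flank(g, "nope", 100), "unknown")
})

test_that("flank uniqueness scan finds planted duplicates on both strands", {
  set.seed(42)
  base <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                collapse = "")
  flank <- substring(base, 1000 - 35, 1000 + 35)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(flank)))
  # plant a forward copy at 3000 and a reverse-complement copy at 5000
  dup_fwd <- paste0(substring(base, 1, 2999), flank,
                    substring(base, 3071, 6000))
  dup_rev <- paste0(substring(base, 1, 4999), rc,
                    substring(base, 5071, 6000))
  mk_genome <- function(seq) {
    structure(list(
      scaffolds = data.frame(scaffold_id = "s1", length = nchar(seq),
                             stringsAsFactors = FALSE),
      genic_intervals = list(s1 = matrix(integer(0), ncol = 2,
                                         dimnames = list(NULL, c("start", "end")))),
      repeat_intervals = list(s1 = matrix(integer(0), ncol = 2,
                                          dimnames = list(NULL, c("start", "end")))),
      sequence = c(s1 = seq)
    ), class = "genome_model")
  }
  snps <- data.frame(snp_id = "snp1", scaffold_id = "s1", pos = 1000,
                     stringsAsFactors = FALSE)
  expect_false(filter_unique_flanks(snps, mk_genome(base))$multi_locus)
  expect_true(filter_unique_flanks(snps, mk_genome(dup_fwd))$multi_locus)
  expect_true(filter_unique_flanks(snps, mk_genome(dup_rev))$multi_locus)
})

test_that("candidate filter reports every applicable reason code", {
  fx <- make_toy_pool(43)
  v <- filter_candidates(fx$pool, fx$genome)
  expect_identical(v$passed, v$reasons == "")
  # tri-allelic SNPs always carry not_biallelic
  tri <- grepl(",", fx$pool$alt, fixed = TRUE)
  expect_true(all(grepl("not_biallelic", v$reasons[tri])))
  # adjacency: positional scan oracle
  adj_oracle <- logical(nrow(fx$pool))
  for (s in unique(fx$pool$scaffold_id)) {
    i <- which(fx$pool$scaffold_id == s)
    p <- fx$pool$pos[i]
    adj_oracle[i] <- vapply(seq_along(p), function(k) {
      any(abs(p[-k] - p[k]) <= 35)
    }, logical(1))
  }
  expect_identical(grepl("adjacent_snp_35bp", v$reasons), adj_oracle)
  # GC bounds applied to the flank
  flanks <- sibmap:::extract_flanks(fx$genome, fx$pool$scaffold_id,
                                    fx$pool$pos)
  gc <- sibmap:::gc_content(flanks)
  out <- !is.na(gc) & (gc < 0.30 | gc > 0.70)
  expect_identical(grepl("gc_out_of_range", v$reasons), out)
  # soft flags do not cause hard failure
  soft_only <- v$reasons %in% c("at_cg_pair", "low_maf", "at_cg_pair,low_maf",
                                "low_maf,at_cg_pair")
  expect_true(all(v$tier[soft_only] == 2L))
  expect_true(all(!v$hard_fail[soft_only]))
})

test_that("hard-filter verdicts are independent of input order", {
  fx <- make_toy_pool(44)
  pool <- fx$pool[seq_len(min(200, nrow(fx$pool))), ]
  v1 <- filter_candidates(pool, fx$genome)
  perm <- withr::with_seed(1, sample(nrow(pool)))
  v2 <- filter_candidates(pool[perm, ], fx$genome)
  v2 <- v2[match(v1$snp_id, v2$snp_id), ]
  split_codes <- function(x) lapply(strsplit(x, ","), sort)
  expect_identical(split_codes(v1$reasons), split_codes(v2$reasons))
  expect_identical(v1$hard_fail, v2$hard_fail)
})

test_that("frequency classifier matches a brute-force rule table", {
  pops <- data.frame(
    name = c("T", "H", "W", "B"),
    species = c("channel", "channel", "channel", "blue"),
    kind = c("domestic_strain", "domestic_strain", "wild", "species_pool"),
    stringsAsFactors = FALSE
  )
  expect_equal(classify_snp(c(T = 0.3, H = 0.2, W = 0.4, B = 0), pops),
               "channel_specific")
  expect_equal(classify_snp(c(T = 0, H = 0, W = 0, B = 1), pops),
               "interspecific_fixed")
  expect_equal(classify_snp(c(T = 0.3, H = 0, W = 0, B = 0), pops),
               "strain_specific:T")
  expect_equal(classify_snp(c(T = 0, H = 0, W = 0.2, B = 0), pops),
               "wild_specific")
  expect_equal(classify_snp(c(T = 0.3, H = 0, W = 0, B = 0.5), pops),
               "shared_heterozygous")
  expect_equal(classify_snp(c(T = 0, H = 0, W = 0, B = 0), pops),
               "monomorphic")

  # brute-force oracle over random tables
  oracle <- function(f, tol = 0.02) {
    poly <- function(x) any(x > tol & x < 1 - tol) ||
      (any(x >= 1 - tol) && !all(x >= 1 - tol))
    ch <- f[1:3]
    bl <- f[4]
    chp <- poly(ch)
    blp <- poly(bl)
    if (chp && blp) return("shared_heterozygous")
    if (!chp && !blp) {
      if (all(ch >= 1 - tol) != (bl >= 1 - tol)) return("interspecific_fixed")
      return("monomorphic")
    }
    if (blp) return("blue_specific")
    single <- which(ch > tol & ch < 1 - tol)
    if (length(single) == 1 && !poly(ch[-single])) {
      if (single == 3) return("wild_specific")
      return(paste0("strain_specific:", c("T", "H", "W")[single]))
    }
    "channel_specific"
  }
  withr::with_seed(45, {
    for (i in 1:200) {
      f <- stats::setNames(sample(c(0, 1, runif(2)), 4, replace = TRUE),
                           pops$name)
      expect_equal(classify_snp(f, pops), oracle(f), info = paste(f, collapse = ","))
    }
  })
})

test_that("greedy spacing reproduces the worked example and the oracle", {
  mk <- function(pos, genic = TRUE) {
    n <- length(pos)
    data.frame(snp_id = sprintf("s%02d", seq_len(n)), scaffold_id = "sc",
               pos = pos, ref = "A", alt = "C", genic = genic,
               in_repeat = FALSE, source = "genome",
               category_true = "channel", freq_X = 0.3,
               stringsAsFactors = FALSE)
  }
  verdict <- function(snps) {
    data.frame(snp_id = snps$snp_id, reasons = "", passed = TRUE,
               hard_fail = FALSE, tier = 1L, maf = 0.3, gc = 0.5,
               stringsAsFactors = FALSE)
  }
  # 3 genic SNPs at 100/250/450, gap 200 -> keep 100 and 450
  s3 <- mk(c(100, 250, 450))
  sel <- greedy_spacing_select(s3, verdict(s3), genic_gap = 200)
  expect_identical(sort(sel$pos), c(100, 450))
  # single SNP is always selected
  s1 <- mk(500)
  expect_equal(nrow(greedy_spacing_select(s1, verdict(s1))), 1L)
  # crowded run keeps exactly one survivor
  sc <- mk(seq(1000, 1150, by = 50))
  expect_equal(nrow(greedy_spacing_select(sc, verdict(sc), genic_gap = 200)),
               1L)

  # exhaustive first-fit oracle on <= 12 candidates
  first_fit <- function(pos, gap) {
    kept <- numeric(0)
    for (p in sort(pos)) {
      if (length(kept) == 0 || all(abs(kept - p) >= gap)) kept <- c(kept, p)
    }
    kept
  }
  withr::with_seed(46, {
    for (i in 1:25) {
      pos <- sort(sample.int(2000, sample(2:12, 1)))
      s <- mk(pos)
      sel <- greedy_spacing_select(s, verdict(s), genic_gap = 200)
      expect_equal(sort(sel$pos), as.integer(first_fit(pos, 200)))
      # feasibility and maximality against full enumeration
      kept <- sort(sel$pos)
      if (length(kept) > 1) {
        expect_true(all(diff(kept) >= 200))
      }
      for (p in setdiff(pos, kept)) {
        expect_true(any(abs(kept - p) < 200))
      }
    }
  })
})

test_that("spacing selection is invariant to input shuffling", {
  fx <- make_toy_pool(47)
  v <- filter_candidates(fx$pool, fx$genome)
  cats <- classify_snp_pool(fx$pool)
  sel1 <- greedy_spacing_select(fx$pool, v, cats)
  perm <- withr::with_seed(2, sample(nrow(fx$pool)))
  sel2 <- greedy_spacing_select(fx$pool[perm, ], v[perm, ], cats[perm])
  expect_identical(sort(sel1$snp_id), sort(sel2$snp_id))
})

test_that("conversion-score thresholding keeps the max probe or both", {
  snps <- data.frame(snp_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  sc <- data.frame(snp_id = c("a", "b", "c"),
                   pconvert_fwd = c(0.9, 0.5, 0.5),
                   pconvert_rev = c(0.7, 0.6, 0.6))
  out <- apply_pconvert_threshold(snps, sc, tau = 0.65)
  expect_identical(out$probe, c("fwd", NA, NA))
  expect_identical(out$retained, c(TRUE, FALSE, FALSE))
  out2 <- apply_pconvert_threshold(snps, sc, tau = 0.65, cover_anyway = "b")
  expect_identical(out2$probe[2], "both")
  expect_identical(out2$n_probes, c(1L, 2L, 0L))
})

test_that("QC probes avoid SNP flanks and split evenly by 31st base", {
  g <- simulate_genome(10, 3e5, seed = 48)
  pool <- simulate_variant_pool(g, density_per_kb = 0.5, seed = 49)
  qc <- select_qc_probes(g, pool, n = 200, seed = 50)
  expect_equal(nrow(qc), 200L)
  expect_equal(sum(qc$class == "AT"), 100L)
  expect_equal(sum(qc$class == "GC"), 100L)
  # direct inspection of the designated base
  b <- unname(substring(g$sequence[qc$scaffold_id], qc$start + 30,
                        qc$start + 30))
  expect_identical(b, qc$base31)
  expect_true(all(ifelse(b %in% c("A", "T"), "AT", "GC") == qc$class))
  # no overlap with any SNP flank
  for (i in seq_len(nrow(qc))) {
    sp <- pool$pos[pool$scaffold_id == qc$scaffold_id[i]]
    expect_false(any(sp >= qc$start[i] - 35 & sp <= qc$start[i] + 105))
  }
  expect_error(select_qc_probes(g, pool, n = 2e6), "eligible")
})

test_that("manifest arithmetic invariants hold and violations error", {
  sel <- data.frame(
    snp_id = sprintf("s%d", 1:10),
    genic = rep(c(TRUE, FALSE), 5),
    category = rep(c("channel_specific", "blue_specific"), 5),
    n_probes = c(rep(1L, 8), 2L, 2L),
    stringsAsFactors = FALSE
  )
  m <- build_manifest(sel)
  expect_equal(m$total_snps, 10L)
  expect_equal(m$genic + m$intergenic, m$total_snps)
  expect_equal(m$total_probes, m$single_probe + 2L * m$dual_probe)
  expect_equal(m$total_probes, 8L + 4L)
  expect_equal(sum(m$categories), m$total_snps)
  # empty selection yields the all-zero manifest
  m0 <- build_manifest(sel[0, ])
  expect_equal(m0$total_snps, 0L)
  expect_equal(m0$total_probes, 0L)
  sel_bad <- sel
  sel_bad$n_probes[1] <- 0L
  expect_error(build_manifest(sel_bad), "probes")
})
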