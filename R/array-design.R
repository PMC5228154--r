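# SNP filtering cascade, category classification, greedy spacing selection,
# probe-quality thresholding and QC-probe selection for array design.

#' Extract the 71-bp flank around a SNP
#'
#' Returns the 35 bp upstream + SNP base + 35 bp downstream. SNPs closer
#' than 35 bp to a scaffold edge cannot be tiled and raise an error.
#'
#' @param genome A `genome_model` with sequence.
#' @param scaffold_id Scaffold name.
#' @param pos 1-based SNP position.
#' @return A 71-character string; the SNP base is character 36.
#' @export
extract_flank <- function(genome, scaffold_id, pos) {
  if (is.null(genome$sequence)) stop_config("genome has no sequence")
  seq <- unname(genome$sequence[scaffold_id])
  if (length(seq) != 1 || is.na(seq)) {
    stop_config("unknown scaffold '%s'", scaffold_id)
  }
  L <- nchar(seq)
  if (pos < 1 || pos > L) stop_config("position %d outside scaffold", pos)
  if (pos < 36 || pos > L - 35) {
    stop_config("SNP at %s:%d is within 35 bp of a scaffold edge; flank truncated",
                scaffold_id, pos)
  }
  substring(seq, pos - 35, pos + 35)
}

# Vectorised flank extraction; NA where the flank would be truncated.
extract_flanks <- function(genome, scaffold_id, pos) {
  lens <- stats::setNames(genome$scaffolds$length, genome$scaffolds$scaffold_id)
  ok <- pos >= 36 & pos <= lens[scaffold_id] - 35
  out <- rep(NA_character_, length(pos))
  out[ok] <- substring(genome$sequence[scaffold_id[ok]],
                       pos[ok] - 35, pos[ok] + 35)
  out
}

#' Flag SNPs whose flank matches more than one genomic locus
#'
#' Counts exact occurrences of each 71-mer flank on both strands of the
#' genome; a SNP whose flank occurs at more than one locus is flagged
#' `multi_locus` (non-specific hybridisation risk).
#'
#' @param snps data.frame with `snp_id`, `scaffold_id`, `pos`.
#' @param genome A `genome_model` with sequence.
#' @return data.frame `snp_id`, `n_hits`, `multi_locus` (`NA` hits where the
#'   flank is edge-truncated).
#' @export
filter_unique_flanks <- function(snps, genome) {
  flanks <- extract_flanks(genome, snps$scaffold_id, snps$pos)
  ok <- !is.na(flanks)
  n_hits <- rep(NA_integer_, nrow(snps))
  if (any(ok)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(flanks[ok]))
    subj <- Biostrings::DNAStringSet(genome$sequence)
    fwd <- rowSums(Biostrings::vcountPDict(pd, subj))
    rev <- rowSums(Biostrings::vcountPDict(
      pd, Biostrings::reverseComplement(subj)))
    n_hits[ok] <- fwd + rev
  }
  data.frame(snp_id = snps$snp_id, n_hits = n_hits,
             multi_locus = !is.na(n_hits) & n_hits > 1L,
             stringsAsFactors = FALSE)
}

gc_content <- function(flank) {
  (nchar(flank) - nchar(gsub("[GCgc]", "", flank))) / nchar(flank)
}

# dinucleotide or homopolymer run of >= run_len bases inside the flank
has_low_complexity_run <- function(flank, run_len = 8) {
  half <- ceiling(run_len / 2) - 1   # copies beyond the first, 2-mer unit
  homo <- sprintf("([ACGT])\\1{%d,}", run_len - 1)
  di <- sprintf("([ACGT]{2})\\1{%d,}", half)
  grepl(homo, flank) | grepl(di, flank)
}

#' Apply the candidate-SNP filter cascade
#'
#' Evaluates every filter criterion for each candidate and reports all
#' applicable reason codes (no short-circuiting): `multi_locus` (flank maps
#' to more than one locus), `adjacent_snp_35bp` (another candidate within
#' 35 bp), `low_complexity_repeat` (homopolymer or dinucleotide run of
#' `run_len` bp or more in the flank), `not_biallelic`, `gc_out_of_range`
#' (flank GC outside `gc_range`) — all hard failures — plus the soft flags
#' `at_cg_pair` (A/T or C/G allele pair, used only when needed) and
#' `low_maf` (best per-population minor allele frequency at or below
#' `maf_pref`). Soft-flagged SNPs remain selectable at lower priority
#' (tier 2) by [greedy_spacing_select()].
#'
#' @param snps An `snp_pool` data.frame (needs `freq_*` columns).
#' @param genome A `genome_model` with sequence (set `check_unique = FALSE`
#'   to skip the flank-uniqueness scan).
#' @param maf_pref Preferential minor-allele-frequency cut (soft).
#' @param gc_range Length-2 GC bounds for the flank.
#' @param run_len Low-complexity run length (bp).
#' @param check_unique Run [filter_unique_flanks()]?
#' @return data.frame `snp_id`, `reasons` (comma-joined codes, `""` when
#'   clean), `passed` (no codes at all), `hard_fail`, `tier` (1 clean,
#'   2 soft flags only, 3 hard fail), `maf`, `gc`.
#' @export
filter_candidates <- function(snps, genome, maf_pref = 0.1,
                              gc_range = c(0.30, 0.70), run_len = 8,
                              check_unique = TRUE) {
  freq_cols <- grep("^freq_", names(snps), value = TRUE)
  if (length(freq_cols) == 0) {
    stop_config("candidate pool carries no per-population frequencies")
  }
  fm <- as.matrix(snps[, freq_cols, drop = FALSE])
  maf <- apply(pmin(fm, 1 - fm), 1, max)

  flanks <- extract_flanks(genome, snps$scaffold_id, snps$pos)
  gc <- ifelse(is.na(flanks), NA_real_, gc_content(flanks))

  codes <- vector("list", nrow(snps))
  add <- function(flag, code) {
    idx <- which(flag)
    for (i in idx) codes[[i]] <<- c(codes[[i]], code)
  }

  if (check_unique) {
    uq <- filter_unique_flanks(snps, genome)
    add(uq$multi_locus, "multi_locus")
  }
  # neighbour within 35 bp on the same scaffold
  ord <- order(snps$scaffold_id, snps$pos)
  adj <- logical(nrow(snps))
  sp <- split(ord, snps$scaffold_id[ord])
  for (idx in sp) {
    p <- snps$pos[idx]
    if (length(p) > 1) {
      d <- diff(p)
      close_next <- c(d <= 35, FALSE)
      close_prev <- c(FALSE, d <= 35)
      adj[idx] <- close_next | close_prev
    }
  }
  add(adj, "adjacent_snp_35bp")
  add(!is.na(flanks) & has_low_complexity_run(flanks, run_len),
      "low_complexity_repeat")
  add(grepl(",", snps$alt, fixed = TRUE), "not_biallelic")
  pair <- paste(pmin(snps$ref, snps$alt), pmax(snps$ref, snps$alt))
  add(!grepl(",", snps$alt, fixed = TRUE) & pair %in% c("A T", "C G"),
      "at_cg_pair")
  add(!is.na(gc) & (gc < gc_range[1] | gc > gc_range[2]), "gc_out_of_range")
  add(maf <= maf_pref, "low_maf")

  soft <- c("at_cg_pair", "low_maf")
  reasons <- vapply(codes, function(x) paste(x, collapse = ","), character(1))
  hard <- vapply(codes, function(x) any(!x %in% soft), logical(1))
  tier <- ifelse(hard, 3L, ifelse(reasons == "", 1L, 2L))
  data.frame(snp_id = snps$snp_id, reasons = reasons,
             passed = reasons == "", hard_fail = hard, tier = tier,
             maf = maf, gc = gc, stringsAsFactors = FALSE)
}

#' Filter a single candidate SNP
#'
#' Convenience scalar wrapper around [filter_candidates()].
#'
#' @param snp One-row `snp_pool` data.frame (or a pool plus `snp_id`).
#' @inheritParams filter_candidates
#' @return One-row verdict data.frame.
#' @export
filter_candidate <- function(snp, genome, maf_pref = 0.1,
                             gc_range = c(0.30, 0.70), run_len = 8,
                             check_unique = TRUE) {
  filter_candidates(snp, genome, maf_pref = maf_pref, gc_range = gc_range,
                    run_len = run_len, check_unique = check_unique)
}

#' Classify a SNP by its cross-population frequency pattern
#'
#' Assigns each SNP to one of the array composition categories: polymorphic
#' only within channel catfish populations (`channel_specific`, with
#' `strain_specific:<name>` / `wild_specific` when polymorphic in exactly one
#' channel population), polymorphic only in blue catfish (`blue_specific`),
#' fixed within each species for different alleles (`interspecific_fixed`),
#' polymorphic in both species (`shared_heterozygous`), or `monomorphic`.
#'
#' @param per_population_freqs Numeric matrix (SNPs x populations) or named
#'   vector of alternative-allele frequencies.
#' @param populations data.frame `name`, `species`, `kind` matching the
#'   frequency columns.
#' @param fixed_tol A population is treated as fixed when its frequency is
#'   within `fixed_tol` of 0 or 1.
#' @return Character vector of categories (scalar input gives length 1).
#' @export
classify_snp <- function(per_population_freqs, populations, fixed_tol = 0.02) {
  f <- per_population_freqs
  if (is.null(dim(f))) f <- matrix(f, nrow = 1, dimnames = list(NULL, names(f)))
  f <- f[, populations$name, drop = FALSE]
  poly <- f > fixed_tol & f < 1 - fixed_tol
  fixed_alt <- f >= 1 - fixed_tol

  ch <- populations$species == "channel"
  bl <- populations$species == "blue"
  # a species is polymorphic if any member population is, or if member
  # populations are fixed for different alleles
  sp_poly <- function(cols) {
    apply(poly[, cols, drop = FALSE], 1, any) |
      (apply(fixed_alt[, cols, drop = FALSE], 1, any) &
         !apply(fixed_alt[, cols, drop = FALSE], 1, all))
  }
  sp_alt <- function(cols) apply(fixed_alt[, cols, drop = FALSE], 1, all)
  ch_poly <- sp_poly(which(ch))
  bl_poly <- sp_poly(which(bl))

  out <- rep("monomorphic", nrow(f))
  out[ch_poly & bl_poly] <- "shared_heterozygous"
  out[ch_poly & !bl_poly] <- "channel_specific"
  out[!ch_poly & bl_poly] <- "blue_specific"
  out[!ch_poly & !bl_poly & (sp_alt(which(ch)) != sp_alt(which(bl)))] <-
    "interspecific_fixed"

  # refine channel-specific SNPs polymorphic in exactly one channel
  # population (the remaining channel populations must agree on one fixed
  # allele, otherwise the polymorphism is channel-wide)
  chan_names <- populations$name[ch]
  others_mixed <- vapply(seq_len(nrow(f)), function(i) {
    pp <- poly[i, chan_names]
    rest <- chan_names[!pp]
    if (length(rest) < 2) return(FALSE)
    any(fixed_alt[i, rest]) && !all(fixed_alt[i, rest])
  }, logical(1))
  one_pop <- out == "channel_specific" &
    rowSums(poly[, chan_names, drop = FALSE]) == 1 & !others_mixed
  if (any(one_pop)) {
    which_pop <- chan_names[apply(poly[one_pop, chan_names, drop = FALSE], 1,
                                  which.max)]
    kind <- populations$kind[match(which_pop, populations$name)]
    out[one_pop] <- ifelse(
      kind == "wild", "wild_specific",
      ifelse(kind == "domestic_strain",
             paste0("strain_specific:", which_pop),
             "channel_specific"))   # a lone species pool stays unrefined
  }
  out
}

#' Classify every SNP of a pool
#'
#' @param pool An `snp_pool` with `freq_*` columns and a populations
#'   attribute carrying `species` and `kind`.
#' @param fixed_tol Fixation tolerance, see [classify_snp()].
#' @return Character vector, one category per pool row.
#' @export
classify_snp_pool <- function(pool, fixed_tol = 0.02) {
  pops <- attr(pool, "populations")
  if (is.null(pops) || is.null(pops$species)) {
    stop_config("pool lacks a populations attribute with species info")
  }
  fm <- as.matrix(pool[, paste0("freq_", pops$name), drop = FALSE])
  colnames(fm) <- pops$name
  classify_snp(fm, pops, fixed_tol)
}

#' Greedy spacing selection of array SNPs
#'
#' Selects SNPs stage by stage — genic SNPs first (minimum spacing
#' `genic_gap` bp), then intergenic SNPs (`intergenic_gap`), finally
#' strain-/wild-specific SNPs not yet taken (`intergenic_gap`) — scanning
#' each scaffold left to right and admitting a SNP when it lies at least the
#' stage gap away from the nearest SNP already selected in that stage.
#' Clean candidates (tier 1) are placed first; soft-flagged candidates
#' (tier 2: low MAF or A/T / C/G pairs) are admitted afterwards only where
#' they sit more than twice the stage gap from every selected SNP of the
#' stage. SNPs from unmapped sources (`source != "genome"`) are exempt from
#' spacing and always included when tier-eligible. Ties at one position are
#' broken by higher MAF, then lexicographic `snp_id`.
#'
#' @param snps Candidate pool (rows must match `verdicts`).
#' @param verdicts Output of [filter_candidates()].
#' @param categories Per-SNP category from [classify_snp_pool()] (used for
#'   the final stage); defaults to `snps$category_true` when present.
#' @param genic_gap,intergenic_gap Stage minimum spacings in bp.
#' @return data.frame of selected SNPs with `stage` and `tier` columns.
#' @export
greedy_spacing_select <- function(snps, verdicts, categories = NULL,
                                  genic_gap = 200, intergenic_gap = 350) {
  stopifnot(nrow(snps) == nrow(verdicts))
  if (is.null(categories)) {
    categories <- if (!is.null(snps$category_true)) snps$category_true
                  else rep("", nrow(snps))
  }
  eligible <- verdicts$tier < 3L
  maf <- verdicts$maf

  selected <- logical(nrow(snps))
  stage_of <- rep(NA_character_, nrow(snps))

  run_stage <- function(stage_idx, gap, stage_name) {
    idx <- stage_idx[eligible[stage_idx] & !selected[stage_idx]]
    if (length(idx) == 0) return(invisible())
    mapped <- snps$source[idx] == "genome"
    # unmapped sources: exempt from spacing
    for (i in idx[!mapped]) {
      selected[i] <<- TRUE
      stage_of[i] <<- stage_name
    }
    idx <- idx[mapped]
    ord <- idx[order(snps$scaffold_id[idx], snps$pos[idx],
                     -maf[idx], snps$snp_id[idx])]
    for (pass in 1:2) {
      tier_now <- if (pass == 1) 1L else 2L
      min_gap <- if (pass == 1) gap else 2 * gap
      for (s in unique(snps$scaffold_id[ord])) {
        sc <- ord[snps$scaffold_id[ord] == s]
        kept_pos <- snps$pos[sc][selected[sc]]
        for (i in sc[verdicts$tier[sc] == tier_now & !selected[sc]]) {
          p <- snps$pos[i]
          if (length(kept_pos) == 0 || all(abs(kept_pos - p) >= min_gap)) {
            selected[i] <<- TRUE
            stage_of[i] <<- stage_name
            kept_pos <- c(kept_pos, p)
          }
        }
      }
    }
    invisible()
  }

  run_stage(which(snps$genic), genic_gap, "genic")
  run_stage(which(!snps$genic), intergenic_gap, "intergenic")
  special <- grepl("^strain_specific|^wild_specific", categories)
  run_stage(which(special), intergenic_gap, "specific")

  out <- snps[selected, , drop = FALSE]
  out$stage <- stage_of[selected]
  out$tier <- verdicts$tier[selected]
  out$category <- categories[selected]
  rownames(out) <- NULL
  out
}

#' Apply the probe conversion-score threshold
#'
#' A SNP is retained when at least one of its two probes reaches `tau`; if
#' both pass, the better probe is kept (single-probe SNP). SNPs whose probes
#' both fail are dropped, unless they are flagged cover-anyway, in which case
#' both probes are tiled (dual-probe SNP) to keep the region covered.
#'
#' @param snps data.frame with `snp_id`.
#' @param scores data.frame from [simulate_pconvert()].
#' @param tau Conversion-score threshold.
#' @param cover_anyway Character vector of snp_ids to tile even when failing.
#' @return data.frame `snp_id`, `probe` (`"fwd"`, `"rev"`, `"both"`),
#'   `n_probes`, `pconvert`, `retained`.
#' @export
apply_pconvert_threshold <- function(snps, scores, tau = 0.6,
                                     cover_anyway = character(0)) {
  i <- match(snps$snp_id, scores$snp_id)
  if (anyNA(i)) stop_config("missing conversion scores for some SNPs")
  fwd <- scores$pconvert_fwd[i]
  rev <- scores$pconvert_rev[i]
  best <- pmax(fwd, rev)
  pass <- best >= tau
  anyway <- snps$snp_id %in% cover_anyway
  probe <- ifelse(pass, ifelse(fwd >= rev, "fwd", "rev"),
                  ifelse(anyway, "both", NA_character_))
  data.frame(
    snp_id = snps$snp_id,
    probe = probe,
    n_probes = ifelse(pass, 1L, ifelse(anyway, 2L, 0L)),
    pconvert = ifelse(pass, best, ifelse(anyway, best, NA_real_)),
    retained = pass | anyway,
    stringsAsFactors = FALSE
  )
}

#' Select quality-control probes from non-polymorphic regions
#'
#' Picks `n` 71-mer windows that overlap no candidate SNP flank, half with
#' A or T at the 31st base and half with G or C, to serve as negative
#' controls on the array.
#'
#' @param genome A `genome_model` with sequence.
#' @param snps Candidate pool whose flanks must be avoided (may be `NULL`).
#' @param n Total QC probes (split evenly between the two base classes).
#' @param seed Integer seed for window sampling.
#' @return data.frame `probe_id`, `scaffold_id`, `start`, `base31`, `class`.
#' @export
select_qc_probes <- function(genome, snps = NULL, n = 2000, seed = 1L) {
  if (is.null(genome$sequence)) stop_config("genome has no sequence")
  if (n %% 2 != 0) stop_config("n must be even (half A/T, half G/C)")
  with_seed(seed, {
    cand <- list()
    for (i in seq_len(nrow(genome$scaffolds))) {
      sid <- genome$scaffolds$scaffold_id[i]
      L <- genome$scaffolds$length[i]
      if (L < 71) next
      k <- min(L - 70L, max(50L, ceiling(4 * n / nrow(genome$scaffolds))))
      starts <- sort(sample.int(L - 70L, k))
      cand[[sid]] <- data.frame(scaffold_id = sid, start = starts,
                                stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand)) stop_config("no scaffold long enough for a 71-mer")
    # drop windows overlapping any candidate SNP flank ([pos-35, pos+35])
    if (!is.null(snps) && nrow(snps) > 0) {
      keep <- rep(TRUE, nrow(cand))
      for (s in unique(cand$scaffold_id)) {
        sp <- snps$pos[snps$scaffold_id == s]
        if (length(sp) == 0) next
        rows <- which(cand$scaffold_id == s)
        st <- cand$start[rows]
        keep[rows] <- vapply(st, function(x) {
          !any(sp >= x - 35 & sp <= x + 105)
        }, logical(1))
      }
      cand <- cand[keep, , drop = FALSE]
    }
    base31 <- unname(substring(genome$sequence[cand$scaffold_id],
                               cand$start + 30L, cand$start + 30L))
    cls <- ifelse(base31 %in% c("A", "T"), "AT", "GC")
    at <- which(cls == "AT")
    gc <- which(cls == "GC")
    if (length(at) < n / 2 || length(gc) < n / 2) {
      stop_config("only %d A/T and %d G/C eligible sites for %d QC probes",
                  length(at), length(gc), n)
    }
    pick <- c(sample(at, n / 2), sample(gc, n / 2))
    out <- cand[pick, , drop = FALSE]
    out$base31 <- base31[pick]
    out$class <- cls[pick]
    out$probe_id <- sprintf("qc%05d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[, c("probe_id", "scaffold_id", "start", "base31", "class")]
  })
}

#' Build the array manifest
#'
#' Aggregates the final selection into composition counts and checks the
#' manifest arithmetic: total SNPs = genic + intergenic, total probes =
#' single-probe + 2 x dual-probe, category counts sum to the SNP total.
#'
#' @param selection data.frame with `genic`, `category` and `n_probes`
#'   columns (retained SNPs only, `n_probes` 1 or 2).
#' @param qc_probes Optional QC probe set counted separately.
#' @return An `array_manifest` list of counts.
#' @export
build_manifest <- function(selection, qc_probes = NULL) {
  if (nrow(selection) == 0) {
    counts <- list(total_snps = 0L, genic = 0L, intergenic = 0L,
                   single_probe = 0L, dual_probe = 0L, total_probes = 0L,
                   categories = integer(0),
                   qc_probes = if (is.null(qc_probes)) 0L else nrow(qc_probes))
    return(structure(counts, class = "array_manifest"))
  }
  if (!all(selection$n_probes %in% c(1L, 2L))) {
    stop_config("selection must contain retained SNPs with 1 or 2 probes")
  }
  genic <- sum(selection$genic)
  intergenic <- sum(!selection$genic)
  single <- sum(selection$n_probes == 1L)
  dual <- sum(selection$n_probes == 2L)
  cats <- table(selection$category)
  m <- structure(
    list(total_snps = genic + intergenic, genic = genic,
         intergenic = intergenic, single_probe = single, dual_probe = dual,
         total_probes = single + 2L * dual,
         categories = c(cats),
         qc_probes = if (is.null(qc_probes)) 0L else nrow(qc_probes)),
    class = "array_manifest"
  )
  stopifnot(m$total_snps == nrow(selection),
            m$total_snps == single + dual,
            sum(m$categories) == m$total_snps)
  m
}

#' @export
print.array_manifest <- function(x, ...) {
  cat(sprintf("Array manifest: %s SNPs (%s genic, %s intergenic)\n",
              format(x$total_snps, big.mark = ","),
              format(x$genic, big.mark = ","),
              format(x$intergenic, big.mark = ",")))
  cat(sprintf("  probes: %s (%s single, %s dual); QC probes: %s\n",
              format(x$total_probes, big.mark = ","),
              format(x$single_probe, big.mark = ","),
              format(x$dual_probe, big.mark = ","),
              format(x$qc_probes, big.mark = ",")))
  if (length(x$categories)) {
    for (nm in names(x$categories)) {
      cat(sprintf("  %-28s %s\n", nm,
                  format(x$categories[[nm]], big.mark = ",")))
    }
  }
  invisible(x)
}

#' Run the full array-design cascade
#'
#' Filters a candidate pool, classifies it, applies greedy spacing
#' selection, thresholds conversion scores and assembles the manifest.
#'
#' @param genome,pool,scores Genome model, candidate pool, conversion scores.
#' @param tau Conversion-score threshold.
#' @param genic_gap,intergenic_gap Spacing parameters (bp).
#' @param cover_anyway_fraction Fraction of threshold-failing SNPs tiled with
#'   both probes anyway (less-unique flank regions kept for coverage).
#' @param qc_n QC probes to select.
#' @param seed Seed for QC probe sampling and cover-anyway choice.
#' @return List with `verdicts`, `selection` (post-threshold, with probes),
#'   `qc_probes`, `manifest`.
#' @export
design_array <- function(genome, pool, scores, tau = 0.6,
                         genic_gap = 200, intergenic_gap = 350,
                         cover_anyway_fraction = 0.3, qc_n = 2000,
                         seed = 1L) {
  verdicts <- filter_candidates(pool, genome)
  categories <- classify_snp_pool(pool)
  picked <- greedy_spacing_select(pool, verdicts, categories,
                                  genic_gap, intergenic_gap)
  thr <- apply_pconvert_threshold(picked, scores, tau = tau)
  failing <- picked$snp_id[!thr$retained]
  cover <- with_seed(child_seed(seed, 1L), {
    sample(failing, round(length(failing) * cover_anyway_fraction))
  })
  thr <- apply_pconvert_threshold(picked, scores, tau = tau,
                                  cover_anyway = cover)
  sel <- cbind(picked[thr$retained, , drop = FALSE],
               thr[thr$retained, c("probe", "n_probes", "pconvert")])
  qc <- select_qc_probes(genome, pool, n = qc_n, seed = child_seed(seed, 2L))
  list(verdicts = verdicts, selection = sel, qc_probes = qc,
       manifest = build_manifest(sel, qc))
}
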