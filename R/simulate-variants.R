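#' Population specification for variant simulation
#'
#' Describes one discovery population: a domestic strain, a wild population,
#' or a whole-species pool, with the Beta parameters used to draw
#' per-SNP alternative-allele frequencies when the population is polymorphic.
#'
#' @param name Population name.
#' @param species `"channel"` or `"blue"`.
#' @param kind `"domestic_strain"`, `"wild"`, or `"species_pool"`.
#' @param shape1,shape2 Beta parameters of the polymorphic frequency draw.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, species = c("channel", "blue"),
                            kind = c("domestic_strain", "wild", "species_pool"),
                            shape1 = 1.2, shape2 = 1.2) {
  species <- match.arg(species)
  kind <- match.arg(kind)
  if (shape1 <= 0 || shape2 <= 0) stop_config("Beta parameters must be > 0")
  structure(list(name = name, species = species, kind = kind,
                 shape1 = shape1, shape2 = shape2),
            class = "population_spec")
}

#' Default discovery populations
#'
#' Five channel catfish populations (four domestic strains and one wild
#' population) plus one blue catfish species pool.
#'
#' @return List of [population_spec()] objects.
#' @export
default_populations <- function() {
  list(
    population_spec("Thompson", "channel", "domestic_strain"),
    population_spec("Hatchery", "channel", "domestic_strain"),
    population_spec("Marion", "channel", "domestic_strain"),
    population_spec("USDA103", "channel", "domestic_strain"),
    population_spec("Wild", "channel", "wild"),
    population_spec("Blue", "blue", "species_pool")
  )
}

#' Simulate a candidate SNP pool
#'
#' Draws candidate SNPs along a synthetic genome with per-population
#' alternative-allele frequencies. SNPs are emitted only when at least one
#' population shows a minor allele frequency of `maf_min` or more, mirroring
#' the discovery threshold applied by upstream variant calling. Configurable
#' fractions of sites are tri-allelic or carry a close neighbour (within
#' 35 bp), and sites falling inside annotated repeat intervals are retained,
#' so every downstream filter has work to do.
#'
#' Each SNP is assigned a ground-truth frequency category (channel-specific,
#' blue-specific, interspecific fixed difference, shared polymorphism, with
#' strain-/wild-specific subsets of the channel-specific class) from which its
#' per-population frequencies are drawn; the category label is kept for
#' classifier oracle tests.
#'
#' @param genome A `genome_model` from [simulate_genome()].
#' @param populations List of [population_spec()]s; must contain both species.
#' @param density_per_kb Expected SNP count per kb (Poisson).
#' @param category_probs Probabilities of the four frequency categories
#'   `channel`, `blue`, `interspecific`, `shared` (normalised internally).
#' @param strain_specific_fraction,wild_specific_fraction Fraction of
#'   channel-specific SNPs polymorphic in exactly one domestic strain / only
#'   in the wild population.
#' @param fraction_triallelic Fraction of sites given two alternative alleles.
#' @param fraction_adjacent Fraction of sites given a partner SNP within
#'   35 bp.
#' @param maf_min Discovery minor-allele-frequency floor (per population).
#' @param seed Integer seed.
#' @return A data.frame of class `snp_pool` with columns `snp_id`,
#'   `scaffold_id`, `pos`, `ref`, `alt` (comma-separated if tri-allelic),
#'   `genic`, `in_repeat`, `source`, `category_true`, and one `freq_<name>`
#'   column per population. The population table is kept in
#'   `attr(, "populations")`.
#' @export
simulate_variant_pool <- function(genome,
                                  populations = default_populations(),
                                  density_per_kb = 1,
                                  category_probs = c(channel = 0.84,
                                                     blue = 0.065,
                                                     interspecific = 0.028,
                                                     shared = 0.067),
                                  strain_specific_fraction = 0.08,
                                  wild_specific_fraction = 0.012,
                                  fraction_triallelic = 0.03,
                                  fraction_adjacent = 0.05,
                                  maf_min = 0.05,
                                  seed = 1L) {
  if (!inherits(genome, "genome_model")) stop_config("genome must be a genome_model")
  if (length(populations) == 0) stop_config("at least one population required")
  if (density_per_kb <= 0) stop_config("density_per_kb must be > 0")
  species <- vapply(populations, `[[`, character(1), "species")
  if (!all(c("channel", "blue") %in% species)) {
    stop_config("populations must include both channel and blue species")
  }
  pop_names <- vapply(populations, `[[`, character(1), "name")
  category_probs <- category_probs / sum(category_probs)

  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(genome$scaffolds))) {
      sid <- genome$scaffolds$scaffold_id[i]
      L <- genome$scaffolds$length[i]
      n <- stats::rpois(1, density_per_kb * L / 1000)
      if (n == 0) next
      pos <- sort(sample.int(L, min(n, L)))
      # plant close neighbours for a fraction of sites
      n_adj <- stats::rbinom(1, length(pos), fraction_adjacent)
      if (n_adj > 0) {
        anchors <- sample(pos, n_adj)
        partners <- anchors + sample(1:35, n_adj, replace = TRUE)
        partners <- partners[partners <= L & !(partners %in% pos)]
        pos <- sort(unique(c(pos, partners)))
      }
      rows[[sid]] <- data.frame(scaffold_id = sid, pos = pos,
                                stringsAsFactors = FALSE)
    }
    pool <- do.call(rbind, rows)
    if (is.null(pool) || nrow(pool) == 0) {
      stop_config("no SNPs drawn; increase density or genome size")
    }
    rownames(pool) <- NULL
    m <- nrow(pool)
    pool$snp_id <- sprintf("snp%07d", seq_len(m))

    # alleles
    bases <- c("A", "C", "G", "T")
    if (!is.null(genome$sequence)) {
      pool$ref <- substring(genome$sequence[pool$scaffold_id], pool$pos, pool$pos)
    } else {
      pool$ref <- sample(bases, m, replace = TRUE)
    }
    alt1 <- vapply(pool$ref, function(r) sample(setdiff(bases, r), 1), character(1))
    tri <- stats::runif(m) < fraction_triallelic
    alt2 <- vapply(seq_len(m), function(j) {
      if (!tri[j]) return(NA_character_)
      sample(setdiff(bases, c(pool$ref[j], alt1[j])), 1)
    }, character(1))
    pool$alt <- ifelse(tri, paste(alt1, alt2, sep = ","), alt1)

    # annotation flags
    pool$genic <- mapply(function(s, p) {
      in_intervals(p, genome$genic_intervals[[s]])
    }, pool$scaffold_id, pool$pos, USE.NAMES = FALSE)
    pool$in_repeat <- mapply(function(s, p) {
      in_intervals(p, genome$repeat_intervals[[s]])
    }, pool$scaffold_id, pool$pos, USE.NAMES = FALSE)
    pool$source <- "genome"

    # ground-truth frequency category and per-population frequencies
    cat_true <- sample(names(category_probs), m, replace = TRUE,
                       prob = category_probs)
    is_channel <- species == "channel"
    strains <- pop_names[species == "channel" &
                         vapply(populations, `[[`, character(1), "kind") ==
                           "domestic_strain"]
    wild <- pop_names[species == "channel" &
                      vapply(populations, `[[`, character(1), "kind") == "wild"]
    freqs <- matrix(0, nrow = m, ncol = length(populations),
                    dimnames = list(NULL, pop_names))
    draw_poly <- function(n, sh1, sh2) {
      # rejection sampling so the population's MAF clears the discovery floor
      f <- stats::rbeta(n, sh1, sh2)
      bad <- pmin(f, 1 - f) < maf_min
      while (any(bad)) {
        f[bad] <- stats::rbeta(sum(bad), sh1, sh2)
        bad <- pmin(f, 1 - f) < maf_min
      }
      f
    }
    for (k in seq_along(populations)) {
      p <- populations[[k]]
      poly <- switch(p$species,
        channel = cat_true %in% c("channel", "shared"),
        blue = cat_true %in% c("blue", "shared"))
      freqs[poly, k] <- draw_poly(sum(poly), p$shape1, p$shape2)
      if (p$species == "blue") {
        freqs[cat_true == "interspecific", k] <- 1
      }
    }
    # carve strain-/wild-specific subsets out of the channel-specific class
    ch_idx <- which(cat_true == "channel")
    n_ss <- round(length(ch_idx) * strain_specific_fraction)
    n_ws <- round(length(ch_idx) * wild_specific_fraction)
    special <- sample(ch_idx, min(n_ss + n_ws, length(ch_idx)))
    ss_idx <- utils::head(special, n_ss)
    ws_idx <- utils::tail(special, length(special) - length(ss_idx))
    chan_cols <- which(is_channel)
    if (length(ss_idx) > 0 && length(strains) > 0) {
      freqs[ss_idx, chan_cols] <- 0
      pick <- sample(strains, length(ss_idx), replace = TRUE)
      for (s in unique(pick)) {
        rows_s <- ss_idx[pick == s]
        freqs[rows_s, s] <- draw_poly(length(rows_s), 1.2, 1.2)
      }
      cat_true[ss_idx] <- paste0("strain:", pick)
    }
    if (length(ws_idx) > 0 && length(wild) == 1) {
      freqs[ws_idx, chan_cols] <- 0
      freqs[ws_idx, wild] <- draw_poly(length(ws_idx), 1.2, 1.2)
      cat_true[ws_idx] <- "wild"
    }

    pool$category_true <- cat_true
    colnames(freqs) <- paste0("freq_", pop_names)
    pool <- cbind(pool[, c("snp_id", "scaffold_id", "pos", "ref", "alt",
                           "genic", "in_repeat", "source", "category_true")],
                  as.data.frame(freqs))

    # drop sites below the discovery floor in every population
    fm <- as.matrix(pool[, paste0("freq_", pop_names), drop = FALSE])
    maf <- pmin(fm, 1 - fm)
    pooled <- rowMeans(fm)
    # polymorphic in some population, or a cross-species fixed difference
    # (polymorphic in the pooled discovery panel)
    keep <- apply(maf, 1, max) >= maf_min |
      pmin(pooled, 1 - pooled) >= maf_min
    pool <- pool[keep, , drop = FALSE]
    rownames(pool) <- NULL

    attr(pool, "populations") <- data.frame(
      name = pop_names,
      species = species,
      kind = vapply(populations, `[[`, character(1), "kind"),
      stringsAsFactors = FALSE
    )
    class(pool) <- c("snp_pool", "data.frame")
    pool
  })
}
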