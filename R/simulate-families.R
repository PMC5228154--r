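#' Ground-truth map configuration for family simulation
#'
#' Describes the true genetic architecture used to simulate full-sib
#' families: chromosome count, map lengths, marker positions and the noise
#' model. Marker positions are on the male map; the female map is a
#' per-chromosome multiplicative expansion of it (default 1.4, the
#' genome-wide female:male ratio typical of catfish linkage maps).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths_cM Male-map length of each chromosome (cM); recycled.
#' @param markers_per_chrom Markers per chromosome (uniform positions drawn
#'   at random) — ignored when `marker_positions` is given.
#' @param marker_positions Optional list (per chromosome) of sorted cM
#'   positions.
#' @param genotyping_error_rate Per-call probability a genotype is replaced
#'   by one of the other two genotypes.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param female_scale Female-map expansion factor; scalar or one value per
#'   chromosome.
#' @param seed Integer seed used for marker-position draws.
#' @return A `true_map_config` list.
#' @export
true_map_config <- function(n_chromosomes = 3,
                            chrom_lengths_cM = c(100, 90, 110),
                            markers_per_chrom = 200,
                            marker_positions = NULL,
                            genotyping_error_rate = 0.01,
                            missing_rate = 0.02,
                            female_scale = 1.4,
                            seed = 1L) {
  if (!is_count(n_chromosomes) || n_chromosomes < 1) {
    stop_config("n_chromosomes must be >= 1")
  }
  chrom_lengths_cM <- rep_len(chrom_lengths_cM, n_chromosomes)
  female_scale <- rep_len(female_scale, n_chromosomes)
  if (!is_prob(genotyping_error_rate) || !is_prob(missing_rate)) {
    stop_config("error and missing rates must lie in [0,1]")
  }
  if (is.null(marker_positions)) {
    if (!is_count(markers_per_chrom) || markers_per_chrom < 1) {
      stop_config("markers_per_chrom must be >= 1")
    }
    marker_positions <- with_seed(seed, {
      lapply(seq_len(n_chromosomes), function(c) {
        sort(stats::runif(markers_per_chrom, 0, chrom_lengths_cM[c]))
      })
    })
  } else {
    marker_positions <- lapply(marker_positions, as.numeric)
    if (length(marker_positions) != n_chromosomes) {
      stop_config("marker_positions must have one entry per chromosome")
    }
    ok <- vapply(marker_positions, function(p) {
      length(p) >= 1 && !is.unsorted(p) && all(p >= 0)
    }, logical(1))
    if (!all(ok)) stop_config("marker positions must be sorted and non-negative")
  }
  structure(
    list(n_chromosomes = n_chromosomes,
         chrom_lengths_cM = chrom_lengths_cM,
         marker_positions = marker_positions,
         genotyping_error_rate = genotyping_error_rate,
         missing_rate = missing_rate,
         female_scale = female_scale,
         seed = seed),
    class = "true_map_config"
  )
}

#' Default four-family pedigree
#'
#' Four full-sib families with two families sharing one sire, 478 offspring
#' in total (120/119/120/119), matching the reference-family design used for
#' high-density catfish mapping.
#'
#' @param n_offspring Offspring per family (length 4 by default).
#' @return data.frame `family_id`, `sire_id`, `dam_id`, `n_offspring`.
#' @export
default_pedigree_spec <- function(n_offspring = c(120, 119, 120, 119)) {
  n_fam <- length(n_offspring)
  if (n_fam < 1 || any(n_offspring < 1)) {
    stop_config("each family needs at least one offspring")
  }
  sires <- sprintf("S%02d", seq_len(n_fam))
  if (n_fam >= 2) sires[2] <- sires[1]   # two families share a sire
  data.frame(
    family_id = sprintf("F%02d", seq_len(n_fam)),
    sire_id = sires,
    dam_id = sprintf("D%02d", seq_len(n_fam)),
    n_offspring = as.integer(n_offspring),
    stringsAsFactors = FALSE
  )
}

#' Simulate genotyped full-sib families
#'
#' Simulates outbred full-sib families segregating at the configured markers.
#' Parent haplotypes carry alleles drawn at frequency 0.5. Gametes follow an
#' interference-free crossover process in which the recombination fraction
#' between adjacent markers is the inverse Kosambi transform of their true cM
#' separation (female separations expanded by `female_scale`), so that
#' Kosambi re-estimation downstream recovers the truth in expectation.
#' Genotyping error and missingness are applied per call; full ground truth
#' (parental haplotypes and gamete origins) is retained for oracle tests.
#'
#' @param map_config A [true_map_config()].
#' @param pedigree_spec data.frame as from [default_pedigree_spec()].
#' @param seed Integer seed governing all randomness of this call.
#' @return An object of class `sib_sim`: list with
#'   \describe{
#'     \item{pedigree}{data.frame `id`, `family_id`, `sire_id`, `dam_id`,
#'       `sex`, `is_parent`.}
#'     \item{genotypes}{integer matrix individuals x markers, coded 0/1/2
#'       (count of allele 1) with `NA` for missing.}
#'     \item{markers}{data.frame `marker_id`, `chrom`, `pos_cM` (male map),
#'       `pos_cM_female`.}
#'     \item{truth}{list: `parent_haplotypes` (parent -> 2 x m allele
#'       matrix), `origins` (family -> list(dam, sire) offspring x markers
#'       haplotype-of-origin matrices), `config`.}
#'   }
#' @export
simulate_families <- function(map_config,
                              pedigree_spec = default_pedigree_spec(),
                              seed = 1L) {
  if (!inherits(map_config, "true_map_config")) {
    stop_config("map_config must be a true_map_config")
  }
  if (nrow(pedigree_spec) < 1) stop_config("pedigree_spec has no families")
  pos <- map_config$marker_positions
  if (sum(lengths(pos)) == 0) stop_config("no markers configured")

  chrom_of <- rep(seq_along(pos), lengths(pos))
  pos_all <- unlist(pos, use.names = FALSE)
  m <- length(pos_all)
  marker_id <- sprintf("mk%02d_%05d", chrom_of,
                       unlist(lapply(lengths(pos), seq_len)))
  fscale <- map_config$female_scale

  # adjacent-gap recombination fractions per chromosome and sex
  r_gaps <- lapply(seq_along(pos), function(c) {
    g <- diff(pos[[c]])
    list(male = kosambi_inverse(g),
         female = kosambi_inverse(g * fscale[c]))
  })

  parents <- unique(c(pedigree_spec$sire_id, pedigree_spec$dam_id))

  with_seed(seed, {
    parent_haps <- lapply(parents, function(p) {
      matrix(stats::rbinom(2L * m, 1L, 0.5), nrow = 2)
    })
    names(parent_haps) <- parents

    meiose <- function(parent, n, sex) {
      # haplotype-of-origin matrix (n x m): 1 or 2, per chromosome Markov
      origin <- matrix(1L, n, m)
      for (c in seq_along(pos)) {
        idx <- which(chrom_of == c)
        k <- length(idx)
        start <- stats::rbinom(n, 1L, 0.5)
        if (k == 1) {
          origin[, idx] <- start + 1L
          next
        }
        r <- r_gaps[[c]][[sex]]
        sw <- matrix(stats::rbinom(n * (k - 1L), 1L, rep(r, each = n)),
                     nrow = n)
        cums <- if (k > 2L) t(apply(sw, 1, cumsum)) else sw
        origin[, idx] <- (start + cbind(0L, cums)) %% 2L + 1L
      }
      origin
    }

    gam_alleles <- function(parent, origin) {
      hp <- parent_haps[[parent]]
      n <- nrow(origin)
      al <- matrix(0L, n, m)
      al[origin == 1L] <- matrix(rep(hp[1, ], each = n), n, m)[origin == 1L]
      al[origin == 2L] <- matrix(rep(hp[2, ], each = n), n, m)[origin == 2L]
      al
    }

    geno_rows <- list()
    ped_rows <- list()
    origins <- list()
    for (f in seq_len(nrow(pedigree_spec))) {
      fam <- pedigree_spec$family_id[f]
      sire <- pedigree_spec$sire_id[f]
      dam <- pedigree_spec$dam_id[f]
      n <- pedigree_spec$n_offspring[f]
      o_dam <- meiose(dam, n, "female")
      o_sire <- meiose(sire, n, "male")
      g <- gam_alleles(dam, o_dam) + gam_alleles(sire, o_sire)
      rownames(g) <- sprintf("%s_O%03d", fam, seq_len(n))
      geno_rows[[fam]] <- g
      origins[[fam]] <- list(dam = o_dam, sire = o_sire)
      ped_rows[[fam]] <- data.frame(
        id = rownames(g), family_id = fam, sire_id = sire, dam_id = dam,
        sex = rep_len(c("F", "M"), n), is_parent = FALSE,
        stringsAsFactors = FALSE
      )
    }

    par_geno <- do.call(rbind, lapply(parents, function(p) {
      as.integer(parent_haps[[p]][1, ] + parent_haps[[p]][2, ])
    }))
    rownames(par_geno) <- parents
    par_sex <- ifelse(parents %in% pedigree_spec$sire_id, "M", "F")
    ped <- rbind(
      data.frame(id = parents, family_id = NA_character_,
                 sire_id = NA_character_, dam_id = NA_character_,
                 sex = par_sex, is_parent = TRUE, stringsAsFactors = FALSE),
      do.call(rbind, ped_rows)
    )
    rownames(ped) <- NULL
    geno <- rbind(par_geno, do.call(rbind, geno_rows))
    colnames(geno) <- marker_id

    # genotyping error then missingness, offspring calls only
    off_rows <- which(!ped$is_parent)
    e <- map_config$genotyping_error_rate
    if (e > 0) {
      sub <- geno[off_rows, , drop = FALSE]
      hit <- which(matrix(stats::runif(length(sub)) < e, nrow(sub)))
      if (length(hit) > 0) {
        shift <- sample(1:2, length(hit), replace = TRUE)
        sub[hit] <- (sub[hit] + shift) %% 3L
        geno[off_rows, ] <- sub
      }
    }
    mr <- map_config$missing_rate
    if (mr > 0) {
      sub <- geno[off_rows, , drop = FALSE]
      sub[matrix(stats::runif(length(sub)) < mr, nrow(sub))] <- NA_integer_
      geno[off_rows, ] <- sub
    }

    structure(
      list(
        pedigree = ped,
        genotypes = geno,
        markers = data.frame(
          marker_id = marker_id, chrom = chrom_of, pos_cM = pos_all,
          pos_cM_female = pos_all * fscale[chrom_of],
          stringsAsFactors = FALSE
        ),
        truth = list(parent_haplotypes = parent_haps, origins = origins,
                     config = map_config)
      ),
      class = "sib_sim"
    )
  })
}

#' Simulate per-sample array quality scores
#'
#' Draws a dish-QC-like scalar per sample plus a call-rate realisation; a
#' configurable fraction of samples is planted as failing either cut.
#'
#' @param sample_ids Character vector of sample names.
#' @param fail_fraction Fraction of samples planted as low-quality.
#' @param seed Integer seed.
#' @return data.frame `sample_id`, `dqc`, `call_rate`.
#' @export
simulate_sample_scores <- function(sample_ids, fail_fraction = 0.015,
                                   seed = 1L) {
  n <- length(sample_ids)
  if (n == 0) stop_config("no samples supplied")
  with_seed(seed, {
    dqc <- 0.9 + 0.1 * stats::rbeta(n, 8, 2)
    cr <- 0.96 + 0.04 * stats::rbeta(n, 8, 2)
    bad <- stats::runif(n) < fail_fraction
    dqc[bad] <- stats::runif(sum(bad), 0.5, 0.84)
    cr[bad] <- stats::runif(sum(bad), 0.7, 0.94)
    data.frame(sample_id = sample_ids, dqc = dqc, call_rate = cr,
               stringsAsFactors = FALSE)
  })
}
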