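# Format readers/writers shared by the pipeline. Internal coordinates are
# 1-based inclusive everywhere; BED conversion (0-based half-open) happens
# only here, at the I/O boundary.

#' Write a genome model to FASTA and BED
#'
#' @param genome A `genome_model` with sequence.
#' @param fasta_path Output FASTA path.
#' @param bed_path Optional BED path for genic/repeat intervals (0-based
#'   half-open, with the feature class in column 4).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta_path, bed_path = NULL) {
  if (is.null(genome$sequence)) stop_config("genome has no sequence to write")
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(bed_path)) {
    bed <- rbind(intervals_to_bed(genome$genic_intervals, "genic"),
                 intervals_to_bed(genome$repeat_intervals, "repeat"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(fasta = fasta_path, bed = bed_path))
}

intervals_to_bed <- function(ivls, label) {
  do.call(rbind, lapply(names(ivls), function(s) {
    m <- ivls[[s]]
    if (nrow(m) == 0) return(NULL)
    data.frame(chrom = s, start = m[, "start"] - 1L, end = m[, "end"],
               name = label, stringsAsFactors = FALSE)
  }))
}

#' Read a genome model back from FASTA (+ optional BED)
#'
#' @param fasta_path FASTA of scaffolds.
#' @param bed_path Optional interval BED written by [write_genome()].
#' @return A `genome_model`.
#' @export
read_genome <- function(fasta_path, bed_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  lens <- Biostrings::width(seqs)
  empty <- function() {
    stats::setNames(lapply(ids, function(.) {
      matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
    }), ids)
  }
  genic <- empty(); reps <- empty()
  if (!is.null(bed_path)) {
    bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "name"))
    for (s in unique(bed$chrom)) {
      for (lab in c("genic", "repeat")) {
        b <- bed[bed$chrom == s & bed$name == lab, , drop = FALSE]
        if (nrow(b) == 0) next
        m <- cbind(start = b$start + 1L, end = b$end)
        if (lab == "genic") genic[[s]] <- m else reps[[s]] <- m
      }
    }
  }
  structure(
    list(scaffolds = data.frame(scaffold_id = ids, length = lens,
                                stringsAsFactors = FALSE),
         genic_intervals = genic, repeat_intervals = reps,
         sequence = stats::setNames(as.character(seqs), ids)),
    class = "genome_model"
  )
}

#' Write a candidate SNP pool as a minimal VCF
#'
#' CHROM/POS/ID/REF/ALT columns plus per-population alternative allele
#' frequencies in INFO (`AF_<pop>=`), the genic flag, and the source class.
#'
#' @param pool An `snp_pool` data.frame.
#' @param path Output path (plain text `.vcf`).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(pool, path) {
  pops <- attr(pool, "populations")$name
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=AF_%s,Number=1,Type=Float,Description=\"Alt allele frequency in %s\">",
            pops, pops),
    "##INFO=<ID=GENIC,Number=0,Type=Flag,Description=\"Inside a genic interval\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Provenance class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  info <- vapply(seq_len(nrow(pool)), function(i) {
    af <- sprintf("AF_%s=%.4f", pops, unlist(pool[i, paste0("freq_", pops)]))
    paste(c(af, if (pool$genic[i]) "GENIC", sprintf("SRC=%s", pool$source[i])),
          collapse = ";")
  }, character(1))
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                     pool$scaffold_id, pool$pos, pool$snp_id,
                     pool$ref, pool$alt, info), con)
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return An `snp_pool`-shaped data.frame (without ground-truth columns).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, character(1), 8)
  af_keys <- unique(unlist(regmatches(info, gregexpr("AF_[A-Za-z0-9]+", info))))
  pops <- sub("^AF_", "", af_keys)
  out <- data.frame(
    snp_id = vapply(f, `[[`, character(1), 3),
    scaffold_id = vapply(f, `[[`, character(1), 1),
    pos = as.integer(vapply(f, `[[`, character(1), 2)),
    ref = vapply(f, `[[`, character(1), 4),
    alt = vapply(f, `[[`, character(1), 5),
    genic = grepl("(^|;)GENIC(;|$)", info),
    source = sub(".*SRC=([^;]+).*", "\\1", info),
    stringsAsFactors = FALSE
  )
  for (p in pops) {
    out[[paste0("freq_", p)]] <-
      as.numeric(sub(sprintf(".*AF_%s=([0-9.eE+-]+).*", p), "\\1", info))
  }
  attr(out, "populations") <- data.frame(name = pops, stringsAsFactors = FALSE)
  class(out) <- c("snp_pool", "data.frame")
  out
}

#' Export pedigree and genotypes in pre-MAKEPED LINKAGE format
#'
#' One row per individual: family, id, father, mother, sex (1 = male,
#' 2 = female), phenotype placeholder 0, then two allele columns per marker
#' coded 1/2 with 0 for missing. Parents appear with unknown parentage.
#'
#' @param sim A `sib_sim` (or list with `pedigree` and `genotypes`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_linkage_ped <- function(sim, path) {
  ped <- sim$pedigree
  g <- sim$genotypes[ped$id, , drop = FALSE]
  a1 <- ifelse(is.na(g), 0L, ifelse(g >= 1L, 2L, 1L))
  a2 <- ifelse(is.na(g), 0L, ifelse(g == 2L, 2L, 1L))
  alle <- matrix(0L, nrow(g), 2 * ncol(g))
  alle[, seq(1, 2 * ncol(g), 2)] <- a1
  alle[, seq(2, 2 * ncol(g), 2)] <- a2
  fam <- ifelse(is.na(ped$family_id), "0", ped$family_id)
  out <- cbind(fam, ped$id,
               ifelse(is.na(ped$sire_id), "0", ped$sire_id),
               ifelse(is.na(ped$dam_id), "0", ped$dam_id),
               ifelse(ped$sex == "M", 1L, 2L), 0L, alle)
  utils::write.table(out, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a genotype matrix as TSV
#'
#' Samples in rows, markers in columns, calls coded 0/1/2 and NA.
#'
#' @param genotypes Integer matrix with dimnames.
#' @param path File path.
#' @return `write_genotypes_tsv` returns `path` invisibly;
#'   `read_genotypes_tsv` returns the integer matrix.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
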