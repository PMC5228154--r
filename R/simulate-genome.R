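#' Simulate a fragmented reference genome
#'
#' Generates a scaffold-level genome model emulating a draft assembly: a set
#' of scaffolds with annotated genic and repeat intervals and (optionally) a
#' synthetic nucleotide sequence per scaffold. All coordinates are 1-based
#' inclusive.
#'
#' Scaffold lengths are drawn from a lognormal size distribution rescaled so
#' the total matches `total_length`. Genic intervals are non-overlapping
#' within each scaffold; repeat intervals are placed independently (they may
#' fall inside genes, as real transposon insertions do). At total sizes of
#' 1 Mb or more the realised genic/repeat base fractions land within about
#' two percentage points of the request.
#'
#' @param n_scaffolds Number of scaffolds (>= 1).
#' @param total_length Total genome size in bp across scaffolds.
#' @param genic_fraction,repeat_fraction Target fraction of bases in genic /
#'   repeat intervals; both in `[0,1]`, summing to at most 1.
#' @param with_sequence Generate a random nucleotide sequence per scaffold
#'   (needed for flank extraction and probe design).
#' @param mean_gene_length,mean_repeat_length Mean interval sizes in bp.
#' @param seed Integer seed; fixed seed gives an identical model.
#' @return An object of class `genome_model`: a list with `scaffolds`
#'   (data.frame `scaffold_id`, `length`), `genic_intervals` and
#'   `repeat_intervals` (named lists of two-column `start`/`end` matrices),
#'   and `sequence` (named character vector or `NULL`).
#' @export
simulate_genome <- function(n_scaffolds,
                            total_length,
                            genic_fraction = 0.3,
                            repeat_fraction = 0.1,
                            with_sequence = TRUE,
                            mean_gene_length = 2000,
                            mean_repeat_length = 500,
                            seed = 1L) {
  if (!is_count(n_scaffolds) || n_scaffolds < 1) {
    stop_config("n_scaffolds must be a positive integer")
  }
  if (!is.numeric(total_length) || total_length < n_scaffolds) {
    stop_config("total_length must allow at least 1 bp per scaffold")
  }
  if (!is_prob(genic_fraction) || !is_prob(repeat_fraction) ||
      genic_fraction + repeat_fraction > 1) {
    stop_config("genic/repeat fractions must lie in [0,1] and sum to <= 1")
  }

  with_seed(seed, {
    raw <- stats::rlnorm(n_scaffolds, meanlog = 0, sdlog = 0.8)
    lens <- pmax(1L, as.integer(round(raw / sum(raw) * total_length)))
    # adjust the largest scaffold so totals match exactly
    lens[which.max(lens)] <- lens[which.max(lens)] + (total_length - sum(lens))
    if (any(lens < 1L)) stop_config("zero-length scaffold requested")
    ids <- sprintf("scf%05d", seq_len(n_scaffolds))

    genic <- vector("list", n_scaffolds)
    reps <- vector("list", n_scaffolds)
    names(genic) <- names(reps) <- ids
    for (i in seq_len(n_scaffolds)) {
      genic[[i]] <- place_intervals(lens[i], genic_fraction, mean_gene_length)
      reps[[i]] <- place_intervals(lens[i], repeat_fraction, mean_repeat_length)
    }

    seqs <- NULL
    if (with_sequence) {
      seqs <- vapply(lens, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, character(1))
      names(seqs) <- ids
    }

    structure(
      list(
        scaffolds = data.frame(scaffold_id = ids, length = lens,
                               stringsAsFactors = FALSE),
        genic_intervals = genic,
        repeat_intervals = reps,
        sequence = seqs
      ),
      class = "genome_model"
    )
  })
}

# Non-overlapping intervals covering ~`fraction` of a scaffold of length L.
# Interval lengths are exponential around `mean_len`; starts are laid down in
# sorted gaps so intervals never overlap and stay inside [1, L].
place_intervals <- function(L, fraction, mean_len) {
  target <- fraction * L
  if (target < 1) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  lens <- integer(0)
  while (sum(lens) < target) {
    lens <- c(lens, pmax(1L, as.integer(stats::rexp(16, 1 / mean_len))))
  }
  cum <- cumsum(lens)
  k <- which(cum >= target)[1]
  lens <- lens[seq_len(k)]
  lens[k] <- max(1L, lens[k] - as.integer(cum[k] - target))
  covered <- sum(lens)
  if (covered >= L) {
    return(matrix(c(1L, as.integer(L)), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  k <- length(lens)
  # distribute the uncovered bases into k+1 gaps around the intervals
  gap_total <- L - covered
  cuts <- sort(sample.int(gap_total + k, k))
  gaps <- diff(c(0L, cuts)) - 1L        # k gap sizes before each interval
  starts <- cumsum(gaps + c(1L, lens[-k] + 0L))
  ends <- starts + lens - 1L
  keep <- ends <= L & starts >= 1L
  cbind(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' @export
print.genome_model <- function(x, ...) {
  n <- nrow(x$scaffolds)
  tot <- sum(x$scaffolds$length)
  cat(sprintf("Synthetic genome: %d scaffold%s, %s bp total\n",
              n, if (n == 1) "" else "s", format(tot, big.mark = ",")))
  cat(sprintf("  genic bases: %.1f%%; repeat bases: %.1f%%; sequence: %s\n",
              100 * interval_bases(x$genic_intervals) / tot,
              100 * interval_bases(x$repeat_intervals) / tot,
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

interval_bases <- function(ivls) {
  sum(vapply(ivls, function(m) {
    if (nrow(m) == 0) 0 else sum(m[, "end"] - m[, "start"] + 1)
  }, numeric(1)))
}

# TRUE for each position that falls inside any interval of `m`
in_intervals <- function(pos, m) {
  if (is.null(m) || nrow(m) == 0) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= m[, "start"] & p <= m[, "end"]), logical(1))
}
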