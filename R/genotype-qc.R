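# Sample-level QC and six-class SNP conversion classification.

#' Sample quality control
#'
#' Flags samples passing both the dish-QC and call-rate cuts. Both
#' comparisons are strict (`>`), so a sample sitting exactly at a cut fails.
#' The array-evaluation cuts are (0.85, 0.95); linkage mapping uses the
#' stricter (0.82, 0.97) — both are plain parameters here.
#'
#' @param genotypes Samples x markers matrix (`NA` = no call); used to
#'   compute call rates when `scores` lacks a `call_rate` column.
#' @param scores data.frame `sample_id`, `dqc` (and optionally `call_rate`).
#' @param dqc_min,cr_min Threshold parameters.
#' @return data.frame `sample_id`, `dqc`, `call_rate`, `passed`, with the
#'   pass count and rate in attributes `n_passed` / `pass_rate`.
#' @export
sample_qc <- function(genotypes, scores, dqc_min = 0.85, cr_min = 0.95) {
  ids <- rownames(genotypes)
  i <- match(ids, scores$sample_id)
  if (anyNA(i)) stop_config("missing dqc score for some samples")
  dqc <- scores$dqc[i]
  cr <- if (!is.null(scores$call_rate)) scores$call_rate[i]
        else rowMeans(!is.na(genotypes))
  out <- data.frame(sample_id = ids, dqc = dqc, call_rate = cr,
                    passed = dqc > dqc_min & cr > cr_min,
                    stringsAsFactors = FALSE)
  attr(out, "n_passed") <- sum(out$passed)
  attr(out, "pass_rate") <- mean(out$passed)
  out
}

#' Classify one SNP's genotype calls into a conversion class
#'
#' Cluster-free analogue of array conversion typing: call rate below
#' `cr_threshold` gives `CallRateBelowThreshold`; all three genotype classes
#' present gives `PolyHighResolution`; heterozygotes plus only one homozygote
#' class gives `NoMinorHom`; a single genotype class gives
#' `MonoHighResolution`. `OTV` and `Other` require signal-intensity clusters
#' and are assigned only via an explicit simulation flag.
#'
#' @param calls Integer vector of calls (0/1/2, `NA` missing).
#' @param cr_threshold Call-rate threshold.
#' @param flag Optional planted label `"OTV"` or `"Other"` taking precedence
#'   over the genotype-based rule (but not over the call-rate rule).
#' @return One of the six class names.
#' @export
classify_snp_clusters <- function(calls, cr_threshold = 0.97, flag = NA) {
  if (length(calls) == 0) stop_config("empty call vector")
  cr <- mean(!is.na(calls))
  if (cr < cr_threshold) return("CallRateBelowThreshold")
  if (!is.na(flag) && flag %in% c("OTV", "Other")) return(flag)
  present <- sort(unique(calls[!is.na(calls)]))
  if (length(present) == 3) return("PolyHighResolution")
  if (length(present) == 2 && 1 %in% present) return("NoMinorHom")
  if (length(present) == 1) return("MonoHighResolution")
  # both homozygote classes with no heterozygote: clusters are malformed
  "Other"
}

#' Classify every marker of a genotype matrix
#'
#' @param genotypes Samples x markers matrix.
#' @param cr_threshold Call-rate threshold.
#' @param flags Optional named vector of planted `"OTV"`/`"Other"` labels.
#' @return Named character vector of classes, one per marker.
#' @export
classify_all_snps <- function(genotypes, cr_threshold = 0.97, flags = NULL) {
  vapply(colnames(genotypes), function(mk) {
    classify_snp_clusters(genotypes[, mk], cr_threshold,
                          flag = if (is.null(flags)) NA else flags[mk])
  }, character(1))
}

#' Summarise conversion classes
#'
#' Aggregates per-SNP classes into the standard conversion report:
#' polymorphic = PolyHighResolution + NoMinorHom; converted = polymorphic +
#' MonoHighResolution. Rates are computed against `total` (defaults to the
#' number of classified SNPs, but can be the array's probe-set size).
#'
#' @param classes Character vector of conversion classes.
#' @param total Denominator for rates.
#' @return A `conversion_summary` list of counts and rates.
#' @export
conversion_summary <- function(classes, total = length(classes)) {
  lvls <- c("PolyHighResolution", "NoMinorHom", "MonoHighResolution",
            "OTV", "CallRateBelowThreshold", "Other")
  bad <- setdiff(unique(classes), lvls)
  if (length(bad) > 0) stop_config("unknown class: %s", bad[1])
  counts <- table(factor(classes, levels = lvls))
  poly <- counts[["PolyHighResolution"]] + counts[["NoMinorHom"]]
  conv <- poly + counts[["MonoHighResolution"]]
  structure(
    list(counts = c(counts), polymorphic = poly, converted = conv,
         total = total, polymorphic_rate = poly / total,
         converted_rate = conv / total),
    class = "conversion_summary"
  )
}

#' @export
print.conversion_summary <- function(x, ...) {
  cat("SNP conversion summary\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-24s %s\n", nm, format(x$counts[[nm]], big.mark = ",")))
  }
  cat(sprintf("  polymorphic: %s (%.1f%%); converted: %s (%.1f%%) of %s\n",
              format(x$polymorphic, big.mark = ","),
              100 * x$polymorphic_rate,
              format(x$converted, big.mark = ","),
              100 * x$converted_rate,
              format(x$total, big.mark = ",")))
  invisible(x)
}
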