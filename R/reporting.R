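# Packaged transcriptions of the published array/map summary tables, and
# recomputation of every derivable quantity with internal consistency checks.

#' Load a packaged summary-table fixture
#'
#' @param table One of `"table3"`, `"table4"`, `"table5"`, `"table6"`.
#' @return data.frame with cells as printed (thousands separators kept).
#' @export
load_table_fixture <- function(table = c("table3", "table4", "table5",
                                         "table6")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, ".tsv"), package = "sibmap")
  if (path == "") stop_config("fixture %s not installed", table)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

# "1,234" -> 1234; "83.5" -> 83.5
parse_number <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))

# "292,185 (42.1%)" -> c(count, pct)
parse_count_pct <- function(x) {
  count <- parse_number(sub("\\s*\\(.*$", "", x))
  pct <- ifelse(grepl("\\(", x),
                as.numeric(sub(".*\\(([0-9.]+)%\\).*", "\\1", x)), NA_real_)
  cbind(count = count, pct = pct)
}

# round half-up at `digits` decimals (matches the printed convention);
# the epsilon keeps decimal boundary cases like 2.055 from falling to the
# wrong side of the binary representation
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Recompute array composition from the packaged summary table
#'
#' Checks the manifest arithmetic of the printed array summary: SNP total =
#' genic + intergenic, probe total = single-probe + 2 x dual-probe, category
#' and strain counts, each compared against the printed values.
#'
#' @param fixture Output of `load_table_fixture("table3")`.
#' @return List of recomputed totals with a `consistent` flag and any
#'   `discrepancies`.
#' @export
recompute_table3 <- function(fixture = load_table_fixture("table3")) {
  v <- stats::setNames(parse_number(fixture$number), fixture$row)
  if (length(v) == 0) {
    return(list(total_snps = 0, total_probes = 0, consistent = TRUE,
                discrepancies = character(0)))
  }
  total <- v[["Number of genic SNPs"]] + v[["Number of intergenic SNPs"]]
  probes <- v[["Number of SNPs tiled with single probe"]] +
    2 * v[["Number of SNPs tiled with two probes"]]
  category_sum <- v[["Channel catfish-specific SNPs"]] +
    v[["Blue catfish-specific SNPs"]] + v[["Inter-species SNPs"]] +
    v[["Channel-blue both possessed"]]
  strain_sum <- v[["Domesticate strain (Thompson)"]] +
    v[["Domesticate strain (Hatchery)"]] +
    v[["Domesticate strain (Marion)"]] +
    v[["Domesticate strain (USDA 103)"]] + v[["Wild population"]]
  tiled_sum <- v[["Number of SNPs tiled with single probe"]] +
    v[["Number of SNPs tiled with two probes"]]
  printed_total <- v[["Total number of SNPs on array"]]
  disc <- character(0)
  if (total != printed_total) {
    disc <- c(disc, sprintf("genic+intergenic=%d vs printed total %d",
                            total, printed_total))
  }
  if (category_sum != printed_total) {
    disc <- c(disc, sprintf("category sum=%d vs printed total %d",
                            category_sum, printed_total))
  }
  if (tiled_sum != printed_total) {
    disc <- c(disc, sprintf("probe-tiling sum=%d vs printed total %d",
                            tiled_sum, printed_total))
  }
  list(total_snps = total, total_probes = probes,
       category_sum = category_sum, strain_specific_sum = strain_sum,
       printed_total = printed_total,
       consistent = length(disc) == 0, discrepancies = disc)
}

#' Recompute SNP conversion metrics from the packaged summary table
#'
#' Derives polymorphic (PolyHighResolution + NoMinorHom) and converted
#' (polymorphic + MonoHighResolution) totals per sample panel and compares
#' them against the printed totals; printed inconsistencies are reported
#' with both values, never reconciled.
#'
#' @param fixture Output of `load_table_fixture("table4")`.
#' @param array_total Probe-set size used for printed percentages.
#' @return List with per-panel recomputations and `discrepancies`.
#' @export
recompute_table4 <- function(fixture = load_table_fixture("table4"),
                             array_total = 690662) {
  cols <- setdiff(names(fixture), "row")
  rows <- fixture$row
  out <- list()
  disc <- character(0)
  for (cn in cols) {
    cells <- stats::setNames(fixture[[cn]], rows)
    poly_parts <- parse_count_pct(cells[c("PolyHighResolution", "NoMinorHom")])
    mono <- unname(parse_count_pct(cells["MonoHighResolution"])[, "count"])
    printed_poly <- unname(parse_count_pct(
      cells["Total Polymorphic SNPs"])[, "count"])
    printed_conv <- unname(parse_count_pct(
      cells["Total converted SNPs"])[, "count"])
    poly <- sum(poly_parts[, "count"])
    conv <- poly + mono
    if (poly != printed_poly) {
      disc <- c(disc, sprintf(
        "%s: PolyHighResolution+NoMinorHom=%d vs printed polymorphic %d",
        cn, poly, printed_poly))
    }
    if (conv != printed_conv) {
      disc <- c(disc, sprintf(
        "%s: polymorphic+MonoHighResolution=%d vs printed converted %d",
        cn, conv, printed_conv))
    }
    n_proc <- unname(parse_number(cells["Samples processed"]))
    n_pass <- unname(parse_count_pct(cells["Samples passed QC"])[, "count"])
    out[[cn]] <- list(
      polymorphic = poly, converted = conv,
      printed_polymorphic = printed_poly, printed_converted = printed_conv,
      polymorphic_rate = 100 * poly / array_total,
      converted_rate = 100 * conv / array_total,
      samples_processed = n_proc, samples_passed = n_pass,
      sample_pass_rate = 100 * n_pass / n_proc
    )
  }
  out$discrepancies <- disc
  out
}

#' Recompute linkage-map summaries from the packaged map tables
#'
#' Per linkage group: marker interval = genetic length / unique positions
#' (half-up to 2 decimals) and the female:male length ratio (2 decimals per
#' group, 1 decimal genome-wide); totals and the female-minus-male length
#' difference are re-derived from the per-group rows.
#'
#' @param t5,t6 Fixtures from [load_table_fixture()].
#' @return List with `sex_average`, `sex_specific` per-LG data.frames and a
#'   `totals` list.
#' @export
recompute_tables56 <- function(t5 = load_table_fixture("table5"),
                               t6 = load_table_fixture("table6")) {
  body5 <- t5[t5$linkage_group != "Total", , drop = FALSE]
  tot5 <- t5[t5$linkage_group == "Total", , drop = FALSE]
  sa <- data.frame(
    lg = as.integer(body5$linkage_group),
    mapped_markers = parse_number(body5$mapped_markers),
    unique_positions = parse_number(body5$unique_positions),
    length_cM = parse_number(body5$genetic_length_cM),
    printed_interval = parse_number(body5$marker_interval),
    stringsAsFactors = FALSE
  )
  sa$interval <- round_half_up(sa$length_cM / sa$unique_positions, 2)

  body6 <- t6[t6$linkage_group != "Total", , drop = FALSE]
  tot6 <- t6[t6$linkage_group == "Total", , drop = FALSE]
  ss <- data.frame(
    lg = as.integer(body6$linkage_group),
    f_unique = parse_number(body6$f_unique_positions),
    f_length = parse_number(body6$f_genetic_length_cM),
    m_unique = parse_number(body6$m_unique_positions),
    m_length = parse_number(body6$m_genetic_length_cM),
    printed_ratio = parse_number(body6$fm_ratio),
    stringsAsFactors = FALSE
  )
  ss$f_interval <- round_half_up(ss$f_length / ss$f_unique, 2)
  ss$m_interval <- round_half_up(ss$m_length / ss$m_unique, 2)
  ss$fm_ratio <- round_half_up(ss$f_length / ss$m_length, 2)

  totals <- list(
    mapped_markers = sum(sa$mapped_markers),
    unique_positions = sum(sa$unique_positions),
    length_avg_cM = sum(sa$length_cM),
    mean_interval_avg = round_half_up(sum(sa$length_cM) /
                                        sum(sa$unique_positions), 2),
    length_female_cM = sum(ss$f_length),
    length_male_cM = sum(ss$m_length),
    f_minus_m_cM = round_half_up(sum(ss$f_length) - sum(ss$m_length), 1),
    fm_ratio_genomewide = round_half_up(sum(ss$f_length) / sum(ss$m_length), 1),
    printed = list(
      mapped_markers = parse_number(tot5$mapped_markers),
      unique_positions = parse_number(tot5$unique_positions),
      length_avg_cM = parse_number(tot5$genetic_length_cM),
      length_female_cM = parse_number(tot6$f_genetic_length_cM),
      length_male_cM = parse_number(tot6$m_genetic_length_cM)
    )
  )
  list(sex_average = sa, sex_specific = ss, totals = totals)
}
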