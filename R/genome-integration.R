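# Anchor assembly scaffolds to linkage groups, orient them, flag marker-order
# discordances as misassembly calls, and export chromosome-level AGP.

#' Anchor scaffolds to linkage groups
#'
#' Each scaffold's linkage group is the majority vote of its mapped markers;
#' its orientation is the sign of the Spearman rank correlation between
#' physical (bp) and genetic (cM) position over unique genetic positions
#' (`|rho| >= rho_min`, otherwise `unknown`). Scaffolds with a single mapped
#' marker are anchored with unknown orientation; scaffolds whose markers
#' split across groups are flagged for review.
#'
#' @param map_positions data.frame `marker_id`, `lg`, `cM` (one sex-average
#'   position per marker).
#' @param marker_coords data.frame `marker_id`, `scaffold_id`, `pos` (bp).
#' @param min_support Minimum mapped markers to anchor a scaffold.
#' @param rho_min Orientation correlation threshold.
#' @return data.frame of class `scaffold_anchors`: `scaffold_id`, `lg`,
#'   `orientation`, `support`, `span_bp`, `cM_min`, `cM_max`, `split_lg`.
#' @export
anchor_scaffolds <- function(map_positions, marker_coords, min_support = 2,
                             rho_min = 0.5) {
  mc <- merge(map_positions, marker_coords, by = "marker_id")
  if (nrow(mc) == 0) stop_config("no mapped marker has physical coordinates")
  skipped <- setdiff(map_positions$marker_id, marker_coords$marker_id)
  if (length(skipped) > 0) {
    warning(sprintf("%d mapped markers lack scaffold coordinates; skipped",
                    length(skipped)))
  }
  out <- lapply(split(mc, mc$scaffold_id), function(d) {
    votes <- table(d$lg)
    lg <- names(votes)[which.max(votes)]
    dd <- d[d$lg == lg, , drop = FALSE]
    support <- nrow(dd)
    if (support < min_support && support < nrow(d)) return(NULL)
    u <- dd[!duplicated(dd$cM), , drop = FALSE]
    orientation <- "unknown"
    if (nrow(u) >= 2 && stats::sd(u$pos) > 0 && stats::sd(u$cM) > 0) {
      rho <- stats::cor(u$pos, u$cM, method = "spearman")
      if (!is.na(rho) && abs(rho) >= rho_min) {
        orientation <- if (rho > 0) "+" else "-"
      }
    }
    data.frame(
      scaffold_id = d$scaffold_id[1], lg = lg, orientation = orientation,
      support = support, span_bp = max(dd$pos) - min(dd$pos) + 1L,
      cM_min = min(dd$cM), cM_max = max(dd$cM),
      split_lg = length(votes) > 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("scaffold_anchors", "data.frame")
  out
}

# Maximal runs of consistent cM monotonicity along bp-sorted unique
# positions; direction +1/-1/0 per adjacent step.
monotone_runs <- function(cm) {
  s <- sign(diff(cm))
  if (length(s) == 0) return(data.frame(start = 1, end = 1, dir = 0))
  brk <- c(0, which(s[-1] != s[-length(s)]), length(s))
  runs <- data.frame(
    start = brk[-length(brk)] + 1,
    end = brk[-1] + 1,
    dir = s[brk[-length(brk)] + 1]
  )
  runs
}

#' Detect misassembly signals within an anchored scaffold
#'
#' Sorts the scaffold's uniquely positioned markers by bp and segments the
#' cM profile into maximal monotone runs in the scaffold's dominant
#' orientation. A run of at least `min_segment_markers` markers with
#' opposite monotonicity is called an `inverted_segment` (bp interval =
#' first to last marker of the run); a run whose genetic positions sit more
#' than `jump_cM` away from the flanking profile, or on another linkage
#' group, is called a `translocated_segment`. Duplicate (stacked) positions
#' are uninformative for within-scaffold order and are dropped before
#' segmentation.
#'
#' @param anchor One row of [anchor_scaffolds()] output.
#' @param markers data.frame `marker_id`, `lg`, `cM`, `pos` for the
#'   scaffold's markers.
#' @param min_segment_markers Minimum markers per called segment.
#' @param jump_cM Genetic-distance jump treated as a translocation signal.
#' @return data.frame of `misassembly_call`s: `scaffold_id`, `type`,
#'   `bp_start`, `bp_end`, `target_lg`, `n_markers`.
#' @export
detect_misassembly <- function(anchor, markers, min_segment_markers = 3,
                               jump_cM = 10) {
  if (is.na(anchor$lg)) stop_config("scaffold is not anchored")
  d <- markers[order(markers$pos), , drop = FALSE]
  calls <- list()
  # off-LG marker blocks: segments translocated to another linkage group
  off <- d$lg != anchor$lg
  if (any(off)) {
    r <- rle(off)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_segment_markers)) {
      blk <- d[starts[k]:ends[k], , drop = FALSE]
      tgt <- names(sort(table(blk$lg), decreasing = TRUE))[1]
      calls[[length(calls) + 1]] <- data.frame(
        scaffold_id = anchor$scaffold_id, type = "translocated_segment",
        bp_start = blk$pos[1], bp_end = blk$pos[nrow(blk)],
        target_lg = tgt, n_markers = nrow(blk),
        stringsAsFactors = FALSE
      )
    }
  }
  d_on <- d[!off, , drop = FALSE]
  u <- d_on[!duplicated(d_on$cM), , drop = FALSE]
  dom <- if (anchor$orientation == "-") -1 else 1
  if (nrow(u) >= 2) {
    runs <- monotone_runs(u$cM)
    runs$n <- runs$end - runs$start + 1
    for (k in seq_len(nrow(runs))) {
      if (runs$n[k] < min_segment_markers) next
      if (runs$dir[k] == -dom) {
        calls[[length(calls) + 1]] <- data.frame(
          scaffold_id = anchor$scaffold_id, type = "inverted_segment",
          bp_start = u$pos[runs$start[k]], bp_end = u$pos[runs$end[k]],
          target_lg = anchor$lg, n_markers = runs$n[k],
          stringsAsFactors = FALSE
        )
      }
    }
    # genetic-distance jumps: a same-direction interior run displaced by
    # more than jump_cM from both flanking markers (runs bordering an
    # opposite-direction run are part of an inversion signal, not a
    # translocation)
    inv_run <- runs$dir == -dom & runs$n >= min_segment_markers
    for (k in seq_len(nrow(runs))) {
      if (runs$n[k] < min_segment_markers || runs$dir[k] == -dom) next
      near_inv <- (k > 1 && inv_run[k - 1]) ||
        (k < nrow(runs) && inv_run[k + 1])
      if (near_inv) next
      gaps <- c(
        if (runs$start[k] > 1) {
          abs(u$cM[runs$start[k]] - u$cM[runs$start[k] - 1])
        },
        if (runs$end[k] < nrow(u)) {
          abs(u$cM[runs$end[k] + 1] - u$cM[runs$end[k]])
        }
      )
      if (length(gaps) > 0 && min(gaps) > jump_cM) {
        calls[[length(calls) + 1]] <- data.frame(
          scaffold_id = anchor$scaffold_id, type = "translocated_segment",
          bp_start = u$pos[runs$start[k]], bp_end = u$pos[runs$end[k]],
          target_lg = anchor$lg, n_markers = runs$n[k],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(calls) == 0) {
    return(data.frame(scaffold_id = character(0), type = character(0),
                      bp_start = integer(0), bp_end = integer(0),
                      target_lg = character(0), n_markers = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Coverage statistics of the anchored assembly
#'
#' @param anchors `scaffold_anchors` data.frame.
#' @param assembly A `genome_model` (for scaffold lengths).
#' @param previously_anchored Optional character vector of scaffolds already
#'   anchored by an earlier map; used to count newly placed scaffolds.
#' @return List `n_anchored`, `anchored_bp`, `total_bp`, `pct_anchored`,
#'   `n_new`.
#' @export
coverage_stats <- function(anchors, assembly, previously_anchored = NULL) {
  lens <- stats::setNames(assembly$scaffolds$length,
                          assembly$scaffolds$scaffold_id)
  anchored_bp <- sum(lens[anchors$scaffold_id])
  total <- sum(lens)
  list(
    n_anchored = nrow(anchors),
    anchored_bp = anchored_bp,
    total_bp = total,
    pct_anchored = 100 * anchored_bp / total,
    n_new = if (is.null(previously_anchored)) NA_integer_ else {
      sum(!anchors$scaffold_id %in% previously_anchored)
    }
  )
}

#' Emit a chromosome-level AGP from anchored scaffolds
#'
#' Writes AGP 2.1 rows: scaffolds ordered by genetic position within each
#' linkage group, separated by fixed-size gaps. Scaffolds with an accepted
#' inverted-segment call are split at the call boundaries and the core
#' segment is flipped.
#'
#' @param anchors `scaffold_anchors` data.frame.
#' @param assembly `genome_model` with scaffold lengths.
#' @param calls Optional accepted misassembly calls (inverted segments are
#'   applied).
#' @param gap_size Gap length between components (bp).
#' @param path Optional file to write; when `NULL` the AGP data.frame is
#'   returned only.
#' @return data.frame of AGP rows (written tab-separated when `path` given).
#' @export
emit_agp <- function(anchors, assembly, calls = NULL, gap_size = 100,
                     path = NULL) {
  lens <- stats::setNames(assembly$scaffolds$length,
                          assembly$scaffolds$scaffold_id)
  rows <- list()
  for (lg in sort(unique(anchors$lg))) {
    a <- anchors[anchors$lg == lg, , drop = FALSE]
    a <- a[order(a$cM_min, a$scaffold_id), , drop = FALSE]
    obj <- paste0("chr_", lg)
    at <- 1L
    part <- 1L
    for (i in seq_len(nrow(a))) {
      sid <- a$scaffold_id[i]
      L <- lens[[sid]]
      ori <- if (a$orientation[i] == "-") "-" else "+"
      segs <- data.frame(start = 1L, end = L, ori = ori,
                         stringsAsFactors = FALSE)
      if (!is.null(calls)) {
        inv <- calls[calls$scaffold_id == sid &
                       calls$type == "inverted_segment", , drop = FALSE]
        if (nrow(inv) == 1) {
          flip <- if (ori == "+") "-" else "+"
          segs <- data.frame(
            start = c(1L, inv$bp_start, inv$bp_end + 1L),
            end = c(inv$bp_start - 1L, inv$bp_end, L),
            ori = c(ori, flip, ori),
            stringsAsFactors = FALSE
          )
          segs <- segs[segs$end >= segs$start, , drop = FALSE]
        }
      }
      for (s in seq_len(nrow(segs))) {
        w <- segs$end[s] - segs$start[s] + 1L
        rows[[length(rows) + 1]] <- data.frame(
          object = obj, object_beg = at, object_end = at + w - 1L,
          part_number = part, component_type = "W", component_id = sid,
          component_beg = segs$start[s], component_end = segs$end[s],
          orientation = segs$ori[s], stringsAsFactors = FALSE
        )
        at <- at + w
        part <- part + 1L
      }
      if (i < nrow(a)) {
        rows[[length(rows) + 1]] <- data.frame(
          object = obj, object_beg = at, object_end = at + gap_size - 1L,
          part_number = part, component_type = "N",
          component_id = as.character(gap_size), component_beg = "scaffold",
          component_end = "yes", orientation = "map", stringsAsFactors = FALSE
        )
        at <- at + gap_size
        part <- part + 1L
      }
    }
  }
  agp <- do.call(rbind, rows)
  rownames(agp) <- NULL
  if (!is.null(path)) {
    utils::write.table(agp, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  agp
}

#' Read an AGP file written by [emit_agp()]
#'
#' @param path AGP path.
#' @return data.frame with the same columns [emit_agp()] produces.
#' @export
read_agp <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("object", "object_beg", "object_end",
                                        "part_number", "component_type",
                                        "component_id", "component_beg",
                                        "component_end", "orientation"),
                          colClasses = "character")
  for (col in c("object_beg", "object_end", "part_number")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}
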