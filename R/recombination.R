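#' Assign sliding windows of a query to the nearer of two references
#'
#' For each window (default 50 bp / 10 bp step over the common alignment),
#' the query is labelled with the reference to which its K2P distance is
#' smaller.  A window is `ambiguous` when either distance is undefined,
#' the references are identical over the window's usable sites, or the
#' distance margin is below `margin_threshold`.
#'
#' @param query,ref_a,ref_b rows of a common alignment (equal length).
#' @param window,step window width and step in alignment columns.
#' @param margin_threshold minimum `|d_a - d_b|` (substitutions/site) for
#'   an informative label.
#' @param min_usable minimum usable sites per window (passed to the
#'   windowed K2P machinery).
#' @param labels the two label names, in (ref_a, ref_b) order.
#' @return data frame of class `"window_assignment"` with columns `start`,
#'   `end` (0-based half-open alignment columns), `d_a`, `d_b`, `margin`,
#'   `label`.
#' @export
assign_windows <- function(query, ref_a, ref_b, window = 50, step = 10,
                           margin_threshold = 0.02, min_usable = 25,
                           labels = c("ref_a", "ref_b")) {
  ta <- sliding_window_divergence(query, ref_a, window, step, min_usable)
  tb <- sliding_window_divergence(query, ref_b, window, step, min_usable)
  tab <- sliding_window_divergence(ref_a, ref_b, window, step,
                                   min_usable = 1)
  margin <- abs(ta$distance - tb$distance)
  refs_same <- !is.na(tab$distance) & tab$distance == 0
  label <- ifelse(is.na(ta$distance) | is.na(tb$distance) | refs_same |
                    margin < margin_threshold,
                  "ambiguous",
                  ifelse(ta$distance <= tb$distance, labels[1], labels[2]))
  out <- data.frame(start = ta$start, end = ta$end,
                    d_a = ta$distance, d_b = tb$distance,
                    margin = margin, label = label)
  attr(out, "labels") <- labels
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("window_assignment", "data.frame")
  out
}

#' Call recombination breakpoints from a window assignment
#'
#' Maximal runs of informative (non-ambiguous) windows shorter than
#' `min_run` are discarded as noise; a breakpoint is reported between each
#' remaining pair of adjacent runs with opposite labels, positioned at the
#' midpoint between the end of the left run's last window and the start of
#' the right run's first window.  Ambiguous windows never break a run.
#'
#' @param assignment an [assign_windows()] result.
#' @param min_run minimum informative windows per supporting run.
#' @param coord_map optional per-alignment-column reference coordinates
#'   (from [msa_ref_coords()]); if given, positions are reported on the
#'   reference, otherwise on alignment columns.
#' @return data frame with columns `position`, `left_label`, `right_label`,
#'   `left_run`, `right_run`; zero rows when no breakpoint is supported.
#' @export
call_breakpoints <- function(assignment, min_run = 3, coord_map = NULL) {
  empty <- data.frame(position = numeric(0), left_label = character(0),
                      right_label = character(0), left_run = integer(0),
                      right_run = integer(0))
  inf <- assignment[assignment$label != "ambiguous", , drop = FALSE]
  if (nrow(inf) == 0) return(empty)
  r <- rle(inf$label)
  keep <- r$lengths >= min_run
  if (!any(keep)) return(empty)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  inf <- inf[run_id %in% which(keep), , drop = FALSE]
  r2 <- rle(inf$label)
  if (length(r2$lengths) < 2) return(empty)
  ends <- cumsum(r2$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  rows <- lapply(seq_len(length(r2$lengths) - 1), function(k) {
    left_last <- inf[ends[k], ]
    right_first <- inf[starts[k + 1], ]
    pos <- (left_last$end + right_first$start) / 2
    if (!is.null(coord_map)) {
      col <- min(max(1, round(pos)), length(coord_map))
      pos <- coord_map[col]
    }
    data.frame(position = pos,
               left_label = r2$values[k], right_label = r2$values[k + 1],
               left_run = r2$lengths[k], right_run = r2$lengths[k + 1])
  })
  do.call(rbind, rows)
}

#' Classify a full-length Ty1 element against two subfamily references
#'
#' The element's gag and pol types are called from the windowed majority
#' within each region: a region is the first reference's type when more
#' than half of its informative windows are nearer that reference and no
#' breakpoint falls inside the region; a region containing a breakpoint is
#' recombinant (its majority group is still recorded, since recombinant
#' elements are counted with the group contributing the majority of their
#' gag); fewer than 50% informative windows give `undetermined`.  An
#' element with a canonical-type gag and a Ty1'-type pol is a mosaic.
#'
#' @param query,ref_a,ref_b rows of a common alignment; `ref_a` is taken
#'   as the canonical reference and `ref_b` as Ty1' (override via
#'   `labels`).
#' @param regions region annotation with `gag` and `pol` intervals on
#'   reference coordinates.
#' @param coord_map per-column reference coordinates; defaults to the
#'   identity map for an indel-free alignment frame.
#' @param labels label names for (ref_a, ref_b).
#' @param element_id id echoed into the call.
#' @param bp_tolerance a breakpoint counts as internal to a region only
#'   when it lies more than this many bp from the region's edges; the
#'   default (twice the breakpoint localisation tolerance,
#'   `window + 2 * step`) keeps an exchange at the gag/pol boundary from
#'   being attributed to either region by call jitter.
#' @inheritParams assign_windows
#' @inheritParams call_breakpoints
#' @return list of class `"subfamily_call"`: `element_id`, `gag_type`,
#'   `pol_type`, `gag_majority`, `pol_majority`,
#'   `fraction_gag_canonical`, `overall`, `breakpoints`, `assignment`.
#' @export
classify_element <- function(query, ref_a, ref_b,
                             regions = load_region_annotation(),
                             window = 50, step = 10, margin_threshold = 0.02,
                             min_usable = 25, min_run = 3, coord_map = NULL,
                             labels = c("canonical", "ty1prime"),
                             element_id = "query",
                             bp_tolerance = window + 2 * step) {
  asg <- assign_windows(query, ref_a, ref_b, window, step, margin_threshold,
                        min_usable, labels)
  if (is.null(coord_map)) coord_map <- seq_len(nchar(as_msa(query)[[1]]))
  bps <- call_breakpoints(asg, min_run, coord_map)
  mid_cols <- pmin(pmax(1, round((asg$start + asg$end) / 2)),
                   length(coord_map))
  mid_ref <- coord_map[mid_cols]

  region_call <- function(interval, tag) {
    in_reg <- mid_ref >= interval[1] & mid_ref <= interval[2]
    lab <- asg$label[in_reg]
    informative <- lab != "ambiguous"
    frac_inf <- if (length(lab) == 0) 0 else mean(informative)
    n_a <- sum(lab == labels[1])
    n_b <- sum(lab == labels[2])
    frac_a <- if (n_a + n_b > 0) n_a / (n_a + n_b) else NA_real_
    majority <- if (is.na(frac_a) || frac_a == 0.5) NA_character_
      else if (frac_a > 0.5) labels[1] else labels[2]
    has_bp <- any(bps$position > interval[1] + bp_tolerance &
                    bps$position < interval[2] - bp_tolerance)
    type <- if (frac_inf < 0.5) {
      message("region ", tag, " of ", element_id,
              ": fewer than 50% informative windows; type undetermined")
      "undetermined"
    } else if (has_bp) {
      paste0("recombinant_", tag)
    } else if (is.na(majority)) {
      "undetermined"
    } else majority
    list(type = type, majority = majority, fraction_a = frac_a)
  }

  gag <- region_call(regions$gag, "gag")
  pol <- region_call(regions$pol, "pol")
  overall <- if (gag$type == labels[1] && pol$type == labels[1]) {
    "pure_canonical"
  } else if (gag$type == labels[2] && pol$type == labels[2]) {
    "pure_ty1prime"
  } else if (gag$type == labels[1] && pol$type == labels[2]) {
    "mosaic"
  } else "other_recombinant"
  out <- list(element_id = element_id,
              gag_type = gag$type, pol_type = pol$type,
              gag_majority = gag$majority, pol_majority = pol$majority,
              fraction_gag_canonical = gag$fraction_a,
              overall = overall, breakpoints = bps, assignment = asg)
  class(out) <- "subfamily_call"
  out
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat(sprintf("%s: gag = %s, pol = %s -> %s (gag canonical fraction %.2f)\n",
              x$element_id, x$gag_type, x$pol_type, x$overall,
              x$fraction_gag_canonical))
  if (nrow(x$breakpoints) > 0) {
    cat("  breakpoints at",
        paste(round(x$breakpoints$position), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarise genotype calls per strain in the content-table layout
#'
#' Full-length elements are counted by the group contributing the majority
#' of their gag sequence (so gag recombinants count with their majority
#' group); truncated elements are counted only when they span the p22
#' region.
#'
#' @param calls list of `subfamily_call`s for full-length elements.
#' @param strains character vector assigning each call to a strain
#'   (recycled if length 1).
#' @param counts optional [count_by_family()]-style counts per strain
#'   (named list) supplying the structural totals.
#' @param truncated_calls optional data frame with columns `strain`,
#'   `spans_p22` (logical), `gag_type` for truncated elements.
#' @return data frame with one row per strain: `strain`,
#'   `full_canonical_gag`, `full_ty1prime_gag`, and (when truncated calls
#'   are given) `trunc_canonical_gag`, `trunc_ty1prime_gag`, plus
#'   structural totals when `counts` is given.
#' @export
summarize_strain <- function(calls, strains, counts = NULL,
                             truncated_calls = NULL) {
  strains <- rep(strains, length.out = length(calls))
  gag_group <- vapply(calls, function(cl) {
    if (cl$gag_type %in% c("canonical", "ty1prime")) cl$gag_type
    else if (!is.na(cl$gag_majority)) cl$gag_majority
    else NA_character_
  }, character(1))
  strain_levels <- unique(strains)
  rows <- lapply(strain_levels, function(s) {
    sel <- strains == s
    row <- data.frame(
      strain = s,
      full_canonical_gag = sum(sel & gag_group == "canonical", na.rm = TRUE),
      full_ty1prime_gag = sum(sel & gag_group == "ty1prime", na.rm = TRUE))
    if (!is.null(counts) && !is.null(counts[[s]])) {
      bf <- counts[[s]]$by_family
      ty1 <- bf[bf$family == "Ty1", , drop = FALSE]
      row$full_length_ty1 <- if (nrow(ty1)) ty1$n_full else 0L
      row$truncated_ty1 <- if (nrow(ty1)) ty1$n_truncated else 0L
      row$solo_ltr_pooled <- counts[[s]]$pooled_ty1_ty2_solo
    }
    if (!is.null(truncated_calls)) {
      tc <- truncated_calls[truncated_calls$strain == s &
                              truncated_calls$spans_p22, , drop = FALSE]
      row$trunc_canonical_gag <- sum(tc$gag_type == "canonical")
      row$trunc_ty1prime_gag <- sum(tc$gag_type == "ty1prime")
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
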