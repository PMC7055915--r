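#' Parse a RepeatMasker .out file into raw repeat hits
#'
#' Reads the standard 15-column .out layout (a 3-line header is tolerated
#' but optional).  Query coordinates are preserved as 1-based inclusive;
#' the `C` strand code is mapped to `-`.
#'
#' @param path path to a .out file.
#' @return data frame of raw hits with columns `score`, `pct_divergence`,
#'   `pct_deleted`, `pct_inserted`, `query_id`, `query_start`, `query_end`,
#'   `query_left`, `strand`, `repeat_name`, `repeat_class`, `rep_start`,
#'   `rep_end`, `rep_left`, `hit_group_id`.  An empty file yields a
#'   zero-row data frame.
#' @export
parse_rm_out <- function(path) {
  lines <- readLines(path)
  is_data <- grepl("^\\s*\\d", lines)
  data_lines <- lines[is_data]
  line_nos <- which(is_data)
  if (length(data_lines) == 0) return(.empty_hits())
  rows <- lapply(seq_along(data_lines), function(i) {
    f <- strsplit(trimws(data_lines[i]), "\\s+")[[1]]
    if (length(f) < 15)
      stop("malformed row at line ", line_nos[i], " of ", path,
           " (", length(f), " fields, expected >= 15)")
    num <- suppressWarnings(as.numeric(f[c(1, 2, 3, 4, 6, 7)]))
    if (anyNA(num))
      stop("malformed row at line ", line_nos[i], " of ", path,
           " (non-numeric coordinate or score field)")
    if (!f[9] %in% c("+", "C"))
      stop("malformed row at line ", line_nos[i], " of ", path,
           " (strand must be '+' or 'C')")
    data.frame(score = num[1], pct_divergence = num[2],
               pct_deleted = num[3], pct_inserted = num[4],
               query_id = f[5],
               query_start = as.integer(num[5]),
               query_end = as.integer(num[6]),
               query_left = suppressWarnings(
                 as.integer(gsub("[()]", "", f[8]))),
               strand = if (f[9] == "C") "-" else "+",
               repeat_name = f[10], repeat_class = f[11],
               rep_start = suppressWarnings(
                 as.integer(gsub("[()]", "", f[12]))),
               rep_end = suppressWarnings(
                 as.integer(gsub("[()]", "", f[13]))),
               rep_left = suppressWarnings(
                 as.integer(gsub("[()]", "", f[14]))),
               hit_group_id = as.integer(f[15]))
  })
  hits <- do.call(rbind, rows)
  if (any(hits$query_start > hits$query_end))
    stop("query_start > query_end in ", path)
  hits
}

.empty_hits <- function() {
  data.frame(score = numeric(0), pct_divergence = numeric(0),
             pct_deleted = numeric(0), pct_inserted = numeric(0),
             query_id = character(0), query_start = integer(0),
             query_end = integer(0), query_left = integer(0),
             strand = character(0), repeat_name = character(0),
             repeat_class = character(0), rep_start = integer(0),
             rep_end = integer(0), rep_left = integer(0),
             hit_group_id = integer(0))
}

#' Write raw hits in RepeatMasker .out layout
#'
#' Produces a file that [parse_rm_out()] reads back bit-exactly (modulo
#' column spacing): 3 header lines followed by one whitespace-delimited row
#' per hit, `-` strands encoded as `C`.
#'
#' @param hits data frame in the layout returned by [parse_rm_out()].
#' @param path output path.
#' @export
write_rm_out <- function(hits, path) {
  header <- c(
    paste("  SW   perc perc perc  query     position in query    matching",
          "repeat        position in repeat"),
    paste("score   div. del. ins.  sequence  begin end     (left)  repeat",
          "name      class/family  begin end  (left)  ID"),
    "")
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(format(h$score, width = 5),
          format(h$pct_divergence, nsmall = 1),
          format(h$pct_deleted, nsmall = 1),
          format(h$pct_inserted, nsmall = 1),
          h$query_id, h$query_start, h$query_end,
          sprintf("(%d)", h$query_left),
          if (h$strand == "-") "C" else "+",
          h$repeat_name, h$repeat_class,
          h$rep_start, h$rep_end, sprintf("(%d)", h$rep_left),
          h$hit_group_id)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

.hit_family <- function(repeat_name) sub("_(LTR|I)$", "", repeat_name)
.hit_kind <- function(repeat_name) {
  ifelse(grepl("_LTR$", repeat_name), "LTR",
         ifelse(grepl("_I$", repeat_name), "I", "other"))
}

#' Remove false-positive hits by divergence
#'
#' Drops all hits whose divergence to the library sequence exceeds
#' `max_divergence` percent; hits at exactly the threshold are retained
#' (the removal rule is strictly greater than).
#'
#' @param hits raw-hit data frame.
#' @param max_divergence percent divergence cutoff (default 20).
#' @return the filtered hits.
#' @export
filter_false_positives <- function(hits, max_divergence = 20) {
  hits[hits$pct_divergence <= max_divergence, , drop = FALSE]
}

#' Relabel mislabelled LTR fragments within hit groups
#'
#' Within any contiguous cluster of fragments (consecutive fragments of
#' the same hit group separated by at most `gap_tolerance` bp) that
#' contains a Ty1 or Ty2 internal fragment, LTR fragments carrying a
#' different family's LTR name are renamed to the internal fragment's
#' family.  Contiguity matters: a distal solo LTR that was wrongly fused
#' into the group is not part of the element's cluster and keeps its
#' name.  Groups without an internal fragment are untouched; a cluster
#' with internal fragments from two different families is flagged with a
#' warning and left unchanged.
#'
#' @param hits raw-hit data frame (grouped by `hit_group_id`).
#' @param gap_tolerance maximum gap (bp) between consecutive fragments of
#'   one contiguous cluster.
#' @return hits with corrected `repeat_name`s.
#' @export
relabel_ltr_fragments <- function(hits, gap_tolerance = 100) {
  if (nrow(hits) == 0) return(hits)
  for (g in unique(hits$hit_group_id)) {
    idx <- which(hits$hit_group_id == g)
    idx <- idx[order(hits$query_start[idx], hits$query_end[idx])]
    gap_prev <- c(0, hits$query_start[idx][-1] -
                    hits$query_end[idx][-length(idx)] - 1)
    cluster <- cumsum(gap_prev > gap_tolerance)
    for (cl in unique(cluster)) {
      cidx <- idx[cluster == cl]
      fam <- .hit_family(hits$repeat_name[cidx])
      kind <- .hit_kind(hits$repeat_name[cidx])
      int_fams <- unique(fam[kind == "I"])
      if (length(int_fams) == 0) next
      if (length(int_fams) > 1) {
        warning("hit group ", g, " contains internal fragments from ",
                "multiple families (", paste(int_fams, collapse = ", "),
                "); left unchanged")
        next
      }
      if (!int_fams %in% c("Ty1", "Ty2")) next
      fix <- cidx[kind == "LTR" & fam != int_fams]
      hits$repeat_name[fix] <- paste0(int_fams, "_LTR")
    }
  }
  hits
}

#' Split tandemly-arrayed elements that share an internal LTR
#'
#' A group whose fragments follow the pattern LTR-I-LTR-I-LTR (adjacent,
#' consistent strand) is split into component copies LTR-I-LTR and
#' LTR-I-LTR, with each shared internal LTR hit duplicated into both
#' copies.  Groups with a single internal fragment, or with no LTR between
#' consecutive internal fragments (fragmented elements), are unchanged.
#' Mixed-strand groups are ambiguous and left unsplit with a warning.
#'
#' @param hits raw-hit data frame.
#' @param gap_tolerance unused here; kept for signature symmetry with the
#'   other curation steps.
#' @return hits with rewritten `hit_group_id`s (shared LTR rows appear once
#'   per component copy).
#' @export
split_tandem_arrays <- function(hits, gap_tolerance = 100) {
  if (nrow(hits) == 0) return(hits)
  next_id <- max(hits$hit_group_id) + 1L
  out <- list()
  for (g in unique(hits$hit_group_id)) {
    grp <- hits[hits$hit_group_id == g, , drop = FALSE]
    grp <- grp[order(grp$query_start, grp$query_end), , drop = FALSE]
    kind <- .hit_kind(grp$repeat_name)
    internals <- which(kind == "I")
    if (length(internals) < 2) {
      out[[length(out) + 1L]] <- grp
      next
    }
    if (length(unique(grp$strand)) > 1) {
      warning("hit group ", g, " mixes strands; tandem split skipped")
      out[[length(out) + 1L]] <- grp
      next
    }
    # a boundary is an LTR fragment lying between two consecutive internals
    boundaries <- integer(0)
    splittable <- TRUE
    for (k in seq_len(length(internals) - 1)) {
      between <- which(kind == "LTR" &
                         seq_len(nrow(grp)) > internals[k] &
                         seq_len(nrow(grp)) < internals[k + 1])
      if (length(between) == 1) {
        boundaries <- c(boundaries, between)
      } else if (length(between) > 1) {
        splittable <- FALSE  # ambiguous: more than one candidate shared LTR
      }
      # zero LTRs between internals: same (fragmented) element, no boundary
    }
    if (!splittable) {
      warning("hit group ", g, " has an ambiguous tandem pattern; unsplit")
      out[[length(out) + 1L]] <- grp
      next
    }
    if (length(boundaries) == 0) {
      out[[length(out) + 1L]] <- grp
      next
    }
    cuts <- c(1L, boundaries, nrow(grp))
    for (cpy in seq_len(length(boundaries) + 1L)) {
      rows <- grp[cuts[cpy]:cuts[cpy + 1L], , drop = FALSE]
      rows$hit_group_id <- next_id
      next_id <- next_id + 1L
      out[[length(out) + 1L]] <- rows
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split solo LTRs incorrectly fused to an adjacent element
#'
#' Within a group that contains internal fragments, the element body is the
#' span of the internal fragments plus at most one immediately adjacent LTR
#' on each side (within `gap_tolerance` bp).  Any further LTR fragment -
#' separated by more than `gap_tolerance` of non-Ty sequence, or a
#' third/fourth LTR beyond a complete structure - is emitted as its own
#' solo-LTR group.  In groups with no internal fragment, LTR fragments
#' separated by more than `gap_tolerance` are likewise split apart.
#'
#' @param hits raw-hit data frame.
#' @param gap_tolerance maximum gap (bp) between a flanking LTR and the
#'   element body for the LTR to stay in the element.
#' @return hits with rewritten `hit_group_id`s.
#' @export
split_fused_solos <- function(hits, gap_tolerance = 100) {
  if (nrow(hits) == 0) return(hits)
  next_id <- max(hits$hit_group_id) + 1L
  out <- list()
  emit <- function(rows, new_group) {
    if (new_group) {
      rows$hit_group_id <- next_id
      next_id <<- next_id + 1L
    }
    out[[length(out) + 1L]] <<- rows
  }
  for (g in unique(hits$hit_group_id)) {
    grp <- hits[hits$hit_group_id == g, , drop = FALSE]
    grp <- grp[order(grp$query_start, grp$query_end), , drop = FALSE]
    kind <- .hit_kind(grp$repeat_name)
    internals <- which(kind == "I")
    if (length(internals) == 0) {
      if (nrow(grp) == 1) {
        emit(grp, FALSE)
        next
      }
      gap_prev <- c(Inf, grp$query_start[-1] - grp$query_end[-nrow(grp)] - 1)
      cluster <- cumsum(gap_prev > gap_tolerance)
      first <- TRUE
      for (cl in unique(cluster)) {
        emit(grp[cluster == cl, , drop = FALSE], !first)
        first <- FALSE
      }
      next
    }
    core <- min(internals):max(internals)
    core_start <- grp$query_start[min(internals)]
    core_end <- grp$query_end[max(internals)]
    left <- setdiff(seq_len(min(internals) - 1), core)
    right <- setdiff(seq(max(internals) + 1, length.out =
                           nrow(grp) - max(internals)), core)
    keep <- core
    if (length(left) > 0) {
      nearest <- max(left)
      if (core_start - grp$query_end[nearest] - 1 <= gap_tolerance) {
        keep <- c(nearest, keep)
        left <- setdiff(left, nearest)
      }
    }
    if (length(right) > 0) {
      nearest <- min(right)
      if (grp$query_start[nearest] - core_end - 1 <= gap_tolerance) {
        keep <- c(keep, nearest)
        right <- setdiff(right, nearest)
      }
    }
    emit(grp[sort(keep), , drop = FALSE], FALSE)
    for (i in c(left, right)) emit(grp[i, , drop = FALSE], TRUE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Structurally classify one curated element group
#'
#' An element with no internal fragment is a solo LTR; otherwise it is
#' full-length if its total length (the sum of aligned fragment lengths)
#' strictly exceeds 95% of the family's canonical length, else truncated.
#'
#' @param group data frame of hits forming one element (same family after
#'   relabelling).
#' @param library a [synthetic_ty_library()] or equivalent list with
#'   per-family `canonical_total_length`.
#' @return list with `family`, `structural_class`, `prefix` (`f`/`t`/`s`),
#'   `total_length`.
#' @export
classify_structure <- function(group, library) {
  fam <- .hit_family(group$repeat_name)
  kind <- .hit_kind(group$repeat_name)
  family <- names(sort(table(fam), decreasing = TRUE))[1]
  if (is.null(library[[family]]))
    stop("unknown family '", family, "' (not in library)")
  total_length <- sum(group$query_end - group$query_start + 1)
  if (!any(kind == "I")) {
    cls <- "solo_ltr"
  } else if (total_length > 0.95 * library[[family]]$canonical_total_length) {
    cls <- "full_length"
  } else {
    cls <- "truncated"
  }
  list(family = family, structural_class = cls,
       prefix = c(full_length = "f", truncated = "t", solo_ltr = "s")[[cls]],
       total_length = total_length)
}

#' Build classified elements from curated hits
#'
#' Groups hits by their (curated) `hit_group_id`, classifies each group
#' with [classify_structure()], and assigns element ids
#' `<strain>_<prefix><serial>` with serials in ascending (chrom, start)
#' order.  Mixed-strand groups are split by strand rather than merged.
#'
#' @param hits curated hits.
#' @param library Ty library with canonical lengths.
#' @param strain strain name used in element ids.
#' @return a data frame of class `"ty_elements"` with columns
#'   `element_id`, `strain`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `family`, `structural_class`, `total_length`, `n_hits`, and
#'   a list-column `blocks` of 0-based half-open block matrices.
#' @export
build_elements <- function(hits, library, strain = "strain") {
  if (nrow(hits) == 0) {
    out <- data.frame(element_id = character(0), strain = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      family = character(0), structural_class = character(0),
                      total_length = integer(0), n_hits = integer(0))
    out$blocks <- list()
    class(out) <- c("ty_elements", "data.frame")
    return(out)
  }
  key <- paste(hits$hit_group_id, hits$strand, hits$query_id, sep = "\r")
  groups <- split(hits, key)
  rows <- lapply(groups, function(grp) {
    grp <- grp[order(grp$query_start, grp$query_end), , drop = FALSE]
    cls <- classify_structure(grp, library)
    blocks <- .merge_blocks(cbind(grp$query_start - 1L, grp$query_end))
    data.frame(strain = strain, chrom = grp$query_id[1],
               start = blocks[1, 1], end = blocks[nrow(blocks), 2],
               strand = grp$strand[1], family = cls$family,
               structural_class = cls$structural_class,
               total_length = cls$total_length, n_hits = nrow(grp),
               prefix = cls$prefix, blocks = I(list(blocks)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out$element_id <- paste0(strain, "_", out$prefix, seq_len(nrow(out)))
  out$prefix <- NULL
  out <- out[, c("element_id", setdiff(names(out), "element_id"))]
  rownames(out) <- NULL
  class(out) <- c("ty_elements", "data.frame")
  out
}

# merge sorted 0-based half-open intervals that touch or overlap
.merge_blocks <- function(iv) {
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[i, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], iv[i, 2])
    } else {
      merged <- rbind(merged, iv[i, , drop = FALSE])
    }
  }
  dimnames(merged) <- list(NULL, c("start", "end"))
  merged
}

#' Run the full hit-curation pipeline
#'
#' Parses (if given a path), removes >`max_divergence`% hits, relabels
#' mislabelled LTR fragments, splits tandem arrays and fused solo LTRs,
#' classifies elements structurally and tallies per-family counts.
#'
#' @param x raw hits data frame or path to a RepeatMasker .out file.
#' @param library Ty library with canonical lengths.
#' @param strain strain name for element ids.
#' @param max_divergence false-positive divergence cutoff (percent).
#' @param gap_tolerance fused-solo gap tolerance (bp).
#' @return list of class `"ty_annotation"`: `elements` ([build_elements()]
#'   output), `counts` ([count_by_family()] output), `hits` (curated hits).
#' @export
annotate_ty <- function(x, library, strain = "strain", max_divergence = 20,
                        gap_tolerance = 100) {
  hits <- if (is.character(x)) parse_rm_out(x) else x
  hits$is_fp <- NULL
  hits <- filter_false_positives(hits, max_divergence)
  hits <- relabel_ltr_fragments(hits)
  hits <- split_tandem_arrays(hits, gap_tolerance)
  hits <- split_fused_solos(hits, gap_tolerance)
  elements <- build_elements(hits, library, strain)
  out <- list(elements = elements, counts = count_by_family(elements),
              hits = hits)
  class(out) <- "ty_annotation"
  out
}

#' @export
print.ty_annotation <- function(x, ...) {
  cat(sprintf("Curated Ty annotation: %d elements from %d hits\n",
              nrow(x$elements), nrow(x$hits)))
  print(x$counts)
  invisible(x)
}

#' Per-family counts of full-length, truncated and solo-LTR elements
#'
#' Solo-LTR counts for Ty1 and Ty2 are additionally pooled, because the
#' similarity of their LTR sequences makes family assignment of solo LTRs
#' unreliable.
#'
#' @param elements a `ty_elements` data frame (or the truth table from
#'   [plant_genome()]).
#' @return list of class `"family_counts"`: `by_family` (data frame with
#'   `family`, `n_full`, `n_truncated`, `n_solo`) and
#'   `pooled_ty1_ty2_solo`.
#' @export
count_by_family <- function(elements) {
  .tally_counts(elements$family, elements$structural_class)
}

.tally_counts <- function(families, classes) {
  fams <- sort(unique(families))
  by_family <- data.frame(
    family = fams,
    n_full = vapply(fams, function(f)
      sum(families == f & classes == "full_length"), integer(1)),
    n_truncated = vapply(fams, function(f)
      sum(families == f & classes == "truncated"), integer(1)),
    n_solo = vapply(fams, function(f)
      sum(families == f & classes == "solo_ltr"), integer(1)),
    row.names = NULL)
  pooled <- sum(by_family$n_solo[by_family$family %in% c("Ty1", "Ty2")])
  structure(list(by_family = by_family,
                 pooled_ty1_ty2_solo = as.integer(pooled)),
            class = "family_counts")
}

#' @export
print.family_counts <- function(x, ...) {
  print(x$by_family, row.names = FALSE)
  cat("Ty1/Ty2 solo LTRs (pooled):", x$pooled_ty1_ty2_solo, "\n")
  invisible(x)
}

# ---- BED12 interchange ----

#' Write / read elements as BED12
#'
#' One BED12 line per element: 0-based half-open chrom coordinates, the
#' element id as name, and blockCount/blockSizes/blockStarts describing the
#' element's blocks.  `read_bed12(write_bed12(x))` reproduces the
#' BED-representable fields exactly.
#'
#' @param elements a `ty_elements` data frame.
#' @param path file path.
#' @param chrom_sizes optional named vector of chromosome lengths; if
#'   given, blocks outside chromosome bounds are an error.
#' @export
write_bed12 <- function(elements, path, chrom_sizes = NULL) {
  if (nrow(elements) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- vapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    b <- e$blocks[[1]]
    if (any(b[, 1] < e$start) || any(b[, 2] > e$end) ||
        any(b[, 1] >= b[, 2]))
      stop("invalid blocks for element ", e$element_id)
    if (!is.null(chrom_sizes)) {
      cs <- chrom_sizes[[e$chrom]]
      if (is.null(cs) || any(b[, 2] > cs) || any(b[, 1] < 0))
        stop("blocks outside chrom bounds for element ", e$element_id)
    }
    paste(e$chrom, e$start, e$end, e$element_id, 0, e$strand,
          e$start, e$end, "0", nrow(b),
          paste(b[, 2] - b[, 1], collapse = ","),
          paste(b[, 1] - e$start, collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed12
#' @return for `read_bed12`: a data frame of class `"ty_elements"` with the
#'   BED-representable fields (`element_id`, `chrom`, `start`, `end`,
#'   `strand`, `structural_class` recovered from the id prefix, `blocks`).
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(element_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), structural_class = character(0))
    out$blocks <- list()
    class(out) <- c("ty_elements", "data.frame")
    return(out)
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      stop("malformed BED12 at line ", i, " of ", path)
    start <- as.integer(f[2])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    starts <- as.integer(strsplit(f[12], ",")[[1]])
    if (length(sizes) != as.integer(f[10]) ||
        length(starts) != as.integer(f[10]))
      stop("inconsistent block fields at line ", i, " of ", path)
    blocks <- cbind(start = start + starts, end = start + starts + sizes)
    prefix <- sub("^.*_([fts])\\d+$", "\\1", f[4])
    data.frame(element_id = f[4], chrom = f[1], start = start,
               end = as.integer(f[3]), strand = f[6],
               structural_class = c(f = "full_length", t = "truncated",
                                    s = "solo_ltr")[prefix],
               blocks = I(list(blocks)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ty_elements", "data.frame")
  out
}
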