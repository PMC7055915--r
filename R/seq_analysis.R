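#' Load the Ty1-H3 region annotation
#'
#' Reads the functional-region configuration (1-based inclusive intervals
#' on Ty1-H3 coordinates): LTRs, gag, pol, the p22 region with its two
#' alternative start codons, the +1 frameshift heptamer, and the
#' helix/antisense interval lists.  The packaged defaults place p22 in the
#' C-terminal half of gag; all intervals are overridable via a custom YAML
#' file.
#'
#' @param path optional path to a YAML region file; defaults to the
#'   configuration shipped with the package.
#' @return a list of class `"region_annotation"`; intervals are integer
#'   vectors `c(start, end)`, list regions are lists of such vectors.
#' @export
load_region_annotation <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ty1h3_regions.yaml", package = "tyland")
  cfg <- yaml::read_yaml(path)
  len <- cfg$element_length
  iv <- function(x) as.integer(unlist(x))
  out <- list(element_length = as.integer(len),
              LTR5 = iv(cfg$LTR5), gag = iv(cfg$gag), pol = iv(cfg$pol),
              LTR3 = iv(cfg$LTR3), p22_region = iv(cfg$p22_region),
              p22_start_codons = iv(cfg$p22_start_codons),
              frameshift_heptamer = iv(cfg$frameshift_heptamer),
              helix_regions = lapply(cfg$helix_regions, iv),
              antisense_regions = lapply(cfg$antisense_regions, iv))
  check <- c(out[c("LTR5", "gag", "pol", "LTR3", "p22_region",
                   "frameshift_heptamer")],
             out$helix_regions, out$antisense_regions)
  for (r in check) {
    if (r[1] < 1 || r[2] > len || r[1] > r[2])
      stop("region interval outside element bounds: ",
           paste(r, collapse = "-"))
  }
  class(out) <- "region_annotation"
  out
}

#' Extract element sequences from a genome, oriented to the element strand
#'
#' Per element, the block substrings are concatenated in genomic order and
#' reverse-complemented when the element is on the minus strand, so the
#' returned sequence reads 5' LTR to 3' LTR in element orientation.
#'
#' @param genome named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param elements a `ty_elements` data frame (e.g. from [read_bed12()]).
#' @return named character vector of element sequences (names are element
#'   ids), with a `"source"` attribute data frame recording chrom, start,
#'   end and strand.
#' @export
extract_sequences <- function(genome, elements) {
  if (inherits(genome, "XStringSet")) genome <- as.character(genome)
  seqs <- vapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    if (!e$chrom %in% names(genome))
      stop("chromosome '", e$chrom, "' not present in the genome")
    chrom_seq <- genome[[e$chrom]]
    b <- e$blocks[[1]]
    if (any(b[, 2] > nchar(chrom_seq)))
      stop("element ", e$element_id, " extends beyond chromosome ", e$chrom)
    s <- paste(substring(chrom_seq, b[, 1] + 1, b[, 2]), collapse = "")
    if (e$strand == "-") reverse_complement(s) else s
  }, character(1))
  names(seqs) <- elements$element_id
  attr(seqs, "source") <- elements[, c("chrom", "start", "end", "strand")]
  seqs
}

# substitution matrix over A/C/G/T/N: N always scores `n_score`
.dna_submat <- function(match, mismatch, n_score = mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- n_score
  m[, "N"] <- n_score
  m
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment where a gap run of length L scores
#' `gap_open + L * gap_extend`.  Ambiguity codes (N) score as mismatches.
#'
#' @param a,b non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters (defaults
#'   1 / -1 / -5 / -1).
#' @return list of class `"pairwise_alignment"` with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length) and `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap_open = -5,
                         gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global",
    substitutionMatrix = .dna_submat(match, mismatch),
    gapOpening = -gap_open, gapExtension = -gap_extend)
  out <- list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
              aligned_b = as.character(Biostrings::alignedSubject(aln)),
              score = Biostrings::score(aln))
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment, score", x$score, "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Project a truncated element onto the Ty1-H3 reference
#'
#' Repeated local alignment of the truncated element against the reference
#' (masking each matched query segment before re-aligning) recovers the
#' reference intervals covered by the element, allowing split coverage for
#' elements assembled from non-contiguous reference parts.  Blocks shorter
#' than `min_block` or below `min_identity` fractional identity are not
#' reported.
#'
#' @param truncated element sequence (element orientation).
#' @param reference the Ty1-H3 reference sequence (5918 bp).
#' @param regions region annotation; used for the `spans_p22` flag.
#' @param min_block minimum aligned block length (bp).
#' @param min_identity minimum fractional identity per block.
#' @param max_blocks maximum number of alignment blocks recovered.
#' @return list with `intervals` (matrix of 1-based inclusive covered
#'   reference intervals, merged and sorted) and `spans_p22` (`TRUE` iff
#'   the union of covered intervals contains the entire p22 region).
#' @export
project_truncated <- function(truncated, reference,
                              regions = load_region_annotation(),
                              min_block = 50, min_identity = 0.8,
                              max_blocks = 10) {
  submat <- .dna_submat(1, -1, n_score = -10)
  query <- toupper(truncated)
  ref <- Biostrings::DNAString(toupper(reference))
  intervals <- NULL
  for (i in seq_len(max_blocks)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), ref, type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 1)
    width <- Biostrings::nchar(Biostrings::alignedSubject(aln))
    if (Biostrings::score(aln) < min_block * (2 * min_identity - 1) ||
        width < min_block ||
        Biostrings::pid(aln) < 100 * min_identity) break
    sub <- aln@subject@range
    intervals <- rbind(intervals, c(sub@start, sub@start + sub@width - 1))
    pat <- aln@pattern@range
    substr(query, pat@start, pat@start + pat@width - 1) <-
      strrep("N", pat@width)
  }
  if (is.null(intervals)) {
    return(list(intervals = matrix(integer(0), 0, 2,
                                   dimnames = list(NULL, c("start", "end"))),
                spans_p22 = FALSE))
  }
  merged <- .merge_blocks(cbind(intervals[, 1] - 1L, intervals[, 2]))
  merged <- cbind(start = merged[, 1] + 1L, end = merged[, 2])
  p22 <- regions$p22_region
  spans <- any(merged[, 1] <= p22[1] & merged[, 2] >= p22[2])
  list(intervals = merged, spans_p22 = spans)
}

#' Check coding capacity for p22/p18 in an element sequence
#'
#' Translates from each configured alternative start codon of p22 in the
#' annotated frame and reports, per start, whether the open reading frame
#' is intact: the start codon is ATG and no stop codon occurs strictly
#' before the final codon of the region (the region's terminal stop is
#' allowed).  p18, the proteolytically processed form of p22, uses the
#' same coding span.  Codons containing N are skipped (never counted as
#' stops).
#'
#' @param seq element (or fragment) sequence covering reference positions
#'   `seq_offset .. seq_offset + nchar(seq) - 1`.
#' @param regions region annotation with `p22_region` and
#'   `p22_start_codons`.
#' @param which `"p22"` or `"p18"` (same coding span).
#' @param seq_offset reference coordinate of the first base of `seq`.
#' @return data frame with one row per alternative start: `start_pos`,
#'   `frame`, `aa_length`, `intact`; attribute `"any_intact"` gives the
#'   overall capacity call.
#' @export
check_orf_capacity <- function(seq, regions = load_region_annotation(),
                               which = c("p22", "p18"), seq_offset = 1) {
  which <- match.arg(which)
  region <- regions$p22_region
  starts <- regions$p22_start_codons
  if (is.null(region) || is.null(starts))
    stop("p22 region/start codons not configured")
  chars <- .as_chars(seq)
  cover <- c(seq_offset, seq_offset + length(chars) - 1)
  rows <- lapply(starts, function(s) {
    if (s < cover[1] || region[2] > cover[2]) {
      return(data.frame(start_pos = s, frame = (s - 1) %% 3,
                        aa_length = 0L, intact = FALSE))
    }
    local <- (s - seq_offset + 1)
    n_codons <- (region[2] - s + 1) %/% 3
    codon_starts <- local + 3 * (seq_len(n_codons) - 1)
    codons <- vapply(codon_starts, function(cs)
      .collapse(chars[cs:(cs + 2)]), character(1))
    aas <- .translate_codons(codons)
    is_stop <- aas == "*"
    intact <- identical(codons[1], "ATG") &&
      !any(is_stop[-length(is_stop)], na.rm = TRUE)
    data.frame(start_pos = s, frame = (s - 1) %% 3,
               aa_length = if (intact) n_codons - 1L else 0L,
               intact = intact)
  })
  out <- do.call(rbind, rows)
  attr(out, "any_intact") <- any(out$intact)
  out
}

.translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[!codons %in% names(gc)] <- NA_character_
  aa
}

#' Remove gap-only columns from a multiple sequence alignment
#'
#' @param msa named character vector of equal-length aligned rows (or
#'   `DNAStringSet`).
#' @return the alignment with columns where every row is a gap (`-` or
#'   `.`) removed; everything else preserved in order.
#' @export
remove_gap_only_columns <- function(msa) {
  msa <- as_msa(msa)
  mat <- do.call(rbind, lapply(msa, .as_chars))
  gap_only <- apply(mat, 2, function(col) all(col %in% c("-", ".")))
  out <- apply(mat[, !gap_only, drop = FALSE], 1, .collapse)
  stats::setNames(out, names(msa))
}

#' Map alignment columns to reference (Ty1-H3) coordinates
#'
#' @param msa alignment containing the reference row.
#' @param ref_id name of the reference row.
#' @return integer vector, one entry per alignment column: the 1-based
#'   reference coordinate of the reference base at that column; gap columns
#'   carry the coordinate of the preceding reference base (0 before the
#'   first).
#' @export
msa_ref_coords <- function(msa, ref_id) {
  msa <- as_msa(msa)
  if (!ref_id %in% names(msa))
    stop("reference '", ref_id, "' not present in alignment")
  ref <- .as_chars(msa[[ref_id]])
  cumsum(!ref %in% c("-", "."))
}

#' Slice alignment columns by a reference-coordinate region
#'
#' Selects the columns whose Ty1-H3 coordinate (via [msa_ref_coords()])
#' falls inside the region; alignment columns where the reference is
#' gapped belong to the region of the preceding reference base, so
#' adjacent regions partition the reference-anchored columns.
#'
#' @param msa alignment containing the reference row.
#' @param region integer `c(start, end)`, 1-based inclusive reference
#'   coordinates.
#' @param ref_id name of the reference row.
#' @return the sliced alignment (named character vector).
#' @export
slice_msa_region <- function(msa, region, ref_id) {
  msa <- as_msa(msa)
  coords <- msa_ref_coords(msa, ref_id)
  if (region[1] < 1 || region[2] > max(coords))
    stop("region ", region[1], "-", region[2],
         " outside the reference coordinate map (1-", max(coords), ")")
  keep <- coords >= region[1] & coords <= region[2]
  vapply(msa, function(row) .collapse(.as_chars(row)[keep]), character(1))
}

#' Read / write (aligned) FASTA
#'
#' Thin wrappers over Biostrings I/O returning/accepting named character
#' vectors, with 60-column wrapping on write.
#'
#' @param path file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60)
  invisible(path)
}

#' Write a planted genome and its ground truth to disk
#'
#' Emits `genome.fa`, `library.fa`, `rawhits.out` (RepeatMasker .out
#' layout) and `truth_elements.tsv` into `outdir`; the files round-trip
#' through the package's own readers.
#'
#' @param truth a [plant_genome()] result.
#' @param outdir output directory (created if needed).
#' @export
write_genome_truth <- function(truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$genome, file.path(outdir, "genome.fa"))
  lib <- unlist(lapply(truth$library, function(e)
    stats::setNames(list(e$ltr, e$internal),
                    paste0(e$family, c("_LTR", "_I")))), recursive = FALSE)
  write_fasta(unlist(lib), file.path(outdir, "library.fa"))
  hits <- truth$raw_hits
  hits$is_fp <- NULL
  write_rm_out(hits, file.path(outdir, "rawhits.out"))
  el <- truth$elements
  el$breakpoints <- vapply(el$breakpoints, function(b)
    paste(b, collapse = ","), character(1))
  el$seq <- NULL
  utils::write.table(el, file.path(outdir, "truth_elements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
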