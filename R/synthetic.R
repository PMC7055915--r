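#' Parameters for the K2P sequence-evolution simulator
#'
#' @param divergence expected substitutions per site (>= 0) between the
#'   ancestor and the evolved copy.
#' @param kappa transition/transversion rate ratio (> 0; `Inf` allowed for
#'   the transitions-only limit).
#' @param indel_rate expected indel events per site (>= 0; default 0 so
#'   synthetic alignments stay column-aligned).
#' @param seed optional integer seed; identical seeds give identical output.
#' @return a list of class `"evolution_params"`.
#' @export
evolution_params <- function(divergence, kappa = 2, indel_rate = 0,
                             seed = NULL) {
  if (!is.finite(divergence) || divergence < 0)
    stop("divergence must be finite and non-negative")
  if (is.na(kappa) || kappa <= 0)
    stop("kappa must be > 0")
  if (!is.finite(indel_rate) || indel_rate < 0)
    stop("indel_rate must be finite and non-negative")
  structure(list(divergence = divergence, kappa = kappa,
                 indel_rate = indel_rate, seed = seed),
            class = "evolution_params")
}

# per-site substitution probabilities of the K80 transition-probability
# matrix at total distance d: returns c(same, transition, each transversion)
.k2p_sub_probs <- function(d, kappa) {
  if (is.infinite(kappa)) {
    at <- d
    bt <- 0
  } else {
    bt <- d / (kappa + 2)
    at <- kappa * bt
  }
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv   = 0.25 - 0.25 * e1)
}

#' Evolve a sequence under the Kimura 2-parameter model
#'
#' Each site is drawn independently from the exact K2P
#' transition-probability matrix at the requested expected distance, so the
#' expected K2P distance between ancestor and output equals
#' `params$divergence` (no Gillespie simulation needed: the closed form has
#' the same marginal law).  With `indel_rate > 0`, Poisson-many indel
#' events (1-3 bp, insertion or deletion with equal probability) are
#' additionally applied.
#'
#' @param ancestor a nucleotide string over A/C/G/T (non-empty).
#' @param params an [evolution_params()] object.
#' @return the evolved nucleotide string.
#' @export
evolve_sequence <- function(ancestor, params) {
  stopifnot(inherits(params, "evolution_params"))
  anc <- .as_chars(ancestor)
  if (length(anc) == 0) stop("ancestor sequence is empty")
  if (!all(anc %in% c("A", "C", "G", "T")))
    stop("ancestor contains non-ACGT characters")
  if (!is.null(params$seed)) set.seed(params$seed)
  out <- .evolve_chars(anc, params$divergence, params$kappa)
  if (params$indel_rate > 0) {
    n_events <- stats::rpois(1, params$indel_rate * length(out))
    for (i in seq_len(n_events)) {
      pos <- sample.int(length(out), 1)
      len <- sample.int(3, 1)
      if (stats::runif(1) < 0.5) {
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        out <- append(out, ins, after = pos)
      } else {
        drop <- pos:min(pos + len - 1, length(out))
        if (length(drop) < length(out)) out <- out[-drop]
      }
    }
  }
  .collapse(out)
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

.evolve_chars <- function(anc, divergence, kappa) {
  if (divergence == 0) return(anc)
  p <- .k2p_sub_probs(divergence, kappa)
  fate <- sample.int(4, length(anc), replace = TRUE,
                     prob = c(p["same"], p["ts"], p["tv"], p["tv"]))
  out <- anc
  i_ts <- fate == 2L
  out[i_ts] <- .TRANSITION[anc[i_ts]]
  i_tv1 <- fate == 3L
  out[i_tv1] <- vapply(anc[i_tv1], function(b) .TRANSVERSIONS[[b]][1],
                       character(1))
  i_tv2 <- fate == 4L
  out[i_tv2] <- vapply(anc[i_tv2], function(b) .TRANSVERSIONS[[b]][2],
                       character(1))
  out
}

# evolve with region-specific divergences: regions is a list of
# list(interval = c(start, end) 1-based, divergence = d); positions not
# covered use `background`
.evolve_by_region <- function(seq, regions, background, kappa) {
  chars <- .as_chars(seq)
  div <- rep(background, length(chars))
  for (r in regions) div[r$interval[1]:r$interval[2]] <- r$divergence
  out <- chars
  for (d in unique(div)) {
    idx <- which(div == d)
    out[idx] <- .evolve_chars(chars[idx], d, kappa)
  }
  .collapse(out)
}

#' Build a recombinant sequence with known breakpoints
#'
#' Segments alternate between `seq_a` and `seq_b` (starting with `seq_a`),
#' switching source exactly at each breakpoint.  Breakpoints are 0-based
#' positions in the shared coordinate system: a breakpoint at `p` means
#' positions `1..p` (1-based) come from the current source and `p+1..`
#' from the other.
#'
#' @param seq_a,seq_b nucleotide strings of equal length (a shared aligned
#'   coordinate system).
#' @param breakpoints strictly increasing integer positions in
#'   `(0, length)`.
#' @return a list with `sequence` (the mosaic string) and `truth` (a list
#'   recording `breakpoints` and the per-segment `source` labels).
#' @export
build_recombinant <- function(seq_a, seq_b, breakpoints = integer(0)) {
  a <- .as_chars(seq_a)
  b <- .as_chars(seq_b)
  if (length(a) != length(b)) stop("seq_a and seq_b must have equal length")
  bp <- as.integer(breakpoints)
  if (length(bp) > 0) {
    if (is.unsorted(bp, strictly = TRUE))
      stop("breakpoints must be strictly increasing")
    if (any(bp <= 0L) || any(bp >= length(a)))
      stop("breakpoints must lie strictly inside the sequence")
  }
  bounds <- c(0L, bp, length(a))
  out <- a
  src <- character(length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    if (i %% 2 == 0) out[idx] <- b[idx]
    src[i] <- if (i %% 2 == 1) "a" else "b"
  }
  list(sequence = .collapse(out),
       truth = list(breakpoints = bp, source = src))
}

#' Error modes injected into synthetic raw annotation hits
#'
#' These emulate the error classes that the curation operations fix:
#' mislabelled LTR fragments, tandem copies joined under one hit-group id,
#' nearby solo LTRs fused to an adjacent element, and false-positive hits
#' to divergent sequence.
#'
#' @param p_mislabel_ltr probability that an LTR fragment of a full-length
#'   or truncated element is emitted under the other family's LTR name.
#' @param p_merge_tandem probability that all copies of a tandem array are
#'   emitted under a single hit-group id (sharing the internal LTR hit).
#' @param p_fuse_solo probability that a nearby solo LTR is emitted under
#'   the adjacent element's hit-group id.
#' @param fp_rate expected false-positive hits per 100 kb.
#' @param fp_div_range range (percent) from which false-positive divergence
#'   is drawn uniformly; lower bound must exceed 20.
#' @return a list of class `"error_modes"`.
#' @export
error_modes <- function(p_mislabel_ltr = 0, p_merge_tandem = 0,
                        p_fuse_solo = 0, fp_rate = 0,
                        fp_div_range = c(25, 45)) {
  probs <- c(p_mislabel_ltr, p_merge_tandem, p_fuse_solo)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (fp_rate < 0) stop("fp_rate must be non-negative")
  if (fp_div_range[1] <= 20)
    stop("false-positive divergence range must lie above 20%")
  structure(list(p_mislabel_ltr = p_mislabel_ltr,
                 p_merge_tandem = p_merge_tandem,
                 p_fuse_solo = p_fuse_solo,
                 fp_rate = fp_rate, fp_div_range = fp_div_range),
            class = "error_modes")
}

#' Synthetic canonical Ty query library
#'
#' Generates random i.i.d. ACGT reference sequences mimicking the layout of
#' a canonical Ty query library: per family an LTR entry (`<family>_LTR`)
#' and an internal entry (`<family>_I`).  Default lengths follow the
#' canonical elements (Ty1: 334 bp LTRs + 5250 bp internal = 5918 bp total;
#' Ty2: 332 + 5296 = 5960 bp total).
#'
#' @param families character vector of family names.
#' @param ltr_lengths,internal_lengths named integer vectors per family.
#' @param seed optional integer seed.
#' @return a list of class `"ty_library"`; per family: `ltr`, `internal`
#'   (sequences), `ltr_length`, `internal_length`, `canonical_total_length`
#'   (`2 * LTR + internal`).
#' @export
synthetic_ty_library <- function(families = c("Ty1", "Ty2"),
                                 ltr_lengths = c(Ty1 = 334, Ty2 = 332),
                                 internal_lengths = c(Ty1 = 5250, Ty2 = 5296),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lib <- lapply(families, function(f) {
    ll <- ltr_lengths[[f]]
    il <- internal_lengths[[f]]
    if (ll <= 0 || il <= 0) stop("library lengths must be positive")
    list(family = f,
         ltr = .collapse(sample(c("A", "C", "G", "T"), ll, replace = TRUE)),
         internal = .collapse(sample(c("A", "C", "G", "T"), il,
                                     replace = TRUE)),
         ltr_length = as.integer(ll),
         internal_length = as.integer(il),
         canonical_total_length = as.integer(2 * ll + il))
  })
  names(lib) <- families
  class(lib) <- "ty_library"
  lib
}

.library_full_seq <- function(lib, family) {
  e <- lib[[family]]
  paste0(e$ltr, e$internal, e$ltr)
}

# slice of the library reference in full-element coordinates
.library_ref_slice <- function(lib, family, start, end) {
  substr(.library_full_seq(lib, family), start, end)
}

#' Subfamily reference sequences for synthetic Ty1 elements
#'
#' One ancestral full-length Ty1 is evolved into a canonical and a Ty1'
#' reference whose pairwise divergence is concentrated in the gag region
#' (default 0.10 substitutions/site in gag, 0.02 elsewhere), plus an
#' S. paradoxus-like reference whose gag stays close to canonical while the
#' backbone diverges, emulating the horizontal-transfer signature.  Default
#' divergences are configurable conventions, not measured values.
#'
#' @param library a [synthetic_ty_library()].
#' @param regions region annotation (see [load_region_annotation()]); its
#'   `gag` interval delimits the high-divergence region.
#' @param gag_divergence,backbone_divergence pairwise canonical-vs-Ty1'
#'   divergence inside/outside gag.
#' @param kappa transition/transversion ratio.
#' @return named list of full-length sequences: `canonical`, `ty1prime`,
#'   `sparadoxus`.
#' @export
subfamily_references <- function(library, regions = load_region_annotation(),
                                 gag_divergence = 0.10,
                                 backbone_divergence = 0.02, kappa = 2) {
  anc <- .library_full_seq(library, "Ty1")
  gag <- list(list(interval = regions$gag, divergence = gag_divergence / 2))
  canonical <- .evolve_by_region(anc, gag, backbone_divergence / 2, kappa)
  ty1prime <- .evolve_by_region(anc, gag, backbone_divergence / 2, kappa)
  spar <- .evolve_by_region(
    canonical,
    list(list(interval = regions$gag, divergence = 0.01)),
    0.08, kappa)
  list(canonical = canonical, ty1prime = ty1prime, sparadoxus = spar)
}

#' Configuration for a synthetic planted genome
#'
#' @param elements data frame of element specs with columns `family`,
#'   `subfamily` (`canonical`, `ty1prime`, `mosaic`, `sparadoxus`, or `NA`
#'   for non-Ty1 families), `structural_class` (`full_length`, `truncated`,
#'   `solo_ltr`), `strand` (`+`/`-`), optional `trunc_kind` (`five_prime` or
#'   `internal`) and optional `start` (0-based genomic; either all `NA` for
#'   automatic layout or all set for explicit placement).
#' @param tandem_arrays list of specs `list(n, family, subfamily)` for
#'   tandem arrays of `n` full-length copies sharing internal LTRs
#'   (planted on the plus strand).
#' @param nearby_solos number of solo LTRs planted 150-400 bp from a
#'   full-length/truncated element (candidates for the fused-solo error).
#' @param chrom chromosome name of the single synthetic sequence.
#' @param errors an [error_modes()] object.
#' @param element_divergence within-subfamily divergence applied per
#'   planted copy.
#' @param kappa transition/transversion ratio.
#' @param gag_divergence,backbone_divergence passed to
#'   [subfamily_references()].
#' @param gap_range range (bp) of background spacer lengths between
#'   planted units.
#' @param fuse_gap_range range (bp) of the distance between a nearby solo
#'   and its host element.
#' @return a list of class `"ty_sim_config"`.
#' @export
ty_sim_config <- function(elements, tandem_arrays = list(),
                          nearby_solos = 0, chrom = "chrI",
                          errors = error_modes(),
                          element_divergence = 0.005, kappa = 2,
                          gag_divergence = 0.10, backbone_divergence = 0.02,
                          gap_range = c(600, 2000),
                          fuse_gap_range = c(150, 400)) {
  stopifnot(is.data.frame(elements) || nrow_null(elements))
  if (!inherits(errors, "error_modes")) stop("errors must be error_modes()")
  if (gap_range[1] <= 100)
    stop("gap_range must exceed the curation gap tolerance")
  structure(list(elements = elements, tandem_arrays = tandem_arrays,
                 nearby_solos = nearby_solos, chrom = chrom, errors = errors,
                 element_divergence = element_divergence, kappa = kappa,
                 gag_divergence = gag_divergence,
                 backbone_divergence = backbone_divergence,
                 gap_range = gap_range, fuse_gap_range = fuse_gap_range),
            class = "ty_sim_config")
}

nrow_null <- function(x) is.null(x) || nrow(x) == 0

#' Draw a random valid synthetic-genome configuration
#'
#' Samples a small strain-like layout: 1-4 full-length Ty1 (mixed
#' subfamilies including occasional mosaics), 0-3 truncated, 1-5 solo LTRs
#' (Ty1 or Ty2), an optional 2-3 copy tandem array, an occasional Ty2
#' full-length element, and 0-2 nearby solos.  Error modes are all enabled.
#'
#' @param seed integer seed.
#' @return a [ty_sim_config()].
#' @export
random_ty_config <- function(seed) {
  set.seed(seed)
  n_full <- sample(1:4, 1)
  n_trunc <- sample(0:3, 1)
  n_solo <- sample(1:5, 1)
  n_ty2 <- stats::rbinom(1, 1, 0.4)
  specs <- rbind(
    data.frame(family = "Ty1",
               subfamily = sample(c("canonical", "ty1prime", "mosaic"),
                                  n_full, replace = TRUE,
                                  prob = c(0.45, 0.45, 0.1)),
               structural_class = "full_length",
               strand = sample(c("+", "-"), n_full, replace = TRUE),
               trunc_kind = NA_character_),
    if (n_trunc > 0)
      data.frame(family = "Ty1",
                 subfamily = sample(c("canonical", "ty1prime"), n_trunc,
                                    replace = TRUE),
                 structural_class = "truncated",
                 strand = sample(c("+", "-"), n_trunc, replace = TRUE),
                 trunc_kind = sample(c("five_prime", "internal"), n_trunc,
                                     replace = TRUE)),
    if (n_solo > 0)
      data.frame(family = sample(c("Ty1", "Ty2"), n_solo, replace = TRUE),
                 subfamily = NA_character_,
                 structural_class = "solo_ltr",
                 strand = sample(c("+", "-"), n_solo, replace = TRUE),
                 trunc_kind = NA_character_),
    if (n_ty2 > 0)
      data.frame(family = "Ty2", subfamily = NA_character_,
                 structural_class = "full_length",
                 strand = sample(c("+", "-"), n_ty2, replace = TRUE),
                 trunc_kind = NA_character_))
  specs$start <- NA_integer_
  tand <- if (stats::runif(1) < 0.5)
    list(list(n = sample(2:3, 1), family = "Ty1",
              subfamily = sample(c("canonical", "ty1prime"), 1)))
  else list()
  ty_sim_config(
    elements = specs[sample.int(nrow(specs)), , drop = FALSE],
    tandem_arrays = tand,
    nearby_solos = sample(0:2, 1),
    errors = error_modes(p_mislabel_ltr = 0.5, p_merge_tandem = 0.5,
                         p_fuse_solo = 0.5, fp_rate = 2))
}

# ---- genome planting ----

#' Plant Ty elements into a synthetic genome with full ground truth
#'
#' Builds a random background genome (i.i.d. uniform ACGT, so it has no
#' homology to the Ty library), inserts the configured elements
#' (reverse-complemented on the minus strand), and emits the raw
#' annotation hits that a homology search would produce - one fragment per
#' LTR/internal region - plus the configured error modes.
#'
#' @param config a [ty_sim_config()].
#' @param seed integer seed; identical `(config, seed)` give byte-identical
#'   output.
#' @return a list of class `"genome_truth"`: `genome` (named character
#'   vector), `elements` (truth data frame with planted coordinates,
#'   classes, subfamilies, breakpoints and element-oriented sequences),
#'   `raw_hits` (data frame in the raw-hit layout, including injected
#'   errors and an `is_fp` flag), `truth_counts` (per-family counts in the
#'   [count_by_family()] layout), `library`, `refs`, `config`, `seed`.
#' @export
plant_genome <- function(config, seed = 1) {
  stopifnot(inherits(config, "ty_sim_config"))
  set.seed(seed)
  regions <- load_region_annotation()
  library <- synthetic_ty_library()
  refs <- subfamily_references(library, regions,
                               gag_divergence = config$gag_divergence,
                               backbone_divergence = config$backbone_divergence,
                               kappa = config$kappa)
  units <- .build_units(config, library, refs, regions)
  .assemble_genome(units, config, library, refs, seed)
}

# one "unit" = a single element or a tandem array, built in element
# orientation with unit-local 1-based coordinates
.build_units <- function(config, library, refs, regions) {
  units <- list()
  specs <- config$elements
  explicit <- FALSE
  if (!nrow_null(specs)) {
    if (is.null(specs$trunc_kind)) specs$trunc_kind <- NA_character_
    if (is.null(specs$start)) specs$start <- NA_integer_
    explicit <- all(!is.na(specs$start))
    if (!explicit && any(!is.na(specs$start)))
      stop("either all or none of the element starts may be given")
    for (i in seq_len(nrow(specs))) {
      units <- c(units, list(.build_single_unit(
        specs[i, ], config, library, refs, regions)))
    }
  }
  for (ta in config$tandem_arrays) {
    units <- c(units, list(.build_tandem_unit(ta, config, library, refs,
                                              regions)))
  }
  # nearby solos attach to a random full/truncated host unit
  host_ok <- vapply(units, function(u)
    any(u$elements$structural_class %in% c("full_length", "truncated")),
    logical(1))
  n_near <- if (any(host_ok)) config$nearby_solos else 0
  for (i in seq_len(n_near)) {
    host <- sample(which(host_ok), 1)
    solo <- .build_single_unit(
      data.frame(family = "Ty1", subfamily = NA_character_,
                 structural_class = "solo_ltr", strand = "+",
                 trunc_kind = NA_character_, start = NA_integer_),
      config, library, refs, regions)
    solo$fused_to <- host
    units <- c(units, list(solo))
  }
  if (explicit) {
    starts <- vapply(units[seq_len(nrow(specs))], function(u) u$spec_start,
                     numeric(1))
    ord <- order(starts)
    ends <- starts + vapply(units[seq_len(nrow(specs))],
                            function(u) nchar(u$seq), numeric(1))
    if (any(starts[ord][-1] < ends[ord][-length(ord)]))
      stop("explicitly placed elements overlap (only tandem arrays may share LTRs)")
    units <- units[ord]
  }
  units
}

.build_single_unit <- function(spec, config, library, refs, regions) {
  fam <- spec$family
  lib <- library[[fam]]
  ep <- evolution_params(config$element_divergence, config$kappa)
  if (fam == "Ty1" && !is.na(spec$subfamily)) {
    base <- switch(spec$subfamily,
                   canonical = refs$canonical,
                   ty1prime = refs$ty1prime,
                   sparadoxus = refs$sparadoxus,
                   mosaic = build_recombinant(refs$canonical, refs$ty1prime,
                                              regions$gag[2])$sequence)
    breakpoints <- if (spec$subfamily == "mosaic") regions$gag[2] else integer(0)
  } else {
    base <- .library_full_seq(library, fam)
    breakpoints <- integer(0)
  }
  total <- lib$canonical_total_length
  ll <- lib$ltr_length
  if (spec$structural_class == "solo_ltr") {
    seq <- evolve_sequence(substr(base, 1, ll), ep)
    frags <- data.frame(kind = "LTR", family = fam, rep_start = 1,
                        rep_end = ll, u_start = 1, u_end = ll)
    el_len <- ll
  } else if (spec$structural_class == "full_length") {
    seq <- evolve_sequence(base, ep)
    frags <- data.frame(
      kind = c("LTR", "I", "LTR"), family = fam,
      rep_start = c(1, ll + 1, total - ll + 1),
      rep_end = c(ll, total - ll, total),
      u_start = c(1, ll + 1, total - ll + 1),
      u_end = c(ll, total - ll, total))
    el_len <- total
  } else {  # truncated: < 95% of canonical length, internal present
    full <- evolve_sequence(base, ep)
    max_len <- floor(0.95 * total) - 100
    kind <- spec$trunc_kind
    if (is.na(kind)) kind <- "five_prime"
    if (kind == "five_prime") {
      keep_to <- sample(seq(ll + 150, min(max_len, total - ll - 100)), 1)
      seq <- substr(full, 1, keep_to)
      frags <- data.frame(
        kind = c("LTR", "I"), family = fam,
        rep_start = c(1, ll + 1), rep_end = c(ll, keep_to),
        u_start = c(1, ll + 1), u_end = c(ll, keep_to))
      el_len <- keep_to
    } else {  # internal-only slice
      len <- sample(500:min(max_len, lib$internal_length - 100), 1)
      from <- sample(seq(ll + 1, total - ll - len), 1)
      seq <- substr(full, from, from + len - 1)
      frags <- data.frame(
        kind = "I", family = fam,
        rep_start = from, rep_end = from + len - 1,
        u_start = 1, u_end = len)
      el_len <- len
    }
    breakpoints <- integer(0)
  }
  list(seq = seq, strand = spec$strand, family = fam,
       frags = frags,
       elements = data.frame(
         family = fam,
         subfamily = if (is.na(spec$subfamily)) NA_character_ else spec$subfamily,
         structural_class = spec$structural_class,
         u_start = 1, u_end = el_len),
       breakpoints = list(breakpoints),
       element_seqs = list(seq),
       fused_to = NA_integer_,
       spec_start = if (!is.null(spec$start)) spec$start else NA_integer_)
}

.build_tandem_unit <- function(ta, config, library, refs, regions) {
  fam <- ta$family
  lib <- library[[fam]]
  ll <- lib$ltr_length
  total <- lib$canonical_total_length
  ep <- evolution_params(config$element_divergence, config$kappa)
  base <- if (fam == "Ty1" && !is.null(ta$subfamily))
    switch(ta$subfamily, canonical = refs$canonical,
           ty1prime = refs$ty1prime, refs$canonical)
  else .library_full_seq(library, fam)
  copies <- lapply(seq_len(ta$n), function(i) evolve_sequence(base, ep))
  # array sequence: copy1 in full, then each later copy minus its 5' LTR
  # (the previous copy's 3' LTR is the shared LTR)
  seq <- paste0(copies[[1]],
                paste(vapply(copies[-1], function(s)
                  substr(s, ll + 1, total), character(1)), collapse = ""))
  frags <- data.frame(kind = "LTR", family = fam, rep_start = 1,
                      rep_end = ll, u_start = 1, u_end = ll)
  off <- ll
  for (i in seq_len(ta$n)) {
    frags <- rbind(frags,
                   data.frame(kind = "I", family = fam,
                              rep_start = ll + 1, rep_end = total - ll,
                              u_start = off + 1,
                              u_end = off + lib$internal_length),
                   data.frame(kind = "LTR", family = fam,
                              rep_start = total - ll + 1, rep_end = total,
                              u_start = off + lib$internal_length + 1,
                              u_end = off + lib$internal_length + ll))
    off <- off + lib$internal_length + ll
  }
  frags$copy <- c(1, rep(seq_len(ta$n), each = 2))
  # element i spans shared LTR (i-1) .. shared LTR i
  step <- lib$internal_length + ll
  el <- data.frame(family = fam,
                   subfamily = if (!is.null(ta$subfamily)) ta$subfamily
                   else NA_character_,
                   structural_class = "full_length",
                   u_start = (seq_len(ta$n) - 1) * step + 1,
                   u_end = (seq_len(ta$n) - 1) * step + total)
  list(seq = seq, strand = "+", family = fam, frags = frags,
       elements = el,
       breakpoints = rep(list(integer(0)), ta$n),
       element_seqs = lapply(seq_len(ta$n), function(i)
         substr(seq, el$u_start[i], el$u_end[i])),
       fused_to = NA_integer_, spec_start = NA_integer_,
       tandem = TRUE)
}

.assemble_genome <- function(units, config, library, refs, seed) {
  err <- config$errors
  pieces <- character(0)
  offset <- 0L  # 0-based genomic position where next piece begins
  hit_rows <- list()
  truth_rows <- list()
  group_counter <- 0L
  unit_offsets <- numeric(length(units))
  unit_first_group <- integer(length(units))

  place_unit <- function(u, g0) {
    L <- nchar(u$seq)
    if (u$strand == "-") {
      piece <- reverse_complement(u$seq)
      to_genomic <- function(s, e) c(g0 + (L - e + 1), g0 + (L - s + 1))
    } else {
      piece <- u$seq
      to_genomic <- function(s, e) c(g0 + s, g0 + e)
    }
    list(piece = piece, to_genomic = to_genomic)
  }

  # order: as given; nearby solos are pulled next to their host unit
  fused_idx <- which(vapply(units, function(u) !is.na(u$fused_to), logical(1)))
  main_idx <- setdiff(seq_along(units), fused_idx)
  order_idx <- integer(0)
  for (i in main_idx) {
    order_idx <- c(order_idx, i, fused_idx[vapply(units[fused_idx],
      function(u) u$fused_to, numeric(1)) == i])
  }

  last_gap_was_fuse <- FALSE
  for (k in seq_along(order_idx)) {
    i <- order_idx[k]
    u <- units[[i]]
    gap <- if (!is.na(u$fused_to))
      sample(seq(config$fuse_gap_range[1], config$fuse_gap_range[2]), 1)
    else
      sample(seq(config$gap_range[1], config$gap_range[2]), 1)
    pieces <- c(pieces, .collapse(sample(c("A", "C", "G", "T"), gap,
                                         replace = TRUE)))
    offset <- offset + gap
    unit_offsets[i] <- offset
    placed <- place_unit(u, offset)
    pieces <- c(pieces, placed$piece)

    # truth elements
    for (j in seq_len(nrow(u$elements))) {
      ge <- placed$to_genomic(u$elements$u_start[j], u$elements$u_end[j])
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        chrom = config$chrom,
        start = ge[1] - 1L, end = ge[2],  # 0-based half-open
        strand = u$strand,
        family = u$elements$family[j],
        subfamily = u$elements$subfamily[j],
        structural_class = u$elements$structural_class[j],
        breakpoints = I(list(u$breakpoints[[j]])),
        seq = u$element_seqs[[j]])
    }

    # hit-group ids
    is_tandem <- isTRUE(u$tandem)
    n_copies <- nrow(u$elements)
    if (is_tandem) {
      merged <- stats::runif(1) < err$p_merge_tandem
      if (merged) {
        group_counter <- group_counter + 1L
        gids_by_copy <- rep(group_counter, n_copies)
      } else {
        gids_by_copy <- group_counter + seq_len(n_copies)
        group_counter <- group_counter + n_copies
      }
    } else {
      merged <- FALSE
      if (!is.na(u$fused_to) && stats::runif(1) < err$p_fuse_solo) {
        gid <- unit_first_group[u$fused_to]
      } else {
        group_counter <- group_counter + 1L
        gid <- group_counter
      }
      gids_by_copy <- gid
    }
    unit_first_group[i] <- gids_by_copy[1]

    # raw hits: one per fragment; shared tandem LTRs are duplicated into
    # both copies when the array is emitted pre-split (see vignette)
    emit_frag <- function(fr, gid) {
      gq <- placed$to_genomic(fr$u_start, fr$u_end)
      frag_seq <- substr(u$seq, fr$u_start, fr$u_end)
      ref_seq <- .library_ref_slice(library, fr$family, fr$rep_start,
                                    fr$rep_end)
      div <- 100 * k2p_distance(frag_seq, ref_seq)$distance
      name_fam <- fr$family
      if (fr$kind == "LTR" &&
          any(u$elements$structural_class %in%
              c("full_length", "truncated")) &&
          stats::runif(1) < err$p_mislabel_ltr) {
        name_fam <- if (fr$family == "Ty1") "Ty2" else "Ty1"
      }
      data.frame(score = round((fr$rep_end - fr$rep_start + 1) *
                                 (1 - div / 100)),
                 pct_divergence = round(div, 1),
                 pct_deleted = 0, pct_inserted = 0,
                 query_id = config$chrom,
                 query_start = gq[1], query_end = gq[2],
                 query_left = 0L,
                 strand = u$strand,
                 repeat_name = paste0(name_fam, "_",
                                      if (fr$kind == "LTR") "LTR" else "I"),
                 repeat_class = "LTR/Copia",
                 rep_start = fr$rep_start, rep_end = fr$rep_end,
                 rep_left = 0L,
                 hit_group_id = gid, is_fp = FALSE)
    }
    if (is_tandem && !merged) {
      # pre-split representation: shared LTR hit appears in both copies
      for (ci in seq_len(n_copies)) {
        lo <- u$elements$u_start[ci]
        hi <- u$elements$u_end[ci]
        sel <- u$frags$u_start >= lo & u$frags$u_end <= hi
        for (fi in which(sel))
          hit_rows[[length(hit_rows) + 1L]] <-
            emit_frag(u$frags[fi, ], gids_by_copy[ci])
      }
    } else {
      for (fi in seq_len(nrow(u$frags)))
        hit_rows[[length(hit_rows) + 1L]] <-
          emit_frag(u$frags[fi, ], gids_by_copy[1])
    }
    offset <- offset + nchar(placed$piece)
  }
  tail_gap <- sample(seq(config$gap_range[1], config$gap_range[2]), 1)
  pieces <- c(pieces, .collapse(sample(c("A", "C", "G", "T"), tail_gap,
                                       replace = TRUE)))
  genome_seq <- paste(pieces, collapse = "")
  glen <- nchar(genome_seq)

  # false positives: divergent hits anywhere, uniform divergence above 20%
  n_fp <- stats::rpois(1, err$fp_rate * glen / 1e5)
  for (i in seq_len(n_fp)) {
    len <- sample(100:400, 1)
    s <- sample.int(max(glen - len, 1), 1)
    fam <- sample(names(library), 1)
    kind <- sample(c("LTR", "I"), 1)
    group_counter <- group_counter + 1L
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      score = sample(200:400, 1),
      pct_divergence = round(stats::runif(1, err$fp_div_range[1],
                                          err$fp_div_range[2]), 1),
      pct_deleted = 0, pct_inserted = 0,
      query_id = config$chrom, query_start = s, query_end = s + len - 1,
      query_left = 0L, strand = sample(c("+", "-"), 1),
      repeat_name = paste0(fam, "_", kind), repeat_class = "LTR/Copia",
      rep_start = 1L, rep_end = len, rep_left = 0L,
      hit_group_id = group_counter, is_fp = TRUE)
  }

  hits <- do.call(rbind, hit_rows)
  hits <- hits[order(hits$query_id, hits$query_start, hits$query_end), ]
  rownames(hits) <- NULL
  elements <- do.call(rbind, truth_rows)
  elements <- elements[order(elements$chrom, elements$start), ]
  rownames(elements) <- NULL

  genome <- stats::setNames(genome_seq, config$chrom)
  out <- list(genome = genome, elements = elements, raw_hits = hits,
              truth_counts = .tally_counts(elements$family,
                                           elements$structural_class),
              library = library, refs = refs, config = config, seed = seed)
  class(out) <- "genome_truth"
  out
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf("Synthetic genome (%s, %d bp) with %d planted Ty elements\n",
              names(x$genome)[1], nchar(x$genome[[1]]), nrow(x$elements)))
  print(x$truth_counts)
  cat(sprintf("%d raw hits (%d false positives)\n",
              nrow(x$raw_hits), sum(x$raw_hits$is_fp)))
  invisible(x)
}

#' Simulate replicate mobility-assay counts
#'
#' Event counts per 1 ml culture are drawn Poisson with mean
#' `true_frequency * cells_per_ml`, emulating replicate cultures plated for
#' revertant colonies.
#'
#' @param true_frequency mobility events per viable cell (>= 0).
#' @param n_replicates number of replicate cultures (default 4,
#'   quadruplicate cultures).
#' @param cells_per_ml viable (Ura+) cells per ml of culture.
#' @param seed optional integer seed.
#' @return a list of class `"mobility_sim"` with `replicate_events` and
#'   `uraplus_per_ml`.
#' @export
simulate_mobility_counts <- function(true_frequency, n_replicates = 4,
                                     cells_per_ml = 1e7, seed = NULL) {
  if (true_frequency < 0) stop("true_frequency must be non-negative")
  if (n_replicates < 1) stop("n_replicates must be positive")
  if (cells_per_ml <= 0) stop("cells_per_ml must be positive")
  lambda <- true_frequency * cells_per_ml
  if (!is.finite(lambda)) stop("expected event count is not finite")
  if (!is.null(seed)) set.seed(seed)
  structure(list(replicate_events = stats::rpois(n_replicates, lambda),
                 uraplus_per_ml = cells_per_ml),
            class = "mobility_sim")
}
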