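#' Mobility frequency and standard deviation from replicate counts
#'
#' Frequency is the mean number of mobility events per 1 ml culture
#' divided by the number of viable (Ura+) cells per ml; the standard
#' deviation is the sample SD (n-1 denominator) of the per-replicate
#' frequencies, i.e. computed from the number of events detected per 1 ml
#' culture.
#'
#' @param replicate_events integer revertant counts per 1 ml culture.
#' @param uraplus_per_ml viable cell titer (> 0).
#' @return list with `frequency` and `sd` (events per viable cell).
#' @export
mobility_frequency <- function(replicate_events, uraplus_per_ml) {
  if (uraplus_per_ml <= 0) stop("titer must be positive")
  if (length(replicate_events) < 1 || any(replicate_events < 0))
    stop("replicate_events must be non-negative counts")
  per_rep <- replicate_events / uraplus_per_ml
  sd <- if (length(per_rep) > 1) stats::sd(per_rep) else 0
  list(frequency = mean(per_rep), sd = sd)
}

#' Fold change between two mobility frequencies
#'
#' When the low value is a detection-limit bound ("< x"), the ratio is a
#' lower bound on the true fold change and is flagged as such.
#'
#' @param high,low frequencies (same units).
#' @param low_is_bound `TRUE` when `low` is a "<" detection-limit value.
#' @return list of class `"fold_change"` with `ratio` and `lower_bound`.
#' @export
fold_change <- function(high, low, low_is_bound = FALSE) {
  if (low < 0 || high < 0) stop("frequencies must be non-negative")
  if (low == 0) {
    ratio <- Inf
    lower_bound <- TRUE
  } else {
    ratio <- high / low
    lower_bound <- isTRUE(low_is_bound)
  }
  structure(list(ratio = ratio, lower_bound = lower_bound),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%s%.1f-fold\n", if (x$lower_bound) ">= " else "", x$ratio))
  invisible(x)
}

#' Spearman rank correlation with exact small-sample option
#'
#' Mid-ranks are used for ties; rho is the Pearson correlation of the rank
#' vectors.  The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df when ties are
#' present (or when `exact = FALSE`); for tie-free data with `n <= 9` the
#' exact permutation distribution over all `n!` rank permutations is
#' enumerated.
#'
#' @param x,y numeric vectors, equal length >= 3, no missing values.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) chooses it automatically for tie-free `n <= 9`.
#' @return list of class `"correlation_result"` with `rho`, `p_value`,
#'   `n`, `tie_note` (`TRUE` when either vector has ties) and `method`.
#' @export
spearman <- function(x, y, exact = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  rx <- rank(x)
  ry <- rank(y)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          tie_note = ties, method = "undefined (constant)"),
                     class = "correlation_result"))
  }
  rho <- stats::cor(rx, ry)
  if (is.null(exact)) exact <- !ties && n <= 9
  if (exact && ties)
    stop("exact permutation p-value requires tie-free data")
  if (exact) {
    perms <- .permutations(n)
    m <- nrow(perms)
    d2 <- (matrix(rx, m, n, byrow = TRUE) -
             matrix(ry[perms], m, n))^2
    rho_perm <- 1 - 6 * rowSums(d2) / (n^3 - n)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, tie_note = ties,
                 method = method),
            class = "correlation_result")
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.7f, p = %.5g (n = %d, %s%s)\n",
              x$rho, x$p_value, x$n, x$method,
              if (x$tie_note) ", ties present" else ""))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's.  A table with a zero margin is degenerate and gives
#' p = 1.
#'
#' @param tab a 2x2 matrix (or something coercible) of non-negative
#'   counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  if (sum(tab) == 0) stop("table total must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Count substitutions between two codon-aligned sequences
#'
#' Shared-gap columns are removed first; the remaining alignment must be a
#' whole number of codons.  Codon pairs containing a gap are counted as
#' indel events (one event per maximal run of gapped codons), not as
#' substitutions.  Amino acid substitutions are codon pairs translating to
#' different residues; nucleotide substitutions are counted per site.
#' Counts are partitioned by region membership of the codon's first
#' nucleotide position (coordinates in the shared-gap-free frame).
#'
#' @param aln_a,aln_b codon-aligned nucleotide strings of equal length.
#' @param regions optional named list; each entry is an interval
#'   `c(start, end)` or a list of intervals (1-based positions in the
#'   shared-gap-free alignment frame).
#' @return list of class `"substitution_summary"`:
#'   `aa_substitutions_total`, `aa_substitutions_by_region`,
#'   `nt_substitutions_total`, `nt_substitutions_by_region`,
#'   `indel_events`, `n_codons`.
#' @export
count_substitutions <- function(aln_a, aln_b, regions = NULL) {
  a <- .as_chars(aln_a)
  b <- .as_chars(aln_b)
  if (length(a) != length(b)) stop("alignments must have equal length")
  shared_gap <- a %in% c("-", ".") & b %in% c("-", ".")
  a <- a[!shared_gap]
  b <- b[!shared_gap]
  if (length(a) %% 3 != 0)
    stop("alignment length not divisible by 3 after removing shared gaps")
  n_codons <- length(a) %/% 3
  starts <- 3 * (seq_len(n_codons) - 1) + 1
  cod_a <- vapply(starts, function(s) .collapse(a[s:(s + 2)]), character(1))
  cod_b <- vapply(starts, function(s) .collapse(b[s:(s + 2)]), character(1))
  has_gap <- grepl("-|\\.", cod_a) | grepl("-|\\.", cod_b)
  aa_a <- .translate_codons(cod_a)
  aa_b <- .translate_codons(cod_b)
  aa_sub <- !has_gap & !is.na(aa_a) & !is.na(aa_b) & aa_a != aa_b
  indel_events <- sum(diff(c(FALSE, has_gap)) == 1)
  nt_diff_site <- a != b & a %in% c("A", "C", "G", "T") &
    b %in% c("A", "C", "G", "T")

  in_any <- function(pos, reg) {
    if (is.numeric(reg)) reg <- list(reg)
    Reduce(`|`, lapply(reg, function(r) pos >= r[1] & pos <= r[2]))
  }
  aa_by_region <- nt_by_region <- NULL
  if (!is.null(regions)) {
    aa_by_region <- vapply(regions, function(reg)
      sum(aa_sub & in_any(starts, reg)), numeric(1))
    nt_by_region <- vapply(regions, function(reg)
      sum(nt_diff_site & in_any(seq_along(a), reg)), numeric(1))
  }
  structure(list(aa_substitutions_total = sum(aa_sub),
                 aa_substitutions_by_region = aa_by_region,
                 nt_substitutions_total = sum(nt_diff_site),
                 nt_substitutions_by_region = nt_by_region,
                 indel_events = indel_events,
                 n_codons = n_codons),
            class = "substitution_summary")
}

#' Nei-Gojobori (1986) dN/dS between two codon-aligned sequences
#'
#' Counting estimator with equal pathway weighting: per codon,
#' synonymous/nonsynonymous site fractions are averaged over the two
#' sequences (mutations creating stop codons count as nonsynonymous);
#' differences are averaged over all orderings of the observed changes,
#' excluding pathways through stop codons when any stop-free pathway
#' exists.  Proportions are Jukes-Cantor corrected
#' (`d = -3/4 log(1 - 4p/3)`); `pS >= 0.75` is saturated and gives
#' `dS = NA`.  Codons containing gaps or ambiguity codes are excluded.
#'
#' @param aln_a,aln_b codon-aligned nucleotide strings.
#' @return list of class `"dnds_result"` with `dN`, `dS`, `ratio`
#'   (`NA` when `dS` is 0 or undefined), `N_sites`, `S_sites`, `N_diffs`,
#'   `S_diffs`, `n_codons`.
#' @export
ng86_dnds <- function(aln_a, aln_b) {
  a <- .as_chars(aln_a)
  b <- .as_chars(aln_b)
  if (length(a) != length(b)) stop("alignments must have equal length")
  shared_gap <- a %in% c("-", ".") & b %in% c("-", ".")
  a <- a[!shared_gap]
  b <- b[!shared_gap]
  if (length(a) %% 3 != 0)
    stop("alignment length not divisible by 3 after removing shared gaps")
  n <- length(a) %/% 3
  nt <- c("A", "C", "G", "T")
  S_sites <- N_sites <- S_diffs <- N_diffs <- 0
  n_used <- 0L
  for (i in seq_len(n)) {
    ca <- a[(3 * i - 2):(3 * i)]
    cb <- b[(3 * i - 2):(3 * i)]
    if (!all(c(ca, cb) %in% nt)) next
    aa_a <- .translate_codons(.collapse(ca))
    aa_b <- .translate_codons(.collapse(cb))
    if (is.na(aa_a) || is.na(aa_b) || aa_a == "*" || aa_b == "*") next
    n_used <- n_used + 1L
    S_sites <- S_sites + (.syn_sites(ca) + .syn_sites(cb)) / 2
    diff_pos <- which(ca != cb)
    if (length(diff_pos) > 0) {
      path <- .pathway_diffs(ca, cb, diff_pos)
      S_diffs <- S_diffs + unname(path["syn"])
      N_diffs <- N_diffs + unname(path["nonsyn"])
    }
  }
  N_sites <- 3 * n_used - S_sites
  pS <- if (S_sites > 0) S_diffs / S_sites else 0
  pN <- if (N_sites > 0) N_diffs / N_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS)
  dN <- jc(pN)
  ratio <- if (is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(list(dN = dN, dS = dS, ratio = ratio,
                 N_sites = N_sites, S_sites = S_sites,
                 N_diffs = N_diffs, S_diffs = S_diffs,
                 n_codons = n_used),
            class = "dnds_result")
}

# fraction of the 9 possible single-base changes that are synonymous,
# expressed in sites (0..3); changes to stop codons are nonsynonymous
.syn_sites <- function(codon) {
  nt <- c("A", "C", "G", "T")
  aa0 <- .translate_codons(.collapse(codon))
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(nt, codon[pos])) {
      mut <- codon
      mut[pos] <- alt
      if (identical(.translate_codons(.collapse(mut)), aa0)) syn <- syn + 1
    }
  }
  syn / 3
}

# average synonymous/nonsynonymous difference counts over all orderings of
# the observed changes between two codons (stop-free pathways preferred)
.pathway_diffs <- function(ca, cb, diff_pos) {
  k <- length(diff_pos)
  orders <- .permutations(k)
  res <- matrix(NA_real_, nrow(orders), 2)
  blocked <- logical(nrow(orders))
  for (o in seq_len(nrow(orders))) {
    cur <- ca
    syn <- nonsyn <- 0
    ok <- TRUE
    for (step in diff_pos[orders[o, ]]) {
      nxt <- cur
      nxt[step] <- cb[step]
      aa1 <- .translate_codons(.collapse(cur))
      aa2 <- .translate_codons(.collapse(nxt))
      if (identical(aa2, "*")) ok <- FALSE
      if (identical(aa1, aa2)) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    res[o, ] <- c(syn, nonsyn)
    blocked[o] <- !ok
  }
  use <- if (all(blocked)) seq_len(nrow(res)) else which(!blocked)
  c(syn = mean(res[use, 1]), nonsyn = mean(res[use, 2]))
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dN = %.4g, dS = %.4g, dN/dS = %s (%d codons)\n",
              x$dN, x$dS,
              if (is.na(x$ratio)) "NA" else sprintf("%.4g", x$ratio),
              x$n_codons))
  invisible(x)
}

#' Bundled reference panel of Saccharomyces strains
#'
#' Returns the package's bundled tables for a ten-strain S. cerevisiae /
#' S. paradoxus panel: per-strain Ty1-H3 mobility frequencies (with
#' detection-limit bounds), the populated-strain mobility comparison, and
#' per-strain Ty1 content partitioned by gag type.  Frequencies are in
#' events per viable cell.
#'
#' @return list of data frames: `mobility`, `populated`, `ty1_content`.
#' @export
ty_strain_panel <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "tyland"),
    stringsAsFactors = FALSE)
  list(mobility = rd("strain_mobility.tsv"),
       populated = rd("populated_mobility.tsv"),
       ty1_content = rd("ty1_content.tsv"))
}
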