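#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the K2P distance `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`
#' where `P` and `Q` are the proportions of transition and transversion
#' differences among usable sites.  Sites where either row carries a gap
#' (`-`, `.`) or an ambiguity code are excluded pairwise (pairwise deletion).
#'
#' @param a,b aligned sequences: single strings or character vectors of
#'   single characters, equal length.
#' @return a list of class `"k2p"` with elements `distance`, `P`, `Q`,
#'   `usable_sites`, and `reason` (`NULL` for a defined distance, otherwise a
#'   string saying why the distance is `NA`: `"no usable sites"` or
#'   `"saturated"`).
#' @examples
#' a <- strrep("ACGT", 25)
#' b <- sub("^A", "G", a)   # one transition among 100 sites
#' k2p_distance(a, b)
#' @export
k2p_distance <- function(a, b) {
  a <- .as_chars(a)
  b <- .as_chars(b)
  if (length(a) != length(b))
    stop("sequences must have equal aligned length")
  cls <- .k2p_site_classes(a, b)
  .k2p_from_counts(sum(cls$usable), sum(cls$ts), sum(cls$tv))
}

# per-site classification reused by the windowed machinery
.k2p_site_classes <- function(a, b) {
  pur <- c("A", "G")
  valid <- c("A", "C", "G", "T")
  usable <- a %in% valid & b %in% valid
  diff <- usable & a != b
  same_class <- (a %in% pur) == (b %in% pur)
  list(usable = usable, ts = diff & same_class, tv = diff & !same_class)
}

.k2p_from_counts <- function(n, n_ts, n_tv) {
  out <- list(distance = NA_real_, P = NA_real_, Q = NA_real_,
              usable_sites = as.integer(n), reason = NULL)
  class(out) <- "k2p"
  if (n == 0L) {
    out$reason <- "no usable sites"
    return(out)
  }
  P <- n_ts / n
  Q <- n_tv / n
  out$P <- P
  out$Q <- Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    out$reason <- "saturated"
    return(out)
  }
  out$distance <- -0.5 * log(w1) - 0.25 * log(w2)
  out
}

#' @export
print.k2p <- function(x, ...) {
  if (is.na(x$distance)) {
    cat(sprintf("K2P distance: NA (%s; usable sites = %d)\n",
                x$reason, x$usable_sites))
  } else {
    cat(sprintf("K2P distance: %.6f (P = %.4f, Q = %.4f, usable sites = %d)\n",
                x$distance, x$P, x$Q, x$usable_sites))
  }
  invisible(x)
}

#' Sliding-window K2P divergence along an aligned pair
#'
#' Divergence is computed in overlapping windows over alignment columns
#' (default 50 bp windows with a 10 bp step).  A window distance is `NA`
#' when fewer than `min_usable` sites are usable or the K2P transform is
#' undefined (saturation).  Window coordinates are 0-based half-open on
#' alignment columns; only full-width windows are emitted unless the
#' alignment is shorter than one window, in which case a single truncated
#' window covers it.
#'
#' @param a,b aligned sequences (strings or character vectors, equal length).
#' @param window window width in alignment columns.
#' @param step step size in alignment columns.
#' @param min_usable minimum usable (non-gap, non-ambiguous in both rows)
#'   sites for a window distance to be reported.
#' @return a data frame of class `"ty_window_track"` with columns
#'   `start`, `end`, `usable_sites`, `P`, `Q`, `distance`.
#' @export
sliding_window_divergence <- function(a, b, window = 50, step = 10,
                                      min_usable = 25) {
  a <- .as_chars(a)
  b <- .as_chars(b)
  if (length(a) != length(b))
    stop("sequences must have equal aligned length")
  if (step <= 0) stop("step must be positive")
  len <- length(a)
  if (len <= window) {
    starts <- 0L
    ends <- len
  } else {
    starts <- seq.int(0L, len - window, by = step)
    ends <- starts + window
  }
  cls <- .k2p_site_classes(a, b)
  cu <- cumsum(cls$usable)
  cts <- cumsum(cls$ts)
  ctv <- cumsum(cls$tv)
  win_sum <- function(cs) cs[ends] - c(0, cs)[starts + 1L]
  n <- win_sum(cu)
  n_ts <- win_sum(cts)
  n_tv <- win_sum(ctv)
  P <- ifelse(n > 0, n_ts / n, NA_real_)
  Q <- ifelse(n > 0, n_tv / n, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- ifelse(n >= min_usable & !is.na(w1) & w1 > 0 & w2 > 0,
              -0.5 * log(pmax(w1, .Machine$double.xmin)) -
                0.25 * log(pmax(w2, .Machine$double.xmin)),
              NA_real_)
  track <- data.frame(start = starts, end = ends,
                      usable_sites = as.integer(n),
                      P = P, Q = Q, distance = d)
  attr(track, "window") <- window
  attr(track, "step") <- step
  class(track) <- c("ty_window_track", "data.frame")
  track
}

#' @exportS3Method graphics::plot
plot.ty_window_track <- function(x, xlab = "alignment position (bp)",
                                 ylab = "K2P distance (subst./site)", ...) {
  mid <- (x$start + x$end) / 2
  graphics::plot(mid, x$distance, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Pairwise K2P distance matrix from a multiple sequence alignment
#'
#' @param msa a named character vector of equal-length aligned sequences
#'   (rows), or a `Biostrings::DNAStringSet`.
#' @return a symmetric numeric matrix with zero diagonal, labelled by the
#'   alignment row names.  Any pair with an undefined K2P distance is an
#'   error naming the offending pair(s).
#' @export
distance_matrix <- function(msa) {
  msa <- as_msa(msa)
  n <- length(msa)
  if (n < 2) stop("need at least 2 aligned sequences")
  rows <- lapply(msa, .as_chars)
  labs <- names(msa)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  bad <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k2p_distance(rows[[i]], rows[[j]])
      if (is.na(k$distance))
        bad <- c(bad, sprintf("%s vs %s (%s)", labs[i], labs[j], k$reason))
      d[i, j] <- d[j, i] <- k$distance
    }
  }
  if (length(bad) > 0)
    stop("undefined K2P distance for pair(s): ", paste(bad, collapse = "; "))
  d
}

# ---- small sequence utilities shared across modules ----

.as_chars <- function(x) {
  if (length(x) == 1L && is.character(x) && nchar(x) != 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1]]
  toupper(as.character(x))
}

.collapse <- function(x) paste(x, collapse = "")

#' Coerce an MSA-like object to a named character vector of aligned rows
#'
#' @param msa named character vector, list of strings, or
#'   `Biostrings::DNAStringSet`.
#' @return named character vector; an error if rows differ in length.
#' @export
as_msa <- function(msa) {
  if (inherits(msa, "XStringSet")) {
    out <- as.character(msa)
  } else if (is.list(msa)) {
    out <- vapply(msa, function(s) .collapse(.as_chars(s)), character(1))
  } else {
    out <- toupper(as.character(msa))
    names(out) <- names(msa)
  }
  if (length(unique(nchar(out))) > 1)
    stop("alignment rows have unequal lengths (ragged alignment)")
  if (is.null(names(out)))
    names(out) <- paste0("seq", seq_along(out))
  out
}

#' Reverse complement of a nucleotide string
#'
#' @param x a single nucleotide string (IUPAC codes allowed).
#' @return the reverse complement string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Length of a 1-based inclusive coordinate interval
#'
#' Standard GenBank-style interval arithmetic: the interval `start..end`
#' (1-based, both ends included) contains `end - start + 1` positions.
#'
#' @param start,end interval bounds, 1-based inclusive.
#' @return integer interval length.
#' @examples
#' interval_length(335, 1496)  # 1162
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  as.integer(end - start + 1)
}
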