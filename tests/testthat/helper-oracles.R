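# Independent oracles used across the suite.  These deliberately avoid the
# package's own implementation paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# closed-form K2P evaluation from explicit P/Q proportions
k2p_formula <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# exhaustive affine-gap global alignment score by enumerating every
# alignment of a and b (tiny inputs only); a gap run of length L scores
# gap_open + L * gap_extend
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap_open = -5, gap_extend = -1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      rec(i + 1, j + 1, score + s, "m")
    }
    if (i <= length(a)) {  # gap in b
      open <- if (state != "gb") gap_open else 0
      rec(i + 1, j, score + open + gap_extend, "gb")
    }
    if (j <= length(b)) {  # gap in a
      open <- if (state != "ga") gap_open else 0
      rec(i, j + 1, score + open + gap_extend, "ga")
    }
  }
  rec(1, 1, 0, "m")
  best
}

# two-sided Fisher exact p by direct hypergeometric enumeration over all
# tables with the observed margins
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  a_vals <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_vals, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force exact two-sided permutation p for Spearman (tie-free data)
brute_force_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- NULL
  gen <- function(v, acc) {
    if (length(v) == 0) {
      perms[[length(perms) + 1]] <<- acc
    } else {
      for (i in seq_along(v)) gen(v[-i], c(acc, v[i]))
    }
  }
  gen(seq_len(n), integer(0))
  hits <- vapply(perms, function(p) {
    abs(stats::cor(rx, ry[p])) >= abs(rho_obs) - 1e-12
  }, logical(1))
  mean(hits)
}

# a random unrooted binary tree on n tips with positive branch lengths,
# plus its exact path-length (additive) distance matrix
random_additive_case <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- paste0("t", seq_len(n))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# hand K2P counting on two character vectors (simple reference loop)
count_ts_tv <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  pur <- c("A", "G")
  usable <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  ts <- 0L
  tv <- 0L
  for (i in which(usable & a != b)) {
    if ((a[i] %in% pur) == (b[i] %in% pur)) ts <- ts + 1L else tv <- tv + 1L
  }
  list(n = sum(usable), ts = ts, tv = tv)
}
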