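test_that("K2P distances match the closed-form formula", {
  a <- strrep("ACGTG", 10)
  expect_equal(k2p_distance(a, a)$distance, 0)
  expect_equal(k2p_distance(a, a)$P, 0)
  # 1 transition among 50 sites: d = -0.5 log(0.96)
  b <- paste0("G", substr(a, 2, 50))
  k <- k2p_distance(a, b)
  expect_equal(k$P, 0.02)
  expect_equal(k$Q, 0)
  expect_equal(k$distance, 0.020411, tolerance = 1e-6)
  expect_equal(k$distance, k2p_formula(0.02, 0), tolerance = 1e-12)
  # saturation: 5 transitions + 3 transversions in 10 sites
  x <- "AAAAAAAAAA"
  y <- "GGGGGCCCAA"
  sat <- k2p_distance(x, y)
  expect_true(is.na(sat$distance))
  expect_identical(sat$reason, "saturated")
  # gaps excluded pairwise
  g <- k2p_distance("AC-T", "ACGT")
  expect_equal(g$usable_sites, 3L)
})

test_that("K2P agrees with an independent reference implementation", {
  set.seed(31)
  anc <- random_dna(600)
  msa <- c(s1 = anc,
           s2 = evolve_sequence(anc, evolution_params(0.08, 3)),
           s3 = evolve_sequence(anc, evolution_params(0.15, 1.5)),
           s4 = evolve_sequence(anc, evolution_params(0.03, 2)))
  mine <- distance_matrix(msa)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(msa), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(mine, ref[rownames(mine), colnames(mine)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isSymmetric(mine))
  expect_true(all(diag(mine) == 0))
})

test_that("K2P approaches the p-distance for small divergence", {
  set.seed(4)
  for (i in 1:20) {
    anc <- random_dna(1000)
    ev <- evolve_sequence(anc, evolution_params(runif(1, 0, 0.05), 2))
    k <- k2p_distance(anc, ev)
    expect_lt(abs(k$distance - (k$P + k$Q)), 0.01)
  }
})

test_that("window tracks tile the alignment as specified", {
  a <- strrep("A", 100)
  tw <- sliding_window_divergence(a, a)
  expect_equal(tw$start, seq(0, 50, 10))
  expect_true(all(tw$distance == 0))
  short <- sliding_window_divergence(strrep("A", 30), strrep("A", 30),
                                     window = 50, min_usable = 25)
  expect_equal(nrow(short), 1)
  expect_equal(short$end, 30)
  # low-coverage windows are NA
  gappy <- sliding_window_divergence(paste0(strrep("-", 40), strrep("A", 60)),
                                     strrep("A", 100))
  expect_true(is.na(gappy$distance[1]))
})

test_that("a recombinant's window track steps at the breakpoint", {
  set.seed(12)
  anc <- random_dna(1000)
  p <- evolution_params(0.05, 2)
  refA <- evolve_sequence(anc, p)
  refB <- evolve_sequence(anc, p)  # A-B divergence ~0.10
  q <- build_recombinant(refA, refB, 500)$sequence
  tw <- sliding_window_divergence(q, refA)
  left <- tw$distance[tw$end <= 450]
  right <- tw$distance[tw$start >= 550]
  expect_lt(mean(left), 0.02)
  expect_gt(mean(right), 0.06)
  # per-window values equal the direct formula on that window
  chars_q <- strsplit(q, "")[[1]]
  chars_a <- strsplit(refA, "")[[1]]
  for (i in c(1, 20, 60)) {
    idx <- (tw$start[i] + 1):tw$end[i]
    direct <- k2p_distance(chars_q[idx], chars_a[idx])$distance
    expect_equal(tw$distance[i], direct)
  }
})

test_that("NJ and BIONJ recover an additive 4-taxon tree exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  for (m in c("nj", "bionj")) {
    tr <- build_tree(d, m)
    expect_identical(tree_splits(tr), "C|D")  # AB|CD
    expect_setequal(round(tr$edge.length, 10), c(1, 2, 1, 3, 4))
    # path lengths reproduce the input matrix
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d)
  }
  expect_error(build_tree(d[1:2, 1:2]), "3 taxa")
  d_na <- d
  d_na[1, 2] <- NA
  expect_error(build_tree(d_na), "NA")
})

test_that("three taxa give the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_tree(d, "nj")
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  # a = (dAB + dAC - dBC)/2 etc.
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 4))
})

test_that("tree-metric recovery holds for random trees up to 8 taxa", {
  set.seed(42)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    case <- random_additive_case(n)
    truth <- tree_splits(case$tree)
    for (m in c("nj", "bionj")) {
      rec <- suppressMessages(build_tree(case$d, m))
      expect_setequal(tree_splits(rec), truth)
    }
  }
})

test_that("NJ and BIONJ agree on ultrametric matrices", {
  set.seed(2)
  tr <- ape::rcoal(6)
  tr$tip.label <- paste0("t", 1:6)
  d <- ape::cophenetic.phylo(tr)
  expect_setequal(tree_splits(suppressMessages(build_tree(d, "nj"))),
                  tree_splits(suppressMessages(build_tree(d, "bionj"))))
})

test_that("bootstrap gives full support to congruent signal", {
  set.seed(5)
  anc <- random_dna(400)
  p <- evolution_params(0.15, 2)
  c1 <- evolve_sequence(anc, p)
  c2 <- evolve_sequence(anc, p)
  msa <- c(A1 = c1, A2 = c1, A3 = c1, B1 = c2, B2 = c2, B3 = c2)
  bt <- suppressMessages(bootstrap_supports(msa, "bionj", replicates = 50,
                                            seed = 11))
  expect_true(all(bt$supports == 100))
  expect_true(all(bt$supports >= 0 & bt$supports <= 100))
  expect_equal(bt$n_used, 50)
  # determinism under a fixed seed
  bt2 <- suppressMessages(bootstrap_supports(msa, "bionj", replicates = 50,
                                             seed = 11))
  expect_identical(bt$supports, bt2$supports)
  # replicates = 0 gives the point tree, no supports
  bt0 <- suppressMessages(bootstrap_supports(msa, "bionj", replicates = 0))
  expect_null(bt0$supports)
  expect_s3_class(bt0$tree, "phylo")
})

test_that("newick output round-trips including support labels", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2,(C:3,D:4):1);", f)
  tr <- read_newick(f)
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_setequal(tree_splits(tr), tree_splits(tr2))
  expect_equal(sort(tr$edge.length), sort(tr2$edge.length))
  # internal labels survive
  tr$node.label <- c("", "97")
  write_newick(tr, f)
  expect_identical(read_newick(f)$node.label, c("", "97"))
  writeLines("(A:1,B:2", f)
  suppressWarnings(expect_error(read_newick(f)))
  # rotation-invariant equality on random trees
  set.seed(3)
  for (i in 1:5) {
    case <- random_additive_case(6)
    rot <- ape::rotate(ape::root(case$tree, "t1", resolve.root = TRUE), 8)
    expect_setequal(tree_splits(case$tree), tree_splits(rot))
  }
})
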