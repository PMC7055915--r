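test_that("extraction respects strand and block structure", {
  genome <- c(chrI = "TTTTAAGGTTTT")
  el <- data.frame(element_id = c("x_s1", "x_s2"), chrom = "chrI",
                   start = c(4L, 4L), end = c(8L, 8L),
                   strand = c("+", "-"), structural_class = "solo_ltr")
  el$blocks <- list(cbind(4L, 8L), cbind(4L, 8L))
  seqs <- extract_sequences(genome, el)
  expect_identical(unname(seqs[1]), "AAGG")
  expect_identical(unname(seqs[2]), "CCTT")  # reverse complement
  bad <- el
  bad$chrom <- "chrII"
  expect_error(extract_sequences(genome, bad), "chrII")
})

test_that("planted elements are recovered exactly by BED-driven extraction", {
  gt <- plant_genome(random_ty_config(13), seed = 13)
  ann <- suppressWarnings(annotate_ty(gt$raw_hits, gt$library, "synth"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(ann$elements, f)
  seqs1 <- extract_sequences(gt$genome, ann$elements)
  seqs2 <- extract_sequences(gt$genome, read_bed12(f))
  # write/read/extract is idempotent
  expect_identical(as.character(seqs1), as.character(seqs2))
  # full-length extractions equal the planted (evolved) element sequences
  fl <- ann$elements$structural_class == "full_length"
  truth_fl <- gt$elements$structural_class == "full_length"
  expect_setequal(unname(seqs1[fl]), gt$elements$seq[truth_fl])
})

test_that("global alignment scores match hand and brute-force oracles", {
  perfect <- global_align("ACGT", "ACGT")
  expect_equal(perfect$score, 4)
  expect_identical(perfect$aligned_a, "ACGT")
  one_mm <- global_align("ACGT", "ACCT")
  expect_equal(one_mm$score, 2)  # 3 matches - 1 mismatch
  expect_error(global_align("", "ACGT"), "empty")
  set.seed(6)
  for (i in 1:12) {
    a <- random_dna(sample(3:6, 1))
    b <- random_dna(sample(3:6, 1))
    expect_equal(global_align(a, b)$score, brute_force_align_score(a, b),
                 info = paste(a, b))
    # score symmetry under swapping inputs
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("truncated elements project onto the reference correctly", {
  set.seed(17)
  ref <- random_dna(5918)
  exact <- project_truncated(substr(ref, 1, 2000), ref)
  expect_equal(nrow(exact$intervals), 1)
  expect_equal(unname(exact$intervals[1, ]), c(1, 2000))
  expect_true(exact$spans_p22)  # p22 region lies inside [1, 2000]

  split2 <- project_truncated(
    paste0(substr(ref, 1, 1000), substr(ref, 3001, 4000)), ref)
  expect_equal(nrow(split2$intervals), 2)
  # block boundaries localized near the true junction (local alignments
  # can trade a handful of chance matches across the join)
  expect_lt(abs(split2$intervals[1, 1] - 1), 25)
  expect_lt(abs(split2$intervals[1, 2] - 1000), 25)
  expect_lt(abs(split2$intervals[2, 1] - 3001), 25)
  expect_lt(abs(split2$intervals[2, 2] - 4000), 25)
  expect_false(split2$spans_p22)

  none <- project_truncated(random_dna(1500), ref)
  expect_equal(nrow(none$intervals), 0)
  expect_false(none$spans_p22)
})

test_that("p22 ORF capacity requires an intact frame from a start codon", {
  regs <- load_region_annotation()
  set.seed(3)
  chars <- strsplit(random_dna(5918), "")[[1]]
  for (s in regs$p22_start_codons) chars[s:(s + 2)] <- c("A", "T", "G")
  frame_starts <- seq(regs$p22_start_codons[1], regs$p22_region[2] - 3, 3)
  for (k in frame_starts) {
    if (paste(chars[k:(k + 2)], collapse = "") %in% c("TAA", "TAG", "TGA"))
      chars[k] <- "C"
  }
  good <- paste(chars, collapse = "")
  oc <- check_orf_capacity(good, regs)
  expect_true(all(oc$intact))
  expect_true(attr(oc, "any_intact"))

  mid <- frame_starts[length(frame_starts) %/% 2]
  stopped <- chars
  stopped[mid:(mid + 2)] <- c("T", "A", "A")
  oc2 <- check_orf_capacity(paste(stopped, collapse = ""), regs)
  expect_false(any(oc2$intact))

  nostart <- chars
  for (s in regs$p22_start_codons) nostart[s + 2] <- "A"  # ATG -> ATA
  oc3 <- check_orf_capacity(paste(nostart, collapse = ""), regs)
  expect_false(any(oc3$intact))
  expect_false(attr(oc3, "any_intact"))
})

test_that("gap-only columns are removed and nothing else", {
  expect_identical(unname(remove_gap_only_columns(c(x = "A-C", y = "A-C"))),
                   c("AC", "AC"))
  expect_identical(unname(remove_gap_only_columns(c(x = "A-C", y = "AGC"))),
                   c("A-C", "AGC"))
  expect_error(remove_gap_only_columns(c("AC", "A")), "ragged")
  set.seed(8)
  rows <- vapply(1:4, function(i) {
    paste(sample(c("A", "C", "G", "T", "-"), 200, replace = TRUE,
                 prob = c(rep(0.2, 4), 0.2)), collapse = "")
  }, character(1))
  mat <- do.call(rbind, strsplit(rows, ""))
  n_gap_only <- sum(apply(mat, 2, function(col) all(col == "-")))
  out <- remove_gap_only_columns(rows)
  expect_equal(nchar(out[[1]]), 200 - n_gap_only)
})

test_that("region slicing follows the reference coordinate map", {
  ref <- strrep("A", 30)
  msa <- c(`Ty1-H3` = ref, q = strrep("C", 30))
  whole <- slice_msa_region(msa, c(1, 30), "Ty1-H3")
  expect_identical(unname(whole), unname(msa))
  sub <- slice_msa_region(msa, c(10, 20), "Ty1-H3")
  expect_equal(nchar(sub[[1]]), 11)
  # a 5-gap run before position 10 shifts the region columns by 5
  gapped <- c(`Ty1-H3` = paste0(strrep("A", 9), "-----", strrep("A", 21)),
              q = strrep("C", 35))
  sub2 <- slice_msa_region(gapped, c(10, 20), "Ty1-H3")
  expect_identical(unname(sub2["q"]), strrep("C", 11))
  coords <- msa_ref_coords(gapped, "Ty1-H3")
  expect_identical(which(coords >= 10 & coords <= 20), 15:25)
  expect_error(slice_msa_region(msa, c(1, 99), "Ty1-H3"), "outside")
  # adjacent regions partition the columns
  left <- slice_msa_region(gapped, c(1, 9), "Ty1-H3")
  right <- slice_msa_region(gapped, c(10, 30), "Ty1-H3")
  expect_equal(nchar(left[[1]]) + nchar(right[[1]]), 35)
})

test_that("FASTA writing and reading round-trips element sets", {
  set.seed(5)
  seqs <- c(a = random_dna(151), b = random_dna(73))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})
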