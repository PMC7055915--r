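make_hit <- function(query_start, query_end, repeat_name, group,
                     div = 5, strand = "+", chrom = "chrI") {
  data.frame(score = 1000, pct_divergence = div, pct_deleted = 0,
             pct_inserted = 0, query_id = chrom,
             query_start = as.integer(query_start),
             query_end = as.integer(query_end), query_left = 0L,
             strand = strand, repeat_name = repeat_name,
             repeat_class = "LTR/Copia", rep_start = 1L,
             rep_end = as.integer(query_end - query_start + 1),
             rep_left = 0L, hit_group_id = as.integer(group))
}

test_that("the .out parser handles empty files, C strands and round-trips", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("header", "header", ""), f)
  expect_equal(nrow(parse_rm_out(f)), 0)

  gt <- plant_genome(random_ty_config(21), seed = 21)
  hits <- gt$raw_hits
  hits$is_fp <- NULL
  write_rm_out(hits, f)
  back <- parse_rm_out(f)
  expect_equal(back$query_start, hits$query_start)
  expect_equal(back$query_end, hits$query_end)
  expect_identical(back$strand, hits$strand)
  expect_identical(back$repeat_name, hits$repeat_name)
  expect_identical(back$hit_group_id, hits$hit_group_id)
  expect_true(all(back$strand %in% c("+", "-")))

  writeLines(c("", "1000 5.0 0.0 0.0 chrI 100"), f)
  expect_error(parse_rm_out(f), "line 2")
})

test_that("the divergence filter removes strictly above 20%", {
  hits <- rbind(make_hit(1, 100, "Ty1_LTR", 1, div = 25.0),
                make_hit(200, 300, "Ty1_LTR", 2, div = 20.0),
                make_hit(400, 500, "Ty1_LTR", 3, div = 5.0))
  kept <- filter_false_positives(hits)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$pct_divergence <= 20))
  # counting oracle on a random mixture
  set.seed(1)
  divs <- runif(50, 0, 40)
  mixed <- do.call(rbind, lapply(seq_along(divs), function(i)
    make_hit(i * 1000, i * 1000 + 99, "Ty1_I", i, div = divs[i])))
  expect_equal(nrow(filter_false_positives(mixed)), sum(divs <= 20))
})

test_that("LTR fragments are relabelled from the contiguous internal", {
  grp <- rbind(make_hit(1, 334, "Ty2_LTR", 1),
               make_hit(335, 5584, "Ty1_I", 1),
               make_hit(5585, 5918, "Ty1_LTR", 1))
  out <- relabel_ltr_fragments(grp)
  expect_identical(out$repeat_name[1], "Ty1_LTR")
  # solo group untouched
  solo <- make_hit(1, 334, "Ty1_LTR", 1)
  expect_identical(relabel_ltr_fragments(solo), solo)
  # conflicting internal families: flagged, unchanged
  conflict <- rbind(make_hit(1, 334, "Ty2_LTR", 1),
                    make_hit(335, 3000, "Ty1_I", 1),
                    make_hit(3001, 5584, "Ty2_I", 1))
  expect_warning(out2 <- relabel_ltr_fragments(conflict), "multiple families")
  expect_identical(out2$repeat_name, conflict$repeat_name)
})

test_that("tandem arrays split into copies sharing the internal LTR", {
  tandem <- rbind(make_hit(1, 334, "Ty1_LTR", 9),
                  make_hit(335, 5584, "Ty1_I", 9),
                  make_hit(5585, 5918, "Ty1_LTR", 9),
                  make_hit(5919, 11168, "Ty1_I", 9),
                  make_hit(11169, 11502, "Ty1_LTR", 9))
  out <- split_tandem_arrays(tandem)
  expect_equal(nrow(out), 6)  # shared LTR duplicated
  expect_length(unique(out$hit_group_id), 2)
  shared <- out[out$query_start == 5585, ]
  expect_equal(nrow(shared), 2)
  expect_length(unique(shared$hit_group_id), 2)
  # simple L-I-L stays one group
  single <- tandem[1:3, ]
  expect_identical(split_tandem_arrays(single)$hit_group_id, rep(9L, 3))
})

test_that("fused solo LTRs are split into their own records", {
  grp <- rbind(make_hit(1, 334, "Ty1_LTR", 4),
               make_hit(335, 5584, "Ty1_I", 4),
               make_hit(5585, 5918, "Ty1_LTR", 4),
               make_hit(6419, 6752, "Ty1_LTR", 4))  # 500 bp downstream
  out <- split_fused_solos(grp)
  expect_length(unique(out$hit_group_id), 2)
  expect_equal(sum(out$hit_group_id == 4L), 3)
  # untouched when there is nothing to split
  clean <- grp[1:3, ]
  expect_identical(split_fused_solos(clean), clean)
})

test_that("the structural classification boundary sits at 95% of canonical", {
  lib <- synthetic_ty_library(seed = 1)
  grp_full <- rbind(make_hit(1, 334, "Ty1_LTR", 1),
                    make_hit(335, 5366, "Ty1_I", 1),
                    make_hit(5367, 5700, "Ty1_LTR", 1))
  expect_identical(classify_structure(grp_full, lib)$structural_class,
                   "full_length")  # 5700/5918 = 0.963 > 0.95
  grp_trunc <- rbind(make_hit(1, 334, "Ty1_LTR", 1),
                     make_hit(335, 5000, "Ty1_I", 1))
  expect_identical(classify_structure(grp_trunc, lib)$structural_class,
                   "truncated")  # 5000/5918 = 0.845
  solo <- make_hit(1, 334, "Ty1_LTR", 1)
  expect_identical(classify_structure(solo, lib)$structural_class,
                   "solo_ltr")
  expect_error(classify_structure(make_hit(1, 300, "Ty9_LTR", 1), lib),
               "unknown family")
  # the class changes exactly once along total length, strictly above 0.95
  canonical <- lib$Ty1$canonical_total_length
  classes <- vapply(c(5621, 5622, 5623), function(len) {
    grp <- rbind(make_hit(1, 334, "Ty1_LTR", 1),
                 make_hit(335, len, "Ty1_I", 1))
    classify_structure(grp, lib)$structural_class
  }, character(1))
  expect_identical(classes,
                   ifelse(c(5621, 5622, 5623) > 0.95 * canonical,
                          "full_length", "truncated"))
})

test_that("BED12 records round-trip and encode blocks correctly", {
  lib <- synthetic_ty_library(seed = 1)
  hits <- rbind(make_hit(101, 438, "Ty1_LTR", 1),
                make_hit(5501, 5838, "Ty1_LTR", 1, div = 4))
  el <- build_elements(hits, lib, strain = "S288c")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(el, f)
  line <- strsplit(readLines(f), "\t")[[1]]
  expect_identical(line[10], "2")
  expect_identical(line[11], "338,338")
  expect_identical(line[12], "0,5400")
  back <- read_bed12(f)
  expect_identical(back$element_id, el$element_id)
  expect_equal(back$blocks[[1]], el$blocks[[1]])
  expect_identical(back$structural_class, el$structural_class)
  # empty set -> empty, header-free file
  write_bed12(el[0, ], f)
  expect_identical(readLines(f), character(0))
  expect_equal(nrow(read_bed12(f)), 0)
})

test_that("hit coordinates survive the 1-based/0-based round trip", {
  lib <- synthetic_ty_library(seed = 1)
  set.seed(9)
  for (i in 1:20) {
    s <- sample.int(1e6, 1)
    e <- s + sample.int(5000, 1)
    hits <- make_hit(s, e, "Ty1_I", 1)
    el <- build_elements(hits, lib)
    b <- el$blocks[[1]]
    expect_equal(unname(b[1, 1]) + 1L, s)  # back to 1-based inclusive
    expect_equal(unname(b[1, 2]), e)
    expect_equal(el$total_length, e - s + 1)
  }
})

test_that("family counts tally classes and pool Ty1/Ty2 solo LTRs", {
  el <- data.frame(
    family = c("Ty1", "Ty1", "Ty1", "Ty2", "Ty2", "Ty2"),
    structural_class = c("full_length", "solo_ltr", "solo_ltr",
                         "solo_ltr", "solo_ltr", "solo_ltr"))
  cnt <- count_by_family(el)
  expect_identical(cnt$pooled_ty1_ty2_solo, 5L)
  expect_identical(cnt$by_family$n_full, c(1L, 0L))
  empty <- count_by_family(el[0, ])
  expect_equal(nrow(empty$by_family), 0)
  expect_identical(empty$pooled_ty1_ty2_solo, 0L)
})

test_that("curation reproduces planted truth and ignores added positives", {
  for (s in c(7, 19, 23, 31, 47, 101, 222, 333, 444, 555)) {
    gt <- plant_genome(random_ty_config(s), seed = s)
    ann <- suppressWarnings(annotate_ty(gt$raw_hits, gt$library,
                                        strain = "synth"))
    expect_identical(unclass(ann$counts), unclass(gt$truth_counts))
    # monotonicity: one more false positive never changes the counts
    extra <- gt$raw_hits[1, ]
    extra$pct_divergence <- 35
    extra$hit_group_id <- max(gt$raw_hits$hit_group_id) + 1L
    ann2 <- suppressWarnings(annotate_ty(rbind(gt$raw_hits, extra),
                                         gt$library, strain = "synth"))
    expect_identical(unclass(ann2$counts), unclass(gt$truth_counts))
  }
})
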