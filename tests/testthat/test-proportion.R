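# Proportion-of-total pipeline: locus scaling, share profiles, threshold
# classification and isomiR dominance.

test_that("locus scaling divides rows by their loci count", {
  x <- cm(c(10, 20, 9, 6), c("two_loci", "one_locus"), c("s1", "s2"))
  ann <- data.frame(mirna_id = c("two_loci", "one_locus"),
                    n_loci = c(2L, 1L))
  sc <- scale_by_loci(x, ann)
  expect_equal(unname(sc["two_loci", ]), c(5, 10))
  expect_equal(sc["one_locus", ], x["one_locus", ])  # n_loci 1 -> identity
  # total attributed reads conserved when split rows are re-summed
  split2 <- cm(c(10, 20, 10, 20), c("locA", "locB"), c("s1", "s2"))
  ann2 <- data.frame(mirna_id = c("locA", "locB"), n_loci = c(2L, 2L))
  expect_equal(colSums(scale_by_loci(split2, ann2)),
               colSums(split2) / 2)
  expect_error(scale_by_loci(x, ann[1, , drop = FALSE]), "one_locus")
})

test_that("share profiles reproduce the published liver share", {
  m <- liver_brain_fixture()
  prof <- proportion_profile(m)
  p122 <- prof[prof$mirna_id == "rno-miR-122-3p", ]
  expect_equal(p122$max_group, "liver")
  expect_equal(p122$max_share,
               4009.98 / (4009.98 + 0.168 + 0.045 + 0.134 + 0.092),
               tolerance = 1e-12)
  expect_gt(p122$max_share, 0.9998)
  # shares per miRNA sum to one
  sh <- attr(prof, "shares")
  expect_true(all(abs(rowSums(sh) - 1) < 1e-9))
  # uniform profile -> 1/N; single-group profile -> 1
  unif <- cm(rep(7, 4), "u", paste0("t", 1:4))
  expect_equal(proportion_profile(unif)$max_share, 0.25)
  solo <- cm(c(0, 0, 3), "s", paste0("t", 1:3))
  expect_equal(proportion_profile(solo)$max_share, 1)
})

test_that("share profiles are invariant to per-miRNA rescaling", {
  set.seed(13)
  m <- matrix(runif(40, 0, 100), 8, 5,
              dimnames = list(paste0("m", 1:8), paste0("t", 1:5)))
  prof1 <- proportion_profile(m)
  prof2 <- proportion_profile(m * runif(8, 0.1, 10))  # row-wise rescale
  expect_equal(attr(prof1, "shares"), attr(prof2, "shares"),
               tolerance = 1e-12)
})

test_that("threshold classification is strict and nested", {
  prof <- data.frame(
    mirna_id = c("hi", "mid", "edge", "low"),
    max_group = "liver",
    max_share = c(0.99989, 0.6, 0.9, 0.3), stringsAsFactors = FALSE)
  class(prof) <- c("proportion_profile", class(prof))
  calls <- classify_proportion(prof, level = "tissue")
  te <- calls$mirna_id[calls$status == "TE"]
  ts <- calls$mirna_id[calls$status == "TS"]
  expect_setequal(te, c("hi", "mid", "edge"))
  expect_setequal(ts, "hi")           # 0.9 exactly is TE only (strict >)
  expect_true(all(ts %in% te))
  org <- classify_proportion(prof, level = "organ")
  expect_setequal(org$mirna_id[org$status == "OS"], "hi")
  expect_error(classify_proportion(prof, te_threshold = 0.95,
                                   ts_threshold = 0.9), "exceed")
})

test_that("dominant isomiR comparison detects a planted switch", {
  sheet <- make_sheet(c("liver", "heart"), 2L)
  ids <- c("mat1.a", "mat1.b", "mat2.a", "mat2.b")
  # mat1: a dominant in liver, b dominant in heart; mat2: a everywhere
  x <- cm(c(90, 92, 10, 12,
            10, 11, 88, 95,
            70, 72, 69, 71,
            30, 29, 31, 28), ids, sheet$sample_id)
  ann <- data.frame(mirna_id = ids, n_loci = 1L,
                    parent_mature_id = rep(c("mat1", "mat2"), each = 2),
                    feature_class = "isomiR", stringsAsFactors = FALSE)
  dom <- isomir_dominance(x, ann, sheet)
  dif <- attr(dom, "differs")
  expect_true(dif[["mat1"]])
  expect_false(dif[["mat2"]])
  expect_equal(dom$dominant_isomir[dom$mature_id == "mat1" &
                                     dom$tissue == "liver"], "mat1.a")
  expect_equal(dom$dominant_isomir[dom$mature_id == "mat1" &
                                     dom$tissue == "heart"], "mat1.b")
  # proportions lie in [0, 1] and the dominant one is maximal (> 1/2 here)
  expect_true(all(dom$proportion >= 0.5 & dom$proportion <= 1))
})

test_that("isomiR ties break lexicographically and are flagged", {
  sheet <- make_sheet("liver", 2L)
  x <- cm(c(50, 50, 50, 50), c("mat1.b", "mat1.a"), sheet$sample_id)
  ann <- data.frame(mirna_id = c("mat1.b", "mat1.a"), n_loci = 1L,
                    parent_mature_id = "mat1", feature_class = "isomiR",
                    stringsAsFactors = FALSE)
  dom <- isomir_dominance(x, ann, sheet)
  expect_equal(dom$dominant_isomir, "mat1.a")
  expect_true(dom$tied)
})

test_that("full proportion pipeline keeps TS inside TE", {
  d <- atlas_design(n_mirnas = 40,
                    planted = planted_effects(3, c("liver", "heart",
                                                   "pancreas")),
                    seed = 5)
  a <- generate_atlas(d)
  fit <- run_proportion_pipeline(a$counts, a$sheet, a$annotation)
  te <- fit$calls$mirna_id[fit$calls$status == "TE"]
  ts <- fit$calls$mirna_id[fit$calls$status == "TS"]
  expect_true(all(ts %in% te))
  expect_true(all(a$truth$mirna_id %in% ts))
})
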