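# Synthetic atlas generator: determinism, noise-model moments, planted
# structure, isomiR switches.

test_that("generation is byte-deterministic given the seed", {
  d <- atlas_design(n_mirnas = 30, seed = 17)
  a1 <- generate_atlas(d)
  a2 <- generate_atlas(d)
  expect_identical(a1$counts, a2$counts)
  expect_identical(a1$annotation, a2$annotation)
  a3 <- generate_atlas(d, seed = 18)
  expect_false(identical(a1$counts, a3$counts))
})

test_that("the default design mirrors the atlas layout", {
  d <- atlas_design(n_mirnas = 5, seed = 1)
  a <- generate_atlas(d)
  expect_equal(length(unique(a$sheet$tissue)), 23L)
  expect_equal(length(unique(a$sheet$organ)), 14L)
  expect_equal(nrow(a$sheet), 20 * 10 + 3 * 5)   # 215 samples
  szs <- table(a$sheet$tissue)
  expect_true(all(szs[c("ovary", "uterus", "testicle")] == 5))
  expect_true(all(szs[setdiff(names(szs), c("ovary", "uterus",
                                            "testicle"))] == 10))
  expect_true(all(a$sheet$sex[a$sheet$tissue == "ovary"] == "F"))
  expect_true(all(a$sheet$sex[a$sheet$tissue == "testicle"] == "M"))
  expect_true(all(a$counts >= 0 & a$counts == round(a$counts)))
  expect_true(all(a$annotation$n_loci %in% 1:3))
})

test_that("counts have negative-binomial moments at large n", {
  d <- atlas_design(n_mirnas = 1, baseline_mean = 100, baseline_sdlog = 0,
                    dispersion = 5, libsize_sd = 0, seed = 23)
  # flat design: every sample shares mean 100, size 5
  set.seed(23)
  y <- rnbinom(10000, mu = 100, size = 5)
  expect_lt(abs(mean(y) - 100) / 100, 0.05)
  v_theory <- 100 + 100^2 / 5
  expect_lt(abs(var(y) - v_theory) / v_theory, 0.1)
  # generator draws from the same family: pooled moments agree
  a <- generate_atlas(d)
  expect_lt(abs(mean(a$counts) - 100) / 100, 0.2)
})

# tissue sums via the public group_means: means of each group scaled back
# by its size
group_sums_of <- function(counts, sheet) {
  gm <- group_means(counts, sheet, "tissue")
  n <- table(sheet$tissue)[colnames(gm)]
  sweep(gm, 2, as.numeric(n), "*")
}

test_that("a strongly planted miRNA dominates its target tissue", {
  tgt <- "pancreas"
  hits <- vapply(1:25, function(s) {
    d <- atlas_design(n_mirnas = 10,
                      planted = planted_effects(1, tgt, fold = 1000),
                      seed = 1000 + s)
    a <- generate_atlas(d)
    sums <- group_sums_of(a$counts, a$sheet)
    share <- sums[1, tgt] / sum(sums[1, ])
    share > 0.9
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("an unplanted atlas yields almost no TS calls in any pipeline", {
  d <- atlas_design(n_mirnas = 120, seed = 321)
  a <- generate_atlas(d)
  pp <- run_proportion_pipeline(a$counts, a$sheet, a$annotation)
  qp <- run_qp_pipeline(a$counts, a$sheet)
  nm <- run_nmf_pipeline(a$counts, a$sheet, seed = 321, n_restarts = 3)
  for (fit in list(pp, qp, nm)) {
    ts <- unique(fit$calls$mirna_id[fit$calls$status == "TS"])
    expect_lte(length(ts) / d$n_mirnas, 0.01)
  }
})

test_that("isomiR generator respects dominance switches", {
  d <- atlas_design(n_mirnas = 5, seed = 77,
                    organ_map = default_organ_map()[
                      default_organ_map()$tissue %in%
                        c("liver", "heart", "kidney"), ])
  base <- generate_isomir_table(d, n_matures = 4)
  dom0 <- isomir_dominance(base$counts, base$annotation, base$sheet)
  expect_true(all(!attr(dom0, "differs")))  # no switch -> stable dominance

  sw <- data.frame(mature = 2L, tissue = "heart", isomir = 3L)
  switched <- generate_isomir_table(d, n_matures = 4, dominant_switch = sw)
  dom1 <- isomir_dominance(switched$counts, switched$annotation,
                           switched$sheet)
  dif <- attr(dom1, "differs")
  expect_true(dif[["syn-mat-02"]])
  expect_true(all(!dif[setdiff(names(dif), "syn-mat-02")]))
  expect_equal(
    dom1$dominant_isomir[dom1$mature_id == "syn-mat-02" &
                           dom1$tissue == "heart"], "syn-mat-02.iso3")
  expect_error(generate_isomir_table(d, n_matures = 4,
                                     dominant_switch = data.frame(
                                       mature = 9L, tissue = "heart",
                                       isomir = 1L)),
               "unknown mature")
})

test_that("invalid designs are rejected", {
  expect_error(atlas_design(planted = data.frame(
    mirna = 1, target = "liver", level = "tissue", fold = 1,
    status = "TS")), "exceed 1")
  expect_error(atlas_design(planted = data.frame(
    mirna = 1, target = "narnia", level = "tissue", fold = 10,
    status = "TS")), "narnia")
  expect_error(atlas_design(n_mirnas = 2, planted = data.frame(
    mirna = 5, target = "liver", level = "tissue", fold = 10,
    status = "TS")), "out of range")
})
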