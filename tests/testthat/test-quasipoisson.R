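# Quasi-Poisson one-vs-rest GLM: IRLS correctness against stats::glm,
# calibration, and the TE/TS/OS decision rules.

qp_sheet <- function(n_t, n_r) {
  rbind(make_sheet("liver", n_t), make_sheet("heart", n_r))
}

test_that("coefficients and p-values match stats::glm on random data", {
  set.seed(77)
  for (k in 1:20) {
    n1 <- sample(3:8, 1); n0 <- sample(3:10, 1)
    y <- c(rnbinom(n1, mu = exp(runif(1, 2, 7)), size = 3) + 1,
           rnbinom(n0, mu = exp(runif(1, 2, 7)), size = 3) + 1)
    sheet <- qp_sheet(n1, n0)
    x <- matrix(y, 1, dimnames = list("m", sheet$sample_id))
    res <- fit_one_vs_rest(x, sheet, "liver")
    g <- glm(y ~ rep(c(1, 0), c(n1, n0)), family = quasipoisson(),
             control = glm.control(epsilon = 1e-14))
    sm <- summary(g)$coefficients
    expect_equal(res$coefficient, unname(sm[2, 1]), tolerance = 1e-6)
    expect_equal(res$p_value, unname(sm[2, 4]), tolerance = 1e-6)
    expect_equal(res$dispersion, summary(g)$dispersion, tolerance = 1e-6)
  }
})

test_that("clear enrichment and null contrasts behave as expected", {
  sheet_a <- rbind(make_sheet("liver", 3L), make_sheet("heart", 4L))
  x <- matrix(c(1000, 1100, 900, 10, 12, 9, 11), 1,
              dimnames = list("m", sheet_a$sample_id))
  res <- fit_one_vs_rest(x, sheet_a, "liver")
  expect_lt(res$p_value, 0.01)
  expect_true(res$direction_positive)

  sheet_b <- rbind(make_sheet("liver", 4L), make_sheet("heart", 4L))
  xb <- matrix(c(10, 11, 12, 10, 10, 11, 12, 10), 1,
               dimnames = list("m", sheet_b$sample_id))
  resb <- fit_one_vs_rest(xb, sheet_b, "liver")
  expect_lt(abs(resb$coefficient), 1e-8)
  expect_gt(resb$p_value, 0.5)

  # swapping target and rest flips the sign, identical p
  res_swap <- fit_one_vs_rest(xb, sheet_b, "heart")
  expect_equal(res_swap$coefficient, -resb$coefficient, tolerance = 1e-10)
  expect_equal(res_swap$p_value, resb$p_value, tolerance = 1e-10)
  res2 <- fit_one_vs_rest(x, sheet_a, "heart")
  expect_equal(res2$coefficient, -res$coefficient, tolerance = 1e-10)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-10)
})

test_that("all-zero and separated miRNAs are flagged, not silent", {
  sheet <- qp_sheet(3L, 3L)
  x <- rbind(zero = rep(0, 6), sep = c(100, 120, 110, 0, 0, 0))
  colnames(x) <- sheet$sample_id
  res <- fit_one_vs_rest(x, sheet, "liver")
  expect_equal(res$flag, c("all_zero", "separation"))
  expect_equal(res$p_value[1], 1)
  expect_equal(res$coefficient[1], 0)
  expect_true(is.finite(res$coefficient[2]))
  expect_true(res$direction_positive[2])
})

test_that("TE rule: strict alpha with positive direction", {
  res <- data.frame(mirna_id = c("a", "b", "c", "d"),
                    target = "liver", level = "tissue",
                    coefficient = c(2, -2, 1, 1),
                    dispersion = 1,
                    p_value = c(0.01, 0.01, 0.05, 0.049),
                    direction_positive = c(TRUE, FALSE, TRUE, TRUE),
                    flag = "ok", stringsAsFactors = FALSE)
  te <- detect_te_qp(res, alpha = 0.05)
  expect_setequal(te$mirna_id, c("a", "d"))  # negative and p == alpha out
})

test_that("percentage-point TS rule fires on the published worked rows", {
  m <- liver_brain_fixture()
  te <- make_calls(rownames(m), "quasipoisson", "TE", "liver",
                   1, 0.001)
  ts_excess <- detect_ts_qp(te, m, percent_points = 90, mode = "excess")
  # excess for rno-miR-122-5p: 100 * (69427.419 - 1.574) / 69427.419
  expect_true("rno-miR-122-5p" %in% ts_excess$mirna_id)
  sc <- ts_excess$score[ts_excess$mirna_id == "rno-miR-122-5p"]
  expect_equal(sc, 100 * (69427.419 - 1.574) / 69427.419, tolerance = 1e-12)
  expect_gte(sc, 90)
  # rno-miR-101b-3p fails under both readings
  ts_share <- detect_ts_qp(te, m, percent_points = 90, mode = "share")
  expect_false("rno-miR-101b-3p" %in% ts_excess$mirna_id)
  expect_false("rno-miR-101b-3p" %in% ts_share$mirna_id)
  # TS calls are a subset of TE calls
  expect_true(all(ts_excess$mirna_id %in% te$mirna_id))
  expect_true(all(ts_share$mirna_id %in% te$mirna_id))
  # target being the only expressed group -> excess 100 -> TS
  only <- cm(c(50, 0, 0), "solo", c("liver", "a", "b"))
  te1 <- make_calls("solo", "quasipoisson", "TE", "liver", 1, 0.001)
  ts1 <- detect_ts_qp(te1, only, percent_points = 90)
  expect_equal(ts1$score, 100)
})

test_that("dispersion estimate tracks the true noise model", {
  set.seed(31)
  sheet <- qp_sheet(10L, 10L)
  n_rep <- 150
  pois <- matrix(rpois(n_rep * 20, 100), n_rep, 20,
                 dimnames = list(paste0("p", 1:n_rep), sheet$sample_id))
  nb <- matrix(rnbinom(n_rep * 20, mu = 100, size = 2), n_rep, 20,
               dimnames = list(paste0("n", 1:n_rep), sheet$sample_id))
  disp_p <- fit_one_vs_rest(pois, sheet, "liver")$dispersion
  disp_n <- fit_one_vs_rest(nb, sheet, "liver")$dispersion
  expect_lt(abs(mean(disp_p) - 1), 0.2)
  expect_gt(mean(disp_n), 1.5)
})

test_that("organ-vs-rest detection needs an organ grouping", {
  sheet <- qp_sheet(3L, 3L)
  sheet$organ <- NA_character_
  x <- matrix(rpois(12, 50), 2, 6,
              dimnames = list(c("a", "b"), sheet$sample_id))
  expect_error(fit_one_vs_rest(x, sheet, "liver", level = "organ"),
               "organ")
})
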