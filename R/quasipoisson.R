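# One-vs-rest quasi-Poisson pipeline: log-link GLM with variance phi * mu,
# fitted by iteratively reweighted least squares; the dispersion phi is the
# Pearson chi-square over residual degrees of freedom, and the target-vs-rest
# coefficient is tested with a dispersion-adjusted Wald t statistic.

# IRLS for a Poisson-mean GLM with log link; design is an n x p matrix.
# Returns beta, the unscaled covariance solve(X'WX), fitted mu and deviance.
qp_irls <- function(y, X, beta0 = NULL, max_iter = 50L, tol = 1e-12) {
  n <- length(y)
  if (is.null(beta0)) {
    beta <- numeric(ncol(X))
    beta[1L] <- log(mean(y) + 0.1)
  } else beta <- beta0
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- pmax(exp(eta), 1e-12)
    z <- eta + (y - mu) / mu
    XtW <- t(X * mu)
    beta <- solve(XtW %*% X, XtW %*% z)
    eta <- drop(X %*% beta)
    mu <- pmax(exp(eta), 1e-12)
    pos <- y > 0
    dev <- 2 * (sum(y[pos] * log(y[pos] / mu[pos])) - sum(y) + sum(mu))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  XtW <- t(X * mu)
  list(beta = drop(beta), cov_unscaled = solve(XtW %*% X), mu = mu,
       deviance = dev, n_iter = it)
}

# one miRNA, binary target-vs-rest contrast
qp_fit_single <- function(y, is_target, cap = log(1e8)) {
  n <- length(y)
  n1 <- sum(is_target); n0 <- n - n1
  m1 <- mean(y[is_target]); m0 <- mean(y[!is_target])
  df <- n - 2L
  if (m1 == 0 && m0 == 0)
    return(list(coefficient = 0, dispersion = NA_real_, p_value = 1,
                direction_positive = FALSE, flag = "all_zero"))
  if (m0 == 0 || m1 == 0) {
    # perfect separation: one group entirely unexpressed; the log mean ratio
    # is unbounded -- cap it and treat the contrast as maximally significant
    return(list(coefficient = if (m0 == 0) cap else -cap,
                dispersion = NA_real_, p_value = 0,
                direction_positive = m0 == 0, flag = "separation"))
  }
  X <- cbind(1, as.numeric(is_target))
  fit <- qp_irls(y, X, beta0 = c(log(m0), log(m1 / m0)))
  pearson <- sum((y - fit$mu)^2 / fit$mu)
  phi <- pearson / df
  se <- sqrt(phi * fit$cov_unscaled[2L, 2L])
  tval <- fit$beta[2L] / se
  list(coefficient = fit$beta[2L], dispersion = phi,
       p_value = 2 * stats::pt(-abs(tval), df),
       direction_positive = fit$beta[2L] > 0, flag = "ok")
}

#' One-vs-rest quasi-Poisson fits for a target tissue or organ
#'
#' Fits, per miRNA, a quasi-Poisson GLM (log link, variance phi * mu) of its
#' per-million-ceiled counts on a target-vs-rest indicator, and tests the
#' target coefficient with a two-sided Wald t test on `n - 2` degrees of
#' freedom, using the Pearson chi-square / df dispersion estimate.
#'
#' All-zero miRNAs get `p = 1`, coefficient 0 and flag `all_zero`. A miRNA
#' expressed in only one of the two groups is perfectly separated: its
#' coefficient is capped (flag `separation`) and, being maximal evidence for
#' the expressed group, its p-value is reported as 0.
#'
#' @param counts miRNA x sample matrix, already transformed with
#'   [per_million_ceil()].
#' @param sheet sample sheet.
#' @param target tissue or organ label.
#' @param level `"tissue"` or `"organ"`; `"auto"` resolves the label against
#'   both columns.
#' @param mirna_ids subset of miRNAs to fit (default: all).
#' @return data.frame of class `qp_results`: one row per miRNA with
#'   `coefficient` (log mean ratio target vs rest), `dispersion`, `p_value`,
#'   `direction_positive`, `flag`, plus `target` and `level`.
#' @export
fit_one_vs_rest <- function(counts, sheet, target,
                            level = c("auto", "tissue", "organ"),
                            mirna_ids = NULL) {
  level <- match.arg(level)
  validate_counts(counts)
  sh <- match_sheet(counts, sheet)
  if (level == "auto")
    level <- if (target %in% sh$tissue) "tissue"
             else if (target %in% sh$organ) "organ"
             else stop("target '", target, "' is neither a tissue nor an organ",
                       call. = FALSE)
  groups <- sh[[level]]
  if (level == "organ" && (anyNA(groups) || !target %in% groups))
    stop("no organ grouping for target '", target, "'", call. = FALSE)
  is_target <- groups == target
  if (sum(is_target) < 2L || sum(!is_target) < 2L)
    stop("need at least 2 samples in the target group and 2 in the rest",
         call. = FALSE)
  if (is.null(mirna_ids)) mirna_ids <- rownames(counts)
  res <- lapply(mirna_ids, function(id)
    qp_fit_single(counts[id, ], is_target))
  out <- data.frame(
    mirna_id = mirna_ids,
    target = target,
    level = level,
    coefficient = vapply(res, `[[`, numeric(1), "coefficient"),
    dispersion = vapply(res, `[[`, numeric(1), "dispersion"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    direction_positive = vapply(res, `[[`, logical(1), "direction_positive"),
    flag = vapply(res, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE)
  class(out) <- c("qp_results", class(out))
  out
}

#' Tissue-enriched calls from quasi-Poisson results
#'
#' TE iff the nominal (or BH-adjusted, if `adjust = "BH"`) p-value is
#' strictly below `alpha` and the target-vs-rest difference is positive.
#'
#' @param results a [fit_one_vs_rest()] table.
#' @param alpha significance level (strict `<`), default 0.05.
#' @param adjust `"none"` (nominal p-values, default) or `"BH"`.
#' @return enrichment-call data.frame (pipeline `"quasipoisson"`, status
#'   TE or OS according to the results' level; `score` = coefficient).
#' @export
detect_te_qp <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- results$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  sel <- p < alpha & results$direction_positive
  status <- if (all(results$level == "organ")) "OS" else "TE"
  make_calls(results$mirna_id[sel], "quasipoisson", status,
             results$target[sel], results$coefficient[sel],
             results$p_value[sel])
}

#' Tissue-specific calls: percentage-point rule on top of TE
#'
#' A TE miRNA is promoted to TS when its mean expression in the target group
#' stands far enough above every other group. Two readings of "percentage
#' points above the maximum other mean" are provided:
#' \describe{
#'   \item{excess}{`100 * (mean_target - max_other_mean) / mean_target >=
#'     percent_points` (default).}
#'   \item{share}{`100 * mean_target / sum(all group means) >=
#'     percent_points`.}
#' }
#' TS calls are a subset of the TE calls by construction.
#'
#' @param te_calls TE (or OS) calls from [detect_te_qp()].
#' @param means miRNA x group mean-expression matrix on the display
#'   normalization (TMM), e.g. from [group_means()].
#' @param percent_points threshold in percentage points, default 90.
#' @param mode `"excess"` or `"share"`.
#' @param status status to assign, `"TS"` (tissue level) or `"OS"`.
#' @return enrichment-call data.frame; `score` is the excess (or share) in
#'   percentage points.
#' @export
detect_ts_qp <- function(te_calls, means, percent_points = 90,
                         mode = c("excess", "share"), status = "TS") {
  mode <- match.arg(mode)
  out <- list()
  for (i in seq_len(nrow(te_calls))) {
    id <- te_calls$mirna_id[i]; tgt <- te_calls$target[i]
    if (!id %in% rownames(means) || !tgt %in% colnames(means)) next
    m_t <- means[id, tgt]
    if (m_t <= 0) {
      warning("miRNA '", id, "' has zero mean in target '", tgt, "'; not TS")
      next
    }
    others <- means[id, setdiff(colnames(means), tgt)]
    score <- if (mode == "excess") 100 * (m_t - max(others)) / m_t
             else 100 * m_t / sum(means[id, ])
    if (score >= percent_points)
      out[[length(out) + 1L]] <-
        make_calls(id, "quasipoisson", status, tgt, score, te_calls$p_value[i])
  }
  do.call(bind_calls, out)
}

#' Organ-specific calls: organ-vs-rest quasi-Poisson
#'
#' Same machinery as TE/TS detection with organ grouping: organ-vs-rest
#' quasi-Poisson fits, `p < alpha` with positive direction, then the
#' percentage-point rule against the other organs' means.
#'
#' @param counts per-million-ceiled miRNA x sample matrix.
#' @param sheet sample sheet with organ grouping.
#' @param target organ label.
#' @param means miRNA x organ TMM mean matrix for the percentage rule.
#' @param alpha significance level.
#' @param percent_points percentage-point threshold.
#' @param mode `"excess"` or `"share"`.
#' @return enrichment-call data.frame with status `"OS"`.
#' @export
detect_os_qp <- function(counts, sheet, target, means, alpha = 0.05,
                         percent_points = 90, mode = "excess") {
  res <- fit_one_vs_rest(counts, sheet, target, level = "organ")
  oe <- detect_te_qp(res, alpha)
  detect_ts_qp(oe, means, percent_points, mode, status = "OS")
}

#' Run the quasi-Poisson detection pipeline on a count atlas
#'
#' Filter (tissue totals strictly above `filter_threshold`, default 3), then
#' per-million ceiling, then for every target tissue a one-vs-rest
#' quasi-Poisson fit per miRNA. TE calls at `p < alpha` with positive
#' direction; TS calls additionally pass the percentage-point rule against
#' the TMM tissue means; OS calls repeat TE + percentage rule at the organ
#' level.
#'
#' @param counts miRNA x sample raw count matrix.
#' @param sheet sample sheet.
#' @param alpha significance level, default 0.05.
#' @param percent_points percentage-point TS threshold, default 90.
#' @param ts_mode `"excess"` or `"share"`.
#' @param filter_threshold read-count filter (strict >, default 3).
#' @param targets tissues to test (default: all with >= 2 samples).
#' @param organ_targets organs to test for OS (default: all).
#' @param adjust p-value adjustment, `"none"` or `"BH"`.
#' @return list of class `qp_pipeline` with `calls`, `results` (per-target
#'   fit tables) and the mean matrices used.
#' @export
run_qp_pipeline <- function(counts, sheet, alpha = 0.05, percent_points = 90,
                            ts_mode = "excess", filter_threshold = 3,
                            targets = NULL, organ_targets = NULL,
                            adjust = "none") {
  validate_counts(counts)
  sh <- match_sheet(counts, sheet)
  counts <- filter_counts(counts, sheet, "niehs", filter_threshold)
  pm <- per_million_ceil(counts)
  tmm <- tmm_normalize(counts)
  tissue_means <- group_means(tmm, sheet, "tissue")
  organ_means <- group_means(tmm, sheet, "organ")

  tis_n <- table(sh$tissue)
  if (is.null(targets))
    targets <- names(tis_n)[tis_n >= 2 & (length(unique(sh$tissue)) > 1)]
  org_n <- table(sh$organ)
  if (is.null(organ_targets))
    organ_targets <- names(org_n)[org_n >= 2]

  calls <- empty_calls()
  results <- list()
  for (tgt in targets) {
    if (sum(sh$tissue != tgt) < 2L) next
    res <- fit_one_vs_rest(pm, sheet, tgt, level = "tissue")
    results[[tgt]] <- res
    te <- detect_te_qp(res, alpha, adjust)
    ts <- detect_ts_qp(te, tissue_means, percent_points, ts_mode)
    calls <- bind_calls(calls, te, ts)
  }
  for (org in organ_targets) {
    if (sum(sh$organ != org, na.rm = TRUE) < 2L) next
    os <- detect_os_qp(pm, sheet, org, organ_means, alpha, percent_points,
                       ts_mode)
    calls <- bind_calls(calls, os)
  }
  validate_calls(calls)
  structure(list(calls = calls, results = results,
                 tissue_means = tissue_means, organ_means = organ_means),
            class = "qp_pipeline")
}

#' @export
print.qp_pipeline <- function(x, ...) {
  tab <- table(x$calls$status)
  cat("Quasi-Poisson detection pipeline:",
      length(x$results), "target tissues tested\n")
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
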