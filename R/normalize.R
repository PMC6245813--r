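# TMM normalization and the pipelines' read-count filters.

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values factors (Robinson & Oshlack): M- and A-values of
#' each sample against a reference sample, double trimming (30% on log
#' ratios, 5% on absolute expression by default), precision-weighted mean of
#' the retained M-values. Computed by `edgeR::calcNormFactors`. Factors are
#' rescaled so their geometric mean is exactly 1, making them comparable
#' across runs. The reference sample is the one whose upper-quartile-scaled
#' library is closest to the mean.
#'
#' @param counts miRNA x sample matrix of raw (or locus-scaled) counts,
#'   at least two samples, every sample with a positive total.
#' @param trim_logratio two-sided trim fraction on M-values.
#' @param trim_abs two-sided trim fraction on A-values.
#' @return object of class `tmm_factors`: list with `factors` (named,
#'   geometric mean 1), `lib_size`, and the trim settings.
#' @export
tmm_factors <- function(counts, trim_logratio = 0.3, trim_abs = 0.05) {
  validate_counts(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "), call. = FALSE)
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_logratio,
                              sumTrim = trim_abs)
  f <- f / exp(mean(log(f)))   # enforce geometric mean exactly 1
  names(f) <- colnames(counts)
  structure(list(factors = f, lib_size = lib,
                 trim_logratio = trim_logratio, trim_abs = trim_abs),
            class = "tmm_factors")
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM scaling factors for", length(x$factors), "samples",
      sprintf("(trims: %.0f%% M, %.0f%% A)\n",
              100 * x$trim_logratio, 100 * x$trim_abs))
  print(round(x$factors, 4))
  invisible(x)
}

#' Apply TMM factors: normalized counts per million
#'
#' Entry (j, s) becomes `count(j, s) / (lib_size(s) * factor(s)) * 1e6`.
#'
#' @param counts matrix the factors were computed from (or one with the same
#'   samples).
#' @param factors a [tmm_factors()] object, or a named numeric vector.
#' @return normalized miRNA x sample matrix ("TMM" expression).
#' @export
apply_tmm <- function(counts, factors) {
  validate_counts(counts)
  f <- if (inherits(factors, "tmm_factors")) factors$factors else factors
  miss <- setdiff(colnames(counts), names(f))
  if (length(miss))
    stop("no TMM factor for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lib <- colSums(counts)
  sweep(counts, 2L, lib * f[colnames(counts)] / 1e6, "/")
}

#' One-call TMM normalization
#'
#' Convenience wrapper: [tmm_factors()] then [apply_tmm()].
#' @inheritParams tmm_factors
#' @return normalized miRNA x sample matrix.
#' @export
tmm_normalize <- function(counts, trim_logratio = 0.3, trim_abs = 0.05) {
  apply_tmm(counts, tmm_factors(counts, trim_logratio, trim_abs))
}

#' Reads-per-million with integer ceiling
#'
#' Scales each sample to reads per million and applies an element-wise
#' ceiling, giving the non-negative integer matrix the quasi-Poisson
#' pipeline models. (For short miRNA reads the per-million transform is a
#' pure depth scaling; no transcript-length term is involved, despite the
#' "TPM" name the convention sometimes carries.)
#'
#' @param counts miRNA x sample matrix with positive library sizes.
#' @return integer-valued matrix of the same shape.
#' @export
per_million_ceil <- function(counts) {
  validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "), call. = FALSE)
  ceiling(sweep(counts, 2L, lib / 1e6, "/"))
}

#' Pipeline read-count filters
#'
#' Removes low-abundance miRNAs under one of the three pipelines' rules:
#' \describe{
#'   \item{lilly}{keep a miRNA iff its summed count in at least one tissue
#'     (or organ) is strictly greater than `threshold` (default 10).}
#'   \item{niehs}{same rule with default threshold 3.}
#'   \item{maastricht}{evaluated on the per-sample values of the matrix as
#'     given (intended: TMM-normalized); a miRNA is removed iff its value is
#'     below `threshold` (default 10) in all samples, i.e. kept iff at least
#'     one sample reaches the threshold.}
#' }
#'
#' @param counts miRNA x sample matrix (TMM-normalized for `maastricht`).
#' @param sheet sample sheet (needed for `lilly`/`niehs` grouping).
#' @param rule `"lilly"`, `"niehs"` or `"maastricht"`.
#' @param threshold filter threshold; defaults depend on `rule`.
#' @param level `"tissue"` or `"organ"` grouping for `lilly`/`niehs`.
#' @return the filtered matrix, row order preserved.
#' @export
filter_counts <- function(counts, sheet = NULL,
                          rule = c("lilly", "niehs", "maastricht"),
                          threshold = NULL, level = c("tissue", "organ")) {
  rule <- match.arg(rule)
  level <- match.arg(level)
  validate_counts(counts)
  if (is.null(threshold))
    threshold <- switch(rule, lilly = 10, niehs = 3, maastricht = 10)
  keep <- switch(rule,
    lilly = ,
    niehs = {
      if (is.null(sheet)) stop("rule '", rule, "' needs a sample sheet")
      gs <- group_sums(counts, sheet, level)
      apply(gs, 1L, max) > threshold          # strict >
    },
    maastricht = apply(counts, 1L, max) >= threshold  # removed iff < in all
  )
  counts[keep, , drop = FALSE]
}
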