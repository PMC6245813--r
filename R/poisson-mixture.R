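# Two-component Poisson mixture used to stratify miRNAs by expression level
# before NMF, so the factorization is not dominated by the highest-expressed
# miRNAs.

# Poisson log-density extended continuously to non-negative reals
pois_logdens <- function(x, lambda) {
  lambda <- max(lambda, 1e-300)
  x * log(lambda) - lambda - lgamma(x + 1)
}

#' Fit a two-component Poisson mixture by EM
#'
#' Models a vector of non-negative counts (typically per-miRNA total tissue
#' counts) as a mixture of a low-rate and a high-rate Poisson component. The
#' posterior probability of the high component per observation is what the
#' stratification uses.
#'
#' @param values non-negative counts, length >= 4, not all zero.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param seed integer seed (used to perturb a degenerate initialization).
#' @return object of class `poisson_mixture`: weights, `lambda_low` <=
#'   `lambda_high`, per-observation `responsibility` (posterior of the high
#'   component), non-decreasing `loglik_trace`, and a `degenerate` flag set
#'   when all observations are identical (single-component fallback).
#' @export
fit_poisson_mixture <- function(values, max_iter = 200L, tol = 1e-8,
                                seed = 1L) {
  if (length(values) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (any(!is.finite(values) | values < 0))
    stop("values must be finite and non-negative", call. = FALSE)
  if (all(values == 0)) stop("all observations are zero", call. = FALSE)

  if (length(unique(values)) == 1L) {
    v <- values[1L]
    return(structure(list(
      weight_low = 1, weight_high = 0, lambda_low = v, lambda_high = v,
      responsibility = rep(0.5, length(values)),
      loglik_trace = sum(pois_logdens(values, v)), degenerate = TRUE,
      converged = TRUE, n_iter = 0L), class = "poisson_mixture"))
  }

  lam <- unname(stats::quantile(values, c(0.25, 0.75)))
  if (diff(lam) < .Machine$double.eps) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    lam <- sort(mean(values) * stats::runif(2L, 0.5, 1.5))
  }
  w <- c(0.5, 0.5)
  ll_trace <- numeric(0L)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lo <- log(w[1L]) + pois_logdens(values, lam[1L])
    hi <- log(w[2L]) + pois_logdens(values, lam[2L])
    m <- pmax(lo, hi)
    denom <- m + log(exp(lo - m) + exp(hi - m))
    r_hi <- exp(hi - denom)
    ll <- sum(denom)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    # M step
    w <- c(mean(1 - r_hi), mean(r_hi))
    w <- pmin(pmax(w, 1e-10), 1 - 1e-10)
    lam[1L] <- sum((1 - r_hi) * values) / sum(1 - r_hi)
    lam[2L] <- sum(r_hi * values) / sum(r_hi)
  }
  if (lam[1L] > lam[2L]) {   # keep low <= high
    lam <- rev(lam); w <- rev(w); r_hi <- 1 - r_hi
  }
  structure(list(
    weight_low = w[1L], weight_high = w[2L],
    lambda_low = lam[1L], lambda_high = lam[2L],
    responsibility = r_hi, loglik_trace = ll_trace,
    degenerate = FALSE, converged = converged, n_iter = length(ll_trace)),
    class = "poisson_mixture")
}

#' @export
print.poisson_mixture <- function(x, ...) {
  cat("Two-component Poisson mixture",
      if (x$degenerate) "(degenerate: single component)\n" else "\n")
  cat(sprintf("  low : weight %.3f, lambda %.3f\n", x$weight_low, x$lambda_low))
  cat(sprintf("  high: weight %.3f, lambda %.3f\n", x$weight_high, x$lambda_high))
  cat(sprintf("  %d EM iterations, %sconverged\n", x$n_iter,
              if (isTRUE(x$converged)) "" else "not "))
  invisible(x)
}

#' Partition miRNAs into high- and low-expression strata
#'
#' A miRNA goes into the high stratum iff its posterior probability of the
#' high mixture component exceeds 0.5; at exactly 0.5 (including the
#' degenerate single-component fit) it goes low. The two strata are disjoint
#' and exhaustive.
#'
#' @param fit a [fit_poisson_mixture()] result whose observations are the
#'   miRNAs in `mirna_ids` (same order).
#' @param mirna_ids character vector of miRNA identifiers.
#' @return list with `high` and `low` character vectors.
#' @export
stratify_by_expression <- function(fit, mirna_ids) {
  stopifnot(inherits(fit, "poisson_mixture"),
            length(mirna_ids) == length(fit$responsibility))
  hi <- fit$responsibility > 0.5
  list(high = mirna_ids[hi], low = mirna_ids[!hi])
}
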