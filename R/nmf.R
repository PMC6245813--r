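# Non-negative matrix factorization with the generalized Kullback-Leibler
# objective and multiplicative updates -- the Poisson-compatible choice for a
# count matrix.

kl_divergence <- function(X, WH, eps = 1e-12) {
  pos <- X > 0
  sum(X[pos] * log(X[pos] / (WH[pos] + eps))) - sum(X) + sum(WH)
}

# column-anchored initialization: each factor starts on one of the `rank`
# highest-mass columns (its basis column = that column of X), with a small
# positive floor everywhere so no entry is locked at zero by the
# multiplicative updates
nmf_init_anchored <- function(X, rank, eps_frac = 0.01) {
  anchors <- order(colSums(X), decreasing = TRUE)[seq_len(rank)]
  floor_w <- eps_frac * mean(X) + 1e-8
  W <- X[, anchors, drop = FALSE] + floor_w
  H <- matrix(eps_frac, rank, ncol(X))
  H[cbind(seq_len(rank), anchors)] <- 1
  list(W = unname(W), H = H)
}

nmf_init_random <- function(X, rank) {
  n <- nrow(X); m <- ncol(X)
  scale0 <- sqrt(mean(X) / rank)
  list(W = matrix(stats::runif(n * rank, 0.1, 1), n, rank) * scale0,
       H = matrix(stats::runif(rank * m, 0.1, 1), rank, m) * scale0)
}

nmf_run_once <- function(X, rank, max_iter, tol, init, eps = 1e-12) {
  n <- nrow(X); m <- ncol(X)
  W <- init$W
  H <- init$H
  obj <- numeric(max_iter)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    H <- H * (t(W) %*% (X / (WH + eps))) / (colSums(W) + eps)
    WH <- W %*% H
    W <- W * ((X / (WH + eps)) %*% t(H)) /
      matrix(rowSums(H) + eps, n, rank, byrow = TRUE)
    obj[it] <- kl_divergence(X, W %*% H, eps)
    if (is.finite(prev) &&
        abs(prev - obj[it]) <= tol * (abs(prev) + eps)) {
      obj <- obj[seq_len(it)]
      break
    }
    prev <- obj[it]
  }
  list(W = W, H = H, objective_trace = obj)
}

#' NMF of a non-negative expression matrix (KL objective)
#'
#' Decomposes X (miRNA x organ or miRNA x tissue) into non-negative W
#' (miRNA x rank basis, each column a miRNA factor group) and H (rank x
#' column coefficients, each row a factor's distribution over organs or
#' tissues), minimizing the generalized Kullback-Leibler divergence
#' D(X || WH) by multiplicative updates. The best of `n_restarts`
#' initializations by final objective is returned (ties broken by lowest
#' restart index): the first restart anchors each factor to one of the
#' `rank` highest-mass columns (which reliably reaches the specialized
#' optimum on column-structured atlases), the remaining restarts are
#' seeded random draws. Deterministic given `seed`.
#'
#' @param X non-negative matrix with dimnames.
#' @param rank factorization rank, default `min(dim(X))` capped at
#'   `ncol(X)` so each factor can specialize to one column.
#' @param seed integer seed.
#' @param n_restarts number of random restarts.
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol relative objective-change convergence tolerance.
#' @return object of class `nmf_fit`: `W`, `H`, `rank`, non-increasing
#'   `objective_trace` of the winning restart, `seed`, `restart` (winning
#'   restart index).
#' @export
nmf_decompose <- function(X, rank = NULL, seed = 1L, n_restarts = 10L,
                          max_iter = 500L, tol = 1e-8) {
  if (any(!is.finite(X) | X < 0)) stop("X must be finite and non-negative")
  if (is.null(rank)) rank <- min(nrow(X), ncol(X))
  if (rank < 1L || rank > min(dim(X)))
    stop("rank must be between 1 and min(dim(X))", call. = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed((as.integer(seed) + r - 1L) %% .Machine$integer.max)
    # restart 1 is column-anchored (deterministic), the rest are random
    init <- if (r == 1L) nmf_init_anchored(X, rank)
            else nmf_init_random(X, rank)
    run <- nmf_run_once(X, rank, max_iter, tol, init)
    final <- run$objective_trace[length(run$objective_trace)]
    if (is.null(best) || final < best$final - 1e-12) {
      best <- list(run = run, final = final, restart = r)
    }
  }
  W <- best$run$W; H <- best$run$H
  dimnames(W) <- list(rownames(X), paste0("factor", seq_len(rank)))
  dimnames(H) <- list(paste0("factor", seq_len(rank)), colnames(X))
  structure(list(W = W, H = H, rank = rank,
                 objective_trace = best$run$objective_trace,
                 seed = seed, restart = best$restart),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("KL-NMF fit: %d x %d = (%d x %d) x (%d x %d), rank %d\n",
              nrow(x$W), ncol(x$H), nrow(x$W), x$rank, x$rank, ncol(x$H),
              x$rank))
  cat(sprintf("  final objective %.6g after %d iterations (restart %d of seed %d)\n",
              x$objective_trace[length(x$objective_trace)],
              length(x$objective_trace), x$restart, x$seed))
  invisible(x)
}

#' Per-miRNA column shares implied by an NMF decomposition
#'
#' Rows of W are scaled to sum to 1 (the miRNA's loading distribution over
#' factors) and rows of H are scaled to sum to 1 (each factor's distribution
#' over organs/tissues); the product of the two gives, per miRNA, its share
#' of total expression attributed to each column. Each share vector sums
#' to 1 for miRNAs with positive loading.
#'
#' @param dec an [nmf_decompose()] fit.
#' @return miRNA x column matrix of shares.
#' @export
nmf_shares <- function(dec) {
  stopifnot(inherits(dec, "nmf_fit"))
  wr <- rowSums(dec$W)
  Wn <- dec$W / ifelse(wr > 0, wr, 1)
  hr <- rowSums(dec$H)
  Hn <- dec$H / ifelse(hr > 0, hr, 1)
  S <- Wn %*% Hn
  rownames(S) <- rownames(dec$W)
  S
}
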