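# NMF pipeline: expression-level stratification by Poisson mixture, KL-NMF
# of tissue- and organ-level matrices, and %-of-total-expression TE/TS/OS
# thresholds with the constraint that a tissue-specific miRNA must also be
# organ-specific.

#' Classify miRNAs from an NMF decomposition by expression share
#'
#' For each miRNA the decomposition implies a share of total expression per
#' column (see [nmf_shares()]). At the organ level: a TE call is made for
#' every organ whose share reaches `te_share` (or, with
#' `te_mode = "exclusive"`, only for the top organ when it alone reaches
#' it); an OS call is made for the organ holding the maximum share when that
#' share reaches `ts_share`; a TS call (at organ granularity) additionally
#' requires the specific-level share in exactly one organ. At the tissue
#' level the same TE/TS logic applies per tissue, and a TS call is retained
#' only if the tissue's organ carries an OS call for the same miRNA
#' (`os_calls` + `organ_map` required): a TS miRNA has to be OS.
#'
#' @param dec [nmf_decompose()] fit of the matching matrix.
#' @param X the matrix that was decomposed (used to flag zero-expression
#'   miRNAs).
#' @param te_share minimum share for tissue/organ enrichment (default 0.60).
#' @param ts_share minimum share for specificity (default 0.80).
#' @param level `"organ"` or `"tissue"` -- what the columns of X are.
#' @param te_mode `"multi"` (TE in every column reaching `te_share`) or
#'   `"exclusive"` (TE only when a single column reaches it).
#' @param os_calls call table with the OS calls (needed when
#'   `level = "tissue"` to enforce TS => OS).
#' @param organ_map data.frame tissue/organ (needed when `level = "tissue"`).
#' @return enrichment-call data.frame (pipeline `"nmf"`); `score` is the
#'   expression share.
#' @export
classify_nmf <- function(dec, X, te_share = 0.60, ts_share = 0.80,
                         level = c("organ", "tissue"),
                         te_mode = c("multi", "exclusive"),
                         os_calls = NULL, organ_map = default_organ_map()) {
  level <- match.arg(level)
  te_mode <- match.arg(te_mode)
  if (te_share > ts_share) stop("te_share must not exceed ts_share")
  S <- nmf_shares(dec)
  tot <- rowSums(X)[rownames(S)]
  out <- list()
  for (j in seq_len(nrow(S))) {
    id <- rownames(S)[j]
    if (!is.finite(tot[j]) || tot[j] <= 0) {
      warning("miRNA '", id, "' has zero total expression; status none")
      out[[length(out) + 1L]] <-
        make_calls(id, "nmf", "none", NA_character_, 0)
      next
    }
    s <- S[j, ]
    te_cols <- which(s >= te_share)
    if (te_mode == "exclusive" && length(te_cols) > 1L) te_cols <- integer(0)
    for (k in te_cols)
      out[[length(out) + 1L]] <-
        make_calls(id, "nmf", "TE", colnames(S)[k], s[k])
    kmax <- which.max(s)
    spec_cols <- which(s >= ts_share)
    if (level == "organ") {
      if (s[kmax] >= ts_share) {
        out[[length(out) + 1L]] <-
          make_calls(id, "nmf", "OS", colnames(S)[kmax], s[kmax])
        if (length(spec_cols) == 1L)
          out[[length(out) + 1L]] <-
            make_calls(id, "nmf", "TS", colnames(S)[kmax], s[kmax])
      }
    } else {
      if (s[kmax] >= ts_share && length(spec_cols) == 1L) {
        tis <- colnames(S)[kmax]
        org <- organ_map$organ[match(tis, organ_map$tissue)]
        if (is.na(org))
          stop("tissue '", tis, "' missing from the organ map", call. = FALSE)
        has_os <- !is.null(os_calls) &&
          any(os_calls$mirna_id == id & os_calls$status == "OS" &
                os_calls$target == org)
        if (has_os)
          out[[length(out) + 1L]] <-
            make_calls(id, "nmf", "TS", tis, s[kmax])
      }
    }
  }
  do.call(bind_calls, out)
}

# shares for a stratum too small to factorize: direct row-normalization
direct_shares <- function(X) {
  rs <- rowSums(X)
  S <- X / ifelse(rs > 0, rs, 1)
  S
}

#' Run the NMF detection pipeline on a count atlas
#'
#' Steps: per-tissue summed counts; read-count filter (keep miRNAs whose
#' maximum tissue total exceeds `filter_threshold`); two-component Poisson
#' mixture on the per-miRNA total counts to split miRNAs into high- and
#' low-expression strata (so the factorization of each stratum sees miRNAs
#' of comparable magnitude); per stratum, KL-NMF of the organ-level matrix
#' (member tissues collapsed by element-wise maximum) and of the
#' tissue-level matrix; share-based TE/TS/OS classification with TS => OS.
#'
#' @param counts miRNA x sample raw count matrix.
#' @param sheet sample sheet.
#' @param rank NMF rank; default = number of columns of the matrix being
#'   factorized (14 organs / 23 tissues in the full atlas design), capped at
#'   the stratum size.
#' @param te_share,ts_share share thresholds, defaults 0.60 / 0.80.
#' @param te_mode see [classify_nmf()].
#' @param filter_threshold read-count filter (strict >, default 10).
#' @param stratify fit the Poisson mixture and factorize each stratum
#'   separately (default TRUE); FALSE runs one global NMF.
#' @param seed,n_restarts,max_iter,tol passed to [nmf_decompose()].
#' @return list of class `nmf_pipeline`: `calls` (enrichment-call table),
#'   `mixture` (the Poisson-mixture fit, or NULL), `strata`, and the
#'   decompositions per stratum and level.
#' @export
run_nmf_pipeline <- function(counts, sheet, rank = NULL,
                             te_share = 0.60, ts_share = 0.80,
                             te_mode = "multi", filter_threshold = 10,
                             stratify = TRUE, seed = 1L, n_restarts = 10L,
                             max_iter = 500L, tol = 1e-8) {
  validate_counts(counts)
  sh <- match_sheet(counts, sheet)
  organ_map <- unique(sh[, c("tissue", "organ")])
  tissue_sums <- group_sums(counts, sheet, "tissue")
  keep <- apply(tissue_sums, 1L, max) > filter_threshold
  tissue_sums <- tissue_sums[keep, , drop = FALSE]
  if (nrow(tissue_sums) == 0L)
    stop("no miRNA passes the read-count filter", call. = FALSE)

  mixture <- NULL
  strata <- list(all = rownames(tissue_sums))
  if (stratify && nrow(tissue_sums) >= 4L) {
    mixture <- fit_poisson_mixture(rowSums(tissue_sums), seed = seed)
    st <- stratify_by_expression(mixture, rownames(tissue_sums))
    strata <- Filter(length, st[c("high", "low")])
  }

  calls <- empty_calls()
  fits <- list()
  for (nm in names(strata)) {
    ids <- strata[[nm]]
    Xt <- tissue_sums[ids, , drop = FALSE]
    Xo <- aggregate_to_organ_max(Xt, organ_map)
    if (length(ids) >= 2L) {
      ko <- min(if (is.null(rank)) ncol(Xo) else rank, nrow(Xo), ncol(Xo))
      kt <- min(if (is.null(rank)) ncol(Xt) else rank, nrow(Xt), ncol(Xt))
      dec_o <- nmf_decompose(Xo, rank = ko, seed = seed,
                             n_restarts = n_restarts, max_iter = max_iter,
                             tol = tol)
      dec_t <- nmf_decompose(Xt, rank = kt, seed = seed,
                             n_restarts = n_restarts, max_iter = max_iter,
                             tol = tol)
      fits[[nm]] <- list(organ = dec_o, tissue = dec_t)
      organ_calls <- classify_nmf(dec_o, Xo, te_share, ts_share,
                                  level = "organ", te_mode = te_mode)
      tissue_calls <- classify_nmf(dec_t, Xt, te_share, ts_share,
                                   level = "tissue", te_mode = te_mode,
                                   os_calls = organ_calls,
                                   organ_map = organ_map)
    } else {
      # stratum of one miRNA: shares are the normalized rows themselves
      So <- direct_shares(Xo); St <- direct_shares(Xt)
      organ_calls <- share_calls(So, Xo, te_share, ts_share, "organ",
                                 te_mode, NULL, organ_map)
      tissue_calls <- share_calls(St, Xt, te_share, ts_share, "tissue",
                                  te_mode, organ_calls, organ_map)
    }
    calls <- bind_calls(calls,
                        organ_calls[organ_calls$status == "OS", , drop = FALSE],
                        tissue_calls)
  }
  validate_calls(calls)
  structure(list(calls = calls, mixture = mixture, strata = strata,
                 fits = fits, tissue_sums = tissue_sums),
            class = "nmf_pipeline")
}

# classification from an explicit share matrix (used for degenerate strata);
# mirrors classify_nmf's rules
share_calls <- function(S, X, te_share, ts_share, level, te_mode,
                        os_calls, organ_map) {
  out <- list()
  tot <- rowSums(X)
  for (j in seq_len(nrow(S))) {
    id <- rownames(S)[j]
    if (tot[j] <= 0) next
    s <- S[j, ]
    te_cols <- which(s >= te_share)
    if (te_mode == "exclusive" && length(te_cols) > 1L) te_cols <- integer(0)
    for (k in te_cols)
      out[[length(out) + 1L]] <- make_calls(id, "nmf", "TE", colnames(S)[k], s[k])
    kmax <- which.max(s)
    spec_cols <- which(s >= ts_share)
    if (level == "organ") {
      if (s[kmax] >= ts_share) {
        out[[length(out) + 1L]] <- make_calls(id, "nmf", "OS", colnames(S)[kmax], s[kmax])
        if (length(spec_cols) == 1L)
          out[[length(out) + 1L]] <- make_calls(id, "nmf", "TS", colnames(S)[kmax], s[kmax])
      }
    } else if (s[kmax] >= ts_share && length(spec_cols) == 1L) {
      tis <- colnames(S)[kmax]
      org <- organ_map$organ[match(tis, organ_map$tissue)]
      if (!is.null(os_calls) &&
          any(os_calls$mirna_id == id & os_calls$status == "OS" &
                os_calls$target == org))
        out[[length(out) + 1L]] <- make_calls(id, "nmf", "TS", tis, s[kmax])
    }
  }
  do.call(bind_calls, out)
}

#' @export
print.nmf_pipeline <- function(x, ...) {
  cat("NMF detection pipeline:", nrow(x$tissue_sums), "miRNAs after filtering\n")
  if (!is.null(x$mixture))
    cat(sprintf("  strata: high %d / low %d (Poisson mixture)\n",
                length(x$strata$high), length(x$strata$low)))
  tab <- table(x$calls$status)
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
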