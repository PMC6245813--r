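# Proportion-of-total pipeline: locus scaling, TMM normalization and
# filtering, share-of-total TE/TS/OS thresholds, and the dominant-isomiR
# comparison across tissues.

#' Divide each miRNA's counts by its number of genomic loci
#'
#' Reads mapping to a multi-locus miRNA are down-weighted by the locus count
#' so multi-mapped reads are not counted once per locus. Fractional counts
#' are permitted downstream.
#'
#' @param counts miRNA x sample matrix.
#' @param annot annotation table with `mirna_id` and `n_loci`.
#' @return scaled matrix.
#' @export
scale_by_loci <- function(counts, annot) {
  validate_counts(counts)
  validate_annotation(annot)
  idx <- match(rownames(counts), annot$mirna_id)
  if (anyNA(idx))
    stop("miRNA(s) missing from the annotation: ",
         paste(rownames(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  counts / annot$n_loci[idx]
}

#' Per-miRNA expression shares over tissues or organs
#'
#' Converts a group-mean matrix into per-miRNA shares: each row divided by
#' its total, so the shares of a miRNA with positive expression sum to 1.
#' Zero-total miRNAs are excluded with a warning.
#'
#' @param means miRNA x group mean matrix (typically TMM-normalized, from
#'   [group_means()]).
#' @return data.frame of class `proportion_profile`: `mirna_id`,
#'   `max_group`, `max_share`, plus the share matrix as attribute `shares`.
#' @export
proportion_profile <- function(means) {
  if (any(means < 0)) stop("means must be non-negative", call. = FALSE)
  tot <- rowSums(means)
  if (any(tot == 0)) {
    warning("excluding ", sum(tot == 0),
            " miRNA(s) with zero total expression")
    means <- means[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  shares <- means / tot
  kmax <- max.col(shares, ties.method = "first")
  out <- data.frame(mirna_id = rownames(means),
                    max_group = colnames(means)[kmax],
                    max_share = shares[cbind(seq_len(nrow(shares)), kmax)],
                    stringsAsFactors = FALSE)
  attr(out, "shares") <- shares
  class(out) <- c("proportion_profile", class(out))
  out
}

#' Threshold expression shares into TE and TS/OS calls
#'
#' TE iff the maximum share is strictly greater than `te_threshold`
#' (default 0.5); TS (tissue level) or OS (organ level) iff strictly
#' greater than `ts_threshold` (default 0.9). TS/OS calls are a subset of
#' the TE calls since `te_threshold <= ts_threshold`.
#'
#' @param profiles a [proportion_profile()] result.
#' @param te_threshold enrichment threshold in (0, 1].
#' @param ts_threshold specificity threshold in (0, 1], `>= te_threshold`.
#' @param level `"tissue"` (specific calls become TS) or `"organ"` (OS).
#' @return enrichment-call data.frame (pipeline `"proportion"`; `score` is
#'   the maximum share).
#' @export
classify_proportion <- function(profiles, te_threshold = 0.5,
                                ts_threshold = 0.9,
                                level = c("tissue", "organ")) {
  level <- match.arg(level)
  if (te_threshold > ts_threshold)
    stop("te_threshold must not exceed ts_threshold", call. = FALSE)
  if (te_threshold <= 0 || ts_threshold > 1)
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  spec_status <- if (level == "tissue") "TS" else "OS"
  te <- profiles$max_share > te_threshold
  ts <- profiles$max_share > ts_threshold
  bind_calls(
    make_calls(profiles$mirna_id[te], "proportion", "TE",
               profiles$max_group[te], profiles$max_share[te]),
    make_calls(profiles$mirna_id[ts], "proportion", spec_status,
               profiles$max_group[ts], profiles$max_share[ts]))
}

#' Dominant isomiR per tissue and whether it changes across tissues
#'
#' For every mature miRNA, each member isomiR's per-tissue proportion is its
#' mean expression divided by the summed mean expression of all isomiRs of
#' that mature miRNA in the tissue. The dominant isomiR is the one with the
#' maximal proportion (exact ties broken lexicographically and flagged);
#' `differs_across_tissues` is TRUE iff the dominant isomiR identifier is
#' not the same in every evaluated tissue. Tissues where the mature total is
#' zero are skipped with a warning.
#'
#' @param iso_counts isomiR x sample count matrix.
#' @param annot annotation with `parent_mature_id` for every isomiR row.
#' @param sheet sample sheet.
#' @return data.frame: one row per (mature, tissue) with `dominant_isomir`,
#'   `proportion`, `tied`; plus per-mature summary attribute `differs`
#'   (named logical).
#' @export
isomir_dominance <- function(iso_counts, annot, sheet) {
  validate_counts(iso_counts)
  validate_annotation(annot)
  idx <- match(rownames(iso_counts), annot$mirna_id)
  if (anyNA(idx))
    stop("isomiR(s) missing from the annotation: ",
         paste(rownames(iso_counts)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  parent <- annot$parent_mature_id[idx]
  if (anyNA(parent))
    stop("isomiR row(s) without parent_mature_id", call. = FALSE)
  means <- group_means(iso_counts, sheet, "tissue")
  rows <- list()
  differs <- logical(0)
  for (mat in unique(parent)) {
    members <- rownames(iso_counts)[parent == mat]
    sub <- means[members, , drop = FALSE]
    tot <- colSums(sub)
    doms <- character(0)
    for (tis in colnames(sub)) {
      if (tot[tis] <= 0) {
        warning("mature '", mat, "' has zero total in tissue '", tis,
                "'; skipped")
        next
      }
      prop <- sub[, tis] / tot[tis]
      top <- max(prop)
      winners <- sort(members[prop == top])
      rows[[length(rows) + 1L]] <- data.frame(
        mature_id = mat, tissue = tis, dominant_isomir = winners[1L],
        proportion = top, tied = length(winners) > 1L,
        stringsAsFactors = FALSE)
      doms <- c(doms, winners[1L])
    }
    differs[mat] <- length(unique(doms)) > 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$differs_across_tissues <- differs[out$mature_id]
  attr(out, "differs") <- differs
  out
}

#' Run the proportion-of-total detection pipeline on a count atlas
#'
#' Steps: locus scaling (when an annotation is given), TMM normalization,
#' removal of miRNAs whose TMM value is below `filter_threshold` in all
#' samples, per-tissue (and per-organ) TMM mean shares, and the > 0.5 / >
#' 0.9 share thresholds for TE and TS (tissue level) or OS (organ level).
#'
#' @param counts miRNA x sample raw count matrix.
#' @param sheet sample sheet.
#' @param annot optional annotation with `n_loci` for locus scaling.
#' @param te_threshold,ts_threshold share thresholds, defaults 0.5 / 0.9.
#' @param filter_threshold TMM filter (removed iff below it in all samples),
#'   default 10.
#' @param use_tmm compute shares on TMM-normalized values (default TRUE);
#'   FALSE uses raw (locus-scaled) counts.
#' @return list of class `proportion_pipeline` with `calls`, the tissue and
#'   organ profiles, and the normalized matrix.
#' @export
run_proportion_pipeline <- function(counts, sheet, annot = NULL,
                                    te_threshold = 0.5, ts_threshold = 0.9,
                                    filter_threshold = 10, use_tmm = TRUE) {
  validate_counts(counts)
  if (!is.null(annot)) counts <- scale_by_loci(counts, annot)
  norm <- if (use_tmm) tmm_normalize(counts) else counts
  norm <- filter_counts(norm, rule = "maastricht",
                        threshold = filter_threshold)
  if (nrow(norm) == 0L)
    stop("no miRNA passes the TMM filter", call. = FALSE)
  tis_prof <- proportion_profile(group_means(norm, sheet, "tissue"))
  org_prof <- proportion_profile(group_means(norm, sheet, "organ"))
  calls <- bind_calls(
    classify_proportion(tis_prof, te_threshold, ts_threshold, "tissue"),
    classify_proportion(org_prof, te_threshold, ts_threshold, "organ"))
  validate_calls(calls)
  structure(list(calls = calls, tissue_profile = tis_prof,
                 organ_profile = org_prof, normalized = norm),
            class = "proportion_pipeline")
}

#' @export
print.proportion_pipeline <- function(x, ...) {
  tab <- table(x$calls$status)
  cat("Proportion-of-total detection pipeline:",
      nrow(x$normalized), "miRNAs after TMM filter\n")
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
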