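# Tissue-specificity index and cross-pipeline set comparison.

#' Tissue-specificity index (TSI)
#'
#' For miRNA j over N >= 2 groups, with `x_ij` the mean expression in group
#' i divided by the maximal mean expression of j over all groups,
#' `TSI_j = sum_i (1 - x_ij) / (N - 1)`. TSI is 0 for a perfectly uniform
#' profile, 1 for expression confined to a single group, and is invariant
#' to rescaling a miRNA's profile. Zero-expression miRNAs are excluded with
#' a warning. Ties for the per-miRNA maximum do not affect the index (the
#' formula only uses the maximum value).
#'
#' @param means miRNA x group matrix of mean expression (typically TMM
#'   means from [group_means()]).
#' @return data.frame of class `tsi_table`: `mirna_id`, `tsi`, `n_groups`;
#'   the max-normalized profile matrix is attached as attribute `profile`.
#' @export
compute_tsi <- function(means) {
  if (ncol(means) < 2L) stop("TSI needs at least 2 groups", call. = FALSE)
  if (any(!is.finite(means) | means < 0))
    stop("means must be finite and non-negative", call. = FALSE)
  mx <- apply(means, 1L, max)
  if (any(mx == 0)) {
    warning("excluding ", sum(mx == 0),
            " miRNA(s) with zero expression in all groups")
    means <- means[mx > 0, , drop = FALSE]
    mx <- mx[mx > 0]
  }
  x <- means / mx
  n <- ncol(means)
  tsi <- rowSums(1 - x) / (n - 1)
  out <- data.frame(mirna_id = rownames(means), tsi = unname(tsi),
                    n_groups = n, stringsAsFactors = FALSE)
  attr(out, "profile") <- x
  class(out) <- c("tsi_table", class(out))
  out
}

#' Map identifier sets onto a common namespace
#'
#' Applies an alias map (old id -> new id; identity for ids not in the map)
#' to each set, e.g. to reconcile miRBase versions across pipelines before
#' computing overlaps. The map must be functional (one output per input);
#' if two members of one set collapse onto the same alias, the duplicate is
#' dropped with a warning.
#'
#' @param sets named list of character vectors.
#' @param alias optional data.frame or 2-column matrix: column 1 = input
#'   id, column 2 = output id.
#' @return named list of reconciled character vectors.
#' @export
reconcile_ids <- function(sets, alias = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(alias)) return(lapply(sets, unique))
  alias <- as.data.frame(alias, stringsAsFactors = FALSE)
  if (ncol(alias) < 2L) stop("alias map needs two columns", call. = FALSE)
  from <- as.character(alias[[1L]]); to <- as.character(alias[[2L]])
  dup <- unique(from[duplicated(from)])
  bad <- dup[vapply(dup, function(d) length(unique(to[from == d])) > 1L,
                    logical(1))]
  if (length(bad))
    stop("alias map is not functional for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    ids <- as.character(sets[[nm]])
    idx <- match(ids, from)
    mapped <- ifelse(is.na(idx), ids, to[idx])
    if (anyDuplicated(mapped))
      warning("set '", nm, "': ", sum(duplicated(mapped)),
              " id(s) collapsed onto an existing alias; deduplicated")
    unique(mapped)
  })
}

#' Exact Venn region partition of 2 or 3 identifier sets
#'
#' Partitions the union of the input sets into the 3 (two sets) or 7 (three
#' sets) disjoint membership regions, with member lists and counts per
#' region.
#'
#' @param sets named list of 2 or 3 character vectors (already reconciled
#'   onto a common namespace, see [reconcile_ids()]).
#' @return object of class `overlap_report`: `sets` (deduplicated inputs),
#'   `regions` (named list of member vectors; names like `"A&B"` built from
#'   set names), `counts`.
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  k <- length(sets)
  if (k < 2L || k > 3L) stop("overlap supports 2 or 3 sets", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1L,
                                         dimnames = list(NULL, names(sets)))
  codes <- apply(memb, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  all_codes <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, paste, collapse = "&")))
  regions <- lapply(stats::setNames(all_codes, all_codes), function(cd)
    if (length(univ)) univ[codes == cd] else character(0))
  structure(list(sets = sets, regions = regions,
                 counts = vapply(regions, length, integer(1))),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Set overlap of", length(x$sets), "call sets (",
      paste(names(x$sets), vapply(x$sets, length, integer(1)),
            sep = "=", collapse = ", "), ")\n")
  for (nm in names(x$regions))
    cat(sprintf("  %-30s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Write overlap regions to CSV files
#'
#' One CSV per region (`<prefix>_<region>.csv`, `&` replaced by `_and_`)
#' plus a summary `<prefix>_regions.csv` with the counts.
#'
#' @param report an [overlap_sets()] result.
#' @param prefix output path prefix.
#' @return paths written, invisibly.
#' @export
write_overlap <- function(report, prefix) {
  paths <- character(0)
  for (nm in names(report$regions)) {
    p <- paste0(prefix, "_", gsub("&", "_and_", nm, fixed = TRUE), ".csv")
    utils::write.csv(data.frame(mirna_id = report$regions[[nm]]),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_regions.csv")
  utils::write.csv(data.frame(region = names(report$counts),
                              n = unname(report$counts)),
                   p, row.names = FALSE)
  invisible(c(paths, p))
}
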