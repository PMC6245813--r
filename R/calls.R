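# Enrichment calls: the common per-miRNA verdict record shared by all
# three pipelines.

#' Construct an enrichment-call table
#'
#' One row per (miRNA, status, target) verdict; the common currency of all
#' three pipelines. Scalar arguments are recycled to the number of miRNAs.
#'
#' @param mirna_id miRNA identifiers.
#' @param pipeline `"nmf"`, `"quasipoisson"` or `"proportion"`.
#' @param status `"TE"`, `"TS"`, `"OS"` or `"none"`.
#' @param target tissue or organ label.
#' @param score share of total expression or excess percentage points.
#' @param p_value p-value (quasi-Poisson calls only), NA otherwise.
#' @return data.frame with the six call columns.
#' @export
make_calls <- function(mirna_id = character(), pipeline = character(),
                       status = character(), target = character(),
                       score = numeric(), p_value = NA_real_) {
  n <- length(mirna_id)
  data.frame(mirna_id = as.character(mirna_id),
             pipeline = rep_len(as.character(pipeline), n),
             status = rep_len(as.character(status), n),
             target = rep_len(as.character(target), n),
             score = rep_len(as.numeric(score), n),
             p_value = rep_len(as.numeric(p_value), n),
             stringsAsFactors = FALSE)
}

empty_calls <- function() make_calls()

#' Row-bind enrichment-call tables, dropping empty ones
#' @param ... call data.frames (NULL and zero-row tables are skipped).
#' @return combined call data.frame.
#' @export
bind_calls <- function(...) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(lst)) return(empty_calls())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Validate an enrichment-call table
#'
#' Checks the invariants of a call table: finite scores, p-values in
#' \[0, 1\] where present, statuses among TE/TS/OS/none, and (for the nmf
#' pipeline) that every TS call is backed by an OS call for the same miRNA.
#'
#' @param calls data.frame as produced by the pipelines.
#' @return the calls, invisibly.
#' @export
validate_calls <- function(calls) {
  stopifnot(all(c("mirna_id", "pipeline", "status", "target", "score",
                  "p_value") %in% colnames(calls)))
  if (nrow(calls) == 0L) return(invisible(calls))
  if (!all(calls$status %in% c("TE", "TS", "OS", "none")))
    stop("unknown status in calls", call. = FALSE)
  if (any(!is.finite(calls$score)))
    stop("non-finite score in calls", call. = FALSE)
  pv <- calls$p_value[!is.na(calls$p_value)]
  if (any(pv < 0 | pv > 1)) stop("p-value outside [0, 1]", call. = FALSE)
  nmf <- calls[calls$pipeline == "nmf", , drop = FALSE]
  ts <- unique(nmf$mirna_id[nmf$status == "TS"])
  os <- unique(nmf$mirna_id[nmf$status == "OS"])
  if (length(setdiff(ts, os)))
    stop("nmf TS call without a matching OS call: ",
         paste(setdiff(ts, os), collapse = ", "), call. = FALSE)
  invisible(calls)
}

#' Write enrichment calls to TSV
#' @param calls call table.
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
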