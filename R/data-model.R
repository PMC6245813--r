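#' mirtisect: tissue-enriched, tissue-specific and organ-specific miRNA detection
#'
#' Detects TE/TS/OS miRNAs from a miRNA x sample count atlas through three
#' pipelines (NMF with Poisson-mixture stratification, one-vs-rest
#' quasi-Poisson GLMs, proportion-of-total thresholds), computes the
#' tissue-specificity index, compares pipeline call sets, and simulates
#' seeded synthetic atlases with planted enrichment structure.
#'
#' @docType package
#' @name mirtisect-package
#' @keywords internal
"_PACKAGE"

# ---- count matrix ----------------------------------------------------------

#' Validate a miRNA x sample count matrix
#'
#' A count matrix is a plain numeric matrix with miRNA identifiers as row
#' names and sample identifiers as column names. Entries must be finite and
#' non-negative; fractional values are allowed (counts may become fractional
#' after locus scaling or normalization). Identifiers must be unique.
#'
#' @param x numeric matrix with row and column names.
#' @param what label used in error messages.
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_counts <- function(x, what = "count matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have miRNA row names and sample column names", call. = FALSE)
  dup_r <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_r))
    stop(what, ": duplicate miRNA identifiers: ", paste(dup_r, collapse = ", "),
         call. = FALSE)
  dup_c <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_c))
    stop(what, ": duplicate sample identifiers: ", paste(dup_c, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(what, ": negative or non-numeric value at row '",
         rownames(x)[bad[1, 1]], "', column '", colnames(x)[bad[1, 2]], "'",
         call. = FALSE)
  invisible(x)
}

#' Read a miRNA x sample count matrix from a delimited text file
#'
#' The first column holds miRNA identifiers (header `mirna_id` or anything
#' else; it is ignored), remaining columns are samples named by the header
#' row. Identifiers are trimmed of surrounding whitespace but otherwise
#' matched exactly and case-sensitively.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return numeric matrix, rows = miRNAs, columns = samples, in file order.
#' @export
read_count_matrix <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("count matrix file needs an ID column plus >= 1 sample")
  ids <- trimws(as.character(df[[1L]]))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        i <- which(is.na(vn))[1L]
        stop("non-numeric cell at row '", ids[i], "', column '",
             colnames(body)[j], "'", call. = FALSE)
      }
      body[[j]] <- vn
    }
  }
  x <- as.matrix(body)
  rownames(x) <- ids
  colnames(x) <- trimws(colnames(x))
  validate_counts(x)
  x
}

#' Write a count matrix to a delimited text file
#'
#' Inverse of [read_count_matrix()]: first column `mirna_id`, one column per
#' sample. Values are written at full double precision so a read/write
#' round-trip is value-stable.
#'
#' @param x count matrix.
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @export
write_count_matrix <- function(x, path, delimiter = "\t") {
  validate_counts(x)
  df <- data.frame(mirna_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- sample sheet ----------------------------------------------------------

#' Default tissue-to-organ map for the rat body atlas
#'
#' 23 tissues grouped into 14 organs: the four brain regions form `brain`,
#' cortex/kidney/medulla form `kidney`, the two stomach compartments form
#' `stomach`, duodenum/ileum/jejunum form `intestine`, biceps/soleus form
#' `muscle`, and every other tissue is its own organ.
#'
#' @return data.frame with columns `tissue` and `organ`.
#' @export
default_organ_map <- function() {
  path <- system.file("extdata", "tissue_organ_map.tsv", package = "mirtisect",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Validate a sample sheet
#'
#' A sample sheet is a data.frame with columns `sample_id`, `tissue`,
#' `organ`, `sex` and `animal`. Sample identifiers must be unique and every
#' tissue must map to exactly one organ.
#'
#' @param sheet data.frame.
#' @return the validated sheet, invisibly.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "tissue", "organ", "sex", "animal")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  if (length(dup))
    stop("duplicate sample_id in sample sheet: ", paste(dup, collapse = ", "),
         call. = FALSE)
  amb <- tapply(sheet$organ, sheet$tissue, function(o) length(unique(o)))
  if (any(amb > 1L))
    stop("tissue(s) mapped to more than one organ: ",
         paste(names(amb)[amb > 1L], collapse = ", "), call. = FALSE)
  invisible(sheet)
}

#' Read a sample sheet from a TSV file
#'
#' Expected columns: `sample_id`, `tissue`, `organ`, `sex`, `animal`. If the
#' `organ` column is absent it is filled from [default_organ_map()]; a
#' user-supplied organ column overrides the default map entirely.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path, delimiter = "\t") {
  sheet <- utils::read.table(path, sep = delimiter, header = TRUE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  for (cn in intersect(c("sample_id", "tissue", "organ"), colnames(sheet)))
    sheet[[cn]] <- trimws(as.character(sheet[[cn]]))
  if (!"organ" %in% colnames(sheet)) {
    map <- default_organ_map()
    idx <- match(sheet$tissue, map$tissue)
    if (anyNA(idx))
      stop("tissue(s) absent from the default organ map: ",
           paste(unique(sheet$tissue[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    sheet$organ <- map$organ[idx]
  }
  if (!"sex" %in% colnames(sheet)) sheet$sex <- NA_character_
  if (!"animal" %in% colnames(sheet)) sheet$animal <- NA_character_
  validate_sample_sheet(sheet)
  sheet
}

# check that counts and sheet cover each other; extra sheet rows are allowed,
# samples in counts missing from the sheet are a hard error (never dropped
# silently -- low-depth sample removal is the user's explicit decision)
match_sheet <- function(counts, sheet) {
  validate_sample_sheet(sheet)
  miss <- setdiff(colnames(counts), sheet$sample_id)
  if (length(miss))
    stop("sample(s) in the count matrix absent from the sample sheet: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
}

# ---- annotation ------------------------------------------------------------

#' Read a miRNA annotation table
#'
#' Columns: `mirna_id`, `n_loci` (positive integer count of genomic loci the
#' miRNA maps to), `parent_mature_id` (required for isomiRs, empty
#' otherwise), `feature_class` (`mature`, `pre` or `isomiR`).
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path, delimiter = "\t") {
  ann <- utils::read.table(path, sep = delimiter, header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", na.strings = c("NA", ""))
  validate_annotation(ann)
  ann
}

#' Validate an annotation table
#' @param ann data.frame with at least `mirna_id` and `n_loci`.
#' @return the validated table, invisibly.
#' @export
validate_annotation <- function(ann) {
  if (!all(c("mirna_id", "n_loci") %in% colnames(ann)))
    stop("annotation needs columns mirna_id and n_loci", call. = FALSE)
  if (any(!is.finite(ann$n_loci) | ann$n_loci < 1 | ann$n_loci != round(ann$n_loci)))
    stop("n_loci must be positive integers", call. = FALSE)
  if ("feature_class" %in% colnames(ann)) {
    iso <- ann$feature_class == "isomiR"
    if (any(iso) && (!"parent_mature_id" %in% colnames(ann) ||
                     anyNA(ann$parent_mature_id[iso])))
      stop("every isomiR record needs a parent_mature_id", call. = FALSE)
  }
  invisible(ann)
}

# ---- group summaries -------------------------------------------------------

#' Per-tissue or per-organ mean expression
#'
#' Collapses the sample columns of a count (or normalized) matrix to group
#' means: entry (j, g) is the arithmetic mean over the samples of group g.
#'
#' @param counts miRNA x sample matrix.
#' @param sheet sample sheet covering all samples in `counts`.
#' @param kind `"tissue"` or `"organ"`.
#' @return miRNA x group matrix with attribute `group_kind`.
#' @export
group_means <- function(counts, sheet, kind = c("tissue", "organ")) {
  kind <- match.arg(kind)
  validate_counts(counts)
  sh <- match_sheet(counts, sheet)
  groups <- sh[[kind]]
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("empty ", kind, " label in sample sheet", call. = FALSE)
  lv <- unique(groups)
  out <- vapply(lv, function(g) {
    cols <- which(groups == g)
    rowMeans(counts[, cols, drop = FALSE])
  }, numeric(nrow(counts)))
  out <- matrix(out, nrow = nrow(counts), dimnames = list(rownames(counts), lv))
  attr(out, "group_kind") <- kind
  out
}

# sum (not mean) over a group's samples, used for tissue-level totals
group_sums <- function(counts, sheet, kind = c("tissue", "organ")) {
  kind <- match.arg(kind)
  sh <- match_sheet(counts, sheet)
  groups <- sh[[kind]]
  lv <- unique(groups)
  out <- vapply(lv, function(g)
    rowSums(counts[, groups == g, drop = FALSE]), numeric(nrow(counts)))
  out <- matrix(out, nrow = nrow(counts), dimnames = list(rownames(counts), lv))
  attr(out, "group_kind") <- kind
  out
}

#' Aggregate tissue-level values to the organ level by element-wise maximum
#'
#' Each organ column is the element-wise maximum over its member tissue
#' columns; single-tissue organs pass through unchanged. The maximum (rather
#' than the average) preserves a strong signal confined to one member tissue.
#'
#' @param tissue_mat miRNA x tissue matrix (sums or means).
#' @param organ_map data.frame with columns `tissue`, `organ`; defaults to
#'   [default_organ_map()].
#' @return miRNA x organ matrix.
#' @export
aggregate_to_organ_max <- function(tissue_mat, organ_map = default_organ_map()) {
  if (is.data.frame(organ_map)) {
    if (all(c("tissue", "organ") %in% colnames(organ_map))) {
      map <- organ_map[!duplicated(organ_map$tissue), c("tissue", "organ")]
    } else stop("organ_map needs columns tissue and organ")
  } else stop("organ_map must be a data.frame")
  idx <- match(colnames(tissue_mat), map$tissue)
  if (anyNA(idx))
    stop("tissue(s) missing from the organ map: ",
         paste(colnames(tissue_mat)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  organs <- map$organ[idx]
  lv <- unique(organs)
  out <- vapply(lv, function(o) {
    m <- tissue_mat[, organs == o, drop = FALSE]
    apply(m, 1L, max)
  }, numeric(nrow(tissue_mat)))
  out <- matrix(out, nrow = nrow(tissue_mat),
                dimnames = list(rownames(tissue_mat), lv))
  attr(out, "group_kind") <- "organ"
  out
}
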