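# Unified entry point: run one or more pipelines on an atlas, compare their
# call sets, compute the TSI table, and optionally write everything to disk
# with the serialized configuration.

#' Run the selected detection pipelines on a count atlas
#'
#' Executes any subset of the three pipelines with a shared configuration,
#' computes the TSI table from the TMM tissue means, and (when at least two
#' pipelines are selected) the Venn region partition of their TS call sets.
#' Deterministic given the configuration and seed. When `out_dir` is given,
#' per-pipeline call TSVs, the TSI table, the overlap regions and a JSON
#' copy of the configuration (with its hash) are written there.
#'
#' @param counts miRNA x sample raw count matrix.
#' @param sheet sample sheet.
#' @param annot optional annotation table (locus scaling in the proportion
#'   pipeline).
#' @param pipelines subset of `c("nmf", "quasipoisson", "proportion")`.
#' @param overlap_status which status' call sets to intersect, default
#'   `"TS"`.
#' @param alpha,percent_points,ts_mode quasi-Poisson settings.
#' @param te_share,ts_share NMF share thresholds.
#' @param te_threshold,ts_threshold proportion thresholds.
#' @param alias optional id alias map for [reconcile_ids()].
#' @param seed integer seed (NMF restarts).
#' @param out_dir optional output directory.
#' @return list of class `mirtisect_run`: `calls` (all pipelines bound),
#'   per-pipeline result objects, `tsi`, `overlap` (or NULL), `config`.
#' @export
run_detection <- function(counts, sheet, annot = NULL,
                          pipelines = c("nmf", "quasipoisson", "proportion"),
                          overlap_status = "TS",
                          alpha = 0.05, percent_points = 90,
                          ts_mode = "excess",
                          te_share = 0.60, ts_share = 0.80,
                          te_threshold = 0.5, ts_threshold = 0.9,
                          alias = NULL, seed = 1L, out_dir = NULL) {
  pipelines <- match.arg(pipelines, several.ok = TRUE)
  validate_counts(counts)
  config <- list(pipelines = pipelines, overlap_status = overlap_status,
                 alpha = alpha, percent_points = percent_points,
                 ts_mode = ts_mode, te_share = te_share,
                 ts_share = ts_share, te_threshold = te_threshold,
                 ts_threshold = ts_threshold, seed = as.integer(seed))
  config$hash <- config_hash(config)

  fits <- list()
  errors <- list()
  for (p in pipelines) {
    fit <- tryCatch(switch(p,
      nmf = run_nmf_pipeline(counts, sheet, te_share = te_share,
                             ts_share = ts_share, seed = seed),
      quasipoisson = run_qp_pipeline(counts, sheet, alpha = alpha,
                                     percent_points = percent_points,
                                     ts_mode = ts_mode),
      proportion = run_proportion_pipeline(counts, sheet, annot,
                                           te_threshold = te_threshold,
                                           ts_threshold = ts_threshold)),
      error = function(e) e)
    if (inherits(fit, "error")) errors[[p]] <- conditionMessage(fit)
    else fits[[p]] <- fit
  }
  calls <- do.call(bind_calls, lapply(fits, function(f) f$calls))

  tmm <- tmm_normalize(counts)
  tsi <- compute_tsi(group_means(tmm, sheet, "tissue"))

  ov <- NULL
  if (length(fits) >= 2L) {
    sets <- lapply(fits, function(f)
      unique(f$calls$mirna_id[f$calls$status == overlap_status]))
    sets <- reconcile_ids(sets, alias)
    ov <- overlap_sets(sets)
  }

  run <- structure(list(calls = calls, fits = fits, tsi = tsi,
                        overlap = ov, config = config, errors = errors),
                   class = "mirtisect_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  if (length(errors))
    warning("pipeline(s) failed: ",
            paste(names(errors), unlist(errors), sep = ": ",
                  collapse = "; "))
  run
}

config_hash <- function(config) {
  config$hash <- NULL
  js <- jsonlite::toJSON(config, auto_unbox = TRUE)
  # content hash of the serialized configuration, stamped on every output
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("# config_hash: ", run$config$hash)
  for (p in names(run$fits)) {
    path <- file.path(out_dir, paste0("calls_", p, ".tsv"))
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(run$fits[[p]]$calls, path,
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  path <- file.path(out_dir, "tsi.tsv")
  writeLines(stamp, path)
  suppressWarnings(utils::write.table(run$tsi, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  if (!is.null(run$overlap))
    write_overlap(run$overlap, file.path(out_dir, "overlap"))
  jsonlite::write_json(run$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mirtisect_run <- function(x, ...) {
  cat("mirtisect run (", paste(names(x$fits), collapse = " + "),
      "), config ", substr(x$config$hash, 1, 8), "\n", sep = "")
  tab <- table(x$calls$pipeline, x$calls$status)
  print(tab)
  if (!is.null(x$overlap)) {
    tri <- names(x$overlap$counts)[which.max(nchar(names(x$overlap$counts)))]
    cat("overlap (", x$config$overlap_status, "): all-pipeline region has ",
        x$overlap$counts[[tri]], " miRNA(s)\n", sep = "")
  }
  if (length(x$errors))
    cat("FAILED pipelines:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

# ---- static plot exports ---------------------------------------------------

# per-row z-scores clipped to [-lim, lim]; constant rows map to 0
row_zscores <- function(m, lim = 4) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  pmin(pmax(z, -lim), lim)
}

#' Export static summary plots for a set of miRNAs
#'
#' Writes three PNGs: a bar chart of mean TMM expression per group with
#' standard-deviation error bars, a box plot of `log2(TMM + 1)` per group,
#' and a heat map of per-row z-scores clipped to \[-4, 4\], with
#' hierarchical clustering (Euclidean distance, complete linkage). A
#' single-miRNA heat map is rendered without clustering, with a warning.
#'
#' @param tmm TMM-normalized miRNA x sample matrix.
#' @param sheet sample sheet.
#' @param mirna_ids miRNAs to plot.
#' @param out_dir output directory.
#' @param kind group by `"tissue"` or `"organ"`.
#' @param z_limit z-score clipping limit for the heat map.
#' @return paths of the written files, invisibly.
#' @export
export_plots <- function(tmm, sheet, mirna_ids, out_dir,
                         kind = "tissue", z_limit = 4) {
  if (!length(mirna_ids)) stop("no miRNAs to plot", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sh <- match_sheet(tmm, sheet)
  groups <- sh[[kind]]
  sub <- tmm[mirna_ids, , drop = FALSE]
  means <- group_means(sub, sheet, kind)
  sds <- vapply(unique(groups), function(g)
    apply(sub[, groups == g, drop = FALSE], 1L, stats::sd),
    numeric(nrow(sub)))
  sds <- matrix(sds, nrow = nrow(sub),
                dimnames = list(rownames(sub), unique(groups)))

  paths <- character(0)

  p <- file.path(out_dir, "bar_mean_sd.png")
  grDevices::png(p, width = 1200, height = 600)
  avg <- colMeans(means); sdv <- colMeans(sds)
  bp <- graphics::barplot(avg, las = 2, ylab = "mean TMM",
                          ylim = c(0, max(avg + sdv) * 1.05),
                          main = "Mean expression by group (SD bars)")
  graphics::arrows(bp, avg, bp, avg + sdv, angle = 90, length = 0.04)
  grDevices::dev.off()
  paths <- c(paths, p)

  p <- file.path(out_dir, "box_log2_tmm.png")
  grDevices::png(p, width = 1200, height = 600)
  graphics::boxplot(split(log2(colMeans(sub) + 1), groups), las = 2,
                    ylab = "log2(TMM + 1)",
                    main = "Expression spread by group")
  grDevices::dev.off()
  paths <- c(paths, p)

  p <- file.path(out_dir, "heatmap_zscore.png")
  z <- row_zscores(means, z_limit)
  grDevices::png(p, width = 900, height = 200 + 24 * nrow(z))
  if (nrow(z) < 2L) {
    warning("single-miRNA heat map rendered without clustering")
    graphics::image(t(z), axes = FALSE, main = rownames(z)[1L],
                    zlim = c(-z_limit, z_limit))
    graphics::axis(1, at = seq(0, 1, length.out = ncol(z)),
                   labels = colnames(z), las = 2)
  } else {
    stats::heatmap(z, distfun = stats::dist,
                   hclustfun = function(d) stats::hclust(d, "complete"),
                   scale = "none", zlim = c(-z_limit, z_limit),
                   margins = c(8, 10))
  }
  grDevices::dev.off()
  invisible(c(paths, p))
}
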