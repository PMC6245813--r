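# Seeded generator of multi-tissue miRNA count atlases with planted
# TE/TS/OS structure, shaped like the rat body-atlas design (23 tissues in
# 14 organs, 10 samples per tissue, 5 for the sex-specific tissues).

local_seed <- function(seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    fn <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    fn <- function() if (exists(".Random.seed", envir = globalenv(),
                               inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  fn
}

#' Default per-tissue sample sizes of the atlas design
#'
#' Ten animals (five male, five female) per tissue, except the sex-specific
#' tissues (ovary, uterus: five females; testicle: five males).
#'
#' @return named integer vector over the 23 default tissues.
#' @export
default_sample_sizes <- function() {
  tis <- default_organ_map()$tissue
  n <- stats::setNames(rep(10L, length(tis)), tis)
  n[c("ovary", "uterus", "testicle")] <- 5L
  n
}

#' Describe a synthetic atlas design
#'
#' Collects the parameters of a synthetic count atlas: the tissue/organ
#' layout, replicate numbers, the negative-binomial noise model
#' (`counts ~ NB(mean = baseline_j * fold * library_factor, size =
#' dispersion)`, with per-miRNA baselines log-normal around
#' `baseline_mean`), and the planted enrichment effects.
#'
#' @param n_mirnas number of miRNAs.
#' @param baseline_mean median per-sample baseline expression (counts).
#' @param baseline_sdlog log-normal spread of per-miRNA baselines; the
#'   default 1.5 spans roughly three orders of magnitude, as real atlases
#'   do.
#' @param dispersion negative-binomial size; `Inf` gives Poisson noise.
#' @param libsize_sd standard deviation of the per-sample log-normal
#'   library-size factor.
#' @param organ_map tissue/organ data.frame, default [default_organ_map()].
#' @param samples_per_tissue named integer vector, default
#'   [default_sample_sizes()].
#' @param planted data.frame of planted effects with columns `mirna`
#'   (index into 1..n_mirnas), `target` (tissue or organ label), `level`
#'   (`"tissue"` or `"organ"`), `fold` (> 1) and `status` (intended
#'   TE/TS/OS); see [planted_effects()].
#' @param loci_probs probabilities of a miRNA mapping to 1, 2 or 3 genomic
#'   loci.
#' @param seed integer seed; the generator is byte-deterministic given the
#'   design.
#' @return list of class `atlas_design`.
#' @export
atlas_design <- function(n_mirnas = 300L, baseline_mean = 100,
                         baseline_sdlog = 1.5, dispersion = 5,
                         libsize_sd = 0.2,
                         organ_map = default_organ_map(),
                         samples_per_tissue = default_sample_sizes(),
                         planted = NULL,
                         loci_probs = c(0.85, 0.10, 0.05), seed = 1L) {
  stopifnot(n_mirnas >= 1L, baseline_mean > 0, dispersion > 0,
            libsize_sd >= 0, abs(sum(loci_probs) - 1) < 1e-9)
  miss <- setdiff(organ_map$tissue, names(samples_per_tissue))
  if (length(miss))
    stop("no sample size for tissue(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(planted)) {
    stopifnot(all(c("mirna", "target", "level", "fold", "status") %in%
                    colnames(planted)))
    if (any(planted$fold <= 1))
      stop("planted folds must exceed 1", call. = FALSE)
    if (any(planted$mirna < 1 | planted$mirna > n_mirnas))
      stop("planted mirna index out of range", call. = FALSE)
    bad <- !(ifelse(planted$level == "tissue",
                    planted$target %in% organ_map$tissue,
                    planted$target %in% organ_map$organ))
    if (any(bad))
      stop("planted target(s) not in the design: ",
           paste(unique(planted$target[bad]), collapse = ", "), call. = FALSE)
  }
  structure(list(n_mirnas = as.integer(n_mirnas),
                 baseline_mean = baseline_mean,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 libsize_sd = libsize_sd, organ_map = organ_map,
                 samples_per_tissue = samples_per_tissue,
                 planted = planted, loci_probs = loci_probs,
                 seed = as.integer(seed)),
            class = "atlas_design")
}

#' Planted enrichment effects, one miRNA per target
#'
#' Convenience constructor for the `planted` slot of [atlas_design()]:
#' assigns miRNAs `first_index, first_index + 1, ...` one target each,
#' recycling over `targets`.
#'
#' @param n number of planted miRNAs.
#' @param targets tissue or organ labels to cycle over.
#' @param fold enrichment fold (> 1).
#' @param level `"tissue"` or `"organ"`.
#' @param status intended status label (TE/TS/OS).
#' @param first_index index of the first planted miRNA.
#' @return data.frame suitable for `atlas_design(planted = ...)`.
#' @export
planted_effects <- function(n, targets, fold = 1000, level = "tissue",
                            status = "TS", first_index = 1L) {
  data.frame(mirna = seq.int(first_index, length.out = n),
             target = rep_len(targets, n), level = level, fold = fold,
             status = status, stringsAsFactors = FALSE)
}

#' Generate a synthetic count atlas from a design
#'
#' Draws a miRNA x sample negative-binomial count matrix with the planted
#' enrichment structure of the design, plus the matching sample sheet,
#' annotation table (loci counts drawn from \{1, 2, 3\}) and truth table.
#' Deterministic given the design's seed.
#'
#' @param design an [atlas_design()].
#' @param seed optional override of the design's seed.
#' @return list with `counts`, `sheet`, `annotation`, `truth` (data.frame
#'   of the planted effects with miRNA identifiers).
#' @export
generate_atlas <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "atlas_design"))
  restore <- local_seed(seed)
  on.exit(restore())

  om <- design$organ_map
  sheets <- lapply(seq_len(nrow(om)), function(i) {
    tis <- om$tissue[i]
    n <- design$samples_per_tissue[[tis]]
    sex <- if (tis %in% c("ovary", "uterus")) rep("F", n)
           else if (tis == "testicle") rep("M", n)
           else rep(c("M", "F"), length.out = n)
    animal <- paste0(sex, stats::ave(seq_len(n), sex, FUN = seq_along))
    data.frame(sample_id = paste(tis, tolower(sex), animal, sep = "_"),
               tissue = tis, organ = om$organ[i], sex = sex,
               animal = animal, stringsAsFactors = FALSE)
  })
  sheet <- do.call(rbind, sheets)
  validate_sample_sheet(sheet)

  n_j <- design$n_mirnas
  n_s <- nrow(sheet)
  mirna_ids <- sprintf("syn-miR-%03d", seq_len(n_j))
  baseline <- stats::rlnorm(n_j, log(design$baseline_mean),
                            design$baseline_sdlog)
  libfac <- stats::rlnorm(n_s, 0, design$libsize_sd)

  fold <- matrix(1, n_j, n_s)
  if (!is.null(design$planted)) {
    for (i in seq_len(nrow(design$planted))) {
      pl <- design$planted[i, ]
      cols <- if (pl$level == "tissue") sheet$tissue == pl$target
              else sheet$organ == pl$target
      fold[pl$mirna, cols] <- pl$fold
    }
  }
  mu <- (baseline * fold) * rep(libfac, each = n_j)
  counts <- if (is.infinite(design$dispersion))
    matrix(stats::rpois(n_j * n_s, mu), n_j, n_s)
  else
    matrix(stats::rnbinom(n_j * n_s, mu = mu, size = design$dispersion),
           n_j, n_s)
  dimnames(counts) <- list(mirna_ids, sheet$sample_id)

  annotation <- data.frame(
    mirna_id = mirna_ids,
    n_loci = sample(seq_along(design$loci_probs), n_j, replace = TRUE,
                    prob = design$loci_probs),
    parent_mature_id = NA_character_, feature_class = "mature",
    stringsAsFactors = FALSE)

  truth <- if (is.null(design$planted)) {
    data.frame(mirna_id = character(), status = character(),
               target = character(), level = character(), fold = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(mirna_id = mirna_ids[design$planted$mirna],
               status = design$planted$status,
               target = design$planted$target,
               level = design$planted$level, fold = design$planted$fold,
               stringsAsFactors = FALSE)
  }
  list(counts = counts, sheet = sheet, annotation = annotation,
       truth = truth)
}

#' Generate an isomiR count table with controllable dominant isoforms
#'
#' Each mature miRNA gets `isos_per_mature` isomiRs with baseline
#' within-mature proportions `base_props` (first isomiR dominant). A
#' `dominant_switch` row (`mature`, `tissue`, `isomir`) swaps the named
#' isomiR's proportion with the dominant one in that tissue, so its
#' dominant isoform differs there in expectation.
#'
#' @param design an [atlas_design()] (supplies tissues, replicate numbers,
#'   noise parameters and seed).
#' @param n_matures number of mature miRNAs.
#' @param isos_per_mature isomiRs per mature miRNA.
#' @param base_props baseline within-mature proportions (sum to 1).
#' @param mean_total expected total mature expression per sample.
#' @param dominant_switch optional data.frame with columns `mature`
#'   (index), `tissue`, `isomir` (index of the isomiR to make dominant).
#' @param seed optional seed override.
#' @return list with `counts` (isomiR x sample), `annotation` (isomiR
#'   records with parents), `sheet`.
#' @export
generate_isomir_table <- function(design, n_matures = 10L,
                                  isos_per_mature = 3L,
                                  base_props = c(0.6, 0.3, 0.1),
                                  mean_total = 1000,
                                  dominant_switch = NULL,
                                  seed = design$seed + 1L) {
  stopifnot(inherits(design, "atlas_design"),
            length(base_props) == isos_per_mature,
            abs(sum(base_props) - 1) < 1e-9)
  if (!is.null(dominant_switch)) {
    stopifnot(all(c("mature", "tissue", "isomir") %in%
                    colnames(dominant_switch)))
    if (any(dominant_switch$mature < 1 |
            dominant_switch$mature > n_matures))
      stop("dominant_switch names an unknown mature miRNA", call. = FALSE)
    if (any(!dominant_switch$tissue %in% design$organ_map$tissue))
      stop("dominant_switch names an unknown tissue", call. = FALSE)
  }
  restore <- local_seed(seed)
  on.exit(restore())

  sheet <- generate_atlas(design, seed = design$seed)$sheet
  mat_ids <- sprintf("syn-mat-%02d", seq_len(n_matures))
  iso_ids <- as.vector(t(outer(mat_ids, seq_len(isos_per_mature),
                               function(m, k) paste0(m, ".iso", k))))
  n_s <- nrow(sheet)
  dom_k <- which.max(base_props)
  counts <- matrix(0, length(iso_ids), n_s,
                   dimnames = list(iso_ids, sheet$sample_id))
  for (m in seq_len(n_matures)) {
    for (s in seq_len(n_s)) {
      props <- base_props
      if (!is.null(dominant_switch)) {
        hit <- dominant_switch$mature == m &
          dominant_switch$tissue == sheet$tissue[s]
        if (any(hit)) {
          k <- dominant_switch$isomir[which(hit)[1L]]
          props[c(dom_k, k)] <- props[c(k, dom_k)]
        }
      }
      mu <- mean_total * props
      y <- if (is.infinite(design$dispersion)) stats::rpois(length(mu), mu)
           else stats::rnbinom(length(mu), mu = mu, size = design$dispersion)
      counts[(m - 1L) * isos_per_mature + seq_len(isos_per_mature), s] <- y
    }
  }
  annotation <- data.frame(
    mirna_id = iso_ids,
    n_loci = 1L,
    parent_mature_id = rep(mat_ids, each = isos_per_mature),
    feature_class = "isomiR", stringsAsFactors = FALSE)
  list(counts = counts, annotation = annotation, sheet = sheet)
}
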