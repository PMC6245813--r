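# Shared fixtures and independent oracles used across the test files.

# minimal sample sheet: n samples per tissue, organs from the default map
# unless an explicit map is given
make_sheet <- function(tissues, n_per = 2L, organ = NULL) {
  if (is.null(organ)) {
    map <- default_organ_map()
    organ <- map$organ[match(tissues, map$tissue)]
    organ[is.na(organ)] <- tissues[is.na(organ)]
  }
  do.call(rbind, lapply(seq_along(tissues), function(i) {
    data.frame(
      sample_id = paste0(tissues[i], "_s", seq_len(n_per)),
      tissue = tissues[i], organ = organ[i],
      sex = rep(c("M", "F"), length.out = n_per),
      animal = paste0("a", seq_len(n_per)), stringsAsFactors = FALSE)
  }))
}

# counts matrix with named dims
cm <- function(values, mirnas, samples) {
  matrix(values, nrow = length(mirnas), byrow = TRUE,
         dimnames = list(mirnas, samples))
}

# bundled example of published liver/brain mean TMM expression
liver_brain_fixture <- function() {
  path <- system.file("extdata", "liver_brain_means.tsv",
                      package = "mirtisect", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$mirna_id
  m
}

# ---- independent TMM oracle -----------------------------------------------
# Straight-line transcription of the published trimmed-mean-of-M-values
# procedure: reference = sample whose upper-quartile-scaled library is
# closest to the mean; per sample, M/A values vs the reference over genes
# positive in both; double trim (30% of M ranks, 5% of A ranks);
# inverse-variance-weighted mean of retained M values; factors rescaled to
# geometric mean 1. Written independently of the package's implementation.
tmm_oracle <- function(x, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(x)
  f75 <- vapply(seq_len(ncol(x)), function(j)
    unname(quantile(x[, j], 0.75)) / lib[j], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(s) {
    if (s == ref) return(1)
    obs <- x[, s]; r <- x[, ref]
    nO <- lib[s]; nR <- lib[ref]
    keep0 <- obs > 0 & r > 0
    obs <- obs[keep0]; r <- r[keep0]
    M <- log2((obs / nO) / (r / nR))
    A <- (log2(obs / nO) + log2(r / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - r) / (nR * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(x)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

# ---- independent TSI oracle ------------------------------------------------
# one-line evaluation of the index for a single profile
tsi_oracle <- function(profile) {
  sum(1 - profile / max(profile)) / (length(profile) - 1)
}

# ---- brute-force Venn regions ----------------------------------------------
# enumerate region membership element by element
venn_oracle <- function(sets) {
  univ <- unique(unlist(sets))
  out <- list()
  for (el in univ) {
    code <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                     logical(1))], collapse = "&")
    out[[code]] <- c(out[[code]], el)
  }
  out
}
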