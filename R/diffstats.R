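#' Mann-Whitney U test between two groups of editing levels
#'
#' Two-sided test. The exact null distribution is used when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' The statistic U is reported for group a (number of (a, b) pairs with
#' a > b, ties counting one half). Two constant, equal groups give p = 1.
#'
#' @param a,b numeric vectors of editing levels (NAs dropped).
#' @return A list with `U`, `p`, and `method` ("exact" or "normal").
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stopf("both groups need at least one non-missing value")
  r <- rank(c(a, b))
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (length(unique(c(a, b))) == 1L)
    return(list(U = U, p = 1, method = "degenerate"))
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(U = U, p = min(1, wt$p.value),
       method = if (exact) "exact" else "normal")
}

#' Differential-editing table between two sample groups
#'
#' Runs a two-sided Mann-Whitney U test per retained site on non-missing
#' cells (pairwise deletion), corrects p-values with Benjamini-Hochberg
#' across all tested sites of the comparison, and reports the direction of
#' change of group a relative to group b.
#'
#' @param aggregate a `site_aggregate` (typically retained sites).
#' @param labels factor/character vector over the aggregate's sample
#'   columns with exactly two levels; the first level is group a (cases).
#' @param alpha significance level on BH-corrected p-values (default 0.05).
#' @return A data.frame of class `diff_table`: one row per tested site with
#'   `name`, `category`, `n_a`, `n_b`, `mean_a`, `mean_b`, `median_a`,
#'   `median_b`, `U`, `p_raw`, `p_bh`, `direction`, `significant`. Sites
#'   with no usable value in either group are skipped (message).
#' @export
differential_table <- function(aggregate, labels, alpha = 0.05) {
  lab <- as.character(labels)
  lv <- if (is.factor(labels)) levels(labels) else unique(lab)
  stopifnot(length(lv) == 2, length(lab) == ncol(aggregate$levels))
  ia <- lab == lv[1]; ib <- lab == lv[2]
  st <- aggregate$sites
  rows <- vector("list", nrow(st))
  skipped <- 0L
  for (i in seq_len(nrow(st))) {
    va <- aggregate$levels[i, ia]; va <- va[!is.na(va)]
    vb <- aggregate$levels[i, ib]; vb <- vb[!is.na(vb)]
    if (!length(va) || !length(vb)) { skipped <- skipped + 1L; next }
    mw <- mann_whitney(va, vb)
    rows[[i]] <- data.frame(
      name = st$name[i], category = st$category[i],
      n_a = length(va), n_b = length(vb),
      mean_a = mean(va), mean_b = mean(vb),
      median_a = stats::median(va), median_b = stats::median(vb),
      U = mw$U, p_raw = mw$p, stringsAsFactors = FALSE)
  }
  if (skipped) message(sprintf("%d site(s) skipped: empty group", skipped))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(name = character(), category = character(),
                      n_a = integer(), n_b = integer(), mean_a = numeric(),
                      mean_b = numeric(), median_a = numeric(),
                      median_b = numeric(), U = numeric(), p_raw = numeric(),
                      p_bh = numeric(), direction = character(),
                      significant = logical(), stringsAsFactors = FALSE)
    class(out) <- c("diff_table", "data.frame")
    return(out)
  }
  out$p_bh <- bh_correct(out$p_raw)
  d <- out$mean_a - out$mean_b
  out$direction <- ifelse(d > 0, "up", ifelse(d < 0, "down", "none"))
  out$significant <- out$p_bh < alpha
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Quantile normalization of an expression/level matrix
#'
#' Standard quantile normalization with columns as samples, backed by
#' [limma::normalizeQuantiles()] with tie averaging: after the transform
#' all complete columns share identical sorted values. Missing cells are
#' excluded from the reference distribution (interpolated quantiles) and
#' restored as missing. A single-column matrix is returned unchanged.
#'
#' @param m numeric matrix, columns = samples.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) <= 1L) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Principal component analysis of samples on editing levels
#'
#' Column-mean-centered, unscaled covariance PCA with samples as
#' observations (sites as variables). Missing cells are imputed to the
#' site's cohort mean beforehand. Loadings follow the sign convention that
#' each component's largest-magnitude element is positive.
#'
#' @param level_matrix sites x samples numeric matrix.
#' @return A list with `scores` (samples x components), `loadings`
#'   (sites x components) and `var_explained` (fractions summing to 1).
#' @export
pca_samples <- function(level_matrix) {
  stopifnot(is.matrix(level_matrix), ncol(level_matrix) >= 2)
  x <- impute_site_means(level_matrix)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  list(scores = scores, loadings = loadings, var_explained = ve)
}

impute_site_means <- function(m) {
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas)) {
    rm <- rowMeans(m, na.rm = TRUE)
    rm[is.nan(rm)] <- 0
    m[nas] <- rm[nas[, 1]]
  }
  m
}

#' Hierarchical clustering of samples by correlation distance
#'
#' Distance between samples i and j is `1 - Pearson(x_i + 1, x_j + 1)`
#' computed on the normalized values (the +1 offset is retained from the
#' original procedure although Pearson correlation is shift-invariant).
#' Agglomeration uses Ward-D2. Missing cells are imputed to the site mean;
#' a constant sample vector has undefined correlation and its distances
#' are set to 1 (message).
#'
#' @param normalized_matrix sites x samples numeric matrix (typically
#'   quantile-normalized).
#' @return An object of class `hclust`.
#' @export
cluster_samples <- function(normalized_matrix) {
  stopifnot(is.matrix(normalized_matrix), ncol(normalized_matrix) >= 2)
  x <- impute_site_means(normalized_matrix) + 1
  sds <- apply(x, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    message("constant sample vector(s): correlation undefined, distance set to 1")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
    diag(cc) <- 1
  }
  d <- stats::as.dist(1 - cc)
  stats::hclust(d, method = "ward.D2")
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` object ([cluster_samples()]).
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}
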