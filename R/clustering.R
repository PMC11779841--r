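#' Biofilm/medium ratio features per monosaccharide
#'
#' For each sugar and each requested day, divides the biofilm integral by
#' the spent-medium integral, giving one partition-profile vector per sugar
#' (length 4 for the default days 2--5; day 1 is excluded by default because
#' medium data can be incomplete there). Sugars with any missing value over
#' the requested days are dropped and the reason recorded; a zero medium
#' integral is an error naming the offending cell, since the ratio is then
#' undefined.
#'
#' @param biofilm,medium tidy tables with columns `sugar`, `day`,
#'   `integral` (`NA` marks a missing measurement).
#' @param days days to use as features; default 2:5.
#' @return a numeric matrix (rows sugars, columns `day_<d>`) of class
#'   `feature_matrix`, with attribute `dropped` (named character vector of
#'   reasons).
#' @export
compute_ratio_features <- function(biofilm, medium, days = 2:5) {
  for (tb in list(biofilm, medium)) {
    if (!all(c("sugar", "day", "integral") %in% names(tb))) {
      stop_input("tables must have columns sugar, day, integral")
    }
  }
  sugars <- sort(unique(biofilm$sugar))
  get_val <- function(tb, sg, d) {
    v <- tb$integral[tb$sugar == sg & tb$day == d]
    if (length(v) == 0) NA_real_ else v[1]
  }
  mat <- matrix(NA_real_, nrow = length(sugars), ncol = length(days),
                dimnames = list(sugars, paste0("day_", days)))
  dropped <- character(0)
  for (sg in sugars) {
    bf <- vapply(days, function(d) get_val(biofilm, sg, d), numeric(1))
    md <- vapply(days, function(d) get_val(medium, sg, d), numeric(1))
    zero <- which(!is.na(md) & md == 0)
    if (length(zero)) {
      stop_computation(sprintf(
        "medium integral is 0 for sugar %s on day %g; ratio undefined",
        sg, days[zero[1]]
      ))
    }
    if (anyNA(bf) || anyNA(md)) {
      miss_md <- days[is.na(md)]
      miss_bf <- days[is.na(bf)]
      reason <- paste(c(
        if (length(miss_md)) paste0("missing medium value on day ",
                                    paste(miss_md, collapse = ",")),
        if (length(miss_bf)) paste0("missing biofilm value on day ",
                                    paste(miss_bf, collapse = ","))
      ), collapse = "; ")
      dropped[sg] <- reason
      next
    }
    mat[sg, ] <- bf / md
  }
  if (length(dropped)) {
    message("dropped sugars: ",
            paste(sprintf("%s (%s)", names(dropped), dropped),
                  collapse = "; "))
  }
  mat <- mat[!rownames(mat) %in% names(dropped), , drop = FALSE]
  attr(mat, "dropped") <- dropped
  attr(mat, "days") <- days
  class(mat) <- c("feature_matrix", class(mat))
  mat
}

#' Column-wise standardization to zero mean and unit (population) SD
#'
#' Each feature column is centered and scaled by its population standard
#' deviation (divide by n), the convention of the standard machine-learning
#' scaler, so features are equally weighted in the subsequent PCA.
#' The means and SDs are stored for exact inversion.
#'
#' @param x a numeric matrix (e.g. a `feature_matrix`).
#' @return the standardized matrix with attributes `center` and `scale`.
#' @export
standardize_features <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2) stop_input("standardization needs >= 2 rows")
  ctr <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  if (any(sdp == 0)) {
    stop_input("constant column(s): ",
               paste(colnames(x)[sdp == 0], collapse = ", "),
               "; standard deviation is zero")
  }
  z <- sweep(sweep(x, 2, ctr), 2, sdp, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- sdp
  class(z) <- c("feature_matrix", "matrix", "array")
  z
}

#' Invert a standardization
#' @param z a matrix from [standardize_features()].
#' @return the matrix on the original scale.
#' @export
unstandardize_features <- function(z) {
  ctr <- attr(z, "center")
  sdp <- attr(z, "scale")
  if (is.null(ctr) || is.null(sdp)) {
    stop_input("matrix carries no standardization parameters")
  }
  out <- sweep(sweep(unclass(z), 2, sdp, "*"), 2, ctr, "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

#' Two-component principal component analysis
#'
#' Singular-value decomposition of the column-centered matrix (via
#' [stats::prcomp()]); the first two component scores are returned together
#' with the explained-variance ratios of all components. Signs follow a
#' deterministic convention: within each component the loading of largest
#' magnitude is made positive, so results do not depend on row order or
#' LAPACK sign choices.
#'
#' @param x a numeric matrix with at least 3 rows, typically standardized.
#' @return list of class `sugar_pca`: `scores` (n x 2), `loadings`,
#'   `explained_variance` (all components, ratios in `[0, 1]`).
#' @export
pca_2d <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 3) stop_input("PCA needs >= 3 rows")
  if (all(abs(scale(x, scale = FALSE)) < 1e-300)) {
    stop_input("matrix has rank 0 after centering")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2, ncol(pc$x))
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(
    list(
      scores = pc$x[, seq_len(k), drop = FALSE],
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      explained_variance = ev
    ),
    class = "sugar_pca"
  )
}

#' @export
print.sugar_pca <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf(
    "2-component PCA: PC1 %.1f%%, PC2 %.1f%% (together %.1f%%) of variance\n",
    100 * ev[1], 100 * ev[min(2, length(ev))],
    100 * sum(ev[seq_len(min(2, length(ev)))])
  ))
  invisible(x)
}

# Mean silhouette width for a labelling; NA when undefined (singleton-free
# configurations with zero dispersion, or k = 1).
mean_silhouette <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- tryCatch(
    cluster::silhouette(labels, stats::dist(scores)),
    error = function(e) NULL
  )
  if (is.null(sil)) return(NA_real_)
  m <- mean(sil[, "sil_width"])
  if (!is.finite(m)) NA_real_ else m
}

#' K-means clustering of PCA scores with silhouette-guided k selection
#'
#' Runs K-means (multiple restarts, fixed seed) on the 2-D PCA scores for
#' every candidate `k`, scores each solution by its mean silhouette width,
#' and selects the `k` with the largest silhouette unless an explicit `k`
#' override is given (mirroring the use of prior biological knowledge
#' alongside the silhouette criterion).
#'
#' @param scores an n x 2 score matrix (rownames identify the samples), or a
#'   `sugar_pca` object.
#' @param k_range candidate cluster counts; every value must be < n rows.
#' @param seed RNG seed for the K-means restarts (default 0).
#' @param nstart number of K-means restarts (default 50).
#' @param k optional override forcing the selected number of clusters.
#' @return object of class `sugar_clustering`: `labels` (named integer
#'   vector), `k`, `silhouettes` (named by candidate k, `NA` when
#'   undefined), `scores`, `seed`.
#' @export
cluster_scores <- function(scores, k_range = 2:6, seed = 0, nstart = 50,
                           k = NULL) {
  if (inherits(scores, "sugar_pca")) scores <- scores$scores
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (any(k_range >= n)) {
    stop_input("every candidate k must be smaller than the number of rows (",
               n, ")")
  }
  if (!is.null(k) && (k >= n || k < 1)) {
    stop_input("k override must be in [1, n)")
  }
  n_distinct <- nrow(unique(scores))
  fits <- list()
  sils <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  for (kk in k_range) {
    if (kk > n_distinct) next  # degenerate geometry: silhouette stays NA
    fit <- with_seed(derive_seed(seed, "kmeans", kk), {
      stats::kmeans(scores, centers = kk, nstart = nstart, iter.max = 100)
    })
    fits[[as.character(kk)]] <- fit
    sils[as.character(kk)] <- mean_silhouette(fit$cluster, scores)
  }
  k_sel <- if (!is.null(k)) {
    k
  } else if (all(is.na(sils))) {
    stop_computation("silhouette undefined for every candidate k")
  } else {
    as.integer(names(which.max(sils)))
  }
  fit_sel <- fits[[as.character(k_sel)]]
  if (is.null(fit_sel) && k_sel > n_distinct) {
    stop_input("k = ", k_sel, " exceeds the ", n_distinct,
               " distinct score points")
  }
  if (is.null(fit_sel)) {
    fit_sel <- with_seed(derive_seed(seed, "kmeans", k_sel), {
      stats::kmeans(scores, centers = k_sel, nstart = nstart, iter.max = 100)
    })
  }
  structure(
    list(
      labels = stats::setNames(fit_sel$cluster, rownames(scores)),
      k = k_sel, silhouettes = sils, scores = scores, seed = seed,
      forced = !is.null(k)
    ),
    class = "sugar_clustering"
  )
}

#' @export
print.sugar_clustering <- function(x, ...) {
  cat(sprintf("K-means on PCA scores: k = %d%s, n = %d\n", x$k,
              if (x$forced) " (forced)" else " (max silhouette)",
              nrow(x$scores)))
  sil <- x$silhouettes
  cat("  silhouettes:",
      paste(sprintf("k=%s %.3f", names(sil), sil), collapse = ", "), "\n")
  for (kk in sort(unique(x$labels))) {
    cat(sprintf("  cluster %d: %s\n", kk,
                paste(names(x$labels)[x$labels == kk], collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.sugar_clustering <- function(x, ...) {
  graphics::plot(x$scores[, 1], x$scores[, 2], col = x$labels, pch = 19,
                 xlab = "PC1", ylab = "PC2", ...)
  graphics::text(x$scores[, 1], x$scores[, 2], labels = rownames(x$scores),
                 pos = 3, cex = 0.8)
  invisible(x)
}

#' Full monosaccharide clustering pipeline
#'
#' Ratio features, standardization, 2-D PCA and silhouette-guided K-means in
#' one call.
#'
#' @inheritParams compute_ratio_features
#' @inheritParams cluster_scores
#' @return a `sugar_clustering` with the `sugar_pca` attached as `$pca` and
#'   the feature matrix as `$features`.
#' @export
cluster_sugars <- function(biofilm, medium, days = 2:5, k_range = 2:6,
                           seed = 0, nstart = 50, k = NULL) {
  feats <- compute_ratio_features(biofilm, medium, days)
  z <- standardize_features(feats)
  pca <- pca_2d(z)
  res <- cluster_scores(pca$scores, k_range = k_range, seed = seed,
                        nstart = nstart, k = k)
  res$pca <- pca
  res$features <- feats
  res
}

#' PCA explained variance for an externally supplied ratio table
#'
#' When a published biofilm/medium ratio table is supplied (CSV with a
#' sugar-label column followed by one column per day, or a numeric matrix),
#' standardizes it and reports the variance captured by the first two
#' principal components. Without a table the check is reported as
#' unavailable rather than silently skipped.
#'
#' @param table path to a CSV file, a data frame, or a numeric matrix;
#'   `NULL` when no reference table is available.
#' @return list with `available` and, when available, `explained_variance_2`
#'   (percent captured by the first two components) and the `sugar_pca`.
#' @export
reference_pca_variance <- function(table = NULL) {
  if (is.null(table)) {
    return(list(available = FALSE,
                reason = "no reference ratio table supplied"))
  }
  if (is.character(table)) {
    table <- utils::read.csv(table, check.names = FALSE)
  }
  if (is.data.frame(table)) {
    lab <- table[[1]]
    m <- as.matrix(table[, -1, drop = FALSE])
    rownames(m) <- lab
  } else {
    m <- as.matrix(table)
  }
  pca <- pca_2d(standardize_features(m))
  ev2 <- 100 * sum(pca$explained_variance[1:min(2, length(
    pca$explained_variance))])
  list(available = TRUE, explained_variance_2 = ev2, pca = pca)
}
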