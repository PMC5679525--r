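#' Standardize meteorology and extract principal components
#'
#' Columns are centred and scaled to unit variance, then decomposed by
#' PCA.  The smallest number of leading components whose cumulative
#' explained-variance ratio reaches `variance_target` is retained (capped
#' at `max_components`), unless `n_components` fixes the count directly.
#'
#' @param met A `met_matrix` (or matrix-like list with `values`).
#' @param variance_target Cumulative explained-variance ratio to reach
#'   (default 0.93).
#' @param max_components Cap on retained components (default 6).
#' @param n_components Optional fixed number of components, overriding the
#'   variance rule.
#' @return List of class `pc_scores`: `scores` (days x k), `loadings`,
#'   `explained` (all variance ratios), `cumulative`, `k`.
#' @export
standardize_and_pca <- function(met, variance_target = 0.93,
                                max_components = 6L, n_components = NULL) {
  v <- if (is.list(met) && !is.data.frame(met)) met$values else as.matrix(met)
  if (nrow(v) < 2L) stop("need at least two days for PCA")
  sds <- apply(v, 2L, sd)
  if (any(sds == 0)) {
    stop("cannot standardize zero-variance column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  }
  pc <- prcomp(v, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(expl)
  k <- if (!is.null(n_components)) {
    as.integer(n_components)
  } else {
    min(match(TRUE, cum >= variance_target, nomatch = length(expl)),
        max_components)
  }
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = expl, cumulative = cum, k = k),
            class = "pc_scores")
}

#' K-means clustering of principal-component scores
#'
#' Best-of-restarts K-means (Hartigan-Wong) on the retained component
#' scores, reproducible given the seed.
#'
#' @param scores A `pc_scores` object or a numeric matrix.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_restarts Independent restarts; the solution with the lowest
#'   total within-cluster sum of squares is kept (default 25).
#' @param iter_max Maximum Lloyd/Hartigan iterations per restart.
#' @return List of class `swt_clustering`: `cluster` (integer labels),
#'   `centers` (in score space), `withinss`, `tot_withinss`, `totss`.
#' @export
kmeans_cluster <- function(scores, k, seed = 1L, n_restarts = 25L,
                           iter_max = 300L) {
  x <- if (inherits(scores, "pc_scores")) scores$scores else as.matrix(scores)
  if (k < 1L) stop("k must be at least 1")
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop("k (", k, ") exceeds the number of distinct points (", n_distinct, ")")
  }
  local_seed(seed, {
    km <- kmeans(x, centers = k, nstart = n_restarts, iter.max = iter_max)
    structure(list(cluster = km$cluster, centers = km$centers,
                   withinss = km$withinss, tot_withinss = km$tot.withinss,
                   totss = km$totss, k = k),
              class = "swt_clustering")
  })
}

#' Choose the number of clusters by the elbow rule
#'
#' Fits K-means over `k_range`, records the within-cluster sum of squares
#' (WSS) curve, and returns the interior k maximizing its second
#' difference (the sharpest bend), with ties broken toward smaller k.
#' When the curve has no pronounced bend -- the maximal curvature does not
#' clearly dominate the typical curvature -- a warning is emitted and
#' `default_k` is returned.
#'
#' @param scores A `pc_scores` object or numeric matrix.
#' @param k_range Candidate cluster counts (>= 3 values).
#' @param seed Integer seed.
#' @param default_k Fallback when no elbow is detected (default 6).
#' @param n_restarts Restarts per k.
#' @param null_r2 The elbow counts as pronounced only when a smooth
#'   power-law decay (log-log linear fit) explains less than this share
#'   of the WSS curve's variance (default 0.97).
#' @return The selected integer k, with the WSS curve attached as
#'   attribute `"wss"`.
#' @export
select_k_elbow <- function(scores, k_range = 1:8, seed = 1L, default_k = 6L,
                           n_restarts = 10L, null_r2 = 0.97) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) stop("k_range must cover at least 3 values")
  wss <- vapply(seq_along(k_range), function(i) {
    kmeans_cluster(scores, k_range[i], seed = seed + i,
                   n_restarts = n_restarts)$tot_withinss
  }, numeric(1))
  # curvature at interior candidates
  d2 <- wss[-c(length(wss), length(wss) - 1L)] -
    2 * wss[-c(1L, length(wss))] + wss[-(1:2)]
  interior <- k_range[-c(1L, length(k_range))]
  # null model for structureless data: WSS decays as a smooth power law
  # in k (log-log linear); a genuine elbow produces a marked kink
  loglog_r2 <- if (all(wss > 0)) {
    f <- stats::lm(log(wss) ~ log(k_range))
    summary(f)$r.squared
  } else 0
  if (max(d2) <= 0 || loglog_r2 >= null_r2) {
    warning("no pronounced elbow in the WSS curve; returning default k = ",
            default_k)
    k <- as.integer(default_k)
  } else {
    k <- interior[which.max(d2)]  # which.max takes the first (smallest k) tie
  }
  attr(k, "wss") <- stats::setNames(wss, k_range)
  k
}

#' Name synoptic-weather-type clusters from their centroids
#'
#' Maps six cluster centroids to the conventional synoptic labels by
#' ranking them on mean temperature and mean humidity: centroids are split
#' at the cross-centroid median humidity into three "dry" and three
#' "humid" types, and within each humidity group ranked by temperature
#' (dry: hot / moderate / cold; humid: warm / moderate / cold).  Ties are
#' broken deterministically by centroid pressure (higher pressure ranked
#' colder), with a warning.
#'
#' @param centroids Data frame or matrix with one row per cluster and
#'   columns `temp_mean` and `humidity_mean` (optionally `pressure_mean`
#'   for tie-breaking).
#' @return Character vector of unique labels, one per centroid row, in
#'   `c("hot dry", "warm humid", "cold dry", "moderate dry",
#'   "moderate humid", "cold humid")`.
#' @export
label_swt_clusters <- function(centroids) {
  cen <- as.data.frame(centroids)
  if (!all(c("temp_mean", "humidity_mean") %in% names(cen))) {
    stop("centroids must carry temp_mean and humidity_mean")
  }
  if (nrow(cen) != 6L) {
    stop("synoptic labelling is defined for exactly 6 centroids, got ",
         nrow(cen))
  }
  pressure <- if ("pressure_mean" %in% names(cen)) cen$pressure_mean else
    rep(0, nrow(cen))
  if (anyDuplicated(cen[, c("temp_mean", "humidity_mean")])) {
    warning("tied centroids; breaking ties by centroid pressure")
  }
  # rank on humidity (pressure as deterministic tie-break)
  hum_rank <- order(cen$humidity_mean, -pressure, seq_len(nrow(cen)))
  dry <- hum_rank[1:3]
  humid <- hum_rank[4:6]
  labels <- character(6L)
  # within groups, hotter centroids first; pressure breaks temperature ties
  dry_by_temp <- dry[order(-cen$temp_mean[dry], cen$humidity_mean[dry],
                           pressure[dry])]
  hum_by_temp <- humid[order(-cen$temp_mean[humid], cen$humidity_mean[humid],
                             pressure[humid])]
  labels[dry_by_temp] <- c("hot dry", "moderate dry", "cold dry")
  labels[hum_by_temp] <- c("warm humid", "moderate humid", "cold humid")
  labels
}

#' Classify days into synoptic weather types
#'
#' Full synoptic-typing chain: standardize the 15 meteorological
#' parameters, retain the leading principal components (variance target
#' 0.93, at most `max_components`), cluster the component scores by
#' best-of-restarts K-means, and name the clusters from their centroids in
#' the original meteorological units.
#'
#' @param met A `met_matrix`.
#' @param k Number of weather types (default 6); `k = NULL` selects k by
#'   [select_k_elbow()].
#' @param seed Integer seed.
#' @param variance_target,max_components Passed to [standardize_and_pca()].
#' @return List of class `swt_labels`: `label` (factor per day),
#'   `cluster`, `centroids` (per-type means of the meteorological
#'   parameters), `pca`, `clustering`.
#' @export
classify_swt <- function(met, k = 6L, seed = 1L, variance_target = 0.93,
                         max_components = 6L) {
  pca <- standardize_and_pca(met, variance_target = variance_target,
                             max_components = max_components)
  if (is.null(k)) k <- select_k_elbow(pca, seed = seed)
  cl <- kmeans_cluster(pca, k = k, seed = seed)
  cen <- aggregate(met$values, by = list(cluster = cl$cluster), FUN = mean)
  labels_by_cluster <- if (k == 6L) {
    label_swt_clusters(cen)
  } else {
    paste("type", cen$cluster)
  }
  lev <- c("hot dry", "warm humid", "cold dry", "moderate dry",
           "moderate humid", "cold humid")
  if (k != 6L) lev <- labels_by_cluster
  label <- factor(labels_by_cluster[match(cl$cluster, cen$cluster)],
                  levels = lev)
  structure(list(label = label, cluster = cl$cluster, centroids = cen,
                 pca = pca, clustering = cl),
            class = "swt_labels")
}
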