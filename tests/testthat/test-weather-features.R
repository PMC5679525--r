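test_that("extreme flags match a brute-force sort-and-threshold oracle", {
  st <- tiny_study(seed = 11, end = "2014-12-31")
  met <- st$met
  flags <- compute_extreme_flags(met)
  expect_named(flags, c("date", flag_names()))
  # oracle: sort values, count strictly beyond the type-7 quantile
  v <- met$values
  oracle_count <- function(x, q, upper) {
    thr <- quantile(x, q, names = FALSE, type = 7)
    if (upper) sum(x > thr) else sum(x < thr)
  }
  expect_equal(sum(flags$hot), oracle_count(v[, "temp_max"], 0.9, TRUE))
  expect_equal(sum(flags$cold), oracle_count(v[, "temp_min"], 0.1, FALSE))
  expect_equal(sum(flags$windless), oracle_count(v[, "wind_mean"], 0.1, FALSE))
  # continuous series: each flag on ~10% of days (within the one-day
  # granularity of the interpolated quantile threshold)
  for (f in flag_names()) {
    expect_lt(abs(mean(flags[[f]]) - 0.10), 0.002)
  }
})

test_that("constant series yield no extreme flags (strict inequality)", {
  n <- 50
  v <- matrix(1, n, 6,
              dimnames = list(NULL, c("temp_min", "temp_max", "pressure_min",
                                      "pressure_max", "humidity_mean",
                                      "wind_mean")))
  met <- list(dates = as.Date("2012-01-01") + seq_len(n) - 1, values = v)
  flags <- compute_extreme_flags(met)
  expect_true(all(colSums(as.matrix(flags[, flag_names()])) == 0))
})

test_that("flags are non-exclusive and missing columns are reported by name", {
  st <- tiny_study(seed = 11, end = "2014-12-31")
  flags <- compute_extreme_flags(st$met)
  co <- sum(rowSums(as.matrix(flags[, flag_names()])) >= 2)
  expect_gt(co, 0)  # co-occurring extremes exist
  met_bad <- st$met
  met_bad$values <- met_bad$values[, setdiff(colnames(met_bad$values), "wind_mean")]
  expect_error(compute_extreme_flags(met_bad), "wind_mean")
})

test_that("PCA on identity-covariance data spreads variance evenly", {
  set.seed(21)
  x <- matrix(rnorm(4000 * 15), ncol = 15)
  pc <- standardize_and_pca(list(values = x), variance_target = 0.93)
  # oracle: eigendecomposition of the sample correlation matrix
  ev <- eigen(cor(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc$explained, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(abs(pc$explained - 1 / 15) < 0.02))
})

test_that("rank-1 data retain a single component; zero-variance errors", {
  set.seed(22)
  f <- rnorm(300)
  x <- outer(f, runif(15, 0.5, 2)) + matrix(rnorm(300 * 15, sd = 1e-4), ncol = 15)
  pc <- standardize_and_pca(list(values = x))
  expect_equal(pc$k, 1L)
  x2 <- cbind(x, const = 1)
  colnames(x2) <- c(paste0("v", 1:15), "const")
  expect_error(standardize_and_pca(list(values = x2)), "const")
})

test_that("retained PC scores are uncorrelated and variance ratios nonincreasing", {
  st <- tiny_study(seed = 11, end = "2014-12-31")
  pc <- standardize_and_pca(st$met)
  cc <- cor(pc$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-8)
})

test_that("k-means recovers planted blobs and degenerates correctly", {
  set.seed(31)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  lab <- rep(1:3, each = 60)
  x <- centers[lab, ] + matrix(rnorm(360, sd = 0.5), ncol = 2)
  cl <- kmeans_cluster(x, 3, seed = 2)
  # oracle: planted labels up to permutation
  tab <- table(cl$cluster, lab)
  expect_equal(sum(apply(tab, 2, max)), length(lab))
  one <- kmeans_cluster(x, 1, seed = 2)
  expect_equal(length(unique(one$cluster)), 1L)
  expect_equal(one$tot_withinss, one$totss, tolerance = 1e-8)
  expect_error(kmeans_cluster(x[1:3, ], 5, seed = 1), "distinct")
})

test_that("k-means is seed-deterministic and WSS nonincreasing in k", {
  set.seed(32)
  x <- matrix(rnorm(500 * 4), ncol = 4)
  a <- kmeans_cluster(x, 4, seed = 9)
  b <- kmeans_cluster(x, 4, seed = 9)
  expect_identical(a$cluster, b$cluster)
  wss <- vapply(1:6, function(k) kmeans_cluster(x, k, seed = 5)$tot_withinss, 0)
  expect_true(all(diff(wss) <= 1e-8))
})

test_that("elbow selection finds planted k and warns without an elbow", {
  set.seed(33)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  x <- centers[rep(1:3, each = 70), ] + matrix(rnorm(420, sd = 0.6), ncol = 2)
  k <- select_k_elbow(x, 1:8, seed = 4)
  expect_equal(as.integer(k), 3L)
  y <- matrix(rnorm(400 * 2), ncol = 2)  # single spherical cloud
  expect_warning(kd <- select_k_elbow(y, 1:8, seed = 4, default_k = 6),
                 "elbow")
  expect_equal(as.integer(kd), 6L)
})

test_that("centroid labelling reproduces the conventional six type names", {
  cen <- data.frame(
    temp_mean = c(28.4, 23.8, 8.0, 18.5, 19.1, 6.7),
    humidity_mean = c(62.0, 79.9, 60.8, 66.4, 82.3, 72.0),
    pressure_mean = c(100.6, 100.8, 102.4, 101.7, 101.1, 102.5))
  lab <- label_swt_clusters(cen)
  expect_equal(lab, c("hot dry", "warm humid", "cold dry", "moderate dry",
                      "moderate humid", "cold humid"))
  expect_equal(anyDuplicated(lab), 0L)
  # identical centroids exercise the deterministic tie-break path
  tied <- cen
  tied[2, ] <- tied[1, ]
  expect_warning(lab2 <- label_swt_clusters(tied), "tie")
  expect_equal(sort(lab2), sort(lab))
})

test_that("synoptic typing partitions all days into six labelled types", {
  st <- tiny_study(seed = 11, end = "2014-12-31")
  swt <- classify_swt(st$met, seed = 5)
  expect_false(anyNA(swt$label))
  expect_equal(nlevels(swt$label), 6L)
  expect_equal(length(unique(swt$label)), 6L)
  expect_equal(length(swt$label), length(st$met$dates))
  # labels partition (each day exactly one type), unlike the flags
  expect_equal(sum(table(swt$label)), length(st$met$dates))
})
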