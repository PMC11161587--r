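test_that("z-scoring standardizes exactly and handles degenerate input", {
  set.seed(41)
  tab <- data.frame(total_gains = rnorm(30, 140, 15),
                    total_losses = rnorm(30, 30, 8))
  z <- zscore_table(tab, names(tab))
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(vapply(z, sd, 0) - 1) < 1e-12))
  expect_equal(as.matrix(zscore_table(z, names(z))), as.matrix(z),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(zscore_table(tab[1, ], names(tab)), "2 rows")
  tab$total_losses <- 5
  expect_warning(z2 <- zscore_table(tab, names(tab)), "constant")
  expect_equal(names(z2), "total_gains")
})

test_that("Ward merges match the exhaustive minimum-SSE oracle at n = 6", {
  set.seed(42)
  for (rep in 1:5) {
    x <- matrix(rnorm(12), 6, 2)
    hc <- ward_cluster(x)
    orc <- oracle_ward(x)
    expect_equal(hclust_members(hc$merge), orc$members)
    expect_equal(hc$height, orc$heights, tolerance = 1e-10)
  }
})

test_that("Ward heights are monotone and separated clouds merge last", {
  set.seed(43)
  x <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 10), 20, 2))
  hc <- ward_cluster(x)
  expect_true(all(diff(hc$height) >= -1e-12))
  top <- cutree(hc, 2)
  expect_equal(length(unique(top[1:20])), 1)
  expect_equal(length(unique(top[21:40])), 1)
  # n = 2: single merge at the SSE increase of joining two points
  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(ward_cluster(two)$height, 25 / 2)
})

test_that("silhouette-based selection finds well-separated blobs", {
  set.seed(44)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(40, 8), 20, 2),
             matrix(rnorm(40, c(0, 16)), 20, 2))
  sol <- choose_k(x, ward_cluster(x), k_range = 2:5, seed = 1)
  expect_equal(sol$chosen_k, 3)
  expect_true(sol$agreement)
  expect_gt(max(sol$silhouette, na.rm = TRUE), 0.7)
  # a single blob supports no clustering (moderate dimension, where chance
  # splits of one Gaussian cannot look cohesive)
  y <- matrix(rnorm(800), 80, 10)
  soly <- choose_k(y, ward_cluster(y), k_range = 2:5, seed = 1)
  expect_lt(max(soly$silhouette, na.rm = TRUE), 0.3)
})

test_that("published-profile cohorts cluster far above chance", {
  skip_if_not_installed("mclust")
  # With variables drawn independently at the published marginal moments,
  # the risk-avoidant and useful-risk profiles overlap substantially, so
  # perfect recovery is not attainable at n = 81; the k = 3 cut must still
  # agree with the generative partition far above chance in every replicate
  # and strongly on average (measured by simulation).
  ari <- vapply(1:10, function(rep) {
    co <- generate_profiles(kdt_published_clusters(), seed = 500 + rep)
    z <- zscore_table(co, kdt_variables())
    sol <- choose_k(z, ward_cluster(z), seed = rep)
    mclust::adjustedRandIndex(sol$labels[, "k3"], co$true_cluster)
  }, 0)
  expect_true(all(ari > 0.4))
  expect_gt(mean(ari), 0.6)
})

test_that("cluster characterization names the published profiles", {
  co <- generate_profiles(kdt_published_clusters(), seed = 7)
  z <- zscore_table(co, kdt_variables())
  sol <- choose_k(z, ward_cluster(z), seed = 2)
  lab <- sol$labels[, paste0("k", sol$chosen_k)]
  names_by_cluster <- characterize_clusters(co, lab)
  truth_by_cluster <- tapply(as.character(co$true_cluster), lab, function(s)
    names(which.max(table(s))))
  expect_equal(unname(names_by_cluster), as.vector(truth_by_cluster))
  # degenerate cases
  expect_equal(unname(characterize_clusters(co, rep(1, nrow(co)))),
               "homogeneous")
  half <- co[rep(1:10, 2), ]
  expect_warning(res <- characterize_clusters(half, rep(1:2, each = 10)),
                 "tie")
  expect_setequal(unname(res), c("risk_avoidant", "useful_risk"))
})

test_that("row permutation permutes labels identically", {
  co <- generate_profiles(small_test_specs(), seed = 9)
  z <- zscore_table(co, kdt_variables())
  sol <- choose_k(z, ward_cluster(z), k_range = 2:4, seed = 3)
  perm <- sample(nrow(z))
  solp <- choose_k(z[perm, ], ward_cluster(z[perm, ]), k_range = 2:4,
                   seed = 3)
  k <- paste0("k", sol$chosen_k)
  expect_equal(solp$chosen_k, sol$chosen_k)
  a <- sol$labels[perm, k]
  b <- solp$labels[, k]
  # same partition up to label names
  expect_equal(length(unique(paste(a, b))), length(unique(a)))
})
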