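make_cluster_scene <- function(seed, n_clusters = 5, per_cluster = 60,
                               csr = 300, domain = 4000, cluster_sd = 40) {
  set.seed(seed)
  cx <- runif(n_clusters, 500, domain - 500)
  cy <- runif(n_clusters, 500, domain - 500)
  # keep clusters well separated
  while (any(dist(cbind(cx, cy)) < 500)) {
    cx <- runif(n_clusters, 500, domain - 500)
    cy <- runif(n_clusters, 500, domain - 500)
  }
  ref <- tibble::tibble(
    x_nm = c(rep(cx, each = per_cluster) + rnorm(n_clusters * per_cluster, 0, cluster_sd),
             runif(csr, 0, domain)),
    y_nm = c(rep(cy, each = per_cluster) + rnorm(n_clusters * per_cluster, 0, cluster_sd),
             runif(csr, 0, domain)))
  list(ref = ref, cx = cx, cy = cy, domain = domain)
}

test_that("planted reference clusters are found and queries counted", {
  sc <- make_cluster_scene(seed = 111)
  inside <- tibble::tibble(x_nm = rep(sc$cx, each = 4) + rnorm(20, 0, 20),
                           y_nm = rep(sc$cy, each = 4) + rnorm(20, 0, 20))
  outside <- tibble::tibble(x_nm = runif(15, 0, sc$domain),
                            y_nm = runif(15, 0, sc$domain))
  # keep only outside points far from every cluster centre
  far <- apply(outer(outside$x_nm, sc$cx, "-")^2 +
                 outer(outside$y_nm, sc$cy, "-")^2, 1,
               function(d2) min(sqrt(d2))) > 400
  outside <- outside[far, ]
  query <- dplyr::bind_rows(inside, outside)
  res <- count_spots_in_foci(sc$ref, query,
                             bounds_nm = c(0, sc$domain, 0, sc$domain))
  expect_identical(nrow(res$per_focus), 5L)
  # every dense-cluster query is inside a focus, no far query is
  expect_identical(res$query$focus[seq_len(nrow(inside))] > 0L,
                   rep(TRUE, nrow(inside)))
  expect_identical(res$query$focus[-seq_len(nrow(inside))],
                   rep(0L, nrow(outside)))
  expect_identical(res$n_inside, nrow(inside))
  expect_identical(sum(res$per_focus$n_query), nrow(inside))
})

test_that("focus centroids land on the planted cluster centres", {
  sc <- make_cluster_scene(seed = 112)
  res <- count_spots_in_foci(sc$ref, sc$ref[0, ],
                             bounds_nm = c(0, sc$domain, 0, sc$domain))
  expect_identical(nrow(res$per_focus), 5L)
  d <- vapply(seq_len(5), function(i) {
    min(sqrt((res$per_focus$x_nm - sc$cx[i])^2 +
               (res$per_focus$y_nm - sc$cy[i])^2))
  }, numeric(1))
  # centroid error well below the cluster SD
  expect_lt(max(d), 25)
})

test_that("nearest-focus distances are exact for the query molecules", {
  sc <- make_cluster_scene(seed = 113)
  query <- tibble::tibble(x_nm = runif(30, 0, sc$domain),
                          y_nm = runif(30, 0, sc$domain))
  res <- count_spots_in_foci(sc$ref, query,
                             bounds_nm = c(0, sc$domain, 0, sc$domain))
  cf <- res$per_focus
  for (k in seq_len(nrow(query))) {
    d <- sqrt((cf$x_nm - query$x_nm[k])^2 + (cf$y_nm - query$y_nm[k])^2)
    expect_identical(res$query$nearest_focus[k], cf$focus[which.min(d)])
    expect_equal(res$query$distance_nm[k], min(d), tolerance = 1e-9)
  }
})

test_that("an empty reference table is rejected", {
  expect_error(count_spots_in_foci(tibble::tibble(x_nm = numeric(),
                                                  y_nm = numeric()),
                                   tibble::tibble(x_nm = 1, y_nm = 1)),
               "no reference", class = "focimetry_error")
})
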