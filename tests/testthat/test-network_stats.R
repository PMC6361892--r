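conn_group <- function(n_subj, nch, shift_edges = NULL, shift = 0) {
  lapply(seq_len(n_subj), function(i) {
    random_conn_matrix(nch, shift_edges = shift_edges, shift = shift)
  })
}

test_that("edge Z matrix matches the closed-form tie-free normal approximation", {
  set.seed(1)
  # planted edge where all 10 A values exceed all 10 B values: U = 100
  ga <- conn_group(10, 4)
  gb <- conn_group(10, 4)
  for (k in 1:10) ga[[k]][2, 1] <- ga[[k]][1, 2] <- 100 + k
  z <- edge_z_matrix(ga, gb)
  expect_equal(z[2, 1], 50 / sqrt(175), tolerance = 1e-12)  # 3.7796
  expect_equal(unname(z), unname(t(z)))

  # identical groups => Z = 0 at every edge
  z0 <- edge_z_matrix(ga, ga)
  expect_true(all(abs(z0[lower.tri(z0)]) < 1e-12))

  # all values tied at one edge => Z defined as 0
  for (k in 1:10) {
    ga[[k]][3, 1] <- ga[[k]][1, 3] <- 5
    gb[[k]][3, 1] <- gb[[k]][1, 3] <- 5
  }
  expect_equal(edge_z_matrix(ga, gb)[3, 1], 0)

  # null: mean Z over edges near 0 across draws
  set.seed(2)
  zm <- replicate(20, {
    z <- edge_z_matrix(conn_group(8, 5), conn_group(8, 5))
    mean(z[lower.tri(z)])
  })
  expect_lt(abs(mean(zm)), 0.15)

  expect_error(edge_z_matrix(conn_group(1, 4), conn_group(5, 4)), "2 subjects")
  expect_error(edge_z_matrix(conn_group(3, 4), conn_group(3, 5)),
               "differ in dimension")
})

test_that("supra-threshold component finder agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (k in 1:25) {
    n <- sample(4:12, 1L)
    z <- random_conn_matrix(n)
    thr <- stats::runif(1, -0.5, 1)
    comps <- supra_components(z, thr)
    pairs <- which(lower.tri(z), arr.ind = TRUE)
    keep <- !is.na(z[pairs]) & z[pairs] > thr
    if (!any(keep)) {
      expect_length(comps, 0L)
      next
    }
    g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                     directed = FALSE)
    memb <- igraph::components(g)$membership
    ig_extents <- sort(as.vector(table(memb[pairs[keep, 1L]])),
                       decreasing = TRUE)
    expect_equal(vapply(comps, `[[`, numeric(1L), "extent"),
                 as.numeric(ig_extents))
    expect_equal(sum(vapply(comps, `[[`, numeric(1L), "extent")), sum(keep))
  }
})

test_that("supra_components handles the simple worked cases", {
  z <- matrix(0, 4, 4)
  z[2, 1] <- z[1, 2] <- 3
  z[3, 2] <- z[2, 3] <- 3
  comps <- supra_components(z, 1.96)
  expect_length(comps, 1L)
  expect_equal(comps[[1L]]$extent, 2)
  expect_equal(comps[[1L]]$nodes, 1:3)

  expect_length(supra_components(matrix(0, 4, 4), 1.96), 0L)

  full <- matrix(5, 4, 4); diag(full) <- NA
  comps4 <- supra_components(full, 1.96)
  expect_length(comps4, 1L)
  expect_equal(comps4[[1L]]$extent, 6)
})

test_that("nbs_test is deterministic under seed and detects a planted subnetwork", {
  set.seed(11)
  planted <- cbind(1:5, 2:6)   # 5-edge path
  ga <- conn_group(10, 10, shift_edges = planted, shift = 3)
  gb <- conn_group(10, 10)
  cfg <- nbs_config(n_permutations = 500, seed = 42)
  r1 <- nbs_test(ga, gb, cfg)
  r2 <- nbs_test(ga, gb, cfg)
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(summary(r1), summary(r2))

  expect_gt(length(r1$components), 0L)
  top <- r1$components[[1L]]
  expect_lt(top$p, 0.05)
  planted_keys <- paste(planted[, 2L], planted[, 1L])
  found_keys <- paste(top$edges[, 1L], top$edges[, 2L])
  expect_gte(sum(planted_keys %in% found_keys), 4L)
  expect_true(all(summary(r1)$p > 0) && all(summary(r1)$p <= 1))
})

test_that("two-sided NBS p-values are invariant under group relabelling", {
  set.seed(3)
  ga <- conn_group(3, 6, shift_edges = cbind(1, 2), shift = 4)
  gb <- conn_group(3, 6)
  cfg <- nbs_config(n_permutations = 5000, tail = "two.sided", seed = 1)
  # choose(6, 3) = 20 distinct assignments: exhaustive enumeration
  r_ab <- suppressWarnings(nbs_test(ga, gb, cfg))
  r_ba <- suppressWarnings(nbs_test(gb, ga, cfg))
  expect_equal(sort(summary(r_ab)$p), sort(summary(r_ba)$p))
  expect_equal(sort(r_ab$null_max), sort(r_ba$null_max))
})

test_that("lowering the threshold never shrinks any observed component", {
  set.seed(9)
  z <- random_conn_matrix(10)
  thresholds <- c(1.5, 1.0, 0.5, 0.0)
  maxima <- vapply(thresholds, function(th) {
    comps <- supra_components(z, th)
    if (length(comps)) comps[[1L]]$extent else 0
  }, numeric(1L))
  expect_true(all(diff(maxima) >= 0))
})
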