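#' Configuration for the Mann-Whitney Network-Based Statistics test
#'
#' @param z_threshold edge-level Z threshold forming the supra-threshold
#'   graph (default 1.96).
#' @param n_permutations group-label permutations for the null of the maximum
#'   component statistic (default 5000).
#' @param alpha component-level significance level.
#' @param tail `"greater"` (one-sided, group A stochastically larger — the
#'   default, matching the hypothesis of higher connectivity in the
#'   atypical-outcome group), `"less"`, or `"two.sided"`.
#' @param statistic component statistic: `"extent"` (edge count, the NBS
#'   default) or `"intensity"` (sum of supra-threshold Z scores).
#' @param seed integer seed making the permutation stream reproducible.
#' @return An object of class `nbs_config`.
#' @export
nbs_config <- function(z_threshold = 1.96, n_permutations = 5000,
                       alpha = 0.05, tail = c("greater", "less", "two.sided"),
                       statistic = c("extent", "intensity"), seed = NULL) {
  tail <- match.arg(tail)
  statistic <- match.arg(statistic)
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (!is.finite(z_threshold)) stop("`z_threshold` must be finite")
  structure(list(z_threshold = z_threshold,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, tail = tail, statistic = statistic,
                 seed = seed),
            class = "nbs_config")
}

# Stack the lower triangles of a list of connectivity matrices into a
# subjects x edges matrix; returns the edge endpoints alongside.
stack_edges <- function(matrices) {
  n <- nrow(as.matrix(matrices[[1L]]))
  pairs <- lower_pairs(n)
  x <- t(vapply(matrices, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(n, n))) stop("connectivity matrices differ in dimension")
    m[pairs]
  }, numeric(nrow(pairs))))
  list(x = x, pairs = pairs, n_channels = n,
       labels = rownames(as.matrix(matrices[[1L]])) %||% paste0("ch", seq_len(n)))
}

# Tie-corrected Mann-Whitney normal-approximation machinery shared by
# edge_z_matrix and the permutation loop. Ranks and the tie-corrected sd are
# invariant under group relabelling, so they are computed once.
mw_edge_setup <- function(x, n1, n2) {
  N <- n1 + n2
  ranks <- apply(x, 2L, rank)
  if (is.null(dim(ranks))) dim(ranks) <- c(N, ncol(x))
  tie_term <- apply(x, 2L, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  sd_u <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1))))
  list(ranks = ranks, sd_u = sd_u, mu_u = n1 * n2 / 2, n1 = n1, n2 = n2)
}

mw_z_from_ranksum <- function(ranksum_a, setup) {
  u <- ranksum_a - setup$n1 * (setup$n1 + 1) / 2
  z <- (u - setup$mu_u) / setup$sd_u
  z[setup$sd_u == 0] <- 0   # all-tied edge: conservative Z = 0
  z
}

#' Edge-wise Mann-Whitney Z matrix between two groups
#'
#' For every channel pair, ranks the pooled per-subject connectivity values
#' and converts the Mann-Whitney U of group A into a Z score by the
#' tie-corrected normal approximation, oriented so that positive Z means
#' group A stochastically larger. Edges where all subjects tie get Z = 0.
#'
#' @param group_a,group_b lists of `connectivity_matrix` objects (one per
#'   subject), at least 2 subjects per group, equal dimensions.
#' @param tail orientation: `"greater"` (default) leaves the sign as
#'   A-larger-positive, `"less"` flips it; `"two.sided"` leaves it unchanged
#'   (thresholding then uses |Z|).
#' @return Symmetric channels x channels Z matrix, diagonal `NA`.
#' @export
edge_z_matrix <- function(group_a, group_b, tail = "greater") {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least 2 subjects per group")
  }
  st <- stack_edges(c(group_a, group_b))
  if (anyNA(st$x)) {
    stop("undefined connectivity entries: drop those edges or subjects first")
  }
  setup <- mw_edge_setup(st$x, length(group_a), length(group_b))
  z <- mw_z_from_ranksum(colSums(setup$ranks[seq_along(group_a), , drop = FALSE]),
                         setup)
  if (tail == "less") z <- -z
  m <- matrix(NA_real_, st$n_channels, st$n_channels,
              dimnames = list(st$labels, st$labels))
  m[st$pairs] <- z
  m[st$pairs[, c(2L, 1L), drop = FALSE]] <- z
  m
}

#' Supra-threshold connected components of a Z matrix
#'
#' Thresholds the edge statistics (strictly greater than `threshold`; for a
#' two-sided test pass `abs(z)`) and returns the connected components of the
#' resulting graph, channels as nodes, sorted by extent (edge count)
#' descending.
#'
#' @param z symmetric numeric matrix of edge statistics (diagonal ignored).
#' @param threshold finite edge-level threshold.
#' @return A list of components; each has `edges` (2-column index matrix),
#'   `nodes`, `extent` (edge count) and `intensity` (sum of supra-threshold
#'   statistics).
#' @export
supra_components <- function(z, threshold) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  z <- as.matrix(z)
  pairs <- lower_pairs(nrow(z))
  v <- z[pairs]
  keep <- !is.na(v) & v > threshold
  if (!any(keep)) return(list())
  ep <- pairs[keep, , drop = FALSE]
  ev <- v[keep]
  ids <- edge_component_ids(ep[, 1L], ep[, 2L])
  comps <- lapply(unique(ids), function(id) {
    e <- ep[ids == id, , drop = FALSE]
    dimnames(e) <- list(NULL, c("i", "j"))
    list(edges = e, nodes = sort(unique(c(e))), extent = nrow(e),
         intensity = sum(ev[ids == id]))
  })
  comps[order(vapply(comps, `[[`, numeric(1L), "extent"), decreasing = TRUE)]
}

#' Network-Based Statistics permutation test
#'
#' Tests for a connected subnetwork of edges on which `group_a` differs from
#' `group_b`. Edge statistics are tie-corrected Mann-Whitney Z scores; edges
#' with Z above `z_threshold` form the supra-threshold graph, whose connected
#' components are scored by extent (or intensity). Group labels are shuffled
#' `n_permutations` times to build the null distribution of the maximum
#' component statistic, and each observed component gets
#' `p = (1 + #{permutation max >= observed}) / (1 + n_permutations)`, which
#' controls the family-wise error over edges. When the number of distinct
#' label assignments does not exceed `n_permutations`, the null is enumerated
#' exhaustively (with a warning).
#'
#' @inheritParams edge_z_matrix
#' @param cfg an [nbs_config()].
#' @return An object of class `nbs_result`: the observed Z matrix, the
#'   component list with p-values, the permutation null of the maximum
#'   component statistic, and the configuration.
#' @export
nbs_test <- function(group_a, group_b, cfg = nbs_config()) {
  stopifnot(inherits(cfg, "nbs_config"))
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 1L || n2 < 1L || n1 + n2 < 3L) {
    stop("need non-empty groups with at least 3 subjects combined")
  }
  st <- stack_edges(c(group_a, group_b))
  x <- st$x
  pairs <- st$pairs
  edge_ok <- !apply(is.na(x), 2L, any)
  if (!all(edge_ok)) {
    warning(sum(!edge_ok), " edge(s) with undefined connectivity dropped from NBS")
    x <- x[, edge_ok, drop = FALSE]
    pairs <- pairs[edge_ok, , drop = FALSE]
  }
  setup <- mw_edge_setup(x, n1, n2)
  two_sided <- cfg$tail == "two.sided"
  edge_stat <- function(rows_a) {
    z <- mw_z_from_ranksum(colSums(setup$ranks[rows_a, , drop = FALSE]), setup)
    if (cfg$tail == "less") z <- -z
    if (two_sided) abs(z) else z
  }
  comp_stat <- function(z) {
    keep <- z > cfg$z_threshold
    m <- sum(keep)
    if (m == 0L) return(0)
    if (cfg$statistic == "extent") {
      if (m == 1L) 1 else {
        ids <- edge_component_ids(pairs[keep, 1L], pairs[keep, 2L])
        max(tabulate(ids))
      }
    } else {
      if (m == 1L) z[keep] else {
        ids <- edge_component_ids(pairs[keep, 1L], pairs[keep, 2L])
        max(tapply(z[keep], ids, sum))
      }
    }
  }

  z_obs <- edge_stat(seq_len(n1))
  zmat <- matrix(NA_real_, st$n_channels, st$n_channels,
                 dimnames = list(st$labels, st$labels))
  zmat[pairs] <- z_obs
  zmat[pairs[, c(2L, 1L), drop = FALSE]] <- z_obs
  comps <- supra_components(zmat, cfg$z_threshold)

  N <- n1 + n2
  null_max <- with_seed(cfg$seed, {
    n_distinct <- choose(N, n1)
    if (n_distinct <= cfg$n_permutations) {
      warning("n_permutations (", cfg$n_permutations, ") >= distinct label ",
              "assignments (", n_distinct, "); enumerating exhaustively")
      assigns <- utils::combn(N, n1, simplify = FALSE)
      vapply(assigns, function(rows) comp_stat(edge_stat(rows)), numeric(1L))
    } else {
      vapply(seq_len(cfg$n_permutations), function(p) {
        comp_stat(edge_stat(sample.int(N, n1)))
      }, numeric(1L))
    }
  })
  n_null <- length(null_max)
  for (k in seq_along(comps)) {
    obs <- if (cfg$statistic == "extent") comps[[k]]$extent else comps[[k]]$intensity
    comps[[k]]$statistic <- obs
    comps[[k]]$p <- (1 + sum(null_max >= obs)) / (1 + n_null)
  }
  structure(
    list(z = zmat, components = comps, null_max = null_max,
         config = cfg, n_a = n1, n_b = n2, labels = st$labels),
    class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Network-Based Statistics (Mann-Whitney edges, %s tail)\n", cfg$tail))
  cat(sprintf("  groups: %d vs %d subjects; Z threshold %.2f; %d permutation(s)\n",
              x$n_a, x$n_b, cfg$z_threshold, length(x$null_max)))
  sig <- Filter(function(cc) cc$p < cfg$alpha, x$components)
  if (length(sig) == 0L) {
    # the conventional NBS report: nothing printed unless p < alpha
    cat(sprintf("  no component significant at alpha = %g (%d supra-threshold component(s))\n",
                cfg$alpha, length(x$components)))
  } else {
    for (cc in sig) {
      cat(sprintf("  component: %d edge(s), %d node(s), %s = %.3g, p = %.4g\n",
                  cc$extent, length(cc$nodes), cfg$statistic, cc$statistic, cc$p))
    }
  }
  invisible(x)
}

#' Summarise an NBS result as a data frame
#' @param object an `nbs_result`.
#' @param ... unused.
#' @return Data frame with one row per supra-threshold component.
#' @export
summary.nbs_result <- function(object, ...) {
  if (length(object$components) == 0L) {
    return(data.frame(extent = integer(0), intensity = numeric(0),
                      n_nodes = integer(0), p = numeric(0)))
  }
  data.frame(
    extent = vapply(object$components, `[[`, numeric(1L), "extent"),
    intensity = vapply(object$components, `[[`, numeric(1L), "intensity"),
    n_nodes = vapply(object$components, function(cc) length(cc$nodes), integer(1L)),
    p = vapply(object$components, `[[`, numeric(1L), "p"))
}
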