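#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
# seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Index pairs (i, j), i > j, of the strictly lower triangle in column order;
# the canonical edge enumeration used throughout the package.
lower_pairs <- function(n) {
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

# Connected components of an edge list by union-find with path halving.
# `a`, `b`: integer endpoint vectors. Returns an integer component id per edge.
edge_component_ids <- function(a, b) {
  m <- length(a)
  if (m == 0L) return(integer(0))
  nodes <- sort(unique(c(a, b)))
  ai <- match(a, nodes)
  bi <- match(b, nodes)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(m)) {
    ra <- find(ai[k]); rb <- find(bi[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(ai, find, integer(1L))
  match(roots, unique(roots))
}

# Largest component size (number of edges) of an edge list; fast path for the
# permutation loop where only the maximum matters.
max_component_extent <- function(a, b) {
  m <- length(a)
  if (m <= 1L) return(m)
  ids <- edge_component_ids(a, b)
  max(tabulate(ids))
}
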