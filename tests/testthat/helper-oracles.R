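# Independent test oracles and shared fixtures.
#
# The d-separation oracle below is deliberately naive and self-contained:
# it enumerates every simple path between the two endpoints and applies the
# chain/fork/collider blocking rules triple by triple, with its own
# descendant computation. It shares no code with the package's
# reachability-based implementation.

oracle_descendants <- function(edges, v) {
  out <- character(0)
  frontier <- v
  while (length(frontier) > 0L) {
    nxt <- unique(edges[edges[, 1L] %in% frontier, 2L])
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  setdiff(out, v)
}

oracle_d_separated <- function(nodes, edges, x, y, z) {
  nbrs <- lapply(stats::setNames(nodes, nodes), function(v)
    unique(c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L])))
  has_edge <- function(p, c) any(edges[, 1L] == p & edges[, 2L] == c)
  path_open <- function(path) {
    if (length(path) < 3L) return(TRUE)
    for (i in 2:(length(path) - 1L)) {
      mid <- path[i]
      collider <- has_edge(path[i - 1L], mid) && has_edge(path[i + 1L], mid)
      if (collider) {
        if (!any(c(mid, oracle_descendants(edges, mid)) %in% z))
          return(FALSE)
      } else if (mid %in% z) return(FALSE)
    }
    TRUE
  }
  found_open <- FALSE
  walk <- function(path) {
    if (found_open) return()
    v <- path[length(path)]
    if (v == y) {
      if (path_open(path)) found_open <<- TRUE
      return()
    }
    for (w in setdiff(nbrs[[v]], path)) walk(c(path, w))
  }
  walk(x)
  !found_open
}

# every labelled DAG on the given nodes: each unordered pair carries
# no edge / forward / backward; keep the acyclic ones
all_dags <- function(nodes) {
  pairs <- utils::combn(nodes, 2L)
  np <- ncol(pairs)
  choices <- expand.grid(rep(list(0:2), np))
  out <- list()
  for (r in seq_len(nrow(choices))) {
    edges <- matrix(character(0), ncol = 2L)
    for (j in seq_len(np)) {
      ch <- choices[r, j]
      if (ch == 1L) edges <- rbind(edges, pairs[, j])
      if (ch == 2L) edges <- rbind(edges, rev(pairs[, j]))
    }
    if (is_acyclic_edges(nodes, edges)) out[[length(out) + 1L]] <- edges
  }
  out
}

is_acyclic_edges <- function(nodes, edges) {
  remaining <- nodes
  e <- edges
  repeat {
    if (length(remaining) == 0L) return(TRUE)
    sinks <- remaining[!remaining %in% e[, 1L]]
    if (length(sinks) == 0L) return(FALSE)
    remaining <- setdiff(remaining, sinks)
    e <- e[!(e[, 1L] %in% sinks | e[, 2L] %in% sinks), , drop = FALSE]
  }
}

random_dag_edges <- function(nodes, p = 0.4) {
  # orient every selected pair along a random topological order: acyclic by
  # construction
  ord <- sample(nodes)
  pairs <- utils::combn(ord, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  t(pairs[, keep, drop = FALSE])
}

edges_to_dag_text <- function(edges, exposure, outcome, isolated = character(0)) {
  paste(c(sprintf("%s -> %s", edges[, 1L], edges[, 2L]), isolated,
          paste("exposure:", exposure), paste("outcome:", outcome)),
        collapse = "\n")
}

# published per-model summaries used as averaging fixtures (same numbers as
# the CSVs shipped in inst/extdata, constructed here in code)
fixture_aic_table <- function() {
  data.frame(
    set_id = rep(1:4, each = 2),
    contrast = rep(c("overweight", "obese"), 4),
    rr = c(1.38, 1.75, 1.27, 1.46, 1.38, 1.74, 1.29, 1.48),
    ci_lower = c(0.92, 1.23, 0.84, 1.04, 0.91, 1.22, 0.85, 1.05),
    ci_upper = c(2.09, 2.50, 1.92, 2.08, 2.09, 2.48, 1.95, 2.10),
    aic = rep(c(552.56, 552.74, 555.12, 556.43), each = 2),
    n = 517,
    stringsAsFactors = FALSE)
}

fixture_iv_table <- function() {
  data.frame(
    set_id = rep(1:4, each = 2),
    contrast = rep(c("overweight", "obese"), 4),
    rr = c(1.41, 1.86, 1.35, 1.48, 1.38, 1.74, 1.33, 1.43),
    ci_lower = c(0.93, 1.32, 0.92, 1.06, 0.91, 1.22, 0.89, 1.02),
    ci_upper = c(2.11, 2.62, 2.00, 2.06, 2.09, 2.48, 1.97, 2.01),
    n = rep(c(538, 588, 517, 556), each = 2),
    stringsAsFactors = FALSE)
}

fig1_text <- "A -> E; A -> B; B -> D; E -> D; exposure: E; outcome: D"
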