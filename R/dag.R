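#' Parse a causal diagram from an edge-list document
#'
#' Reads a plain-text description of a directed acyclic graph (DAG) with
#' designated exposure and outcome nodes. The format is one `parent -> child`
#' statement per line; `;` is accepted as an additional statement separator;
#' `#` starts a comment; `exposure: <node>` and `outcome: <node>` directives
#' designate the causal contrast of interest. A DAGitty-style `dag { ... }`
#' wrapper is tolerated and stripped. Isolated nodes may be declared by
#' writing the bare node label on its own line.
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines describing the DAG, or the path of a file containing them.
#' @return an object of class `causal_dag` with components `nodes`, `edges`
#'   (two-column character matrix, parent then child), `exposure`, `outcome`,
#'   and `graph` (the underlying [igraph][igraph::graph_from_edgelist]
#'   object).
#' @examples
#' dag <- causal_dag("A -> E; A -> B; B -> D; E -> D; exposure: E; outcome: D")
#' dag
#' @export
causal_dag <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 1L && !grepl("[\n;>]", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  # tolerate a dagitty-style wrapper: dag { ... }
  lines <- sub("^\\s*dag\\s*\\{", "", lines)
  lines <- sub("\\}\\s*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  edges <- matrix(character(0), ncol = 2L)
  nodes <- character(0)
  exposure <- NA_character_
  outcome <- NA_character_
  for (ln in lines) {
    if (grepl("^exposure\\s*:", ln, ignore.case = TRUE)) {
      exposure <- trimws(sub("^exposure\\s*:", "", ln, ignore.case = TRUE))
    } else if (grepl("^outcome\\s*:", ln, ignore.case = TRUE)) {
      outcome <- trimws(sub("^outcome\\s*:", "", ln, ignore.case = TRUE))
    } else if (grepl("->", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "->", fixed = TRUE)[[1L]])
      if (length(parts) < 2L || any(!nzchar(parts)) || any(grepl("\\s", parts)))
        stop("cannot parse edge statement: '", ln, "'", call. = FALSE)
      # chains like A -> B -> C expand to consecutive edges
      for (i in seq_len(length(parts) - 1L))
        edges <- rbind(edges, c(parts[i], parts[i + 1L]))
    } else {
      if (grepl("\\s", ln))
        stop("cannot parse statement: '", ln, "'", call. = FALSE)
      nodes <- c(nodes, ln)  # isolated node declaration
    }
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  if (length(nodes) == 0L) stop("DAG document declares no nodes", call. = FALSE)
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loop on node '", edges[edges[, 1L] == edges[, 2L], 1L][1L], "'",
         call. = FALSE)
  edges <- unique(edges)

  if (is.na(exposure)) stop("missing 'exposure:' directive", call. = FALSE)
  if (is.na(outcome)) stop("missing 'outcome:' directive", call. = FALSE)
  if (!exposure %in% nodes)
    stop("exposure node '", exposure, "' is not in the graph", call. = FALSE)
  if (!outcome %in% nodes)
    stop("outcome node '", outcome, "' is not in the graph", call. = FALSE)
  if (exposure == outcome)
    stop("exposure and outcome must be distinct nodes", call. = FALSE)

  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(nodes)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  if (!igraph::is_dag(g)) {
    cyc <- find_cycle(nodes, edges)
    stop("graph contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }

  structure(
    list(nodes = nodes, edges = edges, exposure = exposure,
         outcome = outcome, graph = g),
    class = "causal_dag"
  )
}

# locate one directed cycle by DFS (for the error message only)
find_cycle <- function(nodes, edges) {
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  path <- character(0)
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (state[[w]] == 1L) {
        i <- match(w, path)
        result <<- c(path[i:length(path)], w)
        return()
      }
      if (state[[w]] == 0L) visit(w)
      if (!is.null(result)) return()
    }
    state[[v]] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in nodes) if (state[[v]] == 0L) visit(v)
  result
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("Causal DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  exposure:", x$exposure, "  outcome:", x$outcome, "\n")
  if (nrow(x$edges) > 0L)
    cat("  edges:", paste(x$edges[, 1L], "->", x$edges[, 2L], collapse = "; "),
        "\n")
  invisible(x)
}

check_nodes <- function(dag, v, what = "node") {
  bad <- setdiff(v, dag$nodes)
  if (length(bad) > 0L)
    stop("unknown ", what, ": ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(v)
}

# descendants of v (excluding v itself)
dag_descendants <- function(dag, v) {
  out <- igraph::subcomponent(dag$graph, v, mode = "out")
  setdiff(igraph::V(dag$graph)$name[out], v)
}

#' Test d-separation between two nodes
#'
#' Determines whether every path between `x` and `y` is blocked given the
#' conditioning set `z`, under the standard rules: a chain or fork is blocked
#' when its middle node is in `z`; a collider is blocked unless the collider
#' or one of its descendants is in `z`. Implemented as a reachability search
#' over (node, incoming-direction) states (the "Bayes-ball" formulation),
#' which is linear in the graph size per query.
#'
#' @param dag a [causal_dag] object.
#' @param x,y node labels.
#' @param z character vector of conditioning node labels (default empty).
#' @return logical: `TRUE` if `x` and `y` are d-separated given `z`.
#' @examples
#' dag <- causal_dag("A -> E; A -> B; B -> D; exposure: E; outcome: D")
#' d_separated(dag, "E", "D", "A")  # fork at A blocks E <- A -> B -> D
#' @export
d_separated <- function(dag, x, y, z = character(0)) {
  stopifnot(inherits(dag, "causal_dag"))
  z <- as.character(z)
  check_nodes(dag, c(x, y, z))
  if (x %in% z || y %in% z)
    stop("conditioning set must exclude the endpoint nodes", call. = FALSE)
  if (x == y) return(FALSE)

  nodes <- dag$nodes
  parents <- split(dag$edges[, 1L], factor(dag$edges[, 2L], levels = nodes))
  children <- split(dag$edges[, 2L], factor(dag$edges[, 1L], levels = nodes))
  in_z <- nodes %in% z
  names(in_z) <- nodes
  # ancestors of z (incl. z): needed for the collider rule
  anc_z <- z
  if (length(z) > 0L) {
    for (v in z) {
      idx <- igraph::subcomponent(dag$graph, v, mode = "in")
      anc_z <- union(anc_z, igraph::V(dag$graph)$name[idx])
    }
  }
  is_anc_z <- stats::setNames(nodes %in% anc_z, nodes)

  # states: (node, dir) where dir "up" = reached from a child (edge into the
  # visit points up the arrow), "down" = reached from a parent
  visited_up <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  visited_down <- visited_up
  queue <- list(list(x, "up"))  # start as if entered from below
  while (length(queue) > 0L) {
    item <- queue[[1L]]; queue <- queue[-1L]
    v <- item[[1L]]; dir <- item[[2L]]
    if (dir == "up") {
      if (visited_up[[v]]) next
      visited_up[[v]] <- TRUE
    } else {
      if (visited_down[[v]]) next
      visited_down[[v]] <- TRUE
    }
    if (v == y && v != x) return(FALSE)
    if (dir == "up") {
      if (!in_z[[v]]) {
        for (p in parents[[v]]) queue <- c(queue, list(list(p, "up")))
        for (ch in children[[v]]) queue <- c(queue, list(list(ch, "down")))
      }
    } else {
      if (!in_z[[v]]) {
        for (ch in children[[v]]) queue <- c(queue, list(list(ch, "down")))
      }
      if (is_anc_z[[v]]) {  # collider open: bounce back up the arrows
        for (p in parents[[v]]) queue <- c(queue, list(list(p, "up")))
      }
    }
  }
  TRUE
}

#' Test whether a covariate set satisfies the backdoor criterion
#'
#' A candidate set is sufficient for estimating the total causal effect of
#' the exposure on the outcome when it contains no descendant of the
#' exposure and blocks every backdoor path (paths beginning with an edge
#' into the exposure). Blocking is tested by d-separation of exposure and
#' outcome in the graph with all edges out of the exposure removed.
#'
#' @param dag a [causal_dag] object.
#' @param candidate character vector of covariate labels (may be empty).
#' @return logical.
#' @examples
#' dag <- causal_dag("A -> E; A -> B; B -> D; E -> D; exposure: E; outcome: D")
#' is_sufficient(dag, "A")
#' is_sufficient(dag, character(0))
#' @export
is_sufficient <- function(dag, candidate) {
  stopifnot(inherits(dag, "causal_dag"))
  candidate <- as.character(candidate)
  check_nodes(dag, candidate, "covariate")
  if (dag$exposure %in% candidate || dag$outcome %in% candidate)
    stop("candidate set must exclude exposure and outcome", call. = FALSE)
  if (any(candidate %in% dag_descendants(dag, dag$exposure))) return(FALSE)
  bd <- backdoor_dag(dag)
  d_separated(bd, dag$exposure, dag$outcome, candidate)
}

# the "backdoor graph": dag with edges out of the exposure deleted
backdoor_dag <- function(dag) {
  keep <- dag$edges[, 1L] != dag$exposure
  edges <- dag$edges[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(dag$nodes)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  structure(
    list(nodes = dag$nodes, edges = edges, exposure = dag$exposure,
         outcome = dag$outcome, graph = g),
    class = "causal_dag"
  )
}

#' Enumerate sufficient (or minimally sufficient) adjustment sets
#'
#' Searches all subsets of the eligible covariates — every node other than
#' the exposure, the outcome, and descendants of the exposure — and returns
#' those satisfying the backdoor criterion. A sufficient set is *minimal*
#' when no proper subset of it is sufficient. Output is ordered by set size,
#' then lexicographically by members, so set numbering is reproducible.
#'
#' @param dag a [causal_dag] object.
#' @param minimal_only if `TRUE` (default), return only minimally sufficient
#'   sets.
#' @param max_covariates enumeration ceiling on the eligible-covariate count
#'   (subset search is exponential); default 20.
#' @return an object of class `adjustment_sets`: a list of
#'   `adjustment_set` objects, each with `members`, `sufficient`, `minimal`.
#' @examples
#' dag <- causal_dag("A -> E; A -> B; B -> D; E -> D; exposure: E; outcome: D")
#' adjustment_sets(dag, minimal_only = FALSE)
#' @export
adjustment_sets <- function(dag, minimal_only = TRUE, max_covariates = 20L) {
  stopifnot(inherits(dag, "causal_dag"))
  eligible <- setdiff(dag$nodes, c(dag$exposure, dag$outcome,
                                   dag_descendants(dag, dag$exposure)))
  eligible <- sort(eligible)
  if (length(eligible) > max_covariates)
    stop(length(eligible), " eligible covariates exceed the enumeration ",
         "ceiling (", max_covariates, "); restrict the graph or raise ",
         "'max_covariates'", call. = FALSE)

  subsets <- list(character(0))
  if (length(eligible) > 0L) {
    subsets <- unlist(lapply(0:length(eligible), function(k) {
      if (k == 0L) return(list(character(0)))
      m <- utils::combn(eligible, k, simplify = FALSE)
      # combn on sorted input already yields lexicographic order within size
      m
    }), recursive = FALSE)
  }
  suff <- Filter(function(s) is_sufficient(dag, s), subsets)
  is_min <- vapply(seq_along(suff), function(i) {
    s <- suff[[i]]
    !any(vapply(suff, function(t)
      length(t) < length(s) && all(t %in% s), logical(1)))
  }, logical(1))

  sets <- lapply(seq_along(suff), function(i) {
    structure(list(members = suff[[i]], sufficient = TRUE,
                   minimal = is_min[i]),
              class = "adjustment_set")
  })
  if (minimal_only) sets <- sets[is_min]
  structure(sets, class = "adjustment_sets",
            exposure = dag$exposure, outcome = dag$outcome)
}

#' @export
print.adjustment_set <- function(x, ...) {
  lab <- if (length(x$members) == 0L) "{ }" else
    paste0("{", paste(x$members, collapse = ", "), "}")
  cat(lab, if (x$minimal) "(minimally sufficient)" else "(sufficient)", "\n")
  invisible(x)
}

#' @export
print.adjustment_sets <- function(x, ...) {
  cat(length(x), "adjustment set(s) for", attr(x, "exposure"), "->",
      attr(x, "outcome"), "\n")
  for (i in seq_along(x)) {
    cat(sprintf("  %d: ", i))
    print(x[[i]])
  }
  invisible(x)
}

# all simple undirected paths between a and b, as node sequences
all_undirected_paths <- function(dag, a, b) {
  nbrs <- lapply(stats::setNames(dag$nodes, dag$nodes), function(v)
    unique(c(dag$edges[dag$edges[, 1L] == v, 2L],
             dag$edges[dag$edges[, 2L] == v, 1L])))
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == b) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (w in setdiff(nbrs[[v]], path)) walk(c(path, w))
  }
  walk(a)
  paths
}

# is a specific path blocked given z, applying the chain/fork/collider
# rules triple by triple (diagnostic companion to d_separated)
path_blocked <- function(dag, path, z) {
  if (length(path) < 3L) return(FALSE)
  has_edge <- function(p, c)
    any(dag$edges[, 1L] == p & dag$edges[, 2L] == c)
  for (i in 2:(length(path) - 1L)) {
    mid <- path[i]
    into_left <- has_edge(path[i - 1L], mid)
    into_right <- has_edge(path[i + 1L], mid)
    collider <- into_left && into_right
    if (collider) {
      open_set <- c(mid, dag_descendants(dag, mid))
      if (!any(open_set %in% z)) return(TRUE)
    } else {
      if (mid %in% z) return(TRUE)
    }
  }
  FALSE
}
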