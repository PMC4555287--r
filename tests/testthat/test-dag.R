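test_that("edge-list parsing is order-insensitive and validates structure", {
  dag <- causal_dag(fig1_text)
  expect_s3_class(dag, "causal_dag")
  expect_equal(sort(dag$nodes), c("A", "B", "D", "E"))
  expect_equal(nrow(dag$edges), 4L)
  expect_equal(dag$exposure, "E")
  expect_equal(dag$outcome, "D")

  # shuffled lines, extra whitespace, comments: same graph
  dag2 <- causal_dag(c("  outcome: D ", "B->D  # to outcome", "E -> D",
                       "A->B", "", "A ->E", "exposure:E"))
  expect_equal(dag2$edges[order(dag2$edges[, 1], dag2$edges[, 2]), ],
               dag$edges[order(dag$edges[, 1], dag$edges[, 2]), ])

  minimal <- causal_dag("E->D; exposure:E; outcome:D")
  expect_equal(length(minimal$nodes), 2L)
  expect_equal(nrow(minimal$edges), 1L)

  expect_error(causal_dag("E->D; D->E; exposure:E; outcome:D"), "cycle")
  expect_error(causal_dag("E->D; outcome:D"), "exposure")
  expect_error(causal_dag("E->D; exposure:E"), "outcome")
  expect_error(causal_dag("E->D; exposure:X; outcome:D"), "not in the graph")
  expect_error(causal_dag("E->E; exposure:E; outcome:E"), "self-loop")
})

test_that("parsing reads files and dagitty-style blocks", {
  path <- withr::local_tempfile(fileext = ".dag")
  writeLines(c("dag {", "A -> E", "A -> B", "B -> D", "E -> D", "}",
               "exposure: E", "outcome: D"), path)
  dag <- causal_dag(path)
  expect_equal(nrow(dag$edges), 4L)
})

test_that("d-separation handles chains, forks, colliders and descendants", {
  dag <- causal_dag(fig1_text)
  expect_false(d_separated(dag, "E", "D"))            # direct edge
  expect_false(d_separated(dag, "E", "D", c("A", "B")))

  nobd <- causal_dag("A->E; A->B; B->D; exposure:E; outcome:D")
  expect_false(d_separated(nobd, "E", "D"))
  expect_true(d_separated(nobd, "E", "D", "A"))
  expect_true(d_separated(nobd, "E", "D", "B"))

  coll <- causal_dag("E->C; D->C; exposure:E; outcome:D")
  expect_true(d_separated(coll, "E", "D"))
  expect_false(d_separated(coll, "E", "D", "C"))
  # conditioning on a collider's descendant also opens the path
  coll2 <- causal_dag("E->C; D->C; C->F; exposure:E; outcome:D")
  expect_true(d_separated(coll2, "E", "D"))
  expect_false(d_separated(coll2, "E", "D", "F"))

  expect_error(d_separated(dag, "E", "Q"), "unknown")
  expect_error(d_separated(dag, "E", "D", "E"), "exclude")
})

test_that("d-separation agrees with the brute-force path oracle on all 4-node DAGs", {
  nodes <- c("W", "X", "Y", "Z")
  dags <- all_dags(nodes)
  expect_gt(length(dags), 500)  # 543 labelled DAGs on 4 nodes
  zsets <- function(rest) c(list(character(0)),
                            lapply(seq_along(rest), function(k)
                              utils::combn(rest, k, simplify = FALSE)) |>
                              unlist(recursive = FALSE))
  n_checked <- 0L
  for (edges in dags) {
    dag <- causal_dag(edges_to_dag_text(edges, "W", "Z",
                                        isolated = nodes))
    for (pair in list(c("W", "X"), c("W", "Z"), c("X", "Y"))) {
      rest <- setdiff(nodes, pair)
      for (z in zsets(rest)) {
        got <- d_separated(dag, pair[1], pair[2], z)
        want <- oracle_d_separated(nodes, edges, pair[1], pair[2], z)
        if (got != want) {
          fail(sprintf("disagreement on %s _||_ %s | {%s} in %s",
                       pair[1], pair[2], paste(z, collapse = ","),
                       edges_to_dag_text(edges, "W", "Z")))
        }
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 6000)
  succeed()
})

test_that("d-separation agrees with the oracle on random DAGs up to 8 nodes", {
  set.seed(20240915)
  for (rep in 1:200) {
    nn <- sample(4:8, 1)
    nodes <- LETTERS[1:nn]
    edges <- random_dag_edges(nodes, p = 0.45)
    if (nrow(edges) == 0L) edges <- matrix(c("A", "B"), ncol = 2)
    dag <- causal_dag(edges_to_dag_text(edges, "A", "B", isolated = nodes))
    for (q in 1:5) {
      pair <- sample(nodes, 2)
      rest <- setdiff(nodes, pair)
      z <- rest[stats::runif(length(rest)) < 0.4]
      expect_equal(d_separated(dag, pair[1], pair[2], z),
                   oracle_d_separated(nodes, edges, pair[1], pair[2], z))
    }
  }
})

test_that("backdoor sufficiency matches the two-confounder worked example", {
  dag <- causal_dag(fig1_text)
  expect_true(is_sufficient(dag, "A"))
  expect_true(is_sufficient(dag, "B"))
  expect_true(is_sufficient(dag, c("A", "B")))
  expect_false(is_sufficient(dag, character(0)))
  expect_error(is_sufficient(dag, "E"), "exclude")

  # descendants of the exposure never qualify
  med <- causal_dag("A->E; A->D; E->M; M->D; exposure:E; outcome:D")
  expect_false(is_sufficient(med, c("A", "M")))
  expect_true(is_sufficient(med, "A"))
})

test_that("enumeration returns sorted sufficient and minimal sets", {
  dag <- causal_dag(fig1_text)
  all_sets <- adjustment_sets(dag, minimal_only = FALSE)
  expect_length(all_sets, 3L)
  expect_equal(lapply(all_sets, `[[`, "members"),
               list("A", "B", c("A", "B")))
  expect_true(all(vapply(all_sets, `[[`, logical(1), "sufficient")))
  expect_equal(vapply(all_sets, `[[`, logical(1), "minimal"),
               c(TRUE, TRUE, FALSE))

  min_sets <- adjustment_sets(dag, minimal_only = TRUE)
  expect_equal(lapply(min_sets, `[[`, "members"), list("A", "B"))

  triv <- adjustment_sets(causal_dag("E->D; exposure:E; outcome:D"))
  expect_length(triv, 1L)
  expect_length(triv[[1]]$members, 0L)

  big <- causal_dag(paste(c(sprintf("C%d -> E; C%d -> D", 1:25, 1:25),
                            "E -> D", "exposure: E", "outcome: D"),
                          collapse = "; "))
  expect_error(adjustment_sets(big), "ceiling")
})

test_that("every enumerated set passes the backdoor test and minimality is definitional", {
  set.seed(7)
  for (rep in 1:25) {
    nodes <- LETTERS[1:sample(4:7, 1)]
    edges <- random_dag_edges(nodes, p = 0.45)
    ends <- sample(nodes, 2)
    dag <- causal_dag(edges_to_dag_text(edges, ends[1], ends[2],
                                        isolated = nodes))
    sets <- tryCatch(adjustment_sets(dag, minimal_only = FALSE),
                     error = function(e) NULL)
    if (is.null(sets)) next
    for (s in sets) {
      expect_true(is_sufficient(dag, s$members))
      if (s$minimal && length(s$members) > 0L) {
        for (drop in s$members)
          expect_false(is_sufficient(dag, setdiff(s$members, drop)))
      }
    }
  }
})

test_that("enumeration order is deterministic across runs", {
  text <- "A->E; A->B; B->D; E->D; C->E; C->D; exposure:E; outcome:D"
  s1 <- adjustment_sets(causal_dag(text), minimal_only = FALSE)
  s2 <- adjustment_sets(causal_dag(text), minimal_only = FALSE)
  expect_identical(lapply(s1, `[[`, "members"), lapply(s2, `[[`, "members"))
  sizes <- vapply(s1, function(s) length(s$members), integer(1))
  expect_true(all(diff(sizes) >= 0))  # sorted by size
})
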