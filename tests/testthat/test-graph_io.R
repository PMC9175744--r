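test_that("signed edge lists parse with signs, defaults and comments", {
  f <- withr::local_tempfile(lines = c("# a comment", "A\tB\t+1",
                                       "B C -1", "C D"))
  g <- read_signed_edgelist(f, directed = TRUE)
  expect_setequal(g$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(g$edges), 3)
  expect_equal(g$edges$sign[g$edges$from == "B"], -1L)
  expect_equal(g$edges$sign[g$edges$from == "C"], 1L)  # missing sign -> +1
  expect_equal(g$edges$sign[g$edges$from == "A"], 1L)

  w <- withr::local_tempfile(lines = c("A B activate", "B C inhibit"))
  g2 <- read_signed_edgelist(w)
  expect_equal(sort(g2$edges$sign), c(-1L, 1L))
})

test_that("parser rejects malformed input with a line number", {
  f <- withr::local_tempfile(lines = c("A B", "justone"))
  expect_error(read_signed_edgelist(f), "line 2",
               class = "signetpharm_parse_error")

  f2 <- withr::local_tempfile(lines = c("A B maybe"))
  expect_error(read_signed_edgelist(f2), "maybe",
               class = "signetpharm_value_error")

  f3 <- withr::local_tempfile(lines = c("A B", "A B"))
  expect_error(read_signed_edgelist(f3), "duplicate",
               class = "signetpharm_parse_error")

  # same unordered pair twice is a duplicate in the undirected dialect
  f4 <- withr::local_tempfile(lines = c("A B", "B A"))
  expect_error(read_signed_edgelist(f4, directed = FALSE), "duplicate",
               class = "signetpharm_parse_error")
  expect_silent(g <- read_signed_edgelist(f4, directed = TRUE))
})

test_that("write/read round-trips graphs exactly, deterministically", {
  withr::local_seed(11)
  e <- random_signed_edges(10, p_edge = 0.5)
  e <- e[seq_len(min(50, nrow(e))), ]
  g <- signed_graph(e, nodes = c(LETTERS[1:10], "ISOLATED"))
  f <- withr::local_tempfile()
  write_signed_edgelist(g, f)
  g2 <- read_signed_edgelist(f, directed = TRUE)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$nodes, g$nodes)  # isolated node preserved via header

  # byte-identical across two writes
  f2 <- withr::local_tempfile()
  write_signed_edgelist(g, f2)
  expect_identical(readLines(f), readLines(f2))

  # degenerate: no edges, only isolated nodes
  g0 <- signed_graph(data.frame(from = character(), to = character()),
                     nodes = c("X", "Y"))
  f3 <- withr::local_tempfile()
  write_signed_edgelist(g0, f3)
  g0b <- read_signed_edgelist(f3)
  expect_equal(g0b$nodes, c("X", "Y"))
  expect_equal(nrow(g0b$edges), 0)
})

test_that("graph invariants are enforced at construction", {
  expect_error(signed_graph(data.frame(from = "A", to = "A")),
               "self-loop", class = "signetpharm_value_error")
  expect_error(signed_graph(data.frame(from = "A", to = "B", sign = 2)),
               class = "signetpharm_value_error")
  expect_error(
    signed_graph(data.frame(from = c("A", "B"), to = c("B", "A")),
                 directed = FALSE),
    "duplicate", class = "signetpharm_value_error")
  expect_error(
    signed_graph(data.frame(from = "A", to = "B", sign = -1),
                 directed = FALSE),
    "unsigned", class = "signetpharm_value_error")
})

test_that("GMT parsing collapses duplicates and keeps cardinalities", {
  f <- withr::local_tempfile(lines = c(
    "IS\tdesc\tA\tB\tB",
    "UP\tdesc\tC",
    "DOWN\tdesc\tD\tE\tF\tA"))
  sets <- read_gmt(f)
  expect_named(sets, c("IS", "UP", "DOWN"))
  expect_setequal(sets$IS, c("A", "B"))
  expect_equal(lengths(sets), c(IS = 2L, UP = 1L, DOWN = 4L))

  empty <- withr::local_tempfile(lines = character())
  expect_length(read_gmt(empty), 0)

  bad <- withr::local_tempfile(lines = "name_only\tdesc")
  expect_error(read_gmt(bad), class = "signetpharm_parse_error")

  # round trip
  f2 <- withr::local_tempfile()
  write_gmt(sets, f2)
  expect_equal(read_gmt(f2), sets)
})

test_that("drug tables round-trip with signed, unsigned and empty targets", {
  drugs <- tibble::tibble(
    drug_id = c("d1", "d2", "d3"),
    smiles = c("CCO", NA, "C"),
    targets = list(c(TP53 = -1L, EGFR = 1L),
                   stats::setNames(c(NA_integer_), "PTGS2"),
                   stats::setNames(integer(), character()))
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_drug_table(drugs, f)
  back <- read_drug_table(f)
  expect_equal(back$drug_id, drugs$drug_id)
  expect_equal(back$smiles, drugs$smiles)
  expect_equal(back$targets, drugs$targets)
})

test_that("giant strongly connected component matches definition and oracle", {
  g <- signed_graph(data.frame(from = c("A", "B", "C", "C"),
                               to = c("B", "C", "A", "D")))
  gsc <- giant_strongly_connected(g)
  expect_setequal(gsc$nodes, c("A", "B", "C"))
  expect_equal(nrow(gsc$edges), 3)

  # fully acyclic chain: all SCCs are singletons; smallest label wins
  chain <- signed_graph(data.frame(from = c("B", "C"), to = c("C", "D")),
                        nodes = c("B", "C", "D"))
  expect_equal(giant_strongly_connected(chain)$nodes, "B")

  expect_error(
    giant_strongly_connected(
      signed_graph(data.frame(from = character(), to = character()))),
    "empty", class = "signetpharm_value_error")

  # random graphs against the reachability oracle
  withr::local_seed(5)
  for (rep in 1:5) {
    e <- random_signed_edges(12, p_edge = 0.12)
    g <- signed_graph(e, nodes = LETTERS[1:12])
    comps <- oracle_scc(g$nodes, g$edges)
    sizes <- lengths(comps)
    biggest <- comps[sizes == max(sizes)]
    expected <- biggest[order(vapply(biggest, min, ""))][[1]]
    expect_setequal(giant_strongly_connected(g)$nodes, expected)
  }
})

test_that("GSC output is strongly connected (pairwise reachability)", {
  withr::local_seed(9)
  e <- random_signed_edges(15, p_edge = 0.15)
  g <- signed_graph(e, nodes = LETTERS[1:15])
  gsc <- giant_strongly_connected(g)
  comps <- oracle_scc(gsc$nodes, gsc$edges)
  expect_length(comps, 1)
})
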