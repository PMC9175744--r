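test_that("rwr fixed points match hand-solved small systems", {
  # isolated seed keeps all mass
  g1 <- signed_graph(data.frame(from = "B", to = "C"),
                     nodes = c("A", "B", "C"))
  v <- rwr(g1, "A", restart = 0.6)
  expect_equal(v$score[v$node == "A"], 1, tolerance = 1e-9)

  # chain A -> B with B dangling, c = 0.5: s = (2/3, 1/3)
  g2 <- signed_graph(data.frame(from = "A", to = "B"))
  v2 <- rwr(g2, "A", restart = 0.5)
  expect_equal(v2$score, c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(sum(v2$score), 1, tolerance = 1e-9)

  # mirror-image components with symmetric seeds score identically
  e <- data.frame(from = c("A1", "B1", "A2", "B2"),
                  to = c("B1", "C1", "B2", "C2"))
  gm <- signed_graph(e)
  vm <- rwr(gm, c("A1", "A2"), restart = 0.4)
  s <- stats::setNames(vm$score, vm$node)
  expect_equal(s[c("A1", "B1", "C1")], s[c("A2", "B2", "C2")],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("influence vectors are distributions and respect the c -> 1 limit", {
  withr::local_seed(3)
  for (rep in 1:5) {
    g <- signed_graph(random_signed_edges(8, p_edge = 0.3),
                      nodes = LETTERS[1:8])
    v <- rwr(g, c("A", "B"), restart = 0.75)
    expect_true(all(v$score >= 0))
    expect_equal(sum(v$score), 1, tolerance = 1e-8)
    # near-total restart returns the seed distribution
    v99 <- rwr(g, c("A", "B"), restart = 0.999)
    q <- ifelse(v99$node %in% c("A", "B"), 0.5, 0)
    expect_lt(sum(abs(v99$score - q)), 1e-2)
  }
})

test_that("rwr error handling: absent seeds and non-convergence", {
  g <- signed_graph(data.frame(from = "A", to = "B"))
  expect_message(rwr(g, c("A", "Z"), restart = 0.5), "dropped")
  expect_error(suppressMessages(rwr(g, "Z")),
               class = "signetpharm_value_error")
  expect_error(rwr(g, "A", restart = 0.01, tol = 1e-300, max_iter = 3),
               class = "signetpharm_convergence_error")
  expect_error(rwr(g, "A", restart = 0), class = "signetpharm_value_error")
})

test_that("srwr reduces to rwr on all-positive graphs", {
  withr::local_seed(7)
  e <- random_signed_edges(8, p_edge = 0.3)
  e$sign <- 1L
  g <- signed_graph(e, nodes = LETTERS[1:8])
  sc <- srwr(g, c(A = 1, B = 1), restart = 0.6)
  v <- rwr(g, c("A", "B"), restart = 0.6)
  expect_equal(sc$n, rep(0, 8))
  expect_equal(sc$p, v$score, tolerance = 1e-9)
})

test_that("srwr solves the signed chain and flips channels with seed sign", {
  g <- signed_graph(data.frame(from = "A", to = "B", sign = -1))
  sc <- srwr(g, c(A = 1), restart = 0.5)
  expect_equal(sc$p[sc$node == "A"], 2 / 3, tolerance = 1e-9)
  expect_equal(sc$n[sc$node == "B"], 1 / 3, tolerance = 1e-9)
  expect_equal(sc$r[sc$node == "B"], -1 / 3, tolerance = 1e-9)

  flipped <- srwr(g, c(A = -1), restart = 0.5)
  expect_equal(flipped$p, sc$n, tolerance = 1e-12)
  expect_equal(flipped$n, sc$p, tolerance = 1e-12)
  expect_equal(flipped$r, -sc$r, tolerance = 1e-12)
})

test_that("channel sum (p + n) equals the sign-blind rwr vector", {
  withr::local_seed(21)
  for (rep in 1:20) {
    g <- signed_graph(random_signed_edges(10, p_edge = 0.25, p_neg = 0.4),
                      nodes = LETTERS[1:10])
    seeds <- c(A = 1, D = -1)
    sc <- srwr(g, seeds, restart = 0.5)
    v <- rwr(g, names(seeds), restart = 0.5)
    expect_lt(max(abs(sc$p + sc$n - v$score)), 1e-8)
    expect_equal(sum(sc$p + sc$n), 1, tolerance = 1e-8)
    expect_true(all(sc$r >= -1 - 1e-12 & sc$r <= 1 + 1e-12))
  }
})

test_that("srwr matches the signed-walk enumeration oracle", {
  withr::local_seed(33)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    e <- random_signed_edges(n, p_edge = 0.5, p_neg = 0.4,
                             no_dangling = TRUE)
    g <- signed_graph(e, nodes = LETTERS[seq_len(n)])
    seeds <- stats::setNames(sample(c(-1, 1), 2, replace = TRUE),
                             sample(g$nodes, 2))
    for (c_ in c(0.3, 0.75)) {
      sc <- srwr(g, seeds, restart = c_, tol = 1e-14)
      orc <- oracle_srwr_walks(g$nodes, g$edges, seeds, c_)
      expect_lt(max(abs(sc$p - orc$p[sc$node])), 1e-6)
      expect_lt(max(abs(sc$n - orc$n[sc$node])), 1e-6)
    }
  }
})

test_that("top-fraction signed selection ranks, ties and partitions correctly", {
  sc <- tibble::tibble(node = c("A", "B", "C", "D"),
                       p = c(0, 0.4, 0, 0.05), n = c(0.5, 0, 0.1, 0),
                       r = c(-0.5, 0.4, -0.1, 0.05))
  class(sc) <- c("srwr_scores", class(sc))
  top <- select_top_signed(sc, 0.25, "inhibited")
  expect_equal(top$node, "A")
  expect_equal(select_top_signed(sc, 0.25, "activated")$node, character(0))

  # fraction 1: the stratum is everyone; direction filters by sign
  expect_setequal(select_top_signed(sc, 1, "inhibited")$node, c("A", "C"))
  expect_setequal(select_top_signed(sc, 1, "activated")$node, c("B", "D"))

  # tie exactly at the boundary: both tied nodes retained
  tie <- tibble::tibble(node = c("A", "B", "C", "D"),
                        p = c(0, 0, 0.3, 0.1), n = c(0.3, 0.3, 0, 0),
                        r = c(-0.3, -0.3, 0.3, 0.1))
  class(tie) <- c("srwr_scores", class(tie))
  kept <- select_top_signed(tie, 0.5, "inhibited")  # top 2 ranks, 3 tied
  expect_setequal(kept$node, c("A", "B"))
  expect_equal(nrow(select_top_signed(tie, 0.5, "activated")), 1)

  # inhibited and activated partition the nonzero members of the stratum
  withr::local_seed(2)
  g <- signed_graph(random_signed_edges(12, p_edge = 0.3, p_neg = 0.5),
                    nodes = LETTERS[1:12])
  sc2 <- srwr(g, c(A = 1, B = -1), restart = 0.5)
  inh <- select_top_signed(sc2, 0.4, "inhibited")$node
  act <- select_top_signed(sc2, 0.4, "activated")$node
  expect_length(intersect(inh, act), 0)
  cutoff <- sort(abs(sc2$r), decreasing = TRUE)[ceiling(0.4 * nrow(sc2))]
  stratum <- sc2$node[abs(sc2$r) >= cutoff & sc2$r != 0]
  expect_setequal(union(inh, act), stratum)

  zero <- tibble::tibble(node = "A", p = 0, n = 0, r = 0)
  class(zero) <- c("srwr_scores", class(zero))
  expect_warning(out <- select_top_signed(zero, 0.5), "zero")
  expect_equal(nrow(out), 0)
})

test_that("seeds with unknown sign propagate as activation with a warning", {
  g <- signed_graph(data.frame(from = "A", to = "B", sign = 1))
  expect_warning(sc <- srwr(g, stats::setNames(NA_integer_, "A"),
                            restart = 0.5), "unknown sign")
  expect_gt(sc$p[sc$node == "B"], 0)
  expect_equal(sum(sc$n), 0)
})
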