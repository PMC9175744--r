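test_that("fingerprint Tanimoto: identity, disjoint molecules, errors", {
  expect_equal(fingerprint_tanimoto("CCO", "CCO"), 1)
  # methane and water share no substructure bits
  expect_equal(fingerprint_tanimoto("C", "O"), 0)
  # ethanol and acetic acid share some but not all environments
  t <- fingerprint_tanimoto("CCO", "CC(=O)O")
  expect_gt(t, 0)
  expect_lt(t, 1)
  expect_error(fingerprint_tanimoto("not_a_smiles((", "C"),
               class = "signetpharm_parse_error")
  expect_error(fingerprint_tanimoto("", "C"),
               class = "signetpharm_parse_error")
})

test_that("fingerprints depend on radius and respect bit-length", {
  fp0 <- morgan_fingerprint("c1ccccc1CCO", radius = 0)
  fp2 <- morgan_fingerprint("c1ccccc1CCO", radius = 2)
  expect_length(fp2, 2048)
  expect_true(all(fp2 %in% c(0L, 1L)))
  expect_gt(sum(fp2), sum(fp0))  # larger radius adds environments
  expect_length(morgan_fingerprint("CCO", n_bits = 128), 128)
})

test_that("the two stereoisomeric salvianolic acids share a canonical SMILES", {
  comp <- safi_components()
  b <- comp$smiles[comp$component == "salvianolic_acid_B"]
  y <- comp$smiles[comp$component == "salvianolic_acid_Y"]
  expect_identical(b, y)
  expect_equal(fingerprint_tanimoto(b, y), 1)
})

test_that("structure similarity matrix is symmetric with unit diagonal", {
  comp <- safi_components()
  drugs <- tibble::tibble(drug_id = comp$component, smiles = comp$smiles)
  m <- structure_similarity_matrix(drugs)
  expect_equal(dim(m$sim), c(5, 5))
  expect_equal(m$sim, t(m$sim))
  expect_equal(diag(m$sim), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(m$sim >= 0 & m$sim <= 1))
  expect_equal(m$sim["salvianolic_acid_B", "salvianolic_acid_Y"], 1)

  # drugs without SMILES are excluded with a warning; < 2 usable errors
  drugs$smiles[2] <- NA
  expect_warning(m2 <- structure_similarity_matrix(drugs), "without SMILES")
  expect_equal(dim(m2$sim), c(4, 4))
  expect_error(
    suppressWarnings(structure_similarity_matrix(drugs[1:2, ])),
    class = "signetpharm_value_error")
})

path5 <- function() {
  signed_graph(data.frame(from = c("A", "B", "C", "D"),
                          to = c("B", "C", "D", "E")),
               directed = FALSE)
}

test_that("separation score on hand-solved modules", {
  # path A-B-C-D-E, singletons at the ends
  r <- sab_separation(path5(), "A", "E")
  expect_equal(r$d_ab, 4)
  expect_equal(r$d_aa, 0)
  expect_equal(r$d_bb, 0)
  expect_equal(r$s_ab, 4)

  # coincident singleton modules
  r2 <- sab_separation(path5(), "A", "A")
  expect_equal(r2$d_ab, 0)
  expect_equal(r2$s_ab, 0)

  # overlapping modules on a triangle: frozen from the enumeration oracle
  tri <- signed_graph(data.frame(from = c("A", "B", "A"),
                                 to = c("B", "C", "C")),
                      directed = FALSE)
  dmat <- oracle_distances(tri$nodes, tri$edges)
  orc <- oracle_sab(dmat, c("A", "B"), c("B", "C"))
  r3 <- sab_separation(tri, c("A", "B"), c("B", "C"))
  expect_equal(r3$d_ab, orc$d_ab)   # 0.5 by direct enumeration
  expect_equal(r3$s_ab, orc$s_ab)   # -0.5: negative marks overlap
  expect_lt(r3$s_ab, 0)

  expect_error(suppressMessages(sab_separation(path5(), "ZZ", "A")),
               class = "signetpharm_value_error")
})

test_that("separation is symmetric and self-separation non-positive (fuzzing)", {
  withr::local_seed(14)
  for (rep in 1:10) {
    e <- random_signed_edges(9, p_edge = 0.3)
    e$sign <- 1L
    e <- e[!duplicated(paste(pmin(e$from, e$to), pmax(e$from, e$to))), ]
    e[] <- list(from = pmin(e$from, e$to), to = pmax(e$from, e$to),
                sign = e$sign)
    g <- signed_graph(e, nodes = LETTERS[1:9], directed = FALSE)
    a <- sample(g$nodes, 3)
    b <- sample(g$nodes, 3)
    rab <- try(sab_separation(g, a, b), silent = TRUE)
    rba <- try(sab_separation(g, b, a), silent = TRUE)
    if (!inherits(rab, "try-error")) {
      expect_equal(rab$s_ab, rba$s_ab, tolerance = 1e-12)
      expect_lte(sab_separation(g, a, a)$s_ab, 0)
      # cross-check against the BFS oracle
      dmat <- oracle_distances(g$nodes, g$edges)
      expect_equal(rab$s_ab, oracle_sab(dmat, a, b)$s_ab,
                   tolerance = 1e-12)
    }
  }
})

test_that("PathSim reproduces exhaustive metapath enumeration", {
  # worked micro-example: c1 -> {t1}, c2 -> {t1, t2}, both targets on f1
  ts <- list(c1 = "t1", c2 = c("t1", "t2"))
  ann <- list(t1 = "f1", t2 = "f1")
  m <- pathsim_matrix(ts, ann)
  expect_equal(m$path_counts["c1", "c1"], 1)
  expect_equal(m$path_counts["c2", "c2"], 4)
  expect_equal(m$path_counts["c1", "c2"], 2)
  expect_equal(m$sim["c1", "c2"], 0.8)
  expect_equal(diag(m$sim), c(c1 = 1, c2 = 1))

  # disjoint function vocabularies score zero
  ts2 <- list(a = "t1", b = "t2")
  ann2 <- list(t1 = "f1", t2 = "f2")
  expect_equal(pathsim_matrix(ts2, ann2)$sim["a", "b"], 0)

  # random heterogeneous networks against the enumeration oracle
  withr::local_seed(27)
  for (rep in 1:6) {
    nc <- sample(2:8, 1)
    genes <- paste0("t", 1:6)
    terms <- paste0("f", 1:4)
    ts3 <- stats::setNames(lapply(seq_len(nc), function(i) {
      sample(genes, sample(1:4, 1))
    }), paste0("c", seq_len(nc)))
    ann3 <- stats::setNames(lapply(genes, function(g) {
      sample(terms, sample(1:3, 1))
    }), genes)
    got <- suppressWarnings(pathsim_matrix(ts3, ann3))
    orc <- oracle_pathsim(ts3, ann3)
    keep <- rownames(got$sim)
    expect_equal(got$sim, orc$sim[keep, keep], tolerance = 1e-12)
    expect_equal(got$sim, t(got$sim))
    expect_true(all(got$sim >= 0 & got$sim <= 1 + 1e-12))
  }
})

test_that("drugs with no annotated target are excluded like a target-less compound", {
  ts <- list(known = c("t1", "t2"), orphan = character())
  ann <- list(t1 = "f1", t2 = c("f1", "f2"))
  expect_warning(m <- pathsim_matrix(ts, ann), "orphan")
  expect_equal(rownames(m$sim), "known")
  expect_equal(m$excluded, "orphan")
  expect_error(
    pathsim_matrix(list(a = character()), list()),
    class = "signetpharm_value_error")
})

test_that("hierarchical clustering recovers planted blocks and is order-invariant", {
  ids <- paste0("d", 1:6)
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 1
  m[4:6, 4:6] <- 1
  sm <- signetpharm:::new_similarity_matrix(m, "structure")
  cl <- cluster_similarity(sm, 2)
  expect_equal(cl$cluster, c(1L, 1L, 1L, 2L, 2L, 2L))

  # n_clusters = N gives singletons; bounds are checked
  expect_equal(sort(cluster_similarity(sm, 6)$cluster), 1:6)
  expect_error(cluster_similarity(sm, 7), class = "signetpharm_value_error")

  # permuting drug order permutes, but does not change, the partition
  perm <- c(4, 1, 6, 2, 5, 3)
  smp <- signetpharm:::new_similarity_matrix(m[perm, perm], "structure")
  clp <- cluster_similarity(smp, 2)
  lookup <- stats::setNames(clp$cluster, clp$drug)
  same <- outer(lookup[ids], lookup[ids], `==`)
  expected <- outer(cl$cluster, cl$cluster, `==`)
  expect_equal(unname(same), expected)

  # separation-type matrices are rejected
  sep <- signetpharm:::new_similarity_matrix(
    matrix(c(0, 2, 2, 0), 2, dimnames = list(ids[1:2], ids[1:2])),
    "separation")
  expect_error(cluster_similarity(sep, 2),
               class = "signetpharm_value_error")
})

test_that("sab_matrix assembles symmetric pairwise separations", {
  sets <- list(d1 = c("A", "B"), d2 = c("D", "E"), d3 = c("B", "C"))
  m <- sab_matrix(path5(), sets)
  expect_equal(m$sim, t(m$sim))
  expect_true(all(diag(m$sim) <= 0))
  expect_equal(m$sim["d1", "d2"],
               sab_separation(path5(), sets$d1, sets$d2)$s_ab)
})
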