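test_that("graph construction realizes atoms, bonds, branches and rings", {
  g <- build_graph("CCO")
  expect_equal(g$n, 3)
  expect_equal(nrow(g$edges), 2)

  bz <- benzene()
  expect_equal(bz$n, 6)
  expect_equal(nrow(bz$edges), 6)
  expect_true(all(bz$aromatic))

  # compound 1 of the packaged dataset has 22 heavy atoms
  c1 <- build_graph("COc1ccc(cc1OC)C2=C(O)C(=O)c3ccccc3O2")
  expect_equal(c1$n, 22)

  # explicit bond orders survive; ring-closure bond carries its symbol
  dbl <- build_graph("C=C")
  expect_equal(dbl$edges$order, 2)

  expect_error(build_graph("C1CC"), "unmatched")
  expect_error(build_graph("C(C"), "unbalanced")
  expect_error(build_graph("=O("), "unbalanced")
})

test_that("morgan extended connectivity matches the matrix-power oracle", {
  p3 <- make_molgraph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(morgan_ec(p3, 0), c(1L, 2L, 1L))
  expect_equal(morgan_ec(p3, 1), c(2L, 2L, 2L))
  expect_equal(morgan_ec(benzene(), 1), rep(4L, 6))
  expect_equal(morgan_ec(make_molgraph(1, matrix(numeric(0), 0, 2)), 2), 0L)

  set.seed(11)
  for (rep in 1:25) {
    g <- random_connected_graph(sample(3:8, 1))
    for (ord in 0:3) {
      expect_equal(morgan_ec(g, ord), oracle_morgan_ec(g, ord))
    }
  }
})

test_that("path counts equal exhaustive simple-path enumeration", {
  bz <- benzene()
  expect_equal(path_counts(bz, 2), rep(2L, 6))
  expect_equal(path_counts(bz, 3), rep(2L, 6))

  star <- make_molgraph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(path_counts(star, 2), c(0L, 2L, 2L, 2L))

  edge <- make_molgraph(2, rbind(c(1, 2)))
  expect_equal(path_counts(edge, 2), c(0L, 0L))
  expect_equal(path_counts(edge, 3), c(0L, 0L))

  # exhaustive: every connected labelled graph on up to 4 vertices
  for (n in 2:4) {
    for (g in all_connected_graphs(n)) {
      for (len in c(2L, 3L)) {
        expect_equal(path_counts(g, len),
                     vapply(seq_len(g$n), function(v) oracle_path_count(g, v, len),
                            integer(1)))
      }
    }
  }
  # random connected graphs up to 8 vertices
  set.seed(7)
  for (rep in 1:40) {
    g <- random_connected_graph(sample(5:8, 1))
    for (len in c(2L, 3L)) {
      expect_equal(path_counts(g, len),
                   vapply(seq_len(g$n), function(v) oracle_path_count(g, v, len),
                          integer(1)))
    }
  }
})

test_that("total pt2 equals twice the number of distinct 2-edge paths", {
  set.seed(13)
  for (rep in 1:10) {
    g <- random_connected_graph(sample(4:8, 1))
    # a 2-edge path is an ordered pair from one endpoint; each distinct path
    # is counted once from each of its two endpoints
    deg <- vapply(adj_from_molgraph(g), length, integer(1))
    n_paths <- sum(choose(deg, 2))  # middle-vertex enumeration
    expect_equal(sum(path_counts(g, 2)), 2 * n_paths)
  }
})

test_that("valence shells count vertices at exact distance and sum to |V|-1", {
  bz <- benzene()
  expect_equal(valence_shells(bz, 2), rep(2L, 6))
  expect_equal(valence_shells(bz, 3), rep(1L, 6))
  p3 <- make_molgraph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(valence_shells(p3, 2), c(1L, 0L, 1L))
  expect_equal(valence_shells(make_molgraph(1, matrix(numeric(0), 0, 2)), 2), 0L)

  set.seed(17)
  for (rep in 1:10) {
    g <- random_connected_graph(sample(4:8, 1))
    total <- Reduce(`+`, lapply(1:8, function(r) valence_shells(g, r)))
    expect_equal(total, rep(g$n - 1L, g$n))
  }
})

test_that("ring codes classify SSSR rings by size, aromaticity, heteroatoms", {
  expect_equal(names(ring_codes(benzene())), "RING:6|ar=1|het=0|n=1")
  expect_equal(names(ring_codes(build_graph("C1COCCN1"))), "RING:6|ar=0|het=1|n=1")
  expect_length(ring_codes(build_graph("CCO")), 0)
  # fused bicyclic: SSSR finds the two six-rings, not the ten-ring envelope
  expect_equal(names(ring_codes(build_graph("c1ccc2ccccc2c1"))), "RING:6|ar=1|het=0|n=2")
  # seven-membered rings generate no key
  expect_length(ring_codes(build_graph("C1CCCCCC1")), 0)
})

test_that("graph attribute multiset is invariant under SMILES rewriting", {
  # same molecule entered from different starting atoms / directions
  pairs <- list(
    c("c1ccccc1O", "Oc1ccccc1"),
    c("CCN(CC)CC", "C(C)N(CC)CC"),
    c("C1COCCN1C", "CN1CCOCC1")
  )
  for (p in pairs) {
    a <- graph_attributes(build_graph(p[1]))
    b <- graph_attributes(build_graph(p[2]))
    expect_equal(a[order(names(a), method = "radix")],
                 b[order(names(b), method = "radix")])
  }
})

test_that("per-vertex attribute keys are element-tagged with invariant values", {
  att <- graph_attributes(benzene())
  expect_equal(att[["PT:c|2=2"]], 6L)
  expect_equal(att[["EC:c|1=4"]], 6L)
  expect_equal(att[["SHELL:c|2=2"]], 6L)

  single <- graph_attributes(build_graph("C"))
  expect_equal(single[["EC:C|1=0"]], 1L)
  expect_equal(single[["PT:C|2=0"]], 1L)
  expect_false(any(startsWith(names(single), "RING:")))

  # P3: pt2 = (1,0,1), pt3 = 0 so |pt2-pt3| takes values (1,0,1)
  p3 <- graph_attributes(build_graph("CCC"))
  expect_equal(p3[["COMBO:C|pt2-3=1"]], 2L)
  expect_equal(p3[["COMBO:C|pt2-3=0"]], 1L)
})
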