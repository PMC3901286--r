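potato_tis <- t_invariants(potato_net())

test_that("MCT-sets group transitions by identical occurrence patterns", {
  sets <- mct_sets(potato_tis)
  members <- lapply(sets, `[[`, "transitions")
  expect_length(sets, 3L)
  expect_true(any(vapply(members, function(m) setequal(m, "PGI_f"),
                         logical(1))))
  expect_true(any(vapply(members, function(m) setequal(m, "PGI_b"),
                         logical(1))))
  expect_true(any(vapply(members, function(m)
    setequal(m, c("invertase", "hexokinase", "fructokinase", "glycolysis",
                  "starch_synthase", "sucrose_input", "starch_output")),
    logical(1))))
  expect_length(attr(sets, "uncovered"), 0L)

  # single invariant covering everything: one set
  one <- structure(matrix(c(1, 2, 3), 1, dimnames = list("i1",
                                                         c("a", "b", "c"))),
                   kind = "t", class = c("pn_invariants", "matrix"))
  expect_length(mct_sets(one), 1L)

  # disjoint supports: the two supports
  two <- structure(rbind(i1 = c(1, 1, 0, 0), i2 = c(0, 0, 1, 1)),
                   kind = "t", class = c("pn_invariants", "matrix"))
  colnames(two) <- letters[1:4]
  got <- mct_sets(two)
  expect_length(got, 2L)
  expect_setequal(got[[1]]$transitions, c("a", "b"))
  expect_setequal(got[[2]]$transitions, c("c", "d"))

  expect_error(mct_sets(two[0, , drop = FALSE]), "at least one")
})

test_that("every MCT-set is inside or disjoint from every support", {
  for (seed in 1:10) {
    net <- random_net(3, 5, reversible_fraction = 0.4, seed = seed)
    tis <- t_invariants(net)
    if (nrow(tis) == 0) next
    sets <- mct_sets(tis)
    supports <- invariant_support(tis)
    for (s in sets) for (sup in supports)
      expect_true(all(s$transitions %in% sup) ||
                    !any(s$transitions %in% sup))
    # the sets partition the covered transitions
    covered <- unique(unlist(supports))
    expect_setequal(unlist(lapply(sets, `[[`, "transitions")), covered)
  }
})

test_that("Tanimoto distance behaves as a support dissimilarity", {
  expect_equal(tanimoto_distance(c(1, 2, 0), c(3, 1, 0)), 0)
  expect_equal(tanimoto_distance(c(1, 0), c(0, 5)), 1)
  expect_equal(tanimoto_distance(potato_tis[1, ], potato_tis[2, ]),
               1 - 1 / 9)
  expect_error(tanimoto_distance(c(0, 0), c(0, 0)), "empty")
  expect_error(tanimoto_distance(c(1, 0), c(1, 0, 0)), "universe")

  d <- invariant_distance_matrix(potato_tis)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d[1, 2], 1 - 1 / 9)
})

test_that("t-clustering cuts the UPGMA tree deterministically", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("i1", "i2"),
                                                 c("i1", "i2")))
  cl <- cluster_t_invariants(d2, k = 2)
  expect_equal(cl$k, 2L)
  expect_equal(unname(cl$assignment), c(1L, 2L))

  # two identical support pairs merge first and form the 2-clusters
  tis4 <- rbind(a1 = c(1, 1, 0, 0), a2 = c(2, 1, 0, 0),
                b1 = c(0, 0, 1, 1), b2 = c(0, 0, 3, 1))
  colnames(tis4) <- paste0("t", 1:4)
  d4 <- invariant_distance_matrix(tis4)
  cl4 <- cluster_t_invariants(d4, k = 2)
  expect_equal(cl4$assignment[["a1"]], cl4$assignment[["a2"]])
  expect_equal(cl4$assignment[["b1"]], cl4$assignment[["b2"]])
  expect_false(cl4$assignment[["a1"]] == cl4$assignment[["b1"]])
  expect_true(all(diff(cl4$tree$height) >= 0))  # UPGMA is monotone
  expect_equal(cl4$silhouette, 1)
  # without k, the silhouette picks the same split
  expect_equal(cluster_t_invariants(d4)$k, 2L)

  expect_error(cluster_t_invariants(d4, k = 9), "1..n")
  expect_error(cluster_t_invariants(d2[1, 1, drop = FALSE]), "at least 2")
})

test_that("neighbor-joining trees are cut by longest-branch removal", {
  tis4 <- rbind(a1 = c(1, 1, 0, 0), a2 = c(2, 1, 0, 0),
                b1 = c(0, 0, 1, 1), b2 = c(0, 0, 3, 1))
  colnames(tis4) <- paste0("t", 1:4)
  d4 <- invariant_distance_matrix(tis4)
  cl <- cluster_t_invariants(d4, method = "nj", k = 2)
  expect_equal(cl$k, 2L)
  expect_equal(cl$assignment[["a1"]], cl$assignment[["a2"]])
  expect_false(cl$assignment[["a1"]] == cl$assignment[["b1"]])
  expect_error(cluster_t_invariants(d4[1:3, 1:3], method = "nj", k = 2),
               "at least 4")
})

test_that("silhouette width follows its defining formula", {
  # two tight clusters at distance 1: perfect separation
  d <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(silhouette_width(c(1, 1, 2, 2), d), 1)

  # all points equidistant: any 2-split scores 0
  d5 <- matrix(1, 5, 5); diag(d5) <- 0
  expect_equal(silhouette_width(c(1, 1, 1, 2, 2), d5), 0,
               tolerance = 1e-12)

  # singleton clusters contribute exactly 0
  d3 <- rbind(c(0, .2, .9), c(.2, 0, .9), c(.9, .9, 0))
  s <- silhouette_width(c(1, 1, 2), d3)
  manual <- mean(c((0.9 - 0.2) / 0.9, (0.9 - 0.2) / 0.9, 0))
  expect_equal(s, manual)

  expect_error(silhouette_width(c(1, 1, 1), d3), "k >= 2")
})

test_that("silhouette matches the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(5)
  for (i in 1:5) {
    n <- 8
    x <- matrix(stats::rnorm(n * 2), n)
    d <- as.matrix(stats::dist(x))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ours <- silhouette_width(stats::setNames(lab, rownames(d)), d)
    ref <- mean(cluster::silhouette(lab, stats::as.dist(d))[, "sil_width"])
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("enzyme subsets carry fixed integer flux ratios", {
  es <- enzyme_subsets(potato_tis)
  expect_length(es, 3L)
  big <- es[[which(vapply(es, function(s) length(s$transitions) == 7,
                          logical(1)))]]
  expect_equal(
    big$ratio[c("invertase", "hexokinase", "fructokinase", "glycolysis",
                "starch_synthase", "sucrose_input", "starch_output")],
    c(invertase = 15L, hexokinase = 15L, fructokinase = 15L,
      glycolysis = 2L, starch_synthase = 28L, sucrose_input = 15L,
      starch_output = 28L))

  # a single invariant makes all its support one subset with its own ratio
  one <- structure(matrix(c(2, 4, 6), 1,
                          dimnames = list("i1", c("a", "b", "c"))),
                   kind = "t", class = c("pn_invariants", "matrix"))
  es1 <- enzyme_subsets(one)
  expect_length(es1, 1L)
  expect_equal(unname(es1[[1]]$ratio), c(1L, 2L, 3L))
})

test_that("enzyme subsets refine MCT-sets", {
  for (seed in 1:10) {
    net <- random_net(3, 5, reversible_fraction = 0.4, seed = seed + 50)
    tis <- t_invariants(net)
    if (nrow(tis) == 0) next
    mct <- lapply(mct_sets(tis), `[[`, "transitions")
    for (s in enzyme_subsets(tis)) {
      inside <- vapply(mct, function(m) all(s$transitions %in% m),
                       logical(1))
      expect_equal(sum(inside), 1L)
    }
  }
})

test_that("minimal cut sets are minimal hitting sets of the relevant supports", {
  cs <- minimal_cut_sets(potato_tis, "glycolysis")
  expect_length(cs, 7L)
  expect_true(all(lengths(cs) == 1L))
  expect_setequal(unlist(cs),
                  c("invertase", "hexokinase", "fructokinase", "PGI_b",
                    "starch_synthase", "sucrose_input", "starch_output"))

  # objective outside every invariant
  blocked <- minimal_cut_sets(potato_tis[1, , drop = FALSE], "glycolysis")
  expect_length(blocked, 0L)
  expect_equal(attr(blocked, "status"), "already blocked")

  # two overlapping supports {a,b,o} and {a,c,o}: cut sets {a} and {b,c}
  tis <- structure(rbind(i1 = c(1, 1, 0, 1), i2 = c(1, 0, 1, 1)),
                   kind = "t", class = c("pn_invariants", "matrix"))
  colnames(tis) <- c("a", "b", "c", "o")
  cs2 <- minimal_cut_sets(tis, "o")
  expect_equal(cs2[[1]], "a")
  expect_setequal(cs2[[2]], c("b", "c"))
  expect_length(cs2, 2L)

  expect_error(minimal_cut_sets(tis, "zzz"), "not a transition")
  expect_error(minimal_cut_sets(tis, "o", max_relevant = 1),
               "instance guard")
  # the objective itself is admitted on request
  cs3 <- minimal_cut_sets(tis, "o", include_objective = TRUE)
  expect_true(list("o") %in% cs3 ||
                any(vapply(cs3, function(s) identical(s, "o"),
                           logical(1))))
})

test_that("deleting a cut set leaves no invariant through the objective", {
  checked <- 0L
  for (seed in c(2, 4, 6, 8)) {
    net <- random_net(3, 4, reversible_fraction = 0.5, seed = seed)
    C <- incidence_matrix(net)
    tis <- t_invariants(net)
    if (nrow(tis) == 0) next
    covered <- colnames(tis)[colSums(tis != 0) > 0]
    obj <- covered[1]
    for (cs in minimal_cut_sets(tis, obj)) {
      reduced <- C[, setdiff(colnames(C), cs), drop = FALSE]
      tis2 <- t_invariants(reduced)
      through <- if (nrow(tis2)) sum(tis2[, obj] != 0) else 0
      expect_equal(through, 0)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})
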