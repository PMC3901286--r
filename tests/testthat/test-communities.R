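two_triangles <- data.frame(from = c("a", "b", "c", "d", "e", "f"),
                            to = c("b", "c", "a", "e", "f", "d"))

test_that("unipartite Q matches the module-sum formula", {
  part <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(modularity_unipartite(two_triangles, part)$q, 0.5)

  one <- stats::setNames(rep(1, 6), names(part))
  expect_identical(modularity_unipartite(two_triangles, one)$q, 0)

  singletons <- stats::setNames(1:6, names(part))
  expect_equal(modularity_unipartite(two_triangles, singletons)$q, -1 / 6)

  expect_error(modularity_unipartite(two_triangles[0, ], part), "empty")
  expect_error(modularity_unipartite(data.frame(from = "a", to = "a"),
                                     c(a = 1)), "self-loops")
})

test_that("unipartite Q agrees with the naive adjacency double sum", {
  set.seed(8)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    verts <- paste0("v", 1:n)
    pairs <- t(utils::combn(verts, 2))
    take <- sample(nrow(pairs), max(4, rpois(1, n)))
    edges <- data.frame(from = pairs[take, 1], to = pairs[take, 2])
    mem <- stats::setNames(sample(1:3, n, replace = TRUE), verts)
    expect_equal(modularity_unipartite(edges, mem)$q,
                 naive_modularity(edges, mem))
  }
})

test_that("bipartite directed Q is zero for one module, exactly", {
  net <- potato_net()
  ids <- c(net$places$id, net$transitions$id)
  one <- stats::setNames(rep(1, length(ids)), ids)
  expect_identical(modularity_bipartite(net, one)$q, 0)
  # per-module contributions sum to q
  mem <- stats::setNames(rep(1:3, length.out = length(ids)), ids)
  sc <- modularity_bipartite(net, mem)
  expect_equal(sum(sc$per_module), sc$q)
  expect_lte(sc$q, 1)
  expect_error(modularity_bipartite(net, one[-1]), "missing")
})

test_that("component split of twin subnets maximizes Q over 2-partitions", {
  half <- function(suffix) list(
    places = data.frame(id = paste0(c("A", "B"), suffix)),
    transitions = data.frame(id = paste0(c("r", "s"), suffix)),
    arcs = data.frame(from = paste0(c("A", "r", "B", "s"), suffix),
                      to = paste0(c("r", "B", "s", "A"), suffix),
                      weight = c(1, 2, 1, 1)))
  h1 <- half("1"); h2 <- half("2")
  net <- petri_net(rbind(h1$places, h2$places),
                   rbind(h1$transitions, h2$transitions),
                   rbind(h1$arcs, h2$arcs))
  ids <- c(net$places$id, net$transitions$id)
  by_comp <- stats::setNames(ifelse(grepl("1$", ids), 1L, 2L), ids)
  q_comp <- modularity_bipartite(net, by_comp)$q
  expect_gt(q_comp, 0)
  # exhaustive over all 2-partitions (binary labelings up to symmetry)
  n <- length(ids)
  best <- -Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    lab <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1)] + 1L)
    q <- modularity_bipartite(net, stats::setNames(lab, ids))$q
    best <- max(best, q)
  }
  expect_equal(q_comp, best)
})

test_that("Q of any partition is invariant under reversing every arc", {
  set.seed(3)
  for (i in 1:8) {
    net <- random_net(3, 4, max_weight = 3, seed = i + 10)
    rev <- petri_net(net$places, net$transitions,
                     data.frame(from = net$arcs$to, to = net$arcs$from,
                                weight = net$arcs$weight))
    ids <- c(net$places$id, net$transitions$id)
    mem <- stats::setNames(sample(1:3, length(ids), TRUE), ids)
    expect_equal(modularity_bipartite(net, mem)$q,
                 modularity_bipartite(rev, mem)$q)
  }
})

test_that("the GA is seed-deterministic with a non-decreasing best score", {
  net <- potato_net()
  r1 <- optimize_modules(net, population_size = 30, generations = 40,
                         stagnation_limit = 15, seed = 42)
  r2 <- optimize_modules(net, population_size = 30, generations = 40,
                         stagnation_limit = 15, seed = 42)
  expect_identical(r1$membership, r2$membership)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history) >= 0))
  expect_equal(modularity_bipartite(net, r1$membership)$q, r1$score$q)
  expect_error(optimize_modules(net, seed = NULL), "seed")
})

test_that("the GA attains the exhaustive maximum on tiny nets", {
  for (seed in c(1, 2, 3)) {
    net <- random_net(3, 3, max_weight = 2, seed = seed)
    ids <- c(net$places$id, net$transitions$id)
    best <- max(vapply(all_partitions(length(ids)), function(lab)
      modularity_bipartite(net, stats::setNames(lab, ids))$q, numeric(1)))
    got <- optimize_modules(net, population_size = 60, generations = 250,
                            stagnation_limit = 120, seed = seed)
    expect_equal(got$score$q, best, tolerance = 1e-12)
  }
})

test_that("on the example network the GA separates the starch branch", {
  # soft, logged check: the sucrose-uptake side and the starch-production
  # side of the example net should tend to end up in different modules
  seeds_ok <- 0L
  for (seed in 1:5) {
    res <- optimize_modules(potato_net(), population_size = 60,
                            generations = 120, stagnation_limit = 40,
                            seed = seed)
    m <- res$membership
    starch_side <- unique(m[c("starch", "starch_synthase",
                              "starch_output")])
    sucrose_side <- unique(m[c("sucrose", "sucrose_input", "invertase")])
    if (length(starch_side) == 1 && length(sucrose_side) == 1 &&
        starch_side != sucrose_side)
      seeds_ok <- seeds_ok + 1L
  }
  message(sprintf(
    "starch vs sucrose branch separated in %d/5 GA seed runs", seeds_ok))
  succeed()
})

test_that("partition TSV round trip is exact", {
  mem <- stats::setNames(c(1L, 2L, 1L), c("x", "y", "z"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition_tsv(mem, path)
  expect_identical(read_partition_tsv(path), mem)
})
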