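test_that("the example network has exactly its two minimal t-invariants", {
  tis <- t_invariants(potato_net())
  expect_equal(nrow(tis), 2L)
  supports <- invariant_support(tis)
  trivial <- which(lengths(supports) == 2)
  expect_length(trivial, 1L)
  expect_setequal(supports[[trivial]], c("PGI_f", "PGI_b"))
  expect_equal(unname(tis[trivial, c("PGI_f", "PGI_b")]), c(1, 1))

  main <- tis[-trivial, ]
  # full solution of C t = 0 with the forward isomerase unused
  expect_equal(
    main[c("invertase", "hexokinase", "fructokinase", "PGI_f", "PGI_b",
           "glycolysis", "starch_synthase", "sucrose_input",
           "starch_output")],
    c(invertase = 15, hexokinase = 15, fructokinase = 15, PGI_f = 0,
      PGI_b = 13, glycolysis = 2, starch_synthase = 28,
      sucrose_input = 15, starch_output = 28))
  expect_true(all(incidence_matrix(potato_net()) %*% main == 0))
})

test_that("tableau elimination mirrors the worked steps", {
  C <- incidence_matrix(potato_net())
  tab <- fm_tableau(C)
  expect_equal(nrow(tab$parikh), 9L)

  # first step: sucrose has one producer and one consumer; the combined
  # row (invertase + sucrose_input) replaces them
  tab1 <- eliminate_place(tab, "sucrose")
  expect_equal(nrow(tab1$parikh), 8L)
  new_row <- tab1$parikh[8, ]
  expect_equal(new_row[new_row != 0],
               c(invertase = 1, sucrose_input = 1))
  expect_true(all(tab1$residual[, "sucrose"] == 0))

  # after the chain places and starch, eliminating F6P combines 2 positive
  # with 2 negative rows into four new minimal rows
  for (p in c("glucose", "fructose", "starch")) tab1 <-
      eliminate_place(tab1, p)
  expect_equal(nrow(tab1$parikh), 5L)
  col <- tab1$residual[, "F6P"]
  expect_equal(c(sum(col > 0), sum(col < 0)), c(2, 2))
  tab2 <- eliminate_place(tab1, "F6P")
  expect_equal(nrow(tab2$parikh), 5L)          # 5 - 4 used + 4 new

  # an all-zero column eliminates as a no-op
  Z <- cbind(C, extra = 0)
  rownames(Z) <- rownames(C)
  tabz <- fm_tableau(t(Z))   # place-side tableau with a dead column
  before <- tabz$parikh
  tabz2 <- eliminate_place(tabz, "extra")
  expect_identical(tabz2$parikh, before)

  expect_error(eliminate_place(tab1, "sucrose"), "already eliminated")
})

test_that("the elimination heuristic scores pos*neg - pos - neg with ties by order", {
  # column p: 1 pos / 1 neg (score -1) beats column q: 2 pos / 2 neg (0)
  M <- rbind(p = c(1, -1, 0, 0), q = c(1, 1, -1, -1))
  colnames(M) <- paste0("t", 1:4)
  expect_equal(choose_next_place(fm_tableau(M)), "p")
  # an all-zero column (score 0) ranks after a 1/1 column
  M2 <- rbind(z = c(0, 0), p = c(1, -1))
  colnames(M2) <- c("a", "b")
  expect_equal(choose_next_place(fm_tableau(M2)), "p")
  # equal scores: first place in matrix order wins
  M3 <- rbind(p1 = c(1, -1, 0), p2 = c(0, 1, -1))
  colnames(M3) <- paste0("t", 1:3)
  expect_equal(choose_next_place(fm_tableau(M3)), "p1")
})

test_that("p-invariants identify conserved metabolite pools", {
  pis <- p_invariants(potato_net())
  expect_equal(nrow(pis), 1L)
  expect_equal(pis[1, c("ADP", "ATP")], c(ADP = 1, ATP = 1))
  expect_true(all(pis[1, setdiff(colnames(pis), c("ADP", "ATP"))] == 0))

  pis2 <- p_invariants(cycle_net())
  expect_equal(nrow(pis2), 1L)
  expect_equal(unname(pis2[1, c("A", "B")]), c(1, 1))
})

test_that("FM equals brute-force enumeration on random integer matrices", {
  set.seed(2024)
  for (i in 1:40) {
    C <- random_int_matrix(4, 5)
    expect_true(oracle_agrees(C, t_invariants(C)))
    # and on the transpose, for the place side
    expect_true(oracle_agrees(t(C), p_invariants(C)))
  }
})

test_that("returned invariants are sound, minimal and gcd-normalized", {
  set.seed(7)
  for (i in 1:25) {
    C <- random_int_matrix(sample(2:5, 1), sample(3:6, 1))
    tis <- t_invariants(C)
    if (nrow(tis) == 0) next
    expect_true(all(C %*% t(tis) == 0))
    supp <- tis > 0
    for (a in seq_len(nrow(tis))) {
      nz <- tis[a, tis[a, ] > 0]
      expect_equal(Reduce(function(x, y) {
        while (y) { r <- x %% y; x <- y; y <- r }; x }, nz), 1)
      for (b in seq_len(nrow(tis)))
        if (a != b)
          expect_false(all(supp[a, ] >= supp[b, ]) &&
                         sum(supp[a, ]) > sum(supp[b, ]))
    }
  }
})

test_that("scaling a conservation row leaves the t-invariant set unchanged", {
  set.seed(11)
  for (i in 1:10) {
    C <- random_int_matrix(3, 4)
    C2 <- C
    C2[2, ] <- 7 * C2[2, ]
    expect_identical(canon_inv_set(t_invariants(C)),
                     canon_inv_set(t_invariants(C2)))
  }
})

test_that("the tableau row cap aborts with an explosion error carrying size", {
  C <- incidence_matrix(potato_net())
  err <- tryCatch(t_invariants(C, row_cap = 3), condition = identity)
  expect_s3_class(err, "fm_tableau_explosion")
  expect_true(err$size > 3)
})

test_that("Farkas dual uncovered set agrees with direct CTI coverage", {
  expect_length(farkas_uncovered(table1_matrix()), 0L)

  # a single irreversible internal reaction cannot be balanced
  single <- petri_net(places = data.frame(id = c("A", "B")),
                      transitions = data.frame(id = "r"),
                      arcs = data.frame(from = c("A", "r"),
                                        to = c("r", "B"), weight = 1))
  expect_identical(as.character(farkas_uncovered(incidence_matrix(single))),
                   "r")
  expect_identical(cti_check(single)$uncovered, "r")

  set.seed(31)
  for (i in 1:30) {
    net <- random_net(sample(2:4, 1), sample(2:5, 1),
                      reversible_fraction = 0.4, max_weight = 2, seed = i)
    direct <- cti_check(net)$uncovered
    dual <- farkas_uncovered(incidence_matrix(net))
    expect_setequal(as.character(dual), direct)
  }
})

test_that("coverage reports partition the id set", {
  net <- potato_net()
  cov <- cti_check(net)
  expect_true(cov$is_cti)
  expect_setequal(c(cov$covered, cov$uncovered), net$transitions$id)

  pcov <- cpi_check(net)
  expect_false(pcov$is_cpi)
  expect_setequal(pcov$covered, c("ADP", "ATP"))
})

test_that("invariant TSV and report name reactions with multiplicities", {
  tis <- t_invariants(potato_net())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_invariants_tsv(tis, path)
  df <- utils::read.delim(path, check.names = FALSE)
  expect_equal(dim(df), c(2L, 10L))
  expect_match(invariant_report(tis), "invertase x15")
})
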