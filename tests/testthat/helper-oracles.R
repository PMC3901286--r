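# independent oracles and tiny net builders used across the suite; the
# oracles deliberately avoid every code path of the package solvers

# exhaustive bounded-coefficient enumeration of minimal nonnegative integer
# solutions of C v = 0: all vectors with entries in 0..bound, filtered by the
# defining equation, gcd-normalized, then support-minimality by pairwise test.
# The bound must be at least the largest coefficient of any minimal solution
# for the enumeration to be conclusive; callers grow it adaptively.
brute_force_invariants <- function(C, bound = 12) {
  nt <- ncol(C)
  V <- as.matrix(expand.grid(rep(list(0:bound), nt)))
  colnames(V) <- colnames(C)
  V <- V[rowSums(V) > 0, , drop = FALSE]
  ok <- colSums(abs(C %*% t(V))) == 0
  W <- V[ok, , drop = FALSE]
  if (nrow(W) == 0) return(W)
  gcd1 <- function(v) {
    v <- v[v != 0]
    Reduce(function(a, b) { while (b) { r <- a %% b; a <- b; b <- r }; a },
           v)
  }
  W <- t(apply(W, 1, function(v) v / gcd1(v)))
  W <- W[!duplicated(W), , drop = FALSE]
  supp <- W > 0
  keep <- rep(TRUE, nrow(W))
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W))) {
    if (i != j && keep[i] && all(supp[j, ] >= supp[i, ]) &&
        sum(supp[j, ]) > sum(supp[i, ]))
      keep[j] <- FALSE
  }
  W[keep, , drop = FALSE]
}

# compare a computed invariant set against the brute-force enumeration.
# The enumeration bound grows with the largest computed coefficient so it is
# conclusive; when that would make the grid infeasible (> grid_cap points),
# rows beyond the feasible bound are verified directly (balance equation,
# normalization, support-minimality) while the bounded part is compared
# exactly.  Returns TRUE or a description of the discrepancy.
oracle_agrees <- function(C, got, base = 12, grid_cap = 6e6) {
  nt <- ncol(C)
  b <- max(base, got, 0)
  feasible <- floor(grid_cap^(1 / nt)) - 1
  b <- min(b, feasible)
  oracle <- brute_force_invariants(C, b)
  is_small <- if (nrow(got)) apply(got, 1, max) <= b else logical(0)
  small <- got[is_small, , drop = FALSE]
  big <- got[!is_small, , drop = FALSE]
  if (!identical(canon_inv_set(small), canon_inv_set(oracle)))
    return("bounded part differs from enumeration")
  if (nrow(big)) {
    if (!all(C %*% t(big[, colnames(C)]) == 0))
      return("large-coefficient row violates the balance equation")
    supp <- got > 0
    for (i in seq_len(nrow(got))) for (j in seq_len(nrow(got)))
      if (i != j && all(supp[i, ] >= supp[j, ]) &&
          sum(supp[i, ]) > sum(supp[j, ]))
        return("large-coefficient row is not support-minimal")
  }
  TRUE
}

# canonical string form of an invariant set, for set equality tests
canon_inv_set <- function(M) {
  if (nrow(M) == 0) return(character(0))
  M <- M[, sort(colnames(M)), drop = FALSE]
  sort(unname(apply(M, 1, paste, collapse = ",")))
}

random_int_matrix <- function(np, nt, lo = -2, hi = 2) {
  matrix(sample(lo:hi, np * nt, replace = TRUE), np, nt,
         dimnames = list(paste0("p", 1:np), paste0("t", 1:nt)))
}

# the canonical Table-1 incidence matrix of the example network, entered by
# hand so the fixture can be checked entry-for-entry against it
table1_matrix <- function() {
  C <- rbind(
    sucrose  = c(-1,  0,  0,  0,  0,   0,  0, 1,  0),
    glucose  = c( 1, -1,  0,  0,  0,   0,  0, 0,  0),
    fructose = c( 1,  0, -1,  0,  0,   0,  0, 0,  0),
    F6P      = c( 0,  0,  1,  1, -1,  -1,  0, 0,  0),
    G6P      = c( 0,  1,  0, -1,  1,   0, -1, 0,  0),
    starch   = c( 0,  0,  0,  0,  0,   0,  1, 0, -1),
    ADP      = c( 0,  1,  1,  0,  0, -29,  1, 0,  0),
    ATP      = c( 0, -1, -1,  0,  0,  29, -1, 0,  0))
  colnames(C) <- c("invertase", "hexokinase", "fructokinase", "PGI_f",
                   "PGI_b", "glycolysis", "starch_synthase",
                   "sucrose_input", "starch_output")
  storage.mode(C) <- "double"
  C
}

# all set partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxl) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (l in seq_len(maxl + 1L)) rec(c(prefix, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  out
}

# naive adjacency-matrix double sum for unipartite modularity:
# Q = (1/2m) sum_ij (A_ij - d_i d_j / 2m) delta(c_i, c_j)
naive_modularity <- function(edges, membership) {
  verts <- union(edges$from, edges$to)
  n <- length(verts)
  A <- matrix(0, n, n, dimnames = list(verts, verts))
  for (k in seq_len(nrow(edges))) {
    A[edges$from[k], edges$to[k]] <- A[edges$from[k], edges$to[k]] + 1
    A[edges$to[k], edges$from[k]] <- A[edges$to[k], edges$from[k]] + 1
  }
  d <- rowSums(A)
  m2 <- sum(A)
  q <- 0
  for (i in verts) for (j in verts)
    if (membership[i] == membership[j])
      q <- q + A[i, j] - d[i] * d[j] / m2
  unname(q / m2)
}

# tiny chain net: n_tokens on A, single transition A -> B
chain_net <- function() {
  petri_net(places = data.frame(id = c("A", "B")),
            transitions = data.frame(id = "t"),
            arcs = data.frame(from = c("A", "t"), to = c("t", "B"),
                              weight = 1))
}

# closed two-cycle A -> t1 -> B -> t2 -> A
cycle_net <- function() {
  petri_net(places = data.frame(id = c("A", "B")),
            transitions = data.frame(id = c("t1", "t2")),
            arcs = data.frame(from = c("A", "t1", "B", "t2"),
                              to = c("t1", "B", "t2", "A"),
                              weight = 1))
}
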