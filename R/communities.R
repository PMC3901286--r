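#' Q-modularity of a partition
#'
#' `modularity_unipartite()` scores a partition of an undirected, unweighted
#' graph by the classical sum over modules `Q = sum_c [ l_c/m - (d_c/2m)^2 ]`
#' with `l_c` edges inside module `c`, `d_c` the total degree of its
#' vertices, and `m` the number of edges.
#'
#' `modularity_bipartite()` scores a partition of the places and transitions
#' of a Petri net, respecting arc direction and weight.  It compares the
#' weight of arcs inside each module against a directed configuration null
#' model: `Q = (1/W) * sum over same-module ordered pairs (i, j) of
#' [ w_ij - s_out(i) * s_in(j) / W ]`, with `W` the total arc weight and
#' `s_out`/`s_in` the weighted out-/in-strengths.  The null term is summed
#' over all ordered same-module pairs, which makes `Q` exactly 0 for the
#' single-module partition and invariant under reversal of every arc.  The
#' null model is one admissible choice for bipartite directed nets and is
#' isolated behind this scorer so alternatives can be plugged in.
#'
#' @param edges data.frame with columns `from`, `to`: undirected unweighted
#'   edges, no self-loops.
#' @param membership named vector mapping every vertex id to a module label.
#' @return Object of class `q_modularity`: list with `q` and `per_module`
#'   (named contributions summing to `q`).
#' @examples
#' tri2 <- data.frame(from = c("a","b","c","d","e","f"),
#'                    to   = c("b","c","a","e","f","d"))
#' part <- c(a=1, b=1, c=1, d=2, e=2, f=2)
#' modularity_unipartite(tri2, part)   # 0.5
#' @export
modularity_unipartite <- function(edges, membership) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) stop("empty edge list", call. = FALSE)
  if (any(edges$from == edges$to))
    stop("self-loops are not supported", call. = FALSE)
  verts <- union(edges$from, edges$to)
  miss <- setdiff(verts, names(membership))
  if (length(miss))
    stop("membership missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- nrow(edges)
  mods <- unique(membership[verts])
  per <- stats::setNames(numeric(length(mods)), as.character(mods))
  deg <- table(c(edges$from, edges$to))
  for (i in seq_along(mods)) {
    inside <- names(membership)[membership == mods[i]]
    l_c <- sum(edges$from %in% inside & edges$to %in% inside)
    d_c <- sum(deg[names(deg) %in% inside])
    per[i] <- l_c / m - (d_c / (2 * m))^2
  }
  structure(list(q = sum(per), per_module = per), class = "q_modularity")
}

#' @rdname modularity_unipartite
#' @param net a `petri_net`; `membership` must cover all places and
#'   transitions.
#' @export
modularity_bipartite <- function(net, membership) {
  if (nrow(net$arcs) == 0L) stop("net has no arcs", call. = FALSE)
  ids <- c(place_ids(net), transition_ids(net))
  miss <- setdiff(ids, names(membership))
  if (length(miss))
    stop("membership missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  a <- net$arcs
  W <- sum(a$weight)
  s_out <- stats::setNames(numeric(length(ids)), ids)
  s_in <- s_out
  tf <- tapply(a$weight, a$from, sum)
  tt <- tapply(a$weight, a$to, sum)
  s_out[names(tf)] <- tf
  s_in[names(tt)] <- tt
  mem <- membership[ids]
  mods <- unique(mem)
  per <- stats::setNames(numeric(length(mods)), as.character(mods))
  same <- mem[a$from] == mem[a$to]
  for (i in seq_along(mods)) {
    inside <- ids[mem == mods[i]]
    w_in <- sum(a$weight[same & mem[a$from] == mods[i]])
    per[i] <- w_in / W - sum(s_out[inside]) * sum(s_in[inside]) / W^2
  }
  structure(list(q = sum(per), per_module = per), class = "q_modularity")
}

#' @export
print.q_modularity <- function(x, ...) {
  cat(sprintf("Q-modularity: %.6f over %d modules\n", x$q,
              length(x$per_module)))
  invisible(x)
}

#' Genetic-algorithm optimization of bipartite directed Q-modularity
#'
#' Searches for a partition of the net's places and transitions maximizing
#' [modularity_bipartite()].  Chromosomes are module-label vectors over the
#' vertices; generations apply elitism (the best chromosomes survive
#' unchanged, so the best-so-far score never decreases), binary-tournament
#' selection, one-point crossover with label canonicalization, and
#' per-vertex mutation that reassigns a vertex to a random existing or
#' fresh module.  The run stops after `generations` generations or when the
#' best score has not improved for `stagnation_limit` generations.
#' Deterministic given `seed`.
#'
#' @param net a `petri_net`.
#' @param population_size,generations,mutation_rate,crossover_rate,
#'   elite_count,stagnation_limit GA controls (defaults 100, 500, 0.02,
#'   0.8, 2, 100).
#' @param seed mandatory integer seed.
#' @return Object of class `pn_partition`: list with `membership` (named
#'   module labels, first-appearance order), `score` (a `q_modularity`),
#'   and `history` (best Q per generation, non-decreasing).
#' @examples
#' res <- optimize_modules(potato_net(), population_size = 40,
#'                         generations = 60, seed = 1)
#' res$score
#' @export
optimize_modules <- function(net, population_size = 100, generations = 500,
                             mutation_rate = 0.02, crossover_rate = 0.8,
                             elite_count = 2, stagnation_limit = 100,
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(is_count(population_size, 2), is_count(generations, 1),
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            is_count(elite_count, 0), elite_count < population_size,
            is_count(stagnation_limit, 1))
  ids <- c(place_ids(net), transition_ids(net))
  n <- length(ids)

  fitness <- function(lab)
    modularity_bipartite(net, stats::setNames(lab, ids))$q

  with_seed(seed, {
    kmax <- max(2L, min(n, 8L))
    pop <- lapply(seq_len(population_size), function(i) {
      k <- sample(2:kmax, 1)
      canon_labels(sample.int(k, n, replace = TRUE))
    })
    fit <- vapply(pop, fitness, numeric(1))
    history <- numeric(0)
    best <- -Inf
    stagnant <- 0L
    for (gen in seq_len(generations)) {
      ord <- order(-fit)
      pop <- pop[ord]; fit <- fit[ord]
      if (fit[1] > best + 1e-12) { best <- fit[1]; stagnant <- 0L }
      else stagnant <- stagnant + 1L
      history <- c(history, best)
      if (stagnant >= stagnation_limit) break
      if (gen == generations) break
      nextgen <- pop[seq_len(elite_count)]
      # a few random immigrants per generation guard against premature
      # convergence of the whole population onto one local optimum
      n_imm <- max(1L, floor(population_size * 0.05))
      for (im in seq_len(n_imm)) {
        k <- sample(2:kmax, 1)
        nextgen <- c(nextgen, list(canon_labels(
          sample.int(k, n, replace = TRUE))))
      }
      while (length(nextgen) < population_size) {
        pick <- function() {
          ij <- sample.int(population_size, 2)
          pop[[ij[which.max(fit[ij])]]]
        }
        a <- pick(); b <- pick()
        child <- if (stats::runif(1) < crossover_rate && n > 1) {
          cp <- sample.int(n - 1, 1)
          # shift b's labels so the halves do not collide spuriously
          c(a[seq_len(cp)], b[(cp + 1):n] + max(a))
        } else a
        mut <- stats::runif(n) < mutation_rate
        if (any(mut)) {
          fresh <- max(child) + 1L
          child[mut] <- vapply(which(mut), function(i)
            sample(c(unique(child), fresh), 1), numeric(1))
        }
        nextgen <- c(nextgen, list(canon_labels(child)))
      }
      pop <- nextgen
      fit <- vapply(pop, fitness, numeric(1))
    }
    membership <- stats::setNames(canon_labels(pop[[which.max(fit)]]), ids)
    structure(list(membership = membership,
                   score = modularity_bipartite(net, membership),
                   history = history),
              class = "pn_partition")
  })
}

# canonicalize labels to first-appearance order 1, 2, ...
canon_labels <- function(lab) match(lab, unique(lab))

#' @export
print.pn_partition <- function(x, ...) {
  k <- length(unique(x$membership))
  cat(sprintf("partition into %d modules, Q = %.6f (%d generations)\n",
              k, x$score$q, length(x$history)))
  for (c in seq_len(k))
    cat(sprintf("  module %d: %s\n", c,
                paste(names(x$membership)[x$membership == c],
                      collapse = ", ")))
  invisible(x)
}

#' Partition import/export as two-column TSV
#'
#' @param membership named module labels.
#' @param path file path.
#' @return `path` (write) or a named integer vector (read).
#' @export
write_partition_tsv <- function(membership, path) {
  utils::write.table(
    data.frame(vertex = names(membership), module = as.integer(membership)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$module), df$vertex)
}
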