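#' Carbon-metabolism example network of young potato tubers
#'
#' Reconstructs the small place/transition net of sucrose-to-starch carbon
#' metabolism in young *Solanum tuberosum* tubers that serves as the running
#' example throughout the package: 8 places (metabolites) and 9 transitions
#' (reactions), among them the reversible phosphoglucoisomerase pair
#' (`PGI_f`/`PGI_b`) and the boundary reactions `sucrose_input` and
#' `starch_output` that connect the system to its environment.  Glycolysis
#' is lumped into a single reaction converting fructose 6-phosphate and 29
#' ADP into 29 ATP.
#'
#' @return A `petri_net` whose [incidence_matrix()] is the canonical 8 x 9
#'   stoichiometric matrix of the example.
#' @examples
#' net <- potato_net()
#' incidence_matrix(net)
#' @export
potato_net <- function() {
  places <- data.frame(
    id = c("sucrose", "glucose", "fructose", "F6P", "G6P", "starch",
           "ADP", "ATP"),
    name = c("Sucrose", "Glucose", "Fructose", "Fructose 6-phosphate",
             "Glucose 6-phosphate", "Starch", "ADP", "ATP"),
    stringsAsFactors = FALSE)
  transitions <- data.frame(
    id = c("invertase", "hexokinase", "fructokinase", "PGI_f", "PGI_b",
           "glycolysis", "starch_synthase", "sucrose_input",
           "starch_output"),
    name = c("Invertase", "Hexokinase", "Fructokinase",
             "Phosphoglucoisomerase (forward)",
             "Phosphoglucoisomerase (backward)", "Glycolysis",
             "Starch synthase", "Sucrose input", "Starch output"),
    reverse_of = c(NA, NA, NA, "PGI_b", "PGI_f", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  arcs <- rbind(
    data.frame(from = "sucrose",   to = "invertase",       weight = 1),
    data.frame(from = "invertase", to = "glucose",         weight = 1),
    data.frame(from = "invertase", to = "fructose",        weight = 1),
    data.frame(from = "glucose",   to = "hexokinase",      weight = 1),
    data.frame(from = "ATP",       to = "hexokinase",      weight = 1),
    data.frame(from = "hexokinase", to = "G6P",            weight = 1),
    data.frame(from = "hexokinase", to = "ADP",            weight = 1),
    data.frame(from = "fructose",  to = "fructokinase",    weight = 1),
    data.frame(from = "ATP",       to = "fructokinase",    weight = 1),
    data.frame(from = "fructokinase", to = "F6P",          weight = 1),
    data.frame(from = "fructokinase", to = "ADP",          weight = 1),
    data.frame(from = "G6P",       to = "PGI_f",           weight = 1),
    data.frame(from = "PGI_f",     to = "F6P",             weight = 1),
    data.frame(from = "F6P",       to = "PGI_b",           weight = 1),
    data.frame(from = "PGI_b",     to = "G6P",             weight = 1),
    data.frame(from = "F6P",       to = "glycolysis",      weight = 1),
    data.frame(from = "ADP",       to = "glycolysis",      weight = 29),
    data.frame(from = "glycolysis", to = "ATP",            weight = 29),
    data.frame(from = "G6P",       to = "starch_synthase", weight = 1),
    data.frame(from = "ATP",       to = "starch_synthase", weight = 1),
    data.frame(from = "starch_synthase", to = "starch",    weight = 1),
    data.frame(from = "starch_synthase", to = "ADP",       weight = 1),
    data.frame(from = "sucrose_input", to = "sucrose",     weight = 1),
    data.frame(from = "starch",    to = "starch_output",   weight = 1))
  petri_net(places, transitions, arcs)
}

#' Random connected bipartite Petri nets
#'
#' Generates small random place/transition nets for property tests and
#' oracle comparisons.  The generator grows a random spanning tree over the
#' bipartite vertex set (guaranteeing connectivity), sprinkles extra arcs,
#' draws integer weights uniformly from `1:max_weight`, and optionally turns
#' a fraction of transitions into structurally mirrored reversible pairs
#' linked via `reverse_of`.  Deterministic given `seed`.
#'
#' @param n_places,n_transitions positive vertex counts.
#' @param reversible_fraction fraction of transitions participating in
#'   reversible pairs (rounded down to whole pairs), in \[0, 1\].
#' @param max_weight maximum arc weight (>= 1).
#' @param seed mandatory integer seed.
#' @param extra_arc_factor expected number of extra arcs per vertex beyond
#'   the spanning tree (default 0.4).
#' @return A `petri_net`.
#' @examples
#' random_net(3, 4, reversible_fraction = 0.5, seed = 1)
#' @export
random_net <- function(n_places, n_transitions, reversible_fraction = 0,
                       max_weight = 1, seed, extra_arc_factor = 0.4) {
  if (!is_count(n_places, 1) || !is_count(n_transitions, 1))
    stop("n_places and n_transitions must be positive integers",
         call. = FALSE)
  if (!is_count(max_weight, 1))
    stop("max_weight must be a positive integer", call. = FALSE)
  if (reversible_fraction < 0 || reversible_fraction > 1)
    stop("reversible_fraction must lie in [0, 1]", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n_pairs <- floor(reversible_fraction * n_transitions / 2)
  if (n_pairs * 2 > n_transitions)
    stop("impossible parameter combination: too few transitions for the ",
         "requested reversible fraction", call. = FALSE)

  with_seed(seed, {
    pids <- paste0("p", seq_len(n_places))
    tids <- paste0("t", seq_len(n_transitions))
    type <- c(rep("p", n_places), rep("t", n_transitions))
    ids <- c(pids, tids)

    # spanning tree: seed with one vertex of each type, attach the rest (in
    # random order) to a random earlier vertex of the other type
    order_rest <- sample(seq_along(ids)[-c(1, n_places + 1)])
    seen <- c(1L, n_places + 1L)
    from <- character(0); to <- character(0)
    for (v in order_rest) {
      others <- seen[type[seen] != type[v]]
      u <- if (length(others) == 1L) others else sample(others, 1L)
      if (stats::runif(1) < 0.5) {
        from <- c(from, ids[u]); to <- c(to, ids[v])
      } else {
        from <- c(from, ids[v]); to <- c(to, ids[u])
      }
      seen <- c(seen, v)
    }
    arcs <- data.frame(from = from, to = to, stringsAsFactors = FALSE)

    n_extra <- stats::rpois(1, extra_arc_factor * length(ids))
    for (k in seq_len(n_extra)) {
      p <- sample(pids, 1L); t <- sample(tids, 1L)
      pair <- if (stats::runif(1) < 0.5) c(p, t) else c(t, p)
      if (!any(arcs$from == pair[1] & arcs$to == pair[2]))
        arcs <- rbind(arcs, data.frame(from = pair[1], to = pair[2]))
    }
    arcs$weight <- sample(seq_len(max_weight), nrow(arcs), replace = TRUE)

    reverse_of <- stats::setNames(rep(NA_character_, n_transitions), tids)
    if (n_pairs > 0) {
      chosen <- sample(tids, 2L * n_pairs)
      for (i in seq_len(n_pairs)) {
        fwd <- chosen[2L * i - 1L]; bwd <- chosen[2L * i]
        # make bwd the exact structural mirror of fwd
        arcs <- arcs[arcs$from != bwd & arcs$to != bwd, , drop = FALSE]
        fa <- arcs[arcs$from == fwd | arcs$to == fwd, , drop = FALSE]
        if (nrow(fa)) {
          mirror <- data.frame(
            from = ifelse(fa$from == fwd, fa$to, bwd),
            to = ifelse(fa$from == fwd, bwd, fa$from),
            weight = fa$weight, stringsAsFactors = FALSE)
          arcs <- rbind(arcs, mirror)
        }
        reverse_of[fwd] <- bwd
        reverse_of[bwd] <- fwd
      }
      arcs <- arcs[!duplicated(paste(arcs$from, arcs$to)), , drop = FALSE]
    }

    # mirroring may have orphaned vertices; reconnect deterministically by
    # joining any two components through an opposite-type vertex pair (one
    # always exists while both vertex types are present)
    repeat {
      comp <- connected_components(ids, arcs)
      if (max(comp) == 1L) break
      u <- NA_integer_; v <- NA_integer_
      for (cand_v in seq_along(ids)) {
        w <- which(type != type[cand_v] & comp != comp[cand_v])
        if (length(w)) { v <- cand_v; u <- w[1]; break }
      }
      stopifnot(!is.na(u))
      p_id <- if (type[v] == "p") ids[v] else ids[u]
      t_id <- if (type[v] == "p") ids[u] else ids[v]
      pair <- if (!any(arcs$from == p_id & arcs$to == t_id))
        c(p_id, t_id) else c(t_id, p_id)
      arcs <- rbind(arcs, data.frame(from = pair[1], to = pair[2],
                                     weight = 1))
      arcs <- arcs[!duplicated(paste(arcs$from, arcs$to)), , drop = FALSE]
    }

    petri_net(
      places = data.frame(id = pids, stringsAsFactors = FALSE),
      transitions = data.frame(id = tids, reverse_of = unname(reverse_of),
                               stringsAsFactors = FALSE),
      arcs = arcs)
  })
}

# undirected connected components over the vertex id vector; returns integer
# component label per vertex (1 = component of the first vertex)
connected_components <- function(ids, arcs) {
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(arcs)) {
    for (k in seq_len(nrow(arcs))) {
      a <- find(idx[[arcs$from[k]]]); b <- find(idx[[arcs$to[k]]])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(c(roots[1], roots)))
}
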