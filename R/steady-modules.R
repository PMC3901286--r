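#' Maximal common transition sets (MCT-sets)
#'
#' Groups transitions that occur in exactly the same t-invariants: two
#' reactions belong to the same MCT-set when their binary occurrence
#' patterns across all invariants are identical, so each set is either
#' contained in or disjoint from the support of every invariant.  MCT-sets
#' partition the covered transitions into disjoint building blocks;
#' transitions occurring in no invariant are reported as a separate flagged
#' group.
#'
#' @param invariants a `pn_invariants` matrix of kind "t" (rows =
#'   invariants, columns = transitions), see [t_invariants()].
#' @return Object of class `mct_sets`: list of lists with elements
#'   `transitions` (ids) and `pattern` (binary occurrence vector across
#'   invariants), plus attribute `uncovered` with the flagged extra group.
#' @examples
#' mct_sets(t_invariants(potato_net()))
#' @export
mct_sets <- function(invariants) {
  if (!is.matrix(invariants) || nrow(invariants) == 0L)
    stop("at least one t-invariant is required", call. = FALSE)
  occ <- invariants != 0                      # rows invariants x cols trans
  covered <- colnames(invariants)[colSums(occ) > 0]
  uncovered <- setdiff(colnames(invariants), covered)
  key <- apply(occ[, covered, drop = FALSE], 2, paste, collapse = "")
  groups <- split(covered, key)
  # deterministic order: by first member's column position
  pos <- vapply(groups, function(g) match(g[1], colnames(invariants)),
                integer(1))
  groups <- groups[order(pos)]
  sets <- lapply(groups, function(g)
    list(transitions = g,
         pattern = as.integer(occ[, g[1]])))
  structure(unname(sets), uncovered = uncovered, class = "mct_sets")
}

#' @export
print.mct_sets <- function(x, ...) {
  cat(sprintf("%d MCT-set%s\n", length(x), if (length(x) == 1) "" else "s"))
  for (i in seq_along(x))
    cat(sprintf("  %d: {%s}  pattern %s\n", i,
                paste(x[[i]]$transitions, collapse = ", "),
                paste(x[[i]]$pattern, collapse = "")))
  unc <- attr(x, "uncovered")
  if (length(unc))
    cat("  uncovered (no invariant):", paste(unc, collapse = ", "), "\n")
  invisible(x)
}

#' Tanimoto distance between invariant supports
#'
#' Similarity of two t-invariants is the Tanimoto (Jaccard) coefficient of
#' their supports, `|X & Y| / |X | Y|`; the dissimilarity is one minus
#' that, lying in \[0, 1\].
#'
#' @param x,y nonnegative coefficient vectors over the same transitions.
#' @return A number in \[0, 1\].
#' @examples
#' tis <- t_invariants(potato_net())
#' tanimoto_distance(tis[1, ], tis[2, ])   # 1 - 1/9
#' @export
tanimoto_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must share the transition universe", call. = FALSE)
  sx <- x != 0; sy <- y != 0
  un <- sum(sx | sy)
  if (un == 0) stop("both supports are empty", call. = FALSE)
  1 - sum(sx & sy) / un
}

#' @rdname tanimoto_distance
#' @param invariants a `pn_invariants` matrix.
#' @return `invariant_distance_matrix()`: symmetric matrix of pairwise
#'   Tanimoto distances over the invariants.
#' @export
invariant_distance_matrix <- function(invariants) {
  S <- invariants != 0
  inter <- S %*% t(S)
  sz <- rowSums(S)
  un <- outer(sz, sz, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  dimnames(d) <- list(rownames(invariants), rownames(invariants))
  d
}

#' Hierarchical clustering of t-invariants (t-clusters)
#'
#' Builds overlapping functional modules by agglomerative clustering of the
#' t-invariants under the Tanimoto support distance, with UPGMA (average
#' linkage) or neighbor joining.  The UPGMA tree is cut with
#' [stats::cutree()]; the unrooted NJ tree is cut by repeatedly removing
#' its longest branch until the tips fall into `k` connected components.
#' When `k` is not given it is chosen to maximize the average silhouette
#' width over `k = 2 .. min(10, n - 1)` (first maximum wins).
#'
#' @param d distance matrix over invariants (from
#'   [invariant_distance_matrix()]) or a `dist`.
#' @param method `"upgma"` (default) or `"nj"` (needs n >= 4).
#' @param k number of clusters, or `NULL` to pick by silhouette.
#' @return Object of class `t_clustering`: list with `assignment` (named
#'   integer vector), `k`, `method`, `tree` (`hclust` or `phylo`) and
#'   `silhouette`.
#' @examples
#' tis <- t_invariants(potato_net())
#' cluster_t_invariants(invariant_distance_matrix(tis), k = 2)
#' @export
cluster_t_invariants <- function(d, method = c("upgma", "nj"), k = NULL) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 invariants to cluster", call. = FALSE)
  if (is.null(rownames(d))) dimnames(d) <- list(paste0("inv", 1:n),
                                                paste0("inv", 1:n))
  if (!is.null(k) && (!is_count(k, 1) || k > n))
    stop("k must lie in 1..n", call. = FALSE)

  tree <- if (method == "upgma") {
    stats::hclust(stats::as.dist(d), method = "average")
  } else {
    if (n < 4) stop("neighbor joining needs at least 4 invariants",
                    call. = FALSE)
    ape::nj(stats::as.dist(d))
  }
  cut_k <- function(kk) {
    if (kk == 1) return(stats::setNames(rep(1L, n), rownames(d)))
    if (method == "upgma") stats::cutree(tree, k = kk)
    else cut_nj_tree(tree, kk)[rownames(d)]
  }
  if (is.null(k)) {
    ks <- 2:min(10, n - 1)
    if (length(ks) == 0 || n == 2) {
      k <- min(2L, n)
    } else {
      sil <- vapply(ks, function(kk)
        silhouette_width(cut_k(kk), d), numeric(1))
      k <- ks[which.max(sil)]
    }
  }
  assignment <- cut_k(k)
  assignment <- relabel_first_appearance(assignment)
  sw <- if (k >= 2) silhouette_width(assignment, d) else NA_real_
  structure(list(assignment = assignment, k = as.integer(k),
                 method = method, tree = tree, silhouette = sw),
            class = "t_clustering")
}

# cut an unrooted phylo tree into k tip clusters by removing the longest
# branches (ties by edge index) until the tips split into k components
cut_nj_tree <- function(tree, k) {
  nt <- length(tree$tip.label)
  edges <- tree$edge
  ord <- order(-tree$edge.length, seq_len(nrow(edges)))
  n_nodes <- max(edges)
  removed <- 0L
  repeat {
    keep <- if (removed == 0L) seq_len(nrow(edges))
            else seq_len(nrow(edges))[-ord[seq_len(removed)]]
    comp <- components_from_edges(n_nodes, edges[keep, , drop = FALSE])
    tipc <- comp[seq_len(nt)]
    if (length(unique(tipc)) >= k || removed == nrow(edges)) break
    removed <- removed + 1L
  }
  stats::setNames(match(tipc, unique(tipc)), tree$tip.label)
}

components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

relabel_first_appearance <- function(a) {
  stats::setNames(match(a, unique(a)), names(a))
}

#' @export
print.t_clustering <- function(x, ...) {
  cat(sprintf("t-clustering (%s): k = %d, mean silhouette = %s\n",
              toupper(x$method), x$k,
              if (is.na(x$silhouette)) "NA" else
                format(round(x$silhouette, 4))))
  for (c in seq_len(x$k))
    cat(sprintf("  cluster %d: %s\n", c,
                paste(names(x$assignment)[x$assignment == c],
                      collapse = ", ")))
  invisible(x)
}

#' Average silhouette width of a clustering
#'
#' For each sample the silhouette value is `(b - a) / max(a, b)` where `a`
#' is its mean distance to the other members of its own cluster and `b` the
#' mean distance to the nearest other cluster; members of singleton
#' clusters contribute 0 by convention.  The average over all samples lies
#' in \[-1, 1\] and scores how well the partition matches the distances.
#'
#' @param assignment integer cluster labels (named or in matrix order).
#' @param d symmetric distance matrix.
#' @return Mean silhouette value.
#' @export
silhouette_width <- function(assignment, d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is.null(names(assignment)) && !is.null(rownames(d)))
    assignment <- assignment[rownames(d)]
  labs <- unique(assignment)
  if (length(labs) < 2) stop("silhouette needs k >= 2", call. = FALSE)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(labs, assignment[i]), function(l)
      mean(d[i, assignment == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Enzyme subsets
#'
#' Groups reactions that always operate together in fixed flux proportions:
#' two covered transitions belong to the same enzyme subset when their
#' coefficient vectors across all t-invariants are proportional (tested by
#' exact integer reduction, never floating ratios).  Each subset reports the
#' smallest integer vector of the members' relative fluxes.  Enzyme subsets
#' refine MCT-sets, since proportional vectors share their zero pattern.
#'
#' @param invariants a `pn_invariants` matrix of kind "t".
#' @return Object of class `enzyme_subsets`: list of lists with
#'   `transitions` and `ratio` (named integer vector, gcd 1).
#' @examples
#' enzyme_subsets(t_invariants(potato_net()))
#' @export
enzyme_subsets <- function(invariants) {
  if (!is.matrix(invariants) || nrow(invariants) == 0L)
    stop("at least one t-invariant is required", call. = FALSE)
  covered <- colnames(invariants)[colSums(invariants != 0) > 0]
  # proportional nonnegative integer vectors reduce to the same primitive
  key <- vapply(covered, function(t) {
    v <- invariants[, t]
    paste(v / gcdv(v), collapse = ",")
  }, character(1))
  groups <- split(covered, key)
  pos <- vapply(groups, function(g) match(g[1], colnames(invariants)),
                integer(1))
  groups <- groups[order(pos)]
  sets <- lapply(groups, function(g) {
    # relative fluxes: coefficients within any invariant containing g
    i <- which(invariants[, g[1]] != 0)[1]
    r <- invariants[i, g]
    list(transitions = g,
         ratio = stats::setNames(as.integer(r / gcdv(r)), g))
  })
  structure(unname(sets), class = "enzyme_subsets")
}

#' @export
print.enzyme_subsets <- function(x, ...) {
  cat(sprintf("%d enzyme subset%s\n", length(x),
              if (length(x) == 1) "" else "s"))
  for (i in seq_along(x))
    cat(sprintf("  %d: {%s}  ratio (%s)\n", i,
                paste(x[[i]]$transitions, collapse = ", "),
                paste(x[[i]]$ratio, collapse = ":")))
  invisible(x)
}

#' Minimal cut sets for an objective reaction
#'
#' A minimal cut set is an inclusion-minimal set of reactions whose removal
#' blocks every steady-state flux through the objective reaction, i.e. a
#' minimal hitting set of the supports of all t-invariants that contain the
#' objective.  Computed by exhaustive enumeration with subset pruning,
#' appropriate at didactic scale; the number of relevant invariants is
#' guarded by `max_relevant`.
#'
#' @param invariants a `pn_invariants` matrix of kind "t".
#' @param objective transition id to block.
#' @param include_objective may the objective itself appear in cut sets?
#'   Default `FALSE`.
#' @param max_relevant abort when more invariants than this contain the
#'   objective (default 20).
#' @return Object of class `cut_sets`: list of character vectors sorted by
#'   size then lexicographically (transition order of the net); attribute
#'   `status` is `"ok"` or `"already blocked"` when no invariant contains
#'   the objective.
#' @examples
#' minimal_cut_sets(t_invariants(potato_net()), "glycolysis")
#' @export
minimal_cut_sets <- function(invariants, objective,
                             include_objective = FALSE, max_relevant = 20) {
  universe <- colnames(invariants)
  if (!objective %in% universe)
    stop("objective '", objective, "' is not a transition of the net",
         call. = FALSE)
  supports <- invariant_support(invariants)
  relevant <- Filter(function(s) objective %in% s, supports)
  if (length(relevant) == 0L)
    return(structure(list(), status = "already blocked",
                     objective = objective, class = "cut_sets"))
  if (length(relevant) > max_relevant)
    stop("instance guard: ", length(relevant),
         " invariants contain the objective (limit ", max_relevant, ")",
         call. = FALSE)
  cand <- Reduce(union, relevant)
  if (!include_objective) cand <- setdiff(cand, objective)
  cand <- cand[order(match(cand, universe))]   # net transition order
  hits_all <- function(set) all(vapply(relevant, function(s)
    length(intersect(set, s)) > 0, logical(1)))
  found <- list()
  for (size in seq_along(cand)) {
    if (length(cand) < size) break
    combos <- utils::combn(cand, size, simplify = FALSE)
    for (s in combos) {
      if (any(vapply(found, function(f) all(f %in% s), logical(1))))
        next                      # contains a smaller cut set: not minimal
      if (hits_all(s)) found <- c(found, list(s))
    }
  }
  ord <- order(lengths(found),
               vapply(found, function(s)
                 paste(sprintf("%04d", match(s, universe)), collapse = ","),
                 character(1)))
  structure(found[ord], status = "ok", objective = objective,
            class = "cut_sets")
}

#' @export
print.cut_sets <- function(x, ...) {
  if (identical(attr(x, "status"), "already blocked")) {
    cat(sprintf("objective '%s' occurs in no t-invariant: already blocked\n",
                attr(x, "objective")))
    return(invisible(x))
  }
  cat(sprintf("%d minimal cut set%s for objective '%s'\n", length(x),
              if (length(x) == 1) "" else "s", attr(x, "objective")))
  for (i in seq_along(x))
    cat(sprintf("  {%s}\n", paste(x[[i]], collapse = ", ")))
  invisible(x)
}
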