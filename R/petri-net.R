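#' Construct a place/transition Petri net
#'
#' A Petri net is a directed bipartite graph with passive vertices (places,
#' here: metabolites) and active vertices (transitions, here: reactions),
#' connected by integer-weighted arcs.  Arc weights are stoichiometric
#' coefficients; an arc never connects two vertices of the same type.
#'
#' @param places data.frame with columns `id` (unique token), and optionally
#'   `name` (free text, defaults to `id`), `initial_tokens` (nonnegative
#'   integer, default 0), `capacity` (positive integer or `Inf`, default
#'   `Inf`), `is_logical` (layout fusion flag, no semantic effect, default
#'   `FALSE`).
#' @param transitions data.frame with columns `id`, and optionally `name`
#'   (enzyme name, defaults to `id`) and `reverse_of` (id of the paired
#'   backward transition, `NA` if none; must be symmetric).
#' @param arcs data.frame with columns `from`, `to` (vertex ids of different
#'   types) and optionally `weight` (positive integer, default 1).  At most
#'   one arc per ordered (from, to) pair; a place appearing on both sides of
#'   one transition (a read arc) is simply two arcs.
#' @return An object of class `petri_net`.
#' @examples
#' net <- petri_net(
#'   places      = data.frame(id = c("A", "B")),
#'   transitions = data.frame(id = "r"),
#'   arcs        = data.frame(from = "A", to = "r", weight = 2)
#' )
#' net
#' @export
petri_net <- function(places, transitions, arcs = NULL) {
  places <- as.data.frame(places, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (is.null(arcs) || nrow(as.data.frame(arcs)) == 0L) {
    arcs <- data.frame(from = character(), to = character(),
                       weight = numeric(), stringsAsFactors = FALSE)
  } else {
    arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  }

  if (!"id" %in% names(places) || !"id" %in% names(transitions))
    stop("places and transitions need an 'id' column", call. = FALSE)
  places$id <- as.character(places$id)
  transitions$id <- as.character(transitions$id)
  if (is.null(places$name)) places$name <- places$id
  if (is.null(places$initial_tokens)) places$initial_tokens <- 0
  if (is.null(places$capacity)) places$capacity <- Inf
  if (is.null(places$is_logical)) places$is_logical <- FALSE
  if (is.null(transitions$name)) transitions$name <- transitions$id
  if (is.null(transitions$reverse_of)) transitions$reverse_of <- NA_character_
  transitions$reverse_of <- as.character(transitions$reverse_of)
  if (!"weight" %in% names(arcs)) arcs$weight <- rep(1, nrow(arcs))
  arcs$from <- as.character(arcs$from)
  arcs$to <- as.character(arcs$to)
  arcs$weight <- as.numeric(arcs$weight)

  net <- structure(
    list(places = places[, c("id", "name", "initial_tokens", "capacity",
                             "is_logical")],
         transitions = transitions[, c("id", "name", "reverse_of")],
         arcs = arcs[, c("from", "to", "weight")]),
    class = "petri_net")
  validate_petri_net(net)
  net
}

#' Validate a Petri net
#'
#' Checks id uniqueness, bipartiteness of the arc set, positive integer
#' stoichiometry, symmetric `reverse_of` links, and capacity/marking sanity.
#' Called by [petri_net()]; exported because parsers reuse it.
#'
#' @param net a `petri_net`.
#' @return `net`, invisibly, or an error.
#' @export
validate_petri_net <- function(net) {
  p <- net$places; t <- net$transitions; a <- net$arcs
  ids <- c(p$id, t$id)
  if (anyDuplicated(ids))
    stop("vertex ids must be unique across places and transitions: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(is.na(p$initial_tokens)) || any(p$initial_tokens < 0) ||
      !all_integral(p$initial_tokens))
    stop("initial_tokens must be nonnegative integers", call. = FALSE)
  bounded <- is.finite(p$capacity)
  if (any(p$capacity[bounded] < 1) || !all(p$capacity[bounded] ==
                                           floor(p$capacity[bounded])))
    stop("bounded capacities must be positive integers", call. = FALSE)
  if (nrow(a) > 0) {
    if (any(!is.finite(a$weight)) || any(a$weight < 1) ||
        !all(a$weight == floor(a$weight)))
      stop("arc weights must be positive integers; pre-scale rational ",
           "stoichiometries to integers first", call. = FALSE)
    from_p <- a$from %in% p$id
    from_t <- a$from %in% t$id
    to_p <- a$to %in% p$id
    to_t <- a$to %in% t$id
    if (any(!(from_p | from_t)) || any(!(to_p | to_t)))
      stop("arc endpoint not a vertex of the net: ",
           paste(setdiff(c(a$from, a$to), ids), collapse = ", "),
           call. = FALSE)
    same_type <- (from_p & to_p) | (from_t & to_t)
    if (any(same_type))
      stop("arcs must connect vertices of different types (bipartiteness); ",
           "offending arc: ", a$from[same_type][1], " -> ",
           a$to[same_type][1], call. = FALSE)
    if (anyDuplicated(paste(a$from, a$to)))
      stop("at most one arc per ordered (from, to) pair", call. = FALSE)
  }
  rev <- t$reverse_of
  has_rev <- !is.na(rev)
  if (any(has_rev)) {
    if (!all(rev[has_rev] %in% t$id))
      stop("reverse_of refers to unknown transition", call. = FALSE)
    back <- stats::setNames(t$reverse_of, t$id)
    bad <- t$id[has_rev][back[rev[has_rev]] != t$id[has_rev]]
    if (length(bad))
      stop("reverse_of must be symmetric; broken at: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(net)
}

#' @export
print.petri_net <- function(x, ...) {
  cat(sprintf("Petri net: %d places, %d transitions, %d arcs\n",
              nrow(x$places), nrow(x$transitions), nrow(x$arcs)))
  nrev <- sum(!is.na(x$transitions$reverse_of)) / 2
  if (nrev > 0) cat(sprintf("  reversible reaction pairs: %d\n", nrev))
  cat("  places:      ", paste(utils::head(x$places$id, 8), collapse = ", "),
      if (nrow(x$places) > 8) ", ..." else "", "\n", sep = "")
  cat("  transitions: ",
      paste(utils::head(x$transitions$id, 8), collapse = ", "),
      if (nrow(x$transitions) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

place_ids <- function(net) net$places$id
transition_ids <- function(net) net$transitions$id

# arcs split by orientation relative to one transition
pre_arcs <- function(net, t_id) net$arcs[net$arcs$to == t_id, , drop = FALSE]
post_arcs <- function(net, t_id) net$arcs[net$arcs$from == t_id, , drop = FALSE]

#' Incidence (stoichiometric) matrix of a Petri net
#'
#' Entry `[p, t]` is the net token change of place `p` when transition `t`
#' fires once: weight of the arc t->p minus weight of the arc p->t.  Row and
#' column order follow the net's place/transition order.
#'
#' @param net a `petri_net`.
#' @return Integer-valued matrix with one row per place, one column per
#'   transition, dimnames set to the ids.
#' @examples
#' incidence_matrix(potato_net())["sucrose", ]
#' @export
incidence_matrix <- function(net) {
  P <- place_ids(net)
  Tt <- transition_ids(net)
  C <- matrix(0, nrow = length(P), ncol = length(Tt),
              dimnames = list(P, Tt))
  a <- net$arcs
  if (nrow(a)) {
    tp <- a$from %in% Tt      # transition -> place: production
    if (any(tp))
      C[cbind(a$to[tp], a$from[tp])] <-
        C[cbind(a$to[tp], a$from[tp])] + a$weight[tp]
    pt <- !tp                 # place -> transition: consumption
    if (any(pt))
      C[cbind(a$from[pt], a$to[pt])] <-
        C[cbind(a$from[pt], a$to[pt])] - a$weight[pt]
  }
  C
}

#' Markings (system states)
#'
#' A marking assigns a nonnegative token count to every place.  `marking()`
#' builds one from the net's `initial_tokens`, overridden by named values.
#'
#' @param net a `petri_net`.
#' @param ... named token counts overriding the defaults, e.g. `glucose = 1`.
#' @return Named numeric vector over all places.
#' @examples
#' marking(potato_net(), glucose = 1, ATP = 3)
#' @export
marking <- function(net, ...) {
  m <- stats::setNames(as.numeric(net$places$initial_tokens),
                       net$places$id)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("marking overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(m))
    if (length(unknown))
      stop("not a place of the net: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    m[names(over)] <- as.numeric(unlist(over))
  }
  if (any(m < 0) || !all_integral(m))
    stop("token counts must be nonnegative integers", call. = FALSE)
  cap <- stats::setNames(net$places$capacity, net$places$id)
  if (any(m > cap))
    stop("marking exceeds place capacity", call. = FALSE)
  m
}

# normalize a user-supplied marking (full or partial named vector) to the
# net's place order
as_marking <- function(net, m) {
  if (is.null(names(m))) {
    if (length(m) != nrow(net$places))
      stop("unnamed marking must cover all places", call. = FALSE)
    return(stats::setNames(as.numeric(m), net$places$id))
  }
  out <- stats::setNames(numeric(nrow(net$places)), net$places$id)
  unknown <- setdiff(names(m), names(out))
  if (length(unknown))
    stop("marking names not places of the net: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out[names(m)] <- as.numeric(m)
  out
}

#' Firing semantics
#'
#' A transition is enabled under a marking when every pre-place holds at
#' least the arc weight in tokens and every post-place can absorb the
#' produced tokens within its capacity.  `fire()` consumes and produces
#' tokens accordingly and returns the new marking; firing a transition that
#' is not enabled is an error of class `pn_not_enabled`.
#'
#' @param net a `petri_net`.
#' @param m a marking (named vector; missing places count 0).
#' @param transition a transition id.
#' @return `is_enabled()`: a logical; `fire()`: the new marking.
#' @examples
#' net <- potato_net()
#' m <- marking(net, glucose = 1, ATP = 3)
#' is_enabled(net, m, "hexokinase")
#' fire(net, m, "hexokinase")
#' @export
is_enabled <- function(net, m, transition) {
  if (!transition %in% transition_ids(net))
    stop("unknown transition id: ", transition, call. = FALSE)
  m <- as_marking(net, m)
  pre <- pre_arcs(net, transition)
  post <- post_arcs(net, transition)
  if (nrow(pre) && any(m[pre$from] < pre$weight)) return(FALSE)
  # capacity: tokens after consuming and producing must fit
  m2 <- m
  if (nrow(pre)) m2[pre$from] <- m2[pre$from] - pre$weight
  if (nrow(post)) m2[post$to] <- m2[post$to] + post$weight
  cap <- stats::setNames(net$places$capacity, net$places$id)
  all(m2 <= cap)
}

#' @rdname is_enabled
#' @export
fire <- function(net, m, transition) {
  if (!is_enabled(net, m, transition)) {
    cond <- structure(
      class = c("pn_not_enabled", "error", "condition"),
      list(message = paste0("transition '", transition,
                            "' is not enabled under this marking"),
           call = sys.call(-1)))
    stop(cond)
  }
  m <- as_marking(net, m)
  pre <- pre_arcs(net, transition)
  post <- post_arcs(net, transition)
  if (nrow(pre)) m[pre$from] <- m[pre$from] - pre$weight
  if (nrow(post)) m[post$to] <- m[post$to] + post$weight
  m
}

#' Token change of a firing-count (Parikh) vector
#'
#' Computes `C %*% tau`: the signed token change per place produced by firing
#' each transition the number of times given in `tau`, irrespective of
#' enabledness and ordering.
#'
#' @param C an incidence matrix (from [incidence_matrix()] or a labelled
#'   integer matrix).
#' @param tau named nonnegative counts per transition (missing ids count 0),
#'   or an unnamed vector in column order.
#' @return Named numeric vector over places.
#' @examples
#' C <- incidence_matrix(potato_net())
#' parikh_effect(C, c(PGI_f = 1, PGI_b = 1))   # a t-invariant: all zero
#' @export
parikh_effect <- function(C, tau) {
  if (is.null(names(tau))) {
    if (length(tau) != ncol(C))
      stop("dimension mismatch: need one count per transition",
           call. = FALSE)
    v <- as.numeric(tau)
  } else {
    unknown <- setdiff(names(tau), colnames(C))
    if (length(unknown))
      stop("unknown transitions in Parikh vector: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    v <- stats::setNames(numeric(ncol(C)), colnames(C))
    v[names(tau)] <- as.numeric(tau)
  }
  if (any(v < 0)) stop("Parikh counts must be nonnegative", call. = FALSE)
  drop(C %*% v)
}
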