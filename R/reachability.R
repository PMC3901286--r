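#' Bounded breadth-first reachability graph
#'
#' Explores the state space of a net from an initial marking: states are
#' markings, edges are single transition firings.  Exploration is
#' breadth-first; among simultaneously enabled transitions the queue order
#' follows the net's transition order, which affects state numbering only.
#' Because even small metabolic nets can have an enormous (or infinite)
#' state space, exploration stops after `max_states` distinct states have
#' been stored and sets `truncated = TRUE` instead of looping forever.
#'
#' @param net a `petri_net`.
#' @param initial initial marking (named vector, see [marking()]).
#' @param max_states maximum number of distinct states to store (default
#'   1e6).
#' @return Object of class `state_graph`: list with `states` (list of
#'   markings, element 1 = initial), `edges` (data.frame `from`,
#'   `transition`, `to` of state indices and the fired transition),
#'   `truncated`, `initial = 1`.
#' @examples
#' net <- potato_net()
#' g <- reachability_graph(net, marking(net, F6P = 1, ADP = 29),
#'                         max_states = 50)
#' nrow(g$edges)
#' @export
reachability_graph <- function(net, initial, max_states = 1e6) {
  if (!is_count(max_states, 1))
    stop("max_states must be a positive integer", call. = FALSE)
  initial <- as_marking(net, initial)
  tids <- transition_ids(net)
  key <- function(m) paste(m, collapse = ",")

  states <- list(initial)
  index <- new.env(parent = emptyenv())
  assign(key(initial), 1L, envir = index)
  edges_from <- integer(0); edges_t <- character(0); edges_to <- integer(0)
  queue <- 1L
  truncated <- FALSE

  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    m <- states[[i]]
    for (t in tids) {
      if (!is_enabled(net, m, t)) next
      m2 <- fire(net, m, t)
      k <- key(m2)
      j <- index[[k]]
      if (is.null(j)) {
        if (length(states) >= max_states) {
          truncated <- TRUE
          next
        }
        states[[length(states) + 1L]] <- m2
        j <- length(states)
        assign(k, j, envir = index)
        queue <- c(queue, j)
      }
      edges_from <- c(edges_from, i)
      edges_t <- c(edges_t, t)
      edges_to <- c(edges_to, j)
    }
  }
  if (truncated)
    message("state space truncated at ", max_states, " states")
  structure(list(states = states,
                 edges = data.frame(from = edges_from,
                                    transition = edges_t,
                                    to = edges_to,
                                    stringsAsFactors = FALSE),
                 truncated = truncated, initial = 1L),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat(sprintf("reachability graph: %d states, %d edges%s\n",
              length(x$states), nrow(x$edges),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Export a state graph
#'
#' `write_state_graph_tsv()` writes the edge list as TSV (state indices and
#' fired transition); `state_graph_dot()` renders GraphViz text with
#' markings as vertex labels.
#'
#' @param g a `state_graph`.
#' @param path output file path.
#' @return `path` invisibly, or the GraphViz text.
#' @export
write_state_graph_tsv <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_graph_tsv
#' @export
state_graph_dot <- function(g) {
  lab <- vapply(g$states, function(m) {
    nz <- m[m != 0]
    if (!length(nz)) "0" else
      paste(paste0(names(nz), "=", nz), collapse = ",")
  }, character(1))
  lines <- c("digraph RG {",
             sprintf('  s%d [label="%s"];', seq_along(g$states), lab),
             sprintf('  s%d -> s%d [label="%s"];',
                     g$edges$from, g$edges$to, g$edges$transition),
             "}")
  paste(lines, collapse = "\n")
}
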