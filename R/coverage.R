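#' Coverage by invariants (CTI / CPI)
#'
#' A net is covered by t-invariants (CTI) when every transition belongs to
#' the support of at least one minimal t-invariant; CTI is a completeness
#' condition used to verify metabolic models, since a reaction outside every
#' steady-state mode cannot be compensated and points to a modelling error.
#' Analogously a net is covered by p-invariants (CPI) when every place lies
#' in some conservation relation.
#'
#' @param net a `petri_net`.
#' @param invariants optionally, invariants already computed by
#'   [t_invariants()] / [p_invariants()]; computed on demand otherwise.
#' @param row_cap tableau cap forwarded to the solver.
#' @return An object of class `pn_coverage`: list with `covered`,
#'   `uncovered` (character vectors of ids) and `is_cti` (or `is_cpi`).
#' @examples
#' cti_check(potato_net())   # covered
#' cpi_check(potato_net())   # only the ADP/ATP pool is conserved
#' @export
cti_check <- function(net, invariants = NULL, row_cap = 2e5) {
  ids <- transition_ids(net)
  if (is.null(invariants)) invariants <- t_invariants(net, row_cap = row_cap)
  stopifnot(identical(attr(invariants, "kind"), "t"))
  covered <- ids[colSums(invariants[, ids, drop = FALSE] != 0) > 0]
  uncovered <- setdiff(ids, covered)
  structure(list(kind = "t", covered = covered, uncovered = uncovered,
                 is_cti = length(uncovered) == 0L),
            class = "pn_coverage")
}

#' @rdname cti_check
#' @export
cpi_check <- function(net, invariants = NULL, row_cap = 2e5) {
  ids <- place_ids(net)
  if (is.null(invariants)) invariants <- p_invariants(net, row_cap = row_cap)
  stopifnot(identical(attr(invariants, "kind"), "p"))
  covered <- ids[colSums(invariants[, ids, drop = FALSE] != 0) > 0]
  uncovered <- setdiff(ids, covered)
  structure(list(kind = "p", covered = covered, uncovered = uncovered,
                 is_cpi = length(uncovered) == 0L),
            class = "pn_coverage")
}

#' @export
print.pn_coverage <- function(x, ...) {
  flag <- if (x$kind == "t") x$is_cti else x$is_cpi
  cat(sprintf("%s coverage: %s (%d covered, %d uncovered)\n",
              if (x$kind == "t") "t-invariant (CTI)" else "p-invariant (CPI)",
              if (flag) "complete" else "incomplete",
              length(x$covered), length(x$uncovered)))
  if (length(x$uncovered))
    cat("  uncovered:", paste(x$uncovered, collapse = ", "), "\n")
  invisible(x)
}

#' Uncovered reactions via the Farkas dual system
#'
#' Decides which reactions lie outside every t-invariant without using the
#' t-invariants themselves.  By the Lemma of Farkas, a reaction is uncovered
#' exactly when a separating hyperplane with surface normal `s` exists such
#' that `t(C) s >= 0` with strict inequality at that reaction.  Writing the
#' slack as nu, the system becomes `t(C) s - nu = 0` with `nu >= 0`; the
#' signed normal is split `s = u - v` with `u, v >= 0` so the same
#' nonnegative Fourier-Motzkin engine applies.  Transitions with `nu > 0` in
#' some minimal solution are exactly the uncovered set of [cti_check()];
#' solutions with `nu = 0` (and `s != 0`) are p-invariants and are returned
#' as an attribute.
#'
#' @param C an incidence matrix (or a `petri_net`).
#' @param row_cap tableau cap, see [fm_tableau()].
#' @return Character vector of uncovered transition ids (empty when CTI),
#'   with attribute `p_invariants`: matrix of the signed `nu = 0` solutions
#'   over places.
#' @examples
#' farkas_uncovered(potato_net())   # character(0): the net is CTI
#' @export
farkas_uncovered <- function(C, row_cap = 2e5) {
  if (inherits(C, "petri_net")) C <- incidence_matrix(C)
  C <- as.matrix(C)
  np <- nrow(C); nt <- ncol(C)
  pl <- rownames(C) %||% paste0("p", seq_len(np))
  tr <- colnames(C) %||% paste0("t", seq_len(nt))
  # equations (one per transition): t(C) u - t(C) v - nu = 0
  M <- cbind(t(C), -t(C), -diag(nt))
  colnames(M) <- c(paste0("u.", pl), paste0("v.", pl), paste0("nu.", tr))
  sols <- fm_solutions(M, row_cap = row_cap)
  nu <- sols[, paste0("nu.", tr), drop = FALSE]
  uncovered <- tr[colSums(nu != 0) > 0]
  s <- sols[, paste0("u.", pl), drop = FALSE] -
    sols[, paste0("v.", pl), drop = FALSE]
  colnames(s) <- pl
  pis <- s[rowSums(nu != 0) == 0 & rowSums(s != 0) > 0, , drop = FALSE]
  structure(uncovered, p_invariants = pis)
}
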