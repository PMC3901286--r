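#' Fourier-Motzkin tableau for minimal nonnegative integer solutions
#'
#' The tableau solves `M x = 0` for minimal-support, gcd-normalized,
#' nonnegative integer vectors `x` (for `M = C`, the incidence matrix, these
#' are the minimal t-invariants / elementary flux modes).  It starts as the
#' identity over the variables next to the transposed equation system: each
#' row is a candidate firing-count vector (`parikh`) together with its
#' residual effect on the not-yet-eliminated equations (`residual`).
#' [eliminate_place()] zeroes one equation column by combining every
#' positive row with every negative row (scaled by the entries divided by
#' their gcd), removing the contributing rows, and pruning non-minimal
#' candidates; [choose_next_place()] picks the next column by the classical
#' `pos*neg - pos - neg` growth heuristic.  [fm_solutions()] drives the
#' elimination to completion.
#'
#' All arithmetic is exact integer arithmetic in doubles with per-row gcd
#' reduction; an entry exceeding 2^50 aborts rather than losing precision.
#'
#' @param M integer matrix of the equation system (for t-invariants the
#'   incidence matrix `C`: rows = places, columns = transitions).
#' @param row_cap abort with an error of class `fm_tableau_explosion` when
#'   the tableau exceeds this many rows (default 2e5).
#' @return `fm_tableau()` an object of class `fm_tableau`;
#'   `fm_solutions()` a matrix whose rows are the minimal solutions
#'   (columns = variables of `M`), ordered lexicographically by support.
#' @examples
#' C <- incidence_matrix(potato_net())
#' tab <- fm_tableau(C)
#' choose_next_place(tab)
#' fm_solutions(C)
#' @export
fm_tableau <- function(M, row_cap = 2e5) {
  M <- as.matrix(M)
  if (!all_integral(M)) stop("M must be an integer matrix", call. = FALSE)
  storage.mode(M) <- "double"
  vars <- colnames(M) %||% paste0("x", seq_len(ncol(M)))
  eqs <- rownames(M) %||% paste0("e", seq_len(nrow(M)))
  structure(
    list(parikh = structure(diag(ncol(M)), dimnames = list(NULL, vars)),
         residual = structure(t(M), dimnames = list(NULL, eqs)),
         eliminated = character(0),
         row_cap = row_cap),
    class = "fm_tableau")
}

#' @export
print.fm_tableau <- function(x, ...) {
  cat(sprintf(
    "Fourier-Motzkin tableau: %d rows, %d/%d equations eliminated\n",
    nrow(x$parikh), length(x$eliminated), ncol(x$residual)))
  invisible(x)
}

#' @rdname fm_tableau
#' @param tableau an `fm_tableau`.
#' @export
choose_next_place <- function(tableau) {
  open <- setdiff(colnames(tableau$residual), tableau$eliminated)
  if (!length(open)) return(NA_character_)
  score <- vapply(open, function(e) {
    col <- tableau$residual[, e]
    np <- sum(col > 0); nn <- sum(col < 0)
    np * nn - np - nn
  }, numeric(1))
  open[which.min(score)]    # ties: first in matrix order
}

#' @rdname fm_tableau
#' @param place column (equation) id to eliminate next.
#' @export
eliminate_place <- function(tableau, place) {
  if (place %in% tableau$eliminated)
    stop("equation '", place, "' already eliminated", call. = FALSE)
  if (!place %in% colnames(tableau$residual))
    stop("unknown equation column: ", place, call. = FALSE)
  P <- tableau$parikh; R <- tableau$residual
  col <- R[, place]
  pos <- which(col > 0); neg <- which(col < 0); zero <- which(col == 0)

  n_new <- length(pos) * length(neg)
  if (length(zero) + n_new > tableau$row_cap) {
    cond <- structure(
      class = c("fm_tableau_explosion", "error", "condition"),
      list(message = sprintf(
        "tableau explosion: %d rows would exceed the cap of %d",
        length(zero) + n_new, tableau$row_cap),
        call = sys.call(-1), size = length(zero) + n_new))
    stop(cond)
  }

  newP <- matrix(0, n_new, ncol(P), dimnames = dimnames(P))
  newR <- matrix(0, n_new, ncol(R), dimnames = dimnames(R))
  k <- 0L
  for (i in pos) for (j in neg) {
    g <- gcd2(col[i], -col[j])
    ci <- -col[j] / g          # scale for the positive parent
    cj <- col[i] / g           # scale for the negative parent
    k <- k + 1L
    p <- ci * P[i, ] + cj * P[j, ]
    r <- ci * R[i, ] + cj * R[j, ]
    d <- gcdv(p)               # content reduction keeps entries small
    if (d > 1) { p <- p / d; r <- r / d }
    newP[k, ] <- p
    newR[k, ] <- r
  }
  P2 <- rbind(P[zero, , drop = FALSE], newP)
  R2 <- rbind(R[zero, , drop = FALSE], newR)
  if (nrow(P2) && max(abs(P2), abs(R2)) > 2^50)
    stop("integer overflow in Fourier-Motzkin tableau", call. = FALSE)

  keep <- minimal_rows(P2)
  tableau$parikh <- P2[keep, , drop = FALSE]
  tableau$residual <- R2[keep, , drop = FALSE]
  tableau$eliminated <- c(tableau$eliminated, place)
  tableau
}

# indices of rows that survive the minimality test: drop exact duplicates and
# rows whose support strictly contains another row's support
minimal_rows <- function(P) {
  n <- nrow(P)
  if (n <= 1L) return(seq_len(n))
  dup <- duplicated(P)
  idx <- which(!dup)
  S <- P[idx, , drop = FALSE] > 0
  sz <- rowSums(S)
  # overlap[i, j] = |supp(i) /\ supp(j)|; supp(i) subset of supp(j) iff
  # overlap[i, j] == sz[i]
  overlap <- S %*% t(S)
  subset_of <- overlap == sz            # by row i
  strict <- subset_of & outer(sz, sz, "<")
  drop <- apply(strict, 2, any)         # j dominated by some i
  idx[!drop]
}

#' @rdname fm_tableau
#' @export
fm_solutions <- function(M, row_cap = 2e5) {
  tab <- fm_tableau(M, row_cap = row_cap)
  repeat {
    e <- choose_next_place(tab)
    if (is.na(e)) break
    tab <- eliminate_place(tab, e)
  }
  P <- tab$parikh
  if (nrow(P)) {
    stopifnot(all(tab$residual == 0))
    # final gcd normalization (eliminations normalize combined rows already;
    # untouched identity rows are trivially normalized) and minimal filter
    P <- P[minimal_rows(P), , drop = FALSE]
    P <- P[order(apply(P > 0, 1, paste, collapse = "")), , drop = FALSE]
  }
  rownames(P) <- if (nrow(P)) paste0("inv", seq_len(nrow(P))) else NULL
  P
}

#' Minimal t- and p-invariants
#'
#' A t-invariant is a minimal-support, nontrivial, nonnegative integer
#' solution of `C t = 0`: a set of reactions with relative firing counts
#' whose combined effect leaves every metabolite unchanged (an elementary
#' flux mode, a steady-state pathway).  A p-invariant solves the transposed
#' system `t(C) p = 0` and is a weighted set of metabolites whose token sum
#' is conserved under any firing.  Both are computed by Fourier-Motzkin
#' elimination ([fm_solutions()]); the returned sets are complete, support-
#' minimal and gcd-normalized.
#'
#' @param x a `petri_net` or an incidence matrix.
#' @param row_cap tableau row cap, see [fm_tableau()].
#' @return An object of class `pn_invariants`: a matrix with one row per
#'   invariant and one column per transition (kind "t") or place (kind "p"),
#'   with attribute `kind`.
#' @examples
#' t_invariants(potato_net())
#' p_invariants(potato_net())
#' @export
t_invariants <- function(x, row_cap = 2e5) {
  C <- if (inherits(x, "petri_net")) incidence_matrix(x) else as.matrix(x)
  structure(fm_solutions(C, row_cap = row_cap),
            kind = "t", class = c("pn_invariants", "matrix"))
}

#' @rdname t_invariants
#' @export
p_invariants <- function(x, row_cap = 2e5) {
  C <- if (inherits(x, "petri_net")) incidence_matrix(x) else as.matrix(x)
  structure(fm_solutions(t(C), row_cap = row_cap),
            kind = "p", class = c("pn_invariants", "matrix"))
}

#' @export
print.pn_invariants <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("%d minimal %s-invariant%s over %d %s\n",
              nrow(x), kind, if (nrow(x) == 1) "" else "s", ncol(x),
              if (kind == "t") "transitions" else "places"))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    nz <- v[v != 0]
    cat(sprintf("  %s: {%s}\n", rownames(x)[i],
                paste(ifelse(nz > 1, paste0(nz, " ", names(nz)), names(nz)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Support of invariant vectors
#'
#' @param x a `pn_invariants` object or a single nonnegative vector.
#' @return For a matrix, a list of character vectors of nonzero ids per
#'   invariant; for a vector, one character vector.
#' @export
invariant_support <- function(x) {
  if (is.matrix(x))
    lapply(seq_len(nrow(x)), function(i) colnames(x)[x[i, ] != 0])
  else names(x)[x != 0]
}

#' Write invariants as TSV
#'
#' One row per invariant, columns = transition (or place) ids, plus a
#' human-readable report naming members with multiplicities.
#'
#' @param x a `pn_invariants` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_invariants_tsv <- function(x, path) {
  df <- data.frame(invariant = rownames(x) %||% seq_len(nrow(x)),
                   unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_invariants_tsv
#' @export
invariant_report <- function(x) {
  kind <- attr(x, "kind") %||% "t"
  lines <- c(sprintf("%d minimal %s-invariants", nrow(x), kind))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]; nz <- v[v != 0]
    lines <- c(lines, sprintf(
      "%s: %s", rownames(x)[i] %||% i,
      paste(sprintf("%s x%d", names(nz), as.integer(nz)), collapse = ", ")))
  }
  paste(lines, collapse = "\n")
}
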