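#' Detect common transition pairs (CTP)
#'
#' A CTP is the local structure of a place with exactly one pre-transition
#' and one post-transition (and no other arcs): tokens produced on it can
#' only be removed by the single consumer, so the pair acts in a fixed
#' ratio and the place can be contracted away without changing the CTI
#' property.
#'
#' @param net a `petri_net`.
#' @return data.frame with one row per CTP, in place order: `place`, `pre`,
#'   `post` (transition ids), `w_pre` (weight of the producing arc),
#'   `w_post` (weight of the consuming arc), and the contraction
#'   multipliers `mult_pre = w_post/g`, `mult_post = w_pre/g`,
#'   `g = gcd(w_pre, w_post)`.
#' @examples
#' detect_ctps(potato_net())   # sucrose, glucose, fructose, starch
#' @export
detect_ctps <- function(net) {
  out <- data.frame(place = character(), pre = character(),
                    post = character(), w_pre = numeric(),
                    w_post = numeric(), mult_pre = numeric(),
                    mult_post = numeric(), stringsAsFactors = FALSE)
  a <- net$arcs
  for (p in place_ids(net)) {
    inc <- a[a$to == p, , drop = FALSE]     # producing arc(s) t -> p
    outg <- a[a$from == p, , drop = FALSE]  # consuming arc(s) p -> t
    if (nrow(inc) == 1L && nrow(outg) == 1L && inc$from != outg$to) {
      g <- gcd2(inc$weight, outg$weight)
      out <- rbind(out, data.frame(
        place = p, pre = inc$from, post = outg$to,
        w_pre = inc$weight, w_post = outg$weight,
        mult_pre = outg$weight / g, mult_post = inc$weight / g,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Detect invariant transition pairs (ITP)
#'
#' An ITP is a reversible reaction: a forward and a backward transition
#' whose arcs are exact mirrors with equal weights.  Pairs are found via
#' `reverse_of` metadata when present and by structural mirror detection
#' otherwise; each pair is reported once (forward = earlier transition in
#' net order).  The column `fusable` marks pairs whose forward reaction is
#' 1:1 between exactly two places, the only case [reduce_net()] fuses.
#'
#' @param net a `petri_net`.
#' @return data.frame with columns `forward`, `backward`, `fusable`.
#' @examples
#' detect_itps(potato_net())   # the PGI_f / PGI_b pair
#' @export
detect_itps <- function(net) {
  tids <- transition_ids(net)
  arc_sig <- function(t) {
    pre <- pre_arcs(net, t); post <- post_arcs(net, t)
    list(pre = pre[order(pre$from), c("from", "weight"), drop = FALSE],
         post = post[order(post$to), c("to", "weight"), drop = FALSE])
  }
  sigs <- lapply(stats::setNames(tids, tids), arc_sig)
  mirrored <- function(f, b) {
    sf <- sigs[[f]]; sb <- sigs[[b]]
    nrow(sf$pre) == nrow(sb$post) && nrow(sf$post) == nrow(sb$pre) &&
      identical(sf$pre$from, sb$post$to) &&
      identical(sf$pre$weight, sb$post$weight) &&
      identical(sf$post$to, sb$pre$from) &&
      identical(sf$post$weight, sb$pre$weight)
  }
  seen <- character(0)
  rows <- list()
  for (i in seq_along(tids)) {
    f <- tids[i]
    if (f %in% seen) next
    b <- net$transitions$reverse_of[i]
    if (is.na(b)) {
      # structural search among later transitions
      later <- setdiff(tids[-seq_len(i)], seen)
      hit <- later[vapply(later, function(u) mirrored(f, u), logical(1))]
      if (!length(hit)) next
      b <- hit[1]
    }
    if (b %in% seen || !mirrored(f, b)) next
    sf <- sigs[[f]]
    fusable <- nrow(sf$pre) == 1L && nrow(sf$post) == 1L &&
      sf$pre$weight == 1 && sf$post$weight == 1 &&
      sf$pre$from != sf$post$to
    rows[[length(rows) + 1L]] <- data.frame(
      forward = f, backward = b, fusable = fusable,
      stringsAsFactors = FALSE)
    seen <- c(seen, f, b)
  }
  if (!length(rows))
    return(data.frame(forward = character(), backward = character(),
                      fusable = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' CTI-preserving network reduction
#'
#' Iteratively applies invariant-transition-pair fusions (merge the two
#' interconverted places into one and delete the reversible pair) and then
#' common-transition-pair contractions (replace the producer and consumer
#' of a chain place by one merged transition, fired `w_post/g` and
#' `w_pre/g` times respectively, and delete the place) until a fixpoint.
#' Both rules preserve the CTI property, so the question whether every
#' reaction sits on a steady-state pathway can be decided on the smaller
#' net.  The returned trace records every rule application together with
#' the multiplier mapping from reduced to original transitions, which
#' [lift_invariants()] replays to express invariants of the reduced net on
#' the original one.
#'
#' ITP fusion is restricted to pairs whose forward reaction converts
#' exactly one place into exactly one other place 1:1; other mirrored pairs
#' are left in place with a warning.
#'
#' @param net a `petri_net`.
#' @return Object of class `pn_reduction`: list with `net` (the reduced
#'   net), `original`, `records` (ordered rule applications), `tmap`
#'   (transition id, reduced or intermediate, to named multiplier vector
#'   over original transitions) and `pmap` (place id to original place
#'   ids).
#' @examples
#' red <- reduce_net(potato_net())
#' red$net                      # 3 places, 3 transitions
#' t_invariants(red$net)        # a single minimal t-invariant
#' @export
reduce_net <- function(net) {
  orig <- net
  tmap <- lapply(stats::setNames(transition_ids(net), transition_ids(net)),
                 function(t) stats::setNames(1, t))
  pmap <- lapply(stats::setNames(place_ids(net), place_ids(net)), identity)
  records <- list()
  warned <- character(0)

  repeat {
    changed <- FALSE

    itps <- detect_itps(net)
    for (r in seq_len(nrow(itps))) {
      row <- itps[r, ]
      if (!row$fusable) {
        key <- paste(row$forward, row$backward)
        if (!key %in% warned) {
          warning("ITP fusion refused for pair (", row$forward, ", ",
                  row$backward, "): stoichiometry is not 1:1 between two ",
                  "places; pair left in place", call. = FALSE)
          warned <- c(warned, key)
        }
        next
      }
      res <- apply_itp(net, row$forward, row$backward, pmap)
      net <- res$net
      pmap <- res$pmap
      records[[length(records) + 1L]] <- res$record
      changed <- TRUE
      break                      # re-detect on the new net
    }
    if (changed) next

    ctps <- detect_ctps(net)
    if (nrow(ctps)) {
      row <- ctps[1, ]
      res <- apply_ctp(net, row, tmap)
      net <- res$net
      tmap <- res$tmap
      records[[length(records) + 1L]] <- res$record
      changed <- TRUE
    }
    if (!changed) break
  }

  structure(list(net = net, original = orig, records = records,
                 tmap = tmap, pmap = pmap),
            class = "pn_reduction")
}

# fuse the two places interconverted by a 1:1 reversible pair, delete the pair
apply_itp <- function(net, fwd, bwd, pmap) {
  A <- pre_arcs(net, fwd)$from          # consumed by forward
  B <- post_arcs(net, fwd)$to           # produced by forward
  merged <- make.unique(c(place_ids(net), transition_ids(net),
                          paste0(A, ".", B)))[
                            length(place_ids(net)) +
                              length(transition_ids(net)) + 1L]
  p <- net$places
  keepP <- p[!p$id %in% c(A, B), , drop = FALSE]
  rowA <- p[p$id == A, ]; rowB <- p[p$id == B, ]
  newP <- data.frame(id = merged,
                     name = paste(rowA$name, rowB$name, sep = " / "),
                     initial_tokens = rowA$initial_tokens +
                       rowB$initial_tokens,
                     capacity = Inf, is_logical = FALSE,
                     stringsAsFactors = FALSE)
  tr <- net$transitions
  tr <- tr[!tr$id %in% c(fwd, bwd), , drop = FALSE]
  a <- net$arcs
  a <- a[!(a$from %in% c(fwd, bwd) | a$to %in% c(fwd, bwd)), , drop = FALSE]
  a$from[a$from %in% c(A, B)] <- merged
  a$to[a$to %in% c(A, B)] <- merged
  # collapse duplicate ordered pairs created by the fusion
  key <- paste(a$from, a$to)
  if (anyDuplicated(key)) {
    w <- tapply(a$weight, key, sum)
    a <- a[!duplicated(key), , drop = FALSE]
    a$weight <- as.numeric(w[paste(a$from, a$to)])
  }
  newnet <- petri_net(rbind(keepP, newP), tr, a)
  pmap[[merged]] <- union(pmap[[A]], pmap[[B]])
  list(net = newnet, pmap = pmap,
       record = list(type = "itp", forward = fwd, backward = bwd,
                     place_a = A, place_b = B, merged_place = merged,
                     orig_a = pmap[[A]], orig_b = pmap[[B]]))
}

# contract a chain place: replace its producer and consumer by one merged
# transition scaled to balance the place
apply_ctp <- function(net, row, tmap) {
  u <- row$pre; v <- row$post; p <- row$place
  mu <- row$mult_pre; mv <- row$mult_post
  merged <- make.unique(c(place_ids(net), transition_ids(net),
                          paste0(u, ".", v)))[
                            length(place_ids(net)) +
                              length(transition_ids(net)) + 1L]
  C <- incidence_matrix(net)
  eff <- mu * C[, u] + mv * C[, v]
  eff <- eff[names(eff) != p]
  stopifnot(mu * C[p, u] + mv * C[p, v] == 0)
  tr <- net$transitions
  tr <- tr[!tr$id %in% c(u, v), , drop = FALSE]
  tr <- rbind(tr, data.frame(id = merged,
                             name = paste0(u, " * ", v),
                             reverse_of = NA_character_,
                             stringsAsFactors = FALSE))
  pl <- net$places[net$places$id != p, , drop = FALSE]
  a <- net$arcs
  a <- a[!(a$from %in% c(u, v, p) | a$to %in% c(u, v, p)), , drop = FALSE]
  prod <- names(eff)[eff > 0]
  cons <- names(eff)[eff < 0]
  if (length(prod))
    a <- rbind(a, data.frame(from = merged, to = prod,
                             weight = eff[prod], stringsAsFactors = FALSE))
  if (length(cons))
    a <- rbind(a, data.frame(from = cons, to = merged,
                             weight = -eff[cons], stringsAsFactors = FALSE))
  newnet <- petri_net(pl, tr, a)
  comb <- merge_mult(tmap[[u]], mu, tmap[[v]], mv)
  tmap[[merged]] <- comb
  list(net = newnet, tmap = tmap,
       record = list(type = "ctp", place = p, pre = u, post = v,
                     w_pre = row$w_pre, w_post = row$w_post,
                     mult_pre = mu, mult_post = mv,
                     merged_transition = merged))
}

# a*x + b*y for named multiplier vectors
merge_mult <- function(x, a, y, b) {
  ids <- union(names(x), names(y))
  out <- stats::setNames(numeric(length(ids)), ids)
  out[names(x)] <- out[names(x)] + a * x
  out[names(y)] <- out[names(y)] + b * y
  out
}

#' @export
print.pn_reduction <- function(x, ...) {
  n_ctp <- sum(vapply(x$records, function(r) r$type == "ctp", logical(1)))
  n_itp <- sum(vapply(x$records, function(r) r$type == "itp", logical(1)))
  cat(sprintf("network reduction: %d CTP, %d ITP, %d reactions remain\n",
              n_ctp, n_itp, nrow(x$net$transitions)))
  cat(sprintf("  places %d -> %d, transitions %d -> %d\n",
              nrow(x$original$places), nrow(x$net$places),
              nrow(x$original$transitions), nrow(x$net$transitions)))
  invisible(x)
}

#' Reduction trace report
#'
#' Structured plain-text report of the applied rules, their members and
#' multipliers.
#'
#' @param x a `pn_reduction`.
#' @return Character scalar.
#' @export
reduction_report <- function(x) {
  lines <- character(0)
  for (r in x$records) {
    lines <- c(lines, if (r$type == "itp")
      sprintf("ITP: removed pair (%s, %s), fused places %s + %s -> %s",
              r$forward, r$backward, r$place_a, r$place_b, r$merged_place)
      else
        sprintf("CTP: place %s contracted, %s x%d * %s x%d -> %s",
                r$place, r$pre, as.integer(r$mult_pre), r$post,
                as.integer(r$mult_post), r$merged_transition))
  }
  paste(c(sprintf("%d reduction steps", length(x$records)), lines),
        collapse = "\n")
}

#' Lift invariants of the reduced net back to the original net
#'
#' Replays the reduction trace: the coefficient of each merged transition
#' is distributed onto the original transitions through the recorded CTP
#' multipliers; then each removed reversible pair is fired exactly as often
#' as needed to cancel the residual imbalance at its fused places, so the
#' lifted vector satisfies `C t = 0` on the original net (verified, error
#' otherwise).  Each removed ITP additionally contributes the trivial
#' invariant consisting of its forward and backward reaction once.
#'
#' @param reduction a `pn_reduction` from [reduce_net()].
#' @param invariants t-invariants of the reduced net; computed on demand.
#' @param minimize drop lifted vectors whose support strictly contains
#'   another's, and deduplicate (default `TRUE`).
#' @return A `pn_invariants` matrix (kind "t") over the original
#'   transitions.
#' @examples
#' red <- reduce_net(potato_net())
#' lift_invariants(red)
#' @export
lift_invariants <- function(reduction, invariants = NULL, minimize = TRUE) {
  orig <- reduction$original
  C <- incidence_matrix(orig)
  tids <- transition_ids(orig)
  if (is.null(invariants)) invariants <- t_invariants(reduction$net)
  itp_records <- Filter(function(r) r$type == "itp", reduction$records)

  lift_one <- function(v) {
    t <- stats::setNames(numeric(length(tids)), tids)
    for (id in names(v)[v != 0]) {
      mult <- reduction$tmap[[id]]
      if (is.null(mult))
        stop("transition '", id, "' not in the reduction trace",
             call. = FALSE)
      t[names(mult)] <- t[names(mult)] + v[[id]] * mult
    }
    # rebalance each fused reversible pair, later fusions first
    for (r in rev(itp_records)) {
      delta <- sum((C %*% t)[r$orig_a, ])
      if (delta > 0) {
        t <- t + delta * lift_pair(reduction, r$forward)
      } else if (delta < 0) {
        t <- t + (-delta) * lift_pair(reduction, r$backward)
      }
    }
    if (any(C %*% t != 0))
      stop("lifted invariant does not satisfy C t = 0 on the original net",
           call. = FALSE)
    d <- gcdv(t)
    if (d > 1) t <- t / d
    t
  }
  lift_pair <- function(reduction, id) {
    mult <- reduction$tmap[[id]]
    out <- stats::setNames(numeric(length(tids)), tids)
    out[names(mult)] <- mult
    out
  }

  rows <- lapply(seq_len(nrow(invariants)), function(i)
    lift_one(invariants[i, ]))
  for (r in itp_records) {
    trivial <- lift_pair(reduction, r$forward) +
      lift_pair(reduction, r$backward)
    d <- gcdv(trivial)
    if (d > 1) trivial <- trivial / d
    rows <- c(rows, list(trivial))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else matrix(0, 0, length(tids))
  colnames(out) <- tids
  if (minimize && nrow(out)) out <- out[minimal_rows(out), , drop = FALSE]
  out <- out[order(apply(out > 0, 1, paste, collapse = "")), , drop = FALSE]
  rownames(out) <- if (nrow(out)) paste0("inv", seq_len(nrow(out))) else NULL
  structure(out, kind = "t", class = c("pn_invariants", "matrix"))
}
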