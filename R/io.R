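#' Read and write the METATOOL-style reaction format
#'
#' A plain-text exchange format for metabolic Petri nets, modeled on the
#' classical enzyme-list inputs of elementary-mode tools.  Sections are
#' introduced by header lines and may span several lines:
#'
#' \preformatted{
#' -ENZREV
#' PGI
#' -ENZIRREV
#' invertase hexokinase ...
#' -METINT
#' sucrose glucose ...
#' -METEXT
#' sucrose_ext
#' -CAT
#' invertase : sucrose = glucose + fructose .
#' glycolysis : F6P + 29 ADP = 29 ATP .
#' sucrose_input : sucrose_ext = sucrose .
#' }
#'
#' Reversible enzymes (section `-ENZREV`) are split into a forward and a
#' backward transition linked by `reverse_of`; an entry `name` yields
#' `name_f`/`name_b`, an entry `fwd/bwd` keeps explicit ids.  External
#' metabolites (`-METEXT`) carry no place: a reaction consuming or
#' producing only external species becomes a boundary transition, and a
#' reaction side may also be left empty.  Stoichiometric coefficients are
#' positive integers (default 1).
#'
#' @param path file path (or, for `parse_reaction_text()`, a character
#'   vector of lines).
#' @param net a `petri_net` to serialize.
#' @return `read_reaction_net()`/`parse_reaction_text()` a `petri_net`;
#'   `write_reaction_net()` the path, invisibly;
#'   `format_reaction_net()` the text as a character vector of lines.
#' @examples
#' lines <- format_reaction_net(potato_net())
#' identical_net <- parse_reaction_text(lines)
#' @export
read_reaction_net <- function(path) {
  parse_reaction_text(readLines(path, warn = FALSE))
}

#' @rdname read_reaction_net
#' @param lines character vector of input lines.
#' @export
parse_reaction_text <- function(lines) {
  section <- NULL
  enzrev <- character(0); enzirr <- character(0)
  metint <- character(0); metext <- character(0)
  cat_lines <- character(0); cat_lineno <- integer(0)
  syntax_error <- function(i, msg)
    stop(sprintf("reaction file syntax error, line %d: %s", i, msg),
         call. = FALSE)

  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^-", line)) {
      hdr <- toupper(line)
      if (!hdr %in% c("-ENZREV", "-ENZIRREV", "-METINT", "-METEXT", "-CAT"))
        syntax_error(i, paste0("unknown section header '", line, "'"))
      section <- hdr
      next
    }
    if (is.null(section)) syntax_error(i, "content before a section header")
    if (section == "-CAT") {
      cat_lines <- c(cat_lines, line)
      cat_lineno <- c(cat_lineno, i)
    } else {
      toks <- strsplit(line, "[[:space:]]+")[[1]]
      switch(section,
             "-ENZREV" = enzrev <- c(enzrev, toks),
             "-ENZIRREV" = enzirr <- c(enzirr, toks),
             "-METINT" = metint <- c(metint, toks),
             "-METEXT" = metext <- c(metext, toks))
    }
  }

  parse_side <- function(txt, i) {
    txt <- trimws(txt)
    if (txt == "") return(data.frame(met = character(), coef = numeric()))
    terms <- strsplit(txt, "[[:space:]]*\\+[[:space:]]*")[[1]]
    met <- character(0); coef <- numeric(0)
    for (term in terms) {
      toks <- strsplit(trimws(term), "[[:space:]]+")[[1]]
      if (length(toks) == 1L) {
        met <- c(met, toks); coef <- c(coef, 1)
      } else if (length(toks) == 2L) {
        k <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(k) || k != floor(k) || k <= 0)
          syntax_error(i, paste0("coefficient must be a positive integer: '",
                                 toks[1], "'"))
        met <- c(met, toks[2]); coef <- c(coef, k)
      } else syntax_error(i, paste0("cannot parse term '", term, "'"))
    }
    data.frame(met = met, coef = coef, stringsAsFactors = FALSE)
  }

  transitions <- data.frame(id = character(), name = character(),
                            reverse_of = character(),
                            stringsAsFactors = FALSE)
  arcs <- data.frame(from = character(), to = character(),
                     weight = numeric(), stringsAsFactors = FALSE)
  rev_ids <- function(entry) {
    if (grepl("/", entry, fixed = TRUE)) {
      strsplit(entry, "/", fixed = TRUE)[[1]][1:2]
    } else paste0(entry, c("_f", "_b"))
  }
  enz_of_eq <- function(name) {
    if (name %in% enzirr)
      return(list(ids = name, rev = FALSE, entry = name))
    for (e in enzrev) {
      ids <- rev_ids(e)
      if (name == e || name == ids[1])
        return(list(ids = ids, rev = TRUE, entry = e))
    }
    NULL
  }

  seen_eq <- character(0)
  for (j in seq_along(cat_lines)) {
    i <- cat_lineno[j]
    line <- sub("[[:space:]]*\\.$", "", cat_lines[j])
    m <- regmatches(line, regexec(
      "^([^:[:space:]]+)[[:space:]]*:(.*)=(.*)$", line))[[1]]
    if (length(m) != 4) syntax_error(i, "expected 'name : lhs = rhs .'")
    name <- m[2]
    enz <- enz_of_eq(name)
    if (is.null(enz))
      syntax_error(i, paste0("reaction '", name,
                             "' not declared in -ENZREV or -ENZIRREV"))
    lhs <- parse_side(m[3], i)
    rhs <- parse_side(m[4], i)
    for (met in c(lhs$met, rhs$met))
      if (!met %in% c(metint, metext))
        syntax_error(i, paste0("unknown metabolite '", met, "'"))
    lhs <- lhs[lhs$met %in% metint, , drop = FALSE]
    rhs <- rhs[rhs$met %in% metint, , drop = FALSE]
    seen_eq <- c(seen_eq, enz$entry)
    if (enz$rev) {
      f <- enz$ids[1]; b <- enz$ids[2]
      transitions <- rbind(transitions,
                           data.frame(id = c(f, b), name = c(f, b),
                                      reverse_of = c(b, f),
                                      stringsAsFactors = FALSE))
      if (nrow(lhs)) arcs <- rbind(
        arcs,
        data.frame(from = lhs$met, to = f, weight = lhs$coef),
        data.frame(from = b, to = lhs$met, weight = lhs$coef))
      if (nrow(rhs)) arcs <- rbind(
        arcs,
        data.frame(from = f, to = rhs$met, weight = rhs$coef),
        data.frame(from = rhs$met, to = b, weight = rhs$coef))
    } else {
      transitions <- rbind(transitions,
                           data.frame(id = name, name = name,
                                      reverse_of = NA_character_,
                                      stringsAsFactors = FALSE))
      if (nrow(lhs)) arcs <- rbind(
        arcs, data.frame(from = lhs$met, to = name, weight = lhs$coef))
      if (nrow(rhs)) arcs <- rbind(
        arcs, data.frame(from = name, to = rhs$met, weight = rhs$coef))
    }
  }
  undeclared <- setdiff(c(enzirr, enzrev), c(seen_eq))
  if (length(undeclared))
    stop("declared enzymes without equation: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  petri_net(places = data.frame(id = metint, stringsAsFactors = FALSE),
            transitions = transitions, arcs = arcs)
}

#' @rdname read_reaction_net
#' @export
format_reaction_net <- function(net) {
  tr <- net$transitions
  rev_pairs <- list(); rev_members <- character(0)
  for (i in seq_len(nrow(tr))) {
    f <- tr$id[i]; b <- tr$reverse_of[i]
    if (is.na(b) || f %in% rev_members) next
    rev_pairs[[length(rev_pairs) + 1L]] <- c(f, b)
    rev_members <- c(rev_members, f, b)
  }
  enzrev_entries <- vapply(rev_pairs, function(p) {
    base <- sub("_f$", "", p[1])
    if (identical(p, paste0(base, c("_f", "_b")))) base
    else paste(p, collapse = "/")
  }, character(1))
  irrev <- setdiff(tr$id, rev_members)

  eq_of <- function(t_id) {
    pre <- pre_arcs(net, t_id); post <- post_arcs(net, t_id)
    side <- function(met, coef) {
      if (!length(met)) return("")
      paste(ifelse(coef > 1, paste(coef, met), met), collapse = " + ")
    }
    sprintf("%s : %s = %s .", t_id,
            side(pre$from, pre$weight), side(post$to, post$weight))
  }
  eqs <- c(vapply(rev_pairs, function(p) eq_of(p[1]), character(1)),
           vapply(irrev, eq_of, character(1)))
  c("-ENZREV", enzrev_entries,
    "-ENZIRREV", irrev,
    "-METINT", place_ids(net),
    "-METEXT",
    "-CAT", eqs)
}

#' @rdname read_reaction_net
#' @export
write_reaction_net <- function(net, path) {
  writeLines(format_reaction_net(net), path)
  invisible(path)
}

#' Read and write PNML (ISO 15909-2 place/transition dialect)
#'
#' Basic P/T-net PNML: `place` elements with optional `initialMarking`,
#' `transition` elements, `arc` elements with integer `inscription`
#' (missing inscription = weight 1).  Reversible-pair metadata is carried
#' in a `toolspecific` extension; extensions from other tools are ignored
#' with a warning.  Round-trip write-then-parse preserves the net (same
#' incidence matrix, same ids).
#'
#' @param path file path.
#' @param net a `petri_net`.
#' @return `read_pnml()` a `petri_net`; `write_pnml()` the path invisibly.
#' @export
read_pnml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  get_text <- function(node, xp) {
    n <- xml2::xml_find_first(node, xp)
    if (inherits(n, "xml_missing")) NA_character_ else
      trimws(xml2::xml_text(n))
  }
  foreign <- xml2::xml_find_all(
    doc, ".//toolspecific[not(@tool='petrinetr')]")
  if (length(foreign))
    warning("ignoring ", length(foreign),
            " tool-specific PNML extension(s)", call. = FALSE)

  pnodes <- xml2::xml_find_all(doc, ".//place")
  tnodes <- xml2::xml_find_all(doc, ".//transition")
  anodes <- xml2::xml_find_all(doc, ".//arc")
  places <- data.frame(
    id = xml2::xml_attr(pnodes, "id"),
    name = vapply(pnodes, function(n) {
      nm <- get_text(n, "./name/text")
      if (is.na(nm)) xml2::xml_attr(n, "id") else nm
    }, character(1)),
    initial_tokens = vapply(pnodes, function(n) {
      v <- get_text(n, "./initialMarking/text")
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  transitions <- data.frame(
    id = xml2::xml_attr(tnodes, "id"),
    name = vapply(tnodes, function(n) {
      nm <- get_text(n, "./name/text")
      if (is.na(nm)) xml2::xml_attr(n, "id") else nm
    }, character(1)),
    reverse_of = vapply(tnodes, function(n)
      get_text(n, "./toolspecific[@tool='petrinetr']/reverseOf"),
      character(1)),
    stringsAsFactors = FALSE)
  arcs <- data.frame(
    from = xml2::xml_attr(anodes, "source"),
    to = xml2::xml_attr(anodes, "target"),
    weight = vapply(anodes, function(n) {
      v <- get_text(n, "./inscription/text")
      if (is.na(v)) 1 else as.numeric(v)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  if (nrow(places) == 0 && nrow(transitions) == 0)
    stop("no places or transitions found; not a P/T PNML file?",
         call. = FALSE)
  petri_net(places, transitions, arcs)
}

#' @rdname read_pnml
#' @export
write_pnml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<pnml xmlns="http://www.pnml.org/version-2009/grammar/pnml">',
             paste0('  <net id="net1" type="http://www.pnml.org/',
                    'version-2009/grammar/ptnet">'),
             '    <page id="page1">')
  for (i in seq_len(nrow(net$places))) {
    p <- net$places[i, ]
    lines <- c(lines,
               sprintf('      <place id="%s">', esc(p$id)),
               sprintf('        <name><text>%s</text></name>', esc(p$name)),
               if (p$initial_tokens > 0)
                 sprintf(paste0('        <initialMarking><text>%d</text>',
                                '</initialMarking>'),
                         as.integer(p$initial_tokens)),
               '      </place>')
  }
  for (i in seq_len(nrow(net$transitions))) {
    t <- net$transitions[i, ]
    lines <- c(lines,
               sprintf('      <transition id="%s">', esc(t$id)),
               sprintf('        <name><text>%s</text></name>', esc(t$name)),
               if (!is.na(t$reverse_of))
                 sprintf(paste0('        <toolspecific tool="petrinetr" ',
                                'version="0.1"><reverseOf>%s</reverseOf>',
                                '</toolspecific>'), esc(t$reverse_of)),
               '      </transition>')
  }
  for (i in seq_len(nrow(net$arcs))) {
    a <- net$arcs[i, ]
    lines <- c(lines,
               sprintf('      <arc id="a%d" source="%s" target="%s">',
                       i, esc(a$from), esc(a$to)),
               if (a$weight != 1)
                 sprintf('        <inscription><text>%d</text></inscription>',
                         as.integer(a$weight)),
               '      </arc>')
  }
  lines <- c(lines, '    </page>', '  </net>', '</pnml>')
  writeLines(lines, path)
  invisible(path)
}

#' Read and write incidence matrices as TSV
#'
#' Header row = transition ids, first column = place ids, integer entries.
#'
#' @param path file path.
#' @param C labelled integer matrix (e.g. from [incidence_matrix()]).
#' @return `read_incidence_tsv()` the matrix; `write_incidence_tsv()` the
#'   path invisibly.
#' @export
read_incidence_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  C <- as.matrix(df[, -1, drop = FALSE])
  rownames(C) <- df[[1]]
  if (!all_integral(C)) stop("incidence entries must be integers",
                             call. = FALSE)
  storage.mode(C) <- "double"
  C
}

#' @rdname read_incidence_tsv
#' @export
write_incidence_tsv <- function(C, path) {
  df <- data.frame(place = rownames(C), C, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' GraphViz rendering of a net
#'
#' Places are ellipses, transitions boxes; an optional membership vector
#' (module labels, e.g. from [optimize_modules()] or flattened MCT-sets)
#' colors the vertices by module.
#'
#' @param net a `petri_net`.
#' @param membership optional named module labels over vertex ids.
#' @return GraphViz source text.
#' @export
net_dot <- function(net, membership = NULL) {
  palette <- c("#e41a1c", "#377eb8", "#4daf4a", "#ffff33", "#984ea3",
               "#ff7f00", "#a65628", "#f781bf", "#999999")
  col_of <- function(id) {
    if (is.null(membership) || is.na(membership[id] %||% NA)) return(NULL)
    palette[(as.integer(membership[[id]]) - 1L) %% length(palette) + 1L]
  }
  vert <- function(id, shape) {
    col <- col_of(id)
    sprintf('  "%s" [shape=%s%s];', id, shape,
            if (is.null(col)) "" else
              sprintf(', style=filled, fillcolor="%s"', col))
  }
  lines <- c("digraph PN {",
             vapply(place_ids(net), vert, character(1),
                    shape = "ellipse"),
             vapply(transition_ids(net), vert, character(1), shape = "box"),
             sprintf('  "%s" -> "%s"%s;', net$arcs$from, net$arcs$to,
                     ifelse(net$arcs$weight > 1,
                            sprintf(' [label="%d"]',
                                    as.integer(net$arcs$weight)), "")),
             "}")
  paste(lines, collapse = "\n")
}
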