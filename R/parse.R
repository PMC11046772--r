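## BiSDL source-text parser.
##
## The grammar is keyword-led and indentation-delimited: a line's children
## are the following lines with strictly greater indentation.  Comments
## start with `#`; blank lines are ignored; tabs are rejected (indentation
## must be spaces so that nesting depth is unambiguous).

IDENT_RE <- "[A-Za-z_][A-Za-z0-9_]*"

parse_error <- function(msg, line = NA_integer_) {
  where <- if (is.na(line)) "" else paste0(" (line ", line, ")")
  stop(errorCondition(paste0("BiSDL parse error", where, ": ", msg),
                      class = c("bisdl_parse_error", "error")))
}

## split a construct argument string on top-level commas (no nesting in the
## language, but keep the helper tolerant of stray spaces)
split_args <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  trimws(parts)
}

parse_term <- function(s, direction, line) {
  s <- trimws(s)
  m <- regmatches(s, regexec(
    paste0("^(?:([0-9]+)\\s*\\*\\s*)?(", IDENT_RE, ")$"), s))[[1]]
  if (length(m) == 0L)
    parse_error(paste0("malformed term '", s, "'"), line)
  mult <- if (nzchar(m[2])) as.integer(m[2]) else 1L
  if (mult < 1L)
    parse_error(paste0("malformed multiplier in '", s, "'"), line)
  bisdl_term(m[3], mult, direction)
}

parse_term_list <- function(s, direction, line, sep = ",") {
  s <- trimws(s)
  if (!nzchar(s)) return(list())
  parts <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  lapply(parts, parse_term, direction = direction, line = line)
}

## `a + b -> c + d` reaction expression; either side may be empty
parse_reaction_expr <- function(s, line) {
  sides <- strsplit(s, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    parse_error("reaction expression must contain exactly one '->'", line)
  c(parse_term_list(sides[1], "input", line, sep = "+"),
    parse_term_list(sides[2], "output", line, sep = "+"))
}

parse_construct_line <- function(text, line) {
  m <- regmatches(text, regexec(
    "^([A-Z_]+)\\s*\\(([^()]*)\\)\\s*(.*)$", text))[[1]]
  if (length(m) == 0L)
    parse_error(paste0("cannot parse construct line '", text, "'"), line)
  kind <- m[2]
  if (!kind %in% BISDL_CONSTRUCT_KINDS)
    parse_error(paste0("unknown construct keyword '", kind, "'"), line)
  body <- m[3]
  rest <- trimws(m[4])

  terms <- switch(
    kind,
    TRANSCRIPTION = ,
    TRANSLATION = {
      args <- split_args(body)
      if (length(args) != 2L)
        parse_error(paste0(kind, " takes exactly (input, output)"), line)
      list(parse_term(args[1], "input", line),
           parse_term(args[2], "output", line))
    },
    DEGRADATION = {
      args <- split_args(body)
      if (length(args) != 1L)
        parse_error("DEGRADATION takes exactly one entity", line)
      list(parse_term(args[1], "input", line))
    },
    PROTEIN_COMPLEX_FORMATION = {
      args <- split_args(body)
      if (length(args) < 2L)
        parse_error("PROTEIN_COMPLEX_FORMATION needs components and a product",
                    line)
      n <- length(args)
      c(lapply(args[-n], parse_term, direction = "input", line = line),
        list(parse_term(args[n], "output", line)))
    },
    ENZYMATIC_REACTION = {
      args <- split_args(body)
      if (length(args) != 2L || !grepl("->", args[2], fixed = TRUE))
        parse_error(
          "ENZYMATIC_REACTION takes (enzyme, substrates -> products)", line)
      c(list(parse_term(args[1], "modifier", line)),
        parse_reaction_expr(args[2], line))
    },
    CUSTOM_PROCESS = {
      if (!grepl("->", body, fixed = TRUE))
        parse_error("CUSTOM_PROCESS takes (inputs -> outputs)", line)
      parse_reaction_expr(body, line)
    }
  )

  roles <- list()
  while (nzchar(rest)) {
    rm <- regmatches(rest, regexec(
      "^([A-Z_]+)\\s*\\(([^()]*)\\)\\s*(.*)$", rest))[[1]]
    if (length(rm) == 0L)
      parse_error(paste0("cannot parse role annotation '", rest, "'"), line)
    if (!rm[2] %in% BISDL_ROLE_KEYWORDS)
      parse_error(paste0("unknown role keyword '", rm[2], "'"), line)
    roles[[rm[2]]] <- parse_term_list(rm[3], "modifier", line)
    rest <- trimws(rm[4])
  }

  bisdl_construct(kind, terms, roles, line = line)
}

## build an indentation tree: each node is list(text, line, children)
build_line_tree <- function(text) {
  raw <- strsplit(text, "\n", fixed = TRUE)[[1]]
  nodes <- list()
  for (i in seq_along(raw)) {
    stripped <- sub("#.*$", "", raw[i])
    if (!nzchar(trimws(stripped))) next
    if (grepl("\t", stripped, fixed = TRUE))
      parse_error("tabs are not allowed; indent with spaces", i)
    indent <- nchar(stripped) - nchar(sub("^ *", "", stripped))
    nodes[[length(nodes) + 1L]] <- list(
      text = trimws(stripped), line = i, indent = indent, children = list())
  }
  if (length(nodes) == 0L)
    parse_error("empty source", NA_integer_)

  ## fold the flat list into a forest using an indent stack
  attach_children <- function(idx, parent_indent) {
    children <- list()
    while (idx <= length(nodes)) {
      nd <- nodes[[idx]]
      if (nd$indent <= parent_indent) break
      sub <- attach_children(idx + 1L, nd$indent)
      nd$children <- sub$children
      children[[length(children) + 1L]] <- nd
      idx <- sub$idx
    }
    list(children = children, idx = idx)
  }
  forest <- attach_children(1L, -1L)
  if (forest$idx <= length(nodes))
    parse_error("inconsistent indentation", nodes[[forest$idx]]$line)
  forest$children
}

parse_scope_node <- function(node) {
  m <- regmatches(node$text, regexec(paste0(
    "^SCOPE\\s+(", IDENT_RE, ")\\s*\\(\\s*(-?[0-9]+)\\s*,\\s*(-?[0-9]+)\\s*\\)$"),
    node$text))[[1]]
  if (length(m) == 0L)
    parse_error("expected 'SCOPE <id> (x, y)'", node$line)
  processes <- list(); signals <- list(); markings <- list()
  for (ch in node$children) {
    t <- ch$text
    if (grepl("^PROCESS\\s", t)) {
      pm <- regmatches(t, regexec(paste0("^PROCESS\\s+(", IDENT_RE, ")$"),
                                  t))[[1]]
      if (length(pm) == 0L)
        parse_error("expected 'PROCESS <id>'", ch$line)
      if (length(ch$children) == 0L) {
        processes[[length(processes) + 1L]] <-
          bisdl_process(pm[2], is_ref = TRUE, line = ch$line)
      } else {
        ts <- 1L; constructs <- list()
        for (cc in ch$children) {
          if (grepl("^TIMESCALE\\s", cc$text)) {
            tm <- regmatches(cc$text,
                             regexec("^TIMESCALE\\s+([0-9]+)$", cc$text))[[1]]
            if (length(tm) == 0L)
              parse_error("expected 'TIMESCALE <positive integer>'", cc$line)
            ts <- as.integer(tm[2])
          } else {
            constructs[[length(constructs) + 1L]] <-
              parse_construct_line(cc$text, cc$line)
          }
        }
        processes[[length(processes) + 1L]] <-
          bisdl_process(pm[2], ts, constructs, line = ch$line)
      }
    } else if (grepl("^(JUXTACRINE|PARACRINE)_SIGNAL\\s*\\(", t)) {
      sm <- regmatches(t, regexec(paste0(
        "^((?:JUXTACRINE|PARACRINE)_SIGNAL)\\s*\\(\\s*(", IDENT_RE,
        ")\\s*,\\s*(emit|receive)\\s*(?:,\\s*(", IDENT_RE, ")\\s*)?\\)$"),
        t))[[1]]
      if (length(sm) == 0L)
        parse_error("expected 'SIGNAL(entity, emit|receive[, partner])'",
                    ch$line)
      partner <- if (nzchar(sm[5])) sm[5] else NA_character_
      signals[[length(signals) + 1L]] <-
        bisdl_signal(sm[2], sm[3], sm[4], partner)
    } else if (grepl("^MARKING\\s*\\(", t)) {
      mm <- regmatches(t, regexec(paste0(
        "^MARKING\\s*\\(\\s*(", IDENT_RE, ")\\s*,\\s*([0-9]+)\\s*\\)$"),
        t))[[1]]
      if (length(mm) == 0L)
        parse_error("expected 'MARKING(entity, count)'", ch$line)
      markings[[length(markings) + 1L]] <-
        bisdl_marking(mm[2], as.integer(mm[3]))
    } else {
      parse_error(paste0("unexpected declaration in SCOPE: '", t, "'"),
                  ch$line)
    }
  }
  bisdl_scope(m[2], c(as.integer(m[3]), as.integer(m[4])),
              processes, signals, markings)
}

parse_diffusion_node <- function(node) {
  t <- node$text
  m <- regmatches(t, regexec(paste0(
    "^DIFFUSION\\s*\\(\\s*(", IDENT_RE, ")\\s*,\\s*all\\s*\\)$"), t))[[1]]
  if (length(m) > 0L)
    return(bisdl_diffusion(m[2], "all"))
  m <- regmatches(t, regexec(paste0(
    "^DIFFUSION\\s*\\(\\s*(", IDENT_RE, ")\\s*,\\s*(", IDENT_RE,
    ")\\s*,\\s*(", IDENT_RE, ")\\s*,\\s*(bidirectional|unidirectional)\\s*\\)$"),
    t))[[1]]
  if (length(m) == 0L)
    parse_error(
      "expected 'DIFFUSION(entity, from, to, bidirectional|unidirectional)' or 'DIFFUSION(entity, all)'",
      node$line)
  bisdl_diffusion(m[2], m[3], m[4], m[5] == "bidirectional")
}

#' Parse BiSDL source text into a module AST
#'
#' @param text a single string of BiSDL source, or a character vector of
#'   lines.
#' @return a [bisdl_module()].
#' @examples
#' src <- "
#' MODULE water
#'     TIMESCALE 1
#'     SCOPE s (0, 0)
#'         PROCESS reaction
#'             TIMESCALE 1
#'             CUSTOM_PROCESS(2*H2_molecule + O2_molecule -> 2*H2O_molecule)
#' "
#' mod <- bisdl_parse(src)
#' mod$scopes[[1]]$processes[[1]]$constructs[[1]]
#' @export
bisdl_parse <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  if (!is.character(text) || !nzchar(trimws(text)))
    parse_error("source must be non-empty text", NA_integer_)
  forest <- build_line_tree(text)
  if (length(forest) != 1L)
    parse_error("expected exactly one top-level MODULE",
                forest[[min(2L, length(forest))]]$line)
  root <- forest[[1]]
  m <- regmatches(root$text,
                  regexec(paste0("^MODULE\\s+(", IDENT_RE, ")$"),
                          root$text))[[1]]
  if (length(m) == 0L)
    parse_error("expected 'MODULE <name>'", root$line)

  timescale <- 1L; scopes <- list(); diffusions <- list()
  for (ch in root$children) {
    t <- ch$text
    if (grepl("^TIMESCALE\\s", t)) {
      tm <- regmatches(t, regexec("^TIMESCALE\\s+([0-9]+)$", t))[[1]]
      if (length(tm) == 0L || as.integer(tm[2]) < 1L)
        parse_error("expected 'TIMESCALE <positive integer>'", ch$line)
      timescale <- as.integer(tm[2])
    } else if (grepl("^SCOPE\\s", t)) {
      scopes[[length(scopes) + 1L]] <- parse_scope_node(ch)
    } else if (grepl("^DIFFUSION\\s*\\(", t)) {
      diffusions[[length(diffusions) + 1L]] <- parse_diffusion_node(ch)
    } else {
      parse_error(paste0("unexpected declaration in MODULE: '", t, "'"),
                  ch$line)
    }
  }
  bisdl_module(m[2], timescale, scopes, diffusions)
}

#' Read and parse a `.bisdl` source file
#' @param path path to a UTF-8 BiSDL source file.
#' @return a [bisdl_module()].
#' @export
bisdl_read <- function(path) {
  bisdl_parse(readLines(path, encoding = "UTF-8", warn = FALSE))
}
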