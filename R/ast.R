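#' @title Abstract syntax for the BiSDL description language
#'
#' @description
#' A BiSDL description is a `MODULE`: a named, self-contained account of a
#' multicellular design.  It carries a base `TIMESCALE` (the pace of the
#' module relative to the unit simulator tick), an ordered set of `SCOPE`
#' declarations (biological compartments pinned to cells of a 2-D spatial
#' grid), and a set of `DIFFUSION` declarations connecting scopes through
#' diffusible molecular signals.  Each scope bundles `PROCESS` declarations
#' (gene-circuit behaviours made of typed constructs such as
#' `TRANSCRIPTION` or `ENZYMATIC_REACTION`), optional `JUXTACRINE_SIGNAL` /
#' `PARACRINE_SIGNAL` declarations (contact-dependent and diffusible
#' cell-cell communication), and optional `MARKING` declarations giving
#' initial token counts.
#'
#' These constructors build the in-memory AST; [bisdl_parse()] produces the
#' same objects from source text and [bisdl_deparse()] renders them back.
#'
#' @name bisdl-ast
NULL

#' Construct kinds and role keywords recognised by the language
#' @rdname bisdl-ast
#' @export
BISDL_CONSTRUCT_KINDS <- c(
  "TRANSCRIPTION", "TRANSLATION", "DEGRADATION",
  "PROTEIN_COMPLEX_FORMATION", "ENZYMATIC_REACTION", "CUSTOM_PROCESS"
)

#' @rdname bisdl-ast
#' @export
BISDL_ROLE_KEYWORDS <- c("INDUCERS", "INHIBITORS", "ACTIVATORS")

#' Create a module declaration
#'
#' @param name module identifier.
#' @param timescale positive integer; base pace in simulator ticks.
#' @param scopes list of [bisdl_scope()] objects.
#' @param diffusions list of [bisdl_diffusion()] objects.
#' @return an object of class `bisdl_module`.
#' @export
bisdl_module <- function(name, timescale = 1L, scopes = list(),
                         diffusions = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  timescale <- as.integer(timescale)
  if (is.na(timescale) || timescale < 1L)
    stop("module TIMESCALE must be a positive integer", call. = FALSE)
  structure(
    list(name = name, timescale = timescale,
         scopes = scopes, diffusions = diffusions),
    class = "bisdl_module"
  )
}

#' Create a scope declaration
#'
#' @param id scope identifier, unique within the module.
#' @param coord integer vector `c(x, y)`, 0-based grid cell (origin top-left).
#' @param processes list of [bisdl_process()] objects (definitions or refs).
#' @param signals list of [bisdl_signal()] objects.
#' @param markings list of [bisdl_marking()] initial-count declarations.
#' @return an object of class `bisdl_scope`.
#' @export
bisdl_scope <- function(id, coord, processes = list(), signals = list(),
                        markings = list()) {
  coord <- as.integer(coord)
  stopifnot(length(coord) == 2L)
  structure(
    list(id = id, coord = coord, processes = processes,
         signals = signals, markings = markings),
    class = "bisdl_scope"
  )
}

#' Create a process declaration (or a reuse reference)
#'
#' A process with `is_ref = TRUE` re-instantiates, by name, a process body
#' defined in another scope of the same module; [bisdl_resolve_reuse()]
#' links the reference to its single definition.
#'
#' @param id process identifier.
#' @param timescale positive integer multiplier of the module timescale.
#' @param constructs list of [bisdl_construct()] objects.
#' @param is_ref logical; `TRUE` for a body-less reuse reference.
#' @param line source line, for diagnostics.
#' @return an object of class `bisdl_process`.
#' @export
bisdl_process <- function(id, timescale = 1L, constructs = list(),
                          is_ref = FALSE, line = NA_integer_) {
  structure(
    list(id = id, timescale = as.integer(timescale), constructs = constructs,
         is_ref = isTRUE(is_ref), line = line),
    class = "bisdl_process"
  )
}

#' Create a construct declaration
#'
#' @param kind one of [BISDL_CONSTRUCT_KINDS].
#' @param terms list of [bisdl_term()] participants, in source order.
#' @param roles named list mapping role keywords ("INDUCERS", "INHIBITORS",
#'   "ACTIVATORS") to lists of [bisdl_term()].
#' @param line source line, for diagnostics.
#' @return an object of class `bisdl_construct`.
#' @export
bisdl_construct <- function(kind, terms, roles = list(),
                            line = NA_integer_) {
  if (!kind %in% BISDL_CONSTRUCT_KINDS)
    stop("unknown construct kind: ", kind, call. = FALSE)
  structure(
    list(kind = kind, terms = terms, roles = roles, line = line),
    class = "bisdl_construct"
  )
}

#' Create a stoichiometric term
#'
#' Source syntax `k*entity`; an omitted multiplier materialises as 1.
#'
#' @param entity entity name (see [entity_base_type()]).
#' @param multiplier positive integer stoichiometric coefficient.
#' @param direction one of "input", "output", "modifier".
#' @return an object of class `bisdl_term`.
#' @export
bisdl_term <- function(entity, multiplier = 1L, direction = "input") {
  multiplier <- as.integer(multiplier)
  if (is.na(multiplier) || multiplier < 1L)
    stop("term multiplier must be >= 1", call. = FALSE)
  direction <- match.arg(direction, c("input", "output", "modifier"))
  structure(
    list(entity = entity, multiplier = multiplier, direction = direction),
    class = "bisdl_term"
  )
}

#' Create an intercellular signal declaration
#'
#' @param kind "JUXTACRINE_SIGNAL" (direct contact, needs a grid-adjacent
#'   partner scope) or "PARACRINE_SIGNAL" (diffusible).
#' @param entity signal entity name.
#' @param direction "emit" or "receive".
#' @param partner partner scope id (juxtacrine only; `NA` otherwise).
#' @return an object of class `bisdl_signal`.
#' @export
bisdl_signal <- function(kind, entity, direction, partner = NA_character_) {
  kind <- match.arg(kind, c("JUXTACRINE_SIGNAL", "PARACRINE_SIGNAL"))
  direction <- match.arg(direction, c("emit", "receive"))
  structure(
    list(kind = kind, entity = entity, direction = direction,
         partner = partner),
    class = "bisdl_signal"
  )
}

#' Create a module-level diffusion declaration
#'
#' @param entity diffusing entity name.
#' @param from,to endpoint scope ids, or `from = "all"` for grid-wide
#'   diffusion between every pair of Moore-adjacent cells.
#' @param bidirectional logical.
#' @return an object of class `bisdl_diffusion`.
#' @export
bisdl_diffusion <- function(entity, from, to = NA_character_,
                            bidirectional = TRUE) {
  structure(
    list(entity = entity, from = from, to = to,
         bidirectional = isTRUE(bidirectional)),
    class = "bisdl_diffusion"
  )
}

#' Create an initial-marking declaration
#'
#' @param entity entity name.
#' @param count non-negative initial token count.
#' @return an object of class `bisdl_marking`.
#' @export
bisdl_marking <- function(entity, count) {
  count <- as.integer(count)
  if (is.na(count) || count < 0L)
    stop("MARKING count must be a non-negative integer", call. = FALSE)
  structure(list(entity = entity, count = count), class = "bisdl_marking")
}

#' Infer the base type of an entity from its name suffix
#'
#' Entity names follow the field convention `X_gene`, `X_mRNA`, `X_protein`,
#' `X_complex`, `X_molecule` (case-insensitive suffix match); names without a
#' recognised suffix default to `MOLECULE`.
#'
#' @param name entity name (vectorised).
#' @return character vector of base types
#'   (`GENE`/`MRNA`/`PROTEIN`/`COMPLEX`/`MOLECULE`).
#' @export
entity_base_type <- function(name) {
  suffix <- tolower(sub("^.*_", "", name))
  out <- rep("MOLECULE", length(name))
  out[suffix == "gene"] <- "GENE"
  out[suffix == "mrna"] <- "MRNA"
  out[suffix == "protein"] <- "PROTEIN"
  out[suffix == "complex"] <- "COMPLEX"
  out
}

has_known_suffix <- function(name) {
  suffix <- tolower(sub("^.*_", "", name))
  suffix %in% c("gene", "mrna", "protein", "complex", "molecule")
}

## ---- deparse (pretty-printer) ------------------------------------------

deparse_term <- function(t) {
  if (t$multiplier == 1L) t$entity else paste0(t$multiplier, "*", t$entity)
}

deparse_terms <- function(terms, collapse = ", ") {
  paste(vapply(terms, deparse_term, character(1)), collapse = collapse)
}

deparse_construct <- function(con) {
  ins <- Filter(function(t) t$direction == "input", con$terms)
  outs <- Filter(function(t) t$direction == "output", con$terms)
  mods <- Filter(function(t) t$direction == "modifier", con$terms)
  args <- switch(
    con$kind,
    TRANSCRIPTION = ,
    TRANSLATION = ,
    DEGRADATION = ,
    PROTEIN_COMPLEX_FORMATION = deparse_terms(con$terms),
    ENZYMATIC_REACTION = paste0(
      deparse_terms(mods), ", ",
      deparse_terms(ins, " + "), " -> ", deparse_terms(outs, " + ")
    ),
    CUSTOM_PROCESS = paste0(
      deparse_terms(ins, " + "), " -> ", deparse_terms(outs, " + ")
    )
  )
  line <- paste0(con$kind, "(", args, ")")
  for (role in names(con$roles)) {
    line <- paste0(line, " ", role, "(", deparse_terms(con$roles[[role]]), ")")
  }
  line
}

#' Render an AST back to canonical BiSDL source text
#'
#' The output is canonical (4-space indentation, unit multipliers omitted)
#' and reparses to an equal AST: `bisdl_parse(bisdl_deparse(m))` is
#' identical to `m` up to source-line bookkeeping.
#'
#' @param module a [bisdl_module()].
#' @return a single string of BiSDL source.
#' @export
bisdl_deparse <- function(module) {
  ind <- function(n) strrep(" ", 4L * n)
  out <- c(
    paste0("MODULE ", module$name),
    paste0(ind(1), "TIMESCALE ", module$timescale)
  )
  for (sc in module$scopes) {
    out <- c(out, paste0(ind(1), "SCOPE ", sc$id, " (",
                         sc$coord[1], ", ", sc$coord[2], ")"))
    for (mk in sc$markings)
      out <- c(out, paste0(ind(2), "MARKING(", mk$entity, ", ", mk$count, ")"))
    for (pr in sc$processes) {
      out <- c(out, paste0(ind(2), "PROCESS ", pr$id))
      if (!pr$is_ref) {
        out <- c(out, paste0(ind(3), "TIMESCALE ", pr$timescale))
        for (con in pr$constructs)
          out <- c(out, paste0(ind(3), deparse_construct(con)))
      }
    }
    for (sg in sc$signals) {
      args <- paste0(sg$entity, ", ", sg$direction)
      if (!is.na(sg$partner)) args <- paste0(args, ", ", sg$partner)
      out <- c(out, paste0(ind(2), sg$kind, "(", args, ")"))
    }
  }
  for (df in module$diffusions) {
    if (identical(df$from, "all")) {
      args <- paste0(df$entity, ", all")
    } else {
      args <- paste0(df$entity, ", ", df$from, ", ", df$to, ", ",
                     if (df$bidirectional) "bidirectional" else "unidirectional")
    }
    out <- c(out, paste0(ind(1), "DIFFUSION(", args, ")"))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @export
print.bisdl_module <- function(x, ...) {
  cat("<bisdl_module> ", x$name, "\n", sep = "")
  cat("  timescale: ", x$timescale, "\n", sep = "")
  cat("  scopes: ", length(x$scopes),
      " [", paste(vapply(x$scopes, `[[`, "", "id"), collapse = ", "), "]\n",
      sep = "")
  cat("  diffusions: ", length(x$diffusions), "\n", sep = "")
  invisible(x)
}

#' @export
print.bisdl_process <- function(x, ...) {
  cat("<bisdl_process> ", x$id,
      if (x$is_ref) " (reuse reference)" else
        paste0(" timescale=", x$timescale, " constructs=",
               length(x$constructs)),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.bisdl_construct <- function(x, ...) {
  cat(deparse_construct(x), "\n")
  invisible(x)
}

## strip line-number bookkeeping so structural equality can be tested
strip_lines <- function(x) {
  if (is.list(x)) {
    x$line <- NULL
    x[] <- lapply(x, strip_lines)
  }
  x
}

#' Structural AST equality ignoring source-line bookkeeping
#' @param a,b two AST fragments.
#' @return logical.
#' @export
bisdl_ast_equal <- function(a, b) {
  identical(strip_lines(a), strip_lines(b))
}
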