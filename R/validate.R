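## Static checks on a parsed module, and resolution of PROCESS reuse.

diag_row <- function(severity, message, line = NA_integer_) {
  data.frame(severity = severity, line = line, message = message,
             stringsAsFactors = FALSE)
}

#' Moore adjacency of two grid coordinates
#'
#' Two cells are adjacent when their Chebyshev distance is exactly 1
#' (8-neighbourhood).
#'
#' @param a,b integer coordinate pairs `c(x, y)`.
#' @return logical.
#' @export
grid_adjacent <- function(a, b) {
  d <- max(abs(as.integer(a) - as.integer(b)))
  d == 1L
}

module_process_definitions <- function(module) {
  defs <- list()
  for (sc in module$scopes) {
    for (pr in sc$processes) {
      if (!pr$is_ref)
        defs[[length(defs) + 1L]] <- list(scope = sc$id, process = pr)
    }
  }
  defs
}

all_construct_terms <- function(con) {
  c(con$terms, unlist(con$roles, recursive = FALSE))
}

#' Validate a module AST
#'
#' Checks every language invariant that parsing alone cannot enforce:
#' unique scope ids and grid coordinates, non-negative coordinates,
#' resolvable process reuse, construct arities and base types
#' (e.g. `TRANSCRIPTION` needs a GENE input and an MRNA output),
#' one base type per entity name module-wide, resolvable diffusion
#' endpoints, and grid-adjacent juxtacrine partners.
#'
#' Validation is pure: diagnostics are the return value and the module is
#' never modified.
#'
#' @param module a [bisdl_module()].
#' @return a data.frame with columns `severity` ("error"/"warning"),
#'   `line`, `message`; zero rows iff the module is valid.
#' @export
bisdl_validate <- function(module) {
  diags <- list()
  push <- function(severity, message, line = NA_integer_)
    diags[[length(diags) + 1L]] <<- diag_row(severity, message, line)

  scope_ids <- vapply(module$scopes, `[[`, "", "id")
  dup <- scope_ids[duplicated(scope_ids)]
  for (d in unique(dup))
    push("error", paste0("duplicate scope id '", d, "'"))

  coords <- vapply(module$scopes,
                   function(s) paste(s$coord, collapse = ","), "")
  for (d in unique(coords[duplicated(coords)]))
    push("error", paste0("duplicate coordinate (", d, ")"))
  for (sc in module$scopes) {
    if (any(sc$coord < 0L))
      push("error", paste0("scope '", sc$id,
                           "' has negative grid coordinates"))
  }

  ## process reuse: every ref must have exactly one definition elsewhere
  defs <- module_process_definitions(module)
  def_ids <- vapply(defs, function(d) d$process$id, "")
  for (d in unique(def_ids[duplicated(def_ids)]))
    push("error", paste0("ambiguous reuse: process '", d,
                         "' defined more than once"))
  for (sc in module$scopes) {
    for (pr in sc$processes) {
      if (pr$is_ref && sum(def_ids == pr$id) == 0L)
        push("error", paste0("unresolved process '", pr$id,
                             "' referenced in scope '", sc$id, "'"),
             pr$line)
      if (!pr$is_ref && pr$timescale < 1L)
        push("error", paste0("process '", pr$id,
                             "' has non-positive timescale"), pr$line)
    }
  }

  ## entity base types + construct arities.  Base type is inferred from the
  ## name suffix, so "one base type per name" holds by construction; names
  ## without a recognised suffix are flagged once.
  warned_suffix <- character(0)
  check_entity <- function(name, line) {
    if (!has_known_suffix(name) && !name %in% warned_suffix) {
      warned_suffix <<- c(warned_suffix, name)
      push("warning", paste0("entity '", name,
                             "' has no recognised type suffix; ",
                             "treated as MOLECULE"), line)
    }
  }

  for (sc in module$scopes) {
    for (pr in sc$processes) {
      if (pr$is_ref) next
      for (con in pr$constructs) {
        terms <- all_construct_terms(con)
        for (t in terms) check_entity(t$entity, con$line)
        ins <- Filter(function(t) t$direction == "input", con$terms)
        outs <- Filter(function(t) t$direction == "output", con$terms)
        if (con$kind == "TRANSCRIPTION") {
          if (entity_base_type(ins[[1]]$entity) != "GENE")
            push("error", paste0("TRANSCRIPTION input '", ins[[1]]$entity,
                                 "' is not a GENE"), con$line)
          if (entity_base_type(outs[[1]]$entity) != "MRNA")
            push("error", paste0("TRANSCRIPTION output '", outs[[1]]$entity,
                                 "' is not an MRNA"), con$line)
        }
        if (con$kind == "TRANSLATION") {
          if (entity_base_type(ins[[1]]$entity) != "MRNA")
            push("error", paste0("TRANSLATION input '", ins[[1]]$entity,
                                 "' is not an MRNA"), con$line)
          if (entity_base_type(outs[[1]]$entity) != "PROTEIN")
            push("error", paste0("TRANSLATION output '", outs[[1]]$entity,
                                 "' is not a PROTEIN"), con$line)
        }
        if (con$kind == "CUSTOM_PROCESS" && length(c(ins, outs)) == 0L)
          push("error", "CUSTOM_PROCESS with no inputs and no outputs",
               con$line)
      }
    }
  }

  ## diffusion endpoints
  for (df in module$diffusions) {
    if (identical(df$from, "all")) next
    for (ep in c(df$from, df$to)) {
      if (!ep %in% scope_ids)
        push("error", paste0("diffusion endpoint '", ep,
                             "' is not a declared scope"))
    }
  }

  ## juxtacrine partners: declared and grid-adjacent
  coord_of <- stats::setNames(lapply(module$scopes, `[[`, "coord"), scope_ids)
  for (sc in module$scopes) {
    for (sg in sc$signals) {
      if (sg$kind != "JUXTACRINE_SIGNAL") next
      if (is.na(sg$partner)) {
        ## an emit must name its contact; an open receive matches any
        ## adjacent emitter
        if (sg$direction == "emit")
          push("error", paste0("juxtacrine emit of '", sg$entity,
                               "' in scope '", sc$id, "' has no partner"))
        next
      }
      if (!sg$partner %in% scope_ids) {
        push("error", paste0("juxtacrine partner '", sg$partner,
                             "' of scope '", sc$id, "' is not declared"))
        next
      }
      if (!grid_adjacent(coord_of[[sc$id]], coord_of[[sg$partner]]))
        push("error", paste0("juxtacrine partner '", sg$partner,
                             "' is not grid-adjacent to scope '", sc$id, "'"))
    }
  }

  if (length(diags) == 0L)
    return(data.frame(severity = character(0), line = integer(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, diags)
}

#' Resolve process reuse references
#'
#' Replaces every body-less `PROCESS <id>` reference with a copy of the
#' unique definition of `<id>` found elsewhere in the module, preserving
#' declaration order so the compiler can number instances in source order.
#'
#' @param module a validated [bisdl_module()].
#' @return the module with all references expanded; each expanded process
#'   carries `reused = TRUE`.
#' @export
bisdl_resolve_reuse <- function(module) {
  defs <- module_process_definitions(module)
  def_ids <- vapply(defs, function(d) d$process$id, "")
  for (d in unique(def_ids[duplicated(def_ids)]))
    stop("ambiguous reuse: process '", d, "' defined more than once",
         call. = FALSE)
  for (si in seq_along(module$scopes)) {
    prs <- module$scopes[[si]]$processes
    for (pi in seq_along(prs)) {
      if (!prs[[pi]]$is_ref) next
      hit <- which(def_ids == prs[[pi]]$id)
      if (length(hit) == 0L)
        stop("unresolved process '", prs[[pi]]$id, "'", call. = FALSE)
      def <- defs[[hit]]$process
      def$is_ref <- FALSE
      def$reused <- TRUE
      def$line <- prs[[pi]]$line
      prs[[pi]] <- def
    }
    module$scopes[[si]]$processes <- prs
  }
  module
}
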