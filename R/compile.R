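#' @title Lowering BiSDL modules to nets-within-nets models
#'
#' @description
#' [bisdl_compile()] turns a validated module AST into an [nwn_model()]:
#' a top-level spatial-grid net whose places (one per scope, at the scope's
#' grid coordinate) each host the scope's net as a net token.  Construct
#' declarations expand into net fragments from a fixed template per kind
#' (see [expand_construct()]); fragments touching the same entity name
#' within one scope stitch onto one shared place.  `DIFFUSION`
#' declarations become top-level transitions moving colored tokens between
#' grid places, with mirror bindings so the hosted scope nets see the
#' change; `JUXTACRINE_SIGNAL` pairs become synchronous channels between
#' emit and receive transitions of the partner scope nets.
#'
#' @name bisdl-compiler
NULL

#' Number process instances in source order
#'
#' The i-th instantiation (definition or reuse) of process `P` across the
#' whole module is named `P_process_<i>`, starting at 0.
#'
#' @param module a [bisdl_module()] after [bisdl_resolve_reuse()].
#' @return named character vector: instance name -> `"scope/process_id"`.
#' @export
assign_instance_names <- function(module) {
  counters <- new.env(parent = emptyenv())
  registry <- character(0)
  for (sc in module$scopes) {
    for (pr in sc$processes) {
      i <- if (exists(pr$id, envir = counters, inherits = FALSE))
        get(pr$id, envir = counters) else 0L
      assign(pr$id, i + 1L, envir = counters)
      registry[paste0(pr$id, "_process_", i)] <- paste0(sc$id, "/", pr$id)
    }
  }
  registry
}

role_arcs <- function(roles, reads, inhibitors) {
  for (role in names(roles)) {
    for (t in roles[[role]]) {
      arc <- nwn_arc(t$entity, t$multiplier, t$entity)
      if (role == "INHIBITORS") inhibitors[[length(inhibitors) + 1L]] <- arc
      else reads[[length(reads) + 1L]] <- arc
    }
  }
  list(reads = reads, inhibitors = inhibitors)
}

entity_arc <- function(term) nwn_arc(term$entity, term$multiplier,
                                     term$entity)

#' Expand one construct into a net fragment
#'
#' Templates, one per construct kind (arc weights always equal term
#' multipliers; `INDUCERS`/`ACTIVATORS` roles become read arcs and
#' `INHIBITORS` become inhibitor arcs on every template):
#' \describe{
#'   \item{TRANSCRIPTION}{gene place read arc (the gene persists) ->
#'     transition -> mRNA place.}
#'   \item{TRANSLATION}{mRNA read arc -> protein place.}
#'   \item{DEGRADATION}{consume the entity's tokens, no output (sink).}
#'   \item{PROTEIN_COMPLEX_FORMATION}{consume every component term,
#'     produce the product (last) term.}
#'   \item{ENZYMATIC_REACTION}{enzyme read arc; substrates consumed,
#'     products produced.}
#'   \item{CUSTOM_PROCESS}{literal inputs -> outputs.}
#' }
#'
#' Generated transition names embed the instance name, the kind, and the
#' product (or degraded) entity, keeping the low-level model interpretable.
#'
#' @param construct a [bisdl_construct()].
#' @param instance process instance name (from [assign_instance_names()]).
#' @param timescale transition timescale (the owning process's).
#' @return list with `places` (character entity names touched) and
#'   `transitions` (list of [nwn_transition()]).
#' @export
expand_construct <- function(construct, instance, timescale = 1L) {
  kind <- construct$kind
  terms <- construct$terms
  ins <- Filter(function(t) t$direction == "input", terms)
  outs <- Filter(function(t) t$direction == "output", terms)
  mods <- Filter(function(t) t$direction == "modifier", terms)

  inputs <- list(); outputs <- list(); reads <- list(); inhibitors <- list()

  if (kind %in% c("TRANSCRIPTION", "TRANSLATION")) {
    reads <- list(entity_arc(ins[[1]]))
    outputs <- list(entity_arc(outs[[1]]))
  } else if (kind == "DEGRADATION") {
    inputs <- list(entity_arc(ins[[1]]))
  } else if (kind == "PROTEIN_COMPLEX_FORMATION") {
    inputs <- lapply(ins, entity_arc)
    outputs <- lapply(outs, entity_arc)
  } else if (kind == "ENZYMATIC_REACTION") {
    reads <- lapply(mods, entity_arc)
    inputs <- lapply(ins, entity_arc)
    outputs <- lapply(outs, entity_arc)
  } else if (kind == "CUSTOM_PROCESS") {
    inputs <- lapply(ins, entity_arc)
    outputs <- lapply(outs, entity_arc)
  } else {
    stop("unknown construct kind: ", kind, call. = FALSE)
  }

  ra <- role_arcs(construct$roles, reads, inhibitors)

  tag <- if (length(outs) > 0L) outs[[length(outs)]]$entity
         else ins[[1]]$entity
  tname <- paste0(instance, "_", tolower(kind), "_", tag)

  entities <- unique(vapply(c(terms, unlist(construct$roles,
                                            recursive = FALSE)),
                            `[[`, "", "entity"))
  list(
    places = entities,
    transitions = list(nwn_transition(
      tname, inputs = inputs, outputs = outputs,
      reads = ra$reads, inhibitors = ra$inhibitors,
      timescale = timescale
    ))
  )
}

cell_place_name <- function(coord) paste0("cell_", coord[1], "_", coord[2])

build_scope_net <- function(sc, module, instance_of) {
  entity_names <- character(0)
  transitions <- list()
  used_tnames <- character(0)
  for (pr in sc$processes) {
    inst <- instance_of[[paste0(sc$id, "/", pr$id)]]
    ## reuse consumes instance names in source order
    instance_of[[paste0(sc$id, "/", pr$id)]] <- NULL
    for (con in pr$constructs) {
      frag <- expand_construct(con, inst, pr$timescale)
      entity_names <- union(entity_names, frag$places)
      for (tr in frag$transitions) {
        ## uniquify on collision (e.g. two degradations of one entity)
        base <- tr$name; k <- 1L
        while (tr$name %in% used_tnames) {
          tr$name <- paste0(base, "_", k); k <- k + 1L
        }
        used_tnames <- c(used_tnames, tr$name)
        transitions[[length(transitions) + 1L]] <- tr
      }
    }
  }
  ## places for signal entities even if no construct touches them
  for (sg in sc$signals) entity_names <- union(entity_names, sg$entity)
  for (mk in sc$markings) entity_names <- union(entity_names, mk$entity)

  init <- stats::setNames(rep(0L, length(entity_names)), entity_names)
  for (mk in sc$markings) init[[mk$entity]] <- mk$count

  places <- lapply(entity_names, function(e)
    nwn_place(e, stats::setNames(init[[e]], e)))
  list(net = nwn_net(sc$id, places, transitions,
                     timescale = module$timescale),
       instance_of = instance_of)
}

moore_pairs <- function(coords) {
  ids <- names(coords)
  pairs <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      if (grid_adjacent(coords[[i]], coords[[j]]))
        pairs[[length(pairs) + 1L]] <- c(ids[i], ids[j])
    }
  }
  pairs
}

add_place_if_missing <- function(net, entity) {
  if (!entity %in% names(net$places)) {
    net$places[[entity]] <- nwn_place(entity, stats::setNames(0L, entity))
  }
  net
}

#' Wire module-level diffusion into the top net
#'
#' Each diffusion declaration yields one top-level transition per
#' direction, moving one matching colored token per firing between the two
#' grid places, plus mirror bindings so the hosted scope nets observe the
#' moved tokens.  `DIFFUSION(entity, all)` wires every ordered
#' Moore-adjacent pair of grid cells.
#'
#' @param model an [nwn_model()] under construction.
#' @param module the source module.
#' @return the model with diffusion transitions and bindings added.
#' @keywords internal
wire_diffusion <- function(model, module) {
  coords <- model$coords
  bound <- character(0)  # "scope|entity" pairs already mirror-bound
  for (df in module$diffusions) {
    pairs <- if (identical(df$from, "all")) {
      moore_pairs(coords)
    } else {
      p <- list(c(df$from, df$to))
      if (df$bidirectional) p <- c(p, list(c(df$to, df$from)))
      p
    }
    for (pr in pairs) {
      from <- pr[1]; to <- pr[2]
      if (!from %in% names(coords) || !to %in% names(coords))
        stop("diffusion endpoint missing: ", from, " -> ", to,
             call. = FALSE)
      tname <- paste0("diffusion_", df$entity, "_", from, "_to_", to)
      model$top$transitions[[tname]] <- nwn_transition(
        tname,
        inputs = list(nwn_arc(cell_place_name(coords[[from]]), 1L,
                              df$entity)),
        outputs = list(nwn_arc(cell_place_name(coords[[to]]), 1L,
                               df$entity))
      )
      for (s in c(from, to)) {
        key <- paste0(s, "|", df$entity)
        if (key %in% bound) next
        bound <- c(bound, key)
        model$scopes[[s]] <- add_place_if_missing(model$scopes[[s]],
                                                  df$entity)
        model$bindings[[length(model$bindings) + 1L]] <- list(
          upper_place = cell_place_name(coords[[s]]), label = df$entity,
          scope = s, lower_place = df$entity)
      }
    }
  }
  model
}

#' Wire juxtacrine signals into synchronous channels
#'
#' Pairs every `emit` declaration with a matching `receive` declaration in
#' the partner scope (same entity; partner back-reference optional) and
#' creates a channel interlocking a token-consuming emit transition with a
#' token-producing receive transition: one declared entity token crosses
#' per joint firing.  An emit with no matching receiver is dropped with a
#' warning.
#'
#' @param model an [nwn_model()] under construction.
#' @param module the source module.
#' @return the model with channel transitions and channel records added.
#' @keywords internal
wire_juxtacrine <- function(model, module) {
  scope_of <- stats::setNames(module$scopes,
                              vapply(module$scopes, `[[`, "", "id"))
  for (sc in module$scopes) {
    for (sg in sc$signals) {
      if (sg$kind != "JUXTACRINE_SIGNAL" || sg$direction != "emit") next
      q <- sg$partner
      recv_ok <- FALSE
      if (!is.na(q) && q %in% names(scope_of)) {
        for (rsg in scope_of[[q]]$signals) {
          if (rsg$kind == "JUXTACRINE_SIGNAL" &&
              rsg$direction == "receive" &&
              rsg$entity == sg$entity &&
              (is.na(rsg$partner) || rsg$partner == sc$id)) {
            recv_ok <- TRUE
            break
          }
        }
      }
      if (!recv_ok) {
        warning("juxtacrine emit of '", sg$entity, "' from scope '",
                sc$id, "' has no matching receiver; channel omitted",
                call. = FALSE)
        next
      }
      chan_id <- paste0("chan_", sg$entity, "_", sc$id, "_", q)
      ename <- paste0("jux_emit_", sg$entity, "_to_", q)
      rname <- paste0("jux_recv_", sg$entity, "_from_", sc$id)
      model$scopes[[sc$id]] <- add_place_if_missing(model$scopes[[sc$id]],
                                                    sg$entity)
      model$scopes[[q]] <- add_place_if_missing(model$scopes[[q]],
                                                sg$entity)
      model$scopes[[sc$id]]$transitions[[ename]] <- nwn_transition(
        ename, inputs = list(nwn_arc(sg$entity, 1L, sg$entity)),
        channel = chan_id, channel_role = "initiator")
      model$scopes[[q]]$transitions[[rname]] <- nwn_transition(
        rname, outputs = list(nwn_arc(sg$entity, 1L, sg$entity)),
        channel = chan_id, channel_role = "responder")
      model$channels[[chan_id]] <- list(
        id = chan_id, entity = sg$entity,
        from = list(sc$id, ename), to = list(q, rname))
    }
  }
  model
}

#' Compile a module AST into a nets-within-nets model
#'
#' Validates the module (stopping on errors), resolves process reuse, and
#' lowers it.  Compilation is deterministic and pure: the same AST always
#' yields a structurally identical model.
#'
#' @param module a [bisdl_module()] (or BiSDL source text / file path,
#'   which is parsed first).
#' @return an [nwn_model()].
#' @examples
#' mod <- bisdl_parse(c(
#'   "MODULE water",
#'   "    TIMESCALE 1",
#'   "    SCOPE s (0, 0)",
#'   "        MARKING(H2_molecule, 4)",
#'   "        MARKING(O2_molecule, 2)",
#'   "        PROCESS reaction",
#'   "            TIMESCALE 1",
#'   "            CUSTOM_PROCESS(2*H2_molecule + O2_molecule -> 2*H2O_molecule)"
#' ))
#' model <- bisdl_compile(mod)
#' model
#' @export
bisdl_compile <- function(module) {
  if (is.character(module)) {
    module <- if (length(module) == 1L && file.exists(module))
      bisdl_read(module) else bisdl_parse(module)
  }
  diags <- bisdl_validate(module)
  errs <- diags[diags$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L)
    stop("module does not validate:\n  ",
         paste(errs$message, collapse = "\n  "), call. = FALSE)
  module <- bisdl_resolve_reuse(module)

  registry <- assign_instance_names(module)
  ## per-(scope, process) queues of instance names, in source order
  iq <- if (length(registry) == 0L) list()
        else split(names(registry), unname(registry))  # keeps source order

  scope_ids <- vapply(module$scopes, `[[`, "", "id")
  coords <- stats::setNames(lapply(module$scopes, `[[`, "coord"), scope_ids)

  scopes <- list()
  for (sc in module$scopes) {
    inst_map <- list()
    for (pr in sc$processes) {
      key <- paste0(sc$id, "/", pr$id)
      inst_map[[key]] <- iq[[key]][1]
      iq[[key]] <- iq[[key]][-1]
    }
    built <- build_scope_net(sc, module, inst_map)
    scopes[[sc$id]] <- built$net
  }

  top_places <- lapply(module$scopes, function(sc)
    nwn_place(cell_place_name(sc$coord),
              stats::setNames(1L, paste0(NET_TOKEN_PREFIX, sc$id))))
  top <- nwn_net(module$name, top_places, list(),
                 timescale = module$timescale)

  model <- nwn_model(top, scopes, channels = list(), bindings = list(),
                     coords = coords, registry = registry,
                     name = module$name)
  model <- wire_diffusion(model, module)
  model <- wire_juxtacrine(model, module)
  ## arcs were added to top after construction; re-check references
  model$top <- nwn_net(model$top$name, model$top$places,
                       model$top$transitions, model$top$timescale)
  model
}
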