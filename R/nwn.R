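#' @title A nets-within-nets Petri-net engine
#'
#' @description
#' Bipartite nets of places and transitions over multiset markings.  Tokens
#' are labelled: ordinary resources are colored tokens labelled by entity
#' name (`"black"` is just the anonymous label), and a place of the
#' top-level spatial grid additionally hosts one *net token* per biological
#' scope — an embedded live net instance, giving the two-level hierarchy.
#' Transitions carry a firing probability and an integer timescale;
#' channels interlock transitions of different nets so they fire
#' atomically; mirror bindings keep the colored-token content of a grid
#' place and of a place inside its hosted net identical across levels.
#'
#' Markings are represented as named integer vectors (label -> count) per
#' place; the state of a whole model is an environment created by
#' [nwn_state()].
#'
#' @name nwn-engine
NULL

NET_TOKEN_PREFIX <- "@net:"

#' Arc constructor
#'
#' @param place name of the place the arc touches.
#' @param weight positive integer: tokens required/produced, or the
#'   strictly-exclusive threshold for inhibitor arcs.
#' @param label token label the arc matches ("black" for anonymous tokens).
#' @return a list describing the arc.
#' @export
nwn_arc <- function(place, weight = 1L, label = "black") {
  weight <- as.integer(weight)
  if (is.na(weight) || weight < 1L)
    stop("arc weight must be >= 1", call. = FALSE)
  list(place = place, weight = weight, label = label)
}

#' Transition constructor
#'
#' @param name transition name, unique within its net.
#' @param inputs,outputs lists of [nwn_arc()]; inputs are consumed,
#'   outputs produced.
#' @param reads list of read arcs (tested for `count >= weight`, never
#'   consumed).
#' @param inhibitors list of inhibitor arcs (tested for `count < weight`).
#' @param p firing probability in `[0, 1]`; `NA` means "use the
#'   simulation default".
#' @param timescale positive integer multiplier of the owning net's
#'   timescale; the transition is only visited at ticks divisible by the
#'   product.
#' @param channel optional channel id interlocking this transition with a
#'   counterpart in another net.
#' @param channel_role "initiator" (drives the channel during the sweep) or
#'   "responder" (fires only jointly with its initiator).
#' @return a list describing the transition.
#' @export
nwn_transition <- function(name, inputs = list(), outputs = list(),
                           reads = list(), inhibitors = list(),
                           p = NA_real_, timescale = 1L,
                           channel = NA_character_,
                           channel_role = "initiator") {
  if (!is.na(p) && (p < 0 || p > 1))
    stop("firing probability must lie in [0, 1]", call. = FALSE)
  timescale <- as.integer(timescale)
  if (is.na(timescale) || timescale < 1L)
    stop("transition timescale must be >= 1", call. = FALSE)
  list(name = name, inputs = inputs, outputs = outputs, reads = reads,
       inhibitors = inhibitors, p = p, timescale = timescale,
       channel = channel, channel_role = channel_role)
}

#' Place constructor
#'
#' @param name place name, unique within its net.
#' @param init named integer vector of initial token counts per label; an
#'   unnamed scalar is shorthand for that many "black" tokens.
#' @return a list describing the place.
#' @export
nwn_place <- function(name, init = integer(0)) {
  if (length(init) > 0L && is.null(names(init)))
    init <- stats::setNames(as.integer(init), rep("black", length(init)))
  storage.mode(init) <- "integer"
  if (any(init < 0L)) stop("token counts must be >= 0", call. = FALSE)
  list(name = name, init = init)
}

#' Net constructor
#'
#' @param name net name.
#' @param places list of [nwn_place()].
#' @param transitions list of [nwn_transition()].
#' @param timescale positive integer pace: the net is visited only at ticks
#'   divisible by this.
#' @return an object of class `nwn_net`.
#' @export
nwn_net <- function(name, places = list(), transitions = list(),
                    timescale = 1L) {
  timescale <- as.integer(timescale)
  if (is.na(timescale) || timescale < 1L)
    stop("net timescale must be >= 1", call. = FALSE)
  places <- stats::setNames(places, vapply(places, `[[`, "", "name"))
  transitions <- stats::setNames(transitions,
                                 vapply(transitions, `[[`, "", "name"))
  pn <- names(places)
  for (tr in transitions) {
    for (a in c(tr$inputs, tr$outputs, tr$reads, tr$inhibitors)) {
      if (!a$place %in% pn)
        stop("transition '", tr$name, "' references unknown place '",
             a$place, "'", call. = FALSE)
    }
  }
  structure(list(name = name, timescale = timescale, places = places,
                 transitions = transitions),
            class = "nwn_net")
}

#' Two-level model constructor
#'
#' @param top the top-level (spatial grid) net.
#' @param scopes named list of scope nets hosted as net tokens in grid
#'   places.
#' @param channels named list of channels, each
#'   `list(id, from = c(net, transition), to = c(net, transition))`.
#' @param bindings list of mirror bindings, each
#'   `list(upper_place, label, scope, lower_place)`: the colored-token
#'   count of `label` in the top-level `upper_place` mirrors the count in
#'   `lower_place` of the hosted scope net.
#' @param coords named list of grid coordinates per scope.
#' @param registry named character vector mapping process instance names to
#'   their source process ids.
#' @param name model name.
#' @return an object of class `nwn_model`.
#' @export
nwn_model <- function(top, scopes = list(), channels = list(),
                      bindings = list(), coords = list(),
                      registry = character(0), name = top$name) {
  structure(list(name = name, top = top, scopes = scopes,
                 channels = channels, bindings = bindings,
                 coords = coords, registry = registry),
            class = "nwn_model")
}

#' @export
print.nwn_net <- function(x, ...) {
  cat("<nwn_net> ", x$name, ": ", length(x$places), " places, ",
      length(x$transitions), " transitions, timescale ", x$timescale,
      "\n", sep = "")
  invisible(x)
}

#' @export
print.nwn_model <- function(x, ...) {
  cat("<nwn_model> ", x$name, "\n", sep = "")
  cat("  top net: ", length(x$top$places), " places, ",
      length(x$top$transitions), " transitions\n", sep = "")
  cat("  scope nets: ", length(x$scopes), "\n", sep = "")
  cat("  channels: ", length(x$channels),
      ", mirror bindings: ", length(x$bindings), "\n", sep = "")
  invisible(x)
}

## ---- markings -----------------------------------------------------------

#' Initial marking of a net
#' @param net an [nwn_net()].
#' @return named list: place name -> named integer vector (label -> count).
#' @export
nwn_init_marking <- function(net) {
  lapply(net$places, `[[`, "init")
}

count_of <- function(marking, place, label) {
  if (!place %in% names(marking))
    stop("dangling arc reference: no place '", place, "'", call. = FALSE)
  v <- marking[[place]]
  n <- v[label]
  if (is.na(n)) 0L else as.integer(n)
}

add_tokens <- function(marking, place, label, delta) {
  v <- marking[[place]]
  cur <- v[label]
  if (is.na(cur)) cur <- 0L
  new <- as.integer(cur + delta)
  if (new < 0L)
    stop("negative token count in place '", place, "'", call. = FALSE)
  v[label] <- new
  marking[[place]] <- v
  marking
}

## ---- enabling and firing ------------------------------------------------

#' Is a transition enabled under a marking?
#'
#' A transition is enabled when every input and read arc finds at least
#' `weight` tokens of its label in its place and every inhibitor arc's
#' place holds strictly fewer matching tokens than its threshold.  Channel
#' interlocks are checked by the stepper ([nwn_step()]), which requires the
#' counterpart endpoint to be enabled too.
#'
#' @param net an [nwn_net()].
#' @param transition transition name.
#' @param marking a marking as from [nwn_init_marking()].
#' @return logical.
#' @export
nwn_enabled <- function(net, transition, marking) {
  tr <- net$transitions[[transition]]
  if (is.null(tr))
    stop("no transition '", transition, "' in net '", net$name, "'",
         call. = FALSE)
  for (a in c(tr$inputs, tr$reads)) {
    if (count_of(marking, a$place, a$label) < a$weight) return(FALSE)
  }
  for (a in tr$inhibitors) {
    if (count_of(marking, a$place, a$label) >= a$weight) return(FALSE)
  }
  TRUE
}

#' Fire a transition, returning the updated marking
#'
#' Consumes `weight` tokens of each input arc's label and produces output
#' tokens; read and inhibitor arcs leave the marking untouched.  Tokens of
#' one label are indistinguishable, so the random choice among matching
#' tokens required by the stochastic semantics is the identity on count
#' multisets and consumes no randomness.
#'
#' @inheritParams nwn_enabled
#' @return the updated marking.
#' @export
nwn_fire <- function(net, transition, marking) {
  if (!nwn_enabled(net, transition, marking))
    stop("transition '", transition, "' fired while disabled",
         call. = FALSE)
  tr <- net$transitions[[transition]]
  for (a in tr$inputs)
    marking <- add_tokens(marking, a$place, a$label, -a$weight)
  for (a in tr$outputs)
    marking <- add_tokens(marking, a$place, a$label, +a$weight)
  marking
}

## ---- model state --------------------------------------------------------

all_nets <- function(model) {
  c(stats::setNames(list(model$top), model$top$name), model$scopes)
}

#' Create a fresh mutable simulation state for a model
#'
#' @param model an [nwn_model()].
#' @return an environment holding per-net markings (`m`), cumulative
#'   per-transition firing counts (`fired`), per-net visit counts
#'   (`visits`), the firing event log (`events`), and mirror reference
#'   values (`mref`).
#' @export
nwn_state <- function(model) {
  st <- new.env(parent = emptyenv())
  nets <- all_nets(model)
  st$m <- lapply(nets, nwn_init_marking)
  st$fired <- lapply(nets, function(n)
    stats::setNames(integer(length(n$transitions)), names(n$transitions)))
  st$visits <- stats::setNames(integer(length(nets)), names(nets))
  st$events <- list()
  ## mirror reference: the last value both levels agreed on
  st$mref <- vapply(model$bindings, function(b)
    count_of(st$m[[model$top$name]], b$upper_place, b$label), integer(1))
  ## establish the mirror invariant at t=0 (upper level wins)
  for (bi in seq_along(model$bindings)) nwn_mirror(model, st, bi)
  st
}

#' Token count of one place in the current state
#' @param model an [nwn_model()].
#' @param state a state from [nwn_state()].
#' @param net net name (the top net's name or a scope id).
#' @param place place name.
#' @param label token label; defaults to the place name (entity places) if
#'   present, else sums all labels.
#' @return integer count.
#' @export
nwn_count <- function(model, state, net, place, label = NULL) {
  v <- state$m[[net]][[place]]
  if (is.null(v)) stop("no place '", place, "' in net '", net, "'",
                       call. = FALSE)
  if (is.null(label)) return(as.integer(sum(v)))
  n <- v[label]
  if (is.na(n)) 0L else as.integer(n)
}

## ---- mirror bindings ----------------------------------------------------

#' Re-satisfy one mirror binding
#'
#' Compares both levels against the reference value they last agreed on;
#' the level that changed becomes the source of truth.  If both levels
#' changed inconsistently since the last repair, the upper (grid) level
#' wins and a warning is emitted.
#'
#' @param model an [nwn_model()].
#' @param state a state from [nwn_state()].
#' @param bi index of the binding in `model$bindings`.
#' @return the reconciled count, invisibly.
#' @export
nwn_mirror <- function(model, state, bi) {
  b <- model$bindings[[bi]]
  topn <- model$top$name
  u <- count_of(state$m[[topn]], b$upper_place, b$label)
  l <- count_of(state$m[[b$scope]], b$lower_place, b$label)
  r <- if (length(state$mref) >= bi) state$mref[[bi]] else u
  final <- if (u == l) {
    u
  } else if (u != r && l != r) {
    warning("mirror conflict on ", b$upper_place, "/", b$label,
            ": both levels changed; upper level wins", call. = FALSE)
    u
  } else if (u != r) {
    u
  } else {
    l
  }
  state$m[[topn]] <- add_tokens(state$m[[topn]], b$upper_place, b$label,
                                final - u)
  state$m[[b$scope]] <- add_tokens(state$m[[b$scope]], b$lower_place,
                                   b$label, final - l)
  state$mref[[bi]] <- final
  invisible(final)
}

repair_mirrors <- function(model, state) {
  for (bi in seq_along(model$bindings)) nwn_mirror(model, state, bi)
}

## ---- stepping -----------------------------------------------------------

resolve_endpoint <- function(model, ep) {
  net <- all_nets(model)[[ep[[1]]]]
  list(net = net, trans = net$transitions[[ep[[2]]]])
}

log_fire <- function(state, tick, netname, transname) {
  state$fired[[netname]][[transname]] <-
    state$fired[[netname]][[transname]] + 1L
  state$events[[length(state$events) + 1L]] <-
    list(tick = tick, net = netname, transition = transname)
}

#' Advance a model by one simulator tick
#'
#' Nets are swept in a canonical deterministic order (top net first, then
#' scope nets in model order); a net is visited only when `tick` is
#' divisible by its timescale, and a transition only when `tick` is
#' additionally divisible by net timescale times transition timescale.
#' Within a visited net, transitions are shuffled afresh (randomized
#' conflict resolution) and each enabled one fires at most once, with
#' probability `p` (its own, or `default_p`).  Channel-bound transitions
#' fire atomically with their counterpart when both endpoints are enabled.
#' All mirror bindings are re-satisfied after each net's sweep, hence
#' before the function returns.
#'
#' Randomness comes from R's global RNG stream; seed it (once, per run)
#' for reproducible traces.
#'
#' @param model an [nwn_model()].
#' @param state a state from [nwn_state()]; modified in place.
#' @param tick integer tick, starting at 1.
#' @param default_p default firing probability for transitions with `p = NA`.
#' @return the state, invisibly.
#' @export
nwn_step <- function(model, state, tick, default_p = 0.6) {
  nets <- all_nets(model)
  for (nm in names(nets)) {
    net <- nets[[nm]]
    if (tick %% net$timescale != 0L) next
    state$visits[[nm]] <- state$visits[[nm]] + 1L
    tnames <- names(net$transitions)
    if (length(tnames) == 0L) next
    if (length(tnames) > 1L) tnames <- sample(tnames)
    for (tn in tnames) {
      tr <- net$transitions[[tn]]
      if (tick %% (net$timescale * tr$timescale) != 0L) next
      if (!is.na(tr$channel) && tr$channel_role != "initiator") next
      if (is.na(tr$channel)) {
        if (!nwn_enabled(net, tn, state$m[[nm]])) next
        p <- if (is.na(tr$p)) default_p else tr$p
        if (p < 1 && stats::runif(1) >= p) next
        state$m[[nm]] <- nwn_fire(net, tn, state$m[[nm]])
        log_fire(state, tick, nm, tn)
      } else {
        ch <- model$channels[[tr$channel]]
        other_ep <- if (identical(ch$from[[2]], tn)) ch$to else ch$from
        other <- resolve_endpoint(model, other_ep)
        onm <- other$net$name
        if (!nwn_enabled(net, tn, state$m[[nm]])) next
        if (!nwn_enabled(other$net, other$trans$name, state$m[[onm]])) next
        p <- if (is.na(tr$p)) default_p else tr$p
        if (p < 1 && stats::runif(1) >= p) next
        state$m[[nm]] <- nwn_fire(net, tn, state$m[[nm]])
        state$m[[onm]] <- nwn_fire(other$net, other$trans$name,
                                   state$m[[onm]])
        log_fire(state, tick, nm, tn)
        log_fire(state, tick, onm, other$trans$name)
      }
    }
    if (length(model$bindings)) repair_mirrors(model, state)
  }
  invisible(state)
}

## ---- brute-force reachability oracle ------------------------------------

marking_key <- function(marking) {
  parts <- character(0)
  for (p in sort(names(marking))) {
    v <- marking[[p]]
    v <- v[v > 0L]
    if (length(v) == 0L) next
    v <- v[order(names(v))]
    parts <- c(parts, paste0(p, "{", paste0(names(v), ":", v,
                                            collapse = ","), "}"))
  }
  if (length(parts) == 0L) return("<empty>")
  paste(parts, collapse = ";")
}

#' Exhaustively enumerate reachable markings of a small net
#'
#' Breadth-first exploration firing every enabled transition from every
#' frontier marking (probabilities and timescales are ignored: this is the
#' possibility semantics, used as an independent oracle for the stochastic
#' stepper on small fixture nets).
#'
#' @param net an [nwn_net()] with a handful of places and bounded tokens.
#' @param marking starting marking; defaults to the net's initial marking.
#' @param depth maximum number of firings along any path.
#' @param max_states safety cap on explored states.
#' @return a list of markings; attribute `complete` is `FALSE` if a bound
#'   was hit, and attribute `keys` carries the canonical string form of
#'   every marking for fast membership tests.
#' @export
nwn_reachable <- function(net, marking = nwn_init_marking(net),
                          depth = Inf, max_states = 10000L) {
  seen <- new.env(parent = emptyenv())
  frontier <- list(marking)
  assign(marking_key(marking), TRUE, envir = seen)
  out <- list(marking)
  complete <- TRUE
  d <- 0L
  while (length(frontier) > 0L && d < depth) {
    d <- d + 1L
    nxt <- list()
    for (mk in frontier) {
      for (tn in names(net$transitions)) {
        if (!nwn_enabled(net, tn, mk)) next
        mk2 <- nwn_fire(net, tn, mk)
        key <- marking_key(mk2)
        if (exists(key, envir = seen, inherits = FALSE)) next
        if (length(out) >= max_states) {
          complete <- FALSE
          break
        }
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <- mk2
        nxt[[length(nxt) + 1L]] <- mk2
      }
      if (!complete) break
    }
    if (!complete) break
    frontier <- nxt
  }
  if (length(frontier) > 0L && d >= depth && is.finite(depth))
    complete <- FALSE
  structure(out, complete = complete,
            keys = vapply(out, marking_key, character(1)))
}

#' Canonical string form of a marking (for membership tests)
#' @param marking a marking.
#' @return a single string; empty places are omitted.
#' @export
nwn_marking_key <- function(marking) marking_key(marking)
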