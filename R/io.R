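#' @title File emission and command-line entry points
#'
#' @description
#' DOT (Graphviz) serialization of nets, a stable JSON model manifest for
#' golden-file comparisons, the `tick,scope,place,count` trace CSV, JSON
#' simulation configs mirroring [sim_config()] / [stimulus_schedule()]
#' field names, and the three CLI verbs (`compile`, `simulate`,
#' `fixtures`) behind the `inst/bin/bisdl` script.
#'
#' @name bisdl-io
NULL

dot_id <- function(x) paste0('"', gsub('"', "'", x), '"')

#' Serialize one net to DOT (Graphviz)
#'
#' Places render as circles (grid places hosting net tokens are annotated
#' with the hosted scope), transitions as boxes; input/output arcs as
#' solid edges, read arcs as dashed edges, inhibitor arcs as dashed edges
#' with a dot arrowhead.
#'
#' @param net an [nwn_net()].
#' @param path output file; if `NULL` the DOT text is returned invisibly.
#' @return the DOT lines, invisibly.
#' @export
nwn_write_dot <- function(net, path = NULL) {
  lines <- c(paste0("digraph ", dot_id(net$name), " {"),
             "  rankdir=LR;")
  for (p in net$places) {
    hosted <- names(p$init)[startsWith(names(p$init), NET_TOKEN_PREFIX)]
    lab <- p$name
    if (length(hosted) > 0L)
      lab <- paste0(p$name, "\\n[hosts ",
                    paste(sub(NET_TOKEN_PREFIX, "", hosted, fixed = TRUE),
                          collapse = ", "), "]")
    lines <- c(lines, paste0("  ", dot_id(p$name),
                             " [shape=circle, label=", dot_id(lab), "];"))
  }
  for (tr in net$transitions) {
    lines <- c(lines, paste0("  ", dot_id(tr$name), " [shape=box];"))
    for (a in tr$inputs)
      lines <- c(lines, paste0("  ", dot_id(a$place), " -> ",
                               dot_id(tr$name), " [label=", dot_id(
                                 paste0(a$weight, "x", a$label)), "];"))
    for (a in tr$reads)
      lines <- c(lines, paste0("  ", dot_id(a$place), " -> ",
                               dot_id(tr$name), " [style=dashed, label=",
                               dot_id(paste0(a$weight, "x", a$label)),
                               "];"))
    for (a in tr$inhibitors)
      lines <- c(lines, paste0("  ", dot_id(a$place), " -> ",
                               dot_id(tr$name),
                               " [style=dashed, arrowhead=dot, label=",
                               dot_id(paste0("<", a$weight, " ", a$label)),
                               "];"))
    for (a in tr$outputs)
      lines <- c(lines, paste0("  ", dot_id(tr$name), " -> ",
                               dot_id(a$place), " [label=", dot_id(
                                 paste0(a$weight, "x", a$label)), "];"))
  }
  lines <- c(lines, "}")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

arc_manifest <- function(arcs) {
  lapply(arcs, function(a)
    list(place = a$place, weight = a$weight, label = a$label))
}

net_manifest <- function(net) {
  list(
    name = net$name,
    timescale = net$timescale,
    places = lapply(unname(net$places), function(p)
      list(name = p$name,
           init = as.list(p$init[p$init > 0L]))),
    transitions = lapply(unname(net$transitions), function(tr)
      list(name = tr$name,
           p = if (is.na(tr$p)) "default" else tr$p,
           timescale = tr$timescale,
           channel = if (is.na(tr$channel)) NULL else tr$channel,
           inputs = arc_manifest(tr$inputs),
           outputs = arc_manifest(tr$outputs),
           reads = arc_manifest(tr$reads),
           inhibitors = arc_manifest(tr$inhibitors)))
  )
}

#' Structural manifest of a compiled model
#'
#' A plain list (JSON-ready, stable key order) describing every net,
#' place, transition, arc, channel, mirror binding and generated instance
#' name; suitable for golden-file tests of compiler determinism.
#'
#' @param model an [nwn_model()].
#' @return a named list.
#' @export
model_manifest <- function(model) {
  list(
    model = model$name,
    grid = lapply(model$coords, function(co) as.list(
      stats::setNames(as.integer(co), c("x", "y")))),
    top = net_manifest(model$top),
    scopes = lapply(model$scopes, net_manifest),
    channels = lapply(model$channels, function(ch)
      list(id = ch$id, entity = ch$entity,
           from = paste(unlist(ch$from), collapse = "/"),
           to = paste(unlist(ch$to), collapse = "/"))),
    bindings = lapply(model$bindings, function(b)
      list(upper_place = b$upper_place, label = b$label,
           scope = b$scope, lower_place = b$lower_place)),
    name_registry = as.list(model$registry)
  )
}

#' Write a trace as CSV (`tick,scope,place,count`)
#' @param trace a [bisdl_run()] trace.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  mk <- trace$markings[order(trace$markings$tick, trace$markings$scope,
                             trace$markings$place), , drop = FALSE]
  utils::write.csv(mk, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a JSON simulation config
#'
#' Schema mirrors [sim_config()] and [stimulus_schedule()]:
#' `{"nstep": 100, "seed": 1, "default_p": 0.6, "mode": "exploration",
#'   "draw_nets": false,
#'   "stimuli": [{"scope": "...", "place": "...", "n": 3, "r": 3}]}`.
#' All fields except `nstep` are optional.
#'
#' @param path JSON file.
#' @return list with `config` (a [sim_config()]) and `stimuli` (list of
#'   [stimulus_schedule()]).
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$nstep)) stop("config lacks 'nstep'", call. = FALSE)
  cfg <- sim_config(
    nstep = raw$nstep,
    seed = raw$seed %||0% 1L,
    default_p = raw$default_p %||0% 0.6,
    mode = raw$mode %||0% "exploration",
    draw_nets = isTRUE(raw$draw_nets)
  )
  stimuli <- lapply(raw$stimuli %||0% list(), function(s)
    stimulus_schedule(s$scope, s$place, s$n, s$r))
  list(config = cfg, stimuli = stimuli)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

run_manifest <- function(inputs, config, outputs) {
  list(
    tool = "bisdl",
    version = as.character(utils::packageVersion("bisdl")),
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    seed = config$seed,
    config = list(nstep = config$nstep, seed = config$seed,
                  default_p = config$default_p, mode = config$mode,
                  draw_nets = config$draw_nets),
    outputs = outputs
  )
}

#' Compile a source file and emit the model manifest plus DOT files
#'
#' Writes `manifest.json` and one `.dot` file per net: the top-level grid
#' net and each scope net.
#'
#' @param source path to a `.bisdl` file.
#' @param out_dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
cli_compile <- function(source, out_dir) {
  if (!file.exists(source)) stop("no such source file: ", source,
                                 call. = FALSE)
  model <- bisdl_compile(bisdl_read(source))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, "manifest.json")
  write_json_stable(model_manifest(model), paths)
  for (net in c(list(model$top), unname(model$scopes))) {
    p <- file.path(out_dir, paste0(net$name, ".dot"))
    nwn_write_dot(net, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Simulate a source file under a JSON config and emit trace + manifest
#'
#' @param source path to a `.bisdl` file.
#' @param config_path path to a JSON config (see [read_sim_config()]).
#' @param out_dir output directory (created if missing).
#' @param seed,nstep optional overrides of the config values.
#' @param draw_nets optional override; if `TRUE`, DOT files are emitted
#'   alongside the trace.
#' @return character vector of written paths, invisibly.
#' @export
cli_simulate <- function(source, config_path, out_dir, seed = NULL,
                         nstep = NULL, draw_nets = NULL) {
  if (!file.exists(source)) stop("no such source file: ", source,
                                 call. = FALSE)
  cc <- read_sim_config(config_path)
  cfg <- cc$config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(nstep)) cfg$nstep <- as.integer(nstep)
  if (!is.null(draw_nets)) cfg$draw_nets <- isTRUE(draw_nets)
  model <- bisdl_compile(bisdl_read(source))
  trace <- bisdl_run(model, cfg, cc$stimuli)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trace_path <- file.path(out_dir, "trace.csv")
  write_trace_csv(trace, trace_path)
  outputs <- "trace.csv"
  if (cfg$draw_nets) {
    for (net in c(list(model$top), unname(model$scopes))) {
      nwn_write_dot(net, file.path(out_dir, paste0(net$name, ".dot")))
      outputs <- c(outputs, paste0(net$name, ".dot"))
    }
  }
  manifest_path <- file.path(out_dir, "run_manifest.json")
  write_json_stable(run_manifest(list(source, config_path), cfg,
                                 as.list(outputs)),
                    manifest_path)
  invisible(c(trace_path, manifest_path))
}

fixture_config <- function(fix, scheme = NULL) {
  stimuli <- if (is.null(scheme)) list() else fix$stimuli[[scheme]]
  list(nstep = fix$nstep, seed = 1L, default_p = 0.6,
       mode = "exploration", draw_nets = FALSE,
       stimuli = lapply(stimuli, function(s)
         list(scope = s$scope, place = s$place, n = s$n, r = s$r)))
}

#' Regenerate the fixture tree
#'
#' Writes every shipped fixture as a `.bisdl` source plus JSON simulation
#' config(s) (one per stimulus scheme where the fixture has schemes).
#'
#' @param out_dir output directory.
#' @param overwrite if `FALSE` (default), refuse to clobber existing
#'   files.
#' @return character vector of written paths, invisibly.
#' @export
cli_fixtures <- function(out_dir, overwrite = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(path, writer) {
    if (file.exists(path) && !overwrite)
      stop("refusing to overwrite ", path, " (use overwrite = TRUE)",
           call. = FALSE)
    writer(path)
    paths <<- c(paths, path)
  }
  for (fix in bisdl_fixtures()) {
    emit(file.path(out_dir, paste0(fix$name, ".bisdl")),
         function(p) cat(fix$source, file = p))
    schemes <- if (length(fix$stimuli) > 0L) names(fix$stimuli)
               else NA_character_
    for (scheme in schemes) {
      cfg_name <- if (is.na(scheme)) paste0(fix$name, "_config.json")
                  else paste0(fix$name, "_", scheme, "_config.json")
      local({
        sch <- if (is.na(scheme)) NULL else scheme
        fx <- fix
        emit(file.path(out_dir, cfg_name),
             function(p) write_json_stable(fixture_config(fx, sch), p))
      })
    }
  }
  invisible(paths)
}

#' Plot marking evolution of observed places
#'
#' One line per observed place (optionally filtered); in "exploration"
#' mode the y axis adapts to the data.
#'
#' @param x a [bisdl_run()] trace.
#' @param places optional character vector of place names to show.
#' @param scopes optional character vector of scope names to show.
#' @param ... passed to [graphics::matplot()].
#' @return the plotted wide matrix, invisibly.
#' @export
plot.bisdl_trace <- function(x, places = NULL, scopes = NULL, ...) {
  mk <- x$markings
  if (!is.null(places)) mk <- mk[mk$place %in% places, , drop = FALSE]
  if (!is.null(scopes)) mk <- mk[mk$scope %in% scopes, , drop = FALSE]
  if (nrow(mk) == 0L) stop("nothing to plot", call. = FALSE)
  key <- paste(mk$scope, mk$place, sep = "/")
  wide <- stats::xtabs(count ~ tick + key, data = cbind(mk, key = key))
  graphics::matplot(as.integer(rownames(wide)), unclass(wide), type = "l",
                    lty = 1, xlab = "tick", ylab = "tokens", ...)
  graphics::legend("topleft", legend = colnames(wide), lty = 1,
                   col = seq_len(ncol(wide)), cex = 0.7, bty = "n")
  invisible(wide)
}

#' Per-cell grid counts of one place at one tick
#'
#' Arranges the counts of `place` across all scopes of a compiled spatial
#' model as a matrix indexed by grid coordinate (row = y, column = x),
#' reproducing the case-study heatmap layout.
#'
#' @param trace a [bisdl_run()] trace.
#' @param model the [nwn_model()] that produced it (for coordinates).
#' @param place place (entity) name.
#' @param tick tick to extract (default: final).
#' @return numeric matrix; cells whose scope lacks the place are `NA`.
#' @export
grid_counts <- function(trace, model, place, tick = NULL) {
  mk <- trace$markings
  if (is.null(tick)) tick <- max(mk$tick)
  xs <- vapply(model$coords, `[`, integer(1), 1)
  ys <- vapply(model$coords, `[`, integer(1), 2)
  mat <- matrix(NA_real_, nrow = max(ys) + 1L, ncol = max(xs) + 1L)
  sel <- mk$tick == tick & mk$place == place
  for (i in which(sel)) {
    co <- model$coords[[mk$scope[i]]]
    mat[co[2] + 1L, co[1] + 1L] <- mk$count[i]
  }
  mat
}

#' Command-line driver
#'
#' Implements `bisdl compile <src> -o DIR`, `bisdl simulate <src> -c
#' CONFIG -o DIR [--seed N] [--nstep N] [--draw-nets]` and `bisdl
#' fixtures -o DIR [--overwrite]`; used by the `inst/bin/bisdl` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
bisdl_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage:",
    "  bisdl compile <src.bisdl> -o DIR",
    "  bisdl simulate <src.bisdl> -c CONFIG.json -o DIR [--seed N] [--nstep N] [--draw-nets]",
    "  bisdl fixtures -o DIR [--overwrite]",
    sep = "\n")
  take_opt <- function(args, flag) {
    i <- which(args == flag)
    if (length(i) == 0L) return(list(value = NULL, args = args))
    if (i[1] == length(args)) stop("missing value for ", flag,
                                   call. = FALSE)
    list(value = args[i[1] + 1L], args = args[-c(i[1], i[1] + 1L)])
  }
  has_flag <- function(args, flag) {
    list(value = flag %in% args, args = setdiff(args, flag))
  }
  status <- tryCatch({
    if (length(args) < 1L) stop(usage, call. = FALSE)
    verb <- args[1]; rest <- args[-1]
    o <- take_opt(rest, "-o"); rest <- o$args
    if (verb == "compile") {
      if (length(rest) != 1L || is.null(o$value))
        stop(usage, call. = FALSE)
      cli_compile(rest[1], o$value)
    } else if (verb == "simulate") {
      cfg <- take_opt(rest, "-c"); rest <- cfg$args
      seed <- take_opt(rest, "--seed"); rest <- seed$args
      nstep <- take_opt(rest, "--nstep"); rest <- nstep$args
      dn <- has_flag(rest, "--draw-nets"); rest <- dn$args
      if (length(rest) != 1L || is.null(o$value) || is.null(cfg$value))
        stop(usage, call. = FALSE)
      cli_simulate(rest[1], cfg$value, o$value, seed = seed$value,
                   nstep = nstep$value,
                   draw_nets = if (dn$value) TRUE else NULL)
    } else if (verb == "fixtures") {
      ow <- has_flag(rest, "--overwrite"); rest <- ow$args
      if (is.null(o$value)) stop(usage, call. = FALSE)
      cli_fixtures(o$value, overwrite = ow$value)
    } else {
      stop(usage, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
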