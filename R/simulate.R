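#' @title Discrete-time stochastic simulation
#'
#' @description
#' [bisdl_run()] executes a compiled model for a fixed number of ticks.
#' Each tick applies due external stimuli (black-token injections on a
#' period-`n`/amplitude-`r` schedule), advances every timescale-gated net
#' by one sweep of randomized transition firings ([nwn_step()]), and
#' records the marking of every scope-net place.  A run is fully
#' determined by its seed.
#'
#' @name bisdl-simulator
NULL

#' Simulation configuration
#'
#' @param nstep positive integer number of simulation steps.
#' @param seed integer RNG seed; the run is reproducible given the seed.
#' @param default_p default firing probability for transitions that do not
#'   set their own (the stochastic engine's global default is 0.6).
#' @param mode "exploration" (plot axes adapt to the data) or "fixed-axes";
#'   only affects visual output.
#' @param draw_nets logical; whether CLI runs should also emit DOT files of
#'   the net architectures.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(nstep = 100L, seed = 1L, default_p = 0.6,
                       mode = c("exploration", "fixed-axes"),
                       draw_nets = FALSE) {
  nstep <- as.integer(nstep)
  if (is.na(nstep) || nstep < 1L)
    stop("nstep must be a positive integer", call. = FALSE)
  if (default_p < 0 || default_p > 1)
    stop("default_p must lie in [0, 1]", call. = FALSE)
  structure(list(nstep = nstep, seed = as.integer(seed),
                 default_p = default_p, mode = match.arg(mode),
                 draw_nets = isTRUE(draw_nets)),
            class = "sim_config")
}

#' Stimulus schedule
#'
#' Every `n` ticks (i.e. at ticks `n, 2n, ...`), a uniformly random number
#' of tokens between 0 and `r` is added to the target place, before the
#' tick's transition sweep.  The expected number of tokens added per event
#' is `r / 2`.
#'
#' @param scope scope id of the target place's net.
#' @param place target place name.
#' @param n positive integer period.
#' @param r non-negative integer amplitude.
#' @param label token label to inject; defaults to the place name (entity
#'   places hold tokens labelled by their entity).
#' @return an object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(scope, place, n, r, label = place) {
  n <- as.integer(n); r <- as.integer(r)
  if (is.na(n) || n < 1L) stop("stimulus period n must be >= 1",
                               call. = FALSE)
  if (is.na(r) || r < 0L) stop("stimulus amplitude r must be >= 0",
                               call. = FALSE)
  structure(list(scope = scope, place = place, n = n, r = r, label = label),
            class = "stimulus_schedule")
}

#' Apply one stimulus schedule at one tick
#'
#' No-op unless `tick` is divisible by the schedule's period; otherwise
#' draws `u ~ Uniform{0, ..., r}` from the current RNG stream and adds `u`
#' tokens to the target place.
#'
#' @param model an [nwn_model()].
#' @param state a state from [nwn_state()]; modified in place.
#' @param stim a [stimulus_schedule()].
#' @param tick current tick (1-based).
#' @return the number of tokens added, invisibly.
#' @export
apply_stimulus <- function(model, state, stim, tick) {
  if (tick %% stim$n != 0L) return(invisible(0L))
  if (is.null(state$m[[stim$scope]]) ||
      !stim$place %in% names(state$m[[stim$scope]]))
    stop("stimulus target place missing: ", stim$scope, "/", stim$place,
         call. = FALSE)
  u <- if (stim$r == 0L) 0L else sample.int(stim$r + 1L, 1L) - 1L
  if (u > 0L)
    state$m[[stim$scope]] <- add_tokens(state$m[[stim$scope]], stim$place,
                                        stim$label, u)
  invisible(u)
}

#' Run a model
#'
#' @param model an [nwn_model()] (e.g. from [bisdl_compile()]).
#' @param config a [sim_config()].
#' @param stimuli list of [stimulus_schedule()] objects.
#' @return an object of class `bisdl_trace` with components
#'   \describe{
#'     \item{markings}{long data.frame `tick, scope, place, count`, one row
#'       per observed scope-net place per tick;}
#'     \item{firings}{data.frame `tick, net, transition` of every firing
#'       event;}
#'     \item{fired}{cumulative per-transition firing counts per net;}
#'     \item{visits}{per-net visit counts;}
#'     \item{config}{the configuration echo.}
#'   }
#' @export
bisdl_run <- function(model, config = sim_config(), stimuli = list()) {
  stopifnot(inherits(model, "nwn_model"), inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- nwn_state(model)

  obs <- list()  # columns of the trace matrix
  for (s in names(model$scopes)) {
    for (p in names(model$scopes[[s]]$places)) {
      obs[[length(obs) + 1L]] <- c(s, p)
    }
  }
  ncol <- length(obs)
  counts <- matrix(0L, nrow = config$nstep, ncol = ncol)

  for (tick in seq_len(config$nstep)) {
    for (stim in stimuli) apply_stimulus(model, state, stim, tick)
    nwn_step(model, state, tick, config$default_p)
    for (j in seq_len(ncol)) {
      counts[tick, j] <- sum(state$m[[obs[[j]][1]]][[obs[[j]][2]]])
    }
  }

  markings <- data.frame(
    tick = rep(seq_len(config$nstep), times = ncol),
    scope = rep(vapply(obs, `[`, "", 1), each = config$nstep),
    place = rep(vapply(obs, `[`, "", 2), each = config$nstep),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  ev <- state$events
  firings <- if (length(ev) == 0L) {
    data.frame(tick = integer(0), net = character(0),
               transition = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(
      tick = vapply(ev, function(e) as.integer(e$tick), integer(1)),
      net = vapply(ev, `[[`, "", "net"),
      transition = vapply(ev, `[[`, "", "transition"),
      stringsAsFactors = FALSE
    )
  }
  structure(list(markings = markings, firings = firings,
                 fired = state$fired, visits = state$visits,
                 config = config, model_name = model$name),
            class = "bisdl_trace")
}

#' @export
print.bisdl_trace <- function(x, ...) {
  cat("<bisdl_trace> ", x$model_name, ": ",
      max(x$markings$tick), " ticks, ",
      length(unique(paste(x$markings$scope, x$markings$place))),
      " observed places, ", nrow(x$firings), " firings\n", sep = "")
  invisible(x)
}

#' Tick of the first firing of a transition (or transition-name pattern)
#'
#' @param trace a [bisdl_run()] trace.
#' @param net net name; `NULL` matches any net.
#' @param pattern regular expression matched against transition names.
#' @return the earliest matching tick, or `Inf` if no match fired.
#' @export
first_firing_tick <- function(trace, pattern, net = NULL) {
  f <- trace$firings
  sel <- grepl(pattern, f$transition)
  if (!is.null(net)) sel <- sel & f$net == net
  if (!any(sel)) return(Inf)
  min(f$tick[sel])
}

#' Summarize a trace
#'
#' @param trace a [bisdl_run()] trace.
#' @param terminal_frac fraction of final ticks forming the terminal
#'   window (default the last 20 percent).
#' @return list with `series` (the tidy long marking table) and `terminal`
#'   (data.frame `scope, place, mean` of terminal-window mean counts).
#' @export
summarize_trace <- function(trace, terminal_frac = 0.2) {
  mk <- trace$markings
  nstep <- max(mk$tick)
  lo <- nstep - max(1L, floor(terminal_frac * nstep)) + 1L
  term <- mk[mk$tick >= lo, , drop = FALSE]
  agg <- stats::aggregate(count ~ scope + place, data = term, FUN = mean)
  names(agg)[names(agg) == "count"] <- "mean"
  list(series = mk, terminal = agg[order(agg$scope, agg$place), ,
                                   drop = FALSE])
}

#' Terminal-window mean count of one place
#' @inheritParams summarize_trace
#' @param scope,place the observed place.
#' @return numeric mean over the terminal window.
#' @export
terminal_mean <- function(trace, scope, place, terminal_frac = 0.2) {
  s <- summarize_trace(trace, terminal_frac)$terminal
  hit <- s$scope == scope & s$place == place
  if (!any(hit)) stop("no observed place ", scope, "/", place,
                      call. = FALSE)
  s$mean[hit]
}
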