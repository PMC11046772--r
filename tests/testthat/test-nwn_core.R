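test_that("enabling respects arc weights, reads and inhibitors", {
  net <- water_net_raw(1L, 1L)
  mk <- nwn_init_marking(net)
  # input arc weight 2 on a place with 1 matching token
  expect_false(nwn_enabled(net, "react", mk))
  mk$H2["H2"] <- 2L
  expect_true(nwn_enabled(net, "react", mk))

  # inhibitor threshold 1: enabled only at count 0 (exhaustive over 0..3)
  inhib <- nwn_net("inh",
                   places = list(nwn_place("ctl"), nwn_place("out")),
                   transitions = list(nwn_transition(
                     "t", outputs = list(nwn_arc("out")),
                     inhibitors = list(nwn_arc("ctl", 1L, "black")))))
  for (n in 0:3) {
    mki <- nwn_init_marking(inhib)
    if (n > 0) mki$ctl <- stats::setNames(as.integer(n), "black")
    expect_identical(nwn_enabled(inhib, "t", mki), n < 1L, label = n)
  }

  # dangling arc reference errors
  expect_error(
    nwn_net("bad", places = list(nwn_place("a")),
            transitions = list(nwn_transition(
              "t", inputs = list(nwn_arc("ghost"))))),
    "unknown place")
})

test_that("firing consumes and produces per arc weights; reads never consume", {
  net <- water_net_raw(2L, 1L)
  mk <- nwn_fire(net, "react", nwn_init_marking(net))
  expect_equal(unname(mk$H2O["H2O"]), 2L)
  expect_equal(unname(mk$H2["H2"]), 0L)
  expect_equal(unname(mk$O2["O2"]), 0L)
  expect_error(nwn_fire(net, "react", mk), "disabled")

  reader <- nwn_net("rd",
                    places = list(nwn_place("src", 3L), nwn_place("out")),
                    transitions = list(nwn_transition(
                      "t", reads = list(nwn_arc("src", 2L, "black")),
                      outputs = list(nwn_arc("out")))))
  mk2 <- nwn_fire(reader, "t", nwn_init_marking(reader))
  expect_equal(unname(mk2$src["black"]), 3L)  # untouched
  expect_equal(unname(mk2$out["black"]), 1L)
})

test_that("channel firing is atomic and conserves the payload token", {
  m <- channel_pair_model(initial = 50L)
  set.seed(7)
  st <- nwn_state(m)
  total0 <- nwn_count(m, st, "left", "sig") + nwn_count(m, st, "right", "sig")
  moved_any <- FALSE
  for (tick in 1:1000) {
    nwn_step(m, st, tick, default_p = 0.6)
    l <- nwn_count(m, st, "left", "sig")
    r <- nwn_count(m, st, "right", "sig")
    expect_identical(l + r, total0)
    if (r > 0) moved_any <- TRUE
    if (l == 0L) break
  }
  expect_true(moved_any)
  # both endpoints logged the same number of joint firings
  expect_identical(unname(st$fired$left["emit"]), unname(st$fired$right["recv"]))
  # channel blocked when the responder side is disabled
  m2 <- channel_pair_model(initial = 0L)
  st2 <- run_ticks(m2, 50, seed = 1)
  expect_identical(unname(st2$fired$left["emit"]), 0L)
})

test_that("mirror bindings propagate the changed side; upper wins conflicts", {
  mk_model <- function() {
    top <- nwn_net("grid", places = list(nwn_place("cell")))
    sc <- nwn_net("sc", places = list(nwn_place("AHL_molecule")))
    nwn_model(top, scopes = list(sc = sc),
              bindings = list(list(upper_place = "cell",
                                   label = "AHL_molecule",
                                   scope = "sc",
                                   lower_place = "AHL_molecule")))
  }
  m <- mk_model()
  st <- nwn_state(m)

  # upper gains 3 -> lower gains 3
  st$m$grid$cell["AHL_molecule"] <- 3L
  nwn_mirror(m, st, 1L)
  expect_equal(nwn_count(m, st, "sc", "AHL_molecule"), 3L)

  # neither side changed -> no-op
  before <- st$m
  nwn_mirror(m, st, 1L)
  expect_identical(st$m, before)

  # lower consumed 1 -> upper decremented; replaying the same delta from
  # the upper side gives the same reconciled counts
  st$m$sc$AHL_molecule["AHL_molecule"] <- 2L
  nwn_mirror(m, st, 1L)
  expect_equal(nwn_count(m, st, "grid", "cell", "AHL_molecule"), 2L)
  m2 <- mk_model(); st2 <- nwn_state(m2)
  st2$m$grid$cell["AHL_molecule"] <- 3L; nwn_mirror(m2, st2, 1L)
  st2$m$grid$cell["AHL_molecule"] <- 2L; nwn_mirror(m2, st2, 1L)
  expect_identical(st2$m$sc$AHL_molecule, st$m$sc$AHL_molecule)

  # simultaneous inconsistent modification: upper wins, with a warning
  st$m$grid$cell["AHL_molecule"] <- 5L
  st$m$sc$AHL_molecule["AHL_molecule"] <- 0L
  expect_warning(nwn_mirror(m, st, 1L), "upper level wins")
  expect_equal(nwn_count(m, st, "sc", "AHL_molecule"), 5L)
})

test_that("timescale gating: a net with timescale T is visited floor(K/T) times", {
  for (T in c(2L, 5L, 7L)) {
    m <- nwn_model(source_net(net_timescale = T, p = 1))
    st <- run_ticks(m, 1000, seed = 1)
    expect_identical(unname(st$visits), 1000L %/% T, label = T)
  }
  # net with timescale 2 at tick 3 -> not visited
  m <- nwn_model(source_net(net_timescale = 2L))
  set.seed(1); st <- nwn_state(m)
  nwn_step(m, st, 3L)
  expect_identical(unname(st$visits), 0L)
})

test_that("two processes at timescales 2 and 5 keep the printed 2.5 speed ratio", {
  net <- nwn_net("pace", places = list(nwn_place("sink")),
                 transitions = list(
                   nwn_transition("fast", outputs = list(nwn_arc("sink")),
                                  p = 1, timescale = 2L),
                   nwn_transition("slow", outputs = list(nwn_arc("sink")),
                                  p = 1, timescale = 5L)))
  st <- run_ticks(nwn_model(net), 1000, seed = 1)
  expect_identical(unname(st$fired$pace["fast"]), 500L)
  expect_identical(unname(st$fired$pace["slow"]), 200L)
})

test_that("seed determinism: identical model + seed give identical histories", {
  m <- channel_pair_model(initial = 20L)
  st1 <- run_ticks(m, 200, seed = 99)
  st2 <- run_ticks(m, 200, seed = 99)
  expect_identical(st1$m, st2$m)
  expect_identical(st1$events, st2$events)
  st3 <- run_ticks(m, 200, seed = 100)
  expect_false(identical(st1$events, st3$events))
})

test_that("reachability oracle enumerates the water net and degenerate cases", {
  # {H2:4, O2:2}: reachable H2O counts are exactly {0, 2, 4}
  r <- nwn_reachable(water_net_raw(4L, 2L))
  h2o <- sort(unique(vapply(r, function(mk) {
    v <- mk$H2O["H2O"]; if (is.na(v)) 0L else as.integer(v)
  }, integer(1))))
  expect_identical(h2o, c(0L, 2L, 4L))
  expect_length(r, 3L)
  expect_true(attr(r, "complete"))

  # net with no transitions -> singleton fixpoint
  r0 <- nwn_reachable(nwn_net("still", places = list(nwn_place("a", 2L))))
  expect_length(r0, 1L)

  # single source transition, depth 3 -> 4 markings (counts 0..3)
  r3 <- nwn_reachable(source_net(), depth = 3)
  expect_length(r3, 4L)
  expect_false(attr(r3, "complete"))  # unbounded net, bound was hit
})

test_that("every state visited by long stochastic runs is reachable (oracle equivalence)", {
  net <- water_net_raw(4L, 2L)
  keys <- attr(nwn_reachable(net), "keys")
  m <- nwn_model(net)
  for (seed in 1:5) {
    set.seed(seed)
    st <- nwn_state(m)
    for (tick in 1:200) {
      nwn_step(m, st, tick)
      expect_true(nwn_marking_key(st$m$water_raw) %in% keys)
    }
  }
})

test_that("token conservation holds across arbitrary interleavings", {
  # closed net: tokens only move, totals invariant over 500 random ticks
  net <- nwn_net("ring",
                 places = list(nwn_place("a", 10L), nwn_place("b"),
                               nwn_place("c")),
                 transitions = list(
                   nwn_transition("ab", inputs = list(nwn_arc("a")),
                                  outputs = list(nwn_arc("b"))),
                   nwn_transition("bc", inputs = list(nwn_arc("b")),
                                  outputs = list(nwn_arc("c"))),
                   nwn_transition("ca", inputs = list(nwn_arc("c")),
                                  outputs = list(nwn_arc("a")))))
  m <- nwn_model(net)
  set.seed(5)
  st <- nwn_state(m)
  for (tick in 1:500) {
    nwn_step(m, st, tick)
    tot <- sum(vapply(st$m$ring, sum, numeric(1)))
    expect_identical(as.integer(tot), 10L)
  }
})
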