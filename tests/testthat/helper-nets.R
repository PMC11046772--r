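# Tiny hand-built nets used across the engine tests.

# single always-enabled source transition feeding `sink`
source_net <- function(name = "src_net", p = NA_real_, timescale = 1L,
                       net_timescale = 1L) {
  nwn_net(name,
          places = list(nwn_place("sink")),
          transitions = list(nwn_transition(
            "src", outputs = list(nwn_arc("sink")),
            p = p, timescale = timescale)),
          timescale = net_timescale)
}

# the water-formation net, built directly (independent of the compiler)
water_net_raw <- function(h2 = 4L, o2 = 2L) {
  nwn_net("water_raw",
          places = list(
            nwn_place("H2", stats::setNames(h2, "H2")),
            nwn_place("O2", stats::setNames(o2, "O2")),
            nwn_place("H2O")),
          transitions = list(nwn_transition(
            "react",
            inputs = list(nwn_arc("H2", 2L, "H2"), nwn_arc("O2", 1L, "O2")),
            outputs = list(nwn_arc("H2O", 2L, "H2O")))))
}

# two nets linked by a channel moving one `sig` token left -> right
channel_pair_model <- function(initial = 5L, p = NA_real_) {
  left <- nwn_net("left",
                  places = list(nwn_place("sig",
                                          stats::setNames(initial, "sig"))),
                  transitions = list(nwn_transition(
                    "emit", inputs = list(nwn_arc("sig", 1L, "sig")),
                    p = p, channel = "ch", channel_role = "initiator")))
  right <- nwn_net("right",
                   places = list(nwn_place("sig")),
                   transitions = list(nwn_transition(
                     "recv", outputs = list(nwn_arc("sig", 1L, "sig")),
                     p = p, channel = "ch", channel_role = "responder")))
  top <- nwn_net("top", places = list(nwn_place("cell")))
  nwn_model(top, scopes = list(left = left, right = right),
            channels = list(ch = list(id = "ch", entity = "sig",
                                      from = list("left", "emit"),
                                      to = list("right", "recv"))))
}

run_ticks <- function(model, nticks, seed = 1L, default_p = 0.6) {
  set.seed(seed)
  st <- nwn_state(model)
  for (tick in seq_len(nticks)) nwn_step(model, st, tick, default_p)
  st
}

water_module_src <- function() water_reaction()$source
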