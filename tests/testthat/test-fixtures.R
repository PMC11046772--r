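test_that("water fixture: stoichiometry and run to exhaustion", {
  fix <- water_reaction()
  model <- bisdl_compile(fix$module)
  net <- model$scopes$s
  tname <- names(net$transitions)[1]

  # one firing from {H2:2, O2:1} -> {H2O:2}
  mk <- nwn_init_marking(net)
  mk$H2_molecule["H2_molecule"] <- 2L
  mk$O2_molecule["O2_molecule"] <- 1L
  mk <- nwn_fire(net, tname, mk)
  expect_equal(unname(mk$H2O_molecule["H2O_molecule"]), 2L)
  expect_equal(unname(mk$H2_molecule["H2_molecule"]), 0L)

  # {H2:1, O2:1} -> disabled
  mk2 <- nwn_init_marking(net)
  mk2$H2_molecule["H2_molecule"] <- 1L
  mk2$O2_molecule["O2_molecule"] <- 1L
  expect_false(nwn_enabled(net, tname, mk2))

  # shipped initial marking {4, 2} runs to terminal {H2O: 4}
  tr <- bisdl_run(model, sim_config(nstep = fix$nstep, seed = 1))
  final <- tr$markings[tr$markings$tick == fix$nstep, ]
  expect_equal(final$count[final$place == "H2O_molecule"], 4L)
  expect_equal(final$count[final$place == "H2_molecule"], 0L)
})

test_that("consortium fixture: LacI inversely controls the GFP readout", {
  fix <- bacterial_consortium()
  model <- bisdl_compile(fix$module)
  seeds <- 1:10
  g <- sapply(c("noLacI", "lowLacI", "highLacI"), function(scheme)
    sapply(seeds, function(s) {
      tr <- bisdl_run(model, sim_config(nstep = fix$nstep, seed = s),
                      fix$stimuli[[scheme]])
      terminal_mean(tr, "sensor", "GFP_reporter_protein")
    }))
  expect_gt(mean(g[, "noLacI"]), mean(g[, "lowLacI"]))
  expect_gt(mean(g[, "lowLacI"]), mean(g[, "highLacI"]))
  # highLacI almost shuts down AHL in the sensor
  tr <- bisdl_run(model, sim_config(nstep = fix$nstep, seed = 1),
                  fix$stimuli$highLacI)
  expect_lt(terminal_mean(tr, "sensor", "AHL_molecule"), 1)
})

test_that("rgb fixture: structural adjacency of the pattern rings", {
  fix <- rgb_morphogen()
  expect_length(fix$first_degree, 8L)
  expect_length(fix$second_degree, 16L)
  centre <- rep(2L, 2)
  model <- bisdl_compile(fix$module)
  for (nm in fix$first_degree)
    expect_true(grid_adjacent(model$coords[[nm]], centre))
  for (nm in fix$second_degree)
    expect_false(grid_adjacent(model$coords[[nm]], centre))
  # second-degree cells have no juxtacrine channel at all
  chan_scopes <- unlist(lapply(model$channels, function(ch)
    c(ch$from[[1]], ch$to[[1]])))
  expect_length(intersect(fix$second_degree, chan_scopes), 0L)
})

test_that("rgb fixture: one 60-tick run patterns the first-degree ring only", {
  fix <- rgb_morphogen()
  model <- bisdl_compile(fix$module)
  tr <- bisdl_run(model, sim_config(nstep = fix$nstep, seed = 2))
  mc <- grid_counts(tr, model, "mCherry_protein")
  for (nm in fix$first_degree) {
    co <- model$coords[[nm]]
    expect_gt(mc[co[2] + 1L, co[1] + 1L], fix$mcherry_threshold)
  }
  for (nm in fix$second_degree) {
    co <- model$coords[[nm]]
    expect_equal(mc[co[2] + 1L, co[1] + 1L], 0)
  }
})

test_that("plasmid fixture: transfer ordering and donor retention", {
  fix <- plasmid_transfer()
  model <- bisdl_compile(fix$module)
  for (seed in 1:5) {
    tr <- bisdl_run(model, sim_config(nstep = fix$nstep, seed = seed))
    mk <- tr$markings
    donor <- mk$count[mk$scope == "donor" & mk$place == "R_plasmid_gene"]
    expect_true(all(donor >= 1L))
    # transconjugant starts plasmid-free
    tc_plasmid <- mk$count[mk$scope == "transconjugant" &
                           mk$place == "R_plasmid_gene"]
    expect_equal(tc_plasmid[1], 0L)
    # R protein appears only at/after the first transfer firing
    tc_r <- mk[mk$scope == "transconjugant" & mk$place == "R_protein", ]
    ft <- first_firing_tick(tr, "jux_emit_R_plasmid_ss_gene_to_transconjugant")
    expect_true(all(tc_r$count[tc_r$tick < ft] == 0L))
    expect_gt(max(tc_r$count), 0L)
  }
})

test_that("all fixtures parse, validate, compile and run under one seed", {
  for (fix in bisdl_fixtures()) {
    d <- bisdl_validate(fix$module)
    expect_equal(sum(d$severity == "error"), 0L, label = fix$name)
    model <- bisdl_compile(fix$module)
    nstep <- min(fix$nstep, 30L)  # keep the sweep cheap; long runs above
    tr <- bisdl_run(model, sim_config(nstep = nstep, seed = 1),
                    if (length(fix$stimuli)) fix$stimuli[[1]] else list())
    expect_equal(max(tr$markings$tick), nstep, label = fix$name)
  }
})
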