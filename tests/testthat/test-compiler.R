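test_that("the water module compiles to one grid place hosting the reaction net", {
  model <- bisdl_compile(water_reaction()$module)
  expect_length(model$top$places, 1L)
  expect_named(model$scopes, "s")
  net <- model$scopes$s
  expect_setequal(names(net$places),
                  c("H2_molecule", "O2_molecule", "H2O_molecule"))
  expect_length(net$transitions, 1L)
  tr <- net$transitions[[1]]
  win <- vapply(tr$inputs, `[[`, 1L, "weight")
  expect_setequal(win, c(2L, 1L))
  expect_equal(tr$outputs[[1]]$weight, 2L)
  # the grid place hosts the scope's net token
  expect_equal(unname(model$top$places[[1]]$init["@net:s"]), 1L)
})

test_that("consortium wiring: 2 net-token places, bidirectional AHL transitions, mirrors", {
  model <- bisdl_compile(bacterial_consortium()$module)
  expect_length(model$top$places, 2L)
  expect_setequal(names(model$top$transitions),
                  c("diffusion_AHL_molecule_producer_to_sensor",
                    "diffusion_AHL_molecule_sensor_to_producer"))
  expect_length(model$bindings, 2L)
  for (b in model$bindings) expect_equal(b$label, "AHL_molecule")
  # a module with zero DIFFUSION has no inter-place transitions
  m0 <- bisdl_compile(water_reaction()$module)
  expect_length(m0$top$transitions, 0L)
})

test_that("construct templates expand to the documented arc structure", {
  # PROTEIN_COMPLEX_FORMATION(3*, 3*, 3*): consume 3+3, produce 3,
  # product name embedded in the transition name
  con <- bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1", "    SCOPE s (0, 0)",
    "        PROCESS p", "            TIMESCALE 1",
    "            PROTEIN_COMPLEX_FORMATION(3*LuxR_protein, 3*AHL_molecule, 3*LuxR_AHL_complex)"
  ))$scopes[[1]]$processes[[1]]$constructs[[1]]
  frag <- expand_construct(con, "p_process_0")
  tr <- frag$transitions[[1]]
  expect_equal(vapply(tr$inputs, `[[`, 1L, "weight"), c(3L, 3L))
  expect_equal(tr$outputs[[1]]$weight, 3L)
  expect_match(tr$name, "LuxR_AHL_complex")

  # DEGRADATION: pure sink
  d <- bisdl_construct("DEGRADATION",
                       list(bisdl_term("X_protein", 1L, "input")))
  fd <- expand_construct(d, "p_process_0")
  expect_length(fd$transitions[[1]]$outputs, 0L)
  expect_length(fd$transitions[[1]]$inputs, 1L)

  # TRANSCRIPTION with INHIBITORS: gene read arc + inhibitor arc
  t <- bisdl_construct(
    "TRANSCRIPTION",
    list(bisdl_term("LuxI_gene", 1L, "input"),
         bisdl_term("LuxI_mRNA", 1L, "output")),
    roles = list(INHIBITORS = list(bisdl_term("LacI_protein", 1L,
                                              "modifier"))))
  ft <- expand_construct(t, "p_process_0")
  tt <- ft$transitions[[1]]
  expect_length(tt$inputs, 0L)          # gene never consumed
  expect_equal(tt$reads[[1]]$place, "LuxI_gene")
  expect_equal(tt$inhibitors[[1]]$place, "LacI_protein")
  expect_equal(tt$outputs[[1]]$place, "LuxI_mRNA")

  expect_error(expand_construct(
    structure(list(kind = "NOPE", terms = list(), roles = list()),
              class = "bisdl_construct"), "x"), "unknown construct kind")
})

test_that("process instances are numbered in source order", {
  reg <- assign_instance_names(bisdl_resolve_reuse(rgb_morphogen()$module))
  cd19 <- grep("^CD19_production_process_", names(reg), value = TRUE)
  expect_length(cd19, 24L)  # one per sender cell
  expect_setequal(cd19, paste0("CD19_production_process_", 0:23))

  # single-use process gets suffix _0
  regw <- assign_instance_names(water_reaction()$module)
  expect_named(regw, "reaction_process_0")

  # three uses -> _0, _1, _2 in source order
  mod <- bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1",
    "    SCOPE a (0, 0)",
    "        PROCESS p", "            TIMESCALE 1",
    "            DEGRADATION(X_molecule)",
    "    SCOPE b (0, 1)", "        PROCESS p",
    "    SCOPE c (0, 2)", "        PROCESS p"))
  reg3 <- assign_instance_names(bisdl_resolve_reuse(mod))
  expect_identical(unname(reg3[paste0("p_process_", 0:2)]),
                   c("a/p", "b/p", "c/p"))
})

test_that("fragment stitching: one place per distinct entity name per scope", {
  model <- bisdl_compile(bacterial_consortium()$module)
  producer <- model$scopes$producer
  mod <- bisdl_resolve_reuse(bacterial_consortium()$module)
  entities <- character(0)
  for (pr in mod$scopes[[1]]$processes) {
    for (con in pr$constructs) {
      terms <- c(con$terms, unlist(con$roles, recursive = FALSE))
      entities <- union(entities, vapply(terms, `[[`, "", "entity"))
    }
  }
  expect_setequal(names(producer$places), entities)
  # interpretability: every transition name embeds its kind or product
  for (tr in producer$transitions) {
    expect_match(tr$name, "_(transcription|translation|degradation|enzymatic_reaction|custom_process|protein_complex_formation)_")
  }
})

test_that("compilation is deterministic", {
  a <- bisdl_compile(plasmid_transfer()$module)
  b <- bisdl_compile(plasmid_transfer()$module)
  expect_identical(model_manifest(a), model_manifest(b))
})

test_that("juxtacrine wiring builds the donor->pilus->transconjugant chain", {
  model <- bisdl_compile(plasmid_transfer()$module)
  expect_length(model$channels, 2L)
  expect_setequal(names(model$channels),
                  c("chan_R_plasmid_ss_gene_donor_pilus",
                    "chan_R_plasmid_ss_gene_pilus_transconjugant"))
  # an emit with no receiver is dropped with a warning
  mod <- bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1",
    "    SCOPE a (0, 0)",
    "        JUXTACRINE_SIGNAL(X_molecule, emit, b)",
    "    SCOPE b (0, 1)"))
  expect_warning(m2 <- bisdl_compile(mod), "no matching receiver")
  expect_length(m2$channels, 0L)
})

test_that("RGB wiring: channels from the centre to all 8 Moore neighbours", {
  model <- bisdl_compile(rgb_morphogen()$module)
  gfp_out <- grep("^chan_GFP_lig_protein_receiver_", names(model$channels),
                  value = TRUE)
  expect_length(gfp_out, 8L)
  cd19_in <- grep("^chan_CD19_protein_sender_.*_receiver$",
                  names(model$channels), value = TRUE)
  expect_length(cd19_in, 8L)
})

test_that("grid-wide diffusion wires every Moore-adjacent ordered pair", {
  mod <- bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1",
    "    SCOPE a (0, 0)", "    SCOPE b (1, 0)",
    "    SCOPE c (0, 1)", "    SCOPE d (3, 3)",
    "    DIFFUSION(X_molecule, all)"))
  model <- bisdl_compile(mod)
  # a,b,c mutually adjacent (6 ordered pairs); d isolated
  expect_length(model$top$transitions, 6L)
})
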