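test_that("the water-reaction walkthrough parses with multipliers (2,1,2)", {
  mod <- bisdl_parse(water_module_src())
  expect_s3_class(mod, "bisdl_module")
  expect_equal(mod$timescale, 1L)
  expect_length(mod$scopes, 1L)
  sc <- mod$scopes[[1]]
  expect_equal(sc$coord, c(0L, 0L))
  expect_length(sc$processes, 1L)
  con <- sc$processes[[1]]$constructs[[1]]
  expect_equal(con$kind, "CUSTOM_PROCESS")
  expect_equal(vapply(con$terms, `[[`, 1L, "multiplier"), c(2L, 1L, 2L))
  expect_equal(vapply(con$terms, `[[`, "", "direction"),
               c("input", "input", "output"))
})

test_that("a module with zero scopes parses to an empty scope collection", {
  mod <- bisdl_parse("MODULE empty\n    TIMESCALE 1\n")
  expect_length(mod$scopes, 0L)
  expect_length(mod$diffusions, 0L)
})

test_that("the consortium source yields 2 scopes and a bidirectional diffusion", {
  mod <- bacterial_consortium()$module
  expect_length(mod$scopes, 2L)
  expect_length(mod$diffusions, 1L)
  expect_true(mod$diffusions[[1]]$bidirectional)
  expect_equal(mod$diffusions[[1]]$entity, "AHL_molecule")
  ts <- vapply(mod$scopes[[1]]$processes, `[[`, 1L, "timescale")
  expect_equal(ts[[1]], 2L)  # AHL production at half the base pace
  expect_equal(mod$scopes[[2]]$processes[[1]]$timescale, 3L)
})

test_that("omitted multipliers materialize as 1", {
  mod <- bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1", "    SCOPE s (0, 0)",
    "        PROCESS p", "            TIMESCALE 1",
    "            CUSTOM_PROCESS(A_molecule -> 3*B_molecule)"))
  con <- mod$scopes[[1]]$processes[[1]]$constructs[[1]]
  expect_equal(con$terms[[1]]$multiplier, 1L)
  expect_equal(con$terms[[2]]$multiplier, 3L)
})

test_that("parse errors carry a line number and classed condition", {
  bad <- c("MODULE m", "    TIMESCALE 1", "    SCOPE s (0, 0)",
           "        PROCESS p", "            TIMESCALE 1",
           "            FROBNICATE(A_molecule)")
  err <- tryCatch(bisdl_parse(bad), error = identity)
  expect_s3_class(err, "bisdl_parse_error")
  expect_match(conditionMessage(err), "line 6")
  expect_match(conditionMessage(err), "unknown construct")

  err2 <- tryCatch(bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1", "    SCOPE s (0, 0)",
    "        PROCESS p", "            TIMESCALE 1",
    "            DEGRADATION(0*A_molecule)")), error = identity)
  expect_s3_class(err2, "bisdl_parse_error")

  expect_error(bisdl_parse("   \n  \n"), class = "bisdl_parse_error")
})

test_that("parse/deparse round trip is the identity on every fixture AST", {
  for (fix in bisdl_fixtures()) {
    mod <- fix$module
    round <- bisdl_parse(bisdl_deparse(mod))
    expect_true(bisdl_ast_equal(mod, round), label = fix$name)
  }
  # and the deletion variant of the morphogen fixture
  mod <- rgb_morphogen(gfp_lig_deletion = TRUE)$module
  expect_true(bisdl_ast_equal(mod, bisdl_parse(bisdl_deparse(mod))))
})

test_that("entity base types follow the suffix convention", {
  expect_equal(
    entity_base_type(c("AHL_molecule", "GFP_reporter_protein", "LuxI_gene",
                       "LuxI_mRNA", "LuxR_AHL_complex", "weird_thing")),
    c("MOLECULE", "PROTEIN", "GENE", "MRNA", "COMPLEX", "MOLECULE"))
})

test_that("validation flags duplicate coordinates and dangling process refs", {
  dup <- bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1",
    "    SCOPE a (0, 0)", "    SCOPE b (0, 0)"))
  d <- bisdl_validate(dup)
  expect_true(any(grepl("duplicate coordinate", d$message)))

  dangling <- bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1", "    SCOPE a (0, 0)",
    "        PROCESS nowhere_defined"))
  d2 <- bisdl_validate(dangling)
  expect_true(any(grepl("unresolved process", d2$message)))

  # every shipped fixture validates cleanly at error severity
  for (fix in bisdl_fixtures()) {
    d3 <- bisdl_validate(fix$module)
    expect_equal(sum(d3$severity == "error"), 0L, label = fix$name)
  }
})

test_that("validation is pure and deterministic", {
  mod <- bacterial_consortium()$module
  before <- bisdl_deparse(mod)
  d1 <- bisdl_validate(mod)
  d2 <- bisdl_validate(mod)
  expect_identical(d1, d2)
  expect_identical(bisdl_deparse(mod), before)
})

test_that("resolve_reuse links references and rejects ambiguity", {
  mod <- plasmid_transfer()$module
  res <- bisdl_resolve_reuse(mod)
  tc <- res$scopes[[3]]
  r_expr <- Filter(function(p) p$id == "R_expression", tc$processes)[[1]]
  expect_false(r_expr$is_ref)
  expect_true(isTRUE(r_expr$reused))
  expect_gt(length(r_expr$constructs), 0L)

  # no reuse -> structurally identical module
  w <- water_reaction()$module
  expect_true(bisdl_ast_equal(w, bisdl_resolve_reuse(w)))

  # two bodies for one id -> ambiguous
  amb <- bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1",
    "    SCOPE a (0, 0)",
    "        PROCESS p", "            TIMESCALE 1",
    "            DEGRADATION(X_molecule)",
    "    SCOPE b (0, 1)",
    "        PROCESS p", "            TIMESCALE 1",
    "            DEGRADATION(Y_molecule)"))
  expect_error(bisdl_resolve_reuse(amb), "ambiguous")
})

test_that("juxtacrine partners must be grid-adjacent", {
  mod <- bisdl_parse(c(
    "MODULE m", "    TIMESCALE 1",
    "    SCOPE a (0, 0)",
    "        JUXTACRINE_SIGNAL(X_molecule, emit, b)",
    "    SCOPE b (4, 4)",
    "        JUXTACRINE_SIGNAL(X_molecule, receive, a)"))
  d <- bisdl_validate(mod)
  expect_true(any(grepl("not grid-adjacent", d$message)))
})
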