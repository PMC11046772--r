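#' @title Worked example and case-study fixtures
#'
#' @description
#' Programmatic generators for the BiSDL sources exercised throughout the
#' package: a water-formation chemical reaction (the language walkthrough),
#' a two-cell LacI-controlled bacterial consortium, an RGB synthetic
#' morphogen pattern on a square grid, and a conjugative plasmid transfer
#' chain.  Each generator returns a `bisdl_fixture`: the source text, the
#' parsed module, recommended simulation settings, stimulus schemes, and
#' machine-checkable expectations used by the test suite.
#'
#' Initial token counts are design choices of the fixtures (one token per
#' gene place, substrates replenished by source processes, the recipient
#' cell starting without the plasmid); they are declared explicitly with
#' `MARKING` lines in the generated sources.
#'
#' @name bisdl-fixtures
NULL

new_fixture <- function(name, source, nstep, stimuli = list(),
                        extra = list()) {
  structure(c(list(name = name, source = source,
                   module = bisdl_parse(source),
                   nstep = as.integer(nstep), stimuli = stimuli),
              extra),
            class = "bisdl_fixture")
}

#' @export
print.bisdl_fixture <- function(x, ...) {
  cat("<bisdl_fixture> ", x$name, ": ", length(x$module$scopes),
      " scopes, nstep=", x$nstep, "\n", sep = "")
  invisible(x)
}

#' Water-formation reaction fixture
#'
#' One scope at (0, 0) with a single custom process: two hydrogen
#' molecules and one oxygen molecule transform into two water molecules
#' (stoichiometric multipliers 2, 1, 2).  The initial marking holds 4 H2
#' and 2 O2, enough for exactly two firings and a terminal marking of
#' 4 H2O.
#'
#' @return a `bisdl_fixture`.
#' @export
water_reaction <- function() {
  src <- paste(
    "MODULE water",
    "    TIMESCALE 1",
    "    SCOPE s (0, 0)",
    "        MARKING(H2_molecule, 4)",
    "        MARKING(O2_molecule, 2)",
    "        PROCESS reaction",
    "            TIMESCALE 1",
    "            CUSTOM_PROCESS(2*H2_molecule + O2_molecule -> 2*H2O_molecule)",
    sep = "\n")
  new_fixture("water", paste0(src, "\n"), nstep = 50L)
}

#' Bacterial consortium fixture
#'
#' Two bacterial scopes: a Controller (producer) whose LuxI synthase makes
#' the quorum signal AHL from SAM and ACP substrates, with LuxI
#' transcription inhibited by LacI; and a Target (sensor) whose GFP
#' reporter transcription is induced by AHL.  AHL diffuses bidirectionally
#' between the two grid cells.  The producer's process runs at half the
#' base pace (timescale 2) and the sensor's at one third (timescale 3).
#'
#' Stimulus schemes (`$stimuli`): `noLacI` (no stimulus), `lowLacI`
#' (period n=3, amplitude r=3) and `highLacI` (n=3, r=10), targeting the
#' producer's LacI place.  Expected behaviour: terminal GFP readout
#' decreases monotonically from `noLacI` to `highLacI`.
#'
#' @return a `bisdl_fixture`.
#' @export
bacterial_consortium <- function() {
  src <- paste(
    "MODULE bacterialConsortium",
    "    TIMESCALE 1",
    "    SCOPE producer (0, 0)",
    "        MARKING(LuxI_gene, 1)",
    "        MARKING(SAM_molecule, 5)",
    "        MARKING(ACP_molecule, 5)",
    "        PROCESS AHL_production",
    "            TIMESCALE 2",
    "            TRANSCRIPTION(LuxI_gene, LuxI_mRNA) INHIBITORS(LacI_protein)",
    "            TRANSLATION(LuxI_mRNA, LuxI_protein)",
    "            DEGRADATION(LuxI_mRNA)",
    "            DEGRADATION(LuxI_protein)",
    "            ENZYMATIC_REACTION(LuxI_protein, SAM_molecule + ACP_molecule -> 3*AHL_molecule)",
    "        PROCESS substrate_supply",
    "            TIMESCALE 1",
    "            CUSTOM_PROCESS( -> SAM_molecule + ACP_molecule)",
    "            DEGRADATION(LacI_protein)",
    "        PARACRINE_SIGNAL(AHL_molecule, emit)",
    "    SCOPE sensor (0, 1)",
    "        MARKING(GFP_gene, 1)",
    "        PROCESS GFP_production",
    "            TIMESCALE 3",
    "            TRANSCRIPTION(GFP_gene, GFP_mRNA) INDUCERS(AHL_molecule)",
    "            TRANSLATION(GFP_mRNA, GFP_reporter_protein)",
    "            DEGRADATION(GFP_mRNA)",
    "            DEGRADATION(AHL_molecule)",
    "        PARACRINE_SIGNAL(AHL_molecule, receive)",
    "    DIFFUSION(AHL_molecule, producer, sensor, bidirectional)",
    sep = "\n")
  stim <- list(
    noLacI = list(),
    lowLacI = list(stimulus_schedule("producer", "LacI_protein", 3L, 3L)),
    highLacI = list(stimulus_schedule("producer", "LacI_protein", 3L, 10L))
  )
  new_fixture("bacterial_consortium", paste0(src, "\n"), nstep = 100L,
              stimuli = stim,
              extra = list(readout = c(scope = "sensor",
                                       place = "GFP_reporter_protein")))
}

rgb_cell_ids <- function(grid_side) {
  centre <- (grid_side - 1L) %/% 2L
  ids <- list(centre = c(centre, centre), senders = list())
  for (y in seq_len(grid_side) - 1L) {
    for (x in seq_len(grid_side) - 1L) {
      if (x == centre && y == centre) next
      ids$senders[[paste0("sender_", x, "_", y)]] <- c(x, y)
    }
  }
  ids
}

#' RGB synthetic morphogen fixture
#'
#' A `grid_side` x `grid_side` lattice of Sender cells (type A:
#' constitutive BFP and CD19 ligand, mCherry + low E-cadherin inducible by
#' the GFP ligand) surrounding one central Receiver cell (type B: CD19
#' contact induces high E-cadherin and a membrane GFP ligand, which is
#' displayed back to the contacting Senders).  Juxtacrine channels connect
#' the centre with its 8 first-degree (Moore) neighbours in both
#' directions; second-degree cells have no contact with the centre and
#' must never express mCherry.
#'
#' The GFP-ligand translation yields 8 protein copies per firing so the
#' centre can engage all 8 contacts; by the final tick of a 60-step run
#' every first-degree neighbour is expected to exceed the mCherry
#' threshold (`$mcherry_threshold`, 5 tokens).
#'
#' @param grid_side odd integer >= 5 (default 5, the smallest grid with
#'   complete first- and second-degree rings).
#' @param gfp_lig_deletion if `TRUE`, generate the deletion variant: the
#'   Receiver keeps its CD19 response but neither produces nor displays
#'   the GFP ligand, so no mCherry can appear anywhere.
#' @return a `bisdl_fixture`.
#' @export
rgb_morphogen <- function(grid_side = 5L, gfp_lig_deletion = FALSE) {
  grid_side <- as.integer(grid_side)
  if (grid_side < 5L || grid_side %% 2L == 0L)
    stop("grid_side must be an odd integer >= 5", call. = FALSE)
  ids <- rgb_cell_ids(grid_side)
  centre <- ids$centre

  first_degree <- names(Filter(function(co) grid_adjacent(co, centre),
                               ids$senders))

  lines <- c("MODULE rgbMorphogen", "    TIMESCALE 1")

  ## receiver (type B) at the centre
  lines <- c(lines,
    sprintf("    SCOPE receiver (%d, %d)", centre[1], centre[2]),
    "        MARKING(Ecad_hi_gene, 1)")
  if (!gfp_lig_deletion)
    lines <- c(lines, "        MARKING(GFP_lig_gene, 1)")
  lines <- c(lines,
    "        PROCESS contact_response",
    "            TIMESCALE 1",
    "            TRANSCRIPTION(Ecad_hi_gene, Ecad_hi_mRNA) INDUCERS(CD19_protein)",
    "            TRANSLATION(Ecad_hi_mRNA, Ecad_hi_protein)")
  if (!gfp_lig_deletion) {
    lines <- c(lines,
      "        PROCESS ligand_display",
      "            TIMESCALE 1",
      "            TRANSCRIPTION(GFP_lig_gene, GFP_lig_mRNA) INDUCERS(CD19_protein)",
      "            TRANSLATION(GFP_lig_mRNA, 8*GFP_lig_protein)")
  }
  lines <- c(lines,
    "        JUXTACRINE_SIGNAL(CD19_protein, receive)")
  if (!gfp_lig_deletion) {
    for (nb in first_degree)
      lines <- c(lines, sprintf(
        "        JUXTACRINE_SIGNAL(GFP_lig_protein, emit, %s)", nb))
  }

  ## senders (type A); processes defined once and reused by name
  first_sender <- TRUE
  for (nm in names(ids$senders)) {
    co <- ids$senders[[nm]]
    lines <- c(lines,
      sprintf("    SCOPE %s (%d, %d)", nm, co[1], co[2]),
      "        MARKING(BFP_gene, 1)",
      "        MARKING(CD19_gene, 1)",
      "        MARKING(mCherry_gene, 1)",
      "        MARKING(Ecad_lo_gene, 1)")
    if (first_sender) {
      lines <- c(lines,
        "        PROCESS BFP_production",
        "            TIMESCALE 1",
        "            TRANSCRIPTION(BFP_gene, BFP_mRNA)",
        "            TRANSLATION(BFP_mRNA, BFP_protein)",
        "        PROCESS CD19_production",
        "            TIMESCALE 1",
        "            TRANSCRIPTION(CD19_gene, CD19_mRNA)",
        "            TRANSLATION(CD19_mRNA, CD19_protein)",
        "        PROCESS mCherry_response",
        "            TIMESCALE 1",
        "            TRANSCRIPTION(mCherry_gene, mCherry_mRNA) INDUCERS(GFP_lig_protein)",
        "            TRANSLATION(mCherry_mRNA, mCherry_protein)",
        "            TRANSCRIPTION(Ecad_lo_gene, Ecad_lo_mRNA) INDUCERS(GFP_lig_protein)",
        "            TRANSLATION(Ecad_lo_mRNA, Ecad_lo_protein)")
      first_sender <- FALSE
    } else {
      lines <- c(lines,
        "        PROCESS BFP_production",
        "        PROCESS CD19_production",
        "        PROCESS mCherry_response")
    }
    if (nm %in% first_degree) {
      lines <- c(lines,
        "        JUXTACRINE_SIGNAL(CD19_protein, emit, receiver)")
      if (!gfp_lig_deletion)
        lines <- c(lines,
          "        JUXTACRINE_SIGNAL(GFP_lig_protein, receive)")
    }
  }

  new_fixture(
    if (gfp_lig_deletion) "rgb_morphogen_gfp_lig_deletion"
    else "rgb_morphogen",
    paste0(paste(lines, collapse = "\n"), "\n"),
    nstep = 60L,
    extra = list(grid_side = grid_side,
                 first_degree = first_degree,
                 second_degree = setdiff(names(ids$senders), first_degree),
                 mcherry_threshold = 5L))
}

#' Conjugative plasmid transfer fixture
#'
#' Three scopes in a chain: a Donor carrying one conjugative R plasmid
#' (expressing the Pilus protein and the antibiotic-resistance R protein),
#' a Pilus structure relaying the linearized single-stranded plasmid, and
#' a Transconjugant that starts with no plasmid, circularizes an incoming
#' strand into a double-stranded plasmid and only then expresses the R
#' protein (its `R_expression` process is reused by name from the Donor).
#' Strand replication in the Donor is activated by the Pilus protein and
#' conserves the Donor's plasmid count, so the Donor holds at least one R
#' plasmid at every tick.
#'
#' @return a `bisdl_fixture`.
#' @export
plasmid_transfer <- function() {
  src <- paste(
    "MODULE plasmidTransfer",
    "    TIMESCALE 1",
    "    SCOPE donor (0, 0)",
    "        MARKING(R_plasmid_gene, 1)",
    "        PROCESS pilus_expression",
    "            TIMESCALE 1",
    "            TRANSCRIPTION(R_plasmid_gene, Pilus_mRNA)",
    "            TRANSLATION(Pilus_mRNA, Pilus_protein)",
    "            DEGRADATION(Pilus_mRNA)",
    "        PROCESS R_expression",
    "            TIMESCALE 1",
    "            TRANSCRIPTION(R_plasmid_gene, R_mRNA)",
    "            TRANSLATION(R_mRNA, R_protein)",
    "        PROCESS strand_replication",
    "            TIMESCALE 2",
    "            CUSTOM_PROCESS(R_plasmid_gene -> R_plasmid_gene + R_plasmid_ss_gene) ACTIVATORS(Pilus_protein)",
    "        PROCESS strand_circularization",
    "            TIMESCALE 2",
    "            CUSTOM_PROCESS(R_plasmid_ss_gene -> R_plasmid_gene)",
    "        JUXTACRINE_SIGNAL(R_plasmid_ss_gene, emit, pilus)",
    "    SCOPE pilus (0, 1)",
    "        JUXTACRINE_SIGNAL(R_plasmid_ss_gene, receive, donor)",
    "        JUXTACRINE_SIGNAL(R_plasmid_ss_gene, emit, transconjugant)",
    "    SCOPE transconjugant (0, 2)",
    "        PROCESS strand_circularization",
    "        PROCESS R_expression",
    "        JUXTACRINE_SIGNAL(R_plasmid_ss_gene, receive, pilus)",
    sep = "\n")
  new_fixture("plasmid_transfer", paste0(src, "\n"), nstep = 100L,
              extra = list(
                transfer_channel = "chan_R_plasmid_ss_gene_pilus_transconjugant"))
}

#' All shipped fixtures
#' @return named list of `bisdl_fixture` objects.
#' @export
bisdl_fixtures <- function() {
  list(water = water_reaction(),
       bacterial_consortium = bacterial_consortium(),
       rgb_morphogen = rgb_morphogen(),
       plasmid_transfer = plasmid_transfer())
}
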