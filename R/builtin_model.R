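#' Bundled Huh7 hypoxia network
#'
#' A compartmentalized atom-transition model of central carbon metabolism
#' in hypoxic Huh7 hepatoma cells cultured with extracellular citrate:
#' lumped glycolysis, lactate secretion, pyruvate transport, PDH, pyruvate
#' carboxylase, a full mitochondrial TCA cycle, cytosolic and mitochondrial
#' aconitase/IDH pairs (both reversible), malic enzymes in both
#' compartments, ATP-citrate lyase, palmitate synthesis from 8 cytosolic
#' acetyl-CoA units, a bounded fatty-acid oxidation flux, glutaminolysis,
#' glutamate secretion, aspartate transaminases in both compartments,
#' extracellular citrate uptake (NaCT), mitochondrial citrate exchange
#' (SLC25A1), inter-compartment exchange for exactly malate, aspartate,
#' glutamate, alpha-ketoglutarate and citrate, an unbalanced unlabeled CO2
#' pool (decarboxylation-derived CO2 never reincorporates), and a biomass
#' drain with generic mammalian precursor coefficients.
#'
#' Citrate carbons are numbered so that ATP-citrate lyase returns the
#' acetyl unit to citrate carbons 1-2 and oxaloacetate to carbons 3-6
#' (citrate synthase uses the inverse map), and the two oxidative
#' decarboxylations of the TCA cycle remove citrate carbons 6 (IDH) and 3
#' (alpha-KG dehydrogenase). Under a \[2,4-13C2\]citrate trace this yields
#' M1 acetyl-CoA plus M1 oxaloacetate on ACLY cleavage, while the
#' mitochondrial route retains both labels through to M2 succinate.
#' Succinate and fumarate are symmetric: every producing map is split into
#' two half-weight mirrored variants. Citrate is treated as prochiral (no
#' scrambling at aconitase).
#'
#' The network is a reconstruction constrained by these labeling rules and
#' the model-scope description; it is not a deposited reaction list.
#'
#' @return a validated `flux_network` with three tracers
#'   (`glc6` = \[U-13C6\]glucose, `gln5` = \[U-13C5\]glutamine,
#'   `cit24` = \[2,4-13C2\]citrate) and the default measured-fragment set.
#' @export
builtin_huh7_hypoxia <- function() {
  mets <- rbind(
    metabolite("Glc.x",  "extracellular", 6, balanced = FALSE),
    metabolite("Gln.x",  "extracellular", 5, balanced = FALSE),
    metabolite("Cit.x",  "extracellular", 6, balanced = FALSE),
    metabolite("Lac.x",  "extracellular", 3, balanced = FALSE),
    metabolite("Glu.x",  "extracellular", 5, balanced = FALSE),
    metabolite("CO2",    "extracellular", 1, balanced = FALSE),
    metabolite("Glc.c",  "cytosol",       6),
    metabolite("GAP",    "cytosol",       3),
    metabolite("Pyr.c",  "cytosol",       3),
    metabolite("Pyr.m",  "mitochondrion", 3),
    metabolite("AcCoA.m","mitochondrion", 2),
    metabolite("AcCoA.c","cytosol",       2),
    metabolite("Cit.m",  "mitochondrion", 6),
    metabolite("Cit.c",  "cytosol",       6),
    metabolite("aKG.m",  "mitochondrion", 5),
    metabolite("aKG.c",  "cytosol",       5),
    metabolite("Suc.m",  "mitochondrion", 4),
    metabolite("Fum.m",  "mitochondrion", 4),
    metabolite("Mal.m",  "mitochondrion", 4),
    metabolite("Mal.c",  "cytosol",       4),
    metabolite("OAA.m",  "mitochondrion", 4),
    metabolite("OAA.c",  "cytosol",       4),
    metabolite("Glu.m",  "mitochondrion", 5),
    metabolite("Glu.c",  "cytosol",       5),
    metabolite("Gln.c",  "cytosol",       5),
    metabolite("Asp.m",  "mitochondrion", 4),
    metabolite("Asp.c",  "cytosol",       4),
    metabolite("Palm.c", "cytosol",      16)
  )

  fas_lhs <- paste(sprintf("AcCoA.c (%s)", c("ab", "cd", "ef", "gh",
                                             "ij", "kl", "mn", "op")),
                   collapse = " + ")
  rxns <- list(
    reaction("GLC_UP", "Glc.x (abcdef) -> Glc.c (abcdef)", bounds = c(0, 500)),
    reaction("GLYC",   "Glc.c (abcdef) -> GAP (cba) + GAP (def)",
             bounds = c(0, 500)),
    reaction("PK",     "GAP (abc) -> Pyr.c (abc)", bounds = c(0, 2000)),
    reaction("LDH",    "Pyr.c (abc) -> Lac.x (abc)", bounds = c(0, 2000)),
    reaction("PYT",    "Pyr.c (abc) -> Pyr.m (abc)", bounds = c(0, 2000)),
    reaction("PDH",    "Pyr.m (abc) -> CO2 (a) + AcCoA.m (bc)",
             bounds = c(0, 2000)),
    reaction("PC",     "Pyr.m (abc) + CO2 (d) -> OAA.m (abcd)",
             bounds = c(0, 2000)),
    reaction("CS",     "OAA.m (abcd) + AcCoA.m (ef) -> Cit.m (efabcd)",
             bounds = c(0, 2000)),
    reaction("IDHM",   "Cit.m (abcdef) -> aKG.m (cabde) + CO2 (f)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("IDHC",   "Cit.c (abcdef) -> aKG.c (cabde) + CO2 (f)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("AKGDH",  c("aKG.m (abcde) -> CO2 (a) + Suc.m (bcde)",
                         "aKG.m (abcde) -> CO2 (a) + Suc.m (edcb)"),
             bounds = c(0, 2000)),
    reaction("SDH",    c("Suc.m (abcd) -> Fum.m (abcd)",
                         "Suc.m (abcd) -> Fum.m (dcba)"),
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("FUM",    c("Fum.m (abcd) -> Mal.m (abcd)",
                         "Fum.m (dcba) -> Mal.m (abcd)"),
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("MDHM",   "Mal.m (abcd) -> OAA.m (abcd)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("MDHC",   "Mal.c (abcd) -> OAA.c (abcd)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("MEM",    "Mal.m (abcd) -> Pyr.m (abc) + CO2 (d)",
             bounds = c(0, 2000)),
    reaction("MEC",    "Mal.c (abcd) -> Pyr.c (abc) + CO2 (d)",
             bounds = c(0, 2000)),
    reaction("ACLY",   "Cit.c (abcdef) -> AcCoA.c (ab) + OAA.c (cdef)",
             bounds = c(0, 2000)),
    reaction("FAS",    paste(fas_lhs, "-> Palm.c (abcdefghijklmnop)"),
             bounds = c(0, 100)),
    reaction("FAO",    paste("Palm.c (abcdefghijklmnop) ->",
                             paste(sprintf("AcCoA.m (%s)",
                                           c("ab", "cd", "ef", "gh",
                                             "ij", "kl", "mn", "op")),
                                   collapse = " + ")),
             bounds = c(0, 50)),
    reaction("PALM_OUT", "Palm.c -> ", bounds = c(0, 100)),
    reaction("GLN_UP", "Gln.x (abcde) -> Gln.c (abcde)", bounds = c(0, 500)),
    reaction("GLS",    "Gln.c (abcde) -> Glu.m (abcde)", bounds = c(0, 500)),
    reaction("GDH",    "Glu.m (abcde) -> aKG.m (abcde)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("GOT2",
             "OAA.m (abcd) + Glu.m (efghi) -> Asp.m (abcd) + aKG.m (efghi)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("GOT1",
             "OAA.c (abcd) + Glu.c (efghi) -> Asp.c (abcd) + aKG.c (efghi)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("GLU_SEC", "Glu.c (abcde) -> Glu.x (abcde)", bounds = c(0, 500)),
    reaction("CIT_UP",  "Cit.x (abcdef) -> Cit.c (abcdef)", bounds = c(0, 200)),
    reaction("MAL_T",  "Mal.m (abcd) -> Mal.c (abcd)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("ASP_T",  "Asp.m (abcd) -> Asp.c (abcd)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("GLU_T",  "Glu.m (abcde) -> Glu.c (abcde)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("AKG_T",  "aKG.m (abcde) -> aKG.c (abcde)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("CIT_T",  "Cit.m (abcdef) -> Cit.c (abcdef)",
             reversible = TRUE, bounds = c(-2000, 2000)),
    reaction("BIOMASS",
             "0.4 GAP + 1 Pyr.c + 0.6 Asp.c + 0.6 Glu.c + 0.45 Gln.c + 0.05 Palm.c -> ",
             bounds = c(0, 200))
  )

  tracers <- list(
    tracer("Glc.x", 1:6, id = "glc6"),
    tracer("Gln.x", 1:5, id = "gln5"),
    tracer("Cit.x", c(2, 4), id = "cit24")
  )

  net <- flux_network(mets, rxns, tracers = tracers,
                      fragments = default_fragments(), id = "huh7_hypoxia")
  net
}

#' Default measured GC-MS fragment set
#'
#' Representative tBDMS (polar metabolites) fragment specifications for the
#' TCA intermediates and amino acids used in fitting. Alanine reports the
#' cytosolic pyruvate pool; each fragment is assigned to the compartment
#' pool expected to dominate the whole-cell measurement.
#'
#' @return list of [fragment_spec] objects.
#' @export
default_fragments <- function() {
  list(
    fragment_spec("Pyr.c", 1:3, "C11H26NO2Si2", label = "Ala"),
    fragment_spec("Cit.c", 1:6, "C26H55O7Si4",  label = "Cit"),
    fragment_spec("aKG.c", 1:5, "C14H28NO5Si2", label = "AKG"),
    fragment_spec("Suc.m", 1:4, "C12H23O4Si2",  label = "Suc"),
    fragment_spec("Fum.m", 1:4, "C12H21O4Si2",  label = "Fum"),
    fragment_spec("Mal.m", 1:4, "C18H39O5Si3",  label = "Mal"),
    fragment_spec("Asp.c", 1:4, "C18H40NO4Si3", label = "Asp"),
    fragment_spec("Glu.m", 1:5, "C19H42NO4Si3", label = "Glu")
  )
}

#' Palmitate FAME fragment
#'
#' Fragment specification for the palmitate methyl ester molecular ion,
#' used for natural-abundance correction of fatty-acid MIDs ahead of ISA.
#'
#' @return a [fragment_spec] covering all 16 palmitate carbons.
#' @export
palmitate_fragment <- function() {
  fragment_spec("Palm.c", 1:16, "C17H34O2", label = "C16")
}

#' Default ground-truth flux vector for the bundled Huh7 model
#'
#' A feasible steady-state flux vector qualitatively matching hypoxic,
#' citrate-replete Huh7 cells: high glycolysis with most pyruvate secreted
#' as lactate, reduced PDH flux, glutamine-dominant lipogenesis via
#' glutaminolysis, active extracellular citrate uptake with net cytosolic
#' catabolism through ACLY and cytosolic aconitase/IDH (high cytosolic
#' exchange flux), active pyruvate cycling through the malic enzymes, and a
#' small bounded fatty-acid oxidation flux. Used as the default truth for
#' synthetic datasets.
#'
#' @param net the network from [builtin_huh7_hypoxia()].
#' @param citrate_uptake target extracellular citrate uptake flux; set 0
#'   for a matched no-citrate condition (the least-squares projection
#'   rebalances the remaining fluxes).
#' @return a `flux_vector`.
#' @export
default_huh7_fluxes <- function(net = builtin_huh7_hypoxia(),
                                citrate_uptake = 30) {
  targets <- c(
    GLC_UP = 150, GLYC = 150, LDH = 240, GLN_UP = 60, GLS = 46,
    GLU_SEC = 11, CIT_UP = citrate_uptake, PDH = 55, FAS = 5, FAO = 1,
    BIOMASS = 10, ACLY = 40, IDHC = 10,
    CIT_T = if (citrate_uptake > 0) 20 else 40, MEC = 60, MEM = 25,
    GOT1 = 0, GOT2 = 6, PC = 80
  )
  exchange <- c(
    IDHM = 120, IDHC = 150, SDH = 30, FUM = 150, MDHM = 100, MDHC = 80,
    GDH = 40, GOT2 = 60, GOT1 = 60, MAL_T = 30, ASP_T = 20, GLU_T = 20,
    AKG_T = 20, CIT_T = 15
  )
  steady_state_fluxes(net, targets, exchange = exchange)
}
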