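#' Default lumped central-carbon-metabolism network of E. coli K-12 MG1655
#'
#' Builds the simplified flux model used throughout the package: glycolysis,
#' pentose phosphate pathway, TCA cycle with glyoxylate shunt, Ppc
#' anaplerosis (lumped with gluconeogenic Pck as a reversible reaction), the
#' PTS glucose uptake (consuming one PEP per glucose), the Pta/Ack acetate
#' excretion branch and the Acs re-assimilation branch forming the futile
#' PTA-ACS cycle, the pyrimidine branch (aspartate + carbamoyl-phosphate ->
#' carbamoyl-aspartate -> dihydroorotate -> orotate) with excretion at each
#' intermediate, N-acetyl-aspartate synthesis-and-excretion, lactate
#' excretion, the generic excess-carbon outflow from oxaloacetate (Vprod),
#' CO2 transport, lumped oxidative phosphorylation at the configured P/O
#' ratio, an explicit ATP-dissipation (spilling) reaction, and 18
#' biomass-drain reactions built from monomer-class biosynthetic
#' stoichiometries.
#'
#' The network balances 22 metabolites (19 carbon branch points + ATP, NADH,
#' NADPH) across 50 fluxes: 24 dependent, 1 measured inflow, 7 outflows and
#' 18 biomass drains. FADH2 from succinate dehydrogenase is folded into the
#' NADH pool (discount factor `fadh2_discount`, default 1, i.e. lumped).
#' Every reaction conserves carbon exactly once boundary species (including
#' the biomass carbon sink `BIO.C`) are counted.
#'
#' @param po_ratio mol ATP per mol NADH oxidised (default 2).
#' @param fadh2_discount NADH equivalents credited per FADH2 (default 1).
#' @return A validated `MetabolicNetwork`.
#' @examples
#' net <- build_default_network()
#' dim(stoichiometric_matrix(net))  # 22 x 50
#' @export
build_default_network <- function(po_ratio = 2, fadh2_discount = 1) {
  fd <- fadh2_discount
  rx <- function(id, eq, role = "dependent", rev = FALSE, lump = character())
    reaction(id, parse_reaction_equation(eq), role, rev, lump)

  reactions <- list(
    ## measured inflow -----------------------------------------------------
    rx("PTS", "1 GLC.e + 1 PEP -> 1 G6P + 1 PYR", "measured_inflow",
       lump = c("ptsGHI", "crr")),

    ## outflows (non-CO2 boundary fluxes, fixed from broth measurements) ---
    rx("OUT_ACE",   "1 ACE -> 1 ACE.e", "outflow", rev = TRUE),  # uptake in D-stat
    rx("OUT_LAC",   "1 PYR + 1 NADH -> 1 LAC.e", "outflow", lump = "ldhA"),
    rx("OUT_CBASP", "1 CBASP -> 1 CBASP.e", "outflow"),
    rx("OUT_DHO",   "1 DHO -> 1 DHO.e", "outflow"),
    rx("OUT_ORO",   "1 ORO -> 1 ORO.e", "outflow"),
    rx("OUT_NAA",   "1 ACCOA + 1 ASP -> 1 NAA.e", "outflow", lump = "yjgM"),
    rx("OUT_VPROD", "1 OAA -> 1 VPROD.e", "outflow"),

    ## dependent fluxes ----------------------------------------------------
    rx("PGI",  "1 G6P -> 1 F6P", rev = TRUE, lump = "pgi"),
    rx("PFK",  "1 F6P + 1 ATP -> 2 GAP", lump = c("pfkA", "fbaA", "tpiA")),
    rx("GAPD", "1 GAP -> 1 PGA + 1 ATP + 1 NADH", lump = c("gapA", "pgk")),
    rx("ENO",  "1 PGA -> 1 PEP", rev = TRUE, lump = c("gpmA", "eno")),
    rx("PYK",  "1 PEP -> 1 PYR + 1 ATP", lump = c("pykA", "pykF")),
    rx("PDH",  "1 PYR -> 1 ACCOA + 1 CO2 + 1 NADH", lump = "aceEF-lpd"),
    rx("ZWF",  "1 G6P -> 1 R5P + 1 CO2 + 2 NADPH",
       lump = c("zwf", "pgl", "gnd", "rpiA")),
    rx("TKT1", "3 R5P -> 2 F6P + 1 GAP", rev = TRUE,
       lump = c("tktA", "talB")),
    rx("TKT2", "2 R5P -> 1 F6P + 1 E4P", rev = TRUE,
       lump = c("tktB", "talA")),
    rx("PPC",  "1 PEP + 1 CO2 -> 1 OAA", rev = TRUE, lump = c("ppc", "pck")),
    rx("CS",   "1 ACCOA + 1 OAA -> 1 ICT", lump = c("gltA", "acnB")),
    rx("ICD",  "1 ICT -> 1 AKG + 1 CO2 + 1 NADPH", lump = "icd"),
    rx("AKGDH",
       sprintf("1 AKG -> 1 MAL + 1 CO2 + 1 ATP + %s NADH", format(1 + fd)),
       lump = c("sucAB-lpd", "sucCD", "sdhABCD", "fumA")),
    rx("MDH",  "1 MAL -> 1 OAA + 1 NADH", rev = TRUE, lump = "mdh"),
    rx("GLX",  sprintf("1 ICT + 1 ACCOA -> 2 MAL + %s NADH", format(fd)),
       lump = c("aceA", "aceB", "sdhABCD", "fumA")),
    rx("PTA",  "1 ACCOA -> 1 ACE + 1 ATP", lump = c("pta", "ackA")),
    rx("ACS",  "1 ACE + 2 ATP -> 1 ACCOA", lump = "acs"),  # AMP + PPi cost
    rx("ASPC", "1 OAA + 1 NADPH -> 1 ASP", lump = c("aspC", "gdhA")),
    rx("PYRB", "1 ASP + 1 CO2 + 2 ATP -> 1 CBASP",
       lump = c("carAB", "pyrB")),  # carbamoyl-P drawn from CO2 + 2 ATP
    rx("PYRC", "1 CBASP -> 1 DHO", rev = TRUE, lump = "pyrC"),
    rx("PYRD", "1 DHO -> 1 ORO + 1 NADH", lump = "pyrD"),
    rx("OXPHOS", sprintf("1 NADH -> %s ATP", format(po_ratio)),
       lump = c("nuo", "cyo", "atp")),
    rx("ATPSPILL", "1 ATP -> 0 ATP + 0 CO2"),  # ATP -> ADP + Pi dissipation
    rx("OUT_CO2", "1 CO2 -> 1 CO2.e"),

    ## biomass drains (monomer-class stoichiometries; BIO.C = biomass C) ---
    rx("D_PROT_ALA", "1 PYR + 1 NADPH -> 3 BIO.C", "biomass_drain"),
    rx("D_PROT_SER", "1 PGA + 1 NADPH -> 3 BIO.C", "biomass_drain"),
    rx("D_PROT_ASP", "1 ASP + 2 NADPH + 2 ATP -> 4 BIO.C", "biomass_drain"),
    rx("D_PROT_GLU", "1 AKG + 2 NADPH + 1 ATP -> 5 BIO.C", "biomass_drain"),
    rx("D_PROT_ARO", "1 E4P + 2 PEP + 2 NADPH + 1 ATP -> 10 BIO.C",
       "biomass_drain"),
    rx("D_PROT_HIS", "1 R5P + 2 ATP -> 5 BIO.C + 1 NADH", "biomass_drain"),
    rx("D_RNA_PUR",
       "1 R5P + 2 PGA + 1 ASP + 4 ATP -> 10 BIO.C + 1 MAL + 1 CO2 + 1 NADH",
       "biomass_drain"),
    rx("D_RNA_PYR", "1 ORO + 1 R5P + 1 ATP -> 9 BIO.C + 1 CO2",
       "biomass_drain"),
    rx("D_DNA_PUR",
       "1 R5P + 2 PGA + 1 ASP + 4 ATP + 1 NADPH -> 10 BIO.C + 1 MAL + 1 CO2 + 1 NADH",
       "biomass_drain"),
    rx("D_DNA_PYR", "1 ORO + 1 R5P + 1 ATP + 1 NADPH -> 9 BIO.C + 1 CO2",
       "biomass_drain"),
    rx("D_LIPID", "8 ACCOA + 0.5 GAP + 14 NADPH + 7 ATP -> 17.5 BIO.C",
       "biomass_drain"),
    rx("D_LPS", "2 G6P + 1 F6P + 1 ACCOA + 2 ATP -> 20 BIO.C",
       "biomass_drain"),
    rx("D_MUREIN", "2 F6P + 1 PEP + 1 PYR + 1 ASP + 4 ATP + 1 NADPH -> 22 BIO.C",
       "biomass_drain"),
    rx("D_GLYCOGEN", "1 G6P + 1 ATP -> 6 BIO.C", "biomass_drain"),
    rx("D_SOLUBLE",  "1 G6P + 2 ATP -> 6 BIO.C", "biomass_drain"),
    rx("D_ATP",   "1 ATP -> 0 BIO.C", "biomass_drain"),   # polymerisation etc.
    rx("D_NADPH", "1 NADPH -> 0 BIO.C", "biomass_drain"),
    rx("D_NADH",  "0 BIO.C -> 1 NADH", "biomass_drain")   # biosynthetic surplus
  )
  metabolic_network(reactions, po_ratio = po_ratio)
}
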