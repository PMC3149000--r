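#' Metabolite registry of the central-carbon model
#'
#' Returns the full metabolite table used by the default network: the 22
#' balanced species (19 carbon branch-point metabolites plus the three
#' cofactor pools ATP, NADH, NADPH) and the boundary species that cross the
#' system border (glucose, by-products, CO2, the generic excess-carbon
#' product and the biomass carbon sink).
#'
#' Cofactors carry their pool carbon, not transferable carbon, so their
#' `carbon` is 0 for carbon-balance purposes.
#'
#' @return A data.frame with columns `id`, `name`, `carbon` (atoms per
#'   molecule), `cofactor` (logical) and `external` (logical; boundary
#'   species).
#' @export
metabolite_table <- function() {
  m <- rbind(
    # balanced carbon metabolites (branch points of the lumped network)
    c("G6P",   "glucose 6-phosphate",        6, FALSE, FALSE),
    c("F6P",   "fructose 6-phosphate",       6, FALSE, FALSE),
    c("GAP",   "glyceraldehyde 3-phosphate", 3, FALSE, FALSE),
    c("PGA",   "3-phosphoglycerate",         3, FALSE, FALSE),
    c("PEP",   "phosphoenolpyruvate",        3, FALSE, FALSE),
    c("PYR",   "pyruvate",                   3, FALSE, FALSE),
    c("ACCOA", "acetyl-CoA (acetyl moiety)", 2, FALSE, FALSE),
    c("ACE",   "acetate (intracellular)",    2, FALSE, FALSE),
    c("R5P",   "ribose 5-phosphate (pentose pool)", 5, FALSE, FALSE),
    c("E4P",   "erythrose 4-phosphate",      4, FALSE, FALSE),
    c("ICT",   "citrate/isocitrate",         6, FALSE, FALSE),
    c("AKG",   "2-oxoglutarate",             5, FALSE, FALSE),
    c("MAL",   "malate (C4 pool)",           4, FALSE, FALSE),
    c("OAA",   "oxaloacetate",               4, FALSE, FALSE),
    c("ASP",   "aspartate",                  4, FALSE, FALSE),
    c("CBASP", "carbamoyl-aspartate",        5, FALSE, FALSE),
    c("DHO",   "dihydroorotate",             5, FALSE, FALSE),
    c("ORO",   "orotate",                    5, FALSE, FALSE),
    c("CO2",   "carbon dioxide (dissolved)", 1, FALSE, FALSE),
    # balanced cofactor pools
    c("ATP",   "ATP/ADP pool",   0, TRUE, FALSE),
    c("NADH",  "NADH/NAD pool",  0, TRUE, FALSE),
    c("NADPH", "NADPH/NADP pool", 0, TRUE, FALSE),
    # boundary species
    c("GLC.e",   "glucose (feed)",          6, FALSE, TRUE),
    c("ACE.e",   "acetate (broth)",         2, FALSE, TRUE),
    c("LAC.e",   "lactate (broth)",         3, FALSE, TRUE),
    c("CBASP.e", "carbamoyl-aspartate (broth)", 5, FALSE, TRUE),
    c("DHO.e",   "dihydroorotate (broth)",  5, FALSE, TRUE),
    c("ORO.e",   "orotate (broth)",         5, FALSE, TRUE),
    c("NAA.e",   "N-acetyl-aspartate (broth)", 6, FALSE, TRUE),
    c("VPROD.e", "excess-carbon product (model outflow)", 4, FALSE, TRUE),
    c("CO2.e",   "carbon dioxide (off-gas)", 1, FALSE, TRUE),
    c("BIO.C",   "biomass carbon sink (1 C unit)", 1, FALSE, TRUE)
  )
  data.frame(
    id = m[, 1], name = m[, 2],
    carbon = as.numeric(m[, 3]),
    cofactor = as.logical(m[, 4]),
    external = as.logical(m[, 5]),
    stringsAsFactors = FALSE
  )
}

# species names accepted by carbon_count() in addition to model ids
.carbon_aliases <- c(
  glucose = "GLC.e", acetate = "ACE.e", lactate = "LAC.e",
  CBASP = "CBASP.e", DHO = "DHO.e", orotate = "ORO.e", NAA = "NAA.e",
  CO2 = "CO2", biomass_carbon = "BIO.C", Vprod = "VPROD.e"
)

#' Carbon atoms per molecule of a metabolite
#'
#' @param metabolite_id Metabolite id from [metabolite_table()] or a common
#'   species name (`"glucose"`, `"acetate"`, `"lactate"`, `"CBASP"`, `"DHO"`,
#'   `"orotate"`, `"NAA"`, `"CO2"`).
#' @return Non-negative integer count of carbon atoms. Cofactor pools return 0
#'   (their carbon stays in the carrier, it is not transferred).
#' @examples
#' carbon_count("glucose")  # 6
#' carbon_count("orotate")  # 5
#' @export
carbon_count <- function(metabolite_id) {
  stopifnot(is.character(metabolite_id))
  tab <- metabolite_table()
  out <- vapply(metabolite_id, function(id) {
    if (id %in% names(.carbon_aliases)) id <- .carbon_aliases[[id]]
    i <- match(id, tab$id)
    if (is.na(i)) stop("unknown metabolite id: ", id, call. = FALSE)
    tab$carbon[i]
  }, numeric(1))
  unname(out)
}
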