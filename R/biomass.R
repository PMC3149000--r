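#' @title Growth-rate-dependent biomass composition
#' @name biomass
#' @description
#' Biomass composition enters the flux model twice: the 18 biosynthetic
#' drain fluxes (monomer-class demand x growth rate) and the biomass carbon
#' content used by the carbon balance. A `BiomassComposition` holds the
#' macromolecular mass fractions and the derived monomer-class demands
#' (mmol per g DCW) at one specific growth rate; a `CompositionTable` is an
#' ordered set of compositions over increasing growth rate, interpolated
#' piecewise-linearly.
NULL

# mass fraction categories and the drain classes they feed
.macro_classes <- c("protein", "RNA", "DNA", "lipid", "LPS", "murein",
                    "glycogen", "other")

# amino-acid family split within protein (mol fraction of residues) and
# residue/monomer molar masses (g/mol) used to turn mass fractions into
# monomer-class demands
.protein_split <- c(D_PROT_ALA = 0.35, D_PROT_SER = 0.15, D_PROT_ASP = 0.20,
                    D_PROT_GLU = 0.18, D_PROT_ARO = 0.09, D_PROT_HIS = 0.03)
.monomer_mw <- c(protein = 110, RNA = 322, DNA = 312, lipid = 262,
                 LPS = 580, murein = 950, glycogen = 162, other = 300)

#' Construct a biomass composition at one growth rate
#'
#' Monomer-class demands are derived from the macromolecular mass fractions
#' with standard residue molar masses; growth-associated cofactor demands
#' (ATP for polymerisation and transport, NADPH for biosynthetic reduction
#' not captured by the per-class coefficients, net NADH formed in
#' biosynthesis) are given per g DCW.
#'
#' @param mu Specific growth rate (1/h) the entry refers to.
#' @param macromolecules Named numeric vector of mass fractions over
#'   `protein, RNA, DNA, lipid, LPS, murein, glycogen, other`; must sum to
#'   1 within 0.01.
#' @param cofactor_demands Named vector `c(D_ATP=, D_NADPH=, D_NADH=)` in
#'   mmol per g DCW (D_NADH is net production).
#' @return Object of class `"BiomassComposition"` with a `demands` element:
#'   named mmol/g DCW per drain reaction of the default network.
#' @export
biomass_composition <- function(mu,
                                macromolecules,
                                cofactor_demands = c(D_ATP = 20, D_NADPH = 2,
                                                     D_NADH = 3)) {
  stopifnot(mu >= 0)
  macromolecules <- macromolecules[.macro_classes]
  if (anyNA(macromolecules))
    stop("macromolecules must name all of: ",
         paste(.macro_classes, collapse = ", "))
  if (any(macromolecules < 0)) stop("negative mass fraction")
  if (abs(sum(macromolecules) - 1) > 0.01)
    stop("mass fractions sum to ", format(sum(macromolecules)),
         ", expected 1 +- 0.01")
  mmol <- 1000 * macromolecules / .monomer_mw[.macro_classes]  # mmol/g DCW
  demands <- c(
    mmol[["protein"]] * .protein_split,
    D_RNA_PUR = mmol[["RNA"]] * 0.5, D_RNA_PYR = mmol[["RNA"]] * 0.5,
    D_DNA_PUR = mmol[["DNA"]] * 0.5, D_DNA_PYR = mmol[["DNA"]] * 0.5,
    D_LIPID = mmol[["lipid"]], D_LPS = mmol[["LPS"]],
    D_MUREIN = mmol[["murein"]], D_GLYCOGEN = mmol[["glycogen"]],
    D_SOLUBLE = mmol[["other"]],
    cofactor_demands[c("D_ATP", "D_NADPH", "D_NADH")]
  )
  if (any(demands < 0) || anyNA(demands)) stop("negative or missing demand")
  structure(list(mu = mu, macromolecules = macromolecules,
                 demands = demands),
            class = "BiomassComposition")
}

#' Default growth-rate-dependent composition table (surrogate data)
#'
#' A literature-typical E. coli K-12 composition grid with the RNA mass
#' fraction rising with growth rate and levelling off near mu = 0.40 1/h,
#' protein declining slightly, and structural fractions constant. These are
#' surrogate values assembled from standard sources, not measurements from
#' any specific cultivation; override with [read_composition_table()] for
#' real data.
#'
#' @return A `CompositionTable` (list of `BiomassComposition`, increasing mu).
#' @export
default_composition_table <- function() {
  grid <- data.frame(
    mu       = c(0.10, 0.20, 0.30, 0.40, 0.50),
    protein  = c(0.580, 0.560, 0.540, 0.520, 0.520),
    RNA      = c(0.105, 0.135, 0.165, 0.195, 0.200),
    DNA      = c(0.035, 0.031, 0.029, 0.027, 0.026),
    lipid    = 0.091, LPS = 0.034, murein = 0.025, glycogen = 0.025
  )
  grid$other <- 1 - rowSums(grid[, .macro_classes[.macro_classes != "other"]])
  composition_table(lapply(seq_len(nrow(grid)), function(i)
    biomass_composition(grid$mu[i],
                        unlist(grid[i, .macro_classes]))))
}

#' Build a composition table
#' @param entries List of `BiomassComposition` objects, strictly increasing mu.
#' @return Object of class `"CompositionTable"`.
#' @export
composition_table <- function(entries) {
  if (!length(entries)) stop("empty composition table")
  mus <- vapply(entries, `[[`, 0, "mu")
  if (is.unsorted(mus, strictly = TRUE))
    stop("composition entries must have strictly increasing mu")
  structure(list(entries = entries, mu = mus), class = "CompositionTable")
}

#' Interpolate a composition table at a growth rate
#'
#' Piecewise-linear interpolation of mass fractions, monomer demands and
#' cofactor demands between the bracketing entries; constant extrapolation
#' (with a warning) outside the tabulated range.
#'
#' @param table A `CompositionTable`.
#' @param mu Specific growth rate (1/h), > 0.
#' @return A `BiomassComposition` at `mu`.
#' @export
composition_at_mu <- function(table, mu) {
  stopifnot(inherits(table, "CompositionTable"), mu > 0)
  mus <- table$mu
  if (length(mus) == 1L) {
    e <- table$entries[[1]]
  } else if (mu <= mus[1] || mu >= mus[length(mus)]) {
    if (mu < mus[1] || mu > mus[length(mus)])
      warning("mu = ", format(mu), " outside composition table range [",
              mus[1], ", ", mus[length(mus)], "]; using nearest entry")
    e <- table$entries[[if (mu <= mus[1]) 1L else length(mus)]]
  } else {
    i <- findInterval(mu, mus)
    a <- table$entries[[i]]; b <- table$entries[[i + 1L]]
    w <- (mu - mus[i]) / (mus[i + 1L] - mus[i])
    e <- a
    e$macromolecules <- (1 - w) * a$macromolecules + w * b$macromolecules
    e$demands <- (1 - w) * a$demands + w * b$demands
  }
  e$mu <- mu
  e
}

#' Biosynthetic drain fluxes at a growth rate
#'
#' Each of the 18 drain fluxes equals its monomer-class (or growth-associated
#' cofactor) demand times the growth rate.
#'
#' @param comp A `BiomassComposition`.
#' @param mu Specific growth rate (1/h).
#' @return Named flux vector (mmol per g DCW per h) over the 18 drain
#'   reactions of the default network.
#' @export
drain_fluxes <- function(comp, mu) {
  stopifnot(inherits(comp, "BiomassComposition"), mu >= 0)
  comp$demands * mu
}

#' Biomass carbon content implied by a composition
#'
#' Sums the biomass-carbon-sink coefficients of the network's drain
#' reactions weighted by the composition's demands: mmol carbon fixed into
#' biomass per g DCW.
#'
#' @param comp A `BiomassComposition`.
#' @param network A `MetabolicNetwork` with drain reactions matching the
#'   demand names (default [build_default_network()]).
#' @return mmol C per g DCW (scalar).
#' @export
biomass_carbon <- function(comp, network = build_default_network()) {
  total <- 0
  for (r in network$reactions) {
    if (r$role != "biomass_drain") next
    if (!r$id %in% names(comp$demands))
      stop("composition lacks demand for drain ", r$id)
    bc <- r$stoich["BIO.C"]
    if (!is.na(bc)) total <- total + comp$demands[[r$id]] * unname(bc)
  }
  total
}

#' Write / read the composition table text format
#'
#' Delimited text, one row per growth rate; columns: `mu`, the eight
#' macromolecule mass fractions, and the three growth-associated cofactor
#' demands (`D_ATP`, `D_NADPH`, `D_NADH`, mmol per g DCW).
#'
#' @param table A `CompositionTable`.
#' @param path File path.
#' @return `write_composition_table()`: invisibly `path`;
#'   `read_composition_table()`: a `CompositionTable`.
#' @export
write_composition_table <- function(table, path) {
  rows <- lapply(table$entries, function(e) {
    data.frame(mu = e$mu, t(e$macromolecules),
               D_ATP = e$demands[["D_ATP"]],
               D_NADPH = e$demands[["D_NADPH"]],
               D_NADH = e$demands[["D_NADH"]])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_composition_table
#' @export
read_composition_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  composition_table(lapply(seq_len(nrow(d)), function(i)
    biomass_composition(d$mu[i],
                        unlist(d[i, .macro_classes]),
                        c(D_ATP = d$D_ATP[i], D_NADPH = d$D_NADPH[i],
                          D_NADH = d$D_NADH[i]))))
}
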