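#' @title Metabolic network container and stoichiometric matrix
#' @name network
#' @description
#' A `MetabolicNetwork` holds an ordered metabolite table, an ordered list of
#' reactions (each a signed stoichiometry over metabolite ids, a role flag
#' and a reversibility flag) and the P/O ratio used by the lumped oxidative
#' phosphorylation reaction. Reaction roles partition the flux vector into
#' the measured inflow, the measured outflows, the growth-rate-proportional
#' biomass drains, and the dependent fluxes solved from the metabolite
#' balances.
NULL

#' Construct a reaction
#'
#' @param id Short reaction symbol (e.g. `"PYK"`, `"PPC"`).
#' @param stoich Named numeric vector, metabolite id -> signed coefficient
#'   (negative = consumed).
#' @param role One of `"measured_inflow"`, `"outflow"`, `"biomass_drain"`,
#'   `"dependent"`.
#' @param reversible Logical flag.
#' @param lumped_from Optional character vector of pathway steps lumped into
#'   this reaction (documentation only).
#' @return A list of class `"Reaction"`.
#' @export
reaction <- function(id, stoich, role = "dependent", reversible = FALSE,
                     lumped_from = character()) {
  role <- match.arg(role,
    c("measured_inflow", "outflow", "biomass_drain", "dependent"))
  stopifnot(is.numeric(stoich), !is.null(names(stoich)), all(nzchar(names(stoich))))
  structure(
    list(id = id, stoich = stoich[stoich != 0], role = role,
         reversible = isTRUE(reversible),
         lumped_from = as.character(lumped_from)),
    class = "Reaction"
  )
}

#' Assemble and validate a metabolic network
#'
#' Checks carbon conservation of every reaction (boundary species included),
#' the single-export rule for outflows, and full rank of the dependent
#' system under both acetate regimes (Acs active / Pta active).
#'
#' @param reactions List of [reaction()] objects.
#' @param metabolites Metabolite table, default [metabolite_table()].
#' @param po_ratio mol ATP per mol NADH oxidised in oxidative
#'   phosphorylation (default 2).
#' @param check Validate invariants (default TRUE).
#' @return An object of class `"MetabolicNetwork"`.
#' @export
metabolic_network <- function(reactions, metabolites = metabolite_table(),
                              po_ratio = 2, check = TRUE) {
  stopifnot(po_ratio > 0)
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  net <- structure(
    list(metabolites = metabolites, reactions = reactions,
         po_ratio = po_ratio),
    class = "MetabolicNetwork"
  )
  if (check) validate_network(net)
  net
}

#' @export
print.MetabolicNetwork <- function(x, ...) {
  rl <- reaction_roles(x)
  cat("MetabolicNetwork:", sum(!x$metabolites$external), "balanced metabolites,",
      length(x$reactions), "reactions\n")
  cat("  roles:", paste(names(table(rl)), table(rl), sep = "=", collapse = ", "),
      "\n  P/O ratio:", x$po_ratio, "\n")
  invisible(x)
}

#' Reaction ids of a network
#' @param network A `MetabolicNetwork`.
#' @return Character vector in network order.
#' @export
reaction_ids <- function(network) {
  vapply(network$reactions, `[[`, "", "id")
}

#' Reaction role flags of a network
#' @param network A `MetabolicNetwork`.
#' @return Named character vector (reaction id -> role).
#' @export
reaction_roles <- function(network) {
  r <- vapply(network$reactions, `[[`, "", "role")
  names(r) <- reaction_ids(network)
  r
}

#' Stoichiometric matrix over the balanced metabolites
#'
#' Rows are the balanced (non-boundary) metabolites in network order, columns
#' are the reactions in network order; entry (i, j) is the signed coefficient
#' of metabolite i in reaction j.
#'
#' @param network A `MetabolicNetwork`.
#' @return Numeric matrix (balanced metabolites x reactions) with dimnames.
#' @export
stoichiometric_matrix <- function(network) {
  bal <- network$metabolites$id[!network$metabolites$external]
  S <- matrix(0, nrow = length(bal), ncol = length(network$reactions),
              dimnames = list(bal, reaction_ids(network)))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoich
    keep <- intersect(names(st), bal)
    S[keep, j] <- st[keep]
  }
  S
}

#' Net carbon balance of each reaction, boundary species included
#'
#' For a fully bookkept network every reaction balances to zero: transport
#' reactions move carbon to boundary species, biomass drains move it to the
#' biomass carbon sink.
#'
#' @param network A `MetabolicNetwork`.
#' @return Named numeric vector of carbon imbalances (should be ~0).
#' @export
reaction_carbon_balance <- function(network) {
  cc <- stats::setNames(network$metabolites$carbon, network$metabolites$id)
  out <- vapply(network$reactions, function(r) {
    unknown <- setdiff(names(r$stoich), names(cc))
    if (length(unknown))
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    sum(r$stoich * cc[names(r$stoich)])
  }, numeric(1))
  stats::setNames(out, reaction_ids(network))
}

#' Validate network invariants
#'
#' Carbon conservation of every reaction to 1e-9; outflow reactions export
#' exactly one boundary species; the dependent system (after resolving the
#' acetate-branch switch and removing the CO2 transport column that the
#' measured CO2 rate fixes) has full column rank under both regimes.
#'
#' @param network A `MetabolicNetwork`.
#' @param tol Numeric tolerance for balance and rank checks.
#' @return Invisibly TRUE; raises an error naming the offending reaction
#'   otherwise.
#' @export
validate_network <- function(network, tol = 1e-9) {
  cb <- reaction_carbon_balance(network)
  bad <- names(cb)[abs(cb) > tol]
  if (length(bad))
    stop("carbon imbalance in reaction(s): ", paste(bad, collapse = ", "))
  ext <- network$metabolites$id[network$metabolites$external]
  for (r in network$reactions) {
    if (r$role == "outflow") {
      prod_ext <- names(r$stoich)[r$stoich > 0 & names(r$stoich) %in% ext]
      if (length(prod_ext) != 1L)
        stop("outflow ", r$id, " must export exactly one boundary species")
    }
  }
  # determinedness under both acetate regimes: with the acetate-branch
  # switch resolved and the glyoxylate shunt constrained by its regime rule,
  # the remaining dependent system is square (22 unknowns incl. the CO2
  # transport flux x 22 balances) and must be nonsingular; additionally the
  # constraint-mode system (CO2 transport also fixed by measurement, 21
  # unknowns) must keep full column rank.
  S <- stoichiometric_matrix(network)
  roles <- reaction_roles(network)
  dep <- names(roles)[roles == "dependent"]
  if (all(c("ACS", "PTA", "GLX", "OUT_CO2") %in% dep)) {
    for (drop in c("ACS", "PTA")) {
      cols <- setdiff(dep, c(drop, "GLX"))
      A <- S[, cols, drop = FALSE]
      if (qr(A)$rank < length(cols))
        stop("dependent system singular (", qr(A)$rank, " < ", length(cols),
             ") with ", drop, " inactive")
      cols2 <- setdiff(cols, "OUT_CO2")
      if (qr(S[, cols2, drop = FALSE])$rank < length(cols2))
        stop("constraint-mode system rank-deficient with ", drop, " inactive")
    }
  }
  invisible(TRUE)
}
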