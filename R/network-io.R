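#' Parse a reaction equation string
#'
#' Equations are written `"1 G6P + 1 ATP -> 2 GAP"`. Coefficients are
#' required (decimal fractions such as `0.5` allowed); species on the left
#' get negative signs. A side may be empty or contain zero-coefficient
#' placeholders.
#'
#' @param eq Equation string with a single `"->"`.
#' @return Named numeric stoichiometry vector (zero entries dropped).
#' @export
parse_reaction_equation <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) == 1L && grepl("->", eq, fixed = TRUE))
    sides <- c(sides, "")  # empty product side
  if (length(sides) != 2L) stop("equation must contain one '->': ", eq)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) != 2L)
        stop("malformed term '", tm, "' in equation: ", eq)
      coef <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(coef)) stop("bad coefficient in term '", tm, "'")
      out[parts[2]] <- (if (is.na(out[parts[2]])) 0 else out[parts[2]]) +
        sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (nm in names(rhs)) st[nm] <- (if (is.na(st[nm])) 0 else st[nm]) + rhs[nm]
  st <- st[!is.na(st)]
  st[st != 0]
}

#' Format a stoichiometry vector as an equation string
#' @param stoich Named numeric vector (negative = consumed).
#' @return Equation string, inverse of [parse_reaction_equation()].
#' @export
format_reaction_equation <- function(stoich) {
  fmt <- function(v, nm)
    paste(paste(vapply(v, format, "", digits = 15), nm), collapse = " + ")
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(if (length(lhs)) fmt(-lhs, names(lhs)) else "",
        "->",
        if (length(rhs)) fmt(rhs, names(rhs)) else "")
}

#' Write a network to its tab-delimited text format
#'
#' One record per reaction: id, equation, role, reversibility, lumped steps.
#' The P/O ratio is stored in a header comment so the file round-trips
#' losslessly through [read_network()].
#'
#' @param network A `MetabolicNetwork`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_network <- function(network, path) {
  lines <- c(
    "# coliflux network format v1",
    sprintf("# po_ratio: %s", format(network$po_ratio, digits = 15)),
    "id\tequation\trole\treversible\tlumped_from"
  )
  for (r in network$reactions) {
    lines <- c(lines, paste(
      r$id, trimws(format_reaction_equation(r$stoich)), r$role,
      r$reversible, paste(r$lumped_from, collapse = ","), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from the tab-delimited text format
#'
#' @param path File written by [write_network()] (or hand-edited in the same
#'   format).
#' @param metabolites Metabolite table; defaults to [metabolite_table()].
#' @param check Validate invariants after reading.
#' @return A `MetabolicNetwork`.
#' @export
read_network <- function(path, metabolites = metabolite_table(), check = TRUE) {
  lines <- readLines(path)
  po <- 2
  po_line <- grep("^#\\s*po_ratio:", lines, value = TRUE)
  if (length(po_line)) po <- as.numeric(sub("^#\\s*po_ratio:", "", po_line[1]))
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:4], c("id", "equation", "role", "reversible")))
    stop("unrecognised network file header")
  reactions <- lapply(lines[-1], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    lump <- if (length(f) >= 5 && nzchar(f[5]))
      strsplit(f[5], ",", fixed = TRUE)[[1]] else character()
    reaction(f[1], parse_reaction_equation(f[2]), f[3],
             as.logical(f[4]), lump)
  })
  metabolic_network(reactions, metabolites, po_ratio = po, check = check)
}

#' Export a network as SBML (level 3 version 1, export-only)
#'
#' Writes a minimal, standards-conformant SBML document: compartments for
#' the cytosol and the boundary, every metabolite as a species (boundary
#' species flagged `boundaryCondition`), and every reaction with its
#' stoichiometry and reversibility. Intended for interoperability with
#' constraint-based tool chains; there is no SBML importer.
#'
#' @param network A `MetabolicNetwork`.
#' @param path Output `.xml` path.
#' @return Invisibly `path`.
#' @export
export_sbml <- function(network, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "coliflux_central_carbon")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  xml2::xml_add_child(comps, "compartment", id = "e", constant = "true")
  sp <- xml2::xml_add_child(model, "listOfSpecies")
  sanitize <- function(id) gsub("[^A-Za-z0-9_]", "_", id)
  for (i in seq_len(nrow(network$metabolites))) {
    m <- network$metabolites[i, ]
    xml2::xml_add_child(sp, "species",
      id = paste0("M_", sanitize(m$id)), name = m$name,
      compartment = if (m$external) "e" else "c",
      hasOnlySubstanceUnits = "false",
      boundaryCondition = tolower(as.character(m$external)),
      constant = "false")
  }
  rxs <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    rn <- xml2::xml_add_child(rxs, "reaction",
      id = paste0("R_", sanitize(r$id)),
      reversible = tolower(as.character(r$reversible)), fast = "false")
    reac <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (nm in names(reac))
        xml2::xml_add_child(lr, "speciesReference",
          species = paste0("M_", sanitize(nm)),
          stoichiometry = format(-reac[[nm]], digits = 15),
          constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (nm in names(prod))
        xml2::xml_add_child(lp, "speciesReference",
          species = paste0("M_", sanitize(nm)),
          stoichiometry = format(prod[[nm]], digits = 15),
          constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
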