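test_that("default network matches the published model dimensions", {
  net <- ref_network()
  S <- stoichiometric_matrix(net)
  expect_identical(dim(S), c(22L, 50L))
  expect_identical(sum(!net$metabolites$external), 22L)
  roles <- table(reaction_roles(net))
  expect_equal(unname(roles[c("dependent", "measured_inflow", "outflow",
                              "biomass_drain")]),
               c(24L, 1L, 7L, 18L), ignore_attr = TRUE)
})

test_that("every reaction conserves carbon exactly, boundary species included", {
  cb <- reaction_carbon_balance(ref_network())
  expect_true(all(abs(cb) < 1e-9))
})

test_that("carbon counts follow the molecular formulas", {
  expect_identical(carbon_count("glucose"), 6)
  expect_identical(carbon_count("orotate"), 5)
  expect_identical(carbon_count("NAA"), 6)
  expect_identical(carbon_count(c("acetate", "lactate", "CBASP", "DHO", "CO2")),
                   c(2, 3, 5, 5, 1))
  expect_identical(carbon_count("ATP"), 0)  # cofactor carbon stays on the carrier
  expect_error(carbon_count("unobtainium"), "unknown metabolite")
})

test_that("stoichiometric matrix columns are the signed reaction coefficients", {
  net <- metabolic_network(
    list(reaction("AB", c(G6P = -1, F6P = 1))), check = FALSE)
  S <- stoichiometric_matrix(net)
  expect_equal(S[c("G6P", "F6P"), "AB"], c(G6P = -1, F6P = 1))
  # weighted by carbon atoms, every column of the default network sums to
  # the carbon it exports (zero for purely internal conversions)
  netd <- ref_network()
  Sd <- stoichiometric_matrix(netd)
  cc <- netd$metabolites$carbon[!netd$metabolites$external]
  internal <- c("PGI", "PFK", "GAPD", "ENO", "PYK", "PDH", "ZWF", "TKT1",
                "TKT2", "PPC", "CS", "ICD", "AKGDH", "MDH", "GLX", "PTA",
                "ACS", "ASPC", "PYRB", "PYRC", "PYRD", "OXPHOS", "ATPSPILL")
  expect_true(all(abs(colSums(Sd[, internal] * cc)) < 1e-9))
})

test_that("dependent system is determined under both acetate regimes", {
  net <- ref_network()
  S <- stoichiometric_matrix(net)
  roles <- reaction_roles(net)
  dep <- names(roles)[roles == "dependent"]
  for (inactive in c("ACS", "PTA")) {
    cols <- setdiff(dep, c(inactive, "GLX"))
    expect_length(cols, 22L)
    expect_identical(qr(S[, cols])$rank, 22L)
  }
})

test_that("cofactor pools have producers, consumers, and one free ATP sink", {
  net <- ref_network()
  S <- stoichiometric_matrix(net)
  for (cf in c("ATP", "NADH", "NADPH")) {
    expect_gt(sum(S[cf, ] > 0), 0)
    expect_gt(sum(S[cf, ] < 0), 0)
  }
  # the dissipation reaction is the only dependent flux touching ATP alone
  roles <- reaction_roles(net)
  dep <- colnames(S)[roles[colnames(S)] == "dependent"]
  only_atp <- vapply(dep, function(j)
    identical(rownames(S)[S[, j] != 0], "ATP"), logical(1))
  expect_identical(dep[only_atp], "ATPSPILL")
})

test_that("network construction rejects carbon-imbalanced reactions by name", {
  bad <- reaction("BADRXN", c(G6P = -1, PYR = 1))  # 6 C -> 3 C
  net <- ref_network()
  expect_error(metabolic_network(c(net$reactions, list(bad))),
               "BADRXN")
})

test_that("network text format round-trips losslessly", {
  net <- build_default_network(po_ratio = 1.75)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  net2 <- read_network(path)
  expect_equal(net2$po_ratio, 1.75)
  expect_equal(stoichiometric_matrix(net2), stoichiometric_matrix(net))
  expect_identical(reaction_roles(net2), reaction_roles(net))
  expect_identical(vapply(net2$reactions, `[[`, TRUE, "reversible"),
                   vapply(net$reactions, `[[`, TRUE, "reversible"))
})

test_that("bundled network file loads and equals the built-in default", {
  path <- system.file("extdata", "network_default.tsv", package = "coliflux")
  net <- read_network(path)
  expect_equal(stoichiometric_matrix(net),
               stoichiometric_matrix(ref_network()))
})

test_that("SBML export writes well-formed species and reactions", {
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(ref_network(), path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  species <- xml2::xml_find_all(doc, ".//d1:species", ns)
  rxns <- xml2::xml_find_all(doc, ".//d1:reaction", ns)
  expect_length(species, nrow(ref_network()$metabolites))
  expect_length(rxns, 50L)
  boundary <- xml2::xml_attr(species, "boundaryCondition")
  expect_identical(sum(boundary == "true"),
                   sum(ref_network()$metabolites$external))
})
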