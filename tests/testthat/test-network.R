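test_that("equation strings parse into atom-mapped reactions", {
  rx <- reaction("cs", "OAA.m (abcd) + AcCoA.m (ef) -> Cit.m (efabcd)")
  v <- rx$variants[[1]]
  expect_length(v$substrates, 2)
  expect_equal(v$products[[1]]$atoms, "efabcd")
  # drains parse with coefficients and no products
  dr <- reaction("bm", "0.4 GAP + 1 Pyr.c -> ")
  expect_length(dr$variants[[1]]$products, 0)
  expect_equal(dr$variants[[1]]$substrates[[1]]$coef, 0.4)
  expect_error(reaction("bad", "2 A (ab) -> B (ab)"), "unit coefficient")
})

test_that("a two-reaction toy model parses from text", {
  txt <- "
model: toy
metabolites:
  - {id: A, compartment: extracellular, carbons: 2, balanced: false}
  - {id: B, compartment: cytosol, carbons: 2}
  - {id: C, compartment: extracellular, carbons: 2, balanced: false}
reactions:
  - {id: r1, eq: 'A (ab) -> B (ab)'}
  - {id: r2, eq: 'B (ab) -> C (ab)'}
"
  net <- parse_model(txt)
  expect_equal(nrow(net$metabolites), 3)
  expect_length(net$reactions, 2)
  expect_true(validate_network(net)$ok)
})

test_that("carbon conservation violations are parse errors", {
  txt <- "
model: bad
metabolites:
  - {id: A, compartment: extracellular, carbons: 2, balanced: false}
  - {id: B, compartment: cytosol, carbons: 3}
reactions:
  - {id: r1, eq: 'A (ab) -> B (abc)'}
  - {id: r2, eq: 'B (abc) -> '}
"
  expect_error(parse_model(txt), "conserved|length")
  expect_error(
    parse_model("metabolites:\n  - {id: A, compartment: cytosol}\nreactions: []"),
    "carbons")
})

test_that("duplicate ids are conflict errors", {
  mets <- rbind(metabolite("A", "cytosol", 2), metabolite("A", "cytosol", 3))
  expect_error(flux_network(mets, list()), "duplicate metabolite")
  mets <- rbind(metabolite("A", "extracellular", 2, FALSE),
                metabolite("B", "cytosol", 2))
  rx <- list(reaction("r", "A (ab) -> B (ab)"),
             reaction("r", "B (ab) -> "))
  expect_error(flux_network(mets, rx), "duplicate reaction")
})

test_that("validator reports missing producers/consumers by name", {
  txt <- "
model: open
metabolites:
  - {id: S, compartment: extracellular, carbons: 2, balanced: false}
  - {id: M, compartment: mitochondrion, carbons: 2}
reactions:
  - {id: r1, eq: 'S (ab) -> M (ab)'}
"
  net <- tryCatch(parse_model(txt), error = function(e) e)
  expect_match(conditionMessage(net), "M: no consumer")
})

test_that("internal rearrangement maps pass atom balance", {
  mets <- rbind(metabolite("A", "extracellular", 4, FALSE),
                metabolite("B", "cytosol", 4))
  rx <- list(reaction("r1", "A (abcd) -> B (abdc)"),
             reaction("r2", "B (abcd) -> "))
  expect_true(validate_network(flux_network(mets, rx))$ok)
})

test_that("model serialization round-trips the builtin network", {
  net <- builtin_huh7_hypoxia()
  txt <- serialize_model(net)
  back <- parse_model(txt)
  expect_equal(back$metabolites, net$metabolites)
  expect_equal(length(back$reactions), length(net$reactions))
  for (id in names(net$reactions)) {
    a <- net$reactions[[id]]; b <- back$reactions[[id]]
    expect_equal(vapply(a$variants, citflux:::format_eq, character(1)),
                 vapply(b$variants, citflux:::format_eq, character(1)))
    expect_equal(a$reversible, b$reversible)
    expect_equal(c(a$lb, a$ub), c(b$lb, b$ub))
  }
  # serialization is stable
  expect_identical(txt, serialize_model(back))
})

test_that("bundled model file matches the builtin constructor", {
  path <- system.file("extdata", "huh7_hypoxia.yaml", package = "citflux")
  skip_if(path == "", "bundled model not installed")
  net <- parse_model(file = path)
  expect_identical(serialize_model(net), serialize_model(builtin_huh7_hypoxia()))
})

test_that("builtin network validates and encodes the study assumptions", {
  net <- builtin_huh7_hypoxia()
  vr <- validate_network(net)
  expect_true(vr$ok)
  expect_length(vr$violations, 0)

  # inter-compartment exchange transporters: exactly the five species
  transporters <- c("MAL_T", "ASP_T", "GLU_T", "AKG_T", "CIT_T")
  expect_true(all(transporters %in% names(net$reactions)))
  carried <- vapply(transporters, function(id)
    net$reactions[[id]]$variants[[1]]$substrates[[1]]$met, character(1))
  expect_setequal(sub("\\.m$", "", carried),
                  c("Mal", "Asp", "Glu", "aKG", "Cit"))
  expect_true(all(vapply(net$reactions[transporters], `[[`, logical(1),
                         "reversible")))

  # palmitate synthesis condenses 8 cytosolic acetyl units
  fas <- net$reactions[["FAS"]]$variants[[1]]
  expect_length(fas$substrates, 8)
  expect_true(all(vapply(fas$substrates, `[[`, character(1), "met") ==
                    "AcCoA.c"))

  # CO2 is an unbalanced (sink/source) pool
  expect_false(net$metabolites$balanced[net$metabolites$id == "CO2"])

  # compartmental duplication of the separated metabolite pools
  for (m in c("Asp", "OAA", "Mal", "aKG", "Glu", "AcCoA", "Cit"))
    expect_true(all(paste0(m, c(".m", ".c")) %in% net$metabolites$id))
  expect_true(all(c("Pyr.c", "Pyr.m") %in% net$metabolites$id))
})

test_that("CS and ACLY atom maps are mutually inverse", {
  net <- builtin_huh7_hypoxia()
  cs <- net$reactions[["CS"]]$variants[[1]]
  acly <- net$reactions[["ACLY"]]$variants[[1]]
  # push OAA/acetyl letters through CS, then split by ACLY positions
  cit <- strsplit(cs$products[[1]]$atoms, "")[[1]]
  ac_letters <- strsplit(acly$products[[1]]$atoms, "")[[1]]
  oaa_letters <- strsplit(acly$products[[2]]$atoms, "")[[1]]
  cit_acly <- strsplit(acly$substrates[[1]]$atoms, "")[[1]]
  ac_pos <- match(ac_letters, cit_acly)
  oaa_pos <- match(oaa_letters, cit_acly)
  # acetyl-CoA letters in CS product at ACLY's acetyl positions
  expect_equal(cit[ac_pos], strsplit(cs$substrates[[2]]$atoms, "")[[1]])
  expect_equal(cit[oaa_pos], strsplit(cs$substrates[[1]]$atoms, "")[[1]])
})

test_that("every builtin reaction conserves carbon as a multiset", {
  net <- builtin_huh7_hypoxia()
  vr <- validate_network(net)
  expect_true(all(vr$reaction_status$atom_balance))
})

test_that("stoichiometric matrix reflects coefficients and directions", {
  net <- branch_network()
  S <- stoich_matrix(net)
  expect_equal(S["A", "upt"], 1)
  expect_equal(S["A", "r2"], -1)
  expect_equal(S["D", "out"], -1)
  # glycolysis produces two GAP per glucose in the builtin model
  Sb <- stoich_matrix(builtin_huh7_hypoxia())
  expect_equal(Sb["GAP", "GLYC"], 2)
  expect_equal(Sb["AcCoA.c", "FAS"], -8)
})
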