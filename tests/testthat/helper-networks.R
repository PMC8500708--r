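# Small networks used across tests. All built in code; no fixture files.

# linear chain with a dilution inflow:
# S.x --upt--> A --r2--> B --r4--> D --out-->
#          \--r3--> C --r5--/    U.x --dil--> B
branch_network <- function() {
  mets <- rbind(
    metabolite("S.x", "extracellular", 2, balanced = FALSE),
    metabolite("U.x", "extracellular", 2, balanced = FALSE),
    metabolite("A", "cytosol", 2), metabolite("B", "cytosol", 2),
    metabolite("C", "cytosol", 2), metabolite("D", "cytosol", 2))
  rx <- list(
    reaction("upt", "S.x (ab) -> A (ab)", bounds = c(0, 500)),
    reaction("r2", "A (ab) -> B (ab)", bounds = c(0, 500)),
    reaction("r3", "A (ab) -> C (ab)", bounds = c(0, 500)),
    reaction("dil", "U.x (ab) -> B (ab)", bounds = c(0, 500)),
    reaction("r4", "B (ab) -> D (ab)", bounds = c(0, 500)),
    reaction("r5", "C (ab) -> D (ab)", bounds = c(0, 500)),
    reaction("out", "D (ab) -> ", bounds = c(0, 1000)))
  frg <- list(fragment_spec("B", 1:2, "C2H4", "B"),
              fragment_spec("C", 1:2, "C2H4", "C"),
              fragment_spec("D", 1:2, "C2H4", "D"))
  flux_network(mets, rx, tracers = list(tracer("S.x", 1:2, id = "s")),
               fragments = frg, id = "branch")
}

branch_truth <- function(net = branch_network()) {
  flux_vector(net, c(upt = 100, r2 = 60, r3 = 40, dil = 20, r4 = 80,
                     r5 = 40, out = 120))
}

# three-metabolite loop with reversible step and condensation, for
# simulator-vs-oracle comparisons: includes a cleavage and a convolution
cycle_network <- function() {
  mets <- rbind(
    metabolite("X.x", "extracellular", 2, balanced = FALSE),
    metabolite("Y.x", "extracellular", 1, balanced = FALSE),
    metabolite("A", "cytosol", 2),
    metabolite("B", "mitochondrion", 3),
    metabolite("C", "mitochondrion", 1))
  rx <- list(
    reaction("in_A", "X.x (ab) -> A (ab)", bounds = c(0, 500)),
    reaction("in_C", "Y.x (a) -> C (a)", bounds = c(0, 500)),
    reaction("cond", "A (ab) + C (c) -> B (acb)", bounds = c(0, 500)),
    reaction("rev", "B (abc) -> A (ac) + C (b)", reversible = TRUE,
             bounds = c(-500, 500)),
    reaction("out_B", "B (abc) -> ", bounds = c(0, 1000)),
    reaction("out_A", "A (ab) -> ", bounds = c(0, 1000)))
  frg <- list(fragment_spec("A", 1:2, "C2H4", "A"),
              fragment_spec("B", 1:3, "C3H6", "B"),
              fragment_spec("C", 1, "C1H2", "C"))
  flux_network(mets, rx, tracers = list(tracer("X.x", 1, id = "x1")),
               fragments = frg, id = "cycle")
}

# random feasible flux vector for a network, via targeted projection
random_flux <- function(net, scale = 100, ex_max = 50) {
  rids <- names(net$reactions)
  rev <- vapply(net$reactions, `[[`, logical(1), "reversible")
  for (try in 1:200) {
    tgt <- setNames(runif(length(rids), 0.2, 1) * scale, rids)
    tgt[rev] <- tgt[rev] * sample(c(-1, 1), sum(rev), replace = TRUE)
    v <- tryCatch(steady_state_fluxes(net, tgt, check = FALSE),
                  error = function(e) NULL)
    if (is.null(v)) next
    v$exchange[rev] <- runif(sum(rev), 0, ex_max)
    chk <- check_flux_vector(net, v)
    # require strictly positive inflow everywhere: try the simulation
    ok <- chk$ok && !inherits(tryCatch(
      simulate_mids(net, v, check = FALSE), error = function(e) e), "error")
    if (ok) return(v)
  }
  stop("could not draw a feasible random flux vector")
}

expect_mid_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.numeric(a), as.numeric(b), tolerance = tol)
}
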