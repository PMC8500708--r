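#' @name synthetic_data
#' @title Seeded synthetic datasets with known ground truth
#'
#' @description
#' Generators that emulate the study's measurement structure — parallel
#' labeling experiments with \[U-13C6\]glucose, \[U-13C5\]glutamine and
#' \[2,4-13C2\]citrate read out as replicate fragment MIDs, ISA palmitate
#' distributions, and media time-courses under exponential growth — from a
#' known flux vector (or known D/g), so every estimator can be validated
#' end-to-end. Noise is additive Gaussian per MID entry (truncated at 0
#' and renormalized); the same seed always reproduces the same dataset.
NULL

noisy_mid_replicates <- function(clean, noise_sd, replicates) {
  reps <- matrix(0, replicates, length(clean))
  for (r in seq_len(replicates)) {
    x <- clean + rnorm(length(clean), 0, noise_sd)
    x[x < 0] <- 0
    s <- sum(x)
    reps[r, ] <- if (s > 0) x / s else clean
  }
  list(values = colMeans(reps),
       sd = apply(reps, 2, stats::sd))
}

#' Generate a synthetic multi-tracer MFA dataset
#'
#' Simulates fragment MIDs for each tracer experiment at the true flux
#' vector, adds truncated Gaussian noise per replicate, and emits
#' replicate means and SDs plus noisy extracellular flux measurements.
#'
#' @param net a `flux_network`.
#' @param v true `flux_vector`.
#' @param tracer_ids tracers to run as parallel experiments (default: all
#'   tracers in the network).
#' @param noise_sd MID noise SD in mole-fraction units (default 0.003;
#'   0 gives exact simulator output).
#' @param replicates replicates per experiment (default 3).
#' @param seed RNG seed.
#' @param measured_fluxes reactions with direct flux measurements
#'   (defaults to the uptake/secretion set present in the network).
#' @param flux_rel_sd relative SD of flux measurements (floored at
#'   `flux_abs_sd` absolute).
#' @param flux_abs_sd absolute SD floor for flux measurements.
#' @param system optional precomputed [decompose()] result.
#' @return a `synthetic_mfa` list: `truth`, `data` (list of
#'   [measurement_set]), `noiseless` MIDs, and the generator settings.
#' @export
synth_mfa_dataset <- function(net, v = default_huh7_fluxes(net),
                              tracer_ids = vapply(net$tracers, `[[`,
                                                  character(1), "id"),
                              noise_sd = 0.003, replicates = 3, seed = 1,
                              measured_fluxes =
                                intersect(c("GLC_UP", "LDH", "GLN_UP",
                                            "GLU_SEC", "CIT_UP"),
                                          names(net$reactions)),
                              flux_rel_sd = 0.05, flux_abs_sd = 1,
                              system = NULL) {
  chk <- check_flux_vector(net, v)
  if (!chk$ok) stop("infeasible truth flux vector:\n  ",
                    paste(chk$violations, collapse = "\n  "))
  if (is.null(system)) system <- decompose(net)
  set.seed(seed)
  noiseless <- list()
  data <- list()
  for (i in seq_along(tracer_ids)) {
    trid <- tracer_ids[i]
    sim <- simulate_mids(net, v, tracers = tracer_by_id(net, trid),
                         system = system, check = FALSE)
    noiseless[[trid]] <- sim
    mids <- lapply(sim, function(m) {
      if (noise_sd == 0)
        list(values = as.numeric(m), sd = rep(0, length(m)))
      else noisy_mid_replicates(as.numeric(m), noise_sd, replicates)
    })
    fluxes <- NULL
    if (i == 1L && length(measured_fluxes)) {
      j <- match(measured_fluxes, v$reaction)
      truth <- v$net[j]
      sdv <- pmax(abs(truth) * flux_rel_sd, flux_abs_sd)
      val <- if (noise_sd == 0) truth else truth + rnorm(length(truth), 0, sdv)
      fluxes <- data.frame(reaction = measured_fluxes, value = val, sd = sdv)
    }
    data[[trid]] <- measurement_set(trid, mids, fluxes = fluxes)
  }
  structure(list(truth = v, data = data, noiseless = noiseless,
                 seed = seed, noise_sd = noise_sd, replicates = replicates),
            class = "synthetic_mfa")
}

#' Generate a synthetic ISA palmitate dataset
#'
#' @param D,g true ISA parameters in `[0, 1]`.
#' @param acetyl_mid tracer-derived acetyl-CoA MID (see [isa_forward]).
#' @param noise_sd MID noise SD (0 gives the exact forward model).
#' @param replicates replicates (default 3).
#' @param seed RNG seed.
#' @param chain_length acetyl condensations (default 8, palmitate).
#' @return list with `truth`, `values` (replicate mean), `sd`, and the
#'   settings.
#' @export
synth_isa_dataset <- function(D, g, acetyl_mid = c(0, 0, 1),
                              noise_sd = 0.003, replicates = 3, seed = 1,
                              chain_length = 8) {
  clean <- as.numeric(isa_forward(D, g, acetyl_mid, chain_length))
  set.seed(seed)
  out <- if (noise_sd == 0)
    list(values = clean, sd = rep(0, length(clean)))
  else noisy_mid_replicates(clean, noise_sd, replicates)
  structure(c(out, list(truth = c(D = D, g = g), acetyl_mid = acetyl_mid,
                        chain_length = chain_length, seed = seed,
                        noise_sd = noise_sd)),
            class = "synthetic_isa")
}

#' Generate a synthetic media time-course
#'
#' Forward-simulates media depletion by cells growing exponentially and
#' taking up (or secreting) a metabolite at a constant per-cell flux:
#' `CT = C0 - flux * (NT - N0) / (mu * V)` in concentration units, with
#' counts expressed per 10^6 cells internally.
#'
#' @param flux true per-cell flux (nmol per 10^6 cells per h; uptake
#'   positive).
#' @param mu specific growth rate (1/h).
#' @param N0 starting cell count (cells).
#' @param V_mL media volume (mL).
#' @param T_h duration (h).
#' @param C0 starting concentration (uM).
#' @param noise_sd Gaussian SD added to concentrations (uM).
#' @param seed RNG seed.
#' @return data.frame with columns `metabolite`, `C0_uM`, `CT_uM`, `V_mL`,
#'   `N0`, `NT`, `T_h`, `clipped` plus attribute `truth`.
#' @export
synth_timecourse <- function(flux, mu, N0, V_mL, T_h, C0 = 500,
                             noise_sd = 0, seed = 1,
                             metabolite = "citrate") {
  if (N0 <= 0 || V_mL <= 0 || T_h <= 0) stop("N0, V_mL, T_h must be positive")
  NT <- N0 * exp(mu * T_h)
  cell_hours <- if (abs(mu) < 1e-12) N0 * T_h else (NT - N0) / mu
  CT <- C0 - flux * cell_hours / (V_mL * 1e6)
  set.seed(seed)
  if (noise_sd > 0) {
    C0 <- C0 + rnorm(1, 0, noise_sd)
    CT <- CT + rnorm(1, 0, noise_sd)
  }
  clipped <- FALSE
  if (CT < 0) { CT <- 0; clipped <- TRUE
    warning("time-course clipped at zero concentration") }
  out <- data.frame(metabolite = metabolite, C0_uM = C0, CT_uM = CT,
                    V_mL = V_mL, N0 = N0, NT = NT, T_h = T_h,
                    clipped = clipped, stringsAsFactors = FALSE)
  attr(out, "truth") <- c(flux = flux, mu = mu)
  out
}
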