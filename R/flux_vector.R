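#' Construct a flux vector
#'
#' A flux vector assigns every reaction a net flux (signed for reversible
#' reactions) and every reversible reaction a non-negative exchange flux.
#' The forward and backward rates entering labeling simulations are
#' `fwd = exchange + max(net, 0)` and `bwd = exchange + max(-net, 0)`.
#' Units: nmol per 10^6 cells per hour.
#'
#' @param net a `flux_network`.
#' @param net_flux named numeric of net fluxes (one per reaction; missing
#'   entries default to 0).
#' @param exchange named numeric of exchange fluxes for reversible
#'   reactions (missing entries default to 0).
#' @param check validate steady state and bounds (default `TRUE`).
#' @param tol steady-state tolerance.
#' @return a `flux_vector`: data.frame with columns `reaction`, `net`,
#'   `exchange`.
#' @export
flux_vector <- function(net, net_flux, exchange = numeric(), check = TRUE,
                        tol = 1e-6) {
  rids <- names(net$reactions)
  v <- setNames(numeric(length(rids)), rids)
  if (length(net_flux)) {
    if (is.null(names(net_flux)) && length(net_flux) == length(rids))
      names(net_flux) <- rids
    unknown <- setdiff(names(net_flux), rids)
    if (length(unknown)) stop("unknown reactions: ",
                              paste(unknown, collapse = ", "))
    v[names(net_flux)] <- net_flux
  }
  ex <- setNames(numeric(length(rids)), rids)
  if (length(exchange)) {
    unknown <- setdiff(names(exchange), rids)
    if (length(unknown)) stop("unknown reactions: ",
                              paste(unknown, collapse = ", "))
    ex[names(exchange)] <- exchange
  }
  fv <- structure(data.frame(reaction = rids, net = as.numeric(v),
                             exchange = as.numeric(ex),
                             stringsAsFactors = FALSE),
                  class = c("flux_vector", "data.frame"))
  if (check) {
    chk <- check_flux_vector(net, fv, tol = tol)
    if (!chk$ok)
      stop("invalid flux vector:\n  ", paste(chk$violations, collapse = "\n  "))
  }
  fv
}

#' Check a flux vector against a network
#'
#' Verifies steady-state mass balance `S v = 0` for balanced metabolites,
#' bound compliance, non-negative exchange fluxes, and that exchange is
#' zero on irreversible reactions.
#'
#' @param net a `flux_network`.
#' @param v a `flux_vector`.
#' @param tol balance tolerance (absolute, relative to flux scale).
#' @return list with `ok` and `violations`.
#' @export
check_flux_vector <- function(net, v, tol = 1e-6) {
  violations <- character()
  S <- stoich_matrix(net)
  imb <- S %*% v$net[match(colnames(S), v$reaction)]
  scale <- max(1, max(abs(v$net)))
  bad <- abs(imb) > tol * scale
  if (any(bad))
    violations <- c(violations, paste0("imbalance at ", rownames(S)[bad],
                                       " (", format(imb[bad], digits = 4), ")"))
  for (i in seq_along(net$reactions)) {
    rx <- net$reactions[[i]]
    j <- match(rx$id, v$reaction)
    if (v$net[j] < rx$lb - 1e-9 || v$net[j] > rx$ub + 1e-9)
      violations <- c(violations, paste0(rx$id, ": net ", format(v$net[j]),
                                         " outside [", rx$lb, ", ", rx$ub, "]"))
    if (v$exchange[j] < 0)
      violations <- c(violations, paste0(rx$id, ": negative exchange"))
    if (!rx$reversible && v$exchange[j] != 0)
      violations <- c(violations, paste0(rx$id,
                                         ": exchange on irreversible reaction"))
  }
  list(ok = length(violations) == 0L, violations = violations)
}

# forward/backward rates per reaction (named vectors)
flux_rates <- function(net, v) {
  fwd <- pmax(v$net, 0) + v$exchange
  bwd <- pmax(-v$net, 0) + v$exchange
  names(fwd) <- names(bwd) <- v$reaction
  list(fwd = fwd, bwd = bwd)
}

#' Null-space basis of the stoichiometric matrix
#'
#' Columns span the space of steady-state net-flux vectors; the number of
#' columns is the count of free net fluxes.
#'
#' @param net a `flux_network`.
#' @return matrix with one row per reaction.
#' @export
null_basis <- function(net) {
  S <- stoich_matrix(net)
  N <- MASS::Null(t(S))           # S %*% N = 0
  rownames(N) <- colnames(S)
  N
}

#' Solve for a steady-state flux vector near target values
#'
#' Finds the steady-state net-flux vector closest (weighted least squares)
#' to a set of target values, by projecting onto the null space of the
#' stoichiometric matrix. Used to construct feasible ground-truth vectors
#' and initial points.
#'
#' @param net a `flux_network`.
#' @param targets named numeric of desired net fluxes (soft constraints,
#'   weight `weight` each); unnamed reactions are pulled weakly to zero.
#' @param exchange named numeric of exchange fluxes to attach.
#' @param weight weight on targeted components relative to the ridge.
#' @param check validate the result.
#' @return a `flux_vector`.
#' @export
steady_state_fluxes <- function(net, targets, exchange = numeric(),
                                weight = 1e4, check = TRUE) {
  N <- null_basis(net)
  rids <- rownames(N)
  w <- rep(1e-3, length(rids))
  t0 <- setNames(numeric(length(rids)), rids)
  unknown <- setdiff(names(targets), rids)
  if (length(unknown)) stop("unknown reactions: ",
                            paste(unknown, collapse = ", "))
  w[match(names(targets), rids)] <- weight
  t0[names(targets)] <- targets
  A <- N * sqrt(w)
  b <- t0 * sqrt(w)
  u <- qr.solve(A, b)
  v <- as.numeric(N %*% u)
  names(v) <- rids
  flux_vector(net, v, exchange = exchange, check = check)
}
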