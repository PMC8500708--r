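#' Bundle one tracer experiment's measurements
#'
#' A measurement set holds the natural-abundance-corrected fragment MIDs
#' (with per-isotopomer SDs) from one parallel labeling experiment, plus
#' any directly measured extracellular fluxes. All tracer experiments in a
#' fit share one flux vector (parallel experiments at metabolic steady
#' state).
#'
#' @param tracer tracer id (must exist in the network's tracer list).
#' @param mids named list (by fragment label) of lists with elements
#'   `values` (MID fractions) and `sd` (same length). SDs are floored at
#'   `sd_floor`.
#' @param fluxes data.frame with columns `reaction`, `value`, `sd`
#'   (measured net fluxes; uptake reactions positive by construction of
#'   the network's uptake/secretion directions).
#' @param sd_floor minimum SD for MID entries (mole fraction).
#' @return a `measurement_set`.
#' @export
measurement_set <- function(tracer, mids, fluxes = NULL, sd_floor = 0.003) {
  mids <- lapply(mids, function(m) {
    stopifnot(length(m$values) == length(m$sd))
    if (any(m$sd < 0)) stop("negative SD in MID measurements")
    list(values = as.numeric(m$values), sd = pmax(as.numeric(m$sd), sd_floor))
  })
  if (!is.null(fluxes)) {
    stopifnot(all(c("reaction", "value", "sd") %in% names(fluxes)))
    if (any(fluxes$sd <= 0)) stop("flux measurement SDs must be positive")
  }
  structure(list(tracer = tracer, mids = mids, fluxes = fluxes),
            class = "measurement_set")
}

check_measurements <- function(net, data) {
  labels <- vapply(net$fragments, `[[`, character(1), "label")
  trids <- vapply(net$tracers, `[[`, character(1), "id")
  for (ms in data) {
    if (!(ms$tracer %in% trids))
      stop("measurement set references unknown tracer ", ms$tracer)
    bad <- setdiff(names(ms$mids), labels)
    if (length(bad))
      stop("measurement set references unknown fragments: ",
           paste(bad, collapse = ", "))
    if (!is.null(ms$fluxes)) {
      bad <- setdiff(ms$fluxes$reaction, names(net$reactions))
      if (length(bad))
        stop("measured fluxes reference unknown reactions: ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

tracer_by_id <- function(net, id) {
  Filter(function(tr) tr$id == id, net$tracers)
}

#' Weighted residual vector of a flux vector against measurements
#'
#' Concatenates, over all tracer experiments, `(simulated - measured) / sd`
#' for every MID entry, followed by `(net - measured) / sd` for every
#' measured extracellular flux.
#'
#' @param net a `flux_network`.
#' @param v a `flux_vector`.
#' @param data list of [measurement_set] objects.
#' @param system optional precomputed [decompose()] result.
#' @return numeric residual vector (named).
#' @export
residuals_mfa <- function(net, v, data, system = NULL, check = TRUE) {
  if (check) check_measurements(net, data)
  if (is.null(system)) system <- decompose(net)
  labels <- vapply(system$targets, `[[`, character(1), "label")
  tidx <- setNames(system$compiled$target_idx, labels)
  tracer_sets <- lapply(data, function(ms) tracer_by_id(net, ms$tracer))
  sols <- simulate_experiments(net, v, tracer_sets, system)
  out <- vector("list", length(data) * 2L)
  k <- 0L
  for (e in seq_along(data)) {
    ms <- data[[e]]
    s <- sols[[e]]
    for (lab in names(ms$mids)) {
      m <- ms$mids[[lab]]
      sim <- s[[tidx[[lab]]]]
      sim <- sim / sum(sim)
      if (length(sim) != length(m$values))
        stop("fragment ", lab, ": measured MID length ", length(m$values),
             " != simulated length ", length(sim))
      r <- (sim - m$values) / m$sd
      names(r) <- paste0(ms$tracer, ".", lab, ".M", seq_along(r) - 1L)
      k <- k + 1L; out[[k]] <- r
    }
    if (!is.null(ms$fluxes)) {
      j <- match(ms$fluxes$reaction, v$reaction)
      r <- (v$net[j] - ms$fluxes$value) / ms$fluxes$sd
      names(r) <- paste0(ms$tracer, ".flux.", ms$fluxes$reaction)
      k <- k + 1L; out[[k]] <- r
    }
  }
  unlist(out[seq_len(k)])
}

# parameter vector <-> flux vector plumbing
fit_context <- function(net, data, system, ex_cap) {
  N <- null_basis(net)
  rev_ids <- names(net$reactions)[vapply(net$reactions, `[[`, logical(1),
                                         "reversible")]
  rids <- rownames(N)
  lb <- vapply(net$reactions, `[[`, numeric(1), "lb")[rids]
  ub <- vapply(net$reactions, `[[`, numeric(1), "ub")[rids]
  list(net = net, data = data, system = system, N = N, rev_ids = rev_ids,
       rids = rids, lb = lb, ub = ub, nu = ncol(N), nex = length(rev_ids),
       ex_cap = ex_cap, nresid = count_residuals(data)$total)
}

# lightweight flux container for the optimization hot path (list, not
# data.frame; field-compatible with flux_vector accessors used internally)
par_to_flux <- function(ctx, par) {
  u <- par[seq_len(ctx$nu)]
  ex <- if (ctx$nex) par[ctx$nu + seq_len(ctx$nex)] else numeric(0)
  exch <- setNames(numeric(length(ctx$rids)), ctx$rids)
  exch[ctx$rev_ids] <- ex
  list(reaction = ctx$rids, net = as.numeric(ctx$N %*% u),
       exchange = unname(exch))
}

par_to_flux_vector <- function(ctx, par) {
  v <- par_to_flux(ctx, par)
  structure(data.frame(reaction = v$reaction, net = v$net,
                       exchange = v$exchange, stringsAsFactors = FALSE),
            class = c("flux_vector", "data.frame"))
}

resid_with_penalty <- function(ctx, par, extra = NULL) {
  v <- par_to_flux(ctx, par)
  # a trial step may strand a pool without inflow; return a large finite
  # cost so Levenberg-Marquardt rejects the step rather than aborting
  r <- tryCatch(residuals_mfa(ctx$net, v, ctx$data, system = ctx$system,
                              check = FALSE),
                error = function(e) rep(1e4, ctx$nresid))
  pen <- sqrt(1e6) * (pmax(0, ctx$lb - v$net) + pmax(0, v$net - ctx$ub))
  if (!is.null(extra)) pen <- c(pen, extra(v))
  c(r, pen)
}

data_ssr <- function(ctx, par) {
  v <- par_to_flux(ctx, par)
  r <- tryCatch(residuals_mfa(ctx$net, v, ctx$data, system = ctx$system,
                              check = FALSE),
                error = function(e) rep(1e4, ctx$nresid))
  sum(r^2)
}

random_start <- function(ctx) {
  rev <- ctx$lb < 0
  vt <- numeric(length(ctx$rids))
  vt[rev] <- runif(sum(rev), -150, 150)
  lo <- pmax(ctx$lb[!rev], 0)
  hi <- pmax(pmin(ctx$ub[!rev], 300), lo)
  vt[!rev] <- lo + runif(sum(!rev)) * (hi - lo)
  # include measured fluxes in the start target when available
  for (ms in ctx$data) if (!is.null(ms$fluxes))
    vt[match(ms$fluxes$reaction, ctx$rids)] <- ms$fluxes$value
  u0 <- qr.solve(ctx$N, vt)
  ex0 <- runif(ctx$nex, 5, 150)
  c(u0, ex0)
}

# Levenberg-Marquardt interleaved with bounded quasi-Newton restarts. LM on
# this objective can satisfy its step-size test inside curved valleys while
# the gradient is still large; an L-BFGS-B stage relocates the iterate along
# the valley and LM is restarted, until the SSR stops improving.
optimize_from <- function(ctx, par, extra = NULL, maxiter = 150, rounds = 10,
                          lower = c(rep(-Inf, ctx$nu), rep(0, ctx$nex)),
                          upper = c(rep(Inf, ctx$nu), rep(ctx$ex_cap, ctx$nex))) {
  fn <- function(p) resid_with_penalty(ctx, p, extra)
  f <- function(p) sum(fn(p)^2)
  best <- NULL
  for (round in seq_len(rounds)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = par, fn = fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, nprint = 0)),
      error = function(e) NULL)
    if (!is.null(res)) {
      par <- res$par
      ssr <- f(par)
      if (is.null(best) || ssr < best$ssr)
        best <- list(par = par, ssr = ssr, info = res$info)
    }
    if (is.null(best)) return(NULL)
    if (best$ssr < 1e-10) break
    prev <- best$ssr
    ob <- tryCatch(
      stats::optim(par, f, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 40)),
      error = function(e) NULL)
    if (!is.null(ob)) {
      par <- ob$par
      if (ob$value < best$ssr) best <- list(par = par, ssr = ob$value,
                                            info = best$info)
    }
    # stop when a full LM + quasi-Newton round no longer improves
    if (best$ssr > prev * (1 - 1e-9) - 1e-12 &&
        !is.null(ob) && round > 1) break
  }
  best
}

count_residuals <- function(data) {
  nm <- sum(vapply(data, function(ms)
    sum(vapply(ms$mids, function(m) length(m$values), integer(1))), integer(1)))
  nfrag <- sum(vapply(data, function(ms) length(ms$mids), integer(1)))
  nfl <- sum(vapply(data, function(ms)
    if (is.null(ms$fluxes)) 0L else nrow(ms$fluxes), integer(1)))
  list(total = nm + nfl, independent = (nm - nfrag) + nfl)
}

#' Fit net and exchange fluxes to multi-tracer measurements
#'
#' Minimizes the variance-weighted sum of squared residuals over
#' steady-state net fluxes (parameterized on the null space of the
#' stoichiometric matrix, with bound violations penalized) and raw
#' exchange fluxes (box-bounded at `ex_cap`), by Levenberg-Marquardt from
#' multiple seeded random feasible starts.
#'
#' @param net a `flux_network`.
#' @param data list of [measurement_set] objects (>= 1).
#' @param n_starts number of multistart initializations (default 25).
#' @param seed RNG seed for start generation (default 17).
#' @param ex_cap upper bound on exchange fluxes.
#' @param maxiter per-start Levenberg-Marquardt iteration cap.
#' @param polish number of screened starts (best first) given the full
#'   LM/quasi-Newton polishing treatment.
#' @param system optional precomputed [decompose()] result.
#' @return a `flux_fit`: best flux vector, `ssr`, `dof`, residual counts,
#'   per-start record, and the internal context used by [profile_ci()].
#' @export
fit_fluxes <- function(net, data, n_starts = 25, seed = 17, ex_cap = 1e4,
                       maxiter = 150, polish = 3, system = NULL) {
  check_measurements(net, data)
  if (is.null(system)) system <- decompose(net)
  ctx <- fit_context(net, data, system, ex_cap)
  nres <- count_residuals(data)
  npar <- ctx$nu + ctx$nex
  if (npar > nres$total)
    stop("under-determined fit: ", npar, " free parameters but only ",
         nres$total, " residuals")
  lower <- c(rep(-Inf, ctx$nu), rep(0, ctx$nex))
  upper <- c(rep(Inf, ctx$nu), rep(ex_cap, ctx$nex))

  set.seed(seed)
  starts <- replicate(n_starts, random_start(ctx), simplify = FALSE)
  record <- data.frame(start = seq_len(n_starts), ssr = NA_real_,
                       polished = FALSE, converged = FALSE)
  # screening pass: one Levenberg-Marquardt run per start
  screened <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]],
                         fn = function(p) resid_with_penalty(ctx, p),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, nprint = 0)),
      error = function(e) NULL)
    if (is.null(res)) next
    screened[[i]] <- list(par = res$par, ssr = data_ssr(ctx, res$par),
                          info = res$info)
    record$ssr[i] <- screened[[i]]$ssr
    record$converged[i] <- res$info %in% 1:4
    if (screened[[i]]$ssr < 1e-8) break
  }
  ok <- which(!vapply(screened, is.null, logical(1)))
  if (length(ok) == 0)
    stop("no feasible start converged; check bounds and balances")
  # polishing pass: interleaved LM/quasi-Newton on the most promising starts
  best <- NULL
  for (i in ok[order(vapply(screened[ok], `[[`, numeric(1), "ssr"))][
    seq_len(min(polish, length(ok)))]) {
    if (screened[[i]]$ssr < 1e-8) {
      best <- screened[[i]]
      break
    }
    res <- optimize_from(ctx, screened[[i]]$par, maxiter = maxiter,
                         lower = lower, upper = upper)
    if (is.null(res)) next
    ssr <- data_ssr(ctx, res$par)
    record$ssr[i] <- ssr
    record$polished[i] <- TRUE
    if (is.null(best) || ssr < best$ssr)
      best <- list(par = res$par, ssr = ssr, info = res$info)
    if (ssr < 1e-8) break  # global optimum reached
  }
  if (is.null(best)) {
    i <- ok[which.min(vapply(screened[ok], `[[`, numeric(1), "ssr"))]
    best <- screened[[i]]
  }

  v <- par_to_flux_vector(ctx, best$par)
  chk <- check_flux_vector(net, v, tol = 1e-5)
  structure(list(net = net, data = data, flux = v, par = best$par,
                 ssr = best$ssr, dof = nres$independent - npar,
                 n_residuals = nres$total,
                 n_independent = nres$independent, n_par = npar,
                 feasible = chk$ok, multistart = record, ctx = ctx,
                 seed = seed),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("flux_fit: SSR =", format(x$ssr, digits = 6), "on", x$dof,
      "degrees of freedom (", x$n_par, "parameters );",
      sum(x$multistart$converged, na.rm = TRUE), "/",
      nrow(x$multistart), "starts converged\n")
  invisible(x)
}

#' Chi-square goodness-of-fit verdict for an MFA fit
#'
#' Accepts the fit when the SSR lies between the `alpha/2` and
#' `1 - alpha/2` quantiles of the chi-square distribution with the fit's
#' degrees of freedom. An SSR below the lower bound signals residuals
#' smaller than the declared measurement error (over-fit or noise-free
#' data); above the upper bound, model misspecification.
#'
#' @param fit a `flux_fit`.
#' @param alpha test level (default 0.05).
#' @return list with `accept`, `ssr`, `dof`, `lower`, `upper`, `note`.
#' @export
goodness_of_fit <- function(fit, alpha = 0.05) {
  if (fit$dof <= 0) stop("under-determined fit: dof = ", fit$dof)
  lo <- qchisq(alpha / 2, fit$dof)
  hi <- qchisq(1 - alpha / 2, fit$dof)
  note <- if (fit$ssr < lo)
    "SSR below lower bound: residuals smaller than declared noise"
  else if (fit$ssr > hi)
    "SSR above upper bound: model does not explain the data at the declared noise"
  else "fit accepted"
  list(accept = fit$ssr >= lo && fit$ssr <= hi, ssr = fit$ssr,
       dof = fit$dof, lower = lo, upper = hi, note = note)
}

reoptimize_fixed <- function(fit, what, rxn, value, start = fit$par,
                             maxiter = 60, rounds = 3) {
  ctx <- fit$ctx
  j <- match(rxn, ctx$rids)
  extra <- if (what == "net") {
    function(v) sqrt(1e8) * (v$net[j] - value)
  } else {
    function(v) sqrt(1e8) * (v$exchange[j] - value)
  }
  res <- optimize_from(ctx, start, extra = extra, maxiter = maxiter,
                       rounds = rounds)
  if (is.null(res)) return(NULL)
  list(par = res$par, ssr = data_ssr(ctx, res$par))
}

#' Profile-likelihood confidence interval for one flux
#'
#' Steps the chosen net (or exchange) flux away from its point estimate,
#' re-optimizing all other parameters, until the SSR exceeds the optimum
#' by the chi-square-1 quantile (3.84 at 95%); the crossing is then located
#' by bisection. Directions that reach the flux bounds without crossing
#' are flagged unbounded (structurally non-identifiable fluxes get a
#' one- or two-sided unbounded interval).
#'
#' @param fit a `flux_fit`.
#' @param rxn reaction id.
#' @param what `"net"` or `"exchange"`.
#' @param alpha level (default 0.05, i.e. 95% CI).
#' @param rel_tol bisection termination tolerance (relative to the flux
#'   scale).
#' @param max_iter maximum re-optimizations per direction.
#' @param rounds LM/quasi-Newton rounds per re-optimization (1 is usually
#'   enough for warm-started profiles on small networks).
#' @return list with `lower`, `upper`, `estimate`, flags
#'   `lower_unbounded`, `upper_unbounded`, `failed`, and the SSR
#'   threshold used.
#' @export
profile_ci <- function(fit, rxn, what = c("net", "exchange"), alpha = 0.05,
                       rel_tol = 1e-3, max_iter = 60, rounds = 3) {
  what <- match.arg(what)
  ctx <- fit$ctx
  j <- match(rxn, ctx$rids)
  if (is.na(j)) stop("unknown reaction: ", rxn)
  est <- if (what == "net") fit$flux$net[j] else fit$flux$exchange[j]
  thr <- fit$ssr + qchisq(1 - alpha, df = 1)
  rx <- ctx$net$reactions[[rxn]]
  lims <- if (what == "net") c(rx$lb, rx$ub) else c(0, ctx$ex_cap)
  scale <- max(abs(est), 1)

  one_dir <- function(sgn) {
    lim <- if (sgn > 0) lims[2] else lims[1]
    step <- 0.1 * scale
    inside <- est           # largest |value| known to satisfy SSR <= thr
    outside <- NA_real_     # first value known to exceed thr
    par <- fit$par
    n_eval <- 0L
    val <- est
    while (n_eval < max_iter) {
      val <- val + sgn * step
      hit_lim <- (sgn > 0 && val >= lim) || (sgn < 0 && val <= lim)
      if (hit_lim) val <- lim
      r <- reoptimize_fixed(fit, what, rxn, val, start = par, rounds = rounds)
      n_eval <- n_eval + 1L
      if (is.null(r)) return(list(bound = NA_real_, unbounded = FALSE,
                                  failed = TRUE))
      par <- r$par
      if (r$ssr > thr) { outside <- val; break }
      inside <- val
      if (hit_lim) return(list(bound = lim, unbounded = TRUE, failed = FALSE))
      step <- step * 2
    }
    if (is.na(outside))
      return(list(bound = inside, unbounded = FALSE, failed = TRUE))
    while (abs(outside - inside) > rel_tol * scale && n_eval < max_iter) {
      midv <- (inside + outside) / 2
      r <- reoptimize_fixed(fit, what, rxn, midv, start = par, rounds = rounds)
      n_eval <- n_eval + 1L
      if (is.null(r)) break
      par <- r$par
      if (r$ssr > thr) outside <- midv else inside <- midv
    }
    list(bound = (inside + outside) / 2, unbounded = FALSE, failed = FALSE)
  }

  up <- one_dir(+1)
  dn <- one_dir(-1)
  list(reaction = rxn, what = what, estimate = est,
       lower = if (dn$unbounded) lims[1] else dn$bound,
       upper = if (up$unbounded) lims[2] else up$bound,
       lower_unbounded = dn$unbounded, upper_unbounded = up$unbounded,
       failed = up$failed || dn$failed, threshold = thr)
}

#' Flag identifiable net fluxes by local sensitivity
#'
#' Computes the Jacobian of the data residuals with respect to the free
#' parameters at the optimum; parameter directions with singular values
#' below `sv_tol` times the largest define the locally non-identifiable
#' subspace. A net flux is flagged identifiable when its value is
#' insensitive to movements within that subspace.
#'
#' @param fit a `flux_fit`.
#' @param sv_tol singular-value cutoff relative to the largest.
#' @param move_tol flux-movement cutoff (absolute, per unit movement in
#'   the null directions) relative to the flux scale.
#' @return data.frame with `reaction`, `net`, `identifiable`.
#' @export
identifiable_fluxes <- function(fit, sv_tol = 1e-5, move_tol = 1e-6) {
  ctx <- fit$ctx
  p0 <- fit$par
  r0 <- residuals_mfa(ctx$net, par_to_flux(ctx, p0), ctx$data, ctx$system,
                      check = FALSE)
  h <- 1e-5 * pmax(abs(p0), 1)
  J <- matrix(0, length(r0), length(p0))
  for (k in seq_along(p0)) {
    p1 <- p0; p1[k] <- p1[k] + h[k]
    r1 <- residuals_mfa(ctx$net, par_to_flux(ctx, p1), ctx$data, ctx$system,
                        check = FALSE)
    J[, k] <- (r1 - r0) / h[k]
  }
  sv <- svd(J)
  null_dirs <- sv$v[, sv$d < sv_tol * max(sv$d), drop = FALSE]
  move <- if (ncol(null_dirs) == 0) {
    matrix(0, length(ctx$rids), 0)
  } else {
    ctx$N %*% null_dirs[seq_len(ctx$nu), , drop = FALSE]
  }
  scale <- max(1, max(abs(fit$flux$net)))
  sens <- if (ncol(move)) sqrt(rowSums(move^2)) else numeric(length(ctx$rids))
  data.frame(reaction = ctx$rids, net = fit$flux$net,
             identifiable = sens <= move_tol * scale,
             row.names = NULL, stringsAsFactors = FALSE)
}
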