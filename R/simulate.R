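#' Simulate steady-state fragment MIDs by EMU cascade
#'
#' Solves the steady-state EMU balances of the network at the given flux
#' vector and tracer composition, size by size, as dense linear systems.
#' Reversible reactions contribute forward and backward rates
#' `exchange + max(+-net, 0)`; symmetric-molecule scrambling is already
#' encoded in the network's atom-map variants, so the solver needs no
#' special cases. MIDs are on the tracer-only (natural-abundance-corrected)
#' scale.
#'
#' @param net a `flux_network`.
#' @param v a `flux_vector` (see [flux_vector()]).
#' @param tracers list of active [tracer()] objects for this experiment
#'   (defaults to all tracers in the network — typically you pass the one
#'   tracer used in a given parallel labeling experiment).
#' @param system a precomputed [decompose()] result (recomputed if `NULL`).
#' @param check verify the flux vector first.
#' @return named list of [mid] objects, one per target fragment label.
#' @export
simulate_mids <- function(net, v, tracers = net$tracers, system = NULL,
                          check = TRUE) {
  if (check) {
    chk <- check_flux_vector(net, v)
    if (!chk$ok) stop("infeasible flux vector:\n  ",
                      paste(chk$violations, collapse = "\n  "))
  }
  if (is.null(system)) system <- decompose(net)
  sols <- simulate_experiments(net, v, list(tracers), system)[[1]]
  out <- lapply(seq_along(system$targets), function(k)
    mid(sols[[system$compiled$target_idx[k]]],
        id = system$targets[[k]]$label))
  names(out) <- vapply(system$targets, `[[`, character(1), "label")
  out
}

# Solve the EMU cascade for several tracer experiments that share one flux
# vector: the balance matrix A per size depends only on fluxes, so one LU
# factorization serves all experiments (only the right-hand sides differ).
# Returns, per experiment, a list over global EMU indices of MID vectors.
simulate_experiments <- function(net, v, tracer_sets, system) {
  cmp <- system$compiled
  rates <- flux_rates(net, v)
  fwd <- unname(rates$fwd); bwd <- unname(rates$bwd)
  ntr <- length(tracer_sets)
  sols <- vector("list", ntr)
  for (t in seq_len(ntr)) {
    sols[[t]] <- vector("list", cmp$n_emus)
    for (k in seq_along(cmp$inputs))
      sols[[t]][[cmp$inputs[k]]] <- input_emu_mid(cmp$input_met[k],
                                                  cmp$input_atoms[[k]],
                                                  tracer_sets[[t]])
  }
  for (blk in cmp$per_size) {
    n <- length(blk$unk)
    m <- blk$size + 1L
    A <- matrix(0, n, n)
    B <- matrix(0, n, m * ntr)
    for (tr in blk$trans) {
      rate <- (if (tr$dir == 1L) fwd[tr$rxn] else bwd[tr$rxn]) * tr$w
      if (rate <= 0) next
      i <- tr$i
      A[i, i] <- A[i, i] + rate
      if (tr$src_j > 0L) {
        A[i, tr$src_j] <- A[i, tr$src_j] - rate
      } else {
        for (t in seq_len(ntr)) {
          s <- sols[[t]]
          x <- s[[tr$src[1]]]
          for (g in tr$src[-1]) x <- conv_vec(x, s[[g]])
          cols <- ((t - 1L) * m + 1L):(t * m)
          B[i, cols] <- B[i, cols] + rate * x
        }
      }
    }
    dead <- diag(A) <= 0
    if (any(dead))
      stop("degenerate pool: no labeled inflow reaches ",
           paste(unique(system$emus$met[blk$unk[dead]]), collapse = ", "),
           " at this flux vector")
    X <- tryCatch(solve(A, B), error = function(e)
      stop("singular EMU balance at size ", blk$size,
           " (zero-flux trapped pool among ",
           paste(unique(system$emus$met[blk$unk]), collapse = ", "),
           ")", call. = FALSE))
    for (t in seq_len(ntr)) {
      cols <- ((t - 1L) * m + 1L):(t * m)
      for (i in seq_len(n)) {
        x <- X[i, cols]
        x[x < 0 & x > -1e-12] <- 0
        sols[[t]][[blk$unk[i]]] <- x
      }
    }
  }
  sols
}

# ---- brute-force positional-isotopomer oracle ----------------------------

bit_subset_map <- function(n, positions) {
  # maps full-pattern index (1..2^n) to sub-pattern index (1..2^k) over
  # `positions` (order defines bit order of the sub pattern)
  full <- 0:(2^n - 1L)
  subp <- integer(length(full))
  for (b in seq_along(positions))
    subp <- subp + bitwShiftL(
      as.integer(bitwAnd(bitwShiftR(full, positions[b] - 1L), 1L)), b - 1L)
  subp + 1L
}

popcount_vec <- function(x) {
  out <- integer(length(x))
  while (any(x > 0)) {
    out <- out + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  out
}

#' Brute-force steady-state MIDs from full positional isotopomers
#'
#' Reference implementation used to verify [simulate_mids()]: tracks the
#' complete positional-isotopomer distribution (2^n states per metabolite)
#' and solves the steady-state balance by damped Gauss-Seidel iteration to
#' numerical convergence. Only practical on small networks.
#'
#' @inheritParams simulate_mids
#' @param fragments fragments to report (defaults to the network's list).
#' @param cap maximum total backbone carbons across balanced metabolites.
#' @param tol convergence tolerance on the max absolute change per sweep.
#' @param max_iter sweep limit.
#' @return named list of [mid] objects.
#' @export
brute_force_mids <- function(net, v, tracers = net$tracers,
                             fragments = net$fragments, cap = 24,
                             tol = 1e-13, max_iter = 50000, check = TRUE) {
  if (check) {
    chk <- check_flux_vector(net, v)
    if (!chk$ok) stop("infeasible flux vector:\n  ",
                      paste(chk$violations, collapse = "\n  "))
  }
  bal <- net$metabolites[net$metabolites$balanced, ]
  if (sum(bal$n_carbons) > cap)
    stop("network exceeds brute-force cap of ", cap, " balanced carbons")
  nc <- setNames(net$metabolites$n_carbons, net$metabolites$id)
  balanced <- setNames(net$metabolites$balanced, net$metabolites$id)

  # state: isotopomer distribution per metabolite
  dist <- list()
  for (id in net$metabolites$id) {
    n <- nc[[id]]
    d <- numeric(2^n)
    if (!balanced[[id]]) {
      p_rest <- 1
      for (tr in tracers) {
        if (tr$metabolite != id) next
        p <- tr$purity * tr$fraction
        pat <- sum(2^(tr$positions - 1L))
        d[pat + 1L] <- d[pat + 1L] + p
        p_rest <- p_rest - p
      }
      d[1L] <- d[1L] + max(p_rest, 0)
    } else d[1L] <- 1
    dist[[id]] <- d
  }

  rates <- flux_rates(net, v)
  # precompile production recipes per balanced metabolite
  recipes <- setNames(vector("list", nrow(bal)), bal$id)
  for (rx in net$reactions) {
    dirs <- if (rx$reversible) c(1L, -1L) else 1L
    for (vv in rx$variants) {
      for (dir in dirs) {
        prod_side <- if (dir == 1L) vv$products else vv$substrates
        sub_side  <- if (dir == 1L) vv$substrates else vv$products
        if (length(prod_side) == 0 || length(sub_side) == 0) next
        if (dir == -1L &&
            any(vapply(sub_side, function(s) is.na(s$atoms), logical(1))))
          next
        for (pe in prod_side) {
          if (is.na(pe$atoms) || !isTRUE(balanced[[pe$met]])) next
          np <- nc[[pe$met]]
          pchars <- strsplit(pe$atoms, "")[[1]]
          inst <- list()
          for (s in sub_side) {
            if (is.na(s$atoms)) next
            schars <- strsplit(s$atoms, "")[[1]]
            spos <- which(schars %in% pchars)
            if (!length(spos)) next
            ppos <- match(schars[spos], pchars)
            inst[[length(inst) + 1L]] <- list(
              met = s$met,
              marg = bit_subset_map(nc[[s$met]], spos),
              k = length(spos), ppos = ppos)
          }
          # permutation: combined sub-pattern index -> product pattern index
          order_ppos <- unlist(lapply(inst, `[[`, "ppos"))
          ncomb <- 2^np
          comb <- 0:(ncomb - 1L)
          perm <- integer(ncomb)
          for (b in seq_along(order_ppos))
            perm <- perm + bitwShiftL(
              as.integer(bitwAnd(bitwShiftR(comb, b - 1L), 1L)),
              order_ppos[b] - 1L)
          recipes[[pe$met]][[length(recipes[[pe$met]]) + 1L]] <-
            list(rxn = rx$id, dir = dir, weight = vv$weight,
                 inst = inst, perm = perm + 1L, n = np)
        }
      }
    }
  }

  rate_of <- function(rc) {
    r <- if (rc$dir == 1L) rates$fwd[[rc$rxn]] else rates$bwd[[rc$rxn]]
    r * rc$weight
  }

  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (id in bal$id) {
      total <- 0
      acc <- numeric(2^nc[[id]])
      for (rc in recipes[[id]]) {
        rate <- rate_of(rc)
        if (rate <= 0) next
        part <- 1
        for (ins in rc$inst) {
          m <- numeric(2^ins$k)
          src <- dist[[ins$met]]
          for (p in seq_along(src))
            m[ins$marg[p]] <- m[ins$marg[p]] + src[p]
          part <- as.numeric(outer(part, m))
        }
        out <- numeric(length(acc))
        out[rc$perm] <- part
        acc <- acc + rate * out
        total <- total + rate
      }
      if (total <= 0)
        stop("degenerate pool: ", id, " has no inflow at this flux vector")
      new <- acc / total
      # renormalize: the fixed point has unit mass, but condensation loops
      # amplify rounding noise in the total mass multiplicatively
      s <- sum(new)
      if (!is.finite(s) || s <= 0)
        stop("brute-force isotopomer balance diverged at ", id)
      new <- new / s
      delta <- max(delta, max(abs(new - dist[[id]])))
      dist[[id]] <- new
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("brute-force isotopomer balance did not converge in ", max_iter,
         " sweeps (last delta ", format(delta, digits = 3), ")")

  out <- lapply(fragments, function(fs) {
    d <- dist[[fs$metabolite]]
    mm <- bit_subset_map(nc[[fs$metabolite]], fs$carbons)
    sub <- numeric(2^length(fs$carbons))
    for (p in seq_along(d)) sub[mm[p]] <- sub[mm[p]] + d[p]
    cnt <- popcount_vec(0:(length(sub) - 1L))
    frac <- vapply(0:length(fs$carbons), function(i) sum(sub[cnt == i]),
                   numeric(1))
    mid(frac, id = fs$label)
  })
  names(out) <- vapply(fragments, `[[`, character(1), "label")
  out
}
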