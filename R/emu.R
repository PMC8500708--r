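#' @name emu
#' @title Elementary metabolite unit (EMU) decomposition
#'
#' @description
#' An EMU is a metabolite together with a subset of its backbone carbons.
#' Starting from the measured fragments, the decomposition traces each
#' product EMU back through every atom-map variant (and both directions of
#' reversible reactions) to the substrate EMUs that feed it, producing a
#' size-ordered reaction system whose steady state can be solved size by
#' size as a cascade of small dense linear systems.
NULL

emu_key <- function(met, atoms) paste0(met, "|", paste(atoms, collapse = "_"))

# map a product-side EMU back to substrate-side source EMUs for one variant
# direction. prod_entry: entry of the producing side carrying `met`;
# sub_side: entries of the consumed side. Returns list of (met, atoms).
trace_sources <- function(prod_entry, sub_side, atoms) {
  letters_needed <- strsplit(prod_entry$atoms, "")[[1]][atoms]
  src <- list()
  for (s in sub_side) {
    if (is.na(s$atoms)) next
    schars <- strsplit(s$atoms, "")[[1]]
    pos <- which(schars %in% letters_needed)
    if (length(pos)) src[[length(src) + 1L]] <- list(met = s$met,
                                                     atoms = sort(pos))
  }
  found <- sum(vapply(src, function(s) length(s$atoms), integer(1)))
  if (found != length(atoms))
    stop("atom map inconsistency tracing ", prod_entry$met,
         " atoms ", paste(atoms, collapse = ","))
  src
}

#' Decompose a network into an EMU system
#'
#' @param net a validated `flux_network`.
#' @param targets list of [fragment_spec] objects (defaults to the
#'   network's measured fragments).
#' @return an `emu_system`: the EMU table, the transition list, and the
#'   solve order by EMU size. Deterministic for a fixed network.
#' @export
decompose <- function(net, targets = net$fragments) {
  if (length(targets) == 0) stop("no target fragments to decompose")
  emus <- list()     # key -> list(met, atoms, size, input)
  transitions <- list()
  queue <- list()

  add_emu <- function(met, atoms) {
    key <- emu_key(met, atoms)
    if (is.null(emus[[key]])) {
      balanced <- is_balanced(net, met)
      emus[[key]] <<- list(key = key, met = met, atoms = atoms,
                           size = length(atoms), input = !balanced)
      if (balanced) queue[[length(queue) + 1L]] <<- key
    }
    key
  }

  for (fs in targets) {
    if (is.na(match(fs$metabolite, net$metabolites$id)))
      stop("target fragment ", fs$label, " references unknown metabolite ",
           fs$metabolite)
    add_emu(fs$metabolite, fs$carbons)
  }

  while (length(queue) > 0) {
    key <- queue[[1]]; queue <- queue[-1]
    e <- emus[[key]]
    n_prod <- 0L
    for (rx in net$reactions) {
      dirs <- if (rx$reversible) c(1L, -1L) else 1L
      for (v in rx$variants) {
        for (dir in dirs) {
          prod_side <- if (dir == 1L) v$products else v$substrates
          sub_side  <- if (dir == 1L) v$substrates else v$products
          if (length(prod_side) == 0 || length(sub_side) == 0) next
          if (any(vapply(sub_side, function(s) is.na(s$atoms), logical(1))) &&
              dir == -1L) next   # cannot run a drain backwards
          for (pe in prod_side) {
            if (pe$met != e$met || is.na(pe$atoms)) next
            src <- trace_sources(pe, sub_side, e$atoms)
            src_keys <- vapply(src, function(s) add_emu(s$met, s$atoms),
                               character(1))
            transitions[[length(transitions) + 1L]] <-
              list(to = key, src = src_keys, rxn = rx$id, dir = dir,
                   weight = v$weight)
            n_prod <- n_prod + 1L
          }
        }
      }
    }
    if (n_prod == 0L)
      stop("metabolite ", e$met, " (EMU ", key,
           ") is balanced but has no producing atom map; fragment unreachable")
  }

  keys <- sort(names(emus))
  tab <- data.frame(
    key = keys,
    met = vapply(keys, function(k) emus[[k]]$met, character(1)),
    size = vapply(keys, function(k) emus[[k]]$size, integer(1)),
    input = vapply(keys, function(k) emus[[k]]$input, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  atoms <- lapply(keys, function(k) emus[[k]]$atoms)
  names(atoms) <- keys
  sys <- structure(list(net_id = net$id, emus = tab, atoms = atoms,
                        transitions = transitions,
                        sizes = sort(unique(tab$size[!tab$input])),
                        targets = targets),
                   class = "emu_system")
  sys$compiled <- compile_emu_system(net, sys)
  sys
}

# Precompile the EMU system into integer-indexed tables so that repeated
# simulation (the fitting hot path) avoids name lookups: per size, the
# local unknown indices, and per transition the flux index/direction,
# weight, and source composition (same-size unknown vs. known recipe).
compile_emu_system <- function(net, sys) {
  keys <- sys$emus$key
  key2idx <- setNames(seq_along(keys), keys)
  rxn_idx <- setNames(seq_along(net$reactions), names(net$reactions))
  tsize <- vapply(sys$transitions, function(t) length(sys$atoms[[t$to]]),
                  integer(1))
  per_size <- lapply(sys$sizes, function(sz) {
    unk <- which(!sys$emus$input & sys$emus$size == sz)
    loc <- integer(length(keys)); loc[unk] <- seq_along(unk)
    trans <- lapply(sys$transitions[tsize == sz], function(t) {
      to_g <- key2idx[[t$to]]
      src_g <- unname(key2idx[t$src])
      src_j <- if (length(src_g) == 1L && loc[src_g] > 0L) loc[src_g] else 0L
      list(i = loc[to_g], rxn = rxn_idx[[t$rxn]], dir = t$dir,
           w = t$weight, src_j = src_j, src = src_g)
    })
    list(size = sz, unk = unk, trans = trans)
  })
  inputs <- which(sys$emus$input)
  list(per_size = per_size, inputs = inputs,
       input_met = sys$emus$met[inputs],
       input_atoms = sys$atoms[inputs],
       n_emus = length(keys),
       target_idx = vapply(sys$targets, function(fs)
         key2idx[[emu_key(fs$metabolite, fs$carbons)]], integer(1)))
}

#' @export
print.emu_system <- function(x, ...) {
  cat("emu_system for '", x$net_id, "': ", nrow(x$emus), " EMUs (",
      sum(!x$emus$input), " unknown), ", length(x$transitions),
      " transitions, sizes ", paste(x$sizes, collapse = ","), "\n", sep = "")
  invisible(x)
}

# MID of an input (unbalanced substrate) EMU given active tracers:
# mixture of the pure label pattern (purity * fraction per tracer) with
# unlabeled substrate for the remainder.
input_emu_mid <- function(met, atoms, tracers) {
  k <- length(atoms)
  out <- numeric(k + 1L)
  p_rest <- 1
  for (tr in tracers) {
    if (tr$metabolite != met) next
    p <- tr$purity * tr$fraction
    nlab <- sum(atoms %in% tr$positions)
    out[nlab + 1L] <- out[nlab + 1L] + p
    p_rest <- p_rest - p
  }
  if (p_rest < -1e-9) stop("tracer mixture fractions for ", met, " exceed 1")
  out[1L] <- out[1L] + max(p_rest, 0)
  out
}
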