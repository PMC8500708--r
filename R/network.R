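#' @name network
#' @title Compartmentalized atom-transition networks
#'
#' @description
#' A `flux_network` bundles metabolites (with compartment and carbon count),
#' reactions carrying per-carbon atom maps, tracer definitions, and the
#' measured GC-MS fragments. Reactions may carry several atom-map variants
#' with weights; symmetric molecules (succinate, fumarate) are handled by
#' splitting each producing reaction into two half-weight variants with
#' mirrored maps. Reactions with an empty product side are drains (biomass,
#' lipid incorporation): they enter the stoichiometric balance but carry no
#' atom maps.
#'
#' Flux units throughout are nmol per 10^6 cells per hour.
NULL

#' Define a metabolite
#'
#' @param id metabolite id, unique within compartment (ids are written as
#'   `name.c` / `name.m` / `name.x` by convention but any string works).
#' @param compartment one of `"cytosol"`, `"mitochondrion"`,
#'   `"extracellular"`.
#' @param carbons number of backbone carbons (>= 0).
#' @param balanced logical; extracellular and sink species are unbalanced.
#' @return a one-row data.frame.
#' @export
metabolite <- function(id, compartment, carbons, balanced = TRUE) {
  compartment <- match.arg(compartment,
                           c("cytosol", "mitochondrion", "extracellular"))
  data.frame(id = id, compartment = compartment,
             n_carbons = as.integer(carbons), balanced = balanced,
             stringsAsFactors = FALSE)
}

#' Define a tracer
#'
#' @param metabolite id of the (extracellular) labeled substrate.
#' @param positions 1-based carbon indices carrying 13C.
#' @param purity isotopic purity of the labeled positions in `[0, 1]`.
#' @param fraction fraction of the substrate pool carrying the pattern.
#' @param id tracer name (e.g. `"cit24"`).
#' @return a `tracer` object.
#' @export
tracer <- function(metabolite, positions, purity = 1, fraction = 1,
                   id = paste0(metabolite, "_", paste(positions, collapse = ""))) {
  positions <- sort(as.integer(positions))
  if (purity < 0 || purity > 1 || fraction < 0 || fraction > 1)
    stop("tracer purity and mixture fraction must lie in [0, 1]")
  structure(list(id = id, metabolite = metabolite, positions = positions,
                 purity = purity, fraction = fraction), class = "tracer")
}

# ---- reaction equation parsing -------------------------------------------

# one side of an equation: "OAA.m (abcd) + 0.39 GAP" ->
# list of entries list(met, atoms (string or NA), coef)
parse_eq_side <- function(side) {
  side <- trimws(side)
  if (side == "") return(list())
  terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
  lapply(terms, function(tm) {
    tm <- trimws(tm)
    m <- regexec("^(?:([0-9.]+)\\s+)?([^ ()]+)\\s*(?:\\(([a-zA-Z]*)\\))?$", tm)
    g <- regmatches(tm, m)[[1]]
    if (length(g) == 0) stop("cannot parse reaction term: '", tm, "'")
    coef <- if (g[2] == "") 1 else as.numeric(g[2])
    atoms <- if (g[4] == "") NA_character_ else g[4]
    if (!is.na(atoms) && coef != 1)
      stop("atom-mapped species must have unit coefficient: '", tm, "'")
    list(met = g[3], atoms = atoms, coef = coef)
  })
}

parse_eq <- function(eq) {
  parts <- strsplit(eq, "\\s*->\\s*")[[1]]
  if (!grepl("->", eq) || length(parts) > 2)
    stop("reaction equation must contain exactly one '->': '", eq, "'")
  lhs <- parse_eq_side(parts[1])
  rhs <- if (length(parts) == 2) parse_eq_side(parts[2]) else list()
  if (length(lhs) == 0) stop("reaction has no substrates: '", eq, "'")
  list(substrates = lhs, products = rhs)
}

format_eq_side <- function(entries) {
  paste(vapply(entries, function(e) {
    coef <- if (e$coef != 1) paste0(format(e$coef), " ") else ""
    atoms <- if (!is.na(e$atoms)) paste0(" (", e$atoms, ")") else ""
    paste0(coef, e$met, atoms)
  }, character(1)), collapse = " + ")
}

format_eq <- function(variant) {
  paste0(format_eq_side(variant$substrates), " -> ",
         format_eq_side(variant$products))
}

#' Define a reaction from equation strings
#'
#' @param id reaction id.
#' @param eq equation string, e.g.
#'   `"OAA.m (abcd) + AcCoA.m (ef) -> Cit.m (efabcd)"`. Atom strings use
#'   one lowercase letter per carbon; the multiset of letters must match
#'   across sides. A character vector gives several atom-map variants of
#'   the same reaction (used for symmetric-molecule scrambling); `weights`
#'   then gives their relative weights. An empty right-hand side
#'   (`"A (ab) -> "` or coefficients without atom maps) defines a drain.
#' @param reversible logical.
#' @param bounds length-2 numeric `(lower, upper)` on the net flux.
#' @param weights variant weights, normalized to sum 1.
#' @return a `reaction` object.
#' @export
reaction <- function(id, eq, reversible = FALSE,
                     bounds = if (reversible) c(-1000, 1000) else c(0, 1000),
                     weights = rep(1, length(eq))) {
  if (length(weights) != length(eq) || any(weights <= 0))
    stop("weights must be positive, one per equation variant")
  variants <- lapply(seq_along(eq), function(i) {
    v <- parse_eq(eq[[i]])
    v$weight <- weights[i] / sum(weights)
    v
  })
  # all variants must share stoichiometry
  sig <- function(v) {
    s <- function(es) paste(sort(vapply(es, function(e)
      paste0(e$met, ":", e$coef), character(1))), collapse = ",")
    paste(s(v$substrates), "->", s(v$products))
  }
  if (length(unique(vapply(variants, sig, character(1)))) != 1L)
    stop("reaction ", id, ": atom-map variants differ in stoichiometry")
  structure(list(id = id, reversible = reversible,
                 lb = bounds[1], ub = bounds[2], variants = variants),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  cat(x$id, ":", format_eq(x$variants[[1]]),
      if (x$reversible) "(reversible)" else "",
      sprintf("[%g, %g]", x$lb, x$ub), "\n")
  if (length(x$variants) > 1)
    for (v in x$variants[-1])
      cat("  variant:", format_eq(v), sprintf("w=%.3g", v$weight), "\n")
  invisible(x)
}

#' Assemble a flux network
#'
#' @param metabolites data.frame from rbinding [metabolite()] rows.
#' @param reactions list of [reaction()] objects.
#' @param tracers list of [tracer()] objects.
#' @param fragments list of [fragment_spec()] objects (measured fragments).
#' @param id model name.
#' @return a `flux_network`.
#' @export
flux_network <- function(metabolites, reactions, tracers = list(),
                         fragments = list(), id = "model") {
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "))
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(reactions) <- rids
  net <- structure(list(id = id, metabolites = metabolites,
                        reactions = reactions, tracers = tracers,
                        fragments = fragments),
                   class = "flux_network")
  net
}

#' @export
print.flux_network <- function(x, ...) {
  cat("flux_network '", x$id, "': ", nrow(x$metabolites), " metabolites (",
      sum(x$metabolites$balanced), " balanced), ", length(x$reactions),
      " reactions, ", length(x$tracers), " tracers, ", length(x$fragments),
      " measured fragments\n", sep = "")
  invisible(x)
}

met_row <- function(net, id) {
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop("unknown metabolite: ", id)
  net$metabolites[i, ]
}

met_carbons <- function(net, id) met_row(net, id)$n_carbons

is_balanced <- function(net, id) met_row(net, id)$balanced

#' Validate a network
#'
#' Checks, per reaction, conservation of carbon atoms as a multiset of map
#' letters (each letter exactly once per side, atom-string length equal to
#' the metabolite's carbon count); and, per balanced metabolite, that it is
#' both produced and consumed by at least one reaction (reversible
#' reactions count for both sides). Fragment and tracer references are also
#' checked.
#'
#' @param net a `flux_network`.
#' @return a list with `ok` (logical), `reaction_status` (data.frame),
#'   `metabolite_status` (data.frame), and `violations` (character).
#' @export
validate_network <- function(net) {
  violations <- character()
  # reaction atom balance
  rstat <- lapply(net$reactions, function(rx) {
    msgs <- character()
    for (v in rx$variants) {
      for (e in c(v$substrates, v$products)) {
        if (is.na(match(e$met, net$metabolites$id))) {
          msgs <- c(msgs, paste0("unknown metabolite ", e$met))
          next
        }
        if (!is.na(e$atoms) &&
            nchar(e$atoms) != met_carbons(net, e$met))
          msgs <- c(msgs, paste0("atom string '", e$atoms, "' length != ",
                                 met_carbons(net, e$met), " carbons of ",
                                 e$met))
      }
      if (length(v$products) > 0) {
        sub_atoms <- unlist(strsplit(na.omit(vapply(
          v$substrates, `[[`, character(1), "atoms")), ""))
        prod_atoms <- unlist(strsplit(na.omit(vapply(
          v$products, `[[`, character(1), "atoms")), ""))
        if (anyDuplicated(sub_atoms) || anyDuplicated(prod_atoms))
          msgs <- c(msgs, "atom letter repeated within one side")
        if (!identical(sort(sub_atoms), sort(prod_atoms)))
          msgs <- c(msgs, "carbon atoms not conserved (letter multisets differ)")
      }
    }
    msgs
  })
  for (rid in names(rstat))
    if (length(rstat[[rid]]))
      violations <- c(violations, paste0("reaction ", rid, ": ", rstat[[rid]]))

  # producer/consumer closure for balanced metabolites
  bal <- net$metabolites$id[net$metabolites$balanced]
  produced <- consumed <- setNames(logical(length(bal)), bal)
  for (rx in net$reactions) {
    v <- rx$variants[[1]]
    subs <- vapply(v$substrates, `[[`, character(1), "met")
    prods <- vapply(v$products, `[[`, character(1), "met")
    consumed[subs[subs %in% bal]] <- TRUE
    produced[prods[prods %in% bal]] <- TRUE
    if (rx$reversible) {
      produced[subs[subs %in% bal]] <- TRUE
      consumed[prods[prods %in% bal]] <- TRUE
    }
  }
  for (m in bal) {
    if (!produced[m]) violations <- c(violations,
                                      paste0("metabolite ", m, ": no producer"))
    if (!consumed[m]) violations <- c(violations,
                                      paste0("metabolite ", m, ": no consumer"))
  }

  # fragment and tracer references
  for (fs in net$fragments) {
    nc <- tryCatch(met_carbons(net, fs$metabolite), error = function(e) NA)
    if (is.na(nc))
      violations <- c(violations, paste0("fragment ", fs$label,
                                         ": unknown metabolite ", fs$metabolite))
    else if (any(fs$carbons > nc))
      violations <- c(violations, paste0("fragment ", fs$label,
                                         ": carbon index out of range"))
  }
  for (tr in net$tracers) {
    nc <- tryCatch(met_carbons(net, tr$metabolite), error = function(e) NA)
    if (is.na(nc) || any(tr$positions > nc))
      violations <- c(violations, paste0("tracer ", tr$id,
                                         ": bad metabolite or positions"))
  }

  list(ok = length(violations) == 0L,
       reaction_status = data.frame(
         reaction = names(net$reactions),
         atom_balance = vapply(rstat, function(m) length(m) == 0L, logical(1)),
         row.names = NULL),
       metabolite_status = data.frame(
         metabolite = bal, produced = as.logical(produced),
         consumed = as.logical(consumed), row.names = NULL),
       violations = violations)
}

#' Stoichiometric matrix over balanced metabolites
#'
#' @param net a `flux_network`.
#' @return matrix with one row per balanced metabolite and one column per
#'   reaction; entries are net stoichiometric coefficients for the
#'   reaction's forward direction.
#' @export
stoich_matrix <- function(net) {
  bal <- net$metabolites$id[net$metabolites$balanced]
  S <- matrix(0, length(bal), length(net$reactions),
              dimnames = list(bal, names(net$reactions)))
  for (j in seq_along(net$reactions)) {
    v <- net$reactions[[j]]$variants[[1]]
    for (e in v$substrates)
      if (e$met %in% bal) S[e$met, j] <- S[e$met, j] - e$coef
    for (e in v$products)
      if (e$met %in% bal) S[e$met, j] <- S[e$met, j] + e$coef
  }
  S
}

#' Extract a subnetwork
#'
#' Keeps the named reactions and their metabolites; metabolites listed in
#' `unbalance` (plus metabolites that lose all producers or consumers) are
#' marked unbalanced, turning them into sources/sinks. Useful for isolating
#' a single catabolic route of the full model.
#'
#' @param net a `flux_network`.
#' @param reactions character vector of reaction ids to keep.
#' @param unbalance metabolite ids to force unbalanced.
#' @param drains metabolite ids to terminate with an added drain reaction
#'   (`out_<met>`), keeping them balanced so their labeling is simulated.
#' @param tracers,fragments replacements for the parent network's lists
#'   (defaults keep entries still referenced).
#' @return a `flux_network`.
#' @export
subnetwork <- function(net, reactions, unbalance = character(),
                       drains = character(), tracers = NULL,
                       fragments = NULL) {
  keep <- net$reactions[reactions]
  for (m in drains)
    keep[[paste0("out_", m)]] <- reaction(paste0("out_", m),
                                          paste(m, "-> "), bounds = c(0, 1e4))
  mets <- unique(unlist(lapply(keep, function(rx)
    vapply(c(rx$variants[[1]]$substrates, rx$variants[[1]]$products),
           `[[`, character(1), "met"))))
  mtab <- net$metabolites[net$metabolites$id %in% mets, , drop = FALSE]
  mtab$balanced <- mtab$balanced & !(mtab$id %in% unbalance)
  sub <- flux_network(mtab, keep,
                      tracers = if (is.null(tracers))
                        Filter(function(tr) tr$metabolite %in% mets, net$tracers)
                      else tracers,
                      fragments = if (is.null(fragments))
                        Filter(function(fs) fs$metabolite %in% mets, net$fragments)
                      else fragments,
                      id = paste0(net$id, "_sub"))
  # auto-unbalance species that lost closure
  vr <- validate_network(sub)
  bad <- vr$metabolite_status$metabolite[!(vr$metabolite_status$produced &
                                             vr$metabolite_status$consumed)]
  if (length(bad)) {
    sub$metabolites$balanced[sub$metabolites$id %in% bad] <- FALSE
  }
  sub
}
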