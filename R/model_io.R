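#' Serialize a network to model-file text
#'
#' The model file is a YAML document with four blocks in stable order:
#' `model`, `metabolites`, `reactions`, `tracers`, `fragments`. Each
#' reaction is one mapping with keys `id`, `eq` (string or list of variant
#' strings), `weights` (when several variants), `reversible`, `bounds`.
#' [parse_model()] is the exact inverse.
#'
#' @param net a `flux_network`.
#' @return a single character string of YAML.
#' @export
serialize_model <- function(net) {
  doc <- list(
    model = net$id,
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i) {
      m <- net$metabolites[i, ]
      list(id = m$id, compartment = m$compartment,
           carbons = m$n_carbons, balanced = m$balanced)
    }),
    reactions = lapply(net$reactions, function(rx) {
      eqs <- vapply(rx$variants, format_eq, character(1))
      out <- list(id = rx$id,
                  eq = if (length(eqs) == 1L) eqs else as.list(eqs))
      if (length(eqs) > 1L)
        out$weights <- lapply(rx$variants, `[[`, "weight")
      out$reversible <- rx$reversible
      out$bounds <- c(rx$lb, rx$ub)
      out
    }),
    tracers = lapply(net$tracers, function(tr)
      list(id = tr$id, metabolite = tr$metabolite,
           positions = as.list(tr$positions),
           purity = tr$purity, fraction = tr$fraction)),
    fragments = lapply(net$fragments, function(fs)
      list(label = fs$label, metabolite = fs$metabolite,
           carbons = as.list(fs$carbons), formula = fs$formula))
  )
  names(doc$reactions) <- NULL
  yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop("model file: missing field '", field, "' in ", where, call. = FALSE)
  x[[field]]
}

#' Parse a model file
#'
#' Reads the YAML model dialect written by [serialize_model()]. Schema
#' violations raise errors naming the offending block and field; duplicate
#' ids raise conflict errors; atom-map inconsistencies (carbon conservation,
#' string lengths) are caught by [validate_network()] and raised here.
#'
#' @param text model text (single string), or `NULL` to read from `file`.
#' @param file path to a model file.
#' @return a validated `flux_network`.
#' @export
parse_model <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("give either text or file")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  doc <- yaml::yaml.load(text)
  for (blk in c("metabolites", "reactions"))
    if (is.null(doc[[blk]]))
      stop("model file: missing block '", blk, "'", call. = FALSE)

  mets <- do.call(rbind, lapply(seq_along(doc$metabolites), function(i) {
    m <- doc$metabolites[[i]]
    where <- paste0("metabolites[", i, "]")
    metabolite(need_field(m, "id", where),
               need_field(m, "compartment", where),
               need_field(m, "carbons", where),
               if (is.null(m$balanced)) TRUE else m$balanced)
  }))

  rxns <- lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    where <- paste0("reactions[", i, "]")
    eqs <- unlist(need_field(r, "eq", where))
    rev <- if (is.null(r$reversible)) FALSE else r$reversible
    bounds <- if (is.null(r$bounds)) {
      if (rev) c(-1000, 1000) else c(0, 1000)
    } else unlist(r$bounds)
    w <- if (is.null(r$weights)) rep(1, length(eqs)) else unlist(r$weights)
    reaction(need_field(r, "id", where), eqs, reversible = rev,
             bounds = bounds, weights = w)
  })

  tracers <- lapply(doc$tracers, function(t)
    tracer(need_field(t, "metabolite", "tracers"),
           unlist(need_field(t, "positions", "tracers")),
           purity = if (is.null(t$purity)) 1 else t$purity,
           fraction = if (is.null(t$fraction)) 1 else t$fraction,
           id = need_field(t, "id", "tracers")))

  frags <- lapply(doc$fragments, function(f)
    fragment_spec(need_field(f, "metabolite", "fragments"),
                  unlist(need_field(f, "carbons", "fragments")),
                  need_field(f, "formula", "fragments"),
                  label = need_field(f, "label", "fragments")))

  net <- flux_network(mets, rxns, tracers = tracers, fragments = frags,
                      id = if (is.null(doc$model)) "model" else doc$model)
  vr <- validate_network(net)
  if (!vr$ok)
    stop("model file failed validation:\n  ",
         paste(vr$violations, collapse = "\n  "), call. = FALSE)
  net
}
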