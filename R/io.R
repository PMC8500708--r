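#' Write measurement sets to a delimited MID table
#'
#' Flat CSV with columns `tracer_id`, `fragment`, `M0..Mk`,
#' `sd_M0..sd_Mk`; fragments with fewer isotopomers leave trailing
#' columns empty.
#'
#' @param data list of [measurement_set] objects.
#' @param file output path.
#' @export
write_mid_table <- function(data, file) {
  kmax <- max(unlist(lapply(data, function(ms)
    vapply(ms$mids, function(m) length(m$values), integer(1))))) - 1L
  rows <- list()
  for (ms in data) {
    for (lab in names(ms$mids)) {
      m <- ms$mids[[lab]]
      v <- s <- rep(NA_real_, kmax + 1L)
      v[seq_along(m$values)] <- m$values
      s[seq_along(m$sd)] <- m$sd
      rows[[length(rows) + 1L]] <- data.frame(
        tracer_id = ms$tracer, fragment = lab,
        as.list(setNames(v, paste0("M", 0:kmax))),
        as.list(setNames(s, paste0("sd_M", 0:kmax))),
        stringsAsFactors = FALSE)
    }
  }
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
}

#' Read measurement sets from a delimited MID table
#'
#' Inverse of [write_mid_table()]; one [measurement_set] per `tracer_id`.
#'
#' @param file path to the CSV.
#' @param fluxes optional data.frame (`reaction`, `value`, `sd`) attached
#'   to the first tracer's measurement set.
#' @param sd_floor SD floor passed to [measurement_set()].
#' @return list of [measurement_set] objects.
#' @export
read_mid_table <- function(file, fluxes = NULL, sd_floor = 0.003) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  vcols <- grep("^M[0-9]+$", names(tab), value = TRUE)
  scols <- grep("^sd_M[0-9]+$", names(tab), value = TRUE)
  out <- list()
  for (trid in unique(tab$tracer_id)) {
    sub <- tab[tab$tracer_id == trid, , drop = FALSE]
    mids <- list()
    for (i in seq_len(nrow(sub))) {
      v <- as.numeric(sub[i, vcols]); s <- as.numeric(sub[i, scols])
      keep <- !is.na(v)
      mids[[sub$fragment[i]]] <- list(values = v[keep], sd = s[keep])
    }
    out[[trid]] <- measurement_set(
      trid, mids,
      fluxes = if (length(out) == 0) fluxes else NULL,
      sd_floor = sd_floor)
  }
  out
}

#' Write a flux vector to CSV
#'
#' Columns `reaction`, `net`, `exchange` in network order.
#'
#' @param v a `flux_vector`.
#' @param file output path.
#' @export
write_flux_table <- function(v, file) {
  write.csv(as.data.frame(v), file, row.names = FALSE)
}

#' Read a flux vector from CSV
#'
#' @param net the `flux_network` the fluxes belong to.
#' @param file path to a CSV with columns `reaction`, `net`, `exchange`.
#' @param check validate steady state and bounds.
#' @return a `flux_vector`.
#' @export
read_flux_table <- function(net, file, check = TRUE) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction", "net") %in% names(tab)))
  ex <- if ("exchange" %in% names(tab))
    setNames(tab$exchange, tab$reaction) else numeric()
  flux_vector(net, setNames(tab$net, tab$reaction), exchange = ex,
              check = check)
}
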