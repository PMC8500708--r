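#' Define a measured GC-MS fragment
#'
#' A fragment spec ties a measured ion to the metabolite backbone carbons it
#' covers and to the full elemental formula of the derivatized ion, which
#' drives natural-abundance correction (all atoms other than the tracer-
#' labeled backbone carbons contribute naturally occurring heavy isotopes:
#' Si and C of the TBDMS groups, O, N, H, S).
#'
#' @param metabolite metabolite id (e.g. `"Mal.m"`).
#' @param carbons integer vector of 1-based backbone carbon indices covered
#'   by the fragment.
#' @param formula elemental formula of the derivatized ion, e.g.
#'   `"C18H39O5Si3"`.
#' @param label short fragment name used in measurement tables; defaults to
#'   the metabolite id.
#' @return an object of class `"fragment_spec"`.
#' @export
fragment_spec <- function(metabolite, carbons, formula, label = metabolite) {
  carbons <- as.integer(carbons)
  if (length(carbons) < 1L || any(carbons < 1L) || anyDuplicated(carbons))
    stop("fragment carbons must be distinct positive indices")
  counts <- parse_formula(formula)
  nC <- counts["C"]
  if (is.na(nC) || nC < length(carbons))
    stop("formula ", formula, " has fewer carbons than the fragment backbone")
  structure(list(metabolite = metabolite, carbons = sort(carbons),
                 formula = formula, label = label),
            class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat("Fragment", x$label, "on", x$metabolite, "carbons",
      paste(x$carbons, collapse = ","), "formula", x$formula, "\n")
  invisible(x)
}

# "C18H39O5Si3" -> c(C = 18, H = 39, O = 5, Si = 3)
parse_formula <- function(formula) {
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
    stop("cannot parse elemental formula: ", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]+$", "", parts)
  ct <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", parts)))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

#' Natural isotope abundances
#'
#' Standard terrestrial abundances of the heavy isotopes used in
#' natural-abundance correction, expressed per atom as the probability of
#' each positive mass shift. Override entries to model non-standard
#' abundances (setting all to zero yields an identity correction).
#'
#' @return named list; each element is a numeric vector of probabilities
#'   for mass shifts `+1, +2, ...` (the remainder is the monoisotopic
#'   probability).
#' @export
default_isotope_table <- function() {
  list(
    C  = c(0.0107),            # 13C
    H  = c(0.000115),          # 2H
    N  = c(0.00364),           # 15N
    O  = c(0.00038, 0.00205),  # 17O, 18O
    Si = c(0.04685, 0.03092),  # 29Si, 30Si
    S  = c(0.0076, 0.0429)     # 33S, 34S
  )
}

# mass-shift distribution of a single atom of element `el`
atom_shift_dist <- function(el, isotopes, max_shift) {
  p <- isotopes[[el]]
  if (is.null(p)) stop("no isotope abundances for element: ", el)
  d <- c(1 - sum(p), p)
  length(d) <- max_shift + 1L
  d[is.na(d)] <- 0
  d
}

#' Natural-abundance correction matrix for a fragment
#'
#' Column `j` (0-based isotopomer index) is the predicted measured MID of a
#' species carrying exactly `j` tracer-labeled backbone carbons, accounting
#' for natural heavy-isotope abundance of every other atom in the
#' derivatized ion: the remaining `n - j` backbone carbons, non-backbone
#' carbons (derivatization groups), and all H, N, O, Si, S atoms. The matrix
#' is lower-triangular (natural abundance can only add mass).
#'
#' @param spec a [fragment_spec].
#' @param isotopes isotope table as from [default_isotope_table()].
#' @return `(n+1) x (n+1)` matrix, `n` = number of backbone carbons.
#' @export
correction_matrix <- function(spec, isotopes = default_isotope_table()) {
  counts <- parse_formula(spec$formula)
  n <- length(spec$carbons)
  size <- n + 1L
  # per-atom shift distributions truncated to the measurement window
  els <- names(counts)
  M <- matrix(0, size, size)
  for (j in 0:n) {
    # non-tracer atoms: all elements as in formula, minus j labeled backbone C
    dist <- 1
    for (el in els) {
      k <- counts[[el]]
      if (el == "C") k <- k - j
      if (k > 0) {
        d1 <- atom_shift_dist(el, isotopes, n)
        for (i in seq_len(k)) {
          dist <- conv_vec(dist, d1)
          if (length(dist) > size) dist <- dist[seq_len(size)]
        }
      }
    }
    length(dist) <- size
    dist[is.na(dist)] <- 0
    col <- numeric(size)
    if (j > 0) col[seq_len(size - j) + j] <- dist[seq_len(size - j)]
    else col <- dist
    M[, j + 1L] <- col
  }
  M
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves `correction_matrix %*% x = raw` for the tracer-only MID `x` by
#' non-negative least squares and renormalizes to unit sum. NNLS keeps the
#' solution a valid distribution even when the measurement window truncates
#' the heavy tail.
#'
#' @param raw measured MID (fractions `M0..Mn` over backbone carbons).
#' @param spec a [fragment_spec].
#' @param isotopes isotope table, see [default_isotope_table()].
#' @return corrected [mid].
#' @export
correct_na <- function(raw, spec, isotopes = default_isotope_table()) {
  raw <- as.numeric(as_mid(raw))
  M <- correction_matrix(spec, isotopes)
  if (length(raw) != nrow(M))
    stop("raw MID length ", length(raw), " does not match fragment backbone (",
         nrow(M), " entries expected)")
  cn <- kappa(M, exact = TRUE)
  if (!is.finite(cn) || cn > 1e10)
    stop("correction matrix is numerically singular (condition number ",
         format(cn, digits = 3), ")")
  x <- pracma::lsqnonneg(M, raw)$x
  if (sum(x) <= 0) stop("natural-abundance correction produced an empty MID")
  mid(x, id = spec$label)
}

#' Apply natural-abundance contamination to a clean MID
#'
#' Forward operation of [correct_na]: predicts the measured distribution of
#' a tracer-only MID given the fragment's full formula. Mainly used to
#' emulate raw GC-MS data and to verify the correction round trip.
#'
#' @inheritParams correct_na
#' @param clean tracer-only MID.
#' @return contaminated [mid] (renormalized over the `M0..Mn` window).
#' @export
add_na <- function(clean, spec, isotopes = default_isotope_table()) {
  clean <- as.numeric(as_mid(clean))
  M <- correction_matrix(spec, isotopes)
  mid(as.numeric(M %*% clean), id = spec$label)
}
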