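#' Construct a mass isotopomer distribution (MID)
#'
#' An MID is the vector of fractional abundances `M0..Mn` of a metabolite
#' fragment, where `Mi` is the fraction of molecules carrying exactly `i`
#' heavy (13C) atoms on the fragment's carbon backbone. Fractions must be
#' non-negative and are normalized to sum to one.
#'
#' @param fractions numeric vector of length `n + 1` (abundances `M0..Mn`).
#' @param n number of backbone carbons; defaults to `length(fractions) - 1`.
#' @param id optional fragment/metabolite label.
#' @param normalize if `TRUE` (default) rescale to unit sum.
#' @return an object of class `"mid"`: numeric vector with attributes `n`
#'   and `id`.
#' @examples
#' mid(c(0, 0, 1, 0, 0, 0, 0))   # pure M2 citrate (6 carbons)
#' @export
mid <- function(fractions, n = length(fractions) - 1L, id = NULL,
                normalize = TRUE) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != n + 1L)
    stop("MID for ", n, " carbons must have ", n + 1L, " entries, got ",
         length(fractions))
  if (any(!is.finite(fractions)) || any(fractions < -1e-12))
    stop("MID fractions must be finite and non-negative")
  fractions[fractions < 0] <- 0
  s <- sum(fractions)
  if (normalize) {
    if (s <= 0) stop("MID fractions sum to zero; cannot normalize")
    fractions <- fractions / s
  } else if (abs(s - 1) > 1e-9) {
    stop("MID fractions must sum to 1 (got ", format(s), ")")
  }
  structure(fractions, n = as.integer(n), id = id, class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat("MID", if (!is.null(attr(x, "id"))) paste0("[", attr(x, "id"), "]"),
      "n =", attr(x, "n"), "\n")
  v <- as.numeric(x)
  names(v) <- paste0("M", seq_along(v) - 1L)
  print(round(v, 6))
  invisible(x)
}

is_mid_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= -1e-12) &&
    abs(sum(x) - 1) <= 1e-9
}

as_mid <- function(x, id = NULL) {
  if (inherits(x, "mid")) return(x)
  mid(x, id = id)
}

#' Mole percent enrichment of an MID
#'
#' MPE is the fraction of all carbon atoms in the metabolite pool that carry
#' label: `sum(i * Mi) / n`, with `n` the number of backbone carbons and
#' `Mi` the relative abundance of the `i`-th mass isotopomer. A pure
#' \[2,4-13C2\]citrate pool (all abundance at M2 of 6 carbons) has
#' MPE 1/3; a pure \[U-13C6\]glucose pool has MPE 1.
#'
#' @param x an [mid] or numeric vector of fractions `M0..Mn`.
#' @return enrichment as a fraction in `[0, 1]`.
#' @examples
#' mpe(mid(c(0, 0, 1, 0, 0, 0, 0)))  # 0.3333...
#' @export
mpe <- function(x) {
  x <- as_mid(x)
  n <- attr(x, "n")
  if (n == 0L) stop("MPE is undefined for a zero-carbon fragment")
  sum(seq(0L, n) * as.numeric(x)) / n
}

#' Convolve two MIDs
#'
#' The MID of a molecule formed by condensing two independent fragments is
#' the convolution of their MIDs: the distribution of the sum of the two
#' label counts. Used for polymer condensation (fatty-acid synthesis) and
#' for assembling EMU products from independent substrate units.
#'
#' @param a,b MIDs (or plain fraction vectors).
#' @return an [mid] of length `length(a) + length(b) - 1`.
#' @export
convolve_mid <- function(a, b) {
  a <- as.numeric(as_mid(a)); b <- as.numeric(as_mid(b))
  out <- conv_vec(a, b)
  mid(out, normalize = TRUE)
}

# plain numeric convolution, no class bookkeeping (hot path)
conv_vec <- function(a, b) {
  na <- length(a); nb <- length(b)
  out <- numeric(na + nb - 1L)
  for (i in seq_len(na)) {
    if (a[i] != 0) {
      idx <- i:(i + nb - 1L)
      out[idx] <- out[idx] + a[i] * b
    }
  }
  out
}

# k-fold self convolution
conv_pow <- function(a, k) {
  out <- 1
  for (i in seq_len(k)) out <- conv_vec(out, a)
  out
}

#' M1/M2 diagnostic ratio
#'
#' Ratio of the M1 to the M2 relative abundance of a fragment. Under a
#' \[2,4-13C2\]citrate trace, cytosolic ACLY-mediated catabolism produces M1
#' TCA intermediates (the two labels are split between acetyl-CoA and
#' oxaloacetate), whereas direct mitochondrial import retains both labels
#' and produces M2 intermediates — so this ratio discriminates the two
#' routes.
#'
#' @param x an [mid] with at least three entries.
#' @return a list with `ratio` (numeric; `Inf` when M2 = 0 and M1 > 0, `NaN`
#'   when both are 0) and `status` (`"ok"`, `"infinite"` or `"undefined"`).
#' @export
m1_m2_ratio <- function(x) {
  x <- as_mid(x)
  v <- as.numeric(x)
  if (length(v) < 3L) stop("M1/M2 ratio needs an MID with at least M0..M2")
  m1 <- v[2]; m2 <- v[3]
  if (m2 > 0)       list(ratio = m1 / m2, status = "ok")
  else if (m1 > 0)  list(ratio = Inf,     status = "infinite")
  else              list(ratio = NaN,     status = "undefined")
}
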