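#' Donor-acceptor labeling pair
#'
#' A `forster_pair` bundles the photophysical constants of one tmFRET
#' donor-acceptor pair: the Forster radius \eqn{R_0} (the separation at which
#' energy transfer is 50\%) and the unquenched donor-only fluorescence
#' lifetime \eqn{\tau_D}. Both are treated as fixed experimental inputs and
#' are never fitted.
#'
#' @param donor donor fluorophore name (e.g. `"Acd"`).
#' @param acceptor acceptor complex name.
#' @param R0 Forster radius in Angstrom; must be positive.
#' @param tau_donor donor-only lifetime in nanoseconds; must be positive.
#' @param buffer optional buffer label when the donor lifetime is
#'   buffer-specific.
#' @return An object of class `forster_pair`.
#' @examples
#' fe <- forster_pair("Acd", "Fe(phenM)3", R0 = 41.8, tau_donor = 17.2)
#' efficiency_from_distance(41.8, fe$R0)
#' @export
forster_pair <- function(donor, acceptor, R0, tau_donor, buffer = NA_character_) {
  stopifnot(is.character(donor), is.character(acceptor))
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 <= 0)
    stop("'R0' must be a single positive number (Angstrom)")
  if (!is.numeric(tau_donor) || length(tau_donor) != 1L ||
      !is.finite(tau_donor) || tau_donor <= 0)
    stop("'tau_donor' must be a single positive number (ns)")
  structure(list(donor = donor, acceptor = acceptor, R0 = R0,
                 tau_donor = tau_donor, buffer = buffer),
            class = "forster_pair")
}

#' @export
print.forster_pair <- function(x, ...) {
  cat(sprintf("<forster_pair> %s -> %s: R0 = %.1f A, tau_D = %.2f ns\n",
              x$donor, x$acceptor, x$R0, x$tau_donor))
  invisible(x)
}

#' Registry of the acceptor complexes used with the Acd donor
#'
#' Default registry of named pairs: the two long-range acceptors used for
#' lifetime work, `"Fe(phenM)3"` (R0 = 41.8 A) and `"Ru(bpy)2phenM"`
#' (R0 = 43.5 A), and the short-range `"Cu(TETAC)"` (R0 = 15.6 A) which is
#' registered for steady-state use only. All share the Acd donor lifetime of
#' 17.2 ns. Per-buffer donor lifetimes can be registered by passing
#' additional `forster_pair` objects.
#'
#' @param tau_donor donor-only lifetime (ns) applied to every default entry.
#' @param extra optional named list of additional `forster_pair` objects.
#' @return Named list of `forster_pair` objects.
#' @export
default_pairs <- function(tau_donor = 17.2, extra = NULL) {
  pairs <- list(
    "Fe(phenM)3"   = forster_pair("Acd", "Fe(phenM)3",   41.8, tau_donor),
    "Ru(bpy)2phenM" = forster_pair("Acd", "Ru(bpy)2phenM", 43.5, tau_donor),
    "Cu(TETAC)"    = forster_pair("Acd", "Cu(TETAC)",    15.6, tau_donor)
  )
  if (!is.null(extra)) pairs[names(extra)] <- extra
  pairs
}

#' Look up a pair by acceptor name
#'
#' @param name acceptor name as registered.
#' @param pairs registry, see [default_pairs()].
#' @return A `forster_pair`.
#' @export
get_pair <- function(name, pairs = default_pairs()) {
  if (!name %in% names(pairs))
    stop(sprintf("acceptor '%s' not found in pair registry (known: %s)",
                 name, paste(names(pairs), collapse = ", ")))
  pairs[[name]]
}

#' FRET efficiency at a donor-acceptor distance
#'
#' The Forster equation \eqn{E(r) = 1 / (1 + (r/R_0)^6)}: efficiency is 1/2
#' at \eqn{r = R_0} and falls off with the sixth power of distance.
#'
#' @param r donor-acceptor distance(s) in Angstrom, positive.
#' @param R0 Forster radius in Angstrom, positive.
#' @return Efficiency in (0, 1), vectorized over `r`.
#' @export
efficiency_from_distance <- function(r, R0) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("'r' must be positive and finite (Angstrom)")
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 <= 0)
    stop("'R0' must be a single positive number (Angstrom)")
  1 / (1 + (r / R0)^6)
}

#' Distance from FRET efficiency
#'
#' Exact inverse of [efficiency_from_distance()]:
#' \eqn{r = R_0 ((1 - E)/E)^{1/6}}.
#'
#' @param E efficiency strictly inside (0, 1).
#' @param R0 Forster radius in Angstrom.
#' @return Distance(s) in Angstrom.
#' @export
distance_from_efficiency <- function(E, R0) {
  if (!is.numeric(E) || any(!is.finite(E)) || any(E <= 0) || any(E >= 1))
    stop("'E' must lie strictly inside (0, 1)")
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 <= 0)
    stop("'R0' must be a single positive number (Angstrom)")
  R0 * ((1 - E) / E)^(1 / 6)
}

#' Quenched donor lifetime at a given distance
#'
#' FRET shortens the donor lifetime in proportion to the transfer
#' efficiency: \eqn{\tau_{DA}(r) = \tau_D (1 - E(r))}.
#'
#' @param r donor-acceptor distance(s), Angstrom.
#' @param pair a [forster_pair()].
#' @return Lifetime(s) in ns, strictly between 0 and `pair$tau_donor`.
#' @export
fret_lifetime <- function(r, pair) {
  stopifnot(inherits(pair, "forster_pair"))
  pair$tau_donor * (1 - efficiency_from_distance(r, pair$R0))
}
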