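# Exact-mass chemistry for PFAS quantitation: molecular formulas, ion m/z,
# isotope envelopes, and ppm arithmetic.

# Monoisotopic atomic masses (IUPAC/CIAAW snapshot, packaged -- never fetched).
.MONO_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.9984031627,
  Na = 22.9897692820,
  P  = 30.9737619984,
  S  = 31.9720711744,
  Cl = 34.9688526820,
  K  = 38.9637064864
)

.MASS_13C <- 13.0033548378
.MASS_2H  <- 2.0141017781

# Natural isotope tables: mass (Da) and fractional abundance per element.
.ISOTOPES <- list(
  H  = list(mass = c(1.00782503207, 2.0141017781), abund = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.0033548378), abund = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740048, 15.0001088989), abund = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317565, 17.9991596129),
            abund = c(0.99757, 0.00038, 0.00205)),
  F  = list(mass = 18.9984031627, abund = 1),
  Na = list(mass = 22.9897692820, abund = 1),
  P  = list(mass = 30.9737619984, abund = 1),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.9678670040, 35.9670807100),
            abund = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = list(mass = c(34.9688526820, 36.9659026020), abund = c(0.7576, 0.2424)),
  K  = list(mass = c(38.9637064864, 39.9639981660, 40.9618252579),
            abund = c(0.932581, 0.000117, 0.067302))
)

#' Element counts of a molecular formula
#'
#' Container for a molecular formula as a map of element symbol to atom count,
#' with optional stable-isotope label counts for internal standards. Labels
#' are carried separately from the formula (the registry stores them in
#' dedicated `n13C` / `n2H` columns, never embedded in the formula string):
#' a label count of `n` means `n` of the corresponding light atoms are
#' replaced by the heavy isotope (13C or deuterium).
#'
#' @param counts named numeric vector of non-negative integer atom counts;
#'   names are element symbols from the packaged atomic-mass table.
#' @param n13C number of carbon positions labeled as 13C.
#' @param n2H number of hydrogen positions labeled as deuterium.
#' @return an object of class `element_counts`.
#' @examples
#' element_counts(c(C = 8, H = 5, F = 13, O = 3, S = 1))
#' @export
element_counts <- function(counts, n13C = 0L, n2H = 0L) {
  if (length(counts) == 0L || is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be a named vector of element counts", call. = FALSE)
  unknown <- setdiff(names(counts), names(.MONO_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  counts <- counts[counts != 0]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers", call. = FALSE)
  if (length(counts) == 0L)
    stop("formula must contain at least one atom", call. = FALSE)
  n13C <- as.integer(n13C); n2H <- as.integer(n2H)
  if (n13C < 0L || n2H < 0L)
    stop("label counts must be non-negative", call. = FALSE)
  if (n13C > .count_of(counts, "C"))
    stop("13C label count exceeds carbon count", call. = FALSE)
  if (n2H > .count_of(counts, "H"))
    stop("2H label count exceeds hydrogen count", call. = FALSE)
  structure(list(counts = counts[order(names(counts))], n13C = n13C, n2H = n2H),
            class = "element_counts")
}

.count_of <- function(counts, sym) if (sym %in% names(counts)) unname(counts[[sym]]) else 0

#' @export
print.element_counts <- function(x, ...) {
  lab <- character(0)
  if (x$n13C > 0) lab <- c(lab, sprintf("13C x %d", x$n13C))
  if (x$n2H > 0) lab <- c(lab, sprintf("2H x %d", x$n2H))
  cat("<element_counts> ", format_formula(x),
      if (length(lab)) paste0(" [", paste(lab, collapse = ", "), "]"), "\n", sep = "")
  invisible(x)
}

#' Parse a Hill-style molecular formula string
#'
#' Accepts formulas such as `"C8H5F13O3S"`: element symbols (one capital
#' letter optionally followed by a lowercase letter) each followed by an
#' optional positive integer count (implicit 1). The result round-trips
#' through [format_formula()].
#'
#' @param text a single non-empty formula string.
#' @return an [element_counts()] object (unlabeled).
#' @examples
#' parse_formula("C4HF7O2")   # PFBA
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string", call. = FALSE)
  pos <- 1L
  n <- nchar(text)
  counts <- numeric(0)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
    if (length(m) == 0L)
      stop(sprintf("malformed formula '%s': expected element symbol at position %d",
                   text, pos), call. = FALSE)
    sym <- m
    # prefer the two-letter symbol only if known; fall back to one letter
    if (nchar(sym) == 2L && !(sym %in% names(.MONO_MASS)))
      sym <- substr(sym, 1L, 1L)
    if (!(sym %in% names(.MONO_MASS)))
      stop(sprintf("unknown element symbol '%s' in formula '%s'", m, text),
           call. = FALSE)
    pos <- pos + nchar(sym)
    rest <- substr(text, pos, n)
    d <- regmatches(rest, regexpr("^[0-9]+", rest))
    cnt <- 1L
    if (length(d) == 1L && nzchar(d)) {
      cnt <- suppressWarnings(as.integer(d))
      if (is.na(cnt) || cnt <= 0L)
        stop(sprintf("malformed count in formula '%s' at position %d", text, pos),
             call. = FALSE)
      pos <- pos + nchar(d)
    }
    counts[sym] <- .count_of(counts, sym) + cnt
  }
  element_counts(counts)
}

#' Canonical Hill-order formula string
#'
#' Formats an [element_counts()] as a Hill-order string: C first, H second,
#' remaining elements alphabetically. Labels are never embedded.
#'
#' @param f an `element_counts` object.
#' @return a single string.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "element_counts"))
  cnt <- f$counts
  hill <- c(intersect(c("C", "H"), names(cnt)),
            sort(setdiff(names(cnt), c("C", "H"))))
  paste0(vapply(hill, function(s) {
    k <- cnt[[s]]
    if (k == 1) s else paste0(s, k)
  }, character(1)), collapse = "")
}

#' Combine or subtract formulas
#'
#' Element-wise sum / difference of two formulas. Subtraction requires the
#' minuend to contain the subtrahend (no negative counts); labels follow the
#' first operand.
#'
#' @param f1,f2 `element_counts` objects.
#' @return an `element_counts` object.
#' @export
formula_add <- function(f1, f2) {
  stopifnot(inherits(f1, "element_counts"), inherits(f2, "element_counts"))
  syms <- union(names(f1$counts), names(f2$counts))
  counts <- vapply(syms, function(s) .count_of(f1$counts, s) + .count_of(f2$counts, s),
                   numeric(1))
  names(counts) <- syms
  element_counts(counts, n13C = f1$n13C + f2$n13C, n2H = f1$n2H + f2$n2H)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f1, f2) {
  stopifnot(inherits(f1, "element_counts"), inherits(f2, "element_counts"))
  syms <- union(names(f1$counts), names(f2$counts))
  counts <- vapply(syms, function(s) .count_of(f1$counts, s) - .count_of(f2$counts, s),
                   numeric(1))
  if (any(counts < 0))
    stop("formula subtraction would produce negative counts for: ",
         paste(syms[counts < 0], collapse = ", "), call. = FALSE)
  names(counts) <- syms
  element_counts(counts, n13C = f1$n13C, n2H = f1$n2H)
}

#' Monoisotopic mass of a formula
#'
#' Sum of monoisotopic atomic masses; 13C / 2H label counts substitute the
#' heavy-isotope mass for the light one. Strictly additive over formulas.
#'
#' @param f an `element_counts` object.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("C8H5F13O3S"))  # 427.97518
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "element_counts"))
  m <- sum(.MONO_MASS[names(f$counts)] * f$counts)
  m + f$n13C * (.MASS_13C - .MONO_MASS[["C"]]) +
      f$n2H  * (.MASS_2H  - .MONO_MASS[["H"]])
}

#' Ion species for single-charge PFAS ions
#'
#' The three ion species observed in this assay: `"[M-H]-"` (deprotonated,
#' negative mode -- most PFAS), `"[M+H]+"` (protonated, positive mode --
#' the zwitterions), and `"[M-CO2-H]-"` (deprotonated after in-source
#' decarboxylation, negative mode -- HFPO-DA and PEPA, which lose their
#' carboxyl in the source). Decarboxylation is only legal for formulas with
#' at least one C and two O.
#'
#' @format character constants.
#' @name ion_species
NULL

ION_SPECIES <- c("[M-H]-", "[M+H]+", "[M-CO2-H]-")

ion_polarity <- function(species) {
  switch(species,
         "[M-H]-" = "negative",
         "[M+H]+" = "positive",
         "[M-CO2-H]-" = "negative",
         stop("unknown ion species: ", species, call. = FALSE))
}

#' Theoretical m/z of a singly charged ion
#'
#' Computes the exact ion m/z for the supported species. The default
#' convention adds or removes a *neutral hydrogen atom* and ignores the
#' electron mass, which reproduces the exact masses printed in PFAS method
#' tables (6:2 FTS deprotonated = 426.9674); set `electron_correction = TRUE`
#' for the physically complete convention (subtract a proton, keep the
#' electron: deprotonated m/z larger by 2 x 0.000549).
#'
#' For `"[M-CO2-H]-"` a CO2 unit is removed before deprotonation. For
#' labeled formulas the removed CO2 carbon is taken unlabeled whenever any
#' unlabeled carbon remains (label positions in these standards sit on the
#' retained backbone); if every carbon is labeled, a 13C is removed.
#'
#' @param f an `element_counts` object.
#' @param species one of `"[M-H]-"`, `"[M+H]+"`, `"[M-CO2-H]-"`.
#' @param electron_correction logical; include the electron mass (default
#'   `FALSE`, matching printed method tables).
#' @return m/z in Da (charge is +/-1 throughout).
#' @examples
#' ion_mz(parse_formula("C8H5F13O3S"), "[M-H]-")  # 426.9674
#' @export
ion_mz <- function(f, species = "[M-H]-", electron_correction = FALSE) {
  stopifnot(inherits(f, "element_counts"))
  species <- match.arg(species, ION_SPECIES)
  m_e <- if (electron_correction) 0.00054857990907 else 0
  mH <- .MONO_MASS[["H"]]
  if (species == "[M-CO2-H]-") {
    cnt <- f$counts
    if (.count_of(cnt, "C") < 1 || .count_of(cnt, "O") < 2)
      stop("decarboxylation requires a formula with >= 1 C and >= 2 O",
           call. = FALSE)
    g <- formula_subtract(element_counts(cnt), parse_formula("CO2"))
    # removed carbon is unlabeled unless every carbon carries a 13C label
    n13C_kept <- min(f$n13C, .count_of(g$counts, "C"))
    g <- element_counts(g$counts, n13C = n13C_kept, n2H = f$n2H)
    return(monoisotopic_mass(g) - mH + m_e)
  }
  m <- monoisotopic_mass(f)
  if (species == "[M-H]-") m - mH + m_e else m + mH - m_e
}

#' Parts-per-million mass difference
#'
#' `|mz_ref - mz_other| / mz_ref * 1e6`. The reference mass must be positive.
#'
#' @param mz_ref reference m/z (Da), > 0.
#' @param mz_other comparison m/z (Da).
#' @return ppm difference (non-negative).
#' @examples
#' ppm_difference(426.9674, 426.9657)  # ~3.98 ppm
#' @export
ppm_difference <- function(mz_ref, mz_other) {
  if (any(mz_ref <= 0)) stop("reference m/z must be positive", call. = FALSE)
  abs(mz_ref - mz_other) / mz_ref * 1e6
}

#' Symmetric ppm extraction window
#'
#' Closed interval `[mz (1 - tol/1e6), mz (1 + tol/1e6)]` used for exact-mass
#' XIC extraction.
#'
#' @param mz center m/z (Da), > 0.
#' @param tol tolerance in ppm, >= 0.
#' @return numeric length-2 vector `c(lo, hi)`.
#' @export
mz_window <- function(mz, tol) {
  if (any(mz <= 0)) stop("m/z must be positive", call. = FALSE)
  if (any(tol < 0)) stop("ppm tolerance must be non-negative", call. = FALSE)
  c(mz * (1 - tol / 1e6), mz * (1 + tol / 1e6))
}

#' Theoretical isotope pattern of a formula
#'
#' Expands each element's natural isotope distribution (multinomial over the
#' packaged abundance table), convolves elements together while merging peaks
#' closer than `merge_da` (default 0.01 Da -- far below the profile width at
#' 60k resolving power, far above fine structure), normalizes to base peak
#' = 1, and drops peaks below `threshold`. Labeled positions are fixed at
#' their heavy isotope and contribute no spread.
#'
#' @param f an `element_counts` object.
#' @param threshold abundance threshold in (0,1); peaks below it are dropped.
#' @param merge_da peak merge width in Da.
#' @return a data.frame with columns `mz` (strictly increasing) and
#'   `abundance` (base peak exactly 1), class `isotope_pattern`.
#' @examples
#' isotope_pattern(parse_formula("C8H5F13O3S"))
#' @export
isotope_pattern <- function(f, threshold = 0.001, merge_da = 0.01) {
  stopifnot(inherits(f, "element_counts"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  # fixed-mass contribution from labeled positions
  fixed <- f$n13C * .MASS_13C + f$n2H * .MASS_2H
  dist <- data.frame(mz = fixed, p = 1)
  prune <- threshold * 1e-4  # keep well below the report threshold while convolving
  for (sym in names(f$counts)) {
    n_free <- f$counts[[sym]]
    if (sym == "C") n_free <- n_free - f$n13C
    if (sym == "H") n_free <- n_free - f$n2H
    if (n_free <= 0) next
    iso <- .ISOTOPES[[sym]]
    atom <- data.frame(mz = iso$mass, p = iso$abund)
    elem <- .convolve_n(atom, n_free, merge_da, prune)
    dist <- .convolve_pair(dist, elem, merge_da, prune)
  }
  dist$p <- dist$p / max(dist$p)
  dist <- dist[dist$p >= threshold, , drop = FALSE]
  dist <- dist[order(dist$mz), , drop = FALSE]
  out <- data.frame(mz = dist$mz, abundance = dist$p)
  rownames(out) <- NULL
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

# distribution of n atoms of one element, by binary exponentiation
.convolve_n <- function(atom, n, merge_da, prune) {
  res <- data.frame(mz = 0, p = 1)
  base <- atom
  while (n > 0) {
    if (n %% 2 == 1) res <- .convolve_pair(res, base, merge_da, prune)
    n <- n %/% 2
    if (n > 0) base <- .convolve_pair(base, base, merge_da, prune)
  }
  res
}

.convolve_pair <- function(a, b, merge_da, prune) {
  mz <- outer(a$mz, b$mz, `+`)
  p <- outer(a$p, b$p, `*`)
  d <- data.frame(mz = as.vector(mz), p = as.vector(p))
  d <- d[order(d$mz), , drop = FALSE]
  # merge runs of peaks within merge_da (abundance-weighted centroid)
  grp <- cumsum(c(1, diff(d$mz) > merge_da))
  p_sum <- tapply(d$p, grp, sum)
  mz_c <- tapply(d$p * d$mz, grp, sum) / p_sum
  d <- data.frame(mz = as.numeric(mz_c), p = as.numeric(p_sum))
  d[d$p >= prune * max(d$p), , drop = FALSE]
}

#' Fluorine count of a formula
#'
#' The number of fluorine atoms -- the similarity measure used for surrogate
#' internal-standard selection.
#'
#' @param f an `element_counts` object.
#' @return integer count (0 if no F).
#' @export
fluorine_count <- function(f) {
  stopifnot(inherits(f, "element_counts"))
  as.integer(.count_of(f$counts, "F"))
}
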