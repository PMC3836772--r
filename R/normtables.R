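norm_constants <- function() {
  # columns: theoretical / empirical (ALLOWED region), Miller 1987, Rose 1985
  tab <- tibble::tribble(
    ~aa, ~theoretical, ~empirical, ~miller1987, ~rose1985,
    "A", 129.0, 121.0, 113.0, 118.1,
    "R", 274.0, 265.0, 241.0, 256.0,
    "N", 195.0, 187.0, 158.0, 165.5,
    "D", 193.0, 187.0, 151.0, 158.7,
    "C", 167.0, 148.0, 140.0, 146.1,
    "E", 223.0, 214.0, 183.0, 186.2,
    "Q", 225.0, 214.0, 189.0, 193.2,
    "G", 104.0,  97.0,  85.0,  88.1,
    "H", 224.0, 216.0, 194.0, 202.5,
    "I", 197.0, 195.0, 182.0, 181.0,
    "L", 201.0, 191.0, 180.0, 193.1,
    "K", 236.0, 230.0, 211.0, 225.8,
    "M", 224.0, 203.0, 204.0, 203.4,
    "F", 240.0, 228.0, 218.0, 222.8,
    "P", 159.0, 154.0, 143.0, 146.8,
    "S", 155.0, 143.0, 122.0, 129.8,
    "T", 172.0, 163.0, 146.0, 152.5,
    "W", 285.0, 264.0, 259.0, 266.3,
    "Y", 263.0, 255.0, 229.0, 236.8,
    "V", 174.0, 165.0, 160.0, 164.5
  )
  dplyr::arrange(tab, .data$aa)
}

#' Published maximum-ASA normalization scales
#'
#' All four scales in long form: the proposed theoretical and empirical
#' scales (ALLOWED Ramachandran region) alongside the Miller (1987) and
#' Rose (1985) constants.
#'
#' @return A tibble `provenance`, `aa`, `max_asa` (Angstrom^2).
#' @export
max_asa_scales <- function() {
  tidyr::pivot_longer(norm_constants(), -"aa",
                      names_to = "provenance", values_to = "max_asa")[
    , c("provenance", "aa", "max_asa")]
}

#' Retrieve one normalization scale
#'
#' @param provenance One of `"theoretical"`, `"empirical"`,
#'   `"miller1987"`, `"rose1985"`.
#' @param region Ramachandran region tag; only `"ALLOWED"` constants are
#'   shipped for the theoretical/empirical scales.
#' @return A tibble `aa`, `max_asa` with attributes `provenance` and
#'   `region`.
#' @export
get_scale <- function(provenance = c("theoretical", "empirical",
                                     "miller1987", "rose1985"),
                      region = "ALLOWED") {
  provenance <- match.arg(provenance)
  if (provenance %in% c("theoretical", "empirical") && region != "ALLOWED") {
    abort("only ALLOWED-region constants are shipped for this scale")
  }
  tab <- norm_constants()
  out <- tibble(aa = tab$aa, max_asa = tab[[provenance]])
  attr(out, "provenance") <- provenance
  attr(out, "region") <- if (provenance %in% c("theoretical", "empirical"))
    region else NA_character_
  out
}

#' Percent correction between two normalization scales
#'
#' `100 * (a - b) / a`, rounded to the nearest integer percent: by how much
#' (relative to scale `a`) scale `b`'s constant falls short.
#'
#' @param scale_a,scale_b Scales as from [get_scale()] (or named vectors);
#'   must cover the same amino acids.
#' @return A tibble `aa`, `percent`.
#' @export
correction_vs <- function(scale_a, scale_b) {
  a <- scale_lookup(scale_a)
  b <- scale_lookup(scale_b)
  if (!setequal(names(a), names(b))) abort("scales cover different amino acids")
  b <- b[names(a)]
  if (any(a == 0)) abort("zero denominator in scale_a")
  tibble(aa = names(a), percent = unname(round(100 * (a - b) / a)))
}

#' Convert an ASA table to RSA
#'
#' @param tbl A tibble with columns `aa` and `asa`.
#' @param scale Normalization scale (see [rsa()]).
#' @return The input with an added `rsa` column.
#' @export
normalize_asa <- function(tbl, scale = get_scale("theoretical")) {
  tbl$rsa <- rsa(tbl$asa, tbl$aa, scale)
  tbl
}
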