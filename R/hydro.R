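new_hydro_scale <- function(aa, score, name, derivation) {
  out <- tibble(aa = aa, score = score)
  attr(out, "scale_name") <- name
  attr(out, "derivation") <- derivation
  class(out) <- c("hydro_scale", class(tibble()))
  out
}

#' Hydrophobicity scale from mean RSA
#'
#' Averages RSA over all unflagged occurrences of each amino acid and
#' scores hydrophobicity as `1 - mean RSA` (larger = more hydrophobic; any
#' affine transform leaves the correlation analyses unchanged).
#'
#' @param obs Observation tibble (see [structure_observations()]).
#' @param scale Normalization scale used to compute RSA (see [rsa()]).
#' @param name Name recorded on the output scale.
#' @return A `hydro_scale` tibble `aa`, `score` with `derivation`
#'   `"mean-rsa"`.
#' @export
mean_rsa_scale <- function(obs, scale = get_scale("theoretical"),
                           name = "mean-rsa") {
  obs <- obs[!obs$flagged & !is.na(obs$asa) & !is.na(obs$aa), ]
  missing <- setdiff(AA1, unique(obs$aa))
  if (length(missing)) {
    abort(paste("no observations for:", paste(missing, collapse = ", ")))
  }
  r <- rsa(obs$asa, obs$aa, scale)
  m <- dplyr::summarise(dplyr::group_by(tibble(aa = obs$aa, r = r), .data$aa),
                        mean_rsa = mean(.data$r), .groups = "drop")
  m <- dplyr::arrange(m, .data$aa)
  new_hydro_scale(m$aa, 1 - m$mean_rsa, name, "mean-rsa")
}

#' Hydrophobicity scale from the fraction of buried residues
#'
#' In `"absolute-zero"` mode a residue counts as buried when its reported
#' ASA is exactly 0 (fully buried); in `"rsa-threshold"` mode when its RSA
#' under `scale` is at or below `threshold` (default 0.05, i.e. 95%
#' buried).
#'
#' @param obs Observation tibble (see [structure_observations()]).
#' @param mode Burial criterion.
#' @param threshold RSA cutoff for `"rsa-threshold"` mode.
#' @param scale Normalization scale for RSA (see [rsa()]).
#' @param name Name recorded on the output scale.
#' @return A `hydro_scale` tibble `aa`, `score` (fraction buried in
#'   \[0, 1\]).
#' @export
fraction_buried <- function(obs, mode = c("rsa-threshold", "absolute-zero"),
                            threshold = 0.05,
                            scale = get_scale("theoretical"),
                            name = NULL) {
  mode <- match.arg(mode)
  obs <- obs[!obs$flagged & !is.na(obs$asa) & !is.na(obs$aa), ]
  missing <- setdiff(AA1, unique(obs$aa))
  if (length(missing)) {
    abort(paste("no observations for:", paste(missing, collapse = ", ")))
  }
  buried <- if (mode == "absolute-zero") {
    obs$asa == 0
  } else {
    rsa(obs$asa, obs$aa, scale) <= threshold
  }
  m <- dplyr::summarise(dplyr::group_by(tibble(aa = obs$aa, b = buried), .data$aa),
                        frac = mean(.data$b), .groups = "drop")
  m <- dplyr::arrange(m, .data$aa)
  derivation <- if (mode == "absolute-zero") "frac-100-buried" else "frac-95-buried"
  new_hydro_scale(m$aa, m$frac, name %||% derivation, derivation)
}

#' Correlate two hydrophobicity scales
#'
#' Pearson correlation over the paired per-amino-acid scores; the absolute
#' value of r is reported (hydrophobicity scales differ arbitrarily in
#' sign and offset) together with the two-sided p-value.
#'
#' @param a,b `hydro_scale` tibbles (columns `aa`, `score`).
#' @param complete Drop amino acids with a missing score in either scale
#'   (default FALSE: missing scores are an error).
#' @return A one-row tibble `r_abs`, `p_value`, `n`, `significant`
#'   (p < 0.05).
#' @export
correlate_scales <- function(a, b, complete = FALSE) {
  m <- dplyr::inner_join(dplyr::select(a, "aa", score_a = "score"),
                         dplyr::select(b, "aa", score_b = "score"),
                         by = "aa")
  if (complete) m <- m[!is.na(m$score_a) & !is.na(m$score_b), ]
  if (anyNA(m$score_a) || anyNA(m$score_b)) {
    abort("missing scores; use complete = TRUE to drop incomplete pairs")
  }
  if (nrow(m) < 3) abort("need at least 3 paired scores")
  if (sd(m$score_a) == 0 || sd(m$score_b) == 0) {
    abort("zero variance in one of the scales")
  }
  ct <- cor.test(m$score_a, m$score_b, method = "pearson")
  tibble(r_abs = abs(unname(ct$estimate)), p_value = ct$p.value,
         n = nrow(m), significant = ct$p.value < 0.05)
}

#' Packaged experimental hydrophobicity scales
#'
#' Citation-attributed transfer-energy scales shipped as data: Kyte &
#' Doolittle (1982) hydropathy, Fauchere & Pliska (1983) octanol/water
#' side-chain transfer, and Wolfenden et al. (1981) vapor/water hydration
#' potentials (no proline value). Their numeric values are data inputs.
#'
#' @return Named list of `hydro_scale` tibbles.
#' @export
experimental_scales <- function() {
  path <- system.file("extdata", "experimental_hydrophobicity_scales.tsv",
                      package = "maxasa", mustWork = TRUE)
  tab <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  lapply(split(tab, tab$scale), function(df) {
    full <- dplyr::left_join(tibble(aa = AA1), df[c("aa", "value")], by = "aa")
    new_hydro_scale(full$aa, full$value, df$scale[1], "experimental")
  })
}

#' Correlation matrix between derived and experimental scales
#'
#' @param derived Named list of `hydro_scale` tibbles (e.g. from
#'   [mean_rsa_scale()] and [fraction_buried()]).
#' @param experimental Named list of reference scales; defaults to the
#'   packaged experimental scales.
#' @return A tibble `experimental`, `derived`, `r_abs`, `p_value`, `n`,
#'   `significant`.
#' @export
correlation_table <- function(derived, experimental = experimental_scales()) {
  purrr::map_dfr(names(experimental), function(e) {
    purrr::map_dfr(names(derived), function(d) {
      dplyr::mutate(
        correlate_scales(derived[[d]], experimental[[e]], complete = TRUE),
        experimental = e, derived = d, .before = 1
      )
    })
  })
}
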