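#' Bin an angle on the Ramachandran torus
#'
#' @param angle Angle(s) in degrees.
#' @param bin_width Bin width in degrees (must divide 360).
#' @return Lower edge of the containing bin, in \[-180, 180).
#' @export
bin_of <- function(angle, bin_width = 20) {
  if (360 %% bin_width != 0) abort("bin_width must divide 360")
  floor((wrap180(angle) + 180) / bin_width) * bin_width - 180
}

#' Bin counts of phi/psi observations
#'
#' @param obs A tibble with `phi` and `psi` columns (degrees); rows with
#'   missing angles are dropped.
#' @param bin_width Bin width in degrees.
#' @return A tibble `phi_bin`, `psi_bin`, `n` with attribute `bin_width`.
#' @export
bin_counts <- function(obs, bin_width = 20) {
  obs <- obs[!is.na(obs$phi) & !is.na(obs$psi), ]
  out <- dplyr::count(
    tibble(phi_bin = bin_of(obs$phi, bin_width),
           psi_bin = bin_of(obs$psi, bin_width)),
    .data$phi_bin, .data$psi_bin, name = "n"
  )
  attr(out, "bin_width") <- bin_width
  out
}

new_rama_region <- function(bins, kind, bin_width, threshold = NA_real_) {
  out <- as_tibble(bins[c("phi_bin", "psi_bin")])
  attr(out, "kind") <- kind
  attr(out, "bin_width") <- bin_width
  attr(out, "threshold") <- threshold
  class(out) <- c("rama_region", class(tibble()))
  out
}

# cross-shaped torus dilation by `steps` bins
dilate_bins <- function(bins, bin_width, steps) {
  key <- function(p, q) paste(p, q)
  cur <- bins
  for (s in seq_len(steps)) {
    cand <- dplyr::bind_rows(
      cur,
      dplyr::mutate(cur, phi_bin = wrap180(.data$phi_bin + bin_width)),
      dplyr::mutate(cur, phi_bin = wrap180(.data$phi_bin - bin_width)),
      dplyr::mutate(cur, psi_bin = wrap180(.data$psi_bin + bin_width)),
      dplyr::mutate(cur, psi_bin = wrap180(.data$psi_bin - bin_width))
    )
    cur <- dplyr::distinct(cand, .data$phi_bin, .data$psi_bin)
  }
  cur
}

#' Define a Ramachandran region from bin counts
#'
#' Regions follow the usual nested convention: `CORE` holds the most
#' populated bins covering at least 80% of observations, `ALLOWED` at least
#' 97%, `GENEROUS` is the `ALLOWED` region extended by `extension` degrees
#' in all four torus directions (regardless of observation), and `ALL`
#' contains every non-empty bin. The inclusion threshold is the largest
#' per-bin count such that the included bins reach the coverage.
#'
#' @param counts Bin counts from [bin_counts()] (columns `phi_bin`,
#'   `psi_bin`, `n`).
#' @param kind One of `"CORE"`, `"ALLOWED"`, `"GENEROUS"`, `"ALL"`.
#' @param coverage Coverage fraction in (0, 1\]; defaults to 0.80 for CORE
#'   and 0.97 for ALLOWED/GENEROUS.
#' @param extension GENEROUS dilation in degrees (multiple of the bin width).
#' @param bin_width Bin width; defaults to the `bin_width` attribute of
#'   `counts`.
#' @return A `rama_region` tibble of member bins (lower edges), with
#'   attributes `kind`, `bin_width` and `threshold`.
#' @export
define_region <- function(counts, kind = c("ALLOWED", "CORE", "GENEROUS", "ALL"),
                          coverage = NULL, extension = 20,
                          bin_width = attr(counts, "bin_width") %||% 20) {
  kind <- match.arg(kind)
  counts <- counts[counts$n > 0, ]
  if (!nrow(counts) || sum(counts$n) == 0) abort("no observations in counts")
  if (kind == "ALL") {
    return(new_rama_region(counts, "ALL", bin_width))
  }
  if (kind == "GENEROUS") {
    allowed <- define_region(counts, "ALLOWED", coverage = coverage,
                             bin_width = bin_width)
    steps <- round(extension / bin_width)
    bins <- dilate_bins(allowed, bin_width, steps)
    return(new_rama_region(bins, "GENEROUS", bin_width,
                           attr(allowed, "threshold")))
  }
  coverage <- coverage %||% if (kind == "CORE") 0.80 else 0.97
  if (coverage <= 0 || coverage > 1) abort("coverage must lie in (0, 1]")
  total <- sum(counts$n)
  cand <- sort(unique(counts$n), decreasing = TRUE)
  covered <- vapply(cand, function(t) sum(counts$n[counts$n >= t]), numeric(1))
  ok <- which(covered >= coverage * total)
  threshold <- cand[ok[1]]  # largest count achieving the coverage
  new_rama_region(counts[counts$n >= threshold, ], kind, bin_width, threshold)
}

#' Simulate Ramachandran observations
#'
#' Draws phi/psi pairs from a Gaussian-mixture model of the Ramachandran
#' plot: alpha-helical, beta/extended, polyproline-II and left-handed-alpha
#' basins for the generic amino acid; symmetrized basins for glycine; a
#' narrow phi band with two psi modes for proline. This is a synthetic
#' stand-in for backbone-angle frequencies mined from crystal structures.
#'
#' @param aa One-letter amino-acid code.
#' @param n Number of observations to draw.
#' @param seed Integer seed.
#' @return A tibble with columns `phi`, `psi` (degrees in \[-180, 180)).
#' @export
simulate_rama_angles <- function(aa, n = 20000, seed = 1L) {
  check_aa(aa)
  basins <- switch(aa,
    G = list(
      c(-63, -43, 11, 11, 0.21), c(63, 43, 11, 11, 0.21),
      c(-120, 135, 25, 25, 0.19), c(120, -135, 25, 25, 0.19),
      c(-65, 145, 15, 15, 0.10), c(65, -145, 15, 15, 0.10)
    ),
    P = list(
      c(-63, -30, 8, 12, 0.45), c(-63, 150, 8, 12, 0.55)
    ),
    list(
      c(-63, -43, 11, 11, 0.42), c(-120, 135, 25, 25, 0.38),
      c(-65, 145, 15, 15, 0.15), c(60, 45, 10, 10, 0.05)
    )
  )
  w <- vapply(basins, `[`, numeric(1), 5)
  with_local_seed(seed, {
    which_basin <- sample.int(length(basins), n, replace = TRUE, prob = w)
    phi <- psi <- numeric(n)
    for (b in seq_along(basins)) {
      idx <- which(which_basin == b)
      p <- basins[[b]]
      phi[idx] <- rnorm(length(idx), p[1], p[3])
      psi[idx] <- rnorm(length(idx), p[2], p[4])
    }
    tibble(phi = wrap180(phi), psi = wrap180(psi))
  })
}

#' Simulate Ramachandran bin counts
#'
#' Convenience wrapper: [simulate_rama_angles()] followed by [bin_counts()].
#'
#' @inheritParams simulate_rama_angles
#' @param bin_width Bin width in degrees.
#' @return Bin counts as from [bin_counts()].
#' @export
simulate_rama_counts <- function(aa, n = 20000, bin_width = 20, seed = 1L) {
  bin_counts(simulate_rama_angles(aa, n, seed), bin_width)
}

#' Packaged synthetic Ramachandran reference counts
#'
#' Per-amino-acid phi/psi bin counts shipped with the package, generated by
#' [simulate_rama_counts()] with a fixed seed (see
#' `inst/extdata/rama_reference_counts_synthetic.tsv`). These stand in for
#' backbone-angle frequencies mined from a structure corpus and anchor the
#' CORE/ALLOWED/GENEROUS region definitions used for the theoretical scales.
#'
#' @param aa One-letter amino-acid code.
#' @return Bin counts as from [bin_counts()].
#' @export
rama_reference_counts <- function(aa) {
  check_aa(aa)
  path <- system.file("extdata", "rama_reference_counts_synthetic.tsv",
                      package = "maxasa", mustWork = TRUE)
  all <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  out <- dplyr::select(all[all$aa == aa, ], "phi_bin", "psi_bin", "n")
  attr(out, "bin_width") <- 20
  out
}
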