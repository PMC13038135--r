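#' Number-average length
#'
#' The count-weighted arithmetic mean
#' \eqn{\bar{DP} = \sum_i DP_i N_i / \sum_i N_i}.  Zero-length items (e.g.
#' the end stubs left by a terminal cleavable unit) contribute to the
#' denominator only.
#'
#' @param lengths Item lengths (`>= 0`).
#' @param counts Item counts `N_i`; defaults to 1 per item.
#' @return The number-average length.
#' @examples
#' number_average(c(1, 3)) # 2
#' @export
number_average <- function(lengths, counts = rep(1, length(lengths))) {
  check_hist_input(lengths, counts)
  if (sum(counts) <= 0) abort("Need at least one item (sum of counts > 0).")
  sum(lengths * counts) / sum(counts)
}

#' Length-weighted average length
#'
#' The ratio of second to first moments,
#' \eqn{\bar{DP}_l = \sum_i DP_i^2 N_i / \sum_i DP_i N_i} — the analog of the
#' weight-average molecular weight, insensitive to zero-length items.
#'
#' @inheritParams number_average
#' @return The length-weighted average length; always `>=` the
#'   number-average (Cauchy–Schwarz).
#' @examples
#' length_weighted_average(c(1, 3)) # 2.5
#' @export
length_weighted_average <- function(lengths, counts = rep(1, length(lengths))) {
  check_hist_input(lengths, counts)
  denom <- sum(lengths * counts)
  if (denom <= 0) abort("All lengths are zero; length-weighted average undefined.")
  sum(lengths^2 * counts) / denom
}

#' Length dispersity
#'
#' \eqn{Đ_{DP} = \bar{DP}_l / \bar{DP}}, the length analog of the molecular
#' weight dispersity: 1 for a monodisperse population, 2 for the most
#' probable distribution, larger for blockier length distributions.
#'
#' @inheritParams number_average
#' @return The dispersity, `>= 1` whenever all lengths are equal or spread.
#' @examples
#' dispersity(c(1, 3)) # 1.25
#' @export
dispersity <- function(lengths, counts = rep(1, length(lengths))) {
  dp_n <- number_average(lengths, counts)
  if (dp_n <= 0) abort("Number-average length is zero; dispersity undefined.")
  length_weighted_average(lengths, counts) / dp_n
}

check_hist_input <- function(lengths, counts) {
  if (length(lengths) == 0) abort("Empty input.")
  if (length(lengths) != length(counts)) {
    abort("`lengths` and `counts` must have equal length.")
  }
  if (any(lengths < 0) || any(counts < 0)) {
    abort("`lengths` and `counts` must be non-negative.")
  }
  invisible(NULL)
}

#' Summarize a digestion result as block-length averages
#'
#' Computes the number-average block length, the length-weighted average,
#' and the block-length dispersity of the postdigestion fragment ensemble.
#' All statistics are computed on fragment monomer counts (zero-length end
#' stubs included); on the repeat-unit scale the two averages are divided by
#' 2 while the dispersity, a ratio, is unchanged.  Binning to whole repeat
#' units is a plotting device only (see [digest_histogram()]) and never
#' enters these averages.
#'
#' @param result A `digest_result`.
#' @param scale `"repeat_unit"` (GS pairs, the reporting convention) or
#'   `"monomer"`.
#' @return A one-row tibble: `label`, `scale`, `dp_n`, `dp_l`, `dispersity`,
#'   `n_fragments`, `n_chains`, `n_cleavages`, `seed`.
#' @examples
#' spec <- random_analog_spec(0.2, 5, 10, p = 0.9, n_chains = 2000, seed = 5)
#' summarize_digest(simulate_digest(spec))
#' @export
summarize_digest <- function(result, scale = c("repeat_unit", "monomer")) {
  stopifnot(inherits(result, "digest_result"))
  scale <- match.arg(scale)
  m <- result$counts$monomer_count
  n <- result$counts$count
  div <- if (scale == "repeat_unit") 2 else 1
  spec <- result$spec
  tibble(
    label = if (is.null(spec)) NA_character_ else spec$label,
    scale = scale,
    dp_n = number_average(m, n) / div,
    dp_l = length_weighted_average(m, n) / div,
    dispersity = dispersity(m, n),
    n_fragments = sum(n),
    n_chains = result$n_chains,
    n_cleavages = result$n_cleavages,
    seed = if (is.null(spec)) NA_integer_ else spec$seed
  )
}

#' Fragment-length histogram of a digestion result
#'
#' Number- or length-weighted histogram in monomer or repeat-unit scale.
#' The repeat-unit scale merges monomer counts `2k` and `2k + 1` into bin
#' `k`, which removes the even/odd secondary distribution caused by end
#' fragments.  The length weighting is \eqn{(N_l)_i = DP_i N_i} on the
#' reported scale.
#'
#' @param result A `digest_result`.
#' @param weighting `"number"` (counts `N_i`) or `"length"` (`DP_i N_i`).
#' @param scale `"repeat_unit"` or `"monomer"`.
#' @param by_origin Keep internal / end / intact fragments separate?
#' @return A tibble with columns `length`, (`origin`,) `n`, `n_l`; `n`
#'   totals the fragment count regardless of `weighting`, which only selects
#'   the column plots should use.
#' @examples
#' spec <- random_analog_spec(0.2, 5, 10, p = 0.9, n_chains = 2000, seed = 5)
#' digest_histogram(simulate_digest(spec), weighting = "length")
#' @export
digest_histogram <- function(result, weighting = c("number", "length"),
                             scale = c("repeat_unit", "monomer"),
                             by_origin = FALSE) {
  stopifnot(inherits(result, "digest_result"))
  weighting <- match.arg(weighting)
  scale <- match.arg(scale)
  h <- result$counts |>
    dplyr::mutate(length = if (scale == "repeat_unit") {
      repeat_units(.data$monomer_count)
    } else {
      .data$monomer_count
    })
  keys <- if (by_origin) c("length", "origin") else "length"
  h <- h |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(n_l = .data$length * .data$n) |>
    dplyr::arrange(.data$length)
  attr(h, "weighting") <- weighting
  attr(h, "scale") <- scale
  h
}

#' SEC-like number-weighted trace on a log abscissa
#'
#' Exports the number-weighted fragment-size distribution against a
#' base-10 logarithmic abscissa, mimicking the presentation of
#' size-exclusion chromatography data (in SEC plots the axis is also
#' inverted so small species sit on the right; see
#' [plot_sec_trace()]).  Fragments with no complete repeat unit are
#' excluded (their log size is undefined or meaningless on this axis).
#'
#' By default the abscissa is `log10(repeat units)`.  Supplying `mass_map`,
#' a named vector of per-monomer masses with entries `G` and `S`, switches
#' the abscissa to `log10(fragment mass)`, where the fragment of `m`
#' monomers is taken as the alternating G/S sequence starting with G
#' (`ceiling(m / 2)` G units) — exact for internal fragments, which begin
#' and end in G, and a half-monomer approximation at worst for end
#' fragments.
#'
#' @param result A `digest_result`.
#' @param mass_map Optional named numeric vector of per-monomer masses;
#'   must contain `G` and `S`.
#' @param normalize_to Optional reference trace (another return value of
#'   this function): the exported intensities are rescaled so the maximum
#'   matches the reference's maximum, the convention used when overlaying a
#'   P-S trace on its random analog.
#' @return A tibble with columns `size`, `log10_size`, `intensity`
#'   (number-weighted counts, optionally rescaled).
#' @examples
#' spec <- random_analog_spec(0.2, 5, 10, p = 0.9, n_chains = 2000, seed = 5)
#' sec_like_export(simulate_digest(spec))
#' @export
sec_like_export <- function(result, mass_map = NULL, normalize_to = NULL) {
  stopifnot(inherits(result, "digest_result"))
  h <- digest_histogram(result, weighting = "number", scale = "monomer") |>
    dplyr::filter(.data$length >= 2)
  if (is.null(mass_map)) {
    out <- h |>
      dplyr::mutate(size = repeat_units(.data$length)) |>
      dplyr::group_by(.data$size) |>
      dplyr::summarise(intensity = sum(.data$n), .groups = "drop")
  } else {
    if (!all(c("G", "S") %in% names(mass_map))) {
      abort("`mass_map` must name masses for monomers \"G\" and \"S\".")
    }
    out <- h |>
      dplyr::mutate(
        size = ceiling(.data$length / 2) * mass_map[["G"]] +
          floor(.data$length / 2) * mass_map[["S"]]
      ) |>
      dplyr::group_by(.data$size) |>
      dplyr::summarise(intensity = sum(.data$n), .groups = "drop")
  }
  out <- dplyr::mutate(out, log10_size = log10(.data$size), .after = "size")
  if (!is.null(normalize_to)) {
    out$intensity <- out$intensity * max(normalize_to$intensity) / max(out$intensity)
  }
  out
}

#' @exportS3Method generics::tidy
tidy.digest_result <- function(x, weighting = "number",
                               scale = "repeat_unit", by_origin = FALSE, ...) {
  digest_histogram(x, weighting = weighting, scale = scale,
                   by_origin = by_origin)
}

#' @exportS3Method generics::glance
glance.digest_result <- function(x, ...) {
  summarize_digest(x, scale = "repeat_unit")
}
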