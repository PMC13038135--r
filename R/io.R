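#' Write an ensemble to a plain-text sequence file
#'
#' One chain per line over the G/S/U alphabet, preceded by `#`-prefixed
#' header lines carrying the provenance (composition label, pool specs,
#' extent of reaction, chain count, seed, package version).
#'
#' @param ensemble A `copolymer_ensemble` (or any tibble with a `sequence`
#'   column of valid chains).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_sequences()]
#' @export
write_sequences <- function(ensemble, path) {
  stopifnot(is.data.frame(ensemble), "sequence" %in% names(ensemble))
  validate_chain_seq(ensemble$sequence)
  spec <- attr(ensemble, "spec")
  header <- c(
    provenance_lines(spec),
    sprintf("# n_chains: %d", nrow(ensemble))
  )
  writeLines(c(header, ensemble$sequence), path)
  invisible(path)
}

#' Read a plain-text sequence file
#'
#' Reads chains written by [write_sequences()] (or any file with one G/S/U
#' sequence per line and optional `#` comment lines), validating strict A/B
#' alternation.
#'
#' @param path File path.
#' @return A tibble with columns `chain`, `sequence`, `n_monomers`; header
#'   comment lines are attached as attribute `header`.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  seqs <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(seqs) == 0) abort(sprintf("No sequences found in %s.", path))
  validate_chain_seq(seqs)
  out <- tibble(chain = seq_along(seqs), sequence = seqs,
                n_monomers = nchar(seqs))
  attr(out, "header") <- header
  out
}

spec_to_list <- function(spec) {
  pool_to_list <- function(pool) {
    list(
      end_type = pool$end_type, mode = pool$mode,
      mean_dp = if (pool$mode == "disperse") pool$mean_dp else NULL,
      discrete_dp = if (pool$mode == "discrete") pool$discrete_dp else NULL,
      u_fraction = pool$u_fraction
    )
  }
  list(
    label = spec$label,
    acid_pool = pool_to_list(spec$acid_pool),
    diol_pool = pool_to_list(spec$diol_pool),
    extent_p = spec$extent_p,
    n_chains = spec$n_chains,
    seed = spec$seed
  )
}

list_to_spec <- function(x) {
  pool_from_list <- function(p) {
    oligomer_pool(
      end_type = p$end_type,
      mean_dp = if (identical(p$mode, "discrete")) NULL else p$mean_dp,
      discrete_dp = p$discrete_dp,
      u_fraction = p$u_fraction %||% 0
    )
  }
  copolymer_spec(
    acid_pool = pool_from_list(x$acid_pool),
    diol_pool = pool_from_list(x$diol_pool),
    extent_p = x$extent_p, n_chains = x$n_chains, seed = x$seed,
    label = x$label
  )
}

#' Write / read a run configuration
#'
#' A run configuration is a named list of [copolymer_spec()]s serialized to
#' YAML; labels must be unique and every entry round-trips exactly through
#' the reader.
#'
#' @param specs A list of `copolymer_spec` objects.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the list of specs.
#' @examples
#' spec <- random_analog_spec(0.2, 5, 10, p = 0.9, n_chains = 100, seed = 1)
#' path <- tempfile(fileext = ".yml")
#' write_run_config(list(spec), path)
#' read_run_config(path)[[1]]$label
#' @export
write_run_config <- function(specs, path) {
  if (inherits(specs, "copolymer_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "copolymer_spec")))
  labels <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labels)) abort("Run-config labels must be unique.")
  yaml::write_yaml(list(runs = lapply(specs, spec_to_list)), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$runs)) abort(sprintf("%s has no `runs` entry.", path))
  specs <- lapply(x$runs, list_to_spec)
  labels <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labels)) abort("Run-config labels must be unique.")
  specs
}

#' Write a fragment histogram to CSV
#'
#' Columns `monomer_count`, `repeat_units`, `origin`, `count`, with
#' provenance (spec label, seed, package version) in `#` comment lines.
#'
#' @param result A `digest_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fragment_csv <- function(result, path) {
  stopifnot(inherits(result, "digest_result"))
  tab <- result$counts |>
    dplyr::mutate(repeat_units = repeat_units(.data$monomer_count),
                  .after = "monomer_count")
  csv <- strsplit(readr::format_csv(tab), "\n", fixed = TRUE)[[1]]
  writeLines(c(provenance_lines(result$spec), csv), path)
  invisible(path)
}

provenance_lines <- function(spec) {
  c(
    sprintf("# coposeq v%s", as.character(utils::packageVersion("coposeq"))),
    if (!is.null(spec)) {
      sprintf("# spec: %s | p=%g | n_chains=%g | seed=%d",
              spec$label, spec$extent_p, spec$n_chains, spec$seed)
    }
  )
}
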