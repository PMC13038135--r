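#' Digest a single chain at every cleavable unit
#'
#' Splits a monomer sequence at each U; the U monomer itself is destroyed by
#' cleavage, so `k` U's give `k + 1` fragments in chain order.  The first and
#' last fragments of a cleaved chain carry a chain end (`origin = "end"`; a
#' terminal U leaves a zero-length end stub), fragments bounded by two
#' cleavage sites are `"internal"`, and a U-free chain survives as one
#' `"intact"` fragment.  Because chains strictly alternate A/B monomers,
#' internal fragments always have an odd monomer count; only end fragments
#' can be even.
#'
#' @param chain A monomer sequence string over G/S/U with strict A/B
#'   alternation.
#' @return A tibble with one row per fragment: `fragment` (index along the
#'   chain), `sequence`, `monomer_count`, `repeat_units`, `origin`.
#' @examples
#' digest_chain("SGSGUGSGS")
#' digest_chain("UGU") # two zero-length end stubs around "G"
#' @export
digest_chain <- function(chain) {
  stopifnot(is.character(chain), length(chain) == 1)
  validate_chain_seq(chain)
  len <- nchar(chain)
  hits <- gregexpr("U", chain, fixed = TRUE)[[1]]
  u_pos <- if (hits[1] == -1L) integer() else as.integer(hits)
  k <- length(u_pos)
  starts <- c(1L, u_pos + 1L)
  ends <- c(u_pos - 1L, len)
  pieces <- substring(chain, starts, ends)
  pieces[ends < starts] <- ""
  origin <- if (k == 0L) "intact" else c("end", rep("internal", max(k - 1L, 0L)), "end")
  m <- nchar(pieces)
  tibble(
    fragment = seq_len(k + 1L),
    sequence = pieces,
    monomer_count = m,
    repeat_units = repeat_units(m),
    origin = origin
  )
}

#' Digest every chain of an ensemble
#'
#' Batch driver over [digest_chain()] with exact conservation accounting:
#' the number of fragments equals the number of cleaved U's plus the number
#' of chains, and surviving fragment monomers plus destroyed U's equal the
#' predigestion monomer total.
#'
#' @param ensemble A `copolymer_ensemble` from [simulate_ensemble()], or any
#'   tibble with a `sequence` column of valid chains.
#' @return A `digest_result`: a list with `counts` (tibble of
#'   `monomer_count`, `origin`, `count`), `n_chains`, `n_cleavages`,
#'   `total_monomers_pre`, and the originating `spec` when available.
#' @examples
#' spec <- copolymer_spec(
#'   oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5),
#'   oligomer_pool("diol", mean_dp = 10),
#'   extent_p = 0.9, n_chains = 200, seed = 11
#' )
#' digest_ensemble(simulate_ensemble(spec))
#' @export
digest_ensemble <- function(ensemble) {
  stopifnot(is.data.frame(ensemble), nrow(ensemble) > 0,
            "sequence" %in% names(ensemble))
  seqs <- ensemble$sequence
  chain_len <- nchar(seqs)
  hits <- gregexpr("U", seqs, fixed = TRUE)
  u_list <- lapply(hits, function(v) if (v[1] == -1L) integer() else as.integer(v))
  k_u <- lengths(u_list)
  frags <- fragments_from_positions(
    u_pos = unlist(u_list, use.names = FALSE),
    u_cid = rep.int(seq_along(seqs), k_u),
    chain_len = chain_len
  )
  new_digest_result(
    counts = count_fragments(frags),
    n_chains = length(seqs),
    n_cleavages = sum(k_u),
    total_monomers_pre = sum(chain_len),
    spec = attr(ensemble, "spec")
  )
}

#' Simulate and digest without materializing sequences
#'
#' Streaming equivalent of `digest_ensemble(simulate_ensemble(spec))`: chains
#' are drawn chunk by chunk and cleaved directly from the positions of their
#' U monomers, so ensembles of millions of chains fit in memory as fragment
#' histograms.  With the same `spec` and `chunk_size` the realization — and
#' hence the fragment multiset — is exactly identical to the materialized
#' route.
#'
#' @inheritParams simulate_ensemble
#' @return A `digest_result` (see [digest_ensemble()]).
#' @examples
#' spec <- copolymer_spec(
#'   oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5),
#'   oligomer_pool("diol", mean_dp = 10),
#'   extent_p = 0.9, n_chains = 1000, seed = 11
#' )
#' summarize_digest(simulate_digest(spec))
#' @export
simulate_digest <- function(spec, chunk_size = 1e5) {
  stopifnot(inherits(spec, "copolymer_spec"))
  sizes <- chunk_sizes(spec$n_chains, chunk_size)
  n_cleavages <- 0
  total_monomers <- 0
  parts <- withr::with_seed(spec$seed, lapply(sizes, function(n) {
    ch <- draw_chunk(spec, n)
    keep <- ch$u
    frags <- fragments_from_positions(ch$b_pos[keep], ch$b_cid[keep], ch$chain_len)
    n_cleavages <<- n_cleavages + sum(keep)
    total_monomers <<- total_monomers + ch$total_monomers
    count_fragments(frags)
  }))
  new_digest_result(
    counts = count_fragments(dplyr::bind_rows(parts)),
    n_chains = spec$n_chains,
    n_cleavages = n_cleavages,
    total_monomers_pre = total_monomers,
    spec = spec
  )
}

new_digest_result <- function(counts, n_chains, n_cleavages,
                              total_monomers_pre, spec = NULL) {
  res <- structure(
    list(
      counts = dplyr::arrange(counts, .data$monomer_count, .data$origin),
      n_chains = n_chains,
      n_cleavages = n_cleavages,
      total_monomers_pre = total_monomers_pre,
      spec = spec
    ),
    class = "digest_result"
  )
  stopifnot(
    sum(res$counts$count) == n_cleavages + n_chains,
    sum(res$counts$monomer_count * res$counts$count) + n_cleavages ==
      total_monomers_pre
  )
  res
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf(
    "<digest_result> %s chains, %s cleavages, %s fragments\n",
    format(x$n_chains, big.mark = ","),
    format(x$n_cleavages, big.mark = ","),
    format(x$n_chains + x$n_cleavages, big.mark = ",")
  ))
  if (!is.null(x$spec)) cat("  spec:", x$spec$label, "seed", x$spec$seed, "\n")
  s <- summarize_digest(x, scale = "repeat_unit")
  cat(sprintf(
    "  block length (repeat units): dp_n %.3f, dp_l %.3f, dispersity %.3f\n",
    s$dp_n, s$dp_l, s$dispersity
  ))
  invisible(x)
}

#' Complete repeat units in a fragment
#'
#' A repeat unit is one A-type plus one B-type monomer (a GS pair); a
#' fragment of `m` surviving monomers contains `floor(m / 2)` complete
#' repeat units, so monomer counts `2k` and `2k + 1` fall in the same
#' repeat-unit bin `k`.
#'
#' @param m Non-negative monomer counts.
#' @return Integer repeat-unit counts.
#' @examples
#' repeat_units(0:5) # 0 0 1 1 2 2
#' @export
repeat_units <- function(m) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) || any(m != floor(m))) {
    abort("`m` must contain non-negative integers.")
  }
  as.integer(m) %/% 2L
}

#' Fragment counts by origin and monomer-count parity
#'
#' Bookkeeping behind the secondary distribution visible in postdigestion
#' monomer-scale histograms: internal fragments can only be odd, so all even
#' mass sits on fragments that carry a chain end.
#'
#' @param result A `digest_result`.
#' @return A tibble with columns `origin`, `parity`, `n_fragments`.
#' @export
fragment_class_counts <- function(result) {
  stopifnot(inherits(result, "digest_result"))
  result$counts |>
    dplyr::mutate(parity = ifelse(.data$monomer_count %% 2L == 0L, "even", "odd")) |>
    dplyr::group_by(.data$origin, .data$parity) |>
    dplyr::summarise(n_fragments = sum(.data$count), .groups = "drop")
}

validate_chain_seq <- function(x) {
  bad <- grepl("[^GSU]", x) | nchar(x) == 0 | grepl("GG|[SU][SU]", x)
  if (any(bad)) {
    abort(sprintf(
      "Invalid chain sequence(s): %s (must be non-empty, over G/S/U, strictly alternating A/B).",
      paste(utils::head(x[bad], 3), collapse = ", ")
    ))
  }
  invisible(x)
}
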