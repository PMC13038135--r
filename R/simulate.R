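#' Simulate a copolymer ensemble as explicit monomer sequences
#'
#' Draws `spec$n_chains` polymer chains: oligomers-per-chain from the
#' standard Flory law at `spec$extent_p`, a uniformly chosen starting pool,
#' oligomer lengths from each pool's length law, and an independent U/S coin
#' flip at every B position.  Each chain is returned as a monomer sequence
#' over the alphabet G (diol unit), S (saturated diacid) and U (cleavable
#' diacid), strictly alternating A-type (G) and B-type (S/U) monomers.
#'
#' The RNG is seeded from `spec$seed` (the global RNG state is untouched),
#' so the same spec always yields the same ensemble.  Chains are generated
#' in chunks of `chunk_size`; the realization depends on the chunking, so
#' keep `chunk_size` fixed when exact reproducibility across calls matters.
#' [simulate_digest()] with the same spec and chunk size digests the exact
#' same realization without materializing sequences.
#'
#' @param spec A [copolymer_spec()].
#' @param chunk_size Chains generated per internal chunk.
#' @return A tibble of class `copolymer_ensemble` with columns `chain`,
#'   `sequence`, `n_monomers`, `n_oligomers`, `starts_with`; the spec is
#'   attached as attribute `spec`.
#' @examples
#' spec <- copolymer_spec(
#'   oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5),
#'   oligomer_pool("diol", mean_dp = 10),
#'   extent_p = 0.9, n_chains = 100, seed = 7
#' )
#' ens <- simulate_ensemble(spec)
#' head(ens)
#' @export
simulate_ensemble <- function(spec, chunk_size = 1e5) {
  stopifnot(inherits(spec, "copolymer_spec"))
  sizes <- chunk_sizes(spec$n_chains, chunk_size)
  parts <- withr::with_seed(
    spec$seed,
    lapply(sizes, function(n) materialize_chunk(draw_chunk(spec, n)))
  )
  out <- dplyr::bind_rows(parts)
  out$chain <- seq_len(nrow(out))
  attr(out, "spec") <- spec
  class(out) <- c("copolymer_ensemble", class(out))
  out
}

materialize_chunk <- function(ch) {
  sym <- rep.int("G", ch$total_monomers)
  chain_off <- c(0L, cumsum(ch$chain_len))[seq_len(ch$n)]
  global_b <- chain_off[ch$b_cid] + ch$b_pos
  sym[global_b] <- ifelse(ch$u, "U", "S")
  big <- paste(sym, collapse = "")
  ends <- cumsum(ch$chain_len)
  seqs <- substring(big, ends - ch$chain_len + 1L, ends)
  tibble(
    chain = seq_len(ch$n),
    sequence = seqs,
    n_monomers = ch$chain_len,
    n_oligomers = ch$y,
    starts_with = ifelse(ch$start_acid, "diacid", "diol")
  )
}

#' Draw oligomers from a pool as monomer sequences
#'
#' Single-pool counterpart of [simulate_ensemble()]: draws `n` telechelic
#' oligomers from the pool's length law and U-placement rule.  Uses (and
#' advances) the current RNG stream; call [set.seed()] beforehand for
#' reproducibility.
#'
#' @param pool An [oligomer_pool()].
#' @param n Number of oligomers to draw.
#' @return Character vector of `n` odd-length alternating sequences; diacid
#'   oligomers begin and end with S/U, diol oligomers with G.
#' @examples
#' set.seed(1)
#' build_oligomer(oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5), 3)
#' @export
build_oligomer <- function(pool, n = 1) {
  stopifnot(inherits(pool, "oligomer_pool"), n >= 1)
  len <- draw_pool_lengths(pool, as.integer(n))
  is_acid <- pool$end_type == "diacid"
  n_b <- if (is_acid) (len + 1L) %/% 2L else (len - 1L) %/% 2L
  u <- runif(sum(n_b)) < pool$u_fraction
  b_syms <- ifelse(u, "U", "S")
  olig_id <- rep.int(seq_along(len), n_b)
  vapply(seq_along(len), function(i) {
    s <- rep.int("G", len[i])
    b_slots <- seq.int(if (is_acid) 1L else 2L, by = 2L, length.out = n_b[i])
    s[b_slots] <- b_syms[olig_id == i]
    paste(s, collapse = "")
  }, character(1))
}

#' Assemble parallel-successive copolymer chains one at a time
#'
#' Draws `n` chains under `spec` using the current RNG stream (the spec's
#' seed is ignored here; see [simulate_ensemble()] for the seeded batch
#' driver).  Each chain concatenates an alternating run of oligomers from
#' the two pools; because diacid oligomers end in a B-type monomer and diol
#' oligomers in an A-type one, strict A/B alternation is preserved across
#' junctions.
#'
#' @param spec A [copolymer_spec()].
#' @param n Number of chains.
#' @return Character vector of `n` monomer sequences.
#' @export
build_ps_chain <- function(spec, n = 1) {
  stopifnot(inherits(spec, "copolymer_spec"), n >= 1)
  materialize_chunk(draw_chunk(spec, as.integer(n)))$sequence
}

#' Chain-length histogram of an ensemble
#'
#' @param ensemble A `copolymer_ensemble` from [simulate_ensemble()].
#' @param axis Count chain length in `"monomers"` or in `"oligomers"`.
#' @return A tibble with columns `length` and `n`; `sum(n)` equals the
#'   number of chains.
#' @examples
#' spec <- copolymer_spec(
#'   oligomer_pool("diacid", mean_dp = 5),
#'   oligomer_pool("diol", mean_dp = 10),
#'   extent_p = 0.9, n_chains = 500, seed = 3
#' )
#' chain_length_histogram(simulate_ensemble(spec), "oligomers")
#' @export
chain_length_histogram <- function(ensemble, axis = c("monomers", "oligomers")) {
  axis <- match.arg(axis)
  stopifnot(inherits(ensemble, "copolymer_ensemble"), nrow(ensemble) > 0)
  col <- if (axis == "monomers") "n_monomers" else "n_oligomers"
  dplyr::count(tibble(length = ensemble[[col]]), .data$length, name = "n")
}

#' @exportS3Method generics::glance
glance.copolymer_ensemble <- function(x, ...) {
  spec <- attr(x, "spec")
  tibble(
    label = spec$label,
    n_chains = nrow(x),
    mean_monomers = mean(x$n_monomers),
    mean_oligomers = mean(x$n_oligomers),
    mean_u = mean(vapply(gregexpr("U", x$sequence, fixed = TRUE),
                         function(v) sum(v > 0L), numeric(1))),
    extent_p = spec$extent_p,
    seed = spec$seed
  )
}
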