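# Vectorized chunk engine shared by ensemble materialization and streaming
# digestion.  All stochastic draws happen in draw_chunk(), in a fixed order
# (chain lengths, start pools, diacid oligomer lengths, diol oligomer
# lengths, U coin flips), so every consumer of a chunk sees the same
# realization for the same RNG state.

draw_pool_lengths <- function(pool, n) {
  if (n == 0L) return(integer())
  if (pool$mode == "discrete") {
    rep.int(pool$discrete_dp, n)
  } else {
    sample_flory_odd(n, pool$r)
  }
}

# One chunk of `n` chains from `spec`, consuming the current RNG stream.
# Returns oligomer-level and B-position-level vectors; all positions are
# chain-local (1-based monomer index within the chain).
draw_chunk <- function(spec, n) {
  y <- sample_flory(n, spec$extent_p)         # oligomers per chain
  start_acid <- runif(n) < 0.5                # starting pool, uniform
  n_olig <- sum(y)
  cid <- rep.int(seq_len(n), y)               # chain id per oligomer
  odd_slot <- (sequence(y) %% 2L) == 1L
  sa <- rep(start_acid, y)
  is_acid <- (sa & odd_slot) | (!sa & !odd_slot)

  len <- integer(n_olig)
  len[is_acid] <- draw_pool_lengths(spec$acid_pool, sum(is_acid))
  len[!is_acid] <- draw_pool_lengths(spec$diol_pool, sum(!is_acid))

  # B-type positions: diacid oligomers hold B at local slots 1,3,...,len;
  # diol oligomers at 2,4,...,len-1.
  n_b <- ifelse(is_acid, (len + 1L) %/% 2L, (len - 1L) %/% 2L)
  f <- ifelse(is_acid, spec$acid_pool$u_fraction, spec$diol_pool$u_fraction)
  n_b_total <- sum(n_b)
  u <- runif(n_b_total) < rep(f, n_b)

  olig_end <- cumsum(len)
  olig_off <- olig_end - len                  # monomers before this oligomer (chunk-global)
  chain_last <- cumsum(y)
  chain_len <- as.integer(diff(c(0, olig_end[chain_last])))
  chain_off_of_olig <- rep(olig_off[c(1L, head(chain_last, -1L) + 1L)], y)
  olig_off_local <- olig_off - chain_off_of_olig

  first_b <- ifelse(is_acid, 1L, 2L)
  b_pos <- rep(olig_off_local + first_b, n_b) + 2L * (sequence(n_b) - 1L)
  b_cid <- rep.int(cid, n_b)

  list(
    n = n, y = y, start_acid = start_acid,
    cid = cid, is_acid = is_acid, len = len, n_b = n_b,
    b_pos = b_pos, b_cid = b_cid, u = u,
    chain_len = chain_len, total_monomers = sum(len)
  )
}

# Fragment monomer counts and origins from the chain-local positions of U
# monomers.  `u_pos`/`u_cid` must be sorted by (chain, position); `chain_len`
# has one entry per chain 1..n_chains.  Cleavage removes the U monomer, so k
# U's in a chain yield k + 1 fragments; the flanking two are "end" fragments
# (zero-length when the U sits at a chain terminus), the k - 1 between
# cleavage sites are "internal", and U-free chains survive as one "intact"
# fragment.
fragments_from_positions <- function(u_pos, u_cid, chain_len) {
  n_chains <- length(chain_len)
  n_u <- length(u_pos)
  if (n_u > 0L) {
    new_chain <- c(TRUE, u_cid[-1L] != u_cid[-n_u])
    prev <- c(0L, u_pos[-n_u])
    prev[new_chain] <- 0L
    m_before <- u_pos - prev - 1L
    origin_before <- ifelse(new_chain, "end", "internal")
    last_of_chain <- which(c(u_cid[-1L] != u_cid[-n_u], TRUE))
    m_after <- chain_len[u_cid[last_of_chain]] - u_pos[last_of_chain]
  } else {
    m_before <- integer()
    origin_before <- character()
    m_after <- integer()
  }
  k_u <- tabulate(u_cid, nbins = n_chains)
  m_intact <- chain_len[k_u == 0L]
  tibble(
    monomer_count = c(m_before, m_after, m_intact),
    origin = c(origin_before, rep("end", length(m_after)),
               rep("intact", length(m_intact)))
  )
}

count_fragments <- function(frags) {
  if ("count" %in% names(frags)) {
    dplyr::count(frags, .data$monomer_count, .data$origin,
                 wt = .data$count, name = "count")
  } else {
    dplyr::count(frags, .data$monomer_count, .data$origin, name = "count")
  }
}

chunk_sizes <- function(n_chains, chunk_size) {
  n_full <- n_chains %/% chunk_size
  sizes <- rep.int(chunk_size, n_full)
  if (n_chains %% chunk_size > 0) sizes <- c(sizes, n_chains %% chunk_size)
  sizes
}
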