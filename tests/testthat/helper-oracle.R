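# Independent brute-force oracles used against the vectorized implementation.

# Character-by-character string split at U: the reference digestion.
oracle_digest <- function(chain) {
  chars <- strsplit(chain, "", fixed = TRUE)[[1]]
  frags <- character()
  cur <- ""
  for (ch in chars) {
    if (ch == "U") {
      frags <- c(frags, cur)
      cur <- ""
    } else {
      cur <- paste0(cur, ch)
    }
  }
  frags <- c(frags, cur)
  k <- length(frags) - 1L
  origin <- if (k == 0L) "intact" else c("end", rep("internal", max(k - 1L, 0L)), "end")
  tibble::tibble(sequence = frags, monomer_count = nchar(frags), origin = origin)
}

# Every strictly alternating sequence over {G, S, U} up to max_len monomers.
alternating_seqs <- function(max_len) {
  out <- character()
  grow <- function(s, last_is_b) {
    out[[length(out) + 1L]] <<- s
    if (nchar(s) < max_len) {
      if (last_is_b) {
        grow(paste0(s, "G"), FALSE)
      } else {
        grow(paste0(s, "S"), TRUE)
        grow(paste0(s, "U"), TRUE)
      }
    }
  }
  grow("G", FALSE)
  grow("S", TRUE)
  grow("U", TRUE)
  unlist(out)
}

# Standard small P-S spec used across tests.
test_spec <- function(f_acid = 0.5, f_diol = 0, n_chains = 1000, seed = 101,
                      p = 0.9) {
  copolymer_spec(
    oligomer_pool("diacid", mean_dp = 5, u_fraction = f_acid),
    oligomer_pool("diol", mean_dp = 10, u_fraction = f_diol),
    extent_p = p, n_chains = n_chains, seed = seed
  )
}

count_u <- function(seqs) {
  nchar(seqs) - nchar(gsub("U", "", seqs, fixed = TRUE))
}
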