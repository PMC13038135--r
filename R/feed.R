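#' Split an overall cleavable-unit budget between the two oligomer pools
#'
#' In a parallel-successive copolymerization the cleavable diacid U can be fed
#' to the diacid-terminated pool, the diol-terminated pool, or both.  Given an
#' overall target composition `overall_u = U / (U + S)` across all diacid (B)
#' positions, this solves for the per-pool U fractions.
#'
#' A diacid oligomer of mean length `dp_acid` carries `(dp_acid + 1) / 2` B
#' units on average; a diol oligomer of mean length `dp_diol` carries
#' `(dp_diol - 1) / 2` internal B units.  The per-(diacid + diol) pair U
#' budget is `overall_u * ((dp_acid + 1) / 2 + (dp_diol - 1) / 2)`;
#' `share_in_acid` is the fraction of that budget assigned to the diacid
#' pool, the remainder going to the diol pool.
#'
#' @param overall_u Target overall U fraction of B positions, in `[0, 1]`.
#' @param dp_acid,dp_diol Mean (or discrete) degrees of polymerization of the
#'   diacid and diol pools, both `>= 1`.
#' @param share_in_acid Fraction of the U budget placed in the diacid pool,
#'   in `[0, 1]`.  `1` confines all U to the short diacid oligomers; `0`
#'   confines it to the diol oligomers.
#' @return A one-row tibble with columns `f_acid`, `f_diol` (per-pool U
#'   fractions on B positions), `overall_u`, `share_in_acid`, and the B-unit
#'   counts `b_acid`, `b_diol` used as weights.
#' @examples
#' solve_feed_fractions(0.20, 5, 10, share_in_acid = 1)   # f_acid 0.50
#' solve_feed_fractions(0.20, 5, 10, share_in_acid = 0)   # f_diol 1/3
#' solve_feed_fractions(0.20, 5, 10, share_in_acid = 0.4) # balanced 0.20/0.20
#' @export
solve_feed_fractions <- function(overall_u, dp_acid, dp_diol, share_in_acid) {
  check_fraction(overall_u, "overall_u")
  check_fraction(share_in_acid, "share_in_acid")
  if (dp_acid < 1 || dp_diol < 1) {
    abort("`dp_acid` and `dp_diol` must both be >= 1.")
  }
  b_acid <- (dp_acid + 1) / 2
  b_diol <- (dp_diol - 1) / 2
  budget <- overall_u * (b_acid + b_diol)
  f_acid <- budget * share_in_acid / b_acid
  f_diol <- if (b_diol > 0) budget * (1 - share_in_acid) / b_diol else 0
  if (b_diol == 0 && budget * (1 - share_in_acid) > 1e-12) {
    abort("Infeasible split: the diol pool has no internal B positions to host U.")
  }
  if (f_acid > 1 + 1e-12) {
    abort(sprintf(
      "Infeasible split: the diacid pool would need U fraction %.3f > 1.", f_acid
    ))
  }
  if (f_diol > 1 + 1e-12) {
    abort(sprintf(
      "Infeasible split: the diol pool would need U fraction %.3f > 1.", f_diol
    ))
  }
  tibble(
    f_acid = min(f_acid, 1), f_diol = min(f_diol, 1),
    overall_u = overall_u, share_in_acid = share_in_acid,
    b_acid = b_acid, b_diol = b_diol
  )
}

#' Overall U fraction implied by per-pool feed fractions
#'
#' The B-count-weighted mean of the two per-pool U fractions; inverse of
#' [solve_feed_fractions()].
#'
#' @param f_acid,f_diol Per-pool U fractions on B positions.
#' @inheritParams solve_feed_fractions
#' @return The ensemble-average `U / (U + S)` over all B positions.
#' @export
overall_u_fraction <- function(f_acid, f_diol, dp_acid, dp_diol) {
  b_acid <- (dp_acid + 1) / 2
  b_diol <- (dp_diol - 1) / 2
  (f_acid * b_acid + f_diol * b_diol) / (b_acid + b_diol)
}
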