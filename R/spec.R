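#' Describe one telechelic oligomer pool
#'
#' A pool is one arm of a parallel-successive polymerization: a population of
#' short chains with a fixed end-group type and a length law.  Diacid-ended
#' oligomers begin and end with a B-type monomer (S or U); diol-ended
#' oligomers begin and end with the A-type diol G.  Either way the monomer
#' count is odd.  In `disperse` mode lengths follow the odd-length Flory law
#' at the imbalance ratio that targets `mean_dp` (see [flory_odd_pmf()]);
#' in `discrete` mode every oligomer has exactly `discrete_dp` monomers.
#' Each B position is independently the cleavable unit U with probability
#' `u_fraction`, otherwise the inert S.
#'
#' @param end_type `"diacid"` or `"diol"`.
#' @param mean_dp Target number-average monomer count (disperse mode).
#' @param discrete_dp Exact odd monomer count (discrete mode).  Give exactly
#'   one of `mean_dp` / `discrete_dp`.
#' @param u_fraction Probability that a B position is U, in `[0, 1]`.
#'   For a diol pool this applies to its internal B positions.
#' @return An object of class `oligomer_pool`.
#' @examples
#' oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5)
#' oligomer_pool("diol", discrete_dp = 11)
#' @export
oligomer_pool <- function(end_type = c("diacid", "diol"), mean_dp = NULL,
                          discrete_dp = NULL, u_fraction = 0) {
  end_type <- match.arg(end_type)
  check_fraction(u_fraction, "u_fraction")
  if (is.null(mean_dp) == is.null(discrete_dp)) {
    abort("Give exactly one of `mean_dp` (disperse) or `discrete_dp` (discrete).")
  }
  if (!is.null(discrete_dp)) {
    if (length(discrete_dp) != 1 || discrete_dp < 1 ||
        discrete_dp != floor(discrete_dp) || discrete_dp %% 2 == 0) {
      abort("`discrete_dp` must be a positive odd integer (telechelic chains have odd monomer counts).")
    }
    pool <- list(
      end_type = end_type, mode = "discrete",
      discrete_dp = as.integer(discrete_dp), mean_dp = as.numeric(discrete_dp),
      r = NA_real_, u_fraction = u_fraction
    )
  } else {
    if (length(mean_dp) != 1 || !is.finite(mean_dp) || mean_dp < 1) {
      abort("`mean_dp` must be a single finite number >= 1.")
    }
    pool <- list(
      end_type = end_type, mode = "disperse",
      discrete_dp = NA_integer_, mean_dp = as.numeric(mean_dp),
      r = imbalance_for_mean_dp(mean_dp), u_fraction = u_fraction
    )
  }
  structure(pool, class = "oligomer_pool")
}

#' @export
print.oligomer_pool <- function(x, ...) {
  cat(sprintf(
    "<oligomer_pool> %s, %s DP %s, U fraction %.3g\n",
    x$end_type, x$mode,
    if (x$mode == "discrete") x$discrete_dp else format(x$mean_dp),
    x$u_fraction
  ))
  invisible(x)
}

#' Describe one parallel-successive copolymerization run
#'
#' Couples a diacid-ended and a diol-ended oligomer pool in strict
#' alternation.  The number of oligomers per polymer chain follows the
#' standard Flory law at extent of reaction `extent_p` (see [flory_pmf()]);
#' the first oligomer of each chain is drawn from either pool with equal
#' probability.
#'
#' @param acid_pool An [oligomer_pool()] with `end_type = "diacid"`.
#' @param diol_pool An [oligomer_pool()] with `end_type = "diol"`.
#' @param extent_p Extent of reaction of the coupling step, in `[0, 1)`.
#' @param n_chains Number of polymer chains in the ensemble.
#' @param seed Integer RNG seed; mandatory, echoed in all outputs.
#' @param label Optional composition label, e.g. `"(U50)_5-alt-(U0)_10"`.
#'   Defaults to a label built from the pool compositions.
#' @return An object of class `copolymer_spec`.
#' @examples
#' copolymer_spec(
#'   oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5),
#'   oligomer_pool("diol", mean_dp = 10),
#'   extent_p = 0.9, n_chains = 1000, seed = 1
#' )
#' @export
copolymer_spec <- function(acid_pool, diol_pool, extent_p, n_chains, seed,
                           label = NULL) {
  if (!inherits(acid_pool, "oligomer_pool") || acid_pool$end_type != "diacid") {
    abort("`acid_pool` must be an oligomer_pool with end_type \"diacid\".")
  }
  if (!inherits(diol_pool, "oligomer_pool") || diol_pool$end_type != "diol") {
    abort("`diol_pool` must be an oligomer_pool with end_type \"diol\".")
  }
  check_fraction(extent_p, "extent_p", open_upper = TRUE)
  if (length(n_chains) != 1 || is.na(n_chains) || n_chains < 1 ||
      n_chains != floor(n_chains)) {
    abort("`n_chains` must be a positive integer.")
  }
  if (missing(seed) || length(seed) != 1 || is.na(seed) ||
      seed != floor(seed)) {
    abort("`seed` must be a single integer (mandatory for reproducibility).")
  }
  label <- label %||% ps_label(acid_pool, diol_pool)
  structure(
    list(
      acid_pool = acid_pool, diol_pool = diol_pool,
      extent_p = extent_p, n_chains = as.double(n_chains),
      seed = as.integer(seed), label = label
    ),
    class = "copolymer_spec"
  )
}

#' @export
print.copolymer_spec <- function(x, ...) {
  cat(sprintf(
    "<copolymer_spec> %s: p = %.3g, %g chains, seed %d\n",
    x$label, x$extent_p, x$n_chains, x$seed
  ))
  print(x$acid_pool)
  print(x$diol_pool)
  invisible(x)
}

#' Spec for the statistically random analog of a P-S copolymer
#'
#' When the cleavable unit is fed at the same fraction to both pools, the
#' assembled copolymer is statistically indistinguishable from a one-pot
#' random copolymer of the same overall composition.  This builds that
#' balanced-split spec.
#'
#' @param overall_u Overall U fraction of B positions, in `[0, 1]`.
#' @param acid_dp,diol_dp Mean degrees of polymerization of the two pools.
#' @param p Extent of reaction of the coupling step.
#' @param n_chains,seed As in [copolymer_spec()].
#' @return A `copolymer_spec` with `u_fraction = overall_u` in both pools.
#' @examples
#' random_analog_spec(0.2, 5, 10, p = 0.9, n_chains = 1000, seed = 1)
#' @export
random_analog_spec <- function(overall_u, acid_dp, diol_dp, p, n_chains, seed) {
  check_fraction(overall_u, "overall_u")
  copolymer_spec(
    oligomer_pool("diacid", mean_dp = acid_dp, u_fraction = overall_u),
    oligomer_pool("diol", mean_dp = diol_dp, u_fraction = overall_u),
    extent_p = p, n_chains = n_chains, seed = seed,
    label = sprintf("Rand(U%s)", format(round(100 * overall_u)))
  )
}

#' Composition label in the (Ua)_m-alt-(Ub)_n style
#'
#' @param acid_pool,diol_pool [oligomer_pool()] objects.
#' @return A label string such as `"(U50)_5-alt-(U0)_10"`.
#' @export
ps_label <- function(acid_pool, diol_pool) {
  dp_fmt <- function(pool) {
    if (pool$mode == "discrete") pool$discrete_dp else format(pool$mean_dp)
  }
  sprintf(
    "(U%d)_%s-alt-(U%d)_%s",
    round(100 * acid_pool$u_fraction), dp_fmt(acid_pool),
    round(100 * diol_pool$u_fraction), dp_fmt(diol_pool)
  )
}
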