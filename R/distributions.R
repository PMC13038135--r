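#' Carothers' equation under stoichiometric imbalance
#'
#' At full conversion of the limiting functional group, a step-growth
#' oligomerization run with a stoichiometric imbalance ratio `r` (moles of
#' limiting per moles of excess functional group) caps the number-average
#' degree of polymerization at \eqn{\bar{DP} = (1+r)/(1-r)}.
#'
#' @param r Stoichiometric imbalance ratio, in `[0, 1)`.  `r = 0` is complete
#'   excess (all chains are single monomers); `r -> 1` is stoichiometric
#'   balance (unbounded chains).
#' @return The number-average degree of polymerization (monomers per chain),
#'   a value `>= 1`.
#' @seealso [imbalance_for_mean_dp()] for the inverse,
#'   [flory_odd_pmf()] for the full length distribution at imbalance `r`.
#' @examples
#' carothers_mean_dp(2 / 3)  # 5
#' carothers_mean_dp(9 / 11) # 10
#' @export
carothers_mean_dp <- function(r) {
  check_fraction(r, "r", open_upper = TRUE)
  (1 + r) / (1 - r)
}

#' Imbalance ratio that targets a mean oligomer length
#'
#' Inverts Carothers' equation: returns the stoichiometric imbalance ratio
#' `r` for which the number-average degree of polymerization at full
#' conversion equals `dp`.
#'
#' @param dp Target number-average degree of polymerization, `>= 1`.
#' @return The imbalance ratio `(dp - 1) / (dp + 1)`, in `[0, 1)`.
#' @examples
#' imbalance_for_mean_dp(5)  # 2/3
#' imbalance_for_mean_dp(10) # 9/11
#' @export
imbalance_for_mean_dp <- function(dp) {
  if (!is.numeric(dp) || any(!is.finite(dp)) || any(dp < 1)) {
    abort("`dp` must be a finite numeric >= 1.")
  }
  (dp - 1) / (dp + 1)
}

#' Flory most-probable distribution restricted to odd lengths
#'
#' Length law of telechelic oligomers made by AA/BB step growth under
#' stoichiometric imbalance: chains are capped by the excess monomer at both
#' ends, so every chain has an odd monomer count `x = 2k + 1`.  The
#' probability of a chain of `x` monomers is
#' \eqn{P_x = (1-r)\, r^{(x-1)/2}} for odd `x` (and 0 for even `x`), a
#' geometric law in the half-length `k` whose mean monomer count equals
#' Carothers' \eqn{(1+r)/(1-r)}.
#'
#' @param x Monomer counts (positive integers).  Even values get
#'   probability 0 by construction.
#' @param r Stoichiometric imbalance ratio in `[0, 1)`.
#' @return Probabilities, same length as `x`.
#' @examples
#' flory_odd_pmf(c(1, 2, 3), 2 / 3)
#' sum(flory_odd_pmf(seq(1, 399, by = 2), 2 / 3)) # ~1
#' @export
flory_odd_pmf <- function(x, r) {
  check_fraction(r, "r", open_upper = TRUE)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 1) || any(x != floor(x))) {
    abort("`x` must contain positive integers.")
  }
  p <- numeric(length(x))
  odd <- x %% 2 == 1
  p[odd] <- (1 - r) * r^((x[odd] - 1) / 2)
  p
}

#' Sample odd oligomer lengths from the imbalanced Flory law
#'
#' Inverse-transform sampler for [flory_odd_pmf()]: the half-length
#' `(x - 1) / 2` is geometric with success probability `1 - r`, so
#' `x = 2 * rgeom(n, 1 - r) + 1`.
#'
#' @param n Number of draws.
#' @param r Stoichiometric imbalance ratio in `[0, 1)`.
#' @return Integer vector of `n` odd monomer counts.
#' @examples
#' mean(sample_flory_odd(1e4, 2 / 3)) # ~5
#' @export
sample_flory_odd <- function(n, r) {
  check_fraction(r, "r", open_upper = TRUE)
  2L * rgeom(n, prob = 1 - r) + 1L
}

#' Standard Flory (most probable) distribution
#'
#' Chain-length law of ideal step growth at 1:1 functional-group
#' stoichiometry stopped at extent of reaction `p`:
#' \eqn{P_y = (1-p)\, p^{y-1}} for `y >= 1`, with mean `1 / (1 - p)`.
#' In the coupling step of a parallel-successive polymerization `y` counts
#' oligomers per polymer chain.
#'
#' @param y Chain lengths (positive integers).
#' @param p Extent of reaction in `[0, 1)`.
#' @return Probabilities, same length as `y`.
#' @examples
#' flory_pmf(2, 0.5) # 0.25
#' @export
flory_pmf <- function(y, p) {
  check_fraction(p, "p", open_upper = TRUE)
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 1) || any(y != floor(y))) {
    abort("`y` must contain positive integers.")
  }
  (1 - p) * p^(y - 1)
}

#' Sample chain lengths from the standard Flory law
#'
#' @param n Number of draws.
#' @param p Extent of reaction in `[0, 1)`.
#' @return Integer vector of `n` chain lengths `>= 1`, geometric with mean
#'   `1 / (1 - p)`.
#' @examples
#' mean(sample_flory(1e4, 0.9)) # ~10
#' @export
sample_flory <- function(n, p) {
  check_fraction(p, "p", open_upper = TRUE)
  rgeom(n, prob = 1 - p) + 1L
}

check_fraction <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    if (open_upper) all(x < 1) else all(x <= 1)
  if (!ok) {
    abort(sprintf(
      "`%s` must be numeric in [0, %s.", name,
      if (open_upper) "1)" else "1]"
    ))
  }
  invisible(x)
}
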