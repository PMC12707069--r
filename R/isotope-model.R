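#' Isotope signatures of new nitrogen inputs
#'
#' Constants of the plant--soil \eqn{^{15}}N mass balance: the per-mil
#' \eqn{\delta^{15}}N signature of newly fixed N\eqn{_2}
#' (`delta_bnf`, default \eqn{-2.02}) and of atmospheric N deposition
#' after canopy fractionation (`delta_dep`, default \eqn{1.5}, within the
#' observed \eqn{[-3, 3]} range). Both are treated as spatially constant.
#'
#' @param delta_bnf Per-mil signature of symbiotically fixed N.
#' @param delta_dep Per-mil signature of deposited N taken up by the canopy.
#' @return An object of class `isotope_constants` (a named list).
#' @export
#' @examples
#' isotope_constants()
isotope_constants <- function(delta_bnf = -2.02, delta_dep = 1.5) {
  stopifnot(is.numeric(delta_bnf), length(delta_bnf) == 1L, is.finite(delta_bnf),
            is.numeric(delta_dep), length(delta_dep) == 1L, is.finite(delta_dep))
  if (delta_dep < -3 || delta_dep > 3) {
    warning("delta_dep outside the observed [-3, 3] per-mil range")
  }
  structure(list(delta_bnf = delta_bnf, delta_dep = delta_dep),
            class = "isotope_constants")
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("Isotope signatures (per mil): delta_BNF =", x$delta_bnf,
      " delta_DEP =", x$delta_dep, "\n")
  invisible(x)
}

check_fractions <- function(f_bnfs, f_depd) {
  if (any(!is.finite(f_bnfs)) || any(!is.finite(f_depd))) {
    stop("f_bnfs and f_depd must be finite")
  }
  if (any(f_bnfs < 0) || any(f_depd < 0)) {
    stop("f_bnfs and f_depd must be non-negative")
  }
}

#' Forward plant delta15N from the steady-state mass balance
#'
#' Flux-weighted mixing of the three external N-acquisition pathways:
#' root/mycorrhizal uptake of soil mineral N (signature
#' \eqn{\delta_S - \varepsilon_U}), symbiotic fixation (\eqn{\delta_{BNF}})
#' and canopy uptake of deposition (\eqn{\delta_{DEP}}):
#' \deqn{\delta_P = (1 - f_{BNFs} - f_{DEPd})(\delta_S - \varepsilon_U)
#'   + f_{BNFs}\,\delta_{BNF} + f_{DEPd}\,\delta_{DEP}.}
#' Free-living fixation enters the soil pool directly and is implicit in the
#' uptake term. All arguments are vectorised and recycled.
#'
#' @param f_bnfs Fraction of symbiotic fixation in vegetation-external N demand.
#' @param f_depd Fraction of canopy deposition uptake in that demand.
#' @param eps_u Per-mil isotope fractionation of plant N uptake.
#' @param delta_s Soil delta15N (per mil).
#' @param constants An [isotope_constants()] object.
#' @return Plant delta15N (per mil), no observation noise.
#' @export
#' @examples
#' forward_delta_p(0.06, 0.1, 4.2, 4.8)
forward_delta_p <- function(f_bnfs, f_depd, eps_u, delta_s,
                            constants = isotope_constants()) {
  check_fractions(f_bnfs, f_depd)
  if (any(f_bnfs + f_depd > 1 + 1e-12)) {
    stop("f_bnfs + f_depd must not exceed 1")
  }
  stopifnot(all(is.finite(eps_u)), all(is.finite(delta_s)))
  (1 - f_bnfs - f_depd) * (delta_s - eps_u) +
    f_bnfs * constants$delta_bnf +
    f_depd * constants$delta_dep
}

#' Closed-form symbiotic fraction from a plant/soil isotope pair
#'
#' Inverts the mass balance for \eqn{f_{BNFs}} at a given uptake
#' fractionation and deposition fraction:
#' \deqn{f_{BNFs} = \frac{\delta_P - \delta_S + \varepsilon_U
#'   - f_{DEPd}(\delta_{DEP} - \delta_S + \varepsilon_U)}
#'   {\delta_{BNF} - \delta_S + \varepsilon_U}.}
#' Values outside \eqn{[0, 1 - f_{DEPd}]} are returned raw (the Bayesian
#' inversion applies physical constraints afterwards); callers may clip or
#' flag them. The solution is singular where
#' \eqn{\delta_S - \delta_{BNF} - \varepsilon_U = 0}.
#'
#' @param delta_p Plant delta15N (per mil).
#' @param delta_s Soil delta15N (per mil).
#' @param eps_u Per-mil fractionation of plant uptake.
#' @param f_depd Canopy deposition uptake fraction.
#' @inheritParams forward_delta_p
#' @param tol Denominators smaller than `tol` in absolute value error out.
#' @return The symbiotic fraction (possibly outside \eqn{[0, 1]}).
#' @export
#' @examples
#' solve_f_bnfs(0.8, 4.8, 4.2, 0.1)
solve_f_bnfs <- function(delta_p, delta_s, eps_u, f_depd = 0,
                         constants = isotope_constants(), tol = 1e-12) {
  stopifnot(all(is.finite(delta_p)), all(is.finite(delta_s)),
            all(is.finite(eps_u)), all(is.finite(f_depd)))
  den <- constants$delta_bnf - delta_s + eps_u
  if (any(abs(den) < tol)) {
    stop("singular configuration: delta_s - delta_bnf - eps_u is zero")
  }
  num <- delta_p - delta_s + eps_u -
    f_depd * (constants$delta_dep - delta_s + eps_u)
  num / den
}

#' Closed-form uptake fractionation from a plant/soil isotope pair
#'
#' Rearranges the mass balance for \eqn{\varepsilon_U} at given fractions:
#' \deqn{\varepsilon_U = \delta_S - \frac{\delta_P - f_{BNFs}\delta_{BNF}
#'   - f_{DEPd}\delta_{DEP}}{1 - f_{BNFs} - f_{DEPd}}.}
#' \eqn{\varepsilon_U} is strictly decreasing in \eqn{f_{BNFs}} exactly when
#' \eqn{(\delta_{BNF} - \delta_P) + f_{DEPd}(\delta_{DEP} - \delta_{BNF}) < 0},
#' which holds in almost all field configurations: ecosystems acquiring more N
#' by symbiotic fixation take up the rest via weakly fractionating pathways.
#'
#' @inheritParams solve_f_bnfs
#' @param f_bnfs Symbiotic fixation fraction.
#' @return The uptake fractionation (per mil).
#' @export
solve_eps_u <- function(delta_p, delta_s, f_bnfs, f_depd = 0,
                        constants = isotope_constants()) {
  check_fractions(f_bnfs, f_depd)
  rem <- 1 - f_bnfs - f_depd
  if (any(rem <= 0)) {
    stop("1 - f_bnfs - f_depd must be positive")
  }
  delta_s - (delta_p - f_bnfs * constants$delta_bnf -
               f_depd * constants$delta_dep) / rem
}

#' Validity screening of isotope pairs
#'
#' The mass balance cannot be inverted when the plant signature falls at or
#' below the fixation end-member (\eqn{\delta_P \le \delta_{BNF}}): such
#' pairs are flagged invalid and are excluded from regressions and
#' inversions. Two further conditions hold in most, but not all, natural
#' configurations and are reported as warnings rather than exclusions:
#' \eqn{\delta_S - \delta_{BNF} - \varepsilon_U > 0} and
#' \eqn{\delta_P - \delta_S < 0}.
#'
#' @inheritParams solve_f_bnfs
#' @param eps_u Uptake fractionation used for the warning-level check.
#' @return A tibble with columns `valid` (logical), `reason` (NA or
#'   "plant below fixation signature"), `warn_denominator` (TRUE when
#'   \eqn{\delta_S - \delta_{BNF} - \varepsilon_U \le 0}) and `warn_diff`
#'   (TRUE when \eqn{\delta_P - \delta_S \ge 0}).
#' @export
#' @examples
#' check_validity(c(0.8, -2.5), 4.8, 4.2)
check_validity <- function(delta_p, delta_s, eps_u,
                           constants = isotope_constants()) {
  n <- max(length(delta_p), length(delta_s), length(eps_u))
  delta_p <- rep_len(delta_p, n)
  delta_s <- rep_len(delta_s, n)
  eps_u <- rep_len(eps_u, n)
  valid <- delta_p > constants$delta_bnf
  tibble::tibble(
    valid = valid,
    reason = ifelse(valid, NA_character_, "plant below fixation signature"),
    warn_denominator = delta_s - constants$delta_bnf - eps_u <= 0,
    warn_diff = delta_p - delta_s >= 0
  )
}

#' Acquisition fractions from component fluxes
#'
#' Converts gross fluxes into the two acquisition fractions of the
#' vegetation-external N demand
#' \eqn{\beta_s I_{BNF} + \gamma_d I_{DEP} + U}:
#' \deqn{f_{BNFs} = \frac{\beta_s I_{BNF}}{\beta_s I_{BNF} + \gamma_d I_{DEP} + U},
#' \qquad
#' f_{DEPd} = \frac{\gamma_d I_{DEP}}{\beta_s I_{BNF} + \gamma_d I_{DEP} + U}.}
#'
#' @param i_bnf Total BNF flux (symbiotic + free-living), g N m-2 yr-1.
#' @param beta_s Symbiotic fraction of `i_bnf`, in (0, 1].
#' @param i_dep Total N deposition flux, g N m-2 yr-1.
#' @param gamma_d Canopy-uptake fraction of `i_dep`, in [0, 1].
#' @param u Root uptake of soil mineral N, g N m-2 yr-1.
#' @return A tibble with columns `f_bnfs` and `f_depd`.
#' @export
#' @examples
#' f_fractions_from_fluxes(1, 1, 0, 0, 9)
f_fractions_from_fluxes <- function(i_bnf, beta_s, i_dep, gamma_d, u) {
  stopifnot(all(i_bnf >= 0), all(i_dep >= 0), all(u >= 0),
            all(beta_s >= 0), all(beta_s <= 1),
            all(gamma_d >= 0), all(gamma_d <= 1))
  den <- beta_s * i_bnf + gamma_d * i_dep + u
  if (any(den <= 0)) {
    stop("vegetation-external N demand (denominator) must be positive")
  }
  tibble::tibble(
    f_bnfs = beta_s * i_bnf / den,
    f_depd = gamma_d * i_dep / den
  )
}
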