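#' Derived rates and scales
#'
#' Computes, for each parameter row, the quantities the theory is phrased in:
#' net growth rates `r_k = lambda_k - mu_k` per genotype; the establishment
#' probability of a single mutant lineage `p_m = max(0, r_m / lambda_m)`; the
#' critical time `t_star` an aneuploid lineage must survive (in expectation)
#' to spawn a resistant mutant lineage that escapes drift,
#' `T* = (1 / (2 lambda_a)) * sqrt(lambda_m / (v_a r_m))`; the dimensionless
#' product `ra_tstar = r_a * T*`, which measures how much an aneuploid
#' lineage's log-size changes over the critical time and decides the rescue
#' regime; and the pretreatment aneuploid fraction at
#' missegregation-selection balance, `f_standing = u_pre * lambda_s / c`.
#'
#' `t_star` uses the aneuploid mutation rate `v_a` so that elevated-mutation
#' scenarios stay consistent; with `v_a = v` it reduces to the standard
#' expression.
#'
#' @param params A `rescue_params` tibble (any number of rows).
#' @return A tibble with columns `r_s`, `r_a`, `r_m`, `p_m`, `t_star`,
#'   `ra_tstar`, `f_standing`, one row per parameter row.
#' @examples
#' derived_rates(rescue_preset("melanoma_a375"))
#' @export
derived_rates <- function(params) {
  validate_rescue_params(params, quiet = TRUE)
  r_s <- params$lambda_s - params$mu_s
  r_a <- params$lambda_a - params$mu_a
  r_m <- params$lambda_m - params$mu_m
  if (any(r_m <= 0)) {
    stop("mutant not resistant: lambda_m must exceed mu_m (r_m > 0)")
  }
  if (any(params$u_pre > 0 & params$c <= 0)) {
    stop("standing fraction undefined: c must be positive when u_pre > 0")
  }
  p_m <- pmax(0, r_m / params$lambda_m)
  t_star <- ifelse(params$v_a > 0,
                   sqrt(params$lambda_m / (params$v_a * r_m)) /
                     (2 * params$lambda_a),
                   Inf)
  f_standing <- ifelse(params$u_pre > 0,
                       params$u_pre * params$lambda_s / params$c, 0)
  if (any(f_standing >= 1)) {
    stop("standing aneuploid fraction f = u_pre*lambda_s/c must be < 1")
  }
  tibble::tibble(
    r_s = r_s, r_a = r_a, r_m = r_m, p_m = p_m,
    t_star = t_star, ra_tstar = r_a * t_star, f_standing = f_standing
  )
}

#' Classify the rescue regime
#'
#' Assigns each parameter row to one of four regimes that determine which
#' branch of the threshold-size and time formulas applies.
#'
#' Aneuploidy is too rare to matter -- regime `direct_mutation` -- when
#' `u == 0`, when `u * lambda_a * T* < 1`, or when aneuploids are both rare
#' (`u * lambda_a < -r_a`) and drug-sensitive (`r_a * T* < -1`); rescue then
#' proceeds by a direct resistance mutation in a sensitive cell. Otherwise
#' the sign and size of `r_a * T*` decides: `tolerant` (`r_a T* <= -1`,
#' aneuploids decline but more slowly than sensitive cells and act as a
#' stepping stone), `stationary` (`-1 < r_a T* < 1`, aneuploid lineages
#' hover near constant size), or `resistant` (`r_a T* >= 1`, aneuploidy
#' itself regrows the tumor). The asymptotic conditions ("much less/greater
#' than") are implemented as hard cutoffs at +/-1; the raw condition values
#' are returned so callers can apply stricter cutoffs.
#'
#' @param params A `rescue_params` tibble.
#' The `regime` column answers "which rescue route and formula branch
#' applies"; the `aneuploid_phenotype` column classifies the aneuploid cell
#' itself by `r_a * T*` alone (tolerant / stationary / resistant),
#' regardless of whether missegregation is frequent enough for that
#' phenotype to matter. The two differ exactly when aneuploids are too rare
#' to contribute: the TNBC SA1035/SA535 clones, for instance, carry a
#' strongly tolerant aneuploid phenotype (`r_a T* < -1000`) yet rescue
#' proceeds by direct mutation because `u lambda_a < -r_a`.
#'
#' @return A tibble with columns `regime` (factor with levels
#'   `direct_mutation`, `tolerant`, `stationary`, `resistant`),
#'   `aneuploid_phenotype` (factor: `tolerant`, `stationary`, `resistant`),
#'   `ra_tstar`, `u_lambda_a`, `u_lambda_a_tstar`, `neg_r_a` and
#'   `inv_t_star` (the numeric values the conditions were evaluated on).
#' @examples
#' classify_regime(rescue_preset("melanoma_a375"))
#' classify_regime(rescue_preset("melanoma_a375", lambda_a = 0.095))
#' @export
classify_regime <- function(params) {
  d <- derived_rates(params)
  u_la <- params$u * params$lambda_a
  direct <- params$u == 0 |
    u_la * d$t_star < 1 |
    (u_la < -d$r_a & d$ra_tstar < -1)
  phenotype <- ifelse(d$ra_tstar <= -1, "tolerant",
               ifelse(d$ra_tstar < 1, "stationary", "resistant"))
  regime <- ifelse(direct, "direct_mutation", phenotype)
  tibble::tibble(
    regime = factor(regime, levels = c("direct_mutation", "tolerant",
                                       "stationary", "resistant")),
    aneuploid_phenotype = factor(phenotype,
                                 levels = c("tolerant", "stationary",
                                            "resistant")),
    ra_tstar = d$ra_tstar,
    u_lambda_a = u_la,
    u_lambda_a_tstar = u_la * d$t_star,
    neg_r_a = -d$r_a,
    inv_t_star = 1 / d$t_star
  )
}
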