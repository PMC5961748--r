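#' Rheology models
#'
#' Blood viscosity models used by the network flow solver: a constant
#' (newtonian) viscosity, and the Carreau-Yasuda shear-thinning law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'   \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}}
#' which interpolates between the zero-shear viscosity \eqn{\mu_0} and the
#' infinite-shear viscosity \eqn{\mu_\infty}.
#'
#' @param mu,mu0,mu_inf viscosities in Pa s (`mu0 >= mu_inf > 0`).
#' @param lambda relaxation time in seconds.
#' @param a,n dimensionless Yasuda and power-law exponents (`n <= 1` for
#'   shear thinning).
#' @return an object of class `rheology_model`.
#' @examples
#' effective_viscosity(100, newtonian(3.5e-3))
#' effective_viscosity(0, default_blood_rheology())
#' @name rheology
NULL

#' @rdname rheology
#' @export
newtonian <- function(mu = 3.5e-3) {
  stopifnot(is.numeric(mu), mu > 0)
  structure(list(kind = "newtonian", mu = mu), class = "rheology_model")
}

#' @rdname rheology
#' @export
carreau_yasuda <- function(mu0, mu_inf, lambda, a, n) {
  stopifnot(mu0 > 0, mu_inf > 0, mu0 >= mu_inf, lambda >= 0, a > 0)
  if (n > 1) stop("`n` > 1 would make viscosity increase with shear rate")
  structure(list(kind = "carreau_yasuda", mu0 = mu0, mu_inf = mu_inf,
                 lambda = lambda, a = a, n = n), class = "rheology_model")
}

#' @rdname rheology
#' @details `default_blood_rheology()` loads the Carreau-Yasuda parameter set
#'   shipped in `inst/extdata/rheology_carreau_yasuda.json`. These are
#'   standard literature values for whole blood, not measurements from any
#'   single study this package reproduces.
#' @export
default_blood_rheology <- function() {
  path <- system.file("extdata", "rheology_carreau_yasuda.json",
                      package = "vaspol", mustWork = TRUE)
  p <- jsonlite::read_json(path)
  carreau_yasuda(p$mu0_pa_s, p$mu_inf_pa_s, p$lambda_s, p$a, p$n)
}

#' Effective viscosity at a given shear rate
#'
#' @param gamma_dot wall shear rate(s) in 1/s, all >= 0. Vectorized.
#' @param rheology a [rheology] model.
#' @return viscosity in Pa s, same length as `gamma_dot`.
#' @export
effective_viscosity <- function(gamma_dot, rheology) {
  stopifnot(inherits(rheology, "rheology_model"))
  if (any(gamma_dot < 0)) stop("shear rate must be >= 0")
  if (rheology$kind == "newtonian")
    return(rep(rheology$mu, length(gamma_dot)))
  with(rheology,
       mu_inf + (mu0 - mu_inf) * (1 + (lambda * gamma_dot)^a)^((n - 1) / a))
}
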