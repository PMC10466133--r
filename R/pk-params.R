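#' Structural pharmacokinetic parameters for one subject
#'
#' Builds and validates the parameter set of the three-compartment mammillary
#' model with an effect-site compartment: central clearance `CL` (L/min),
#' compartment volumes `V1`--`V3` (L), inter-compartmental clearances `Q2`,
#' `Q3` (L/min) and the effect-site equilibration rate constant `ke0` (1/min).
#'
#' @param CL central (elimination) clearance, L/min.
#' @param V1,V2,V3 central and peripheral volumes of distribution, L.
#' @param Q2,Q3 inter-compartmental clearances, L/min.
#' @param ke0 effect-site elimination rate constant, 1/min.
#' @return An object of class `pk_params` (a validated named list).
#' @examples
#' pk_params(CL = 1.79, V1 = 6.28, V2 = 25.5, V3 = 273,
#'           Q2 = 1.75, Q3 = 1.11, ke0 = 0.146)
#' @export
pk_params <- function(CL, V1, V2, V3, Q2, Q3, ke0) {
  p <- list(CL = CL, V1 = V1, V2 = V2, V3 = V3, Q2 = Q2, Q3 = Q3, ke0 = ke0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("pk_params: field '", nm, "' must be a single finite positive number",
           call. = FALSE)
  }
  structure(p, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params>  CL", x$CL, "L/min | V1/V2/V3", x$V1, "/", x$V2, "/", x$V3,
      "L | Q2/Q3", x$Q2, "/", x$Q3, "L/min | ke0", x$ke0, "/min\n")
  invisible(x)
}

.pk_param_names <- c("CL", "V1", "V2", "V3", "Q2", "Q3", "ke0")

#' Derive first-order micro-constants from structural parameters
#'
#' Converts the volume/clearance parameterization into the first-order rate
#' constants of the mammillary model: `k10 = CL/V1`, `k12 = Q2/V1`,
#' `k21 = Q2/V2`, `k13 = Q3/V1`, `k31 = Q3/V3`, and the effect-site pair
#' `k41 = ke0`, `k14 = ke0/10000` (the effect compartment exchanges
#' concentration, not mass; `k14` is retained for completeness but carries no
#' mass flux in the state equations).
#'
#' @param params a [pk_params()] object.
#' @return An object of class `rate_constants`: named list of rates (1/min)
#'   plus the central volume `V1` needed to convert amount to concentration.
#' @examples
#' derive_rate_constants(pk_params(1, 10, 20, 30, 0.5, 0.3, 0.2))
#' @export
derive_rate_constants <- function(params) {
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  rc <- list(
    k10 = params$CL / params$V1,
    k12 = params$Q2 / params$V1,
    k21 = params$Q2 / params$V2,
    k13 = params$Q3 / params$V1,
    k31 = params$Q3 / params$V3,
    k41 = params$ke0,
    k14 = params$ke0 / 10000,
    V1  = params$V1
  )
  structure(rc, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants> (1/min)\n")
  print(unlist(x[c("k10", "k12", "k21", "k13", "k31", "k41", "k14")]))
  invisible(x)
}

# System matrix for state (A1, A2, A3, C4); row 4 couples plasma concentration
# A1/V1 into the effect site with no reverse mass transfer.
pk_matrix <- function(rc) {
  matrix(c(
    -(rc$k10 + rc$k12 + rc$k13), rc$k21, rc$k31, 0,
    rc$k12, -rc$k21, 0, 0,
    rc$k13, 0, -rc$k31, 0,
    rc$k41 / rc$V1, 0, 0, -rc$k41
  ), nrow = 4, byrow = TRUE)
}
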