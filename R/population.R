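#' Population pharmacokinetic model
#'
#' Population means of the structural parameters together with the
#' inter-individual variability (log-scale standard deviations `omega`) and
#' the residual-error (intra-individual) terms of the combined
#' additive/proportional model.
#'
#' @param means a [pk_params()] object: population values `PAR_k`.
#' @param omegas named numeric vector of log-scale SDs, one per parameter in
#'   `c("CL","V1","V2","V3","Q2","Q3","ke0")`; missing names default to 0 (a
#'   parameter with `omega = 0` is fixed at its population value).
#' @param prop proportional residual-error term, dimensionless (`>= 0`).
#' @param add additive residual-error term, mg/L (`>= 0`).
#' @return Object of class `population_model`.
#' @examples
#' population_model(pk_params(1.79, 6.28, 25.5, 273, 1.75, 1.11, 0.146),
#'                  omegas = c(CL = 0.5, V1 = 0.8), prop = 0.19, add = 0.02)
#' @export
population_model <- function(means, omegas = NULL, prop = 0, add = 0) {
  if (!inherits(means, "pk_params")) means <- do.call(pk_params, as.list(means))
  om <- setNames(rep(0, length(.pk_param_names)), .pk_param_names)
  if (length(omegas)) {
    bad <- setdiff(names(omegas), .pk_param_names)
    if (length(bad)) stop("population_model: unknown omega name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    om[names(omegas)] <- as.numeric(omegas)
  }
  if (any(om < 0)) stop("population_model: omegas must be >= 0", call. = FALSE)
  if (prop < 0 || add < 0) stop("population_model: prop and add must be >= 0", call. = FALSE)
  structure(list(means = means, omegas = om, prop = prop, add = add),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model>\n  means: "); print(x$means)
  cat("  omegas (log-scale SD):\n"); print(x$omegas)
  cat("  residual error: prop =", x$prop, ", add =", x$add, "mg/L\n")
  invisible(x)
}

#' Draw one virtual subject from the population
#'
#' Each random effect `eta_k` is drawn independently from `N(0, omega_k^2)`
#' and the individual parameter is `PAR_k * exp(eta_k)` — a log-normal
#' inter-individual model whose median equals the population value.
#'
#' @param pop a [population_model()].
#' @param subject_id label for the subject.
#' @param demographics named list (age, weight_kg, height_cm, sex); metadata
#'   only, not used in parameter computation.
#' @return Object of class `virtual_subject` with fields `subject_id`,
#'   `demographics`, `etas` and `params`.
#' @export
sample_subject <- function(pop, subject_id = "S1", demographics = NULL) {
  etas <- setNames(rnorm(length(pop$omegas), 0, pop$omegas), names(pop$omegas))
  subject_from_etas(pop, etas, subject_id, demographics)
}

subject_from_etas <- function(pop, etas, subject_id, demographics = NULL) {
  pv <- unlist(pop$means[.pk_param_names]) * exp(etas[.pk_param_names])
  structure(list(subject_id = subject_id,
                 demographics = demographics,
                 etas = etas,
                 params = do.call(pk_params, as.list(pv))),
            class = "virtual_subject")
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat("<virtual_subject>", x$subject_id, "\n  ")
  print(x$params)
  invisible(x)
}

#' Generate a reproducible virtual cohort
#'
#' Draws `n` subjects from the population. All random effects for the cohort
#' come from one seeded stream drawn as a single block in subject-major
#' order, so membership does not depend on evaluation order and an identical
#' `(pop, n, seed)` triple reproduces the cohort bit-for-bit.
#'
#' @param pop a [population_model()].
#' @param n cohort size (`>= 1`).
#' @param seed integer RNG seed.
#' @param demographics shared demographics list (the trial cohort is
#'   demographically homogeneous).
#' @return Object of class `pk_cohort`: list with `subjects` (list of
#'   [sample_subject()] results), `seed`, `population`.
#' @examples
#' pop <- population_model(pk_params(1.79, 6.28, 25.5, 273, 1.75, 1.11, 0.146),
#'                         omegas = c(CL = 0.5))
#' coh <- generate_cohort(pop, n = 5, seed = 1)
#' @export
generate_cohort <- function(pop, n, seed,
                            demographics = list(age = 36, weight_kg = 70,
                                                height_cm = 170, sex = "female")) {
  if (n < 1) stop("generate_cohort: n must be >= 1", call. = FALSE)
  K <- length(pop$omegas)
  eta_mat <- withr::with_seed(as.integer(seed), {
    matrix(rnorm(n * K, 0, rep(pop$omegas, each = n)), nrow = n)
  })
  colnames(eta_mat) <- names(pop$omegas)
  ids <- sprintf("S%04d", seq_len(n))
  subjects <- lapply(seq_len(n), function(j)
    subject_from_etas(pop, eta_mat[j, ], ids[j], demographics))
  structure(list(subjects = subjects, seed = as.integer(seed), population = pop),
            class = "pk_cohort")
}

#' @export
print.pk_cohort <- function(x, ...) {
  cat("<pk_cohort> ", length(x$subjects), " subject(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Cohort as a data frame
#'
#' One row per subject: id, demographics, individual parameters and the
#' underlying random effects (`eta_*` columns).
#' @param x a `pk_cohort`.
#' @param ... unused.
#' @export
as.data.frame.pk_cohort <- function(x, ...) {
  subs <- x$subjects
  d <- subs[[1]]$demographics
  pmat <- t(vapply(subs, function(s) unlist(s$params), numeric(7)))
  emat <- t(vapply(subs, function(s) s$etas, numeric(length(subs[[1]]$etas))))
  colnames(emat) <- paste0("eta_", names(subs[[1]]$etas))
  data.frame(subject_id = vapply(subs, `[[`, "", "subject_id"),
             age = d$age %||% NA, weight_kg = d$weight_kg %||% NA,
             height_cm = d$height_cm %||% NA, sex = d$sex %||% NA,
             pmat, emat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort parameter table as CSV
#' @param cohort a `pk_cohort`.
#' @param path CSV path.
#' @return the path (write) or a data frame (read), one row per subject.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) read.csv(path)

#' Apply the combined residual-error model to a true concentration
#'
#' Observed value `Y = C + sqrt(prop^2 C^2 + add^2) * eps`, `eps ~ N(0,1)`:
#' proportional and additive error components combine in variance, so
#' `prop = 0` gives a purely additive model with SD `add` and `add = 0` a
#' purely proportional model with SD `prop * C`. Values may come back
#' negative — they are raw sensor readings; clipping is a consumer decision.
#'
#' @param C true concentration(s), mg/L (`>= 0`).
#' @param pop a [population_model()] supplying `prop` and `add`.
#' @return observed concentration(s) `Y`, mg/L.
#' @export
apply_residual_error <- function(C, pop) {
  if (any(C < 0)) stop("apply_residual_error: C must be >= 0", call. = FALSE)
  C + residual_sd(C, pop) * rnorm(length(C))
}

residual_sd <- function(C, pop) sqrt(pop$prop^2 * C^2 + pop$add^2)
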