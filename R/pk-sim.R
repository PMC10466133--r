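#' Right-hand side of the compartmental state equations
#'
#' Time-derivatives of the state `(A1, A2, A3, C4)`:
#' \deqn{dA_1/dt = A_2 k_{21} + A_3 k_{31} - A_1 (k_{10}+k_{12}+k_{13}) + U(t)}
#' \deqn{dA_2/dt = A_1 k_{12} - A_2 k_{21}}
#' \deqn{dA_3/dt = A_1 k_{13} - A_3 k_{31}}
#' \deqn{dC_4/dt = (C_1 - C_4) k_{e0}, \quad C_1 = A_1/V_1}
#' The effect site is massless: no drug amount is removed from the central
#' compartment through the effect-site coupling.
#'
#' @param state numeric vector `(A1, A2, A3, C4)` (mg, mg, mg, mg/L).
#' @param rc a [derive_rate_constants()] object.
#' @param U infusion rate at this instant, mg/min.
#' @return numeric vector of the four derivatives.
#' @export
pk_rhs <- function(state, rc, U) {
  A1 <- state[[1]]; A2 <- state[[2]]; A3 <- state[[3]]; C4 <- state[[4]]
  C1 <- A1 / rc$V1
  c(A2 * rc$k21 + A3 * rc$k31 - A1 * (rc$k10 + rc$k12 + rc$k13) + U,
    A1 * rc$k12 - A2 * rc$k21,
    A1 * rc$k13 - A3 * rc$k31,
    (C1 - C4) * rc$k41)
}

#' Simulate the compartmental model under a piecewise-constant infusion
#'
#' Integrates the state equations with an adaptive stiff-capable solver
#' ([deSolve::lsoda()], relative tolerance `1e-8`), restarting the integration
#' at every infusion breakpoint so that rate discontinuities never cross a
#' solver step. A cumulative-elimination state is integrated alongside, so
#' mass balance can be audited at solver accuracy.
#'
#' @param params a [pk_params()] object (the subject's true parameters).
#' @param infusion an [infusion_profile()].
#' @param grid output times, min; non-negative, strictly increasing, within
#'   the profile span.
#' @param init initial state `(A1, A2, A3, C4)`; default drug-naive (all 0).
#' @param rtol,atol solver tolerances.
#' @return A `pk_trajectory`: data frame with columns `time`, `A1`, `A2`,
#'   `A3` (mg), `C1`, `C2`, `C3`, `C4` (mg/L), `eliminated` (cumulative mg
#'   cleared) and `U` (mg/min), with the parameters attached as an attribute.
#' @examples
#' p <- pk_params(1.79, 6.28, 25.5, 273, 1.75, 1.11, 0.146)
#' prof <- infusion_profile(c(0, 2), c(100, 10), end = 20)
#' traj <- simulate_pk(p, prof, grid = seq(0, 20, 0.5))
#' @export
simulate_pk <- function(params, infusion, grid, init = c(0, 0, 0, 0),
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(infusion, "infusion_profile"))
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("simulate_pk: grid must be strictly increasing", call. = FALSE)
  if (min(grid) < 0 || max(grid) > infusion$end + 1e-9)
    stop("simulate_pk: grid outside the infusion profile span", call. = FALSE)
  if (length(init) != 4L || any(init < 0))
    stop("simulate_pk: init must be four non-negative values", call. = FALSE)

  rc <- derive_rate_constants(params)
  deriv <- function(t, y, parms) {
    d <- pk_rhs(y[1:4], rc, parms$U)
    list(c(d, y[1] * rc$k10))   # 5th state: cumulative eliminated amount
  }

  seg <- profile_segments(infusion, max(grid))
  y <- c(as.numeric(init), 0)
  out_t <- numeric(0); out_y <- NULL; out_u <- numeric(0)
  if (grid[1] == 0) {
    out_t <- 0; out_y <- matrix(y, nrow = 1); out_u <- rate_at(infusion, 0)
  }
  for (i in seq_along(seg$rates)) {
    t0 <- seg$bounds[i]; t1 <- seg$bounds[i + 1]
    inner <- grid[grid > t0 + 1e-12 & grid <= t1 + 1e-12]
    tt <- sort(unique(c(t0, inner, t1)))
    sol <- deSolve::lsoda(y, tt, deriv, parms = list(U = seg$rates[i]),
                          rtol = rtol, atol = atol)
    y <- as.numeric(sol[nrow(sol), -1])
    if (length(inner)) {
      rows <- match(round(inner, 12), round(tt, 12))
      out_t <- c(out_t, inner)
      out_y <- rbind(out_y, unname(sol[rows, -1, drop = FALSE]))
      out_u <- c(out_u, rate_at(infusion, inner))
    }
    if (t1 >= max(grid)) break
  }
  traj <- data.frame(time = out_t,
                     A1 = out_y[, 1], A2 = out_y[, 2], A3 = out_y[, 3],
                     C1 = out_y[, 1] / params$V1, C2 = out_y[, 2] / params$V2,
                     C3 = out_y[, 3] / params$V3, C4 = out_y[, 4],
                     eliminated = out_y[, 5], U = out_u)
  attr(traj, "params") <- params
  attr(traj, "infusion") <- infusion
  class(traj) <- c("pk_trajectory", "data.frame")
  traj
}

#' Closed-form solution under a constant infusion rate
#'
#' Independent analytic solution of the same linear system, via
#' eigendecomposition of the system matrix (with a scaled Taylor-series matrix
#' exponential as fallback when the eigenvector basis is ill-conditioned).
#' Shares no code with the numerical integrator; serves as its oracle.
#'
#' @param params a [pk_params()] object.
#' @param U constant infusion rate, mg/min (`>= 0`).
#' @param t time(s), min.
#' @param init initial state `(A1, A2, A3, C4)`.
#' @return data frame with columns `time`, `A1`, `A2`, `A3`, `C4`, `C1`.
#' @export
analytic_constant_infusion <- function(params, U, t, init = c(0, 0, 0, 0)) {
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  if (U < 0) stop("analytic_constant_infusion: U must be >= 0", call. = FALSE)
  rc <- derive_rate_constants(params)
  M <- pk_matrix(rc)
  b <- c(U, 0, 0, 0)
  xss <- solve(M, -b)              # M is invertible: k10 > 0
  x0 <- as.numeric(init)

  eg <- eigen(M)
  V <- eg$vectors
  use_eigen <- is.double(rcond_ok <- tryCatch(rcond(V), error = function(e) 0)) &&
    rcond_ok > 1e-8 && all(abs(Im(eg$values)) < 1e-12 * (1 + max(abs(eg$values))))
  sol_one <- function(tt) {
    if (use_eigen) {
      lam <- Re(eg$values)
      w <- solve(V, x0 - xss)
      Re(V %*% (exp(lam * tt) * w)) + xss
    } else {
      expm_taylor(M * tt) %*% (x0 - xss) + xss
    }
  }
  out <- t(vapply(t, function(tt) as.numeric(sol_one(tt)), numeric(4)))
  data.frame(time = t, A1 = out[, 1], A2 = out[, 2], A3 = out[, 3],
             C4 = out[, 4], C1 = out[, 1] / params$V1)
}

# scaling-and-squaring Taylor matrix exponential (fallback for defective or
# ill-conditioned eigenbases)
expm_taylor <- function(A, order = 16L) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Convert compartment amounts to concentrations
#'
#' Divides each amount column by its volume of distribution
#' (`C_i = A_i / V_i`); the effect-site series `C4` is already a
#' concentration and passes through unchanged.
#'
#' @param traj a `pk_trajectory` or data frame with columns `A1`, `A2`, `A3`
#'   (and optionally `C4`).
#' @param params a [pk_params()] object supplying `V1`, `V2`, `V3`.
#' @return data frame with columns `time` (if present), `C1`, `C2`, `C3`,
#'   `C4` (if present), mg/L.
#' @export
amounts_to_concentrations <- function(traj, params) {
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  out <- data.frame(C1 = traj$A1 / params$V1,
                    C2 = traj$A2 / params$V2,
                    C3 = traj$A3 / params$V3)
  if (!is.null(traj$time)) out <- cbind(time = traj$time, out)
  if (!is.null(traj$C4)) out$C4 <- traj$C4
  out
}

#' Export a trajectory as CSV
#'
#' Columns `time_min`, `A1_mg`, `A2_mg`, `A3_mg`, `C1_mg_per_L`,
#' `C4_mg_per_L`, `U_mg_per_min`.
#' @param traj a `pk_trajectory`.
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_min = traj$time, A1_mg = traj$A1, A2_mg = traj$A2,
                   A3_mg = traj$A3, C1_mg_per_L = traj$C1,
                   C4_mg_per_L = traj$C4, U_mg_per_min = traj$U)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# fast exact trajectory of the same system via the C++ matrix-exponential
# propagator; used by the controller and the trial engine
propagate_exact <- function(params, infusion, grid, init = c(0, 0, 0, 0)) {
  rc <- derive_rate_constants(params)
  seg <- profile_segments(infusion, max(max(grid), infusion$end))
  st <- cpp_pw_states(pk_matrix(rc), as.numeric(init), seg$bounds, seg$rates,
                      as.numeric(grid))
  data.frame(time = as.numeric(grid),
             A1 = st[1, ], A2 = st[2, ], A3 = st[3, ],
             C1 = st[1, ] / params$V1, C4 = st[4, ],
             U = rate_at(infusion, as.numeric(grid)))
}
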