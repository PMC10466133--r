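#' Piecewise-constant infusion profile
#'
#' A delivery-rate schedule U(t): rate `rates[i]` (mg/min) applies on
#' `[times[i], times[i+1])`, the last interval ending at `end`.
#'
#' @param times segment start times, min; strictly increasing, first must be 0.
#' @param rates delivery rate per segment, mg/min; all `>= 0`.
#' @param end profile end time, min; `> max(times)`.
#' @return Object of class `infusion_profile`.
#' @examples
#' infusion_profile(c(0, 2), c(10, 0), end = 30)
#' @export
infusion_profile <- function(times, rates, end) {
  if (length(times) != length(rates))
    stop("infusion_profile: times and rates must have equal length", call. = FALSE)
  if (length(times) == 0L) stop("infusion_profile: empty profile", call. = FALSE)
  if (times[1] != 0) stop("infusion_profile: profile must start at t = 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("infusion_profile: times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("infusion_profile: rates must be finite and >= 0", call. = FALSE)
  if (!is.finite(end) || end <= times[length(times)])
    stop("infusion_profile: end must exceed the last breakpoint", call. = FALSE)
  structure(list(times = as.numeric(times), rates = as.numeric(rates),
                 end = as.numeric(end)), class = "infusion_profile")
}

#' @export
print.infusion_profile <- function(x, ...) {
  cat("<infusion_profile> ", length(x$rates), " segment(s) over [0, ", x$end,
      "] min, rates in [", min(x$rates), ", ", max(x$rates), "] mg/min\n", sep = "")
  invisible(x)
}

#' Delivery rate at given times
#' @param profile an [infusion_profile()].
#' @param t times, min.
#' @return rates at `t` (0 beyond `end`), mg/min.
#' @export
rate_at <- function(profile, t) {
  idx <- findInterval(t, profile$times)
  r <- ifelse(idx >= 1, profile$rates[pmax(idx, 1L)], 0)
  r[t >= profile$end | t < 0] <- 0
  r
}

#' Total drug delivered by a profile
#' @param profile an [infusion_profile()].
#' @param until integrate up to this time, min (default: profile end).
#' @return delivered amount, mg.
#' @export
total_infused <- function(profile, until = profile$end) {
  b <- c(profile$times, profile$end)
  b <- pmin(b, until)
  sum(profile$rates * pmax(diff(b), 0))
}

# segment boundaries covering [0, t_end] (zero-rate tail appended past the
# profile end), with one rate per segment; used by the solvers
profile_segments <- function(profile, t_end) {
  keep <- which(profile$times < t_end)
  starts <- profile$times[keep]
  rates <- profile$rates[keep]
  last_end <- min(profile$end, t_end)
  bounds <- c(starts, last_end)
  if (t_end > profile$end) {
    bounds <- c(bounds, t_end)
    rates <- c(rates, 0)
  }
  list(bounds = bounds, rates = rates)
}

#' Write / read an infusion profile as two-column CSV
#'
#' Columns `t_start_min`, `rate_mg_per_min`; the profile end time is stored as
#' a final row with rate `NA`.
#' @param profile an [infusion_profile()].
#' @param path CSV file path.
#' @return `write_infusion_csv` the path, invisibly; `read_infusion_csv` an
#'   [infusion_profile()].
#' @export
write_infusion_csv <- function(profile, path) {
  df <- data.frame(t_start_min = c(profile$times, profile$end),
                   rate_mg_per_min = c(profile$rates, NA))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_infusion_csv
#' @export
read_infusion_csv <- function(path) {
  df <- read.csv(path)
  n <- nrow(df)
  infusion_profile(df$t_start_min[-n], df$rate_mg_per_min[-n], end = df$t_start_min[n])
}
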