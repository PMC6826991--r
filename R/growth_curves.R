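# Logistic growth-curve fitting: intensity time series -> cell
# proliferation parameters (CPPs) K, r, L.

#' Classify a culture as no-growth
#'
#' A culture is no-growth when its maximum intensity stays below
#' `min_final_intensity`, or when the fold change from the initial
#' measurement stays below `min_fold_change` (both strict inequalities, so
#' a series exactly at a threshold counts as growth).
#'
#' @param intensities intensity series, non-negative.
#' @param min_fold_change minimum max/initial intensity ratio for growth.
#' @param min_final_intensity minimum maximum intensity for growth; when
#'   fitting whole plates, [fit_cpp_table()] sets this to 5% of the
#'   plate-median final intensity.
#' @return logical flag.
#' @export
classify_no_growth <- function(intensities, min_fold_change = 1.5,
                               min_final_intensity = 5) {
  mx <- max(intensities)
  if (mx < min_final_intensity) return(TRUE)
  init <- max(intensities[1], 1e-8)
  mx / init < min_fold_change
}

# initial values from the data: K from the max, L from the half-max
# crossing, r from a logit-line regression over the interior points
.logistic_init <- function(times, y, K0) {
  p <- pmin(pmax(y / K0, 0.02), 0.98)
  lg <- log(p / (1 - p))
  use <- p > 0.05 & p < 0.95
  if (sum(use) < 2) use <- rep(TRUE, length(times))
  cf <- stats::coef(stats::lm(lg[use] ~ times[use]))
  r0 <- cf[[2]]
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.2
  l0 <- -cf[[1]] / r0
  # fall back to interpolated half-max crossing when the logit line is poor
  if (!is.finite(l0) || l0 < min(times) - 24 || l0 > 2 * max(times)) {
    above <- which(y >= K0 / 2)
    l0 <- if (length(above)) times[above[1]] else stats::median(times)
  }
  c(K = K0, r = min(r0, 9), l = l0)
}

#' Fit the logistic growth model to one intensity time series
#'
#' Least-squares fit of `G(t) = K / (1 + exp(-r (t - l)))` (see
#' [logistic_growth()]), assuming the starting intensity is below the
#' carrying capacity. Initial values come from the series itself (K from
#' the maximum, r and l from a logit-line regression); fitting uses
#' Levenberg-Marquardt with box constraints and, on failure, up to
#' `n_restarts` deterministic jittered restarts.
#'
#' @param times strictly increasing time vector (hours), length >= 4.
#' @param intensities non-negative intensity vector aligned with `times`.
#' @param min_fold_change,min_final_intensity no-growth thresholds, see
#'   [classify_no_growth()].
#' @param n_restarts jittered restarts attempted on non-convergence.
#' @param seed integer seed for the restart jitter (deterministic).
#' @param background `"none"` (default) fits intensities as-is; `"min2"`
#'   subtracts the minimum of the first two timepoints first, for real
#'   plate data carrying an agar background the 3-parameter logistic
#'   cannot absorb.
#' @return one-row data.table: `K`, `r`, `L` (CPPs; `K = r = 0`, `L = NA`
#'   for no-growth cultures), `rss`, `converged`, `no_growth`.
#' @export
fit_logistic <- function(times, intensities,
                         min_fold_change = 1.5, min_final_intensity = 5,
                         n_restarts = 5L, seed = 1L,
                         background = c("none", "min2")) {
  background <- match.arg(background)
  if (length(times) < 4) stop("need >= 4 timepoints to fit 3 parameters")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(times) != length(intensities))
    stop("times and intensities must align")
  y <- intensities
  if (background == "min2") y <- y - min(y[1:2])

  if (classify_no_growth(y, min_fold_change, min_final_intensity)) {
    return(data.table::data.table(K = 0, r = 0, L = NA_real_,
                                  rss = NA_real_, converged = TRUE,
                                  no_growth = TRUE))
  }

  K0 <- max(y)
  lower <- c(1e-6, 1e-4, -24)
  upper <- c(2 * K0, 10, 2 * max(times))
  start <- .logistic_init(times, y, K0)
  start <- pmin(pmax(start, lower + 1e-8), upper - 1e-8)

  fit1 <- function(st) {
    tryCatch({
      f <- minpack.lm::nlsLM(
        y ~ K / (1 + exp(-r * (times - l))),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 100))
      cf <- stats::coef(f)
      list(K = cf[["K"]], r = cf[["r"]], L = cf[["l"]],
           rss = sum(stats::resid(f)^2), ok = TRUE)
    }, error = function(e) NULL)
  }

  best <- fit1(start)
  if (is.null(best)) {
    jitters <- with_seed(seed, replicate(n_restarts, runif(3, 0.5, 1.5)))
    for (i in seq_len(n_restarts)) {
      st <- pmin(pmax(start * jitters[, i], lower + 1e-8), upper - 1e-8)
      best <- fit1(st)
      if (!is.null(best)) break
    }
  }
  if (is.null(best)) {
    return(data.table::data.table(K = start[["K"]], r = start[["r"]],
                                  L = start[["l"]], rss = NA_real_,
                                  converged = FALSE, no_growth = FALSE))
  }
  data.table::data.table(K = best$K, r = best$r, L = best$L, rss = best$rss,
                         converged = TRUE, no_growth = FALSE)
}

#' Fit logistic curves to every culture in a long-format time series table
#'
#' Groups the table by culture (plate, row, col, strain, drug, dose) and
#' fits each series with [fit_logistic()]. The no-growth intensity floor is
#' set per plate to `0.05 *` the plate-median final-timepoint intensity,
#' which separates blank spots from slow growers without an absolute unit
#' convention.
#'
#' @param timeseries data.table/data.frame with columns `plate, row, col,
#'   strain, drug, dose, time_h, intensity` (a `strain_class` column is
#'   carried through if present, otherwise inferred via
#'   [infer_strain_class()]).
#' @param min_fold_change see [classify_no_growth()].
#' @param background see [fit_logistic()].
#' @return CPP table (data.table): `strain, strain_class, drug, dose, plate,
#'   row, col, K, r, L, rss, converged, no_growth`.
#' @export
fit_cpp_table <- function(timeseries, min_fold_change = 1.5,
                          background = c("none", "min2")) {
  background <- match.arg(background)
  ts <- data.table::as.data.table(timeseries)
  need <- c("plate", "row", "col", "strain", "drug", "dose", "time_h",
            "intensity")
  miss <- setdiff(need, names(ts))
  if (length(miss)) stop("timeseries missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"strain_class" %in% names(ts))
    ts[, strain_class := infer_strain_class(strain)]

  # plate-level no-growth floor: 5% of the median final intensity
  finals <- ts[, .(final = intensity[which.max(time_h)]),
               by = .(plate, dose, row, col)]
  floors <- finals[, .(floor = 0.05 * stats::median(final)), by = plate]
  ts <- floors[ts, on = "plate"]

  data.table::setorder(ts, drug, plate, row, col, dose, time_h)
  fits <- ts[, fit_logistic(time_h, intensity,
                            min_fold_change = min_fold_change,
                            min_final_intensity = floor[1],
                            seed = string_seed(paste(strain[1], dose[1])),
                            background = background),
             by = .(strain, strain_class, drug, dose, plate, row, col)]
  fits[]
}
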