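#' Normalize luminescence traces to their initial timepoint
#'
#' Subtracts, within each sample/run/replicate trace, the relative light
#' units measured at the earliest timepoint, so every trace starts at 0.
#'
#' @param curves Tibble with columns `sample_id`, `run_id`, `time_h`,
#'   `replicate`, `rlu`.
#' @return The same tibble with `rlu` replaced by the normalized values.
#' @export
normalize_luminescence <- function(curves) {
  curves |>
    group_by(.data$sample_id, .data$run_id, .data$replicate) |>
    mutate(rlu = .data$rlu - .data$rlu[which.min(.data$time_h)]) |>
    ungroup()
}

spline_basis <- function(times, knots) {
  X <- cbind(1, times)
  for (k in knots) X <- cbind(X, pmax(times - k, 0))
  colnames(X) <- c("(Intercept)", "time", paste0("hinge_", knots))
  X
}

#' Fit a continuous piecewise-linear (linear spline) model
#'
#' Least-squares fit of a continuous piecewise-linear function with the
#' given interior knots, via a truncated-power (hinge) basis.
#'
#' @param times,values Observation times and responses (replicates appear as
#'   repeated times).
#' @param knots Knot positions, strictly inside the time range. Defaults to
#'   all interior unique timepoints, making the fit the maximum-flexibility
#'   piecewise-linear curve through the per-timepoint replicate means.
#' @return A `linear_spline` object with elements `coef`, `knots`, `times`,
#'   `values`, `fitted`, `residuals`.
#' @export
fit_linear_spline <- function(times, values, knots = NULL) {
  if (length(times) != length(values)) abort("`times` and `values` differ in length.")
  ut <- sort(unique(times))
  if (length(ut) < 2) abort("At least 2 distinct timepoints are required.")
  knots <- knots %||% ut[-c(1, length(ut))]
  if (length(knots) && (min(knots) <= min(ut) || max(knots) >= max(ut))) {
    abort("Knots must lie strictly inside the time range.")
  }
  X <- spline_basis(times, knots)
  if (length(values) < ncol(X)) {
    abort("Fewer observations than spline parameters.")
  }
  fit <- lm.fit(X, values)
  structure(
    list(coef = fit$coefficients, knots = knots, times = times,
         values = values, fitted = fit$fitted.values,
         residuals = fit$residuals),
    class = "linear_spline"
  )
}

#' @export
predict.linear_spline <- function(object, newtimes = NULL, ...) {
  newtimes <- newtimes %||% object$times
  drop(spline_basis(newtimes, object$knots) %*% object$coef)
}

#' @export
print.linear_spline <- function(x, ...) {
  cat(sprintf("<linear_spline> %d obs, %d knots, sigma %.4g\n",
              length(x$values), length(x$knots),
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy linear_spline
#' @export
tidy.linear_spline <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @importFrom generics glance
#' @method glance linear_spline
#' @export
glance.linear_spline <- function(x, ...) {
  tss <- sum((x$values - mean(x$values))^2)
  rss <- sum(x$residuals^2)
  dfres <- length(x$values) - length(x$coef)
  tibble(
    r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
    sigma = if (dfres > 0) sqrt(rss / dfres) else NA_real_,
    df.residual = dfres,
    nobs = length(x$values)
  )
}

trapezoid_area <- function(times, values) {
  o <- order(times)
  t <- times[o]; v <- values[o]
  sum((head(v, -1) + tail(v, -1)) / 2 * diff(t))
}

#' Area under a curve by the trapezoid rule
#'
#' Sums the trapezoid areas between the horizontal axis and the line
#' connecting adjacent points. For a fitted [fit_linear_spline()] model the
#' spline is evaluated at its endpoints and knots, where the trapezoid sum
#' is exact.
#'
#' @param x A `linear_spline` object, or a numeric vector of times.
#' @param values Responses matching `x` when `x` is a time vector.
#' @return The area (response units x time units).
#' @examples
#' auc_trapezoid(c(0, 24, 48), c(0, 10, 30))
#' @export
auc_trapezoid <- function(x, values = NULL) {
  if (inherits(x, "linear_spline")) {
    u <- sort(unique(c(range(x$times), x$knots)))
    return(trapezoid_area(u, predict(x, u)))
  }
  if (is.null(values)) abort("Supply `values` alongside the time vector.")
  if (length(x) < 2) abort("At least 2 points are required.")
  trapezoid_area(x, values)
}

# AUC of the least-squares spline is linear in the data: auc = a' y.
# Returns list(auc, a, fitted, residuals) for fast residual bootstrapping.
auc_functional <- function(times, values, knots = NULL) {
  fit <- fit_linear_spline(times, values, knots)
  u <- sort(unique(c(range(times), fit$knots)))
  Xu <- spline_basis(u, fit$knots)
  # trapezoid weights over the evaluation grid
  w <- c(diff(u) / 2, 0) + c(0, diff(u) / 2)
  X <- spline_basis(times, fit$knots)
  a <- X %*% solve(crossprod(X), crossprod(Xu, w))
  list(auc = sum(a * values), a = drop(a),
       fitted = fit$fitted, residuals = fit$residuals)
}

#' Bootstrap AUC fold changes relative to a reference line
#'
#' Quantifies proliferation differences as ratios of growth-curve areas.
#' Per sample and experimental run, traces are normalized to their initial
#' timepoint and a linear spline is fitted; residual bootstrapping (pooled
#' within each curve) generates `n_boot` refitted AUC values. Each bootstrap
#' AUC is divided by the reference line's bootstrap AUC within the same run,
#' ratios are averaged over runs, and the 2.5% and 97.5% quantiles of the
#' run-averaged ratios give the empirical 95% confidence interval. Bootstrap
#' replicates in which a reference AUC is non-positive are discarded (the
#' count is reported, with a warning above 1%).
#'
#' @param curves Tibble with columns `sample_id`, `run_id`, `time_h`,
#'   `replicate`, `rlu` (raw or already-normalized; normalization is
#'   idempotent).
#' @param reference_id Sample id of the reference line, present in every run.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed; per-curve substreams are derived from it.
#' @param knots Optional knot positions passed to [fit_linear_spline()].
#' @return An `auc_estimate` tibble: sample_id, mean_auc_fold_change,
#'   ci_low, ci_high, n_bootstrap, n_dropped.
#' @export
bootstrap_auc_ratio <- function(curves, reference_id, n_boot = 10000L,
                                seed = 1L, knots = NULL) {
  runs <- unique(curves$run_id)
  has_ref <- curves |>
    filter(.data$sample_id == reference_id) |>
    pull(.data$run_id) |>
    unique()
  if (!all(runs %in% has_ref)) {
    abort("`reference_id` must be measured in every run.")
  }
  norm <- normalize_luminescence(curves)
  withr::local_seed(seed)

  keys <- norm |> distinct(.data$sample_id, .data$run_id) |> arrange(.data$sample_id, .data$run_id)
  keys$subseed <- draw_subseeds(nrow(keys))

  # per curve: n_boot bootstrap AUCs via the linear functional
  boot_auc <- pmap(keys, function(sample_id, run_id, subseed) {
    d <- filter(norm, .data$sample_id == .env$sample_id,
                .data$run_id == .env$run_id)
    af <- auc_functional(d$time_h, d$rlu, knots)
    withr::with_seed(subseed, {
      E <- matrix(sample(af$residuals, length(af$residuals) * n_boot,
                         replace = TRUE),
                  ncol = n_boot)
      drop(af$auc + crossprod(af$a, E))
    })
  })
  names(boot_auc) <- paste(keys$sample_id, keys$run_id, sep = "\r")

  ref_auc <- map(runs, function(r) boot_auc[[paste(reference_id, r, sep = "\r")]])
  names(ref_auc) <- runs
  keep <- Reduce(`&`, map(ref_auc, function(v) v > 0))
  n_dropped <- sum(!keep)
  if (n_dropped > 0.01 * n_boot) {
    warn(sprintf("%d of %d bootstrap replicates dropped (non-positive reference AUC).",
                 n_dropped, n_boot))
  }

  out <- map(unique(keys$sample_id), function(sid) {
    sruns <- keys$run_id[keys$sample_id == sid]
    ratios <- map(sruns, function(r) {
      boot_auc[[paste(sid, r, sep = "\r")]][keep] / ref_auc[[r]][keep]
    })
    avg <- Reduce(`+`, ratios) / length(ratios)
    tibble(
      sample_id = sid,
      mean_auc_fold_change = mean(avg),
      ci_low = unname(quantile(avg, 0.025)),
      ci_high = unname(quantile(avg, 0.975)),
      n_bootstrap = as.integer(n_boot),
      n_dropped = as.integer(n_dropped)
    )
  }) |> list_rbind()
  new_result_tbl(out, "auc_estimate")
}
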