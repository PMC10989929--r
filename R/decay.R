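#' Half-life from a first-order decay constant
#'
#' @param lambda Decay constant(s), min^-1, strictly positive.
#' @return Half-life in minutes, `log(2) / lambda`.
#' @export
#' @examples
#' half_life(log(2) / 3.1)  # 3.1
half_life <- function(lambda) {
  check_positive(lambda, "lambda")
  log(2) / lambda
}

#' Decay constant from a half-life
#'
#' @param t_half Half-life/lives in minutes, strictly positive.
#' @return Decay constant in min^-1, `log(2) / t_half`.
#' @export
decay_constant <- function(t_half) {
  check_positive(t_half, "t_half")
  log(2) / t_half
}

validate_course <- function(data) {
  if (!all(c("time_min", "rq") %in% names(data))) {
    stop("decay course needs columns `time_min` and `rq`", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!"series" %in% names(data)) data$series <- "s1"
  if (any(!is.finite(data$rq)) || any(data$rq <= 0)) {
    stop("`rq` must be finite and strictly positive", call. = FALSE)
  }
  if (length(unique(data$time_min)) < 3L) {
    stop("need at least 3 distinct timepoints", call. = FALSE)
  }
  data
}

# Newton refinement of the profiled least-squares optimum. For fixed
# lambda the optimal n0 is a/b with a = sum(rq e), b = sum(e^2),
# e = exp(-lambda t); the profiled objective is rss(lambda) =
# sum(rq^2) - a^2/b. Solving d/dlambda (a^2/b) = 0 analytically makes
# the optimum reproducible to machine precision (the port algorithm
# stops at ~1e-7 relative), which the scale-equivariance guarantee
# relies on.
polish_lambda <- function(lambda, time, rq, max_iter = 40) {
  for (i in seq_len(max_iter)) {
    e <- exp(-lambda * time)
    a <- sum(rq * e);        b <- sum(e^2)
    a1 <- -sum(rq * time * e); b1 <- -2 * sum(time * e^2)
    a2 <- sum(rq * time^2 * e); b2 <- 4 * sum(time^2 * e^2)
    if (b <= 0 || a == 0) break
    # maximize q(lambda) = a^2/b; q', q'' by the quotient rule
    q1 <- (2 * a * a1) / b - (a^2 * b1) / b^2
    q2 <- (2 * (a1^2 + a * a2)) / b -
      (4 * a * a1 * b1 + a^2 * b2) / b^2 +
      (2 * a^2 * b1^2) / b^3
    if (!is.finite(q1) || !is.finite(q2) || q2 >= 0) break
    step <- q1 / q2
    lambda_new <- lambda - step
    if (!is.finite(lambda_new) || lambda_new <= 0) break
    if (abs(step) <= 1e-15 * lambda) {
      lambda <- lambda_new
      break
    }
    lambda <- lambda_new
  }
  e <- exp(-lambda * time)
  list(lambda = lambda, n0 = sum(rq * e) / sum(e^2))
}

#' Fit a single-exponential decay to relative-quantity data
#'
#' Minimizes `sum((rq - n0 * exp(-lambda * t))^2)` over `lambda > 0`,
#' `n0 > 0` by nonlinear least squares across all points pooled
#' (regions and biological replicates together, matching a pooled fit
#' per compartment). Starting values come from ordinary least squares of
#' `log(rq)` on `t`; the bounded "port" algorithm of [stats::nls()] is
#' used (iteration cap 500), with an L-BFGS-B [stats::optim()] refinement
#' as fallback if `nls` fails to converge. `n0` is free rather than
#' pinned to 1 so calibrator noise is absorbed instead of biasing
#' `lambda`.
#'
#' If the points show no decay (non-negative log-linear slope and a
#' least-squares optimum at the `lambda = 0` boundary), the fit is
#' flagged and the half-life is the `Inf` sentinel.
#'
#' @param data Tibble with columns `time_min`, `rq` and optionally
#'   `series` (used by [bootstrap_ci()]); at least 3 distinct timepoints.
#' @param n_boot If > 0 and the course has >= 2 series, a percentile
#'   bootstrap confidence interval on the half-life is attached (see
#'   [bootstrap_ci()]).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `decay_fit`: list with `lambda_hat`,
#'   `n0_hat`, `half_life` (min), `ci_low`, `ci_high`, `rss`,
#'   `n_points`, `n_series`, `converged`, `flagged`, and the data.
#' @seealso [fit_decay()] for the grouped, tibble-in/tibble-out verb;
#'   [generics::tidy()], [generics::glance()], [ggplot2::autoplot()]
#'   methods.
#' @export
#' @examples
#' tc <- tibble::tibble(time_min = c(0, 5, 10, 30),
#'                      rq = exp(-log(2) / 3.1 * c(0, 5, 10, 30)))
#' fit <- fit_exponential_decay(tc)
#' fit$half_life  # 3.1
fit_exponential_decay <- function(data, n_boot = 0, seed = 1L) {
  data <- validate_course(data)
  n <- nrow(data)

  ols <- stats::lm(log(rq) ~ time_min, data = data)
  slope <- unname(stats::coef(ols)[2])
  n0_start <- exp(unname(stats::coef(ols)[1]))

  make_fit <- function(lambda_hat, n0_hat, converged, flagged, method) {
    resid <- data$rq - n0_hat * exp(-lambda_hat * data$time_min)
    structure(
      list(
        lambda_hat = lambda_hat,
        n0_hat = n0_hat,
        half_life = if (flagged) Inf else log(2) / lambda_hat,
        ci_low = NA_real_, ci_high = NA_real_,
        rss = sum(resid^2),
        n_points = n,
        n_series = length(unique(data$series)),
        converged = converged,
        flagged = flagged,
        method = method,
        data = data
      ),
      class = "decay_fit"
    )
  }

  if (!is.finite(slope) || slope >= 0) {
    # no decaying trend: optimum sits on the lambda = 0 boundary
    fit <- make_fit(0, mean(data$rq), converged = TRUE, flagged = TRUE,
                    method = "boundary")
  } else {
    start <- list(n0 = max(n0_start, 1e-8), lambda = -slope)
    nls_fit <- tryCatch(
      stats::nls(
        rq ~ n0 * exp(-lambda * time_min),
        data = data, start = start,
        algorithm = "port",
        lower = c(n0 = 1e-12, lambda = 1e-12),
        control = stats::nls.control(maxiter = 500, warnOnly = FALSE)
      ),
      error = function(e) e
    )
    if (!inherits(nls_fit, "error")) {
      pol <- polish_lambda(unname(stats::coef(nls_fit)["lambda"]),
                           data$time_min, data$rq)
      fit <- make_fit(pol$lambda, pol$n0,
                      converged = TRUE, flagged = FALSE, method = "nls")
    } else {
      rss_fun <- function(p) {
        sum((data$rq - p[1] * exp(-p[2] * data$time_min))^2)
      }
      opt <- stats::optim(
        c(start$n0, start$lambda), rss_fun,
        method = "L-BFGS-B", lower = c(1e-12, 1e-12),
        control = list(maxit = 500)
      )
      if (opt$convergence != 0) {
        stop(sprintf(
          paste0("decay fit did not converge (%s); best iterate ",
                 "n0 = %.4g, lambda = %.4g, rss = %.4g"),
          conditionMessage(nls_fit), opt$par[1], opt$par[2], opt$value
        ), call. = FALSE)
      }
      flagged <- opt$par[2] <= 2e-12
      pol <- if (flagged) list(lambda = opt$par[2], n0 = opt$par[1])
             else polish_lambda(opt$par[2], data$time_min, data$rq)
      fit <- make_fit(pol$lambda, pol$n0,
                      converged = TRUE, flagged = flagged,
                      method = "optim")
    }
  }

  if (n_boot > 0 && fit$n_series >= 2L) {
    ci <- bootstrap_ci(data, n_boot = n_boot, seed = seed)
    fit$ci_low <- ci[[1]]
    fit$ci_high <- ci[[2]]
  }
  fit
}

#' Bootstrap confidence interval for a fitted half-life
#'
#' Nonparametric bootstrap at the series (biological-replicate) level:
#' whole series are resampled with replacement `n_boot` times, the pooled
#' exponential fit is repeated on each resample, and the 2.5/97.5
#' percentiles of the refitted half-lives form the interval. Resampling
#' the experiment's natural unit (a replicate curve) respects the
#' correlation of points within a curve. Deterministic for a given seed.
#'
#' @param data Decay course as in [fit_exponential_decay()], with a
#'   `series` column containing at least 2 distinct series.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer RNG seed.
#' @return Named numeric vector `c(ci_low, ci_high)` in minutes.
#' @export
bootstrap_ci <- function(data, n_boot = 1000, seed = 1L) {
  data <- validate_course(data)
  ids <- unique(data$series)
  if (length(ids) < 2L) {
    stop("bootstrap over series needs >= 2 distinct series", call. = FALSE)
  }
  split_data <- split(data, data$series)

  hl <- withr::with_seed(derive_seed(seed, 4L), {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      boot <- dplyr::bind_rows(split_data[take], .id = NULL)
      # re-key so duplicated series stay distinguishable
      boot$series <- rep(seq_along(take),
                         times = vapply(split_data[take], nrow, 1L))
      fit_exponential_decay(boot)$half_life
    }, numeric(1))
  })

  ci <- stats::quantile(hl, c(0.025, 0.975), names = FALSE, type = 7)
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Fit pooled decay curves per group
#'
#' The pipeline verb around [fit_exponential_decay()]: groups a
#' relative-quantity table (the output of [delta_delta_ct()]), pools all
#' regions and biological replicates within each group, fits each group,
#' and returns one tidy row per group.
#'
#' @param rq Tibble with columns `time_min`, `rq`, `series` plus the
#'   grouping columns.
#' @param by Character vector of grouping columns (default
#'   `c("condition", "compartment")`).
#' @param n_boot Bootstrap resamples for the 95% CI on the half-life
#'   (0 to skip).
#' @param seed Seed for the bootstrap.
#' @return A tibble with the grouping columns plus `lambda`,
#'   `half_life`, `ci_low`, `ci_high`, `rss`, `n_points`, `n_series`,
#'   `flagged`, and a list-column `fit` of `decay_fit` objects.
#' @export
#' @examples
#' rq <- simulate_chase(simulation_params(seed = 2)) |> delta_delta_ct()
#' fit_decay(rq)
fit_decay <- function(rq, by = c("condition", "compartment"),
                      n_boot = 0, seed = 1L) {
  missing_cols <- setdiff(by, names(rq))
  if (length(missing_cols)) {
    stop("grouping columns absent: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rq |>
    tidyr::nest(course = !dplyr::all_of(by)) |>
    dplyr::mutate(
      fit = purrr::map(.data$course, fit_exponential_decay,
                       n_boot = n_boot, seed = seed),
      lambda = purrr::map_dbl(.data$fit, "lambda_hat"),
      half_life = purrr::map_dbl(.data$fit, "half_life"),
      ci_low = purrr::map_dbl(.data$fit, "ci_low"),
      ci_high = purrr::map_dbl(.data$fit, "ci_high"),
      rss = purrr::map_dbl(.data$fit, "rss"),
      n_points = purrr::map_int(.data$fit, "n_points"),
      n_series = purrr::map_int(.data$fit, "n_series"),
      flagged = purrr::map_lgl(.data$fit, "flagged")
    ) |>
    dplyr::select(-"course")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>", if (x$flagged) "(flagged: no decaying trend)", "\n")
  cat(sprintf("  lambda: %.5g /min,  half-life: %.3g min\n",
              x$lambda_hat, x$half_life))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% bootstrap CI (half-life): [%.3g, %.3g] min\n",
                x$ci_low, x$ci_high))
  }
  cat(sprintf("  n0: %.4g, rss: %.4g, points: %d, series: %d\n",
              x$n0_hat, x$rss, x$n_points, x$n_series))
  invisible(x)
}

#' Tidy a decay fit
#'
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "n0", "half_life"),
    estimate = c(x$lambda_hat, x$n0_hat, x$half_life)
  )
}

#' One-row summary of a decay fit
#'
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the fitted quantities and diagnostics.
#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda_hat, n0 = x$n0_hat, half_life = x$half_life,
    ci_low = x$ci_low, ci_high = x$ci_high, rss = x$rss,
    n_points = x$n_points, n_series = x$n_series,
    converged = x$converged, flagged = x$flagged
  )
}

#' Diagnostic plot of a decay fit
#'
#' Observed relative quantities by series with the fitted exponential
#' overlaid on a log-scaled y axis.
#'
#' @param object A `decay_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.decay_fit <- function(object, ...) {
  tm <- seq(min(object$data$time_min), max(object$data$time_min),
            length.out = 100)
  curve <- tibble::tibble(
    time_min = tm,
    rq = object$n0_hat * exp(-object$lambda_hat * tm)
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_min, y = .data$rq)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$series)) +
    ggplot2::geom_line(data = curve, colour = "black") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time after transcription arrest (min)",
      y = "relative quantity",
      subtitle = sprintf("half-life %.2f min", object$half_life)
    )
}
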