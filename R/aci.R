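# The CO2-response of net assimilation is modelled as a nonrectangular
# hyperbola: gross assimilation G is the lower root of
#   theta * G^2 - G * (CE*Ci + A_sat) + CE*Ci*A_sat = 0
# and net assimilation is A = G - R. CE is the initial-slope parameter
# (maximum carboxylation efficiency), A_sat the asymptote, theta the
# curvature, and R an apparent respiratory offset. The empirical form makes
# no mechanistic assumption, so the same fit applies to C3, C4,
# intermediate and hybrid physiologies.

#' Nonrectangular-hyperbola net assimilation
#'
#' @param ci intercellular CO2 concentration (umol mol-1).
#' @param ce initial slope (umol m-2 s-1 per umol mol-1).
#' @param a_sat asymptotic gross assimilation (umol m-2 s-1).
#' @param theta curvature, in (0, 1].
#' @param r_offset apparent respiratory offset (umol m-2 s-1).
#' @return Net assimilation A (umol m-2 s-1), vectorised over `ci`.
#' @export
nrh_assimilation <- function(ci, ce, a_sat, theta, r_offset) {
  s <- ce * ci + a_sat
  disc <- pmax(s^2 - 4 * theta * ce * ci * a_sat, 0)
  g <- (s - sqrt(disc)) / (2 * theta)
  g - r_offset
}

#' Fit an A/Ci curve with the empirical nonrectangular hyperbola
#'
#' Least-squares fit of [nrh_assimilation()] to one measured curve, by
#' bounded Levenberg-Marquardt from multiple data-driven starts (best
#' residual sum of squares kept). The CO2 compensation point (CCP) is then
#' solved from A(CCP) = 0 by bracketed root finding. Bounds are generous
#' physical ranges: CE in (0, 5], A_sat in (0, 200], theta in (0.01, 1],
#' R in [0, 20].
#'
#' @param data tibble with columns `ci` and `a_net` (one curve; an
#'   `individual_id` column may be present but must be constant — use
#'   [fit_aci_curves()] for cohorts). At least 4 distinct `ci` values are
#'   required. If a `reference_co2` column is present, the return-to-400
#'   measurement (any 400-step after the first) can be excluded with
#'   `exclude_return_point`.
#' @param n_starts number of jittered initialisations (default 10).
#' @param seed integer seed for the jitter; identical seed and data give
#'   identical fits.
#' @param exclude_return_point drop the return-to-ambient step before
#'   fitting (default `FALSE`).
#' @return A `hyperbola_fit` object; see [tidy.hyperbola_fit()] and
#'   [glance.hyperbola_fit()].
#' @export
fit_aci <- function(data, n_starts = 10, seed = NULL, exclude_return_point = FALSE) {
  data <- tibble::as_tibble(data)
  id <- NA_character_
  if ("individual_id" %in% names(data)) {
    ids <- unique(data$individual_id)
    if (length(ids) > 1) {
      abort("data contains several individuals; use fit_aci_curves()")
    }
    id <- ids
  }
  if (!all(c("ci", "a_net") %in% names(data))) {
    abort("data needs columns ci and a_net")
  }
  if (exclude_return_point && "reference_co2" %in% names(data)) {
    at400 <- which(data$reference_co2 == 400)
    if (length(at400) > 1) data <- data[-at400[-1], , drop = FALSE]
  }
  data <- data[is.finite(data$ci) & is.finite(data$a_net), , drop = FALSE]
  if (length(unique(data$ci)) < 4) abort("need >= 4 distinct ci values to fit")
  if (diff(range(data$a_net)) == 0) abort("degenerate curve: all a_net identical")

  starts <- aci_starts(data, n_starts, seed)
  lower <- c(ce = 1e-6, a_sat = 1e-3, theta = 0.01, r_offset = 0)
  upper <- c(ce = 5, a_sat = 200, theta = 1, r_offset = 20)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        a_net ~ nrh_assimilation(ci, ce, a_sat, theta, r_offset),
        data = data, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    return(structure(list(individual_id = id, coef = c(ce = NA_real_, a_sat = NA_real_,
                                                       theta = NA_real_, r_offset = NA_real_),
                          ccp = NA_real_, rss = NA_real_, converged = FALSE,
                          n_obs = nrow(data), data = data),
                     class = "hyperbola_fit"))
  }

  cf <- coef(best$fit)
  ccp <- solve_ccp(cf[["ce"]], cf[["a_sat"]], cf[["theta"]], cf[["r_offset"]],
                   ci_max = max(data$ci))
  structure(list(individual_id = id, coef = cf, ccp = ccp, rss = best$rss,
                 converged = TRUE, n_obs = nrow(data), data = data),
            class = "hyperbola_fit")
}

# data-driven multi-start initialisation: CE from OLS on the <=3 lowest-Ci
# points, A_sat from the largest observed A, theta 0.7, R from the most
# negative A; jittered lognormally across starts
aci_starts <- function(data, n_starts, seed) {
  ord <- order(data$ci)
  low <- data[ord, ][seq_len(min(3, nrow(data))), ]
  ce0 <- if (nrow(low) >= 2 && diff(range(low$ci)) > 0) {
    max(coef(stats::lm(a_net ~ ci, data = low))[["ci"]], 1e-3)
  } else 0.1
  r0 <- max(-min(data$a_net), 0) + 1
  a0 <- max(data$a_net) + r0
  base <- c(ce = min(ce0, 5), a_sat = min(max(a0, 1), 200), theta = 0.7, r_offset = min(r0, 20))
  jitter_one <- function() {
    c(ce = clamp(base[["ce"]] * exp(rnorm(1, 0, 0.3)), 1e-5, 5),
      a_sat = clamp(base[["a_sat"]] * exp(rnorm(1, 0, 0.3)), 0.1, 200),
      theta = clamp(base[["theta"]] * exp(rnorm(1, 0, 0.2)), 0.05, 1),
      r_offset = clamp(base[["r_offset"]] * exp(rnorm(1, 0, 0.3)), 0, 20))
  }
  gen <- function() c(list(base), replicate(max(n_starts - 1, 0), jitter_one(), simplify = FALSE))
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# CCP: the non-negative zero of net assimilation, found by bracketed root
# finding (A(0) = -R <= 0; the bracket is expanded until A > 0)
solve_ccp <- function(ce, a_sat, theta, r_offset, ci_max = 1500, tol = 1e-10) {
  if (r_offset <= 0) return(0)
  if (a_sat - r_offset <= 0) return(NA_real_)  # A never reaches zero
  f <- function(ci) nrh_assimilation(ci, ce, a_sat, theta, r_offset)
  hi <- max(ci_max, 1)
  while (f(hi) <= 0 && hi < 1e9) hi <- hi * 2
  if (f(hi) <= 0) return(NA_real_)
  uniroot(f, c(0, hi), tol = tol)$root
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  cat(sprintf("<hyperbola_fit> %s (%d obs, %s)\n",
              ifelse(is.na(x$individual_id), "curve", x$individual_id), x$n_obs,
              ifelse(x$converged, "converged", "NOT converged")))
  cat(sprintf("  CE=%.4g  A_sat=%.4g  theta=%.3g  R=%.4g  CCP=%.4g  RSS=%.4g\n",
              x$coef[["ce"]], x$coef[["a_sat"]], x$coef[["theta"]],
              x$coef[["r_offset"]], x$ccp, x$rss))
  invisible(x)
}

#' @export
coef.hyperbola_fit <- function(object, ...) object$coef

#' @export
predict.hyperbola_fit <- function(object, newdata = NULL, ...) {
  ci <- if (is.null(newdata)) object$data$ci else newdata$ci
  cf <- object$coef
  nrh_assimilation(ci, cf[["ce"]], cf[["a_sat"]], cf[["theta"]], cf[["r_offset"]])
}

#' Tidy / summarise a hyperbola fit
#'
#' `tidy()` returns one row per fitted parameter (plus the derived CCP);
#' `glance()` a one-row model summary.
#'
#' @param x a `hyperbola_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.hyperbola_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ce", "a_sat", "theta", "r_offset", "ccp"),
    estimate = c(unname(x$coef), x$ccp)
  )
}

#' @rdname tidy.hyperbola_fit
#' @export
glance.hyperbola_fit <- function(x, ...) {
  tibble::tibble(
    individual_id = x$individual_id,
    ce = x$coef[["ce"]], a_sat = x$coef[["a_sat"]], theta = x$coef[["theta"]],
    r_offset = x$coef[["r_offset"]], ccp = x$ccp,
    rss = x$rss, converged = x$converged, n_obs = x$n_obs
  )
}

#' Fit every curve of a gas-exchange cohort
#'
#' @param data tibble with columns `individual_id`, `ci`, `a_net` (and
#'   optionally `reference_co2`, `group`).
#' @param n_starts,seed,exclude_return_point passed to [fit_aci()]; each
#'   curve gets a deterministic seed derived from `seed`.
#' @return One [glance()] row per individual (plus `group` if present).
#' @export
fit_aci_curves <- function(data, n_starts = 10, seed = NULL, exclude_return_point = FALSE) {
  data <- tibble::as_tibble(data)
  if (!"individual_id" %in% names(data)) abort("data needs an individual_id column")
  ids <- unique(data$individual_id)
  res <- purrr::map_dfr(seq_along(ids), function(i) {
    d <- data[data$individual_id == ids[i], , drop = FALSE]
    s <- if (is.null(seed)) NULL else seed + i
    g <- glance(fit_aci(d, n_starts = n_starts, seed = s,
                        exclude_return_point = exclude_return_point))
    if ("group" %in% names(d)) g$group <- d$group[1]
    g
  })
  res
}

#' Steady-state metrics at ambient CO2
#'
#' Extracts, per individual, the pre-ramp steady-state observation at
#' reference CO2 = 400 umol mol-1 (the first 400-step in measurement
#' order) and computes intrinsic water-use efficiency iWUE = A400 / gs400.
#'
#' @param data tibble with columns `reference_co2`, `a_net`, `gs`, and
#'   optionally `individual_id` and `group`; rows in measurement order.
#' @return Tibble with `individual_id`, `a_400`, `gs_400`, `iwue`.
#' @export
steady_state_metrics <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("reference_co2", "a_net", "gs")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (!"individual_id" %in% names(data)) data$individual_id <- NA_character_
  out <- data |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(function(d, key) {
      w <- which(d$reference_co2 == 400)
      if (length(w) == 0) {
        abort(paste0("no steady-state record at reference CO2 = 400 for ",
                     ifelse(is.na(key$individual_id), "curve", key$individual_id)))
      }
      r <- d[w[1], ]
      res <- tibble::tibble(a_400 = r$a_net, gs_400 = r$gs, iwue = r$a_net / r$gs)
      if ("group" %in% names(d)) res$group <- r$group
      res
    }) |>
    dplyr::ungroup()
  out
}

#' Flag curves measured at anomalous leaf temperature
#'
#' Flags individuals whose per-curve median leaf temperature exceeds the
#' grand median (over every observation of every curve) by more than
#' `delta`.
#'
#' @param data tibble with columns `individual_id` and `t_leaf`.
#' @param delta excess over the grand median, degrees C (default 1.0).
#' @return Tibble `individual_id`, `median_t_leaf`, `grand_median`,
#'   `excess`, `flagged`. Flagged ids: `dplyr::filter(out, flagged)`.
#' @export
flag_tleaf_outliers <- function(data, delta = 1.0) {
  data <- tibble::as_tibble(data)
  if (!all(c("individual_id", "t_leaf") %in% names(data))) {
    abort("data needs columns individual_id and t_leaf")
  }
  if (anyNA(data$t_leaf)) abort("every observation needs a t_leaf value")
  grand <- median(data$t_leaf)
  data |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(median_t_leaf = median(.data$t_leaf), .groups = "drop") |>
    dplyr::mutate(grand_median = grand,
                  excess = .data$median_t_leaf - grand,
                  flagged = .data$excess > delta)
}
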