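#' Ordinary least-squares allometric fit
#'
#' Simple linear regression for log-log allometry, a non-phylogenetic
#' reference alongside [pgls_fit()] and [sma_fit()]. Wraps [stats::lm()]
#' with the standard diagnostics gathered into an object with
#' [tidy][generics::tidy] / [glance][generics::glance] methods.
#'
#' @param data Data frame with the model variables.
#' @param formula Two-sided formula `y ~ x` (simple regression).
#' @return Object of class `ols_fit`.
#' @examples
#' ols_fit(data.frame(x = 0:2, y = c(0, 1, 1)), y ~ x)
#' @export
ols_fit <- function(data, formula) {
  mf <- stats::model.frame(formula, data = data)
  x <- mf[[2]]
  y <- mf[[1]]
  if (length(y) < 3) stop("need at least 3 cases", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in fit variables", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("zero variance in predictor", call. = FALSE)
  lm_fit <- stats::lm(formula, data = data)
  sm <- suppressWarnings(summary(lm_fit))
  # a constant response carries no allometric signal: report R2 = F = 0
  # instead of the numerical noise of a perfect zero-variance fit
  degenerate <- stats::sd(y) == 0
  if (degenerate) {
    sm$r.squared <- 0
    sm$fstatistic <- c(value = 0, numdf = 1, dendf = length(y) - 2)
  }
  structure(list(
    lm = lm_fit,
    coefficients = stats::coef(lm_fit),
    se = sm$coefficients[, "Std. Error"],
    t_values = sm$coefficients[, "t value"],
    p_values = sm$coefficients[, "Pr(>|t|)"],
    r_squared = sm$r.squared,
    f_statistic = unname(sm$fstatistic["value"]),
    df = c(model = unname(sm$fstatistic["numdf"]),
           residual = unname(sm$fstatistic["dendf"])),
    sigma = sm$sigma,
    n = length(y),
    residuals = stats::resid(lm_fit),
    fitted = stats::fitted(lm_fit),
    formula = formula
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit (", deparse(x$formula), "), n = ", x$n,
      ", R2 = ", formatC(x$r_squared, digits = 3), "\n", sep = "")
  print(generics::tidy(x))
  invisible(x)
}

#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(x$t_values),
                 p.value = unname(x$p_values))
}

#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma,
                 statistic = x$f_statistic,
                 df = x$df[["model"]], df.residual = x$df[["residual"]],
                 nobs = x$n)
}

#' Standardized major axis (SMA) line fit
#'
#' Fits the standardized major axis: `|slope| = sd(y)/sd(x)` with the sign
#' of the correlation, and intercept through the bivariate mean. This is
#' the line-fitting method of choice when both axes carry comparable
#' "error" and the slope itself is the quantity of interest, as in
#' allometric scaling. With `robust = TRUE` locations, variances and the
#' covariance are estimated by iteratively reweighted Huber means and
#' variances (tuning constant 1.345) so that extreme outliers do not drag
#' the axis.
#'
#' @param data Data frame with the fit variables.
#' @param formula Two-sided formula `y ~ x`.
#' @param robust Use Huber-M estimation of the moments (default FALSE).
#' @param alpha Level for the slope confidence interval (default 0.05).
#' @return Object of class `sma_fit` with `slope`, `intercept`, `ci`
#'   (slope confidence interval), `r` (correlation), `n`, `method`.
#' @seealso [isometry_test()]
#' @export
sma_fit <- function(data, formula, robust = FALSE, alpha = 0.05) {
  mf <- stats::model.frame(formula, data = data)
  x <- as.numeric(mf[[2]])
  y <- as.numeric(mf[[1]])
  if (length(y) < 3) stop("need at least 3 cases", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a fit variable", call. = FALSE)
  }
  if (robust) {
    mom <- huber_moments(x, y)
  } else {
    mom <- list(mx = mean(x), my = mean(y), vx = stats::var(x),
                vy = stats::var(y), cxy = stats::cov(x, y))
  }
  r <- mom$cxy / sqrt(mom$vx * mom$vy)
  if (r == 0) stop("zero correlation: SMA slope sign undefined",
                   call. = FALSE)
  slope <- sign(r) * sqrt(mom$vy / mom$vx)
  intercept <- mom$my - slope * mom$mx
  n <- length(y)
  # F-based slope CI (uses the plain correlation for the interval width)
  r_ci <- stats::cor(x, y)
  B <- stats::qf(1 - alpha, 1, n - 2) * (1 - r_ci^2) / (n - 2)
  ci <- sort(slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B)))
  structure(list(
    slope = slope, intercept = intercept, ci = ci, r = r, n = n,
    method = if (robust) "Huber-M" else "least-squares",
    x = x, y = y, formula = formula, alpha = alpha
  ), class = "sma_fit")
}

# IRLS Huber estimates of bivariate location/scale/covariance; weights from
# the SMA residual axis, tuning constant 1.345, tol 1e-8, max 100 iters.
huber_moments <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 100) {
  w <- rep(1, length(x))
  slope_old <- Inf
  intercept_old <- Inf
  mom <- NULL
  for (i in seq_len(max_iter)) {
    sw <- sum(w)
    mx <- sum(w * x) / sw
    my <- sum(w * y) / sw
    vx <- sum(w * (x - mx)^2) / sw
    vy <- sum(w * (y - my)^2) / sw
    cxy <- sum(w * (x - mx) * (y - my)) / sw
    slope <- sign(cxy) * sqrt(vy / vx)
    intercept <- my - slope * mx
    if (max(abs(slope - slope_old), abs(intercept - intercept_old)) < tol) {
      mom <- list(mx = mx, my = my, vx = vx, vy = vy, cxy = cxy)
      break
    }
    slope_old <- slope
    intercept_old <- intercept
    d <- y - intercept - slope * x
    s <- stats::mad(d, center = 0)
    if (s == 0) s <- stats::sd(d)
    if (s == 0) {
      mom <- list(mx = mx, my = my, vx = vx, vy = vy, cxy = cxy)
      break
    }
    u <- abs(d / s)
    w <- ifelse(u <= k, 1, k / u)
  }
  if (is.null(mom)) {
    mom <- list(mx = mx, my = my, vx = vx, vy = vy, cxy = cxy)
  }
  mom
}

#' @export
print.sma_fit <- function(x, ...) {
  cat("SMA fit (", x$method, "), n = ", x$n, "\n", sep = "")
  cat("  slope = ", formatC(x$slope, digits = 4),
      "  [", formatC(x$ci[1], digits = 4), ", ",
      formatC(x$ci[2], digits = 4), "]\n", sep = "")
  cat("  intercept = ", formatC(x$intercept, digits = 4),
      ",  r = ", formatC(x$r, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy sma_fit
#' @export
tidy.sma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(NA_real_, x$ci[1]),
    conf.high = c(NA_real_, x$ci[2])
  )
}

#' @method glance sma_fit
#' @export
glance.sma_fit <- function(x, ...) {
  iso <- isometry_test(x, b0 = 1)
  tibble::tibble(slope = x$slope, r = x$r, n = x$n, method = x$method,
                 isometry.statistic = iso$statistic,
                 isometry.p.value = iso$p.value)
}

#' Test an SMA slope against a hypothesized value
#'
#' Standard SMA slope test: under H0 `slope = b0` the residual axis
#' `y - b0 x` and the fitted axis `y + b0 x` are uncorrelated; the test
#' statistic is `F = r'^2 (n-2) / (1-r'^2)` on that correlation, compared
#' with an F(1, n-2) distribution. With `b0 = 1` this is the isometry test
#' for log-log scaling when body size is a length or cube-root mass.
#'
#' @param fit An `sma_fit`.
#' @param b0 Hypothesized slope (default 1 = isometry).
#' @return One-row tibble: `b0`, `statistic` (F), `df1`, `df2`, `p.value`,
#'   `r.residual` (the tested correlation).
#' @export
isometry_test <- function(fit, b0 = 1) {
  stopifnot(inherits(fit, "sma_fit"))
  n <- fit$n
  if (n < 4) stop("need at least 4 cases for the slope test", call. = FALSE)
  b0 <- b0 * sign(fit$slope)  # test on the magnitude, sign from the data
  res_axis <- fit$y - b0 * fit$x
  fit_axis <- fit$y + b0 * fit$x
  if (stats::sd(res_axis) == 0 || stats::sd(fit_axis) == 0) {
    rr <- 0
  } else {
    rr <- stats::cor(res_axis, fit_axis)
  }
  Fstat <- rr^2 * (n - 2) / (1 - rr^2)
  tibble::tibble(
    b0 = b0, statistic = Fstat, df1 = 1, df2 = n - 2,
    p.value = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
    r.residual = rr
  )
}

#' Calibration transform from external eye diameter to axial length
#'
#' Axial eye length (AL) cannot be measured externally on intact museum
#' specimens. Given paired measurements (external transverse eye diameter,
#' dissected axial length) from fresh specimens, fits the OLS transform
#' `AL = a + b * ED` on raw millimetres; [apply_calibration()] maps new ED
#' values to predicted AL.
#'
#' @param pairs Data frame with columns `ed` and `al` (mm), or two numeric
#'   vectors via `ed`/`al`.
#' @param ed,al Optional numeric vectors used when `pairs` is missing.
#' @return Object of class `ed_al_calibration` (contains the underlying
#'   `ols_fit`).
#' @export
ed_to_al_calibration <- function(pairs = NULL, ed = NULL, al = NULL) {
  if (is.null(pairs)) pairs <- data.frame(ed = ed, al = al)
  if (!all(c("ed", "al") %in% names(pairs))) {
    stop("calibration pairs need columns 'ed' and 'al'", call. = FALSE)
  }
  fit <- ols_fit(pairs, al ~ ed)
  structure(list(
    intercept = unname(fit$coefficients[1]),
    slope = unname(fit$coefficients[2]),
    r_squared = fit$r_squared,
    n = fit$n,
    fit = fit
  ), class = "ed_al_calibration")
}

#' @rdname ed_to_al_calibration
#' @param calibration An `ed_al_calibration`.
#' @param new_ed Numeric vector of external eye diameters (mm).
#' @return `apply_calibration()`: predicted axial lengths (mm).
#' @export
apply_calibration <- function(calibration, new_ed) {
  stopifnot(inherits(calibration, "ed_al_calibration"))
  calibration$intercept + calibration$slope * new_ed
}

#' @export
print.ed_al_calibration <- function(x, ...) {
  cat("ED -> AL calibration: AL = ", formatC(x$intercept, digits = 4),
      " + ", formatC(x$slope, digits = 4), " * ED  (R2 = ",
      formatC(x$r_squared, digits = 3), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Batch per-clade scaling fits
#'
#' Fits one scaling comparison per clade and model family for cross-clade
#' comparison of eye-body allometry (e.g. AL~RM, ED~SVL across vertebrate
#' groups). PGLS (ML lambda) is fitted when a tree is supplied; OLS is
#' always fitted. Per-row failures are recorded and the batch continues.
#'
#' @param datasets A list; each element is a list with `name` (clade
#'   label), `data` (species-level data frame with a `species` column when
#'   a tree is used), optional `tree` (a `phylo` or NULL), and
#'   `comparisons` (character vector of formulas like `"log_ed ~ log_rm"`).
#' @return A tibble with one row per clade x comparison x method: `clade`,
#'   `comparison`, `method` ("PGLS"/"OLS"), `slope`, `intercept`, `n`,
#'   `lambda` (NA for OLS), `error` (NA unless the fit failed).
#' @export
batch_clade_fits <- function(datasets) {
  rows <- purrr::map(datasets, function(ds) {
    purrr::map(ds$comparisons, function(cmp) {
      fml <- stats::as.formula(cmp)
      out <- list()
      if (!is.null(ds$tree)) {
        out$pgls <- clade_fit_row(ds$name, cmp, "PGLS", function() {
          fit <- pgls_fit(ds$data, fml, ds$tree)
          list(slope = unname(fit$coefficients[2]),
               intercept = unname(fit$coefficients[1]),
               n = fit$n, lambda = fit$lambda)
        })
      }
      out$ols <- clade_fit_row(ds$name, cmp, "OLS", function() {
        fit <- ols_fit(ds$data, fml)
        list(slope = unname(fit$coefficients[2]),
             intercept = unname(fit$coefficients[1]),
             n = fit$n, lambda = NA_real_)
      })
      dplyr::bind_rows(out)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

clade_fit_row <- function(clade, comparison, method, fn) {
  res <- tryCatch(fn(), error = function(e) conditionMessage(e))
  if (is.character(res)) {
    tibble::tibble(clade = clade, comparison = comparison, method = method,
                   slope = NA_real_, intercept = NA_real_, n = NA_integer_,
                   lambda = NA_real_, error = res)
  } else {
    tibble::tibble(clade = clade, comparison = comparison, method = method,
                   slope = res$slope, intercept = res$intercept,
                   n = as.integer(res$n), lambda = res$lambda,
                   error = NA_character_)
  }
}
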