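#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits a linear model whose residual covariance is proportional to a
#' lambda-transformed phylogenetic covariance matrix. With
#' `lambda = "ML"` (the default) Pagel's lambda is estimated by maximizing
#' the profile log-likelihood over \[0, 1\]; with a numeric `lambda` the
#' fit is a plain GLS at that value. `lambda = 0` reduces to ordinary least
#' squares; `lambda = 1` assumes full Brownian covariance.
#'
#' Computation whitens the model through the Cholesky factor of
#' C(lambda): coefficients are `(X' C^-1 X)^-1 X' C^-1 y`, the ML residual
#' variance uses divisor n, standard errors use divisor n - p, and R^2 is
#' `1 - RSS/TSS` in the whitened space with TSS taken about the
#' GLS-estimated mean under the same C(lambda).
#'
#' @param data A data frame with one row per species, containing the
#'   variables in `formula` and a species-label column.
#' @param formula Model formula, e.g. `log_ed ~ log_rm` or
#'   `log_ed ~ log_rm * adult_habitat`. Factors are dummy-coded with
#'   treatment contrasts, reference level = alphabetically first state.
#' @param tree A rooted `phylo` with branch lengths, or a `phylo_cov`.
#'   Species present in only one of `data`/`tree` are dropped with a
#'   message.
#' @param lambda `"ML"` or a fixed value in \[0, 1\].
#' @param species Name of the species-label column in `data`.
#' @return An object of class `pgls_fit`; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()] for tibble summaries.
#' @examples
#' sim <- simulate_dataset(sim_config(n_species = 40, seed = 1))
#' fit <- pgls_fit(sim$species, log_ed ~ log_rm, sim$tree)
#' generics::tidy(fit)
#' @export
pgls_fit <- function(data, formula, tree, lambda = "ML",
                     species = "species") {
  md <- build_pgls_design(data, formula, tree, species)
  if (identical(lambda, "ML")) {
    prof <- profile_lambda_ml(md$X, md$y, md$C)
    fit <- gls_core(md$X, md$y, lambda_transform(md$C, prof$lambda))
    fit$lambda <- prof$lambda
    fit$lambda_ml <- TRUE
    fit$flat_lambda <- prof$flat
    fit$profile <- prof$grid
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must be \"ML\" or a number in [0, 1]", call. = FALSE)
    }
    fit <- gls_core(md$X, md$y, lambda_transform(md$C, lambda))
    fit$lambda <- lambda
    fit$lambda_ml <- FALSE
    fit$flat_lambda <- FALSE
  }
  fit$formula <- formula
  fit$taxa <- md$taxa
  fit$model_frame <- md$frame
  fit$C0 <- md$C
  fit$dropped <- md$dropped
  class(fit) <- "pgls_fit"
  fit
}

# Align trait rows with tree tips, prune both sides, build design matrix.
build_pgls_design <- function(data, formula, tree, species) {
  if (!species %in% names(data)) {
    stop("no '", species, "' column in data", call. = FALSE)
  }
  labs <- normalize_labels(as.character(data[[species]]))
  if (anyDuplicated(labs)) {
    stop("duplicated species in data: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  if (inherits(tree, "phylo_cov")) {
    taxa_tree <- tree$taxa
  } else {
    taxa_tree <- tree$tip.label
  }
  vars <- all.vars(formula)
  frame <- as.data.frame(data[, c(species, vars), drop = FALSE])
  frame[[species]] <- labs
  complete <- stats::complete.cases(frame)
  shared <- intersect(labs[complete], taxa_tree)
  dropped <- setdiff(union(labs, taxa_tree), shared)
  if (length(shared) == 0) {
    stop("no species shared between data and tree", call. = FALSE)
  }
  if (length(dropped) > 0) {
    message("dropping ", length(dropped),
            " species absent from tree, data or with missing values")
  }
  if (inherits(tree, "phylo_cov")) {
    keep <- match(shared, tree$taxa)
    C <- tree$C[keep, keep, drop = FALSE]
    taxa <- tree$taxa[keep]
  } else {
    sub <- prune_to_taxa(tree, shared)
    cv <- phylo_covariance(sub)
    C <- cv$C
    taxa <- cv$taxa
  }
  frame <- frame[match(taxa, frame[[species]]), , drop = FALSE]
  frame <- droplevels(frame)
  # alphabetical reference level for factors (treatment contrasts)
  for (v in vars) {
    if (is.character(frame[[v]])) frame[[v]] <- factor(frame[[v]])
    if (is.factor(frame[[v]])) {
      frame[[v]] <- factor(frame[[v]], levels = sort(levels(frame[[v]])))
    }
  }
  X <- stats::model.matrix(formula, frame)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (aliased terms: ",
         paste(colnames(X)[-seq_len(qr(X)$rank)], collapse = ", "), ")",
         call. = FALSE)
  }
  y <- stats::model.response(stats::model.frame(formula, frame))
  if (nrow(X) < ncol(X) + 1) {
    stop("too few species (", nrow(X), ") for ", ncol(X), " parameters",
         call. = FALSE)
  }
  rownames(X) <- taxa
  list(X = X, y = stats::setNames(as.numeric(y), taxa), C = C,
       taxa = taxa, frame = tibble::as_tibble(frame), dropped = dropped)
}

lambda_transform <- function(C, lambda) {
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

# GLS at a fixed covariance: whitened least squares via Cholesky.
gls_core <- function(X, y, C) {
  R <- tryCatch(chol(C), error = function(e) {
    stop("phylogenetic covariance is not positive definite", call. = FALSE)
  })
  # C = R'R with R upper triangular; whitening W = (R')^-1
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) {
    stop("design matrix is rank deficient after whitening", call. = FALSE)
  }
  beta <- qr.coef(qx, yw)
  fitted <- as.numeric(X %*% beta)
  resid <- as.numeric(y) - fitted
  resid_w <- yw - Xw %*% beta
  n <- nrow(X)
  p <- ncol(X)
  rss <- sum(resid_w^2)
  sigma2_ml <- rss / n
  logdetC <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + n + logdetC)
  XtX_inv <- chol2inv(qr.R(qx))
  vcov <- XtX_inv * rss / (n - p)
  se <- sqrt(diag(vcov))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  # whitened TSS about the GLS mean under the same C
  onew <- backsolve(R, rep(1, n), transpose = TRUE)
  mu <- sum(onew * yw) / sum(onew^2)
  tss <- sum((yw - mu * onew)^2)
  hat <- rowSums(qr.Q(qx)[, seq_len(p), drop = FALSE]^2)
  list(
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    t_values = stats::setNames(as.numeric(tval), colnames(X)),
    p_values = stats::setNames(as.numeric(pval), colnames(X)),
    vcov = vcov,
    df = c(model = p - 1, residual = n - p),
    n = n,
    r_squared = 1 - rss / tss,
    sigma2 = sigma2_ml,
    log_likelihood = ll,
    residuals = stats::setNames(resid, rownames(X)),
    fitted = stats::setNames(fitted, rownames(X)),
    whitened = list(X = Xw, y = as.numeric(yw),
                    residuals = as.numeric(resid_w), hat = hat,
                    rss = rss, tss = tss, chol = R)
  )
}

# Profile log-likelihood of lambda (beta, sigma2 profiled out analytically).
profile_loglik <- function(lambda, X, y, C) {
  Cl <- lambda_transform(C, lambda)
  R <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  qx <- qr(Xw)
  resid_w <- qr.resid(qx, yw)
  n <- nrow(X)
  rss <- sum(resid_w^2)
  -0.5 * (n * log(2 * pi) + n * log(rss / n) + n + 2 * sum(log(diag(R))))
}

# Coarse 21-point grid on [0,1], then bounded scalar optimization in the
# bracketing interval; endpoints 0 and 1 are always candidates.
profile_lambda_ml <- function(X, y, C, grid_n = 21, tol = 1e-6) {
  grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(grid, function(l) profile_loglik(l, X, y, C), numeric(1))
  if (all(!is.finite(ll))) {
    stop("profile likelihood non-finite across the lambda grid",
         call. = FALSE)
  }
  if (diff(range(ll[is.finite(ll)])) < 1e-8) {
    # no phylogenetic information (e.g. star tree): report 0 by convention
    return(list(lambda = 0, loglik = ll[1], flat = TRUE,
                grid = tibble::tibble(lambda = grid, loglik = ll)))
  }
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(grid_n, i + 1)]
  opt <- stats::optimize(profile_loglik, interval = c(lo, hi), maximum = TRUE,
                         tol = tol, X = X, y = y, C = C)
  cand <- c(opt$maximum, 0, 1)
  cll <- c(opt$objective, ll[1], ll[grid_n])
  best <- which.max(cll)
  list(lambda = cand[best], loglik = cll[best], flat = FALSE,
       grid = tibble::tibble(lambda = grid, loglik = ll))
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit (", deparse(x$formula), ")\n", sep = "")
  cat("  n = ", x$n, ", lambda = ", formatC(x$lambda, digits = 3),
      if (x$lambda_ml) " (ML)" else " (fixed)",
      if (isTRUE(x$flat_lambda)) " [flat likelihood]" else "", "\n", sep = "")
  cat("  logLik = ", formatC(x$log_likelihood, digits = 6),
      ", R2 = ", formatC(x$r_squared, digits = 3), "\n", sep = "")
  print(generics::tidy(x))
  invisible(x)
}

#' Tidy a PGLS fit into a coefficient tibble
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: estimate, standard error,
#'   t statistic and p value.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$t_values),
    p.value = unname(x$p_values)
  )
}

#' One-row model summary of a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return A one-row tibble: r.squared, lambda, sigma2, logLik, model and
#'   residual df, n.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    lambda = x$lambda,
    sigma2 = x$sigma2,
    logLik = x$log_likelihood,
    df = x$df[["model"]],
    df.residual = x$df[["residual"]],
    nobs = x$n
  )
}

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
fitted.pgls_fit <- function(object, ...) object$fitted

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients) + 2,
            class = "logLik")
}

#' Externally Studentized residuals of a PGLS fit
#'
#' Residuals are Studentized in the whitened (decorrelated) space:
#' `t_i = e_i / (s_(-i) * sqrt(1 - h_ii))` with the hat matrix of the
#' whitened design and the leave-one-out residual standard deviation. With
#' a diagonal covariance these coincide with the textbook externally
#' Studentized residuals of OLS.
#'
#' @param fit A `pgls_fit`.
#' @return Named numeric vector, one value per species.
#' @export
studentized_residuals <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  n <- fit$n
  p <- length(fit$coefficients)
  if (n - p < 2) stop("residual df < 2", call. = FALSE)
  e <- fit$whitened$residuals
  h <- fit$whitened$hat
  rss <- fit$whitened$rss
  out <- numeric(n)
  at_limit <- h >= 1 - 1e-12
  if (any(at_limit)) {
    warning("leverage ~ 1 for: ",
            paste(fit$taxa[at_limit], collapse = ", "), call. = FALSE)
    out[at_limit] <- Inf * sign(e[at_limit] + (e[at_limit] == 0))
  }
  ok <- !at_limit
  s2 <- (rss - e[ok]^2 / (1 - h[ok])) / (n - p - 1)
  s2 <- pmax(s2, 0)
  out[ok] <- e[ok] / sqrt(s2 * (1 - h[ok]))
  stats::setNames(out, fit$taxa)
}

#' Iterative outlier-sensitivity refit
#'
#' Repeatedly fits the PGLS model (re-estimating lambda by ML each round),
#' finds the species with the largest absolute externally Studentized
#' residual, and removes it if it exceeds `threshold`, until none does.
#' Reports every removal and the drift of each coefficient between the
#' initial and final fits — a sensitivity check that extreme phylogenetic
#' outliers are not driving parameter estimates.
#'
#' @inheritParams pgls_fit
#' @param threshold Absolute Studentized-residual cutoff (default 3).
#' @param max_removals Safety cap on removals.
#' @return An object of class `outlier_report`: a list with `removals`
#'   (tibble of taxon, Studentized residual, iteration), `initial_fit`,
#'   `final_fit`, and `drift` (per-coefficient difference final - initial).
#' @export
iterative_outlier_refit <- function(data, formula, tree, threshold = 3,
                                    species = "species",
                                    max_removals = Inf) {
  fit0 <- pgls_fit(data, formula, tree, lambda = "ML", species = species)
  fit <- fit0
  dat <- data
  removals <- tibble::tibble(iteration = integer(), taxon = character(),
                             studentized = numeric())
  p <- length(fit0$coefficients)
  iter <- 0L
  repeat {
    st <- studentized_residuals(fit)
    worst <- max(abs(st))
    if (!is.finite(worst) || worst <= threshold) break
    if (fit$n - 1 <= p + 2) {
      warning("stopping: further removal would leave n <= p + 2",
              call. = FALSE)
      break
    }
    if (nrow(removals) >= max_removals) break
    iter <- iter + 1L
    cand <- sort(names(st)[abs(st) == worst])  # alphabetical tie-break
    drop_taxon <- cand[1]
    removals <- dplyr::bind_rows(
      removals,
      tibble::tibble(iteration = iter, taxon = drop_taxon,
                     studentized = unname(st[drop_taxon]))
    )
    dat <- dat[normalize_labels(as.character(dat[[species]])) != drop_taxon, ,
               drop = FALSE]
    fit <- pgls_fit(dat, formula, tree, lambda = "ML", species = species)
  }
  structure(list(
    removals = removals,
    initial_fit = fit0,
    final_fit = fit,
    drift = fit$coefficients - fit0$coefficients,
    threshold = threshold
  ), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Outlier sensitivity check (|Studentized residual| > ",
      x$threshold, ")\n", sep = "")
  if (nrow(x$removals) == 0) {
    cat("  no species removed\n")
  } else {
    print(x$removals)
    cat("  coefficient drift (final - initial):\n")
    print(round(x$drift, 5))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
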