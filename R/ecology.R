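#' Ecological trait state sets
#'
#' The six categorical traits scored per species and their admissible
#' states. Empty strings / NA denote missing information; species missing
#' a trait are excluded from analyses of that trait only.
#'
#' @format A named list of character vectors.
#' @export
ecology_states <- list(
  adult_habitat = c("aquatic", "fossorial", "ground-dwelling", "scansorial",
                    "semiaquatic", "subfossorial"),
  activity = c("both", "diurnal", "nocturnal"),
  mating_habitat = c("ground", "lentic water", "lotic water", "plants"),
  life_history = c("free-living larvae", "no free-living larvae"),
  larval_habitat = c("lentic water", "lotic water", "obscured", "on land"),
  dichromatism = c("absent", "present")
)

check_ecology_states <- function(ecology) {
  for (trait in intersect(names(ecology_states), names(ecology))) {
    vals <- ecology[[trait]]
    bad <- setdiff(unique(vals[!is.na(vals) & vals != ""]),
                   ecology_states[[trait]])
    if (length(bad) > 0) {
      stop("unknown ", trait, " state(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(ecology)
}

#' Eye-investment factors from phylogenetic residuals
#'
#' Converts the residuals of a PGLS allometric fit into investment factors
#' `10^residual`: the factor by which a species' eye exceeds (\eqn{>1}) or
#' falls short of (\eqn{<1}) the allometric expectation for its body size,
#' after phylogenetic correction. A residual of 0.2 on the log10 scale is
#' an eye about 1.6x (10^0.2) the predicted diameter.
#'
#' @param fit A `pgls_fit` (canonically of log10 eye diameter on log10
#'   cube-root mass).
#' @param ecology Optional species-level data frame (must contain a
#'   `species` column) whose columns — ecological states, raw trait values —
#'   are joined onto the result.
#' @return A tibble of class `investment_tbl`: `species`, `residual`
#'   (log10 units), `investment` (dimensionless factor), plus any joined
#'   columns.
#' @examples
#' investment_factor(0.2)  # ~1.585, an eye ~1.6x the expected diameter
#' @export
investment_scores <- function(fit, ecology = NULL) {
  stopifnot(inherits(fit, "pgls_fit"))
  out <- tibble::tibble(
    species = fit$taxa,
    residual = unname(fit$residuals),
    investment = investment_factor(unname(fit$residuals))
  )
  if (!is.null(ecology)) {
    eco <- tibble::as_tibble(ecology)
    if (!"species" %in% names(eco)) {
      stop("ecology table needs a 'species' column", call. = FALSE)
    }
    eco$species <- normalize_labels(as.character(eco$species))
    check_ecology_states(eco)
    out <- dplyr::left_join(out, eco, by = "species")
  }
  class(out) <- c("investment_tbl", class(out))
  out
}

#' @rdname investment_scores
#' @param residual Numeric vector of log10-scale residuals.
#' @export
investment_factor <- function(residual) 10^residual

#' Summarize investment by ecological state
#'
#' Per-state mean, median and n of the investment factor (and of any extra
#' numeric column supplied, e.g. raw eye diameter in mm). Species missing
#' the trait are excluded from this trait's summary only.
#'
#' @param table An `investment_tbl` (from [investment_scores()]).
#' @param trait Name of the ecological trait column to group by.
#' @param extra Optional name of an additional numeric column to summarize
#'   alongside investment.
#' @return A tibble with one row per observed state.
#' @export
group_summary <- function(table, trait, extra = NULL) {
  if (!trait %in% names(table)) {
    stop("unknown trait column: ", trait, call. = FALSE)
  }
  tab <- dplyr::filter(table, !is.na(.data[[trait]]),
                       .data[[trait]] != "")
  out <- dplyr::summarise(
    dplyr::group_by(tab, state = .data[[trait]]),
    n = dplyr::n(),
    mean_investment = mean(.data$investment),
    median_investment = stats::median(.data$investment),
    mean_residual = mean(.data$residual),
    .groups = "drop"
  )
  if (!is.null(extra)) {
    ex <- dplyr::summarise(
      dplyr::group_by(tab, state = .data[[trait]]),
      "mean_{extra}" := mean(.data[[extra]], na.rm = TRUE),
      "median_{extra}" := stats::median(.data[[extra]], na.rm = TRUE),
      .groups = "drop"
    )
    out <- dplyr::left_join(out, ex, by = "state")
  }
  dplyr::arrange(out, dplyr::desc(.data$mean_investment))
}

#' Kruskal-Wallis rank test across ecological states
#'
#' Nonparametric k-sample test of whether a quantity (eye diameter,
#' relative investment, ...) differs among categorical states. Uses the
#' tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom, via [stats::kruskal.test()]. Cases with a missing
#' value or state are excluded.
#'
#' @param data A data frame.
#' @param values Column with the per-case values (tidy-eval).
#' @param groups Column with the per-case states (tidy-eval).
#' @return One-row tibble: `statistic` (H), `df`, `p.value`, `n`,
#'   `n_groups`.
#' @examples
#' kruskal_wallis(data.frame(v = 1:4, g = c("a", "a", "b", "b")), v, g)
#' @export
kruskal_wallis <- function(data, values, groups) {
  v <- dplyr::pull(data, {{ values }})
  g <- dplyr::pull(data, {{ groups }})
  declared <- if (is.factor(g)) levels(g) else unique(g[!is.na(g) & g != ""])
  keep <- !is.na(v) & !is.na(g) & g != ""
  v <- v[keep]
  g <- factor(as.character(g[keep]))
  empty <- setdiff(declared, levels(g))
  if (length(empty) > 0) {
    stop("group(s) empty after missing-value removal: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(v) < 3) stop("need at least 3 cases in total", call. = FALSE)
  small <- table(g) < 5
  if (any(small)) {
    warning("group(s) with n < 5: ",
            paste(names(which(small)), collapse = ", "),
            "; chi-square approximation may be coarse", call. = FALSE)
  }
  if (stats::sd(v) == 0) {
    # no rank variation: H = 0 by convention (tie-correction guard)
    return(tibble::tibble(statistic = 0, df = k - 1, p.value = 1,
                          n = length(v), n_groups = k))
  }
  kt <- stats::kruskal.test(v, g)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p.value = kt$p.value,
                 n = length(v), n_groups = k)
}

#' Phylogenetic ANCOVA of a trait on body size and an ecological factor
#'
#' Fits the PGLS model `response ~ covariate * factor` (ML lambda by
#' default) and decomposes it by a sequential (Type I) analysis of
#' variance computed in the whitened space, in formula order: covariate,
#' factor, interaction, residual. Treatment contrasts with the
#' alphabetically first state as reference. Species missing any involved
#' variable are dropped (and logged) for this model only.
#'
#' @param data Species-level data frame (with a `species` column).
#' @param response,covariate,group Column names (strings) of the response,
#'   the continuous covariate and the categorical ecological trait.
#' @param tree A rooted `phylo` with branch lengths.
#' @param lambda `"ML"` or a fixed value in \[0, 1\].
#' @param species Name of the species-label column.
#' @return An object of class `phylo_ancova`: list with `table` (tibble of
#'   term, df, sumsq, meansq, statistic, p.value) and `fit` (the
#'   `pgls_fit`).
#' @export
phylo_ancova <- function(data, response, covariate, group, tree,
                         lambda = "ML", species = "species") {
  g <- data[[group]]
  if (is.null(g)) stop("unknown factor column: ", group, call. = FALSE)
  g[g == ""] <- NA
  data[[group]] <- g
  lv <- unique(g[!is.na(g)])
  if (length(lv) < 2) {
    stop("factor '", group, "' has fewer than 2 observed levels",
         call. = FALSE)
  }
  fml <- stats::as.formula(
    paste0("`", response, "` ~ `", covariate, "` * `", group, "`"))
  fit <- pgls_fit(data, fml, tree, lambda = lambda, species = species)
  X <- stats::model.matrix(fml, fit$model_frame)
  asg <- attr(X, "assign")
  term_labels <- attr(stats::terms(fml), "term.labels")
  R <- fit$whitened$chol
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- fit$whitened$y
  n <- fit$n
  rss_prev <- fit$whitened$tss  # intercept-only whitened RSS = total SS
  rows <- vector("list", length(term_labels))
  for (k in seq_along(term_labels)) {
    cols <- which(asg <= k)
    rss_k <- sum(qr.resid(qr(Xw[, cols, drop = FALSE]), yw)^2)
    rows[[k]] <- tibble::tibble(
      term = term_labels[k],
      df = sum(asg == k),
      sumsq = rss_prev - rss_k
    )
    rss_prev <- rss_k
  }
  rss <- fit$whitened$rss
  df_res <- n - ncol(X)
  tab <- dplyr::bind_rows(rows)
  tab$meansq <- tab$sumsq / tab$df
  ms_res <- rss / df_res
  tab$statistic <- tab$meansq / ms_res
  tab$p.value <- stats::pf(tab$statistic, tab$df, df_res, lower.tail = FALSE)
  tab <- dplyr::bind_rows(
    tab,
    tibble::tibble(term = "Residuals", df = df_res, sumsq = rss,
                   meansq = ms_res, statistic = NA_real_,
                   p.value = NA_real_)
  )
  structure(list(table = tab, fit = fit,
                 response = response, covariate = covariate, group = group),
            class = "phylo_ancova")
}

#' @export
print.phylo_ancova <- function(x, ...) {
  cat("Phylogenetic ANCOVA: ", x$response, " ~ ", x$covariate, " * ",
      x$group, "  (lambda = ", formatC(x$fit$lambda, digits = 3), ")\n",
      sep = "")
  print(x$table)
  invisible(x)
}

#' @method tidy phylo_ancova
#' @export
tidy.phylo_ancova <- function(x, ...) x$table

#' @method glance phylo_ancova
#' @export
glance.phylo_ancova <- function(x, ...) glance.pgls_fit(x$fit)
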