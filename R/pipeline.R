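#' Collapse specimen records into a species-level trait table
#'
#' Per specimen, eye and cornea diameters are the mean of the left and
#' right measurements (a single side is accepted with a warning); species
#' values are arithmetic means over specimens; the body-size proxy RM is
#' the cube root of the species-mean wet mass, so isometry with length
#' measurements occurs at slope 1; log10 columns are appended. Records
#' with non-positive measurements are rejected and logged.
#'
#' @param records Specimen-level data frame with columns `species`,
#'   `svl_mm`, `mass_g`, `ed_left_mm`, `ed_right_mm`, `cd_left_mm`,
#'   `cd_right_mm`, optionally `al_mm` and `condition`.
#' @param conditions Which specimen conditions to use (default both
#'   fresh and preserved).
#' @return A tibble with one row per species: mean `ed_mm`, `cd_mm`,
#'   `svl_mm`, `mass_g`, `al_mm` (NA when never measured), `rm`,
#'   `n_specimens`, and `log_ed`, `log_cd`, `log_svl`, `log_rm`.
#' @export
prepare_species_table <- function(records,
                                  conditions = c("fresh", "preserved")) {
  records <- tibble::as_tibble(records)
  if (!"species" %in% names(records)) {
    stop("no 'species' column in specimen records", call. = FALSE)
  }
  if ("condition" %in% names(records)) {
    records <- dplyr::filter(records, .data$condition %in% conditions)
  }
  meas <- intersect(c("svl_mm", "mass_g", "ed_left_mm", "ed_right_mm",
                      "cd_left_mm", "cd_right_mm", "al_mm"),
                    names(records))
  bad <- rep(FALSE, nrow(records))
  for (v in meas) {
    bad <- bad | (!is.na(records[[v]]) & records[[v]] <= 0)
  }
  if (any(bad)) {
    message("rejected ", sum(bad), " record(s) with non-positive ",
            "measurements")
    records <- records[!bad, , drop = FALSE]
  }
  one_side <- xor(is.na(records$ed_left_mm), is.na(records$ed_right_mm))
  if (any(one_side)) {
    warning(sum(one_side), " specimen(s) with a single-side eye ",
            "measurement", call. = FALSE)
  }
  no_eye <- is.na(records$ed_left_mm) & is.na(records$ed_right_mm)
  if (any(no_eye)) {
    message("dropped ", sum(no_eye), " record(s) with no eye measurement")
    records <- records[!no_eye, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no usable specimen records", call. = FALSE)
  records$species <- normalize_labels(as.character(records$species))
  pair_mean <- function(a, b) {
    ifelse(is.na(a) & is.na(b), NA_real_,
           rowMeans(cbind(a, b), na.rm = TRUE))
  }
  records$ed_mm_spec <- pair_mean(records$ed_left_mm, records$ed_right_mm)
  records$cd_mm_spec <- pair_mean(records$cd_left_mm, records$cd_right_mm)
  if (!"al_mm" %in% names(records)) records$al_mm <- NA_real_
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$species),
    ed_mm = mean(.data$ed_mm_spec, na.rm = TRUE),
    cd_mm = mean_or_na(.data$cd_mm_spec),
    svl_mm = mean_or_na(.data$svl_mm),
    mass_g = mean_or_na(.data$mass_g),
    al_mm = mean_or_na(.data$al_mm),
    n_specimens = dplyr::n(),
    .groups = "drop"
  )
  out$rm <- out$mass_g^(1 / 3)
  safe_log10 <- function(x) ifelse(!is.na(x) & x > 0, log10(x), NA_real_)
  out$log_ed <- safe_log10(out$ed_mm)
  out$log_cd <- safe_log10(out$cd_mm)
  out$log_svl <- safe_log10(out$svl_mm)
  out$log_rm <- safe_log10(out$rm)
  out
}

mean_or_na <- function(x) {
  if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
}

#' The six standard allometric comparisons
#'
#' Response/predictor pairs fitted by [run_pipeline()]: eye diameter and
#' cornea diameter against each body-size proxy, cornea against eye, and
#' the two body-size proxies against each other (all log10 species means).
#'
#' @return Character vector of model formulas.
#' @export
standard_comparisons <- function() {
  c("log_ed ~ log_rm", "log_ed ~ log_svl", "log_cd ~ log_ed",
    "log_cd ~ log_rm", "log_cd ~ log_svl", "log_svl ~ log_rm")
}

#' Run the full comparative analysis pipeline
#'
#' End-to-end driver: specimen records are collapsed to species means,
#' the tree is matched to the data (tip substitutions, polytomy grafts,
#' random resolution, pruning to the shared species set), the six
#' standard allometric comparisons are fitted by PGLS (ML lambda), OLS
#' and SMA, PGLS residuals become eye- and cornea-investment factors,
#' each ecological trait is tested by Kruskal-Wallis (on eye diameter and
#' on investment) and by phylogenetic ANCOVA, and the eye-body PGLS gets
#' the iterative outlier-sensitivity check. Every stage logs its species
#' counts; the run is a pure function of (inputs, seed).
#'
#' @param specimens Specimen-level records (data frame or CSV path), or
#'   NULL when `species_table` is given directly.
#' @param tree A `phylo` or Newick file path.
#' @param ecology Species-level ecology table (data frame or CSV path),
#'   optional.
#' @param species_table Precomputed species-level table (bypasses
#'   [prepare_species_table()]).
#' @param substitutions Optional two-column mapping (`old`, `new`) or CSV
#'   path of tip-label substitutions.
#' @param grafts Optional two-column table (`new_taxon`, `sister`) or CSV
#'   path of polytomy grafts.
#' @param comparisons Model formulas to fit (default
#'   [standard_comparisons()]).
#' @param investment_model Formula whose PGLS residuals define eye
#'   investment (default `log_ed ~ log_rm`).
#' @param ecology_traits Ecological trait columns to test (default: those
#'   of [ecology_states] present in `ecology`).
#' @param outlier_threshold Studentized-residual cutoff for the
#'   sensitivity check.
#' @param seed Integer seed (polytomy resolution).
#' @return A list of class `pipeline_result`: `species` (analysis table),
#'   `tree` (final analysis tree), `allometry` (tibble of fits),
#'   `fits` (named list of `pgls_fit`s), `investment` (tibble),
#'   `corneal_investment` (tibble), `ecology_tests` (tibble),
#'   `group_summaries` (tibble), `outliers` (an `outlier_report`).
#' @export
run_pipeline <- function(specimens = NULL, tree, ecology = NULL,
                         species_table = NULL,
                         substitutions = NULL, grafts = NULL,
                         comparisons = standard_comparisons(),
                         investment_model = log_ed ~ log_rm,
                         ecology_traits = NULL,
                         outlier_threshold = 3,
                         seed = 1L) {
  # -- inputs ---------------------------------------------------------
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(specimens)) {
    specimens <- readr::read_csv(specimens, show_col_types = FALSE)
  }
  if (is.character(ecology)) {
    ecology <- readr::read_csv(ecology, show_col_types = FALSE)
  }
  if (is.character(substitutions)) {
    substitutions <- readr::read_csv(substitutions, show_col_types = FALSE)
  }
  if (is.character(grafts)) {
    grafts <- readr::read_csv(grafts, show_col_types = FALSE)
  }
  if (is.null(species_table)) {
    if (is.null(specimens)) {
      stop("supply either specimens or species_table", call. = FALSE)
    }
    species_table <- prepare_species_table(specimens)
  }
  species_table$species <- normalize_labels(
    as.character(species_table$species))
  message("stage prepare: ", nrow(species_table), " species")

  # -- tree matching --------------------------------------------------
  if (!is.null(substitutions) && nrow(substitutions) > 0) {
    tree <- substitute_tips(tree, substitutions)
  }
  if (!is.null(grafts) && nrow(grafts) > 0) {
    for (i in seq_len(nrow(grafts))) {
      tree <- graft_polytomy_tip(tree, grafts$new_taxon[i],
                                 grafts$sister[i])
    }
  }
  tree <- resolve_polytomies(tree, seed = seed)
  shared <- intersect(species_table$species, tree$tip.label)
  if (length(shared) == 0) {
    stop("no species shared between trait table and tree", call. = FALSE)
  }
  n_drop <- length(union(species_table$species, tree$tip.label)) -
    length(shared)
  if (n_drop > 0) {
    message("stage match: dropping ", n_drop,
            " species not shared between data and tree")
  }
  tree <- prune_to_taxa(tree, shared)
  species_table <- species_table[
    match(tree$tip.label, species_table$species), , drop = FALSE]
  message("stage match: ", length(shared), " species in analysis")

  # -- allometric fits ------------------------------------------------
  fits <- list()
  allo_rows <- list()
  for (cmp in comparisons) {
    fml <- stats::as.formula(cmp)
    pg <- pgls_fit(species_table, fml, tree)
    fits[[cmp]] <- pg
    sub <- species_table[stats::complete.cases(
      species_table[, all.vars(fml)]), , drop = FALSE]
    ol <- ols_fit(sub, fml)
    sm <- sma_fit(sub, fml)
    iso <- isometry_test(sm, b0 = 1)
    allo_rows[[cmp]] <- tibble::tibble(
      model = cmp,
      method = c("PGLS", "OLS", "SMA"),
      slope = c(unname(pg$coefficients[2]), unname(ol$coefficients[2]),
                sm$slope),
      intercept = c(unname(pg$coefficients[1]), unname(ol$coefficients[1]),
                    sm$intercept),
      slope_se = c(unname(pg$se[2]), unname(ol$se[2]), NA_real_),
      lambda = c(pg$lambda, NA_real_, NA_real_),
      r_squared = c(pg$r_squared, ol$r_squared, NA_real_),
      n = c(pg$n, ol$n, sm$n),
      isometry_p = c(NA_real_, NA_real_, iso$p.value)
    )
  }
  allometry <- dplyr::bind_rows(allo_rows)
  message("stage fits: ", length(comparisons), " comparisons x 3 methods")

  # -- investment -----------------------------------------------------
  inv_key <- deparse(investment_model)
  inv_fit <- fits[[inv_key]]
  if (is.null(inv_fit)) {
    inv_fit <- pgls_fit(species_table, investment_model, tree)
  }
  eco_join <- if (is.null(ecology)) NULL else {
    dplyr::left_join(
      tibble::as_tibble(ecology) |>
        dplyr::mutate(species = normalize_labels(as.character(.data$species))),
      species_table[, c("species", "ed_mm")], by = "species")
  }
  investment <- investment_scores(inv_fit, ecology = eco_join)
  corneal <- if (!is.null(fits[["log_cd ~ log_ed"]])) {
    investment_scores(fits[["log_cd ~ log_ed"]], ecology = eco_join)
  }
  message("stage investment: ", nrow(investment), " species scored")

  # -- ecology tests --------------------------------------------------
  ecology_tests <- NULL
  group_summaries <- NULL
  if (!is.null(ecology)) {
    if (is.null(ecology_traits)) {
      ecology_traits <- intersect(names(ecology_states), names(ecology))
    }
    test_rows <- list()
    summ_rows <- list()
    for (trait in ecology_traits) {
      kw_ed <- try_test(kruskal_wallis(investment, "ed_mm", trait))
      kw_inv <- try_test(kruskal_wallis(investment, "investment", trait))
      anc <- try_test({
        eco_dat <- dplyr::left_join(
          species_table, investment[, c("species", trait)], by = "species")
        a <- phylo_ancova(eco_dat, "log_ed", "log_rm", trait, tree)
        frow <- a$table[a$table$term %in%
                          c(trait, paste0("`", trait, "`")), ]
        tibble::tibble(statistic = frow$statistic, df = frow$df,
                       df2 = a$table$df[a$table$term == "Residuals"],
                       p.value = frow$p.value, n = a$fit$n,
                       lambda = a$fit$lambda)
      })
      test_rows[[trait]] <- dplyr::bind_rows(
        tag_test(kw_ed, trait, "kruskal_wallis_ed"),
        tag_test(kw_inv, trait, "kruskal_wallis_investment"),
        tag_test(anc, trait, "phylo_ancova")
      )
      s <- try_test(group_summary(investment, trait, extra = "ed_mm"))
      if (is.data.frame(s) && !"error" %in% names(s)) {
        s$trait <- trait
        summ_rows[[trait]] <- s
      }
    }
    ecology_tests <- dplyr::bind_rows(test_rows)
    group_summaries <- dplyr::bind_rows(summ_rows)
    message("stage ecology: ", length(ecology_traits), " traits tested")
  }

  # -- outlier sensitivity -------------------------------------------
  outliers <- iterative_outlier_refit(species_table, investment_model,
                                      tree, threshold = outlier_threshold)
  message("stage outliers: ", nrow(outliers$removals), " species removed")

  structure(list(
    species = species_table, tree = tree,
    allometry = allometry, fits = fits,
    investment = investment, corneal_investment = corneal,
    ecology_tests = ecology_tests, group_summaries = group_summaries,
    outliers = outliers, seed = seed
  ), class = "pipeline_result")
}

try_test <- function(expr) {
  tryCatch(suppressWarnings(expr), error = function(e) {
    tibble::tibble(error = conditionMessage(e))
  })
}

tag_test <- function(tab, trait, test) {
  dplyr::bind_cols(tibble::tibble(trait = trait, test = test), tab)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$species), " species\n", sep = "")
  cat("Allometric fits:\n")
  print(x$allometry, n = Inf)
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Serializes the result bundle as plain-text reports: `allometry.csv`,
#' `investment.csv`, `corneal_investment.csv`, `ecology_tests.csv`,
#' `group_summaries.csv`, `outliers.csv`, `species_table.csv`,
#' `analysis_tree.nwk` and `fits.json` (coefficients, lambda, logLik and
#' residuals of every PGLS fit).
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f) {
    if (!is.null(x)) readr::write_csv(x, file.path(dir, f))
  }
  wr(result$allometry, "allometry.csv")
  wr(result$investment, "investment.csv")
  wr(result$corneal_investment, "corneal_investment.csv")
  wr(result$ecology_tests, "ecology_tests.csv")
  wr(result$group_summaries, "group_summaries.csv")
  wr(result$outliers$removals, "outliers.csv")
  wr(result$species, "species_table.csv")
  write_newick(result$tree, file.path(dir, "analysis_tree.nwk"))
  fits <- lapply(result$fits, function(f) {
    list(formula = deparse(f$formula),
         coefficients = as.list(f$coefficients),
         se = as.list(f$se),
         lambda = f$lambda, r_squared = f$r_squared,
         log_likelihood = f$log_likelihood, n = f$n,
         residuals = as.list(round(f$residuals, 10)))
  })
  jsonlite::write_json(fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
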