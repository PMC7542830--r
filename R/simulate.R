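#' Configuration for the synthetic comparative dataset
#'
#' Bundles every ground-truth parameter of the generator. Defaults mirror
#' the scale of a typical anuran-wide museum study: 220 species under a
#' Yule (pure-birth) phylogeny, hypoallometric eye-body scaling with slope
#' 0.82 and strong phylogenetic residual signal (lambda = 0.96), a
#' residual variance set so the allometry explains about 80% of whitened
#' variance, six adult-habitat states evolving along the tree with
#' additive log10 investment offsets, and 1-7 measured specimens per
#' species with multiplicative (lognormal) measurement noise and a
#' preservation-shrinkage factor for museum material.
#'
#' @param n_species Number of species (tips).
#' @param birth_rate Yule speciation rate (per unit time).
#' @param scale_tree_depth If TRUE (default) the simulated tree is rescaled
#'   to unit root-to-tip depth, so the variance parameters below are tip
#'   variances.
#' @param intercept,slope Allometric intercept and slope of log10 eye
#'   diameter on log10 cube-root mass.
#' @param lambda True Pagel's lambda of the residuals.
#' @param predictor_sigma2 Brownian tip variance of log10 cube-root mass.
#' @param r2_target Target whitened R^2 of the eye-body allometry; sets
#'   `sigma2` when that is NULL.
#' @param sigma2 Residual tip variance (log10^2); overrides `r2_target`.
#' @param state_offsets Named log10 offsets added to the response per
#'   adult-habitat state (defaults are log10 of investment factors ranging
#'   from 0.65x for fossorial to 1.24x for scansorial species).
#' @param state_frequencies Stationary habitat frequencies.
#' @param state_rate Habitat transition rate for the Markov walk, per
#'   unit branch length. The default `"auto"` targets `max(12, 0.085 n)`
#'   expected transitions over the whole tree; `NULL` draws states
#'   i.i.d. instead.
#' @param cd_slope,cd_intercept,cd_sigma2,cd_lambda Cornea-on-eye scaling.
#' @param svl_slope,svl_intercept,svl_sigma2,svl_lambda Snout-vent-length-
#'   on-cube-root-mass scaling.
#' @param al_slope,al_intercept Axial length as a linear function of eye
#'   diameter (raw mm), measurable only in fresh specimens.
#' @param specimens_min,specimens_max Per-species specimen count range.
#' @param measurement_cv Coefficient of variation of a single measurement.
#' @param preservation_shrinkage Multiplicative linear shrinkage of
#'   preserved specimens (masses shrink with its cube).
#' @param n_fresh Number of species that also get one fresh (unpreserved)
#'   specimen with a dissected axial-length measurement.
#' @param missing_rate Probability that a species' state for each of the
#'   five non-habitat ecological traits is unrecorded.
#' @param seed Integer RNG seed; identical seeds give identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 220,
                       birth_rate = 1,
                       scale_tree_depth = TRUE,
                       intercept = 0.5,
                       slope = 0.82,
                       lambda = 0.96,
                       predictor_sigma2 = 0.09,
                       r2_target = 0.80,
                       sigma2 = NULL,
                       state_offsets = c(
                         "aquatic" = log10(0.72),
                         "fossorial" = log10(0.65),
                         "ground-dwelling" = log10(1.12),
                         "scansorial" = log10(1.24),
                         "semiaquatic" = log10(1.18),
                         "subfossorial" = log10(0.91)
                       ),
                       state_frequencies = c(
                         "aquatic" = 0.12,
                         "fossorial" = 0.10,
                         "ground-dwelling" = 0.33,
                         "scansorial" = 0.22,
                         "semiaquatic" = 0.12,
                         "subfossorial" = 0.11
                       ),
                       state_rate = "auto",
                       cd_slope = 0.92, cd_intercept = -0.035,
                       cd_sigma2 = 0.003, cd_lambda = 0.40,
                       svl_slope = 0.98, svl_intercept = 1.28,
                       svl_sigma2 = 0.0036, svl_lambda = 0.75,
                       al_slope = 0.99, al_intercept = 0.02,
                       specimens_min = 1, specimens_max = 7,
                       measurement_cv = 0.03,
                       preservation_shrinkage = 0.95,
                       n_fresh = 67,
                       missing_rate = 0.02,
                       seed = 1L) {
  if (is.null(sigma2)) {
    # residual variation around the allometry = habitat effects + noise;
    # partition so the fitted eye-body model explains ~ r2_target
    total <- slope^2 * predictor_sigma2 * (1 / r2_target - 1)
    f <- state_frequencies / sum(state_frequencies)
    o <- state_offsets[names(f)]
    v_off <- if (length(o) > 0 && !anyNA(o)) {
      sum(f * (o - sum(f * o))^2)
    } else 0
    sigma2 <- max(total - v_off, 0.2 * total)
  }
  stopifnot(n_species >= 2, birth_rate > 0, predictor_sigma2 > 0,
            sigma2 > 0, lambda >= 0, lambda <= 1,
            all(state_frequencies >= 0), measurement_cv >= 0,
            is.null(state_rate) || identical(state_rate, "auto") ||
              (is.numeric(state_rate) && state_rate >= 0))
  state_frequencies <- state_frequencies / sum(state_frequencies)
  cfg <- list(
    n_species = as.integer(n_species), birth_rate = birth_rate,
    scale_tree_depth = scale_tree_depth,
    intercept = intercept, slope = slope, lambda = lambda,
    predictor_sigma2 = predictor_sigma2, sigma2 = sigma2,
    state_offsets = state_offsets,
    state_frequencies = state_frequencies, state_rate = state_rate,
    cd_slope = cd_slope, cd_intercept = cd_intercept,
    cd_sigma2 = cd_sigma2, cd_lambda = cd_lambda,
    svl_slope = svl_slope, svl_intercept = svl_intercept,
    svl_sigma2 = svl_sigma2, svl_lambda = svl_lambda,
    al_slope = al_slope, al_intercept = al_intercept,
    specimens_min = as.integer(specimens_min),
    specimens_max = as.integer(specimens_max),
    measurement_cv = measurement_cv,
    preservation_shrinkage = preservation_shrinkage,
    n_fresh = as.integer(min(n_fresh, n_species)),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else local_seed(seed, expr)
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Constant-rate speciation without extinction: while k lineages are
#' alive the next split occurs after an Exp(k * birth_rate) waiting time
#' on a uniformly chosen lineage, until n tips exist; a final
#' Exp(n * birth_rate) wait gives the terminal branches positive length.
#' The expected root-to-tip depth is `sum(1 / (k * birth_rate))` for
#' k = 2..n.
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed (NULL = use the current RNG state).
#' @param labels Optional tip labels (default `sp001`...).
#' @return A rooted, bifurcating `phylo` object.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, seed = NULL,
                               labels = NULL) {
  if (n < 2) stop("need at least 2 tips", call. = FALSE)
  if (is.null(labels)) {
    labels <- sprintf("sp%03d", seq_len(n))
  } else if (length(labels) != n) {
    stop("labels must have length n", call. = FALSE)
  }
  with_seed_or_current(seed, {
    birth <- c(0, 0)           # birth time of each lineage id
    alive <- c(1L, 2L)
    expansion <- character(2)
    t <- 0
    next_id <- 3L
    while (length(alive) < n) {
      k <- length(alive)
      t <- t + stats::rexp(1, k * birth_rate)
      i <- alive[sample.int(k, 1)]
      id1 <- next_id
      id2 <- next_id + 1L
      next_id <- next_id + 2L
      expansion[c(id1, id2)] <- ""
      birth[c(id1, id2)] <- t
      expansion[i] <- sprintf("(<%d>,<%d>):%.17g", id1, id2, t - birth[i])
      alive <- c(alive[alive != i], id1, id2)
    }
    t <- t + stats::rexp(1, n * birth_rate)
    for (j in seq_along(alive)) {
      i <- sort(alive)[j]
      expansion[i] <- sprintf("%s:%.17g", labels[j], t - birth[i])
    }
    txt <- "(<1>,<2>);"
    for (id in seq_len(next_id - 1L)) {
      txt <- sub(sprintf("<%d>", id), expansion[id], txt, fixed = TRUE)
    }
    tree <- ape::read.tree(text = txt)
    validate_phylogeny(tree)
    tree
  })
}

tree_depth <- function(tree) {
  max(diag(ape::vcv.phylo(tree)))
}

#' Simulate a Brownian predictor on a tree
#'
#' One multivariate-normal draw of a continuous trait (canonically log10
#' cube-root mass) with covariance `sigma2 * C(1)` where C is the
#' phylogenetic covariance of the tree.
#'
#' @param tree A `phylo`.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param seed Integer seed (NULL = current RNG state).
#' @param mean Grand mean added to the draw.
#' @return Named numeric vector in tip order.
#' @export
simulate_predictor <- function(tree, sigma2, seed = NULL, mean = 0) {
  C <- ape::vcv.phylo(tree)
  with_seed_or_current(seed, {
    mean + mvn_draw(sigma2 * C)
  })
}

# one MVN(0, S) draw via Cholesky (pivoting tolerated for PSD S)
mvn_draw <- function(S) {
  n <- nrow(S)
  if (all(S == 0)) return(stats::setNames(rep(0, n), rownames(S)))
  R <- chol(S + diag(1e-12 * max(diag(S)), n))
  stats::setNames(as.numeric(t(R) %*% stats::rnorm(n)), rownames(S))
}

#' Simulate an allometric response with phylogenetic residuals
#'
#' `y = intercept + slope * x + e` with
#' `e ~ MVN(0, sigma2 * C(lambda))`: residuals carry phylogenetic
#' correlation governed by Pagel's lambda.
#'
#' @param tree A `phylo`.
#' @param x Named predictor vector aligned with the tips.
#' @param intercept,slope,sigma2,lambda Generative parameters.
#' @param seed Integer seed (NULL = current RNG state).
#' @return Named numeric response vector in tip order.
#' @export
simulate_allometry <- function(tree, x, intercept, slope, sigma2, lambda,
                               seed = NULL) {
  stopifnot(setequal(names(x), tree$tip.label))
  x <- x[tree$tip.label]
  Cl <- lambda_transform(ape::vcv.phylo(tree), lambda)
  with_seed_or_current(seed, {
    e <- if (sigma2 == 0) rep(0, length(x)) else mvn_draw(sigma2 * Cl)
    stats::setNames(intercept + slope * x + as.numeric(e), tree$tip.label)
  })
}

#' Simulate categorical states on a tree
#'
#' Either i.i.d. draws from the supplied frequencies, or a continuous-time
#' Markov jump process along branches: changes occur at `rate` per unit
#' branch length and each change resamples the state from the stationary
#' frequencies, so states are phylogenetically clumped (as real habitat
#' use is).
#'
#' @param tree A `phylo`.
#' @param frequencies Named state probabilities.
#' @param rate Jump rate per unit branch length; NULL for i.i.d. draws.
#' @param seed Integer seed (NULL = current RNG state).
#' @return Named character vector of states in tip order.
#' @export
simulate_states <- function(tree, frequencies, rate = NULL, seed = NULL) {
  stopifnot(length(frequencies) >= 1, all(frequencies >= 0))
  states <- names(frequencies)
  p <- frequencies / sum(frequencies)
  n <- ape::Ntip(tree)
  with_seed_or_current(seed, {
    if (is.null(rate)) {
      out <- sample(states, n, replace = TRUE, prob = p)
      return(stats::setNames(out, tree$tip.label))
    }
    nn <- ape::Nnode(tree)
    node_state <- character(n + nn)
    root <- n + 1L
    node_state[root] <- sample(states, 1, prob = p)
    # preorder: parents always precede children in reorder(tree)$edge
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]
      child <- ord$edge[e, 2]
      jumps <- stats::rpois(1, rate * ord$edge.length[e])
      node_state[child] <- if (jumps > 0) {
        sample(states, 1, prob = p)
      } else {
        node_state[parent]
      }
    }
    stats::setNames(node_state[seq_len(n)], tree$tip.label)
  })
}

apply_state_offsets <- function(y, states, offsets) {
  if (is.null(offsets)) return(y)
  unknown <- setdiff(unique(states), names(offsets))
  if (length(unknown) > 0) {
    stop("no offset defined for state(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  y + unname(offsets[states[names(y)]])
}

#' Simulate specimen-level measurement records
#'
#' Expands species-level true trait values into noisy per-specimen
#' records: a uniform 1-7 specimens per species, left/right eye and cornea
#' measurements with independent multiplicative lognormal noise, preserved
#' specimens shrunk linearly by `preservation_shrinkage` (mass by its
#' cube), and one fresh specimen with a dissected axial-length measurement
#' for a subset of species.
#'
#' @param species_truth Data frame with columns `species`, `ed_mm`,
#'   `cd_mm`, `svl_mm`, `mass_g`, `al_mm`.
#' @param config A [sim_config()] (specimen-related fields are used).
#' @param seed Integer seed (NULL = current RNG state).
#' @return A tibble of specimen records: `species`, `collection_id`,
#'   `condition`, `svl_mm`, `mass_g`, `ed_left_mm`, `ed_right_mm`,
#'   `cd_left_mm`, `cd_right_mm`, `al_mm` (NA unless fresh).
#' @export
simulate_specimens <- function(species_truth, config, seed = NULL) {
  cv <- config$measurement_cv
  sdlog <- sqrt(log(1 + cv^2))
  shrink <- config$preservation_shrinkage
  with_seed_or_current(seed, {
    n_sp <- nrow(species_truth)
    fresh_species <- species_truth$species[
      sample.int(n_sp, config$n_fresh)]
    rows <- purrr::pmap(species_truth, function(species, ed_mm, cd_mm,
                                                svl_mm, mass_g, al_mm,
                                                ...) {
      k <- sample(seq(config$specimens_min, config$specimens_max), 1)
      is_fresh <- species %in% fresh_species
      cond <- c(rep("preserved", k), if (is_fresh) "fresh")
      m <- length(cond)
      noise <- function() stats::rlnorm(m, -sdlog^2 / 2, sdlog)
      s <- ifelse(cond == "preserved", shrink, 1)
      tibble::tibble(
        species = species,
        collection_id = sprintf("%s_%02d", species, seq_len(m)),
        condition = cond,
        svl_mm = svl_mm * s * noise(),
        mass_g = mass_g * s^3 * noise(),
        ed_left_mm = ed_mm * s * noise(),
        ed_right_mm = ed_mm * s * noise(),
        cd_left_mm = cd_mm * s * noise(),
        cd_right_mm = cd_mm * s * noise(),
        al_mm = ifelse(cond == "fresh", al_mm * noise(), NA_real_)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a complete synthetic comparative dataset
#'
#' Runs the whole generative model of [sim_config()]: Yule tree (rescaled
#' to unit depth by default), Brownian log10 cube-root mass, adult-habitat
#' states with additive investment offsets, eye diameter from the
#' allometric model with lambda-correlated residuals, cornea and
#' snout-vent length from their own scaling relations, the remaining five
#' ecological traits, and specimen-level records. The ground truth travels
#' with the data so recovery can be scored automatically.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_dataset`: `tree` (phylo), `species`
#'   (species-level tibble incl. log10 columns), `specimens`, `ecology`,
#'   `truth` (the config plus derived truths).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    tree <- simulate_yule_tree(config$n_species, config$birth_rate)
    if (config$scale_tree_depth) {
      tree$edge.length <- tree$edge.length / tree_depth(tree)
    }
    log_rm <- simulate_predictor(tree, config$predictor_sigma2)
    # habitat rate: "auto" targets an expected number of habitat shifts
    # that grows with clade size, so every guild is represented while
    # habitat stays strongly clade-conserved
    rate <- config$state_rate
    if (identical(rate, "auto")) {
      rate <- max(12, 0.085 * config$n_species) / sum(tree$edge.length)
    }
    # all states must be represented well enough to fit the factor models;
    # redraw the (clumped) walk until the rarest state has enough species
    # (like a study design that targets all habitat guilds), escalating
    # the rate if extreme clumping keeps a guild empty
    min_per_state <- min(5L, floor(config$n_species /
                                     (3 * length(config$state_frequencies))))
    for (try in 1:200) {
      habitat <- simulate_states(tree, config$state_frequencies,
                                 rate = rate)
      counts <- table(factor(habitat,
                             levels = names(config$state_frequencies)))
      if (min(counts) >= min_per_state) break
      if (try %% 50 == 0) rate <- rate * 1.5
    }
    log_ed <- simulate_allometry(tree, log_rm, config$intercept,
                                 config$slope, config$sigma2,
                                 config$lambda)
    log_ed <- apply_state_offsets(log_ed, habitat, config$state_offsets)
    log_cd <- simulate_allometry(tree, log_ed, config$cd_intercept,
                                 config$cd_slope, config$cd_sigma2,
                                 config$cd_lambda)
    log_svl <- simulate_allometry(tree, log_rm, config$svl_intercept,
                                  config$svl_slope, config$svl_sigma2,
                                  config$svl_lambda)
    ed_mm <- 10^log_ed
    species <- tibble::tibble(
      species = tree$tip.label,
      ed_mm = unname(ed_mm),
      cd_mm = unname(10^log_cd),
      svl_mm = unname(10^log_svl),
      mass_g = unname((10^log_rm)^3),
      al_mm = unname(config$al_intercept + config$al_slope * ed_mm),
      rm = unname(10^log_rm),
      log_ed = unname(log_ed),
      log_cd = unname(log_cd),
      log_svl = unname(log_svl),
      log_rm = unname(log_rm)
    )
    ecology <- simulate_ecology_traits(tree, habitat, config)
    specimens <- simulate_specimens(species, config)
    truth <- c(unclass(config),
               list(tree_depth = tree_depth(tree),
                    habitat = habitat))
    structure(list(tree = tree, species = species, specimens = specimens,
                   ecology = ecology, truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

# the five non-habitat traits: i.i.d. states with a little missingness
simulate_ecology_traits <- function(tree, habitat, config) {
  n <- ape::Ntip(tree)
  draw <- function(states, prob) {
    s <- sample(states, n, replace = TRUE, prob = prob)
    s[stats::runif(n) < config$missing_rate] <- NA
    s
  }
  tibble::tibble(
    species = tree$tip.label,
    adult_habitat = unname(habitat),
    activity = draw(ecology_states$activity, c(0.15, 0.15, 0.70)),
    mating_habitat = draw(ecology_states$mating_habitat,
                          c(0.25, 0.45, 0.15, 0.15)),
    life_history = draw(ecology_states$life_history, c(0.85, 0.15)),
    larval_habitat = draw(ecology_states$larval_habitat,
                          c(0.50, 0.20, 0.15, 0.15)),
    dichromatism = draw(ecology_states$dichromatism, c(0.7, 0.3))
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$species), " species, ",
      nrow(x$specimens), " specimens (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Emits `tree.nwk`, `traits.csv` (specimen-level), `species_ecology.csv`
#' and `truth.json` into a directory; the files round-trip through the
#' pipeline readers.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  readr::write_csv(dataset$specimens, file.path(dir, "traits.csv"))
  readr::write_csv(dataset$ecology, file.path(dir, "species_ecology.csv"))
  truth <- dataset$truth
  truth$habitat <- as.list(truth$habitat)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
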