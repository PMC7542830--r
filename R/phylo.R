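#' Read a rooted phylogram from a Newick file
#'
#' Reads a Newick tree with branch lengths, normalizes tip labels (spaces
#' become underscores, surrounding quotes stripped) and validates that the
#' tree is usable for phylogenetic regression: every edge must carry a
#' finite, non-negative length and tip labels must be unique.
#'
#' @param path Path to a Newick file, or a Newick string passed via `text`.
#' @param text Optional Newick string; used instead of `path` when supplied.
#' @return An [ape::phylo] object (rooted, branch lengths in the input's
#'   units).
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) {
      stop("Newick file not found: ", path, call. = FALSE)
    }
    tree <- ape::read.tree(path)
  } else {
    tree <- ape::read.tree(text = text)
  }
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  tree$tip.label <- normalize_labels(tree$tip.label)
  validate_phylogeny(tree)
  tree
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Spaces and underscores are used interchangeably by Newick producers;
# internal representation is underscores.
normalize_labels <- function(x) {
  x <- gsub("^['\"]|['\"]$", "", x)
  gsub(" ", "_", trimws(x))
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  bad <- which(!is.finite(tree$edge.length) | tree$edge.length < 0)
  if (length(bad) > 0) {
    lab <- edge_labels(tree, bad)
    stop("missing or negative branch length on edge(s): ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  invisible(tree)
}

edge_labels <- function(tree, idx) {
  child <- tree$edge[idx, 2]
  ifelse(child <= ape::Ntip(tree), tree$tip.label[child],
         paste0("node#", child))
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips not in `keep`, collapsing the resulting degree-2 internal
#' nodes by summing branch lengths, so that path lengths between every pair
#' of retained tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (spaces and
#'   underscores equivalent).
#' @return A pruned `phylo` object with exactly the kept tips.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- normalize_labels(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Rename tip labels (close-relative substitution)
#'
#' Replaces tip labels according to a mapping, leaving topology and branch
#' lengths untouched. Used to substitute sampled species for close relatives
#' present in a source phylogeny.
#'
#' @param tree A `phylo` object.
#' @param mapping Named character vector (`old = new`) or a data frame with
#'   columns `old` and `new`.
#' @param quiet Suppress the per-substitution log.
#' @return The relabelled `phylo` object, with the substitution log attached
#'   as attribute `"substitutions"` (a tibble).
#' @export
substitute_tips <- function(tree, mapping, quiet = FALSE) {
  if (is.data.frame(mapping)) {
    map <- stats::setNames(as.character(mapping$new), as.character(mapping$old))
  } else {
    map <- mapping
  }
  if (length(map) == 0) return(tree)
  old <- normalize_labels(names(map))
  new <- normalize_labels(unname(map))
  missing_old <- setdiff(old, tree$tip.label)
  if (length(missing_old) > 0) {
    stop("tips to substitute not in tree: ",
         paste(missing_old, collapse = ", "), call. = FALSE)
  }
  out <- tree$tip.label
  idx <- match(old, out)
  out[idx] <- new
  clash <- unique(out[duplicated(out)])
  if (length(clash) > 0) {
    stop("substitution would duplicate tip label(s): ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  tree$tip.label <- out
  log <- tibble::tibble(old = old, new = new)
  if (!quiet) {
    message("substituted ", nrow(log), " tip label(s)")
  }
  attr(tree, "substitutions") <- log
  tree
}

#' Graft a new tip as a polytomous sister
#'
#' Attaches `new_taxon` at the parent node of `sister`, creating (or
#' extending) a polytomy. The new terminal branch copies the sister's
#' terminal branch length, so the pair is exchangeable: their root-to-tip
#' depths are equal and their mutual distance is twice the sister's pendant
#' branch.
#'
#' @param tree A `phylo` object.
#' @param new_taxon Label for the new tip.
#' @param sister Label of an existing tip to attach beside.
#' @return A `phylo` object with one additional tip.
#' @export
graft_polytomy_tip <- function(tree, new_taxon, sister) {
  new_taxon <- normalize_labels(new_taxon)
  sister <- normalize_labels(sister)
  tip <- match(sister, tree$tip.label)
  if (is.na(tip)) stop("sister tip not in tree: ", sister, call. = FALSE)
  if (new_taxon %in% tree$tip.label) {
    stop("tip already present: ", new_taxon, call. = FALSE)
  }
  n <- ape::Ntip(tree)
  edge_idx <- which(tree$edge[, 2] == tip)
  len <- tree$edge.length[edge_idx]
  # direct edge-matrix surgery keeps every existing branch length
  # bit-identical: shift internal node ids up one to free id n + 1 for the
  # new tip, then hang it off the sister's parent
  edge <- tree$edge
  edge[edge > n] <- edge[edge > n] + 1L
  parent <- edge[edge_idx, 1]
  tree$edge <- rbind(edge, c(parent, n + 1L))
  tree$edge.length <- c(tree$edge.length, len)
  tree$tip.label <- c(tree$tip.label, new_taxon)
  attr(tree, "order") <- NULL
  out <- ape::reorder.phylo(tree, "cladewise")
  message("grafted ", new_taxon, " as polytomous sister of ", sister,
          " (pendant length ", format(len), ")")
  out
}

#' Randomly resolve polytomies into a bifurcating tree
#'
#' Multifurcations are binarized by random sequential splitting with
#' zero-length inserted edges, so all pairwise tip path lengths (and hence
#' the phylogenetic covariance) are unchanged. Identical seeds give
#' identical resolutions.
#'
#' @param tree A `phylo` object.
#' @param seed Integer RNG seed.
#' @return A fully bifurcating `phylo` object on the same tip set.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  out <- local_seed(seed, ape::multi2di(tree, random = TRUE))
  if (is.null(out$edge.length)) out$edge.length <- numeric(nrow(out$edge))
  out
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Phylogenetic covariance matrix of a tree
#'
#' Builds the among-species covariance structure implied by a rooted
#' phylogram under Brownian motion: `C[i, j]` is the shared root-to-tip path
#' length of tips i and j, and the diagonal holds root-to-tip distances.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param jitter_zero_rows If two tips are phylogenetically identical
#'   (zero-length pendant edges on the same node make C singular), add a
#'   diagonal jitter of `1e-8 *` tree depth and warn.
#' @return An object of class `phylo_cov`: a list with `taxa` (tip order),
#'   `C` (the matrix) and `lambda` (1 for the untransformed structure).
#' @seealso [apply_lambda()]
#' @export
phylo_covariance <- function(tree, jitter_zero_rows = TRUE) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  dup <- duplicated(C) | duplicated(C, fromLast = TRUE)
  if (any(dup) && jitter_zero_rows) {
    eps <- 1e-8 * max(diag(C))
    diag(C) <- diag(C) + eps
    warning("phylogenetically identical tips detected; diagonal jitter of ",
            format(eps), " applied", call. = FALSE)
  }
  new_phylo_cov(rownames(C), C, lambda = 1)
}

new_phylo_cov <- function(taxa, C, lambda) {
  structure(list(taxa = taxa, C = C, lambda = lambda), class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat("<phylo_cov> ", length(x$taxa), " taxa, lambda = ",
      format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' Apply Pagel's lambda transform to a phylogenetic covariance
#'
#' Multiplies the off-diagonal elements by `lambda`, leaving root-to-tip
#' variances (the diagonal) unchanged. `lambda = 1` is the Brownian
#' expectation; `lambda = 0` removes all phylogenetic correlation.
#'
#' @param cov A `phylo_cov` object (as from [phylo_covariance()]).
#' @param lambda Real in \[0, 1\].
#' @return A `phylo_cov` with the transformed matrix.
#' @export
apply_lambda <- function(cov, lambda) {
  stopifnot(inherits(cov, "phylo_cov"))
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must be in [0, 1], got ", lambda, call. = FALSE)
  }
  C <- cov$C * lambda
  diag(C) <- diag(cov$C)
  new_phylo_cov(cov$taxa, C, lambda = lambda)
}

#' Pairwise tip path-length matrix
#'
#' Patristic distances between all tip pairs; the invariance oracle for the
#' tree-editing operations.
#'
#' @param tree A `phylo` object.
#' @return A symmetric matrix of tip-to-tip path lengths.
#' @export
tip_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
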