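# Phylogenetic characteristics of rearranged genomes: per-clade upper-tail
# hypergeometric enrichment of binary tip labels (with Bonferroni correction
# over the tested internal nodes), a hypergeometric test of whether rare
# arrangements track sparse taxon sampling, and MRCA-age bounds on the
# occurrence time of shared arrangement patterns. Trees come in as ape
# "phylo" objects; tree inference is out of scope.

# upper-tail hypergeometric probability P(X >= k) for a draw of n from a
# population of N containing K successes
.hyper_upper <- function(k, N, K, n) {
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

# coerce labels to a named logical over the tree's tips
.tip_labels <- function(tree, labels) {
  if (is.data.frame(labels)) {
    stopifnot(ncol(labels) >= 2)
    labels <- stats::setNames(as.logical(labels[[2]]), labels[[1]])
  }
  if (is.null(names(labels))) {
    stop("`labels` must be named by species_id (or be a 2-column data frame)",
         call. = FALSE)
  }
  miss <- setdiff(names(labels), tree$tip.label)
  if (length(miss)) {
    stop("labelled species not in the tree: ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(rep(FALSE, length(tree$tip.label)), tree$tip.label)
  out[names(labels)] <- as.logical(labels)
  out
}

#' Hypergeometric clade enrichment of binary tip labels
#'
#' Tests whether labelled tips (e.g. genomes with rearranged arrangements)
#' cluster phylogenetically. For every internal node whose clade contains
#' between 2 and N-1 tips, the number of labelled tips in the clade is
#' compared to drawing the clade at random from all tips: the raw p-value is
#' the upper-tail hypergeometric probability of at least the observed
#' overlap, and p-values are Bonferroni-adjusted for the number of nodes
#' tested. The summary statistic is the minimum adjusted p over nodes. When
#' all tips carry the same label the test is degenerate and every p is 1.
#'
#' @param tree An `ape::phylo` tree whose tip labels are species ids.
#' @param labels A logical vector named by species id, or a 2-column data
#'   frame (species_id, label); species absent from `labels` count as
#'   unlabelled.
#' @return An object of class `mgr_enrichment`: a tibble with one row per
#'   tested node (`node`, `clade_size`, `k_labeled`, `p_value`, `p_adj`),
#'   with attributes `N`, `K`, `n_tests`, `min_p_adj`.
#' @export
#' @examples
#' tree <- ape::read.tree(text = "((a,b),(c,d));")
#' clade_enrichment(tree, c(a = TRUE, b = TRUE, c = FALSE, d = FALSE))
clade_enrichment <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  lab <- .tip_labels(tree, labels)
  N <- length(lab)
  K <- sum(lab)
  parts <- ape::prop.part(tree)   # tip index sets per internal node
  nodes <- seq_along(parts) + N
  rows <- purrr::map2(parts, nodes, function(tips, node) {
    n <- length(tips)
    if (n < 2 || n > N - 1) return(NULL)
    k <- sum(lab[tips])
    tibble::tibble(node = node, clade_size = n, k_labeled = k,
                   p_value = .hyper_upper(k, N, K, n))
  })
  out <- dplyr::bind_rows(rows)
  n_tests <- nrow(out)
  out$p_adj <- pmin(1, out$p_value * n_tests)
  structure(out,
            class = c("mgr_enrichment", class(out)),
            N = N, K = K, n_tests = n_tests,
            min_p_adj = if (n_tests) min(out$p_adj) else NA_real_)
}

#' @export
print.mgr_enrichment <- function(x, ...) {
  cat("<clade enrichment: N = ", attr(x, "N"), ", labelled K = ", attr(x, "K"),
      ", ", attr(x, "n_tests"), " nodes tested, min adjusted p = ",
      format(attr(x, "min_p_adj"), digits = 3), ">\n", sep = "")
  NextMethod()
}

#' Do rare arrangements track sparse taxon sampling?
#'
#' Upper-tail hypergeometric test of the overlap between rare-arrangement
#' species and species from sparsely sampled families. The population is
#' all species in the taxon table; successes are species whose family
#' contributes at most `sparse_max` sampled species; the draw is the set of
#' rare-arrangement species from the census.
#'
#' @param census An [census()] result (its `single`/`double` classes define
#'   the rare species).
#' @param taxa A data frame with columns `species_id` and `family` (or a
#'   gene-order tibble, in which case family is taken as the second
#'   `";"`-rank of `taxon`). Every census species must have a family.
#' @param sparse_max A family is "sparsely sampled" when it has at most this
#'   many species in the table (default 2).
#' @return A one-row tibble: `N`, `K_sparse`, `n_rare`, `k_overlap`,
#'   `p_value`.
#' @export
sampling_density_test <- function(census, taxa, sparse_max = 2) {
  stopifnot(inherits(census, "mgr_census"))
  if (!"family" %in% names(taxa)) {
    stopifnot(all(c("species_id", "taxon") %in% names(taxa)))
    taxa <- taxa |>
      dplyr::distinct(species_id, taxon) |>
      dplyr::mutate(
        family = purrr::map_chr(strsplit(taxon, ";", fixed = TRUE), function(r) {
          if (length(r) >= 2 && nzchar(trimws(r[2]))) trimws(r[2]) else NA_character_
        })
      )
  }
  taxa <- dplyr::distinct(taxa, species_id, family)
  if (anyNA(taxa$family) || any(!nzchar(taxa$family))) {
    bad <- taxa$species_id[is.na(taxa$family) | !nzchar(taxa$family)]
    stop("species without family annotation: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  rare <- unlist(census$members[census$class %in% c("double", "single")])
  miss <- setdiff(rare, taxa$species_id)
  if (length(miss)) {
    stop("rare species missing from the taxon table: ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  fam_n <- dplyr::count(taxa, family)
  sparse_fams <- fam_n$family[fam_n$n <= sparse_max]
  sparse_sp <- taxa$species_id[taxa$family %in% sparse_fams]
  N <- nrow(taxa)
  K <- length(sparse_sp)
  n <- length(rare)
  k <- length(intersect(rare, sparse_sp))
  tibble::tibble(N = N, K_sparse = K, n_rare = n, k_overlap = k,
                 p_value = .hyper_upper(k, N, K, n))
}

#' Latest possible occurrence time of a shared pattern
#'
#' The age of the most recent common ancestor of a set of species sharing an
#' arrangement pattern bounds the pattern's origin: assuming the pattern was
#' inherited from a common ancestor rather than arising convergently, it
#' must be at least as old as their divergence, so the MRCA age is the
#' latest possible occurrence time.
#'
#' @param tree An `ape::phylo` tree; species must be tips.
#' @param species Character vector (length >= 2) of species sharing the
#'   pattern.
#' @param ages Optional named numeric vector of node ages in Ma, named by
#'   the tree's node labels. When `NULL`, ages are taken from the tree's
#'   branch lengths via [ape::branching.times()] (the tree must then be
#'   ultrametric in time units).
#' @return The MRCA age in Ma (a single number).
#' @export
#' @examples
#' tree <- ape::read.tree(text = "((frog1:250,frog2:250)anura:100,sal:350)root;")
#' mrca_age(tree, c("frog1", "frog2"))   # 250
mrca_age <- function(tree, species, ages = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(species) < 2) {
    stop("need at least 2 species to bound a pattern's age", call. = FALSE)
  }
  miss <- setdiff(species, tree$tip.label)
  if (length(miss)) {
    stop("species not in the tree: ", paste(sQuote(miss), collapse = ", "),
         call. = FALSE)
  }
  node <- ape::getMRCA(tree, species)
  if (!is.null(ages)) {
    if (is.null(tree$node.label)) {
      stop("`ages` given but the tree has no node labels", call. = FALSE)
    }
    lab <- tree$node.label[node - length(tree$tip.label)]
    if (!lab %in% names(ages)) {
      stop("no age for MRCA node ", sQuote(lab), call. = FALSE)
    }
    return(unname(ages[[lab]]))
  }
  bt <- ape::branching.times(tree)   # one entry per internal node, root first
  unname(bt[[node - length(tree$tip.label)]])
}

#' Read a node-age sidecar table
#'
#' Reads a two-column TSV (node label, age in Ma; `#` comments allowed)
#' into the named vector [mrca_age()] expects.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of ages.
#' @export
read_node_ages <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("ages table needs 2 columns: node label, age (Ma)",
                          call. = FALSE)
  ages <- stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  if (any(ages < 0, na.rm = TRUE)) stop("negative node age", call. = FALSE)
  ages
}
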