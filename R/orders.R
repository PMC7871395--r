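# Tidy representation of circular gene orders: one row per gene occurrence,
# columns species_id, taxon, position, label, copy, strand. `position` runs
# 1..n within a species in reading order and is interpreted circularly (the
# last occurrence is adjacent to the first).

#' Build a gene-order tibble from token vectors
#'
#' The package's working representation of gene orders is a long tibble with
#' one row per gene occurrence and columns `species_id`, `taxon`,
#' `position`, `label`, `copy` and `strand`. `position` is the 1-based
#' reading-order index, interpreted circularly; `copy` is the 1-based
#' ordinal among occurrences of the same label within the species (so a
#' tandemly duplicated trnT appears as copies 1 and 2); `strand` is `"+"`,
#' `"-"` or `"?"`. Strand is carried through I/O but ignored by all scoring
#' and pattern comparison by default.
#'
#' @param species_id Species identifier (single string).
#' @param tokens Character vector of gene tokens in reading order; a leading
#'   `"-"` marks the minus strand. Tokens are resolved through
#'   [normalize_gene_tokens()].
#' @param taxon Taxonomic ranks as a single `";"`-joined string
#'   (order;family at minimum) or a character vector of ranks.
#' @return A gene-order tibble.
#' @export
#' @examples
#' gene_order("sp1", c("F", "rrnS", "V"), taxon = "Anura;Ranidae")
gene_order <- function(species_id, tokens, taxon = "") {
  stopifnot(is.character(species_id), length(species_id) == 1)
  if (length(taxon) > 1) taxon <- paste(taxon, collapse = ";")
  if (length(tokens) == 0) {
    stop("empty token list for species ", sQuote(species_id), call. = FALSE)
  }
  strand <- ifelse(startsWith(tokens, "-"), "-", "+")
  tokens <- sub("^-", "", tokens)
  labels <- normalize_gene_tokens(tokens, context = species_id)
  out <- tibble::tibble(
    species_id = species_id,
    taxon = taxon,
    position = seq_along(labels),
    label = labels,
    copy = stats::ave(seq_along(labels), labels, FUN = seq_along),
    strand = strand
  )
  as_gene_orders(out)
}

#' Validate and normalise a gene-order tibble
#'
#' Checks the gene-order contract: required columns present, labels in the
#' closed alphabet, every species has at least 2 occurrences, positions are
#' a contiguous 1..n run per species. Rows are sorted by species (first-seen
#' order preserved) and position, and `copy` is (re)assigned by reading
#' order so that copies of a label are numbered consecutively from 1.
#'
#' @param orders A data frame with at least `species_id` and `label`
#'   columns; `taxon`, `position` and `strand` are filled with defaults when
#'   absent.
#' @return A validated gene-order tibble.
#' @export
as_gene_orders <- function(orders) {
  stopifnot(is.data.frame(orders))
  miss <- setdiff(c("species_id", "label"), names(orders))
  if (length(miss)) {
    stop("gene orders need columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  orders <- tibble::as_tibble(orders)
  if (!"taxon" %in% names(orders)) orders$taxon <- ""
  if (!"strand" %in% names(orders)) orders$strand <- "+"
  if (!"position" %in% names(orders)) {
    orders <- orders |>
      dplyr::mutate(position = dplyr::row_number(), .by = "species_id")
  }
  bad <- setdiff(unique(orders$label), gene_alphabet())
  if (length(bad)) {
    stop("labels outside the gene alphabet: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  orders <- orders |>
    dplyr::mutate(.sp_order = match(species_id, unique(species_id))) |>
    dplyr::arrange(.sp_order, position) |>
    dplyr::mutate(
      position = dplyr::row_number(),
      .by = "species_id"
    ) |>
    dplyr::mutate(
      copy = stats::ave(seq_along(label), paste(.sp_order, label), FUN = seq_along)
    ) |>
    dplyr::select(-".sp_order")
  n_by <- dplyr::count(orders, species_id)
  short <- n_by$species_id[n_by$n < 2]
  if (length(short)) {
    stop("gene orders must have length >= 2; too short: ",
         paste(sQuote(short), collapse = ", "), call. = FALSE)
  }
  orders |>
    dplyr::select(dplyr::all_of(c("species_id", "taxon", "position",
                                  "label", "copy", "strand")),
                  dplyr::everything())
}

# token vectors per species, preserving first-seen species order
order_tokens <- function(orders) {
  orders <- as_gene_orders(orders)
  split(orders$label, factor(orders$species_id, levels = unique(orders$species_id)))
}

#' Circular flanking neighbours of a position
#'
#' Returns the labels at the two nearest flanking positions of a gene
#' occurrence, with circular wrap-around: for the first position the left
#' neighbour is the last element, and vice versa.
#'
#' @param order A gene-order tibble for a single species, or a character
#'   vector of labels.
#' @param position 1-based position in the circular order.
#' @return Named character vector `c(left = ..., right = ...)`.
#' @export
#' @examples
#' ref <- typical_vertebrate()
#' neighbor_context(ref$label, which(ref$label == "F"))
neighbor_context <- function(order, position) {
  tokens <- if (is.character(order)) order else {
    stopifnot(is.data.frame(order))
    if (dplyr::n_distinct(order$species_id) != 1) {
      stop("neighbor_context() expects a single species", call. = FALSE)
    }
    order$label[base::order(order$position)]
  }
  n <- length(tokens)
  if (n < 2) stop("circular neighbours need length >= 2", call. = FALSE)
  if (position < 1 || position > n) stop("position out of range", call. = FALSE)
  c(left = tokens[if (position == 1) n else position - 1],
    right = tokens[if (position == n) 1 else position + 1])
}
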