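# qMGR-style rearrangement scoring. Each gene occurrence is compared to the
# single reference context of its label: the rearrangement score (RS) of an
# occurrence is the number of its two circular flanking neighbours that
# differ from the reference neighbours (0, 1 or 2). A genome's RS is the sum
# over all occurrences; a gene's rearrangement frequency (RF) within a group
# is its accumulated RS over its maximum possible RS (2 per occurrence), as
# a percentage.

#' Score every gene occurrence against a reference arrangement
#'
#' For each occurrence, the observed circular left/right neighbours are
#' compared with the reference neighbours of that label. In `"ordered"` mode
#' (the default) left is compared with left and right with right, matching
#' the fixed reading direction of mitogenome records. In `"unordered"` mode
#' the observed neighbour pair is compared with the reference pair as an
#' unordered multiset; the score is the size of the multiset difference, so
#' unordered RS never exceeds ordered RS. Every occurrence of a duplicated
#' label is scored independently against the label's single reference
#' context (neighbour labels, not copy identities, are compared, so a
#' tandem duplication scores 2 in total). Genes absent from the genome
#' contribute nothing themselves; their loss surfaces through the changed
#' flanks of surviving neighbours.
#'
#' @param orders A gene-order tibble (any number of species); see
#'   [as_gene_orders()].
#' @param reference A reference arrangement: an object from
#'   [reference_arrangement()], `"vertebrate"`, `"neobatrachian"`, or a path
#'   to a single-arrangement gene-order TSV.
#' @param mode `"ordered"` (default) or `"unordered"`.
#' @return A tibble with one row per occurrence: `species_id`, `position`,
#'   `label`, `copy`, `left_obs`, `right_obs`, `left_changed`,
#'   `right_changed`, `rs`. `rs = left_changed + right_changed` always.
#' @seealso [score_genomes()], [rf_table()]
#' @export
#' @examples
#' dup <- gene_order("dupT", append(typical_vertebrate()$label, "T",
#'                                  after = which(typical_vertebrate()$label == "T")))
#' score_genes(dup)[score_genes(dup)$rs > 0, ]
score_genes <- function(orders, reference = typical_vertebrate(),
                        mode = c("ordered", "unordered")) {
  mode <- match.arg(mode)
  orders <- as_gene_orders(orders)
  reference <- as_reference(reference)
  missing_ref <- setdiff(unique(orders$label), reference$label)
  if (length(missing_ref)) {
    stop("label(s) absent from the reference arrangement: ",
         paste(sQuote(missing_ref), collapse = ", "), call. = FALSE)
  }

  # observed circular neighbours, vectorised across all species:
  # rows are sorted species-block-wise with position 1..n, so the row index
  # of a neighbour is pure arithmetic.
  n_occ <- dplyr::add_count(orders, species_id, name = ".n")$.n
  idx <- seq_len(nrow(orders))
  first <- idx - orders$position + 1L
  left_idx <- ifelse(orders$position == 1L, first + n_occ - 1L, idx - 1L)
  right_idx <- ifelse(orders$position == n_occ, first, idx + 1L)

  scored <- orders |>
    dplyr::mutate(left_obs = label[left_idx], right_obs = label[right_idx]) |>
    dplyr::left_join(ref_neighbors(reference), by = "label")

  if (mode == "ordered") {
    scored <- scored |>
      dplyr::mutate(
        left_changed = as.integer(left_obs != ref_left),
        right_changed = as.integer(right_obs != ref_right)
      )
  } else {
    # best matching between the observed pair and the reference pair as
    # 2-element multisets: straight pairing vs crossed pairing
    scored <- scored |>
      dplyr::mutate(
        .straight = (left_obs == ref_left) + (right_obs == ref_right),
        .crossed = (left_obs == ref_right) + (right_obs == ref_left),
        left_changed = ifelse(.straight >= .crossed,
                              as.integer(left_obs != ref_left),
                              as.integer(left_obs != ref_right)),
        right_changed = ifelse(.straight >= .crossed,
                               as.integer(right_obs != ref_right),
                               as.integer(right_obs != ref_left))
      ) |>
      dplyr::select(-".straight", -".crossed")
  }
  scored |>
    dplyr::mutate(rs = left_changed + right_changed) |>
    dplyr::select(dplyr::all_of(c("species_id", "taxon", "position", "label",
                                  "copy", "left_obs", "right_obs",
                                  "left_changed", "right_changed", "rs")))
}

#' Genome-level rearrangement scores
#'
#' Sums the per-occurrence rearrangement scores of [score_genes()] over each
#' genome. The number of rearranged genes is reported both at occurrence
#' level and at label level: a tandem duplication yields two scoring
#' occurrences (RS = 1 each) of one rearranged gene label.
#'
#' @inheritParams score_genes
#' @return A tibble with one row per species: `species_id`, `taxon`, `rs`,
#'   `n_rearranged_occurrences`, `n_rearranged_labels`, `n_occurrences`.
#' @export
#' @examples
#' score_genomes(gene_order("neo", typical_neobatrachian()$label))  # rs 10
score_genomes <- function(orders, reference = typical_vertebrate(),
                          mode = c("ordered", "unordered")) {
  score_genes(orders, reference, mode) |>
    dplyr::summarise(
      taxon = taxon[1],
      n_rearranged_occurrences = sum(rs > 0),
      n_rearranged_labels = dplyr::n_distinct(label[rs > 0]),
      n_occurrences = dplyr::n(),
      rs = sum(rs),
      .by = "species_id"
    ) |>
    dplyr::select(dplyr::all_of(c("species_id", "taxon", "rs",
                                  "n_rearranged_occurrences",
                                  "n_rearranged_labels", "n_occurrences")))
}

# group label per species from the ";"-joined taxon string
.group_labels <- function(orders, group_by) {
  sp <- orders |> dplyr::distinct(species_id, taxon)
  if (identical(group_by, "all")) {
    return(stats::setNames(rep("all", nrow(sp)), sp$species_id))
  }
  rank_idx <- if (is.numeric(group_by)) as.integer(group_by) else {
    switch(group_by, order = 1L, family = 2L,
           stop("unknown group_by: ", group_by,
                " (use 'all', 'order', 'family' or a rank index)",
                call. = FALSE))
  }
  ranks <- strsplit(sp$taxon, ";", fixed = TRUE)
  grp <- purrr::map_chr(ranks, function(r) {
    if (length(r) >= rank_idx && nzchar(trimws(r[rank_idx]))) {
      trimws(r[rank_idx])
    } else NA_character_
  })
  stats::setNames(grp, sp$species_id)
}

#' Per-gene rearrangement frequencies within groups
#'
#' For each taxonomic group and each gene label, accumulates the
#' rearrangement scores of all occurrences of that label and divides by the
#' maximum possible RS (2 per occurrence), giving the rearrangement
#' frequency RF as a percentage. Duplicated genes therefore enlarge the
#' denominator, and a gene with no occurrence in a group has RF `NA`
#' (missing), not zero. RF is computed in full precision and rendered to
#' 2 decimals.
#'
#' @inheritParams score_genes
#' @param group_by `"all"` (one group, the default), `"order"`, `"family"`,
#'   or a 1-based index into the `";"`-joined taxon ranks.
#' @return A tibble with columns `group`, `label`, `occurrence_count`,
#'   `accumulated_rs`, `rf_percent`, one row per group x alphabet-or-
#'   reference label. Species whose taxon string lacks the requested rank
#'   are omitted with a warning.
#' @export
#' @examples
#' orders <- dplyr::bind_rows(
#'   gene_order("typ", typical_vertebrate()$label, taxon = "Anura;Ranidae"),
#'   gene_order("neo", typical_neobatrachian()$label, taxon = "Anura;Ranidae")
#' )
#' rf <- rf_table(orders)
#' rf[which(rf$rf_percent > 0), ]
rf_table <- function(orders, reference = typical_vertebrate(),
                     group_by = "all", mode = c("ordered", "unordered")) {
  mode <- match.arg(mode)
  orders <- as_gene_orders(orders)
  reference <- as_reference(reference)
  grp <- .group_labels(orders, group_by)
  if (anyNA(grp)) {
    warning("omitting ", sum(is.na(grp)), " species with no '",
            group_by, "' rank: ",
            paste(sQuote(names(grp)[is.na(grp)]), collapse = ", "),
            call. = FALSE)
    orders <- orders[orders$species_id %in% names(grp)[!is.na(grp)], , drop = FALSE]
    if (nrow(orders) == 0) stop("no species left after dropping unresolvable groups",
                                call. = FALSE)
  }
  scored <- score_genes(orders, reference, mode)
  scored$group <- unname(grp[scored$species_id])
  all_labels <- union(reference$label, unique(scored$label))
  scored |>
    dplyr::summarise(
      occurrence_count = dplyr::n(),
      accumulated_rs = sum(rs),
      .by = c("group", "label")
    ) |>
    tidyr::complete(
      group = unique(scored$group),
      label = all_labels,
      fill = list(occurrence_count = 0L, accumulated_rs = 0L)
    ) |>
    dplyr::mutate(
      rf_percent = ifelse(
        occurrence_count > 0,
        round(100 * accumulated_rs / (2 * occurrence_count), 2),
        NA_real_
      )
    ) |>
    dplyr::arrange(group, match(label, all_labels))
}

#' Conserved segments of a reference arrangement
#'
#' Identifies maximal runs of consecutive reference-adjacent genes whose RF
#' is exactly zero: such runs have kept both internal adjacencies intact in
#' every genome of the group and form rearranged-conserved segments. Runs
#' are circular, require length >= 2, and are returned longest first. Genes
#' with missing RF (no occurrence in the group) break a run.
#'
#' @param rf An RF table from [rf_table()]; may contain several groups.
#' @param reference The same reference the RF table was computed on.
#' @return A tibble with columns `group`, `segment` (comma-joined labels in
#'   reference order), `length`.
#' @export
conserved_segments <- function(rf, reference = typical_vertebrate()) {
  reference <- as_reference(reference)
  stopifnot(all(c("group", "label", "rf_percent") %in% names(rf)))
  per_group <- function(d) {
    zero <- stats::setNames(!is.na(d$rf_percent) & d$rf_percent == 0, d$label)
    flag <- unname(zero[reference$label])
    flag[is.na(flag)] <- FALSE
    n <- length(flag)
    if (all(flag)) {
      return(tibble::tibble(segment = paste(reference$label, collapse = ","),
                            length = n))
    }
    # rotate so the circle starts on a non-conserved gene, then take runs
    cut <- which(!flag)[1]
    rot <- c(cut:n, seq_len(cut - 1))
    r <- rle(flag[rot])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values & r$lengths >= 2)
    segs <- purrr::map(keep, function(k) {
      labs <- reference$label[rot[starts[k]:ends[k]]]
      tibble::tibble(segment = paste(labs, collapse = ","),
                     length = length(labs))
    })
    dplyr::bind_rows(
      tibble::tibble(segment = character(), length = integer()),
      segs
    )
  }
  rf |>
    dplyr::group_by(group) |>
    dplyr::group_modify(~ per_group(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(group, dplyr::desc(length))
}
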