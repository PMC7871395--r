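# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an arrangement census
#'
#' One row per pattern class, with the member species unnested into a
#' comma-joined column.
#'
#' @param x An `mgr_census`.
#' @param ... Unused.
#' @return A tibble with columns `pattern_rank`, `class`, `count`,
#'   `members`, `pattern`.
#' @method tidy mgr_census
#' @export
tidy.mgr_census <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(members = purrr::map_chr(members, paste, collapse = ",")) |>
    dplyr::select(dplyr::all_of(c("pattern_rank", "class", "count",
                                  "members", "pattern")))
}

#' @rdname tidy.mgr_census
#' @method glance mgr_census
#' @export
glance.mgr_census <- function(x, ...) {
  tibble::tibble(
    scope = attr(x, "scope"),
    n_genomes = attr(x, "n_genomes"),
    n_patterns = nrow(x),
    n_major = sum(x$class == "major"),
    n_double = sum(x$class == "double"),
    n_single = sum(x$class == "single"),
    n_rare_genomes = sum(x$count[x$class != "major"]),
    prop_major = sum(x$count[x$class == "major"]) / attr(x, "n_genomes")
  )
}

#' Tidy a clade-enrichment result
#'
#' @param x An `mgr_enrichment`.
#' @param ... Unused.
#' @return `tidy()`: the per-node tibble (`node`, `clade_size`, `k_labeled`,
#'   `p_value`, `p_adj`). `glance()`: a one-row summary with the population
#'   size, labelled count, number of nodes tested and the minimum adjusted
#'   p-value.
#' @method tidy mgr_enrichment
#' @export
tidy.mgr_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.mgr_enrichment
#' @method glance mgr_enrichment
#' @export
glance.mgr_enrichment <- function(x, ...) {
  tibble::tibble(
    N = attr(x, "N"),
    K = attr(x, "K"),
    n_tests = attr(x, "n_tests"),
    min_p_adj = attr(x, "min_p_adj")
  )
}

#' Tidy a simulated dataset
#'
#' @param x An `mgr_sim`.
#' @param ... Unused.
#' @return `tidy()`: the event log tibble. `glance()`: a one-row summary
#'   (tips, events, events by type).
#' @method tidy mgr_sim
#' @export
tidy.mgr_sim <- function(x, ...) {
  x$events
}

#' @rdname tidy.mgr_sim
#' @method glance mgr_sim
#' @export
glance.mgr_sim <- function(x, ...) {
  counts <- table(factor(x$events$type, levels = EVENT_TYPES))
  out <- tibble::tibble(
    n_tips = dplyr::n_distinct(x$orders$species_id),
    n_events = nrow(x$events),
    root = attr(x$root, "name")
  )
  dplyr::bind_cols(out, tibble::as_tibble(as.list(counts)))
}

#' Tidy a rare-arrangement RS summary
#'
#' @param x An `mgr_rare`.
#' @param ... Unused.
#' @return `tidy()`: per-species tibble (`species_id`, `class`, `rs`).
#'   `glance()`: one row with `n_rare`, `mean_rs`, `min_rs`, `max_rs` and
#'   the species attaining the extremes.
#' @method tidy mgr_rare
#' @export
tidy.mgr_rare <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.mgr_rare
#' @method glance mgr_rare
#' @export
glance.mgr_rare <- function(x, ...) {
  tibble::tibble(
    n_rare = nrow(x),
    mean_rs = attr(x, "mean_rs"),
    min_rs = if (nrow(x)) min(x$rs) else NA_integer_,
    max_rs = if (nrow(x)) max(x$rs) else NA_integer_,
    min_species = attr(x, "min_species"),
    max_species = attr(x, "max_species")
  )
}
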