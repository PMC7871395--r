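# Arrangement patterns: canonicalization of circular orders (so records
# linearized at different cut points merge), a census of identical
# arrangements with major (count >= 3) vs rare (double = 2, single = 1)
# classes, projection to gene subsets (e.g. PCGs only), and extraction of
# anchored local regions.

# lexicographically minimal rotation among candidate start offsets
.lex_min_rotation <- function(tokens, starts) {
  n <- length(tokens)
  best <- NULL
  for (s in starts) {
    cand <- tokens[c(s:n, seq_len(s - 1))[seq_len(n)]]
    if (is.null(best)) {
      best <- cand
    } else {
      for (i in seq_len(n)) {
        if (cand[i] < best[i]) { best <- cand; break }
        if (cand[i] > best[i]) break
      }
    }
  }
  best
}

#' Canonicalize a circular gene order
#'
#' Rotates a circular token sequence to a deterministic start so that two
#' records of the same circular arrangement, linearized at different cut
#' points, become identical tuples. The sequence is rotated to begin at the
#' start gene (default `F`, the conventional vertebrate record start); if
#' that gene is absent the fallback priority list `F, rrnS, cox1, nad5` is
#' tried in turn; if all are absent the lexicographically minimal rotation
#' is used. When the start gene is duplicated, the occurrence giving the
#' lexicographically minimal tuple is chosen. Idempotent and
#' rotation-invariant for any input.
#'
#' @param tokens Character vector of labels (one circular arrangement), or a
#'   single-species gene-order tibble.
#' @param start_gene Preferred start label.
#' @return Character vector of labels, rotated; attribute `start_used`
#'   records the start rule applied.
#' @export
#' @examples
#' rot <- c(typical_vertebrate()$label[16:38], typical_vertebrate()$label[1:15])
#' head(canonicalize(rot))
canonicalize <- function(tokens, start_gene = "F") {
  if (is.data.frame(tokens)) {
    tokens <- order_tokens(tokens)
    if (length(tokens) != 1) {
      stop("canonicalize() expects one arrangement; use census() for many",
           call. = FALSE)
    }
    tokens <- tokens[[1]]
  }
  stopifnot(is.character(tokens), length(tokens) >= 2)
  for (g in unique(c(start_gene, "F", "rrnS", "cox1", "nad5"))) {
    hits <- which(tokens == g)
    if (length(hits)) {
      out <- .lex_min_rotation(tokens, hits)
      attr(out, "start_used") <- g
      return(out)
    }
  }
  out <- .lex_min_rotation(tokens, seq_along(tokens))
  attr(out, "start_used") <- "lexicographic"
  out
}

#' Region specifications for local arrangements
#'
#' A region is the circular span strictly between two anchor genes of the
#' reference, read in reading direction, optionally after projecting the
#' order onto a label subset. Built-ins follow the rearrangement-hotspot
#' regions of amphibian mitogenomes:
#' * `region1` -- between `nad4` and `rrnS`: the H, S2, L2, nad5, nad6, E,
#'   cob, T, P, CR, F span around the control region;
#' * `region2` -- between `nad1` and `cox1`: the IQM, nad2, WANCY tRNA
#'   cluster span;
#' * `region3` -- the PCG projection between `nad4` and `nad1`: the
#'   nad5, nad6, cob cluster.
#'
#' @param name `"region1"`, `"region2"`, `"region3"` for a built-in, or any
#'   other name for a custom region (then `left`/`right` are required).
#' @param left,right Anchor labels delimiting the extracted span
#'   (exclusive).
#' @param keep Optional label subset to project onto before extraction.
#' @return An object of class `mgr_region`.
#' @export
#' @examples
#' region_spec("region2")
region_spec <- function(name, left = NULL, right = NULL, keep = NULL) {
  if (is.null(left)) {
    builtin <- switch(name,
      region1 = list(left = "nad4", right = "rrnS", keep = NULL),
      region2 = list(left = "nad1", right = "cox1", keep = NULL),
      region3 = list(left = "nad4", right = "nad1", keep = pcg_labels()),
      stop("no built-in region ", sQuote(name),
           "; give `left` and `right` anchors", call. = FALSE)
    )
    left <- builtin$left; right <- builtin$right; keep <- builtin$keep
  }
  left <- normalize_gene_tokens(left)
  right <- normalize_gene_tokens(right)
  structure(list(name = name, left = left, right = right, keep = keep),
            class = "mgr_region")
}

#' @export
print.mgr_region <- function(x, ...) {
  cat("<region '", x$name, "': between ", x$left, " and ", x$right,
      if (!is.null(x$keep)) paste0(", projected to ", length(x$keep), " labels"),
      ">\n", sep = "")
  invisible(x)
}

#' Project gene orders onto a label subset
#'
#' Removes all occurrences whose label is not in `keep`, preserving the
#' circular relative order of the survivors. Used for local arrangements,
#' e.g. PCG-only patterns.
#'
#' @param orders A gene-order tibble.
#' @param keep Non-empty character vector of labels to retain.
#' @return A gene-order tibble with positions renumbered.
#' @export
#' @examples
#' pcg <- project_genes(gene_order("typ", typical_vertebrate()$label), pcg_labels())
#' pcg$label
project_genes <- function(orders, keep) {
  stopifnot(length(keep) >= 1)
  keep <- normalize_gene_tokens(keep)
  orders <- as_gene_orders(orders)
  kept <- orders[orders$label %in% keep, , drop = FALSE]
  lost <- setdiff(unique(orders$species_id), unique(kept$species_id))
  short <- c(lost, with(dplyr::count(kept, species_id), species_id[n < 2]))
  if (length(short)) {
    stop("projection leaves fewer than 2 occurrences for: ",
         paste(sQuote(short), collapse = ", "), call. = FALSE)
  }
  as_gene_orders(dplyr::select(kept, -"position", -"copy"))
}

#' Extract an anchored local region from gene orders
#'
#' For each species, returns the (possibly empty) circular span strictly
#' between the region's left and right anchor, in reading direction starting
#' after the left anchor. Species in which either anchor is missing or
#' duplicated are excluded with a warning, since the span is then ill
#' defined.
#'
#' @param orders A gene-order tibble.
#' @param region An [region_spec()] object or built-in region name.
#' @return A tibble with one row per retained species: `species_id`,
#'   `tokens` (comma-joined span labels; empty string for an empty span),
#'   `n_tokens`.
#' @export
#' @examples
#' extract_region(gene_order("typ", typical_vertebrate()$label), "region2")
extract_region <- function(orders, region) {
  if (is.character(region)) region <- region_spec(region)
  stopifnot(inherits(region, "mgr_region"))
  orders <- as_gene_orders(orders)
  if (!is.null(region$keep)) orders <- project_genes(orders, region$keep)
  toks <- order_tokens(orders)
  rows <- purrr::imap(toks, function(tk, sp) {
    li <- which(tk == region$left); ri <- which(tk == region$right)
    if (length(li) != 1 || length(ri) != 1) {
      return(tibble::tibble(species_id = sp, tokens = NA_character_,
                            n_tokens = NA_integer_))
    }
    n <- length(tk)
    ids <- ((li + seq_len(n - 1) - 1L) %% n) + 1L   # li+1, ..., wrapping
    span <- tk[ids[seq_len(which(ids == ri) - 1L)]]
    tibble::tibble(species_id = sp, tokens = paste(span, collapse = ","),
                   n_tokens = length(span))
  })
  out <- dplyr::bind_rows(rows)
  bad <- out$species_id[is.na(out$tokens)]
  if (length(bad)) {
    warning("excluding species with missing/duplicated region anchor (",
            region$left, "/", region$right, "): ",
            paste(sQuote(bad), collapse = ", "), call. = FALSE)
    out <- out[!is.na(out$tokens), , drop = FALSE]
  }
  out
}

#' Census of arrangement patterns
#'
#' Canonicalizes every genome's arrangement and merges genomes with
#' identical circular gene orders into pattern classes. A class observed at
#' least 3 times is a major arrangement; classes observed twice or once are
#' rare (labelled `double` and `single`). Major classes are ranked 1, 2, ...
#' in descending count order (ties broken by first appearance in the input),
#' mirroring the convention of numbering major patterns by frequency.
#'
#' Scope `"global"` uses all genes; `"pcg"` projects to the 13
#' protein-coding genes first (species that cannot be projected are dropped
#' with a warning); a region scope extracts the anchored span, which is
#' compared as an anchored linear tuple rather than re-canonicalized.
#'
#' @param orders A gene-order tibble.
#' @param scope `"global"`, `"pcg"`, a built-in region name
#'   (`"region1"`, `"region2"`, `"region3"`), or an [region_spec()].
#' @param start_gene Start gene for canonicalization (global/pcg scopes).
#' @return An object of class `mgr_census`: a tibble with columns
#'   `pattern` (canonical comma-joined arrangement), `count`, `class`
#'   (`major`/`double`/`single`), `pattern_rank` (majors only), `members`
#'   (list of species ids).
#' @export
#' @examples
#' orders <- dplyr::bind_rows(
#'   purrr::map(1:3, ~ gene_order(paste0("v", .x), typical_vertebrate()$label)),
#'   gene_order("neo", typical_neobatrachian()$label)
#' )
#' census(orders)
census <- function(orders, scope = "global", start_gene = "F") {
  orders <- as_gene_orders(orders)
  scope_name <- if (inherits(scope, "mgr_region")) scope$name else scope
  if (inherits(scope, "mgr_region") ||
      (is.character(scope) && scope %in% c("region1", "region2", "region3"))) {
    spans <- extract_region(orders, scope)
    keyed <- tibble::tibble(species_id = spans$species_id, key = spans$tokens)
  } else {
    if (identical(scope, "pcg_only")) scope <- "pcg"
    scope <- match.arg(scope, c("global", "pcg"))
    work <- orders
    if (scope == "pcg") {
      ok <- tryCatch({ project_genes(orders, pcg_labels()); TRUE },
                     error = function(e) FALSE)
      if (!ok) {
        keep <- pcg_labels()
        counts <- orders |>
          dplyr::filter(label %in% keep) |>
          dplyr::count(species_id)
        good <- counts$species_id[counts$n >= 2]
        dropped <- setdiff(unique(orders$species_id), good)
        warning("dropping species not projectable to PCGs: ",
                paste(sQuote(dropped), collapse = ", "), call. = FALSE)
        orders <- orders[orders$species_id %in% good, , drop = FALSE]
      }
      work <- project_genes(orders, pcg_labels())
    }
    toks <- order_tokens(work)
    keyed <- tibble::tibble(
      species_id = names(toks),
      key = unname(purrr::map_chr(toks, ~ paste(canonicalize(.x, start_gene),
                                                collapse = ",")))
    )
  }
  classes <- keyed |>
    dplyr::mutate(.first = dplyr::row_number()) |>
    dplyr::summarise(
      count = dplyr::n(),
      members = list(species_id),
      .first = min(.first),
      .by = "key"
    ) |>
    dplyr::arrange(dplyr::desc(count), .first) |>
    dplyr::mutate(
      class = dplyr::case_when(count >= 3 ~ "major",
                               count == 2 ~ "double",
                               TRUE ~ "single"),
      pattern_rank = ifelse(class == "major", cumsum(class == "major"), NA_integer_)
    ) |>
    dplyr::select(pattern = "key", dplyr::all_of(c("count", "class",
                                                   "pattern_rank", "members")))
  structure(classes,
            class = c("mgr_census", class(classes)),
            scope = scope_name, start_gene = start_gene,
            n_genomes = sum(classes$count))
}

#' @export
print.mgr_census <- function(x, ...) {
  cat("<arrangement census: scope ", attr(x, "scope"), ", ",
      attr(x, "n_genomes"), " genomes, ", nrow(x), " pattern class(es), ",
      sum(x$class == "major"), " major>\n", sep = "")
  NextMethod()
}

#' Summarise genome RS of rare-arrangement species
#'
#' Rare arrangements are the census classes seen only once or twice. This
#' summarises the genome rearrangement scores of those species: the mean RS
#' and the species attaining the extremes.
#'
#' @param census An [census()] result.
#' @param scores A genome score tibble from [score_genomes()] computed
#'   against the same reference.
#' @return An object of class `mgr_rare`: a tibble of the rare species
#'   (`species_id`, `class`, `rs`) with attributes `mean_rs`, `min_species`,
#'   `max_species`; empty when there are no rare species.
#' @export
rare_rs_summary <- function(census, scores) {
  stopifnot(inherits(census, "mgr_census"),
            all(c("species_id", "rs") %in% names(scores)))
  rare <- census[census$class %in% c("double", "single"), , drop = FALSE]
  members <- tibble::tibble(
    species_id = as.character(unlist(rare$members)),
    class = rep(rare$class, lengths(rare$members))
  )
  out <- members |>
    dplyr::inner_join(dplyr::select(scores, dplyr::all_of(c("species_id", "rs"))),
                      by = "species_id")
  if (nrow(out) < nrow(members)) {
    warning("no genome score for ",
            nrow(members) - nrow(out), " rare species", call. = FALSE)
  }
  attr(out, "mean_rs") <- if (nrow(out)) mean(out$rs) else NA_real_
  attr(out, "min_species") <- if (nrow(out)) out$species_id[which.min(out$rs)] else NA_character_
  attr(out, "max_species") <- if (nrow(out)) out$species_id[which.max(out$rs)] else NA_character_
  class(out) <- c("mgr_rare", class(out))
  out
}

#' @export
print.mgr_rare <- function(x, ...) {
  if (!nrow(x)) {
    cat("<rare-arrangement RS summary: no rare species>\n")
    return(invisible(x))
  }
  cat("<rare-arrangement RS summary: ", nrow(x), " species, mean RS ",
      round(attr(x, "mean_rs"), 2), ", max ", attr(x, "max_species"),
      ", min ", attr(x, "min_species"), ">\n", sep = "")
  NextMethod()
}
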