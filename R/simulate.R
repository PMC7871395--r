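# Gene-order evolution simulator: rearrangement events (tandem duplication,
# tandem duplication-random loss, transposition, inversion, single-gene
# loss) placed on the branches of a phylogeny with counts Poisson in branch
# length, and event positions drawn from hotspot weights over gene labels so
# rearrangements concentrate where they do in real mitogenomes (the
# nad5-CR region and the IQM/WANCY region). Every event is logged with
# enough detail to replay the history exactly.

EVENT_TYPES <- c("tandem_duplication", "tdrl", "transposition", "inversion", "loss")

#' Labels of a built-in region span
#'
#' The gene labels a region covers on a reference arrangement, optionally
#' including the two anchor genes. Used to build hotspot weights and to
#' check which genes a hotspot-confined simulation can touch: events
#' confined to a region can change the flanks of the span genes and of the
#' two anchors, but of nothing else.
#'
#' @param region An [region_spec()] or built-in region name.
#' @param reference Reference arrangement to read the span from.
#' @param inclusive Include the anchor genes themselves?
#' @return Character vector of labels.
#' @export
#' @examples
#' region_labels("region1")
region_labels <- function(region, reference = typical_vertebrate(),
                          inclusive = FALSE) {
  if (is.character(region)) region <- region_spec(region)
  reference <- as_reference(reference)
  ord <- gene_order(".ref", reference$label)
  span <- extract_region(ord, region)
  labs <- strsplit(span$tokens, ",", fixed = TRUE)[[1]]
  if (inclusive) labs <- c(region$left, labs, region$right)
  labs
}

#' Specify a rearrangement event model
#'
#' Collects the per-event-type rates (events per unit branch length), the
#' hotspot weights governing where events land, and the span-length
#' distribution. Hotspot weights are a probability mass over gene labels of
#' the reference; an event's span is drawn so that every gene in it has
#' positive weight, so zero-weight genes are never moved (though genes
#' adjacent to the hotspot can still see their flanks change).
#'
#' The default rates are placeholders -- realistic relative rates of the
#' five event types are not known -- chosen so duplicative mechanisms
#' (tandem duplication, TDRL) dominate, as they do in published accounts of
#' mitogenome rearrangement. Span lengths are geometric with mean
#' `span_mean` genes, truncated at `span_max`; small blocks match the
#' observed tRNA-cluster scale of rearrangements.
#'
#' @param rates Named non-negative rates for
#'   `tandem_duplication`, `tdrl`, `transposition`, `inversion`, `loss`.
#' @param hotspot `"regions12"` (default: uniform mass over the Region 1 and
#'   Region 2 spans of the reference), `"region1"`, `"region2"`,
#'   `"uniform"`, or a named numeric vector of weights over labels
#'   (normalised internally).
#' @param span_mean,span_max Mean and cap of the geometric span length, in
#'   genes.
#' @param reference Reference arrangement the hotspot spans are read from.
#' @return An object of class `mgr_event_model`.
#' @export
#' @examples
#' event_model(rates = c(tandem_duplication = 0.4, tdrl = 0.1))
event_model <- function(rates = c(tandem_duplication = 0.15, tdrl = 0.15,
                                  transposition = 0.10, inversion = 0.05,
                                  loss = 0.05),
                        hotspot = "regions12",
                        span_mean = 2, span_max = 6,
                        reference = typical_vertebrate()) {
  reference <- as_reference(reference)
  full <- stats::setNames(rep(0, length(EVENT_TYPES)), EVENT_TYPES)
  bad <- setdiff(names(rates), EVENT_TYPES)
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  full[names(rates)] <- rates
  if (any(full < 0)) stop("event rates must be >= 0", call. = FALSE)
  if (is.character(hotspot)) {
    labs <- switch(hotspot,
      uniform = reference$label,
      regions12 = c(region_labels("region1", reference),
                    region_labels("region2", reference)),
      region1 = region_labels("region1", reference),
      region2 = region_labels("region2", reference),
      stop("unknown hotspot spec: ", hotspot, call. = FALSE)
    )
    weights <- stats::setNames(rep(1 / length(labs), length(labs)), labs)
  } else {
    stopifnot(is.numeric(hotspot), !is.null(names(hotspot)), all(hotspot >= 0),
              sum(hotspot) > 0)
    weights <- hotspot / sum(hotspot)
  }
  structure(list(rates = full, weights = weights,
                 span_mean = span_mean, span_max = span_max,
                 reference = reference),
            class = "mgr_event_model")
}

#' @export
print.mgr_event_model <- function(x, ...) {
  on <- x$rates[x$rates > 0]
  cat("<event model: total rate ", sum(x$rates), " per branch-length unit (",
      paste(names(on), on, sep = "=", collapse = ", "), "); hotspot over ",
      length(x$weights), " labels; span ~ Geom(mean ", x$span_mean,
      ") capped at ", x$span_max, ">\n", sep = "")
  invisible(x)
}

#' Apply one rearrangement event to a circular gene order
#'
#' Deterministic given its arguments, so a logged event can be replayed.
#' `span` is a contiguous run of 1-based positions in the circular order
#' (it may wrap past the end; the result is then returned rotated so the
#' span leads -- a rotation is immaterial for a circular arrangement).
#'
#' Event semantics:
#' * `tandem_duplication` -- the span is copied in place, the copy following
#'   the original (so duplicating `[T]` in `...cob,T,P...` gives
#'   `...cob,T,T,P...`);
#' * `tdrl` -- tandem duplication followed by loss of one copy of each
#'   duplicated gene; `drop_original[i]` says whether the original (TRUE) or
#'   the new (FALSE) copy of the i-th span gene is deleted (drawn uniformly
#'   at random when `NULL`). Dropping every new copy reproduces the original
#'   order, an allowed outcome of the mechanism;
#' * `transposition` -- the span is excised and reinserted after position
#'   `insert_after` of the remaining sequence (0 = at the front);
#' * `inversion` -- the span's label sequence is reversed (strand is not
#'   modelled in comparisons, so only the order changes);
#' * `loss` -- the span (length 1 only) is removed; an event that would
#'   leave fewer than 2 genes is an error.
#'
#' @param tokens Character vector: one circular gene order.
#' @param type One of `tandem_duplication`, `tdrl`, `transposition`,
#'   `inversion`, `loss`.
#' @param span Integer vector of contiguous circular positions.
#' @param insert_after Transposition only: gap index in the excised order.
#' @param drop_original TDRL only: logical vector along the span.
#' @return The new character vector of tokens.
#' @export
#' @examples
#' ref <- typical_vertebrate()$label
#' out <- apply_event(ref, "tandem_duplication", span = which(ref == "T"))
#' out[35:39]
apply_event <- function(tokens, type, span, insert_after = NULL,
                        drop_original = NULL) {
  type <- match.arg(type, EVENT_TYPES)
  n <- length(tokens)
  stopifnot(all(span >= 1), all(span <= n), length(span) >= 1)
  if (length(span) >= n) stop("span must leave the circle non-trivial", call. = FALSE)
  # make the span contiguous from position 1 if it wraps
  if (any(diff(span) != 1L)) {
    shift <- span[1] - 1L
    tokens <- tokens[c((shift + 1):n, seq_len(shift))]
    span <- seq_along(span)
  }
  len <- length(span)
  switch(type,
    tandem_duplication = append(tokens, tokens[span], after = span[len]),
    tdrl = {
      if (is.null(drop_original)) {
        drop_original <- sample(c(TRUE, FALSE), len, replace = TRUE)
      }
      stopifnot(length(drop_original) == len)
      dup <- append(tokens, tokens[span], after = span[len])
      del <- ifelse(drop_original, span, span + len)
      dup[-del]
    },
    transposition = {
      block <- tokens[span]
      remaining <- tokens[-span]
      if (is.null(insert_after)) insert_after <- sample(0:length(remaining), 1)
      stopifnot(insert_after >= 0, insert_after <= length(remaining))
      append(remaining, block, after = insert_after)
    },
    inversion = {
      tokens[span] <- rev(tokens[span])
      tokens
    },
    loss = {
      if (len != 1) stop("loss events remove a single gene", call. = FALSE)
      if (n - 1 < 2) stop("loss would leave fewer than 2 genes", call. = FALSE)
      tokens[-span]
    }
  )
}

# draw a span whose genes all carry positive hotspot weight; falls back to a
# single-gene span at a weighted start when no longer span fits
.sample_span <- function(tokens, model, len = NULL, tries = 50) {
  n <- length(tokens)
  w <- model$weights[tokens]
  w[is.na(w)] <- 0
  if (sum(w) == 0) w <- rep(1, n)   # order has drifted out of the hotspot
  for (i in seq_len(tries)) {
    start <- sample.int(n, 1, prob = w)
    l <- if (is.null(len)) {
      min(stats::rgeom(1, 1 / model$span_mean) + 1L, model$span_max, n - 1L)
    } else len
    span <- ((start + seq_len(l) - 2L) %% n) + 1L
    ww <- model$weights[tokens[span]]
    if (!anyNA(ww) && all(ww > 0)) return(span)
  }
  start <- sample.int(n, 1, prob = w)
  ((start - 1L) %% n) + 1L
}

# one random event on `tokens`; returns list(type, span, insert_after,
# drop_original, result) or NULL if no event is applicable
.random_event <- function(tokens, model) {
  n <- length(tokens)
  rates <- model$rates
  if (n <= 2) rates["loss"] <- 0
  if (sum(rates) == 0) return(NULL)
  type <- sample(names(rates), 1, prob = rates)
  span <- .sample_span(tokens, model, len = if (type == "loss") 1L else NULL)
  insert_after <- NA_integer_
  drop_original <- NA_character_
  if (type == "transposition") {
    remaining <- tokens[-span]
    m <- length(remaining)
    wl <- model$weights[remaining]
    wl[is.na(wl)] <- 0
    wr <- wl[c(seq_len(m)[-1], 1)]
    allowed <- which(wl > 0 | wr > 0)   # gap g sits after remaining[g]
    g <- if (length(allowed)) {
      allowed[sample.int(length(allowed), 1)]
    } else sample.int(m, 1)
    insert_after <- g
  } else if (type == "tdrl") {
    drop <- sample(c(TRUE, FALSE), length(span), replace = TRUE)
    drop_original <- paste(ifelse(drop, "T", "F"), collapse = "")
  }
  result <- apply_event(
    tokens, type, span,
    insert_after = if (is.na(insert_after)) NULL else insert_after,
    drop_original = if (is.na(drop_original)) NULL else
      strsplit(drop_original, "")[[1]] == "T"
  )
  list(type = type, span_start = span[1], span_len = length(span),
       span_labels = paste(tokens[span], collapse = ","),
       insert_after = insert_after, drop_original = drop_original,
       result = result)
}

#' Simulate gene-order evolution on a phylogeny
#'
#' Starting from a root arrangement, draws rearrangement events on every
#' branch (counts Poisson with mean total-rate x branch length), applies
#' them sequentially root-to-tip, and returns the tip gene orders together
#' with a complete event log. Descendant lineages inherit their ancestor's
#' arrangement, so a single event on the stem of a clade makes exactly that
#' clade share a derived arrangement -- the phylogenetically clustered
#' structure the enrichment test looks for. Identical seeds give identical
#' datasets.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param model An [event_model()].
#' @param root Root arrangement (an `mgr_reference`, name, or label vector).
#' @param taxa Optional named character vector mapping tip labels to
#'   `";"`-joined taxon strings; defaults to `"simulated;simulated"`.
#' @param seed Optional integer seed; the RNG state is restored afterwards.
#' @return An object of class `mgr_sim`: a list with `orders` (tip
#'   gene-order tibble), `events` (one row per applied event: branch,
#'   nodes, type, span, parameters, resulting order), `tree`, `model`,
#'   `root`.
#' @export
#' @examples
#' tree <- ape::rcoal(8)
#' sim <- simulate_tree_dataset(tree, event_model(), seed = 1)
#' sim$events[, c("child", "type", "span_labels")]
simulate_tree_dataset <- function(tree, model = event_model(),
                                  root = typical_vertebrate(),
                                  taxa = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("the tree needs branch lengths to place events on", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  root <- as_reference(root)
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  ntip <- length(tree$tip.label)
  total_rate <- sum(model$rates)

  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1]] <- root$label
  logs <- list()
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1]
    child <- tree$edge[i, 2]
    tokens <- states[[parent]]
    n_ev <- stats::rpois(1, total_rate * tree$edge.length[i])
    if (n_ev > 0) {
      for (e in seq_len(n_ev)) {
        ev <- .random_event(tokens, model)
        if (is.null(ev)) break
        tokens <- ev$result
        logs[[length(logs) + 1]] <- tibble::tibble(
          edge = i, parent = parent, child = child, event_index = e,
          type = ev$type, span_start = ev$span_start, span_len = ev$span_len,
          span_labels = ev$span_labels, insert_after = ev$insert_after,
          drop_original = ev$drop_original,
          result = paste(ev$result, collapse = ",")
        )
      }
    }
    states[[child]] <- tokens
  }
  taxon_of <- function(tip) {
    if (!is.null(taxa) && tip %in% names(taxa)) taxa[[tip]] else "simulated;simulated"
  }
  orders <- dplyr::bind_rows(purrr::map(seq_len(ntip), function(t) {
    gene_order(tree$tip.label[t], states[[t]], taxon = taxon_of(tree$tip.label[t]))
  }))
  events <- if (length(logs)) dplyr::bind_rows(logs) else tibble::tibble(
    edge = integer(), parent = integer(), child = integer(),
    event_index = integer(), type = character(), span_start = integer(),
    span_len = integer(), span_labels = character(),
    insert_after = integer(), drop_original = character(), result = character()
  )
  structure(list(orders = orders, events = events, tree = tree,
                 model = model, root = root),
            class = "mgr_sim")
}

#' @export
print.mgr_sim <- function(x, ...) {
  cat("<simulated dataset: ", dplyr::n_distinct(x$orders$species_id),
      " tips, ", nrow(x$events), " events from root '",
      attr(x$root, "name"), "'>\n", sep = "")
  invisible(x)
}

#' Replay a simulation's event log
#'
#' Re-applies every logged event from the root arrangement along the tree
#' and checks that each intermediate result and every tip order matches the
#' simulation output exactly. The ground-truth log is only trustworthy for
#' parameter-recovery work if this holds.
#'
#' @param sim An [simulate_tree_dataset()] result.
#' @return `TRUE` invisibly; errors on any mismatch.
#' @export
replay_events <- function(sim) {
  stopifnot(inherits(sim, "mgr_sim"))
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1]] <- sim$root$label
  ev <- sim$events
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1]
    child <- tree$edge[i, 2]
    tokens <- states[[parent]]
    rows <- ev[ev$edge == i, , drop = FALSE]
    if (nrow(rows)) {
      rows <- rows[base::order(rows$event_index), , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        n <- length(tokens)
        span <- ((rows$span_start[r] + seq_len(rows$span_len[r]) - 2L) %% n) + 1L
        tokens <- apply_event(
          tokens, rows$type[r], span,
          insert_after = if (is.na(rows$insert_after[r])) NULL else rows$insert_after[r],
          drop_original = if (is.na(rows$drop_original[r])) NULL else
            strsplit(rows$drop_original[r], "")[[1]] == "T"
        )
        if (!identical(paste(tokens, collapse = ","), rows$result[r])) {
          stop("replay diverged from the log on edge ", i, call. = FALSE)
        }
      }
    }
    states[[child]] <- tokens
  }
  tip_toks <- order_tokens(sim$orders)
  for (t in seq_len(ntip)) {
    if (!identical(unname(tip_toks[[tree$tip.label[t]]]), states[[t]])) {
      stop("replayed tip order differs for ", tree$tip.label[t], call. = FALSE)
    }
  }
  invisible(TRUE)
}
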