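# I/O: the package's gene-order TSV dialect, and a minimal reader for
# GenBank flat files that turns annotated features into a gene order.
#
# TSV dialect: UTF-8, tab-separated, "#" comment lines; columns
# species_id, taxon (ranks joined by ";"), tokens (comma-separated gene
# tokens in reading order, leading "-" = minus strand). No standard
# gene-order exchange format exists; this one stays greppable.

#' Read gene orders from a TSV file
#'
#' Reads the package's gene-order TSV dialect: tab-separated columns
#' `species_id`, `taxon` (ranks joined by `";"`), `tokens` (comma-separated
#' gene tokens in reading order; a leading `-` marks the minus strand).
#' Lines starting with `#` are comments; a literal header row is tolerated.
#' Tokens are validated against the closed alphabet: an unknown token is an
#' error naming the offending row and token.
#'
#' @param path Path to the TSV file.
#' @param dialect Input dialect; only `"tsv"` is defined.
#' @return A gene-order tibble (see [as_gene_orders()]), rows in file order.
#' @seealso [write_gene_orders()], [read_genbank_order()]
#' @export
read_gene_orders <- function(path, dialect = "tsv") {
  dialect <- match.arg(dialect, "tsv")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  row_no <- which(keep)
  if (length(lines) &&
      grepl("^species_id\t", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
    row_no <- row_no[-1]
  }
  if (!length(lines)) stop("no gene-order rows in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map2(parts, row_no, function(p, i) {
    if (length(p) < 3) {
      stop("line ", i, " of ", path,
           ": expected 3 tab-separated fields (species_id, taxon, tokens)",
           call. = FALSE)
    }
    tokens <- trimws(strsplit(p[3], ",", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens)) {
      stop("line ", i, " of ", path, ": empty token list for ",
           sQuote(p[1]), call. = FALSE)
    }
    strand <- ifelse(startsWith(tokens, "-"), "-", "+")
    labels <- normalize_gene_tokens(sub("^-", "", tokens),
                                    context = paste0(path, " line ", i))
    tibble::tibble(species_id = p[1], taxon = p[2],
                   label = labels, strand = strand)
  })
  as_gene_orders(dplyr::bind_rows(rows))
}

#' Write gene orders to a TSV file
#'
#' Inverse of [read_gene_orders()]: `read_gene_orders(write_gene_orders(x))`
#' reproduces `x` including copy indices and strands.
#'
#' @param orders A gene-order tibble (non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(orders, path) {
  if (is.null(orders) || nrow(orders) == 0) {
    stop("refusing to write an empty set of gene orders", call. = FALSE)
  }
  orders <- as_gene_orders(orders)
  rows <- orders |>
    dplyr::mutate(tok = ifelse(strand == "-", paste0("-", label), label)) |>
    dplyr::summarise(
      taxon = taxon[1],
      tokens = paste(tok, collapse = ","),
      .by = "species_id"
    )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# species_id\ttaxon\ttokens", con)
  writeLines(paste(rows$species_id, rows$taxon, rows$tokens, sep = "\t"), con)
  invisible(path)
}

# ---- GenBank flat files -----------------------------------------------------

# Parse the FEATURES table of one GenBank record into (type, start, end,
# strand, qualifiers). Only what the gene-order extraction needs.
.parse_genbank_features <- function(lines) {
  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) stop("no FEATURES section found", call. = FALSE)
  end_markers <- grep("^(ORIGIN|CONTIG|//)", lines)
  feat_end <- if (length(end_markers)) min(end_markers[end_markers > feat_start[1]]) - 1 else length(lines)
  block <- lines[(feat_start[1] + 1):feat_end]

  feats <- list()
  cur <- NULL
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {            # new feature line: type + location
      if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
      type <- trimws(substr(ln, 1, 20))
      loc <- trimws(substr(ln, 21, nchar(ln)))
      cur <- list(type = type, loc = loc, quals = character())
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (length(cur$quals)) {        # continuation of a qualifier
        cur$quals[length(cur$quals)] <- paste(cur$quals[length(cur$quals)], txt)
      } else {                               # continuation of the location
        cur$loc <- paste0(cur$loc, txt)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
  feats
}

.qual_value <- function(quals, name) {
  pat <- paste0("^/", name, "=")
  hit <- quals[grepl(pat, quals)]
  if (!length(hit)) return(NA_character_)
  gsub('^"|"$', "", sub(pat, "", hit[1]))
}

#' Read a gene order from a GenBank flat file
#'
#' Extracts the circular gene order from the FEATURES table of a GenBank
#' record: tRNA, rRNA, CDS, D-loop and control-region features are mapped
#' through the synonym table and sorted by 1-based start coordinate, with a
#' feature spanning the origin placed first. Pseudogene-flagged features and
#' the origin of light-strand replication (`rep_origin`, O_L) are excluded
#' -- their annotation is too inconsistent across records to compare.
#' `gene` and `source` features are ignored (their CDS/tRNA/rRNA partners
#' carry the product). A control region is emitted once per annotated
#' feature, so a genome with two CRs yields two `CR` tokens.
#'
#' @param path Path to a GenBank flat file containing one record.
#' @param taxon Optional taxon string recorded on the resulting order; by
#'   default the first two ranks of the ORGANISM lineage are used when
#'   present.
#' @return A gene-order tibble for one species (see [as_gene_orders()]).
#' @export
read_genbank_order <- function(path, taxon = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  org_i <- grep("^ {0,2}ORGANISM", lines)
  species <- if (length(org_i)) {
    trimws(sub("^ *ORGANISM *", "", lines[org_i[1]]))
  } else {
    sub("^LOCUS +(\\S+).*$", "\\1", lines[grep("^LOCUS", lines)[1]])
  }
  if (is.null(taxon) && length(org_i)) {
    lineage <- character()
    j <- org_i[1] + 1
    while (j <= length(lines) && grepl("^ {8,}\\S", lines[j])) {
      lineage <- c(lineage, trimws(lines[j]))
      j <- j + 1
    }
    lineage <- unlist(strsplit(paste(lineage, collapse = " "), ";\\s*"))
    lineage <- sub("\\.$", "", trimws(lineage))
    lineage <- lineage[nzchar(lineage)]
    if (length(lineage)) taxon <- paste(utils::tail(lineage, 2), collapse = ";")
  }
  if (is.null(taxon)) taxon <- ""

  feats <- .parse_genbank_features(lines)
  keep_types <- c("tRNA", "rRNA", "CDS", "D-loop", "misc_feature")
  rows <- purrr::map(feats, function(f) {
    if (!f$type %in% keep_types) return(NULL)
    if (any(grepl("^/pseudo\\b", f$quals) | grepl("^/pseudogene", f$quals))) {
      return(NULL)
    }
    nums <- as.numeric(regmatches(f$loc, gregexpr("[0-9]+", f$loc))[[1]])
    if (!length(nums)) return(NULL)
    spans_origin <- grepl("^join", f$loc) &&
      length(nums) >= 4 && nums[3] < nums[2]
    name <- .qual_value(f$quals, "product")
    if (is.na(name)) name <- .qual_value(f$quals, "gene")
    if (f$type == "D-loop") name <- "CR"
    if (f$type == "misc_feature") {
      note <- .qual_value(f$quals, "note")
      if (!is.na(note) && grepl("control region", note, ignore.case = TRUE)) {
        name <- "CR"
      } else {
        return(NULL)
      }
    }
    if (is.na(name)) return(NULL)
    tibble::tibble(
      name = name,
      start = if (spans_origin) -Inf else nums[1],
      end = max(nums),
      strand = if (grepl("complement", f$loc)) "-" else "+"
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) {
    stop("no mappable gene features in ", path, call. = FALSE)
  }
  tab$label <- normalize_gene_tokens(tab$name, context = path)
  tab <- tab[base::order(tab$start), ]

  # overlapping duplicate annotations of the same feature: keep first
  drop <- rep(FALSE, nrow(tab))
  if (nrow(tab) > 1) {
    for (i in 2:nrow(tab)) {
      prev <- max(which(!drop[seq_len(i - 1)]))
      if (tab$label[i] == tab$label[prev] && tab$start[i] <= tab$end[prev]) {
        drop[i] <- TRUE
      }
    }
  }
  if (any(drop)) {
    warning("dropping ", sum(drop), " overlapping duplicate annotation(s) of ",
            paste(unique(tab$label[drop]), collapse = ", "), " in ", path,
            call. = FALSE)
    tab <- tab[!drop, ]
  }
  if (nrow(tab) < 2) stop("fewer than 2 mappable features in ", path, call. = FALSE)
  tokens <- ifelse(tab$strand == "-", paste0("-", tab$label), tab$label)
  gene_order(species, tokens, taxon = taxon)
}
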