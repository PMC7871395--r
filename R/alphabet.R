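# Closed gene alphabet for vertebrate mitogenomes: 13 protein-coding genes,
# 2 rRNAs, 22 tRNAs (single amino-acid letters, with L1/L2 and S1/S2 for the
# two leucine/serine isoacceptors) and the control region (CR) treated as a
# single gene.

PCG_LABELS <- c(
  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
  "cox1", "cox2", "cox3", "cob", "atp6", "atp8"
)

RRNA_LABELS <- c("rrnS", "rrnL")

TRNA_LABELS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
  "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y"
)

#' The mitochondrial gene alphabet
#'
#' The closed alphabet of 38 labels used throughout the package: the 13
#' protein-coding genes (`nad1`--`nad6`, `nad4L`, `cox1`--`cox3`, `cob`,
#' `atp6`, `atp8`), the two rRNAs (`rrnS`, `rrnL`), the 22 tRNAs abbreviated
#' by single amino-acid letters (`L1`/`L2` and `S1`/`S2` distinguish the two
#' leucine and serine isoacceptors), and `CR`, the control region, which is
#' treated as a single gene.
#'
#' Leucine/serine numbering follows positional usage in the typical
#' vertebrate arrangement -- `L1` sits after `rrnL` (tRNA-Leu(UUR)), `L2`
#' next to `nad5` (tRNA-Leu(CUN)), `S1` after `cox1` (tRNA-Ser(UCN)) and
#' `S2` after `H` (tRNA-Ser(AGY)) -- rather than the anticodon-based
#' numbering some annotation pipelines use. The synonym table behind
#' [normalize_gene_tokens()] accepts both spellings (e.g. `"tRNA-Leu(CUN)"`
#' maps to `L2`).
#'
#' @return A character vector of 38 gene labels.
#' @seealso [normalize_gene_tokens()], [typical_vertebrate()]
#' @export
#' @examples
#' gene_alphabet()
gene_alphabet <- function() {
  c(PCG_LABELS, RRNA_LABELS, TRNA_LABELS, "CR")
}

#' The 13 protein-coding gene labels
#'
#' @return Character vector of the 13 PCG labels, used e.g. as the `keep`
#'   set when projecting arrangements to protein-coding genes only.
#' @export
pcg_labels <- function() PCG_LABELS

# lookup key: lower case, spaces/underscores collapsed
.norm_key <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ _]+", " ", x)
  x
}

# synonym key -> canonical label
.build_synonyms <- function() {
  syn <- list()
  add <- function(canonical, ...) {
    for (s in c(...)) syn[[.norm_key(s)]] <<- canonical
  }
  add("nad1", "nad1", "nd1", "nadh1", "nadh dehydrogenase subunit 1")
  add("nad2", "nad2", "nd2", "nadh2", "nadh dehydrogenase subunit 2")
  add("nad3", "nad3", "nd3", "nadh3", "nadh dehydrogenase subunit 3")
  add("nad4", "nad4", "nd4", "nadh4", "nadh dehydrogenase subunit 4")
  add("nad4L", "nad4l", "nd4l", "nadh4l", "nadh dehydrogenase subunit 4l", "nadh dehydrogenase subunit 4L")
  add("nad5", "nad5", "nd5", "nadh5", "nadh dehydrogenase subunit 5")
  add("nad6", "nad6", "nd6", "nadh6", "nadh dehydrogenase subunit 6")
  add("cox1", "cox1", "co1", "coi", "coxi", "cox i",
      "cytochrome c oxidase subunit 1", "cytochrome c oxidase subunit i")
  add("cox2", "cox2", "co2", "coii", "coxii", "cox ii",
      "cytochrome c oxidase subunit 2", "cytochrome c oxidase subunit ii")
  add("cox3", "cox3", "co3", "coiii", "coxiii", "cox iii",
      "cytochrome c oxidase subunit 3", "cytochrome c oxidase subunit iii")
  add("cob", "cob", "cytb", "cyt b", "cytochrome b", "cyb")
  add("atp6", "atp6", "atpase6", "atpase 6", "atp synthase f0 subunit 6")
  add("atp8", "atp8", "atpase8", "atpase 8", "atp synthase f0 subunit 8")
  add("rrnS", "rrns", "12s", "12s rrna", "12s ribosomal rna", "s-rrna",
      "srrna", "rrn12", "small subunit ribosomal rna")
  add("rrnL", "rrnl", "16s", "16s rrna", "16s ribosomal rna", "l-rrna",
      "lrrna", "rrn16", "large subunit ribosomal rna")
  add("CR", "cr", "d-loop", "dloop", "d loop", "control region",
      "putative control region", "misc control region")
  aa3 <- c(A = "ala", C = "cys", D = "asp", E = "glu", F = "phe", G = "gly",
           H = "his", I = "ile", K = "lys", M = "met", N = "asn", P = "pro",
           Q = "gln", R = "arg", T = "thr", V = "val", W = "trp", Y = "tyr")
  for (one in names(aa3)) {
    add(one, one, paste0("trn", tolower(one)), paste0("trna-", aa3[[one]]),
        paste0("trn-", aa3[[one]]), paste0("trna ", aa3[[one]]))
  }
  add("L1", "l1", "trnl1", "trna-leu(uur)", "trnl(uur)", "trna-leu (uur)", "leu1")
  add("L2", "l2", "trnl2", "trna-leu(cun)", "trnl(cun)", "trna-leu (cun)", "leu2")
  add("S1", "s1", "trns1", "trna-ser(ucn)", "trns(ucn)", "trna-ser (ucn)", "ser1")
  add("S2", "s2", "trns2", "trna-ser(agy)", "trns(agy)", "trna-ser (agy)", "ser2")
  unlist(syn)
}

.SYNONYMS <- .build_synonyms()

#' Map gene tokens onto the closed alphabet
#'
#' Resolves free-form gene names (GenBank products, qMGR-style short labels,
#' single amino-acid letters) onto the 38-label alphabet through a
#' case-insensitive synonym table: `"ND5"` becomes `nad5`, `"tRNA-Met"`
#' becomes `M`, `"D-loop"` becomes `CR`. Unknown tokens are an error, never
#' silently dropped. The undefined token `"V1"`, which occurs in some
#' published arrangement strings, is mapped to `V` with a warning.
#'
#' Plain `"trnL"`/`"trnS"` without an isoacceptor qualifier are rejected as
#' ambiguous: the alphabet distinguishes `L1`/`L2` and `S1`/`S2`.
#'
#' @param tokens Character vector of gene names.
#' @param context Optional string (e.g. a file name or row id) prefixed to
#'   error messages.
#' @return Character vector of canonical labels, same length as `tokens`.
#' @export
#' @examples
#' normalize_gene_tokens(c("ND5", "tRNA-Met", "D-loop", "trnL2"))
normalize_gene_tokens <- function(tokens, context = NULL) {
  stopifnot(is.character(tokens))
  keys <- .norm_key(tokens)
  v1 <- keys == "v1"
  if (any(v1)) {
    warning("token 'V1' is not a defined gene label; mapping to 'V'",
            call. = FALSE)
    keys[v1] <- "v"
  }
  out <- unname(.SYNONYMS[keys])
  if (anyNA(out)) {
    bad <- unique(tokens[is.na(out)])
    where <- if (is.null(context)) "" else paste0(" in ", context)
    stop("unknown gene token(s)", where, ": ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  out
}

# ---- reference arrangements -------------------------------------------------

TYPICAL_VERTEBRATE_ORDER <- c(
  "F", "rrnS", "V", "rrnL", "L1", "nad1", "I", "Q", "M", "nad2",
  "W", "A", "N", "C", "Y", "cox1", "S1", "D", "cox2", "K",
  "atp8", "atp6", "cox3", "G", "nad3", "R", "nad4L", "nad4", "H", "S2",
  "L2", "nad5", "nad6", "E", "cob", "T", "P", "CR"
)

TYPICAL_NEOBATRACHIAN_ORDER <- c(
  "F", "rrnS", "V", "rrnL", "L1", "nad1", "I", "Q", "M", "nad2",
  "W", "A", "N", "C", "Y", "cox1", "S1", "D", "cox2", "K",
  "atp8", "atp6", "cox3", "G", "nad3", "R", "nad4L", "nad4", "H", "S2",
  "nad5", "nad6", "E", "cob", "CR", "L2", "T", "P"
)

#' Construct a reference arrangement
#'
#' A reference arrangement is a circular benchmark gene order in which every
#' label occurs exactly once, so each gene has a unique left and right
#' reference neighbour. Rearrangement scores are computed against it.
#'
#' @param labels Character vector of gene labels (validated against the
#'   alphabet, each label unique).
#' @param name Name of the arrangement, recorded in reports.
#' @return A tibble of class `mgr_reference` with columns `position` and
#'   `label`, and a `name` attribute.
#' @seealso [typical_vertebrate()], [typical_neobatrachian()]
#' @export
reference_arrangement <- function(labels, name = "custom") {
  labels <- normalize_gene_tokens(labels)
  if (anyDuplicated(labels)) {
    stop("reference arrangement labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(labels) < 2) stop("a reference needs at least 2 genes", call. = FALSE)
  out <- tibble::tibble(position = seq_along(labels), label = labels)
  attr(out, "name") <- name
  class(out) <- c("mgr_reference", class(out))
  out
}

#' Typical vertebrate mitogenome arrangement
#'
#' The conserved vertebrate gene order (F, rrnS, V, rrnL, L1, nad1, IQM,
#' nad2, WANCY, cox1, S1, D, cox2, K, atp8, atp6, cox3, G, nad3, R, nad4L,
#' nad4, H, S2, L2, nad5, nad6, E, cob, T, P, CR), read circularly. This is
#' the default benchmark for all scoring.
#'
#' @return An `mgr_reference` (see [reference_arrangement()]).
#' @export
#' @examples
#' typical_vertebrate()
typical_vertebrate <- function() {
  reference_arrangement(TYPICAL_VERTEBRATE_ORDER, name = "vertebrate")
}

#' Typical neobatrachian mitogenome arrangement
#'
#' The derived gene order shared by most neobatrachian frogs. It differs
#' from the typical vertebrate arrangement only between `nad4` and `rrnS`:
#' the L2-T-P-F tRNA cluster is relocated 3' of the control region, giving
#' ... nad4, H, S2, nad5, nad6, E, cob, CR, L2, T, P, F, rrnS ...
#'
#' @return An `mgr_reference` (see [reference_arrangement()]).
#' @export
typical_neobatrachian <- function() {
  reference_arrangement(TYPICAL_NEOBATRACHIAN_ORDER, name = "neobatrachian")
}

# resolve a reference given by object, built-in name, or gene-order TSV path
as_reference <- function(reference) {
  if (inherits(reference, "mgr_reference")) return(reference)
  if (is.character(reference) && length(reference) == 1) {
    if (reference %in% c("vertebrate", "typical_vertebrate")) {
      return(typical_vertebrate())
    }
    if (reference %in% c("neobatrachian", "typical_neobatrachian")) {
      return(typical_neobatrachian())
    }
    if (file.exists(reference)) {
      ord <- read_gene_orders(reference)
      sp <- unique(ord$species_id)
      if (length(sp) != 1) {
        stop("reference file must contain exactly one arrangement", call. = FALSE)
      }
      return(reference_arrangement(ord$label, name = sp))
    }
  }
  if (is.character(reference) && length(reference) > 1) {
    return(reference_arrangement(reference))
  }
  stop("cannot interpret `reference`; give an mgr_reference, 'vertebrate', ",
       "'neobatrachian', a label vector, or a gene-order TSV path",
       call. = FALSE)
}

# left/right reference neighbours, one row per label
ref_neighbors <- function(reference) {
  lab <- reference$label
  n <- length(lab)
  tibble::tibble(
    label = lab,
    ref_left = lab[c(n, seq_len(n - 1))],
    ref_right = lab[c(seq_len(n - 1) + 1, 1)]
  )
}

#' @export
print.mgr_reference <- function(x, ...) {
  cat("<reference arrangement '", attr(x, "name"), "': ",
      nrow(x), " genes>\n", sep = "")
  cat(paste(x$label, collapse = ", "), "\n")
  invisible(x)
}
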