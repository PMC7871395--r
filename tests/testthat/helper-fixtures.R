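# Shared fixture builders. Everything is constructed in code; the only
# on-disk fixtures are the small synthetic files under inst/extdata.

ref_tokens <- function() typical_vertebrate()$label
neo_tokens <- function() typical_neobatrachian()$label

# insert a second copy of `label` immediately after the first
tandem_dup <- function(tokens, label) {
  append(tokens, label, after = which(tokens == label)[1])
}

extdata <- function(...) {
  path <- system.file("extdata", ..., package = "mgrquant")
  if (!nzchar(path)) stop("extdata fixture not found: ", ...)
  path
}

# a small multi-species order set: n_typical reference genomes plus any
# extra token vectors given as a named list
orders_fixture <- function(n_typical = 0, extra = list(), taxon = "Anura;Ranidae") {
  base <- purrr::map(seq_len(n_typical),
                     ~ gene_order(paste0("typ", .x), ref_tokens(), taxon = taxon))
  more <- purrr::imap(extra, ~ gene_order(.y, .x, taxon = taxon))
  dplyr::bind_rows(c(base, more))
}

# all token sequences of a given length over an alphabet, as a matrix
all_orders <- function(len, alphabet) {
  as.matrix(expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE))
}
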