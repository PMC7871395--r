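test_that("a reference scored against itself is zero everywhere, both modes", {
  for (mode in c("ordered", "unordered")) {
    for (ref in list(typical_vertebrate(), typical_neobatrachian())) {
      g <- score_genomes(gene_order("self", ref$label), ref, mode = mode)
      expect_equal(g$rs, 0)
      expect_equal(g$n_rearranged_occurrences, 0)
    }
  }
})

test_that("a tandem duplication scores 1+1: right flank of the first copy, left of the second", {
  dup <- gene_order("dupT", tandem_dup(ref_tokens(), "T"))
  per <- score_genes(dup)
  ts <- per[per$label == "T", ]
  expect_equal(ts$rs, c(1L, 1L))
  expect_equal(ts$left_changed, c(0L, 1L))
  expect_equal(ts$right_changed, c(1L, 0L))
  # neighbours of the pair are untouched
  expect_equal(per$rs[per$label %in% c("cob", "P")], c(0L, 0L))
})

test_that("gene relocation scores 2 when both flanks change", {
  # in the neobatrachian order L2 has moved next to CR: both flanks differ
  # from its reference context (S2, nad5)
  per <- score_genes(gene_order("neo", neo_tokens()))
  expect_equal(per$rs[per$label == "L2"], 2L)
})

test_that("the neobatrachian arrangement scores RS 10 with the known per-gene decomposition", {
  per <- score_genes(gene_order("neo", neo_tokens()))
  contrib <- setNames(per$rs[per$rs > 0], per$label[per$rs > 0])
  expect_equal(
    contrib[order(names(contrib))],
    c(CR = 2L, F = 1L, L2 = 2L, P = 1L, S2 = 1L, T = 1L, cob = 1L, nad5 = 1L)
  )
  expect_equal(sum(per$rs), 10L)
  expect_equal(oracle_score_genome(neo_tokens(), ref_tokens()), 10L)
})

test_that("duplicated occurrences are scored independently against the label's one reference context", {
  # IQMM: first M keeps (Q, .) -> right changed; second M keeps (., nad2)
  per <- score_genes(gene_order("iqmm", tandem_dup(ref_tokens(), "M")))
  ms <- per[per$label == "M", ]
  expect_equal(ms$copy, c(1L, 2L))
  expect_equal(ms$rs, c(1L, 1L))
})

test_that("gene loss scores through the surviving neighbours only", {
  lost <- ref_tokens()[ref_tokens() != "V"]   # drop trnV between rrnS and rrnL
  g <- score_genes(gene_order("lossV", lost))
  expect_equal(sum(g$rs), 2L)   # rrnS lost its right, rrnL its left neighbour
  expect_equal(g$rs[g$label %in% c("rrnS", "rrnL")], c(1L, 1L))
  expect_false("V" %in% g$label)
})

test_that("implementation matches the brute-force oracle on random rearranged genomes", {
  withr::local_seed(101)
  ref <- ref_tokens()
  for (i in 1:25) {
    tokens <- ref
    for (e in seq_len(sample(1:4, 1))) {
      type <- sample(c("tandem_duplication", "transposition", "inversion", "loss"), 1)
      len <- if (type == "loss") 1 else sample(1:4, 1)
      start <- sample(length(tokens), 1)
      span <- ((start + seq_len(len) - 2) %% length(tokens)) + 1
      tokens <- apply_event(tokens, type, span,
                            insert_after = sample(0:(length(tokens) - len), 1))
    }
    orders <- gene_order("rnd", tokens)
    for (mode in c("ordered", "unordered")) {
      expect_equal(sum(score_genes(orders, mode = mode)$rs),
                   oracle_score_genome(tokens, ref, mode))
    }
  }
})

test_that("unordered RS never exceeds ordered RS and both respect the 2-per-occurrence bound", {
  withr::local_seed(7)
  for (i in 1:20) {
    tokens <- sample(ref_tokens())   # arbitrary permutation
    orders <- gene_order("perm", tokens)
    ord <- score_genes(orders, mode = "ordered")
    uno <- score_genes(orders, mode = "unordered")
    expect_true(all(uno$rs <= ord$rs))
    expect_true(all(ord$rs %in% 0:2))
    expect_equal(ord$rs, ord$left_changed + ord$right_changed)
    expect_equal(uno$rs, uno$left_changed + uno$right_changed)
    expect_lte(sum(ord$rs), 2 * nrow(orders))
  }
})

test_that("rf_table matches hand-enumerated occurrence counts and flank changes", {
  orders <- dplyr::bind_rows(
    gene_order("a", ref_tokens(), taxon = "Anura;Ranidae"),
    gene_order("b", tandem_dup(ref_tokens(), "T"), taxon = "Anura;Ranidae")
  )
  rf <- rf_table(orders)
  expect_equal(rf$rf_percent[rf$label == "T"], round(100 * 2 / (2 * 3), 2))  # 33.33
  expect_equal(rf$occurrence_count[rf$label == "T"], 3L)
  expect_true(all(rf$rf_percent[rf$label != "T"] == 0))
  expect_true(all(rf$rf_percent >= 0 & rf$rf_percent <= 100, na.rm = TRUE))
  expect_true(all(rf$accumulated_rs <= 2 * rf$occurrence_count))
})

test_that("identical reference genomes give RF 0 for every gene", {
  rf <- rf_table(orders_fixture(n_typical = 4))
  expect_true(all(rf$rf_percent == 0))
})

test_that("a gene absent from a group has missing RF, not zero", {
  lost <- ref_tokens()[ref_tokens() != "V"]
  rf <- rf_table(dplyr::bind_rows(gene_order("a", lost), gene_order("b", lost)))
  expect_true(is.na(rf$rf_percent[rf$label == "V"]))
  expect_equal(rf$occurrence_count[rf$label == "V"], 0L)
})

test_that("grouping by taxon rank splits RF tables and drops unresolvable species", {
  orders <- dplyr::bind_rows(
    gene_order("a", ref_tokens(), taxon = "Anura;Ranidae"),
    gene_order("b", neo_tokens(), taxon = "Anura;Ranidae"),
    gene_order("c", ref_tokens(), taxon = "Caudata;Salamandridae")
  )
  rf <- rf_table(orders, group_by = "order")
  expect_setequal(unique(rf$group), c("Anura", "Caudata"))
  expect_true(all(rf$rf_percent[rf$group == "Caudata"] == 0))
  expect_gt(max(rf$rf_percent[rf$group == "Anura"]), 0)

  nogroup <- dplyr::bind_rows(orders,
                              gene_order("d", ref_tokens(), taxon = "Anura"))
  expect_warning(rf2 <- rf_table(nogroup, group_by = "family"), "d")
  expect_false("d" %in% rf2$group)
})

test_that("about 45% changed CR flanks gives RF(CR) about 45", {
  # 9 of 20 genomes carry the neobatrachian CR relocation (both CR flanks
  # changed): accumulated RS = 18 of a possible 40
  orders <- dplyr::bind_rows(
    purrr::map(1:11, ~ gene_order(paste0("t", .x), ref_tokens())),
    purrr::map(1:9, ~ gene_order(paste0("n", .x), neo_tokens()))
  )
  rf <- rf_table(orders)
  expect_equal(rf$rf_percent[rf$label == "CR"], 45)
})

test_that("conserved segments are maximal circular zero-RF runs of length >= 2", {
  ref <- typical_vertebrate()
  zeros <- c("atp6", "cox3", "G", "nad3", "R", "nad4L", "S1", "D")
  rf <- dplyr::tibble(
    group = "all", label = ref$label,
    occurrence_count = 5L,
    accumulated_rs = ifelse(ref$label %in% zeros, 0L, 3L)
  ) |>
    dplyr::mutate(rf_percent = round(100 * accumulated_rs / (2 * occurrence_count), 2))
  segs <- conserved_segments(rf, ref)
  expect_equal(segs$segment,
               c("atp6,cox3,G,nad3,R,nad4L", "S1,D"))
  expect_equal(segs$length, c(6L, 2L))
})

test_that("an all-zero RF table yields one whole-circle segment and a lone zero is excluded", {
  ref <- typical_vertebrate()
  base <- dplyr::tibble(group = "all", label = ref$label,
                        occurrence_count = 2L, accumulated_rs = 4L)
  all_zero <- dplyr::mutate(base, accumulated_rs = 0L,
                            rf_percent = 0)
  expect_equal(conserved_segments(all_zero, ref)$length, nrow(ref))
  one_zero <- base |>
    dplyr::mutate(accumulated_rs = ifelse(label == "G", 0L, accumulated_rs),
                  rf_percent = round(100 * accumulated_rs / 4, 2))
  expect_equal(nrow(conserved_segments(one_zero, ref)), 0)
})

test_that("circular zero runs crossing the linearization origin are joined", {
  ref <- typical_vertebrate()
  zeros <- c("CR", "F")   # last and first gene of the written-out order
  rf <- dplyr::tibble(group = "all", label = ref$label,
                      occurrence_count = 2L,
                      accumulated_rs = ifelse(ref$label %in% zeros, 0L, 2L)) |>
    dplyr::mutate(rf_percent = round(100 * accumulated_rs / 4, 2))
  segs <- conserved_segments(rf, ref)
  expect_equal(segs$segment, "CR,F")
})
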