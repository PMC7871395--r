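test_that("canonicalize is rotation-invariant and idempotent", {
  ref <- ref_tokens()
  withr::local_seed(11)
  for (i in 1:10) {
    s <- sample(length(ref), 1)
    rot <- ref[c(s:length(ref), seq_len(s - 1))]
    can <- canonicalize(rot)
    expect_equal(as.character(can), ref)
    expect_equal(as.character(canonicalize(can)), ref)
  }
})

test_that("canonicalization falls back through the start-gene priority list", {
  noF <- ref_tokens()[ref_tokens() != "F"]
  can <- canonicalize(noF)
  expect_equal(can[1], "rrnS")
  expect_equal(attr(can, "start_used"), "rrnS")
  toy <- c("nad2", "W", "A")   # none of the priority genes present
  expect_equal(as.character(canonicalize(toy)), c("A", "nad2", "W"))
})

test_that("a duplicated start gene resolves to the lexicographically minimal rotation", {
  toy <- c("F", "rrnL", "F", "rrnS")
  can <- canonicalize(toy)
  # candidates: F,rrnL,F,rrnS vs F,rrnS,F,rrnL -> rrnL < rrnS
  expect_equal(as.character(can), c("F", "rrnL", "F", "rrnS"))
})

test_that("census merges identical circular arrangements across linearizations", {
  ref <- ref_tokens()
  rot <- ref[c(16:38, 1:15)]
  cen <- census(dplyr::bind_rows(
    gene_order("a", ref), gene_order("b", rot), gene_order("c", ref)
  ))
  expect_equal(nrow(cen), 1)
  expect_equal(cen$count, 3L)
  expect_equal(cen$class, "major")
})

test_that("census classes and ranks follow the >=3 / 2 / 1 convention", {
  orders <- dplyr::bind_rows(
    purrr::map(1:5, ~ gene_order(paste0("v", .x), ref_tokens())),
    purrr::map(1:3, ~ gene_order(paste0("n", .x), neo_tokens())),
    purrr::map(1:2, ~ gene_order(paste0("d", .x), tandem_dup(ref_tokens(), "M"))),
    gene_order("s1", tandem_dup(ref_tokens(), "T"))
  )
  cen <- census(orders)
  expect_equal(sum(cen$count), 11L)               # counts partition the input
  expect_equal(cen$class, c("major", "major", "double", "single"))
  expect_equal(cen$pattern_rank, c(1L, 2L, NA, NA))
  expect_equal(cen$pattern[1], paste(ref_tokens(), collapse = ","))
  expect_equal(cen$pattern[2], paste(neo_tokens(), collapse = ","))
  expect_setequal(cen$members[[3]], c("d1", "d2"))
})

test_that("census ties in count are broken by first-seen input order", {
  orders <- dplyr::bind_rows(
    purrr::map(1:3, ~ gene_order(paste0("n", .x), neo_tokens())),
    purrr::map(1:3, ~ gene_order(paste0("v", .x), ref_tokens()))
  )
  cen <- census(orders)
  expect_equal(cen$pattern_rank, c(1L, 2L))
  expect_equal(cen$pattern[1], paste(neo_tokens(), collapse = ","))
})

test_that("genomes identical globally remain identical after PCG projection", {
  orders <- dplyr::bind_rows(
    gene_order("a", ref_tokens()), gene_order("b", ref_tokens()),
    gene_order("c", neo_tokens())
  )
  glob <- census(orders)
  pcg <- census(orders, scope = "pcg")
  for (m in glob$members) {
    in_class <- purrr::map_lgl(pcg$members, ~ all(m %in% .x))
    expect_equal(sum(in_class), 1)   # each global class sits inside one PCG class
  }
  # the vertebrate and neobatrachian orders share the PCG arrangement
  expect_equal(nrow(pcg), 1)
})

test_that("PCG projection keeps the 13 protein-coding genes in circular order", {
  pcg <- project_genes(gene_order("typ", ref_tokens()), pcg_labels())
  expect_equal(pcg$label,
               c("nad1", "nad2", "cox1", "cox2", "atp8", "atp6", "cox3",
                 "nad3", "nad4L", "nad4", "nad5", "nad6", "cob"))
  # a caudatan-style swap shows up as nad5, cob, nad6 after projection
  swp <- ref_tokens()
  i <- match(c("nad6", "cob"), swp)
  swp[i] <- swp[rev(i)]
  proj <- project_genes(gene_order("caud", swp), pcg_labels())
  j <- which(proj$label == "nad5")
  expect_equal(proj$label[j:(j + 2)], c("nad5", "cob", "nad6"))
})

test_that("projection to fewer than 2 survivors is an error", {
  expect_error(project_genes(gene_order("x", c("F", "rrnS", "V")), "F"),
               "fewer than 2")
})

test_that("region extraction matches the anchored spans of the references", {
  expect_equal(extract_region(gene_order("t", ref_tokens()), "region2")$tokens,
               "I,Q,M,nad2,W,A,N,C,Y")
  expect_equal(extract_region(gene_order("n", neo_tokens()), "region1")$tokens,
               "H,S2,nad5,nad6,E,cob,CR,L2,T,P,F")
  expect_equal(extract_region(gene_order("t", ref_tokens()), "region1")$tokens,
               "H,S2,L2,nad5,nad6,E,cob,T,P,CR,F")
  iqmm <- gene_order("i", tandem_dup(ref_tokens(), "M"))
  expect_equal(extract_region(iqmm, "region2")$tokens, "I,Q,M,M,nad2,W,A,N,C,Y")
  expect_equal(extract_region(gene_order("t", ref_tokens()), "region3")$tokens,
               "nad5,nad6,cob")
})

test_that("species with a missing or duplicated region anchor are excluded with a warning", {
  orders <- dplyr::bind_rows(
    gene_order("ok", ref_tokens()),
    gene_order("norrnS", ref_tokens()[ref_tokens() != "rrnS"])
  )
  expect_warning(spans <- extract_region(orders, "region1"), "norrnS")
  expect_equal(spans$species_id, "ok")
  cen <- suppressWarnings(census(orders, scope = "region1"))
  expect_equal(attr(cen, "n_genomes"), 1L)
})

test_that("an adjacent empty span extracts as zero tokens", {
  toy <- gene_order("t", c("nad4", "rrnS", "F", "V"))
  out <- extract_region(toy, "region1")
  expect_equal(out$n_tokens, 0L)
  expect_equal(out$tokens, "")
})

test_that("rare_rs_summary averages the single/double classes and finds the extremes", {
  withr::local_seed(3)
  orders <- dplyr::bind_rows(
    purrr::map(1:3, ~ gene_order(paste0("v", .x), ref_tokens())),
    gene_order("r1", tandem_dup(ref_tokens(), "T")),
    gene_order("r2", tandem_dup(ref_tokens(), "P")),
    gene_order("r3", sample(ref_tokens()))   # heavily rearranged singleton
  )
  scores <- score_genomes(orders)
  rare <- rare_rs_summary(census(orders), scores)
  expect_setequal(rare$species_id, c("r1", "r2", "r3"))
  expect_equal(attr(rare, "mean_rs"),
               mean(scores$rs[scores$species_id %in% c("r1", "r2", "r3")]))
  expect_equal(attr(rare, "max_species"), "r3")
  g <- glance(rare)
  expect_equal(g$n_rare, 3L)
  expect_equal(g$min_rs, 2L)

  # explicit arithmetic case: rare RS values {2, 2, 32} -> mean 12
  fake_scores <- dplyr::tibble(species_id = c("r1", "r2", "r3"),
                               rs = c(2L, 2L, 32L))
  rare2 <- rare_rs_summary(census(orders), fake_scores)
  expect_equal(attr(rare2, "mean_rs"), 12)
  expect_equal(attr(rare2, "max_species"), "r3")
})

test_that("a census with no rare species gives an empty summary", {
  orders <- orders_fixture(n_typical = 4)
  rare <- rare_rs_summary(census(orders), score_genomes(orders))
  expect_equal(nrow(rare), 0)
  expect_true(is.na(attr(rare, "mean_rs")))
})
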