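make_qtl <- function(rs, gene, tissue, type = "eQTL") {
  tibble::tibble(
    variant_id = paste0(rs, "_vid"), rs_id = rs, gene_id = gene,
    tissue = tissue, slope = 0.3, pval_nominal = 1e-10, qtl_type = type
  )
}

test_that("QTL matching is exact, with no LD relaxation", {
  qtl <- dplyr::bind_rows(
    make_qtl("rs1", "LIPA", paste0("T", 1:19)),
    make_qtl("rs1", "LIPA", "Whole Blood", type = "sQTL"),
    make_qtl("rs9", "OTHER", "Liver")
  )
  lv <- tibble::tibble(rs_id = "rs1")
  hits <- match_qtls(lv, qtl)
  expect_equal(sum(hits$qtl_type == "eQTL"), 19)
  # same variant as both eQTL and sQTL in one tissue: two records
  both <- match_qtls(lv, dplyr::bind_rows(
    make_qtl("rs1", "LIPA", "Whole Blood", "eQTL"),
    make_qtl("rs1", "LIPA", "Whole Blood", "sQTL")
  ))
  expect_equal(nrow(both), 2)
  expect_setequal(both$qtl_type, c("eQTL", "sQTL"))
  # absent variant: empty result, not an error
  none <- match_qtls(tibble::tibble(rs_id = "rs404"), qtl)
  expect_equal(nrow(none), 0)
  # coordinate identity works when no rsID is given
  qtl2 <- make_qtl("rsX", "GENE", "Liver")
  qtl2$variant_id <- "chr2_500_A_G_b38"
  byc <- match_qtls(
    tibble::tibble(rs_id = NA_character_, chrom = "chr2", pos = 500L,
                   ref = "A", alt = "G"),
    qtl2
  )
  expect_equal(nrow(byc), 1)
  expect_error(
    match_qtls(tibble::tibble(rs_id = NA_character_), qtl),
    "unresolvable"
  )
})

test_that("evidence builds the union over a locus's markers with source attribution", {
  qtl <- dplyr::bind_rows(
    make_qtl("rs1", "GA", c("Liver", "Lung")),
    make_qtl("rs2", "GA", c("Lung", "Spleen")),
    make_qtl("rs2", "GB", "Liver", type = "sQTL")
  )
  rec <- match_qtls(tibble::tibble(rs_id = c("rs1", "rs2")), qtl)
  ev <- build_evidence("L1", rec, positional_genes = "GC")
  expect_setequal(ev$gene_id, c("GA", "GB", "GC"))
  expect_equal(ev$eqtl_tissues[ev$gene_id == "GA"], "Liver;Lung;Spleen")
  expect_equal(ev$added_by[ev$gene_id == "GA"], "eQTL")
  expect_equal(ev$added_by[ev$gene_id == "GB"], "sQTL")
  expect_equal(ev$added_by[ev$gene_id == "GC"], "position")
  # multi-source gene goes to combination
  ev2 <- build_evidence("L1", rec, positional_genes = "GA")
  expect_equal(ev2$added_by[ev2$gene_id == "GA"], "combination")
  # positional evidence only
  ev3 <- build_evidence("L2", rec[0, ], positional_genes = "GX")
  expect_equal(ev3$gene_id, "GX")
  expect_true(ev3$positional)
  # nothing at all
  expect_equal(nrow(build_evidence("L3", rec[0, ])), 0)
})

test_that("tier assignment reproduces the published locus patterns", {
  expect_equal(assign_tier("FLT1", "FLT1")$tier, "1")
  expect_equal(assign_tier(c("ABCG8", "ABCG5"), "ABCG8")$tier, "1")
  expect_equal(
    assign_tier("LDLR", c("SMARCA4", "CARM1", "YIPF2", "RGL3", "SLC44A2"))$tier,
    "2C"
  )
  expect_equal(assign_tier(c("MC4R", "PMAIP1"), character(0))$tier, "3")
  expect_equal(assign_tier(character(0), character(0))$tier, "3")
  # degenerate: no GWAS annotation but evidence genes exist
  expect_equal(assign_tier(character(0), "GA")$tier, "2C")
  expect_equal(assign_tier("GA", c("GA", "GB"))$tier, "2A")
  expect_equal(assign_tier(c("GA", "GB"), c("GA", "GC"))$tier, "2B")
})

test_that("tier assignment matches the brute-force oracle on every membership configuration", {
  genes <- paste0("G", 1:4)
  states <- c("g_only", "q_only", "both")
  grid <- expand.grid(rep(list(states), 4), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(grid))) {
    st <- unlist(grid[k, ])
    g <- genes[st %in% c("g_only", "both")]
    q <- genes[st %in% c("q_only", "both")]
    expect_equal(assign_tier(g, q)$tier, oracle_tier(g, q),
                 label = paste(st, collapse = ","))
  }
})

test_that("adding evidence never removes genes and never demotes to tier 3", {
  set.seed(29)
  for (k in 1:100) {
    g <- sample(paste0("G", 1:5), sample(0:3, 1))
    q1 <- sample(paste0("G", 1:8), sample(1:4, 1))
    extra <- sample(paste0("G", 1:8), sample(1:3, 1))
    t1 <- assign_tier(g, q1)$tier
    t2 <- assign_tier(g, union(q1, extra))$tier
    expect_false(t2 == "3")
    if (t1 == "3") expect_true(t2 %in% c("1", "2A", "2B", "2C"))
  }
})

test_that("proxy expansion honours the window and the strict r2 threshold", {
  # block 1 in tight LD; block 2 independent; blocks separated by 500 kb
  pan <- simulate_haplotypes(400, list(c(3, 1), c(3, 1)), seed = 37,
                             spacing_bp = 2000, block_gap_bp = 600000)
  got <- expand_markers("v0001", pan, window = 1e6, r2_min = 0.8)
  expect_setequal(got, c("v0001", "v0002", "v0003"))
  # a perfect proxy beyond the half-window (+/- 2 kb here) is excluded
  narrow <- expand_markers("v0001", pan, window = 4000, r2_min = 0.8)
  expect_setequal(narrow, c("v0001", "v0002"))
  # no proxies above threshold: the query comes back alone
  lone <- expand_markers("v0004", pan, window = 4e5, r2_min = 0.8)
  expect_true(all(lone %in% c("v0004", "v0005", "v0006")))
  expect_error(expand_markers("vXXX", pan), "not present")
})

test_that("tier tallies and source bookkeeping are deterministic", {
  cat1 <- simulate_locus_catalog(seed = 43)
  res <- reprioritize_loci(cat1$gwas, cat1$qtl, cat1$transcripts)
  s <- summarize_tiers(res$assignments, res$evidence)
  expect_equal(unname(s$tier_counts), rep(1L, 5))
  # total newly added genes equals the per-source tally
  n_new <- sum(lengths(strsplit(
    res$assignments$new_genes[res$assignments$new_genes != ""], ";"
  )))
  expect_equal(sum(s$added_by_source), n_new)
  empty <- summarize_tiers(tibble::tibble(tier = character(0),
                                          new_genes = character(0),
                                          locus = character(0)))
  expect_equal(unname(empty$tier_counts), rep(0L, 5))
})

test_that("the classifier recovers every planted tier label end to end", {
  for (s in c(1, 2, 3)) {
    cat1 <- simulate_locus_catalog(seed = s)
    res <- reprioritize_loci(cat1$gwas, cat1$qtl, cat1$transcripts)
    m <- match(cat1$truth$locus, res$assignments$locus)
    expect_equal(res$assignments$tier[m], cat1$truth$true_tier)
  }
})
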