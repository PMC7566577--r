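test_that("a canonical 76-nt dot-bracket parses into a 7/4/5/5 cloverleaf", {
  s <- parse_dotbracket(PHE_SEQ, PHE_DB)
  expect_s3_class(s, "cloverleaf")
  expect_equal(unname(s$layout[c("aspan", "dspan", "acspan", "tspan")]),
               c(7L, 4L, 5L, 5L))
  expect_true(s$cca)
  expect_false(s$long_arm)
})

test_that("non-cloverleaf topologies are rejected with a named violation", {
  hairpin <- paste0(strrep("(", 10), strrep(".", 56), strrep(")", 10))
  expect_error(parse_dotbracket(PHE_SEQ, hairpin),
               class = "trnaclover_topology_error")
  # two inner helices
  db2 <- paste0(strrep("(", 7), "..",
                strrep("(", 4), strrep(".", 8), strrep(")", 4), ".",
                strrep("(", 5), strrep(".", 7), strrep(")", 5),
                strrep(".", 22),
                strrep(")", 7), "....")
  err <- expect_error(parse_dotbracket(PHE_SEQ, db2),
                      class = "trnaclover_topology_error")
  expect_match(conditionMessage(err), "2 inner helices")
  expect_error(parse_dotbracket("ACGU", "(().."),
               class = "trnaclover_topology_error")
  expect_error(parse_dotbracket("ACGUA", "(()))"),
               class = "trnaclover_topology_error")
})

test_that("a long variable arm parses as a fourth inner helix and is flagged", {
  # 13-bp variable arm between the AC and T arms
  lay <- c(aspan = 7, dspan = 4, acspan = 5, tspan = 5, dloop = 8,
           vlen = 0, tail = 1)
  arm <- paste0(strrep("(", 13), strrep(".", 4), strrep(")", 13))
  db <- paste0(strrep("(", 7), "..", strrep("(", 4), strrep(".", 8),
               strrep(")", 4), ".", strrep("(", 5), strrep(".", 7),
               strrep(")", 5), arm, strrep("(", 5), strrep(".", 7),
               strrep(")", 5), strrep(")", 7), ".")
  seqx <- strrep("A", nchar(db))
  s <- parse_dotbracket(seqx, db)
  expect_true(s$long_arm)
  expect_equal(unname(s$layout[["vlen"]]), 30L)
})

test_that("folding recovers the yeast tRNA-Phe cloverleaf and 1..76 labels", {
  s <- fold_cloverleaf(PHE_SEQ)
  m <- assign_numbering(s, PHE_SEQ)
  expect_identical(m$labels, as.character(1:76))
  ch <- strsplit(PHE_SEQ, "")[[1]]
  expect_equal(paste(ch[m$reverse[c("34", "35", "36")]], collapse = ""), "GAA")
  # parse and fold agree when both succeed
  s2 <- parse_dotbracket(PHE_SEQ, PHE_DB)
  expect_identical(s$layout, s2$layout)
  expect_identical(s$stems, s2$stems)
})

test_that("an unpairable sequence is a fold failure carrying the best score", {
  err <- expect_error(fold_cloverleaf(strrep("A", 76)),
                      class = "trnaclover_fold_error")
  expect_true(is.numeric(err$best_partial))
  expect_error(fold_cloverleaf(strrep("A", 20)), "length")
  expect_error(fold_cloverleaf(paste0(strrep("A", 75), "X")), "A/C/G/U")
})

test_that("one acceptor-stem mismatch still folds, with 6 acceptor pairs", {
  ch <- strsplit(PHE_SEQ, "")[[1]]
  # break the Watson-Crick pair 5:68 (C5=G68) without creating a wobble
  expect_equal(ch[5], "A"); expect_equal(ch[68], "U")
  ch[5] <- "C"
  mut <- paste(ch, collapse = "")
  s <- fold_cloverleaf(mut)
  expect_equal(nrow(s$stems$acceptor), 6L)
  expect_equal(unname(s$layout[["aspan"]]), 7L)
  m <- assign_numbering(s, mut)
  expect_identical(m$labels, as.character(1:76))
})

test_that("introns splice by 1-based inclusive bounds and idempotently", {
  g <- empty_genes()
  g[1, c("id", "raw_sequence", "intron_start", "intron_end")] <-
    list("x", "ACGUACG", 3L, 5L)
  out <- splice_intron(g)
  expect_equal(out$sequence[1], "ACCG")
  # idempotent when no intron
  g2 <- empty_genes()
  g2[1, c("id", "raw_sequence")] <- list("y", "ACGUACG")
  expect_equal(splice_intron(splice_intron(g2))$sequence[1], "ACGUACG")
  g$intron_start[1] <- 1L; g$intron_end[1] <- 7L
  expect_error(splice_intron(g), "whole sequence")
  g$intron_end[1] <- 99L
  expect_error(splice_intron(g), "outside sequence")
})

test_that("a 7-residue D-loop drops label 17, keeping all others", {
  cfg <- sim_config(seed = 41L, n_genes = 6L, d_loop_length_range = c(7L, 7L),
                    variable_region_length_range = c(5L, 5L), p_intron = 0)
  sim <- generate_gene_set(cfg)
  for (i in seq_len(nrow(sim$genes))) {
    s <- fold_cloverleaf(sim$genes$sequence[i])
    m <- assign_numbering(s, sim$genes$sequence[i])
    expect_false("17" %in% m$labels)
    expect_identical(setdiff(as.character(1:73), m$labels), "17")
  }
})

test_that("numbering is bijective and canonically ordered across loop sizes", {
  k <- 0L
  for (dloop in 7:10) for (vlen in c(3L, 4L, 5L, 9L, 15L, 23L)) {
    k <- k + 1L
    cfg <- sim_config(seed = 100L + k, n_genes = 2L,
                      d_loop_length_range = c(dloop, dloop),
                      variable_region_length_range = c(vlen, vlen),
                      p_intron = 0,
                      feature_probs = list(`mammal|AGC-like` =
                        c(F_extraU17 = if (dloop > 7L) 1 else 0)))
    sim <- generate_gene_set(cfg)
    for (i in seq_len(nrow(sim$genes))) {
      seqx <- sim$genes$sequence[i]
      m <- assign_numbering(fold_cloverleaf(seqx), seqx)
      expect_false(anyDuplicated(m$labels) > 0)
      rk <- match(m$labels, canonical_label_order())
      expect_false(anyNA(rk))
      expect_true(all(diff(rk) > 0))
      # 34-36 central in the anticodon loop, 33 immediately before 34
      expect_equal(unname(m$reverse["34"] - m$reverse["33"]), 1L)
      expect_equal(unname(m$reverse["36"] - m$reverse["34"]), 2L)
      expect_true("48" %in% m$labels)
      if (vlen >= 4L) expect_true("47" %in% m$labels)
      if (vlen > 5L) expect_true(all(paste0("e", seq_len(vlen - 5L)) %in%
                                       m$labels))
    }
  }
})

test_that("parse and fold agree on generator scaffolds with their true dot-bracket", {
  sim <- small_set("mammal", n = 15L, seed = 17L, p_intron = 0)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    lay <- c(aspan = tr$aspan[i], dspan = tr$dspan[i], acspan = tr$acspan[i],
             tspan = tr$tspan[i], dloop = tr$dloop[i], vlen = tr$vlen[i],
             tail = 1)
    db <- db_from_layout(lay)
    seqx <- sim$genes$sequence[i]
    sp <- parse_dotbracket(seqx, db)
    sf <- fold_cloverleaf(seqx)
    expect_identical(sp$layout, sf$layout)
    expect_identical(assign_numbering(sp, seqx)$labels,
                     assign_numbering(sf, seqx)$labels)
  }
})
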