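test_that("the score filter partitions at the quoted thresholds", {
  recs <- data.frame(id = letters[1:4], score = c(72.1, 60.0, 59.9, 54.9))
  out <- filter_by_score(recs, threshold = 60)
  expect_equal(out$kept$id, c("a", "b"))          # >= is inclusive
  expect_equal(out$dropped$id, c("c", "d"))
  expect_equal(out$pseudo_flagged$id, "d")        # below 55.0
  # threshold 0 keeps everything scored
  expect_equal(nrow(filter_by_score(recs, threshold = 0)$kept), 4L)
  # empty input: three empty parts
  e <- filter_by_score(recs[0, ])
  expect_equal(vapply(e, nrow, 1L), c(kept = 0L, dropped = 0L,
                                      pseudo_flagged = 0L))
  # missing scores drop with a reason
  recs$score[2] <- NA
  out2 <- filter_by_score(recs, threshold = 60)
  expect_true("no score" %in% out2$dropped$reason)
  expect_false("b" %in% out2$kept$id)
})

test_that("crosstab frequencies are counts over weighted gene totals", {
  prof <- data.frame(
    taxon = "t", isotype = "Ala", anticodon_class = "AGC-like",
    gene_copies = 1L,
    F_30o40 = rep(c(TRUE, FALSE), c(6, 4)))
  tab <- crosstab(prof, group_by = "isotype", flags = "F_30o40")
  expect_equal(tab$freq_F_30o40, 0.6)
  expect_equal(tab$n_genes, 10)
  # gene-copy weighting is the default
  prof$gene_copies <- rep(c(3L, 1L), c(6, 4))
  tabw <- crosstab(prof, group_by = "isotype", flags = "F_30o40")
  expect_equal(tabw$n_genes, 22)
  expect_equal(tabw$n_F_30o40, 18)
  tabu <- crosstab(prof, group_by = "isotype", flags = "F_30o40",
                   weight_by_gene_copies = FALSE)
  expect_equal(tabu$freq_F_30o40, 0.6)
})

test_that("the mammalian AGC/YGC split reproduces on a hand-counted fixture", {
  # six genes built to the mammalian pattern: AGC-like carry the 54/58
  # purine-purine pair, YGC-like never do
  prof <- data.frame(
    taxon = "mammal", isotype = "Ala",
    anticodon_class = rep(c("AGC-like", "YGC-like"), each = 3),
    gene_copies = 1L,
    F_54_58_AA = rep(c(TRUE, FALSE), each = 3),
    F_30o40 = rep(c(FALSE, TRUE), each = 3))
  tab <- crosstab(prof, flags = c("F_54_58_AA", "F_30o40"))
  expect_equal(tab$anticodon_class, c("AGC-like", "YGC-like"))
  expect_equal(tab$freq_F_54_58_AA, c(1, 0))
  expect_equal(tab$freq_F_30o40, c(0, 1))
})

test_that("crosstab is empty on empty input and permutation-invariant", {
  expect_equal(nrow(crosstab(profile_set(empty_genes()))), 0L)
  sim <- small_set("insect", n = 30L, seed = 59L)
  prof <- profile_set(sim$genes, use_dotbracket = FALSE)
  t1 <- crosstab(prof)
  t2 <- crosstab(prof[rev(seq_len(nrow(prof))), ])
  rownames(t2) <- NULL
  expect_equal(t1, t2)
  # marginal conservation: group totals add up to the weighted input total
  expect_equal(sum(t1$n_genes), sum(prof$gene_copies))
  for (fl in flag_names())
    expect_true(all(t1[[paste0("n_", fl)]] <= t1$n_genes))
})

test_that("co-occurrence counts equal a brute-force double loop", {
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(1:20, 1)
    prof <- data.frame(F_15_48_RR = sample(c(TRUE, FALSE), n, replace = TRUE),
                       F_54_58_AA = sample(c(TRUE, FALSE), n, replace = TRUE))
    co <- cooccurrence(prof)
    counts <- c(both = 0L, a_only = 0L, b_only = 0L, neither = 0L)
    for (i in seq_len(n)) {
      a <- prof$F_15_48_RR[i]; b <- prof$F_54_58_AA[i]
      counts[if (a && b) "both" else if (a) "a_only"
             else if (b) "b_only" else "neither"] <-
        counts[if (a && b) "both" else if (a) "a_only"
               else if (b) "b_only" else "neither"] + 1L
    }
    expect_equal(unlist(co[c("both", "a_only", "b_only", "neither")]),
                 counts)
    expect_equal(sum(counts), n)
    # phi agrees with the Pearson correlation of the indicator vectors
    if (!is.na(co$phi))
      expect_equal(co$phi, suppressWarnings(cor(prof$F_15_48_RR,
                                                prof$F_54_58_AA)))
  }
})

test_that("degenerate and independent 2x2 tables give the expected phi", {
  four <- data.frame(F_15_48_RR = c(TRUE, TRUE, FALSE, FALSE),
                     F_54_58_AA = c(TRUE, FALSE, TRUE, FALSE))
  co <- cooccurrence(four)
  expect_equal(unlist(co[c("both", "a_only", "b_only", "neither")]),
               c(both = 1L, a_only = 1L, b_only = 1L, neither = 1L))
  expect_equal(co$phi, 0)
  one <- data.frame(F_15_48_RR = TRUE, F_54_58_AA = TRUE)
  co1 <- cooccurrence(one)
  expect_equal(co1$both, 1L)
  expect_true(is.na(co1$phi))
})

test_that("generator linkage forces empty off-diagonals", {
  cfg <- sim_config(seed = 67L, n_genes = 120L,
                    isotype_mix = c(Ala = 1),
                    anticodon_mix = list(Ala = c(AGC = 1)),
                    feature_probs = list(`mammal|AGC-like` =
                      c(F_15_48_RR = 0.5, F_54_58_AA = 0.5)))
  sim <- generate_gene_set(cfg)
  prof <- profile_set(sim$genes, use_dotbracket = FALSE)
  co <- cooccurrence(prof)
  expect_equal(co$a_only, 0L)
  expect_equal(co$b_only, 0L)
  expect_gt(co$both, 0L)
})

test_that("configured flag frequencies are recovered within binomial error", {
  p_true <- 0.8
  cfg <- sim_config(seed = 71L, n_genes = 500L,
                    taxa = c(insect = 1), isotype_mix = c(Ala = 1),
                    anticodon_mix = list(Ala = c(AGC = 1)),
                    feature_probs = list(`insect|AGC-like` =
                      c(F_30o40 = p_true)))
  sim <- generate_gene_set(cfg)
  prof <- profile_set(sim$genes, use_dotbracket = FALSE)
  tab <- crosstab(prof, group_by = "taxon", weight_by_gene_copies = FALSE)
  se <- sqrt(p_true * (1 - p_true) / nrow(prof))
  expect_lt(abs(tab$freq_F_30o40 - p_true), 3 * se)
  # a branch configured to zero stays exactly zero
  cfg0 <- sim_preset("fungi", n_genes = 100L, seed = 73L)
  prof0 <- profile_set(generate_gene_set(cfg0)$genes, use_dotbracket = FALSE)
  tab0 <- crosstab(prof0, group_by = "taxon", weight_by_gene_copies = FALSE)
  for (fl in setdiff(flag_names(), "F_3o70"))
    expect_equal(tab0[[paste0("freq_", fl)]], 0)
})
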