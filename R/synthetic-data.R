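# Seeded generator of GtRNAdb-like tRNA gene sets with ground-truth
# structures and feature labels, so every pipeline stage is testable without
# any download. Scaffolds carry the conserved anchors (U8, A14, G18, G19,
# U33, G53=C61, U54, U55, C56), stems are sampled as complementary random
# duplexes, and the diagnostic positions are overwritten according to the
# sampled feature flags.

#' Configuration for the synthetic gene-set generator
#'
#' @param seed Integer master seed; per-gene substreams are derived by
#'   counter, so gene i is identical whatever \code{n_genes} is.
#' @param n_genes Number of genes to generate.
#' @param taxa Named numeric vector of taxon weights.
#' @param isotype_mix Named numeric vector of isotype weights.
#' @param anticodon_mix Named list: isotype -> named weights over anticodons.
#' @param feature_probs Named list: \code{"<taxon>|<anticodon class>"} ->
#'   named probabilities for the flags F_3o70, F_30o40, F_15_48_RR,
#'   F_54_58_AA, F_extraU17, F_R60 (missing entries are 0).
#' @param enforce_linkage_15_48_54_58 Couple F_15_48_RR and F_54_58_AA to a
#'   single Bernoulli draw (their probabilities must then agree), reproducing
#'   the observed strict co-occurrence of the two purine-purine pairs.
#' @param score_distribution c(mean, sd) of the simulated tRNAscan-SE scores.
#' @param p_intron Probability of an intron (inserted after position 37, the
#'   canonical tRNA intron site; length 8-20).
#' @param d_loop_length_range Range of D-loop lengths (7-11 supported; genes
#'   flagged F_extraU17 use at least 8 so that label 17 exists).
#' @param variable_region_length_range Range of variable-region lengths
#'   (3-23 supported).
#' @param copy_weights Probabilities of gene-copy numbers 1..k.
#' @return A \code{sim_config} list (validated).
#' @export
sim_config <- function(seed = 1L, n_genes = 100L, taxa = c(mammal = 1),
                       isotype_mix = c(Ala = 0.7, Gly = 0.3),
                       anticodon_mix = list(
                         Ala = c(AGC = 0.5, CGC = 0.25, UGC = 0.25),
                         Gly = c(GCC = 0.5, CCC = 0.2, UCC = 0.3)),
                       feature_probs = list(),
                       enforce_linkage_15_48_54_58 = TRUE,
                       score_distribution = c(mean = 72, sd = 6),
                       p_intron = 0.1,
                       d_loop_length_range = c(7L, 10L),
                       variable_region_length_range = c(4L, 5L),
                       copy_weights = c(0.6, 0.2, 0.1, 0.1)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              taxa = taxa, isotype_mix = isotype_mix,
              anticodon_mix = anticodon_mix, feature_probs = feature_probs,
              enforce_linkage_15_48_54_58 = enforce_linkage_15_48_54_58,
              score_distribution = score_distribution, p_intron = p_intron,
              d_loop_length_range = as.integer(d_loop_length_range),
              variable_region_length_range =
                as.integer(variable_region_length_range),
              copy_weights = copy_weights)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_w <- function(w, what) {
    if (any(w < 0) || sum(w) <= 0)
      trna_error(sprintf("%s weights must be nonnegative with positive sum",
                         what), "trnaclover_config_error")
  }
  if (cfg$n_genes < 1L)
    trna_error("n_genes must be positive", "trnaclover_config_error")
  chk_w(cfg$taxa, "taxon"); chk_w(cfg$isotype_mix, "isotype")
  for (iso in names(cfg$anticodon_mix)) chk_w(cfg$anticodon_mix[[iso]],
                                              paste("anticodon", iso))
  for (fp in cfg$feature_probs)
    if (any(fp < 0 | fp > 1))
      trna_error("feature probabilities must lie in [0, 1]",
                 "trnaclover_config_error")
  if (cfg$enforce_linkage_15_48_54_58)
    for (fp in cfg$feature_probs) {
      p15 <- if ("F_15_48_RR" %in% names(fp)) fp[["F_15_48_RR"]] else 0
      p54 <- if ("F_54_58_AA" %in% names(fp)) fp[["F_54_58_AA"]] else 0
      if (!isTRUE(all.equal(unname(p15), unname(p54))))
        trna_error("with linkage enforced, P(F_15_48_RR) must equal P(F_54_58_AA)",
                   "trnaclover_config_error")
    }
  rng <- cfg$d_loop_length_range
  if (rng[1] < 7L || rng[2] > 11L || rng[1] > rng[2])
    trna_error("d_loop_length_range must lie within 7-11",
               "trnaclover_config_error")
  vr <- cfg$variable_region_length_range
  if (vr[1] < 3L || vr[2] > 23L || vr[1] > vr[2])
    trna_error("variable_region_length_range must lie within 3-23",
               "trnaclover_config_error")
  if (cfg$p_intron < 0 || cfg$p_intron > 1)
    trna_error("p_intron must lie in [0, 1]", "trnaclover_config_error")
  invisible(cfg)
}

#' Preset generator configurations for the main phylogenetic patterns
#'
#' Alanine-tRNA gene sets reproducing the headline per-branch patterns:
#' \describe{
#'   \item{mammal}{A34 (AGC-like) isodecoders carry both purine-purine pairs
#'     R15/A48 and A54/A58 but a Watson-Crick 30-40; Y34 (YGC-like)
#'     isodecoders carry G30oU40 only.}
#'   \item{insect}{AGC-like isodecoders carry all three unusual pairs
#'     simultaneously.}
#'   \item{fungi}{no unusual pairs at all (the null branch).}
#' }
#' Every alanine class keeps the identity wobble G3oU70. Where the
#' purine-purine pairs are present, the accompanying context features (extra
#' U17, R60) are switched on as well.
#'
#' @param name One of "mammal", "insect", "fungi".
#' @param n_genes,seed Passed through to [sim_config()].
#' @return A \code{sim_config}.
#' @export
sim_preset <- function(name = c("mammal", "insect", "fungi"), n_genes = 120L,
                       seed = 1L) {
  name <- match.arg(name)
  base <- c(F_3o70 = 1, F_30o40 = 0, F_15_48_RR = 0, F_54_58_AA = 0,
            F_extraU17 = 0, F_R60 = 0)
  on <- function(...) { p <- base; p[c(...)] <- 1; p }
  fp <- switch(name,
    mammal = list(
      `mammal|AGC-like` = on("F_15_48_RR", "F_54_58_AA", "F_extraU17", "F_R60"),
      `mammal|YGC-like` = on("F_30o40")),
    insect = list(
      `insect|AGC-like` = on("F_30o40", "F_15_48_RR", "F_54_58_AA",
                             "F_extraU17", "F_R60"),
      `insect|YGC-like` = base),
    fungi = list(`fungi|AGC-like` = base, `fungi|YGC-like` = base))
  sim_config(seed = seed, n_genes = n_genes,
             taxa = stats::setNames(1, name),
             isotype_mix = c(Ala = 1),
             anticodon_mix = list(Ala = c(AGC = 0.5, CGC = 0.25, UGC = 0.25)),
             feature_probs = fp)
}

sample_weighted <- function(w) names(w)[sample.int(length(w), 1L, prob = w)]

anticodon_class_of <- function(anticodon) {
  b34 <- substr(anticodon, 1, 1)
  if (b34 == "A") "AGC-like" else if (b34 %in% PYRIMIDINES) "YGC-like"
  else "other"
}

# sample a 5' strand of n random bases and return both strands of a perfect
# Watson-Crick duplex
sample_duplex <- function(n) {
  s5 <- sample(RNA_BASES, n, replace = TRUE)
  list(s5 = s5, s3 = rev(unname(WC_PARTNER[s5])))
}

# does the sequence contain an off-target reverse-complement 6-mer match,
# i.e. a 6-bp duplex not fully explained by the true stem pairs?
has_off_target_duplex <- function(ch, stems) {
  L <- length(ch)
  paired <- integer(L)
  for (st in stems) for (k in seq_len(nrow(st))) {
    paired[st[k, 1]] <- st[k, 2]; paired[st[k, 2]] <- st[k, 1]
  }
  s <- paste(ch, collapse = "")
  hex <- substring(s, 1:(L - 5L), 6:L)
  rc <- unname(WC_PARTNER[ch])
  rchex <- vapply(seq_len(L - 5L),
                  function(i) paste(rc[(i + 5L):i], collapse = ""), "")
  for (i in seq_len(L - 14L)) {
    js <- seq(i + 9L, L - 5L)          # hairpin loop of >= 3 between windows
    hits <- js[hex[js] == rchex[i]]
    for (j in hits)
      if (!all(paired[i:(i + 5L)] == (j + 5L):j)) return(TRUE)
  }
  FALSE
}

generate_one <- function(cfg, i) {
  taxon <- sample_weighted(cfg$taxa)
  isotype <- sample_weighted(cfg$isotype_mix)
  anticodon <- sample_weighted(cfg$anticodon_mix[[isotype]])
  klass <- anticodon_class_of(anticodon)
  fp <- cfg$feature_probs[[paste(taxon, klass, sep = "|")]] %||% numeric(0)
  p <- function(f) if (f %in% names(fp)) unname(fp[[f]]) else 0
  draw <- function(f) stats::runif(1) < p(f)
  flags <- c(F_3o70 = draw("F_3o70"), F_30o40 = draw("F_30o40"))
  if (cfg$enforce_linkage_15_48_54_58) {
    link <- stats::runif(1) < p("F_15_48_RR")
    flags <- c(flags, F_15_48_RR = link, F_54_58_AA = link)
  } else {
    flags <- c(flags, F_15_48_RR = draw("F_15_48_RR"),
               F_54_58_AA = draw("F_54_58_AA"))
  }
  flags <- c(flags, F_extraU17 = draw("F_extraU17"), F_R60 = draw("F_R60"))
  sample1 <- function(v) v[sample.int(length(v), 1L)]
  dlr <- cfg$d_loop_length_range
  dloop <- if (flags[["F_extraU17"]])
    sample1(seq(max(8L, dlr[1]), max(8L, dlr[2])))
  else sample1(seq(dlr[1], dlr[2]))
  vlen <- sample1(seq(cfg$variable_region_length_range[1],
                      cfg$variable_region_length_range[2]))
  layout <- c(aspan = 7L, dspan = 4L, acspan = 5L, tspan = 5L,
              dloop = dloop, vlen = vlen, tail = 1L)
  for (attempt in 1:200) {
    ch <- build_scaffold(layout, anticodon, flags)
    seg <- layout_segments(layout)
    spans <- stem_spans(seg)
    if (!has_off_target_duplex(ch, spans)) break
    if (attempt == 200L)
      trna_error("could not sample a scaffold free of off-target duplexes",
                 "trnaclover_sim_error")
  }
  seq0 <- paste(ch, collapse = "")
  # intron after the residue at label 37 (canonical site)
  intron <- c(NA_integer_, NA_integer_)
  raw <- seq0
  if (stats::runif(1) < cfg$p_intron) {
    pos37 <- seg$acloop[6]   # 32..38 -> sixth residue is 37
    ilen <- sample(8:20, 1L)
    ins <- paste(sample(RNA_BASES, ilen, replace = TRUE), collapse = "")
    raw <- paste0(substr(seq0, 1, pos37), ins,
                  substr(seq0, pos37 + 1L, nchar(seq0)))
    intron <- c(pos37 + 1L, pos37 + ilen)
  }
  score <- round(stats::rnorm(1, cfg$score_distribution[["mean"]],
                              cfg$score_distribution[["sd"]]), 1)
  copies <- sample.int(length(cfg$copy_weights), 1L, prob = cfg$copy_weights)
  species <- sprintf("%s_sp%d", taxon, sample.int(3L, 1L))
  list(taxon = taxon, species = species, isotype = isotype,
       anticodon = anticodon, klass = klass, flags = flags, layout = layout,
       sequence = seq0, raw = raw, intron = intron, score = score,
       copies = copies)
}

# assemble one scaffold; bases at diagnostic positions are set by the flags,
# conserved anchors are fixed, everything else is sampled
build_scaffold <- function(layout, anticodon, flags) {
  seg <- layout_segments(layout)
  L <- layout_length(layout)
  ch <- character(L)
  spans <- stem_spans(seg)
  for (s in names(spans)) {
    sp <- spans[[s]]
    dup <- sample_duplex(nrow(sp))
    ch[sp[, 1]] <- dup$s5
    ch[sp[, 2]] <- rev(dup$s3)
  }
  put <- function(idx, val) ch[idx] <<- val
  acc <- spans$acceptor
  put(acc[1, ], c("G", "C"))                                   # G1=C72
  put(acc[3, ], if (flags[["F_3o70"]]) c("G", "U") else {
    b <- sample(setdiff(RNA_BASES, "G"), 1L)                   # avoid GoU
    c(b, unname(WC_PARTNER[b]))
  })
  ac <- spans$ac
  put(ac[3, ], c("C", "G"))                                    # C29=G41
  put(ac[4, ], if (flags[["F_30o40"]]) c("G", "U") else c("G", "C"))
  tst <- spans$t
  put(tst[5, ], c("G", "C"))                                   # G53=C61
  put(seg$conn, c("U", "A"))                                   # U8, R9
  put(seg$n26, "A")                                            # R26
  dl <- seg$dloop
  n <- length(dl)
  # D-loop: A14, 15/16 by flags, optional 17/17a, G18 G19, 20(+ins), 21;
  # non-anchor positions avoid G so the GG anchor stays unique
  pre_n <- min(3L + max(0L, n - 7L), 5L)
  post_n <- n - pre_n - 2L
  base15 <- if (flags[["F_15_48_RR"]]) sample(PURINES, 1L) else "G"
  base16 <- if (flags[["F_15_48_RR"]]) sample(PURINES, 1L) else "C"
  base17 <- if (flags[["F_extraU17"]]) "U" else sample(c("A", "C"), 1L)
  pre <- c("A", base15, base16, base17,
           sample(c("A", "C", "U"), 1L))[seq_len(pre_n)]
  post <- c("U", sample(c("A", "C", "U"), 2L, replace = TRUE),
            "A")[c(seq_len(post_n - 1L), 4L)]
  put(dl, c(pre, "G", "G", post))
  put(seg$acloop, c("C", "U", seq_chars(anticodon), "A", "A"))
  vl <- seg$var
  vbases <- c("A", "G", sample(c("A", "C", "U"), max(0L, length(vl) - 3L),
                               replace = TRUE),
              if (flags[["F_15_48_RR"]]) "A" else "C")
  put(vl, vbases)
  put(seg$tloop, c(if (flags[["F_54_58_AA"]]) "A" else "U", "U", "C", "A",
                   "A", sample(PYRIMIDINES, 1L),
                   if (flags[["F_R60"]]) sample(PURINES, 1L) else "C"))
  put(seg$disc, "A")                                           # discriminator
  ch
}

derive_gene_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 16807) %% 2147483647
}

#' Generate a synthetic tRNA gene set with ground truth
#'
#' Deterministic for a fixed seed (per-gene substreams are derived by
#' counter). When \code{dir} is given, writes the same dialects the I/O layer
#' reads: \code{genes.fasta} (raw sequences with metadata headers),
#' \code{genes_scan.tsv} (tRNAscan-SE-style table with intron bounds given
#' 1-based on the gene sequence), \code{taxonomy.tsv} (species to taxon) and
#' \code{truth.tsv} (per-gene true flags, layout and canonical labels).
#'
#' @param config A \code{sim_config}.
#' @param dir Optional output directory (created if needed).
#' @return List with \code{genes} (a \code{trna_genes} data.frame),
#'   \code{truth} (data.frame), \code{taxonomy} (data.frame) and, when
#'   \code{dir} is given, \code{paths}.
#' @export
generate_gene_set <- function(config, dir = NULL) {
  validate_sim_config(config)
  rows <- vector("list", config$n_genes)
  truths <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    set.seed(derive_gene_seed(config$seed, i))
    g <- generate_one(config, i)
    id <- sprintf("%s.trna%d", g$species, i)
    rows[[i]] <- data.frame(
      id = id, species = g$species, taxon = g$taxon, isotype = g$isotype,
      anticodon = g$anticodon, score = g$score, gene_copies = g$copies,
      intron_start = g$intron[1], intron_end = g$intron[2],
      sequence = g$sequence, raw_sequence = g$raw,
      dotbracket = NA_character_, stringsAsFactors = FALSE)
    str <- new_cloverleaf(g$layout, layout_segments(g$layout),
                          stem_spans(layout_segments(g$layout)),
                          nchar(g$sequence))
    labels <- assign_numbering(str, g$sequence)$labels
    truths[[i]] <- data.frame(
      gene_id = id, taxon = g$taxon, species = g$species,
      isotype = g$isotype, anticodon = g$anticodon,
      anticodon_class = g$klass,
      as.list(g$flags),
      aspan = g$layout[["aspan"]], dspan = g$layout[["dspan"]],
      acspan = g$layout[["acspan"]], tspan = g$layout[["tspan"]],
      dloop = g$layout[["dloop"]], vlen = g$layout[["vlen"]],
      labels = paste(labels, collapse = ","), stringsAsFactors = FALSE)
  }
  genes <- new_trna_genes(do.call(rbind, rows))
  truth <- do.call(rbind, truths)
  taxonomy <- unique(data.frame(species = genes$species, taxon = genes$taxon,
                                stringsAsFactors = FALSE))
  taxonomy <- taxonomy[order(taxonomy$species), , drop = FALSE]
  out <- list(genes = genes, truth = truth, taxonomy = taxonomy)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "genes.fasta"),
                  scan = file.path(dir, "genes_scan.tsv"),
                  taxonomy = file.path(dir, "taxonomy.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    write_fasta(genes, paths$fasta)
    scan <- data.frame(
      name = genes$species,
      number = seq_len(nrow(genes)),
      begin = 1L, end = nchar(genes$raw_sequence),
      isotype = genes$isotype, anticodon = genes$anticodon,
      intron_begin = ifelse(is.na(genes$intron_start), 0L, genes$intron_start),
      intron_end = ifelse(is.na(genes$intron_end), 0L, genes$intron_end),
      score = genes$score)
    utils::write.table(scan, paths$scan, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(taxonomy, paths$taxonomy, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
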