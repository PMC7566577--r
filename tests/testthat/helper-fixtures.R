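# Shared fixtures, all built in code.

# yeast tRNA-Phe, 76 nt with CCA; the defining scaffold of the numbering
PHE_SEQ <- "GCGGAUUUAGCUCAGUUGGGAGAGCGCCAGACUGAAGAUCUGGAGGUCCUGUGUUCGAUCCACAGAAUUCGCACCA"

# dot-bracket for a cloverleaf layout (used to cross-check parse vs fold)
db_from_layout <- function(layout) {
  a <- layout[["aspan"]]; d <- layout[["dspan"]]; ac <- layout[["acspan"]]
  tt <- layout[["tspan"]]; dl <- layout[["dloop"]]; v <- layout[["vlen"]]
  tail <- layout[["tail"]]
  paste0(strrep("(", a), "..", strrep("(", d), strrep(".", dl),
         strrep(")", d), ".", strrep("(", ac), strrep(".", 7), strrep(")", ac),
         strrep(".", v), strrep("(", tt), strrep(".", 7), strrep(")", tt),
         strrep(")", a), ".", if (tail == 4L) "..." else "")
}

PHE_DB <- db_from_layout(c(aspan = 7, dspan = 4, acspan = 5, tspan = 5,
                           dloop = 8, vlen = 5, tail = 4))

# hand-written oracle for pair classification: all 16 ordered dinucleotides
PAIR_ORACLE <- data.frame(
  base5 = rep(c("A", "C", "G", "U"), each = 4),
  base3 = rep(c("A", "C", "G", "U"), times = 4),
  pair_class = c(
    "purine_purine", "other_mismatch", "purine_purine", "WC_AU",
    "other_mismatch", "pyrimidine_pyrimidine", "WC_GC", "pyrimidine_pyrimidine",
    "purine_purine", "WC_GC", "purine_purine", "wobble_GU",
    "WC_AU", "pyrimidine_pyrimidine", "wobble_UG", "pyrimidine_pyrimidine"),
  symbol = c("/", "/", "/", "-",
             "/", "/", "=", "/",
             "/", "=", "/", "o",
             "-", "/", "o", "/"),
  stringsAsFactors = FALSE
)

# small generated set shared across tests
small_set <- function(preset = "insect", n = 40L, seed = 3L, p_intron = 0.2) {
  cfg <- sim_preset(preset, n_genes = n, seed = seed)
  cfg$p_intron <- p_intron
  generate_gene_set(cfg)
}

flag_names <- function() c("F_3o70", "F_30o40", "F_15_48_RR", "F_54_58_AA",
                           "F_extraU17", "F_R60")

empty_genes <- function() {
  f <- tempfile(fileext = ".fasta")
  on.exit(unlink(f))
  writeLines(character(0), f)
  read_fasta(f)
}
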