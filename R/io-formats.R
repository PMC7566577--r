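# Reading and writing the external formats the pipeline touches: FASTA with a
# key=value header dialect, tRNAscan-SE-style tables, MODOMICS-coded sequences,
# Stockholm alignments with a canonical-label annotation, and TSV feature tables.
#
# Coordinate convention: everything file-facing is 1-based inclusive (the
# tRNAscan-SE convention); conversions to R indexing stay inside this file.

#' Table of MODOMICS-style modification codes
#'
#' One row per single-character modification symbol with the parent base it is
#' derived from. The default table covers the codes needed for tRNA gene work:
#' dihydrouridine (D, parent U), inosine (I, parent A; an A34 gene position is
#' read as inosine), pseudouridine (P, parent U) and ribothymidine /
#' 5-methyluridine (T, parent U). The mapping symbol to parent must be a
#' function; the table is data, so other codes can be added by the caller.
#'
#' @param extra Optional data.frame with columns \code{symbol}, \code{parent},
#'   \code{name} appended to the default table.
#' @return data.frame with columns \code{symbol}, \code{parent}, \code{name}.
#' @export
modomics_table <- function(extra = NULL) {
  tab <- data.frame(
    symbol = c("D", "I", "P", "T"),
    parent = c("U", "A", "U", "U"),
    name = c("dihydrouridine", "inosine", "pseudouridine", "ribothymidine"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(all(c("symbol", "parent", "name") %in% names(extra)))
    tab <- rbind(tab, extra[, c("symbol", "parent", "name")])
  }
  if (anyDuplicated(tab$symbol))
    trna_error("modification table maps a symbol to two parents",
               "trnaclover_modomics_error")
  if (!all(tab$parent %in% RNA_BASES))
    trna_error("modification parent bases must be one of A, C, G, U",
               "trnaclover_modomics_error")
  tab
}

#' Replace modification codes by their parent bases
#'
#' Rewrites a MODOMICS-coded sequence over plain A/C/G/U, recording where each
#' modification sat. Positions are 1-based on the output (same length as the
#' input). The function is idempotent on its own output.
#'
#' @param raw Character scalar; sequence over A/C/G/U plus modification codes.
#' @param table Modification table, see [modomics_table()].
#' @return List with \code{sequence} (plain RNA string) and \code{mods}, a
#'   data.frame with columns \code{position}, \code{symbol}, \code{parent},
#'   \code{name} (zero rows when nothing was modified).
#' @export
normalize_modomics <- function(raw, table = modomics_table()) {
  stopifnot(is.character(raw), length(raw) == 1L)
  ch <- seq_chars(raw)
  known <- c(RNA_BASES, table$symbol)
  bad <- which(!(ch %in% known))
  if (length(bad))
    trna_error(sprintf("unknown symbol '%s' at position %d", ch[bad[1]], bad[1]),
               "trnaclover_modomics_error")
  hit <- which(ch %in% table$symbol)
  mods <- data.frame(position = hit,
                     symbol = ch[hit],
                     stringsAsFactors = FALSE)
  if (nrow(mods)) {
    m <- match(mods$symbol, table$symbol)
    mods$parent <- table$parent[m]
    mods$name <- table$name[m]
    ch[mods$position] <- mods$parent
  } else {
    mods$parent <- character(0)
    mods$name <- character(0)
  }
  list(sequence = paste(ch, collapse = ""), mods = mods)
}

new_trna_genes <- function(df) {
  needed <- c("id", "species", "taxon", "isotype", "anticodon", "score",
              "gene_copies", "intron_start", "intron_end", "sequence",
              "raw_sequence", "dotbracket")
  for (col in setdiff(needed, names(df))) df[[col]] <- rep(NA, nrow(df))
  df <- df[, needed, drop = FALSE]
  df$gene_copies[is.na(df$gene_copies)] <- 1L
  class(df) <- c("trna_genes", "data.frame")
  df
}

#' @export
print.trna_genes <- function(x, ...) {
  cat(sprintf("tRNA gene set: %d gene(s)\n", nrow(x)))
  if (nrow(x)) {
    tab <- table(paste(x$isotype, x$anticodon, sep = "-"))
    cat("  isoacceptors:", paste(sprintf("%s (%d)", names(tab), tab),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

parse_header_metadata <- function(header) {
  toks <- strsplit(trimws(header), "[ \t]+")[[1]]
  id <- toks[1]
  meta <- list()
  for (tok in toks[-1]) {
    if (!grepl("=", tok, fixed = TRUE)) next     # free text is ignored
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- paste(kv[-1], collapse = "=")
  }
  list(id = id, meta = meta)
}

#' Read tRNA gene sequences from FASTA
#'
#' Headers follow a declared dialect: the first whitespace-delimited token is
#' the record id; any further \code{key=value} tokens are parsed, with the keys
#' \code{species}, \code{taxon}, \code{isotype}, \code{anticodon},
#' \code{score}, \code{copies} and \code{intron} (as \code{start-end}, 1-based
#' inclusive on the stored sequence) recognised. Unknown keys are ignored.
#' Bodies are case-insensitive; T is normalized to U and MODOMICS codes are
#' replaced by their parent bases ([normalize_modomics()]). The stored
#' \code{raw_sequence} is the body as read (uppercased); \code{sequence} is
#' the normalized, intron-spliced gene.
#'
#' @param path Path to a FASTA file.
#' @param modomics Modification table used for normalization.
#' @return A \code{trna_genes} data.frame, one row per record (zero rows for
#'   an empty file).
#' @export
read_fasta <- function(path, modomics = modomics_table()) {
  if (!file.exists(path))
    trna_error(sprintf("FASTA file not found: %s", path), "trnaclover_io_error")
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first) && !startsWith(trimws(lines[first]), ">"))
    trna_error(sprintf("malformed FASTA in %s: line %d does not start a record",
                       path, first), "trnaclover_io_error")
  if (is.na(first)) return(new_trna_genes(data.frame(id = character(0))))
  set <- Biostrings::readBStringSet(path)
  n <- length(set)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    h <- parse_header_metadata(names(set)[i])
    raw <- toupper(as.character(set[[i]]))
    body <- chartr("T", "U", raw)
    norm <- tryCatch(normalize_modomics(body, modomics), error = function(e) e)
    if (inherits(norm, "error")) {
      ch <- seq_chars(body)
      bad <- which(!(ch %in% c(RNA_BASES, modomics$symbol)))[1]
      trna_error(sprintf("record '%s': invalid character '%s' at position %d",
                         h$id, ch[bad], bad), "trnaclover_io_error")
    }
    intron <- c(NA_integer_, NA_integer_)
    if (!is.null(h$meta$intron)) {
      se <- suppressWarnings(as.integer(strsplit(h$meta$intron, "-")[[1]]))
      if (length(se) != 2L || anyNA(se))
        trna_error(sprintf("record '%s': bad intron spec '%s'", h$id,
                           h$meta$intron), "trnaclover_io_error")
      intron <- se
    }
    score <- suppressWarnings(as.numeric(h$meta$score %||% NA))
    rows[[i]] <- data.frame(
      id = h$id,
      species = h$meta$species %||% NA_character_,
      taxon = h$meta$taxon %||% NA_character_,
      isotype = h$meta$isotype %||% "Und",
      anticodon = chartr("T", "U", toupper(h$meta$anticodon %||% NA_character_)),
      score = score,
      gene_copies = as.integer(h$meta$copies %||% 1L),
      intron_start = intron[1], intron_end = intron[2],
      sequence = norm$sequence,
      raw_sequence = raw,
      dotbracket = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  genes <- new_trna_genes(do.call(rbind, rows))
  splice_intron(genes)
}

#' Write tRNA genes to FASTA
#'
#' Inverse of [read_fasta()]: emits the raw (unspliced) sequence with all
#' known metadata in the key=value header dialect, so that write-then-read
#' round-trips sequences and parsed metadata.
#'
#' @param genes A \code{trna_genes} data.frame.
#' @param path Output path.
#' @export
write_fasta <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    kv <- character(0)
    if (!is.na(g$species)) kv <- c(kv, paste0("species=", g$species))
    if (!is.na(g$taxon)) kv <- c(kv, paste0("taxon=", g$taxon))
    if (!is.na(g$isotype)) kv <- c(kv, paste0("isotype=", g$isotype))
    if (!is.na(g$anticodon)) kv <- c(kv, paste0("anticodon=", g$anticodon))
    if (!is.na(g$score)) kv <- c(kv, paste0("score=", format(g$score)))
    if (!is.na(g$gene_copies) && g$gene_copies != 1L)
      kv <- c(kv, paste0("copies=", g$gene_copies))
    if (!is.na(g$intron_start))
      kv <- c(kv, sprintf("intron=%d-%d", g$intron_start, g$intron_end))
    writeLines(c(paste(c(paste0(">", g$id), kv), collapse = " "),
                 g$raw_sequence), con)
  }
  invisible(path)
}

#' Read a tRNAscan-SE-style tabular gene list
#'
#' Column contract (whitespace- or tab-delimited, the standard tRNAscan-SE
#' output layout): sequence name, tRNA number, begin, end, isotype, anticodon,
#' intron begin, intron end, score. Intron bounds of 0/0 mean no intron; the
#' record id is \code{<name>.trna<number>}. Header/separator lines of the
#' native format (starting with \code{Sequence}, \code{Name} or \code{-----})
#' are skipped. Sequences are attached later by joining on id against a FASTA
#' ([join_sequences()]). Reverse-strand genes (begin > end) keep their FASTA
#' sequence as given; the coordinate order is metadata only.
#'
#' @param path Path to the table.
#' @return A \code{trna_genes} data.frame without sequences.
#' @export
read_trnascan_table <- function(path) {
  if (!file.exists(path))
    trna_error(sprintf("table not found: %s", path), "trnaclover_io_error")
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(Sequence|Name|-+\\s)", lines))
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) != 9L)
      trna_error(sprintf("%s line %d: expected 9 columns, found %d",
                         path, ln, length(f)), "trnaclover_io_error")
    score <- suppressWarnings(as.numeric(f[9]))
    if (is.na(score))
      trna_error(sprintf("%s line %d: non-numeric score '%s'", path, ln, f[9]),
                 "trnaclover_io_error")
    ib <- suppressWarnings(as.integer(f[7])); ie <- suppressWarnings(as.integer(f[8]))
    if (is.na(ib) || is.na(ie))
      trna_error(sprintf("%s line %d: bad intron bounds", path, ln),
                 "trnaclover_io_error")
    no_intron <- ib == 0L && ie == 0L
    rows[[k]] <- data.frame(
      id = sprintf("%s.trna%s", f[1], f[2]),
      species = f[1],
      isotype = f[5],
      anticodon = chartr("T", "U", toupper(f[6])),
      score = score,
      intron_start = if (no_intron) NA_integer_ else ib,
      intron_end = if (no_intron) NA_integer_ else ie,
      stringsAsFactors = FALSE
    )
  }
  new_trna_genes(if (length(rows)) do.call(rbind, rows)
                 else data.frame(id = character(0)))
}

#' Attach FASTA sequences to a scan-table gene list by id
#'
#' @param genes \code{trna_genes} rows (typically from [read_trnascan_table()]).
#' @param fasta \code{trna_genes} rows carrying sequences (from [read_fasta()]).
#' @return \code{genes} with \code{raw_sequence}/\code{sequence} filled in and
#'   introns spliced.
#' @export
join_sequences <- function(genes, fasta) {
  m <- match(genes$id, fasta$id)
  if (anyNA(m))
    trna_error(sprintf("no FASTA sequence for id(s): %s",
                       paste(genes$id[is.na(m)], collapse = ", ")),
               "trnaclover_io_error")
  genes$raw_sequence <- fasta$raw_sequence[m]
  genes$sequence <- fasta$sequence[m]
  splice_intron(genes)
}

#' Read a species-to-taxon mapping table
#'
#' Two-plus-column TSV: \code{species}, \code{taxon} (an optional third column
#' may carry a semicolon-joined lineage and is kept as \code{lineage}).
#'
#' @param path Path to the TSV.
#' @return data.frame with columns \code{species}, \code{taxon}
#'   (and \code{lineage} when present).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("species", "taxon") %in% names(df)))
    trna_error(sprintf("%s: expected columns 'species' and 'taxon'", path),
               "trnaclover_io_error")
  df
}

#' Assign taxa to genes from a species mapping
#'
#' Species missing from the mapping are assigned the taxon
#' \code{"unassigned"}.
#'
#' @param genes \code{trna_genes} data.frame.
#' @param taxonomy data.frame from [read_taxonomy()], or NULL to leave
#'   existing assignments.
#' @return \code{genes} with the \code{taxon} column filled.
#' @export
assign_taxa <- function(genes, taxonomy = NULL) {
  if (!is.null(taxonomy)) {
    m <- match(genes$species, taxonomy$species)
    genes$taxon <- ifelse(is.na(m), "unassigned", taxonomy$taxon[m])
  }
  genes$taxon[is.na(genes$taxon)] <- "unassigned"
  genes
}

#' Write a feature table as TSV
#'
#' Long layout: one row per (grouping keys, feature) with the weighted gene
#' count, the count of genes carrying the feature and its frequency. An empty
#' table produces a header-only file.
#'
#' @param table A \code{trna_feature_table} from [crosstab()].
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  keys <- attr(table, "group_by") %||% character(0)
  flags <- attr(table, "flags") %||% FLAG_NAMES
  long <- data.frame(matrix(nrow = 0, ncol = length(keys) + 4))
  names(long) <- c(keys, "feature", "n_genes", "n_with_flag", "freq")
  if (nrow(table)) {
    pieces <- lapply(flags, function(fl) {
      out <- table[, keys, drop = FALSE]
      out$feature <- fl
      out$n_genes <- table$n_genes
      out$n_with_flag <- table[[paste0("n_", fl)]]
      out$freq <- table[[paste0("freq_", fl)]]
      out
    })
    long <- do.call(rbind, pieces)
    ord <- do.call(order, c(unname(as.list(long[, keys, drop = FALSE])),
                            list(long$feature)))
    long <- long[ord, , drop = FALSE]
  }
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotated alignment in Stockholm 1.0 format
#'
#' Sequences are aligned on their canonical position labels: the columns are
#' the union of all labels in canonical order, each row shows a gene's residue
#' under each label (gap \code{-} where the label is absent). The labels
#' themselves are carried in a \code{#=GF CC COLS} line (space-separated, one
#' per column) and a \code{#=GC RF} line marks core columns \code{x} and
#' insertion columns (17a, 20a, 20b, e-labels) \code{.}.
#'
#' @param genes \code{trna_genes} rows.
#' @param maps List of \code{canonical_map} objects, one per gene, parallel to
#'   \code{genes}.
#' @param path Output path.
#' @export
write_alignment <- function(genes, maps, path) {
  stopifnot(nrow(genes) == length(maps))
  all_labels <- unique(unlist(lapply(maps, function(m) m$labels)))
  cols <- all_labels[order(label_rank(all_labels))]
  rows <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ch <- seq_chars(genes$sequence[i])
    idx <- maps[[i]]$reverse[cols]
    rows[i] <- paste(ifelse(is.na(idx), "-", ch[idx]), collapse = "")
  }
  core <- ifelse(grepl("^[0-9]+$", cols), "x", ".")
  idw <- max(nchar(genes$id), nchar("#=GC RF"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF CC Canonical position labels, one per column:",
               paste("#=GF CC COLS", paste(cols, collapse = " ")),
               sprintf("%-*s %s", idw, genes$id, rows),
               sprintf("%-*s %s", idw, "#=GC RF", paste(core, collapse = "")),
               "//"), con)
  invisible(path)
}
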