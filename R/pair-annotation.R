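# Base identities at diagnostic canonical positions, pair classification with
# the alignment symbols "-" (A-U/U-A), "=" (G=C/C=G), "o" (wobble) and "/"
# (non-Watson-Crick), and the unusual-feature flags of alanine tRNAs.

# the named pairs read out of every gene, 5' label : 3' label
PROFILE_PAIRS <- c("3:70", "27:43", "28:42", "29:41", "30:40", "31:39",
                   "15:48", "54:58", "16:59", "13:22", "26:44", "18:55",
                   "19:56", "8:14", "53:61")
PROFILE_SINGLES <- c("9", "17", "20", "21", "32", "33", "37", "38", "60", "73")

#' Classify an ordered base pair
#'
#' Total over the 16 ordered dinucleotides plus incomplete cases (NA bases).
#' The symbol convention follows tRNA alignment practice: \code{-} for A-U /
#' U-A, \code{=} for G=C / C=G, \code{o} for GoU / UoG wobble and \code{/}
#' for any other (non-Watson-Crick) combination; \code{?} when a base is
#' missing. Orientation is kept: GoU and UoG are distinct classes.
#'
#' @param base5,base3 Character vectors over A/C/G/U (NA for an absent base).
#' @return data.frame with columns \code{base5}, \code{base3},
#'   \code{pair_class} and \code{symbol}, one row per input pair.
#' @export
classify_pair <- function(base5, base3) {
  n <- max(length(base5), length(base3))
  b5 <- rep_len(as.character(base5), n)
  b3 <- rep_len(as.character(base3), n)
  cls <- character(n)
  inc <- is.na(b5) | is.na(b3)
  cls[inc] <- "incomplete"
  ok <- !inc
  au <- ok & ((b5 == "A" & b3 == "U") | (b5 == "U" & b3 == "A"))
  gc <- ok & ((b5 == "G" & b3 == "C") | (b5 == "C" & b3 == "G"))
  gu <- ok & b5 == "G" & b3 == "U"
  ug <- ok & b5 == "U" & b3 == "G"
  rr <- ok & b5 %in% PURINES & b3 %in% PURINES
  yy <- ok & b5 %in% PYRIMIDINES & b3 %in% PYRIMIDINES
  cls[au] <- "WC_AU"; cls[gc] <- "WC_GC"
  cls[gu] <- "wobble_GU"; cls[ug] <- "wobble_UG"
  rest <- ok & !(au | gc | gu | ug)
  cls[rest & rr] <- "purine_purine"
  cls[rest & yy] <- "pyrimidine_pyrimidine"
  cls[rest & !rr & !yy] <- "other_mismatch"
  sym <- rep("/", n)
  sym[au] <- "-"; sym[gc] <- "="
  sym[gu | ug] <- "o"; sym[inc] <- "?"
  data.frame(base5 = b5, base3 = b3, pair_class = cls, symbol = sym,
             stringsAsFactors = FALSE)
}

base_at <- function(ch, map, label) {
  i <- map$reverse[label]
  if (is.na(i)) NA_character_ else ch[i]
}

#' Extract the diagnostic-position profile of one gene
#'
#' Reads the base identities at every named diagnostic pair and single
#' position, classifies the pairs, and computes the unusual-feature flags:
#' \describe{
#'   \item{F_3o70}{G3oU70 wobble in the acceptor stem (G at 3, U at 70; the
#'     reversed UoG does not count).}
#'   \item{F_30o40}{G30oU40 wobble in the anticodon stem (again orientation
#'     matters; U30oG40 does not raise the flag).}
#'   \item{F_15_48_RR}{purine-purine tertiary pair: R at 15 with A at 48.}
#'   \item{F_54_58_AA}{purine-purine T-loop pair: A54 with A58.}
#'   \item{F_extraU17}{the extra D-loop residue: label 17 present and U.}
#'   \item{F_R60}{purine at T-loop position 60.}
#' }
#' The anticodon class is read from the gene-level base at 34: A34 (decoded
#' as inosine) gives \code{AGC-like}, a pyrimidine gives \code{YGC-like},
#' anything else \code{other}.
#'
#' @param map \code{canonical_map} from [assign_numbering()].
#' @param sequence The gene sequence the map was computed on.
#' @param isotype Amino-acid 3-letter code (or "Und").
#' @param gene_id Optional record id carried into the profile.
#' @return A \code{trna_profile} list with elements \code{gene_id},
#'   \code{isotype}, \code{anticodon}, \code{anticodon_class}, \code{pairs}
#'   (named list of pair observations), \code{singles} (named character) and
#'   \code{flags} (named logical).
#' @export
extract_profile <- function(map, sequence, isotype = "Und", gene_id = NA_character_) {
  ch <- seq_chars(sequence)
  ac <- map$reverse[c("34", "35", "36")]
  if (anyNA(ac))
    trna_error("labels 34-36 missing: anticodon (and profile) undefined",
               "trnaclover_profile_error")
  anticodon <- paste(ch[ac], collapse = "")
  b34 <- ch[ac[1]]
  anticodon_class <- if (b34 == "A") "AGC-like"
                     else if (b34 %in% PYRIMIDINES) "YGC-like" else "other"
  pairs <- lapply(PROFILE_PAIRS, function(p) {
    lb <- strsplit(p, ":", fixed = TRUE)[[1]]
    obs <- classify_pair(base_at(ch, map, lb[1]), base_at(ch, map, lb[2]))
    list(pos5 = lb[1], pos3 = lb[2], base5 = obs$base5, base3 = obs$base3,
         pair_class = obs$pair_class, symbol = obs$symbol)
  })
  names(pairs) <- PROFILE_PAIRS
  singles <- vapply(PROFILE_SINGLES, function(l) base_at(ch, map, l), "")
  g <- function(p) pairs[[p]]
  flags <- c(
    F_3o70 = g("3:70")$pair_class == "wobble_GU",
    F_30o40 = g("30:40")$pair_class == "wobble_GU",
    F_15_48_RR = isTRUE(g("15:48")$base5 %in% PURINES &&
                          identical(g("15:48")$base3, "A")),
    F_54_58_AA = isTRUE(identical(g("54:58")$base5, "A") &&
                          identical(g("54:58")$base3, "A")),
    F_extraU17 = isTRUE(!is.na(singles[["17"]]) && singles[["17"]] == "U"),
    F_R60 = isTRUE(!is.na(singles[["60"]]) && singles[["60"]] %in% PURINES)
  )
  prof <- list(gene_id = gene_id, isotype = isotype, anticodon = anticodon,
               anticodon_class = anticodon_class, pairs = pairs,
               singles = singles, flags = flags)
  class(prof) <- "trna_profile"
  prof
}

render_pair <- function(obs) {
  if (obs$symbol == "?") "?" else paste0(obs$base5, obs$symbol, obs$base3)
}

#' @export
print.trna_profile <- function(x, ...) {
  cat(sprintf("tRNA profile%s: %s, anticodon %s (%s)\n",
              if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
              x$isotype, x$anticodon, x$anticodon_class))
  cat("  pairs:", paste(sprintf("%s %s", names(x$pairs),
                                vapply(x$pairs, render_pair, "")),
                        collapse = "  "), "\n")
  on <- names(x$flags)[x$flags]
  cat("  flags:", if (length(on)) paste(on, collapse = " ") else "none", "\n")
  invisible(x)
}

#' Profile a whole gene set
#'
#' Batch driver: splice introns, determine the structure of each gene (from
#' its dot-bracket when present and \code{use_dotbracket} is TRUE, by
#' [fold_cloverleaf()] otherwise), assign canonical numbering and extract the
#' feature profile. Per-record failures are collected in a report attached as
#' the \code{failures} attribute (columns id, stage, reason), never silently
#' dropped.
#'
#' @param genes \code{trna_genes} data.frame (ids must be unique).
#' @param use_dotbracket Use a provided dot-bracket instead of folding.
#' @param taxonomy Optional species-to-taxon mapping ([read_taxonomy()]).
#' @return A \code{trna_profiles} data.frame, one row per successfully
#'   profiled gene: metadata columns, one logical column per flag, one
#'   rendered column per named pair (e.g. \code{pair_30_40 = "GoU"}) and one
#'   per single position.
#' @export
profile_set <- function(genes, use_dotbracket = TRUE, taxonomy = NULL) {
  if (anyDuplicated(genes$id))
    trna_error(sprintf("duplicate gene id(s): %s",
                       paste(unique(genes$id[duplicated(genes$id)]),
                             collapse = ", ")), "trnaclover_profile_error")
  genes <- assign_taxa(genes, taxonomy)
  genes <- splice_intron(genes)
  rows <- list()
  fails <- list()
  maps <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    stage <- "structure"
    res <- tryCatch({
      str <- if (use_dotbracket && !is.na(g$dotbracket))
        parse_dotbracket(g$sequence, g$dotbracket)
      else fold_cloverleaf(g$sequence)
      stage <- "numbering"
      map <- assign_numbering(str, g$sequence)
      stage <- "profile"
      prof <- extract_profile(map, g$sequence, isotype = g$isotype,
                              gene_id = g$id)
      list(prof = prof, map = map)
    }, trnaclover_error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        id = g$id, stage = stage, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
      next
    }
    prof <- res$prof
    row <- data.frame(gene_id = g$id, species = g$species, taxon = g$taxon,
                      isotype = g$isotype, anticodon = prof$anticodon,
                      anticodon_class = prof$anticodon_class,
                      score = g$score, gene_copies = g$gene_copies,
                      stringsAsFactors = FALSE)
    for (fl in names(prof$flags)) row[[fl]] <- unname(prof$flags[fl])
    for (p in names(prof$pairs))
      row[[paste0("pair_", gsub(":", "_", p))]] <- render_pair(prof$pairs[[p]])
    for (s in names(prof$singles))
      row[[paste0("pos", s)]] <- unname(prof$singles[s])
    rows[[length(rows) + 1L]] <- row
    maps[[g$id]] <- res$map
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else {
           tmpl <- data.frame(gene_id = character(0), species = character(0),
                              taxon = character(0), isotype = character(0),
                              anticodon = character(0),
                              anticodon_class = character(0),
                              score = numeric(0), gene_copies = integer(0))
           for (fl in FLAG_NAMES) tmpl[[fl]] <- logical(0)
           tmpl
         }
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails)
                           else data.frame(id = character(0),
                                           stage = character(0),
                                           reason = character(0))
  attr(out, "maps") <- maps
  class(out) <- c("trna_profiles", "data.frame")
  out
}

#' @export
print.trna_profiles <- function(x, ...) {
  fails <- attr(x, "failures")
  cat(sprintf("tRNA feature profiles: %d gene(s), %d failure(s)\n",
              nrow(x), if (is.null(fails)) 0L else nrow(fails)))
  if (nrow(x)) {
    for (fl in intersect(FLAG_NAMES, names(x)))
      cat(sprintf("  %-12s %d/%d\n", fl, sum(x[[fl]]), nrow(x)))
  }
  invisible(x)
}

#' Write profiles as TSV (one row per gene)
#'
#' @param profiles \code{trna_profiles} data.frame.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
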