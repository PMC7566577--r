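# Cloverleaf secondary structure and canonical (yeast tRNA-Phe style)
# numbering.
#
# A cloverleaf is represented by its layout -- the spans of the four stems,
# the D-loop length, the variable-region length and the 3' tail (discriminator
# with or without CCA) -- plus, for each stem, the list of index pairs that
# actually base-pair (Watson-Crick or GoU wobble). All indices are 1-based on
# the spliced sequence.

STEM_MIN <- c(acceptor = 6L, d = 3L, ac = 4L, t = 4L)

pair_kind <- function(b5, b3) {
  # 2 = Watson-Crick, 1 = GoU/UoG wobble, 0 = no pair
  ifelse(WC_PARTNER[b5] == b3, 2L,
         ifelse((b5 == "G" & b3 == "U") | (b5 == "U" & b3 == "G"), 1L, 0L))
}

# segment index ranges implied by a layout, in 5'->3' order
layout_segments <- function(layout) {
  a <- layout[["aspan"]]; d <- layout[["dspan"]]; dl <- layout[["dloop"]]
  ac <- layout[["acspan"]]; v <- layout[["vlen"]]; t <- layout[["tspan"]]
  tail <- layout[["tail"]]
  ends <- cumsum(c(a, 2L, d, dl, d, 1L, ac, 7L, ac, v, t, 7L, t, a, 1L,
                   if (tail == 4L) 3L else 0L))
  starts <- c(1L, ends[-length(ends)] + 1L)
  seg <- Map(function(s, e) if (e >= s) s:e else integer(0), starts, ends)
  names(seg) <- c("acc5", "conn", "d5", "dloop", "d3", "n26", "ac5", "acloop",
                  "ac3", "var", "t5", "tloop", "t3", "acc3", "disc",
                  "cca")[seq_along(seg)]
  if (tail != 4L) seg$cca <- integer(0)
  seg
}

layout_length <- function(layout) {
  with(as.list(layout), 2L * aspan + 2L + 2L * dspan + dloop + 1L +
         2L * acspan + 7L + vlen + 2L * tspan + 7L + tail)
}

# stem pair matrices (all opposing positions, paired or not)
stem_spans <- function(seg) {
  list(acceptor = cbind(seg$acc5, rev(seg$acc3)),
       d = cbind(seg$d5, rev(seg$d3)),
       ac = cbind(seg$ac5, rev(seg$ac3)),
       t = cbind(seg$t5, rev(seg$t3)))
}

new_cloverleaf <- function(layout, seg, stems, length, score = NA_real_,
                           long_arm = FALSE) {
  structure(list(layout = layout, segments = seg, stems = stems,
                 length = length, cca = layout[["tail"]] == 4L,
                 long_arm = long_arm, score = score),
            class = "cloverleaf")
}

#' @export
print.cloverleaf <- function(x, ...) {
  np <- vapply(x$stems, nrow, 1L)
  cat(sprintf(
    "tRNA cloverleaf (%d nt%s): acceptor %d bp, D %d bp (loop %d), AC %d bp, T %d bp, variable %d nt%s\n",
    x$length, if (x$cca) ", CCA" else "", np["acceptor"], np["d"],
    x$layout[["dloop"]], np["ac"], np["t"], x$layout[["vlen"]],
    if (isTRUE(x$long_arm)) " (long arm)" else ""))
  if (!is.na(x$score)) cat(sprintf("  fold score: %d\n", x$score))
  invisible(x)
}

# evaluate one candidate layout on a sequence; NULL when the stems do not
# reach their minimum pair counts
score_layout <- function(ch, layout) {
  seg <- layout_segments(layout)
  spans <- stem_spans(seg)
  stems <- vector("list", 4L)
  names(stems) <- names(spans)
  score <- 0L
  for (s in names(spans)) {
    k <- pair_kind(ch[spans[[s]][, 1]], ch[spans[[s]][, 2]])
    if (sum(k > 0L) < STEM_MIN[[s]]) return(NULL)
    stems[[s]] <- spans[[s]][k > 0L, , drop = FALSE]
    score <- score + sum(k)
  }
  # conserved anchors at their label-predicted indices, +3 each
  dl <- seg$dloop
  split <- d_loop_split(ch[dl])
  i18 <- dl[split$g]; i19 <- dl[split$g + 1L]
  anchors <- c(ch[seg$conn[1]] == "U",            # U8
               ch[dl[1]] == "A",                  # A14
               ch[i18] == "G", ch[i19] == "G",    # G18 G19
               ch[seg$acloop[2]] == "U",          # U33
               ch[seg$t5[length(seg$t5)]] == "G", # G53
               ch[seg$tloop[1]] == "U",           # U54 (T54 as DNA/modified)
               ch[seg$tloop[2]] == "U",           # U55
               ch[seg$tloop[3]] == "C")           # C56
  list(layout = layout, seg = seg, stems = stems,
       score = score + 3L * sum(anchors),
       npairs_acc = nrow(stems$acceptor))
}

# Split a D-loop into (pre, 18-19, post) segments. G18/G19 are anchored by
# the leftmost GG whose flanks admit the canonical label counts (3-5 residues
# before, 2-4 after); without such a GG a fixed split is used (three residues
# 14-16, then 17/17a as available, two to four residues 20(20a)(20b)21).
d_loop_split <- function(loop_ch) {
  n <- length(loop_ch)
  gg <- which(loop_ch[-n] == "G" & loop_ch[-1] == "G")
  for (g in gg) {
    if ((g - 1L) >= 3L && (g - 1L) <= 5L && (n - g - 1L) >= 2L &&
        (n - g - 1L) <= 4L)
      return(list(g = g, pre = g - 1L, post = n - g - 1L))
  }
  pre <- min(n - 4L, 5L)
  list(g = pre + 1L, pre = pre, post = n - pre - 2L)
}

#' Fold a tRNA sequence into a cloverleaf by template-constrained search
#'
#' Enumerates every admissible cloverleaf layout (acceptor stem 6-7 bp, D stem
#' 3-4 bp with a 7-11 nt loop, anticodon stem 4-5 bp with its 7 nt loop,
#' variable region 3-23 nt, T stem 4-5 bp with its 7 nt loop, discriminator
#' with optional CCA) and scores each: +2 per Watson-Crick pair, +1 per GoU
#' wobble pair, +3 per conserved anchor (U8, A14, G18, G19, U33, G53, U54,
#' U55, C56) found at its label-predicted position. A stem position that does
#' not pair is tolerated as long as the stem keeps its minimum number of real
#' pairs (acceptor 6, D 3, AC 4, T 4). Ties are broken deterministically:
#' highest score, then most acceptor pairs, then longest acceptor span, then
#' leftmost D stem, then the lexicographically smallest layout tuple.
#'
#' @param sequence RNA string (A/C/G/U), length 60-100.
#' @return A \code{cloverleaf} object with the winning score attached.
#' @export
fold_cloverleaf <- function(sequence) {
  ch <- seq_chars(sequence)
  L <- length(ch)
  if (L < 60L || L > 100L)
    trna_error(sprintf("sequence length %d outside the supported 60-100 nt", L),
               "trnaclover_fold_error")
  if (!all(ch %in% RNA_BASES))
    trna_error("sequence must be over A/C/G/U (normalize first)",
               "trnaclover_fold_error")
  tails <- if (identical(ch[(L - 2):L], c("C", "C", "A"))) c(1L, 4L) else 1L
  best <- NULL
  best_key <- NULL
  best_partial <- 0L
  for (aspan in c(7L, 6L)) for (dspan in c(4L, 3L))
    for (acspan in c(5L, 4L)) for (tspan in c(5L, 4L))
      for (dloop in 7:11) for (tail in tails) {
        vlen <- L - (2L * aspan + 2L + 2L * dspan + dloop + 1L +
                       2L * acspan + 7L + 2L * tspan + 7L + tail)
        if (vlen < 3L || vlen > 23L) next
        layout <- c(aspan = aspan, dspan = dspan, acspan = acspan,
                    tspan = tspan, dloop = dloop, vlen = vlen, tail = tail)
        cand <- score_layout(ch, layout)
        if (is.null(cand)) {
          next
        }
        best_partial <- max(best_partial, cand$score)
        # tie-break key: score desc, acceptor pairs desc, acceptor span desc,
        # D-stem start asc, layout tuple asc
        key <- c(-cand$score, -cand$npairs_acc, -aspan, aspan + 3L,
                 dspan, acspan, tspan, dloop, vlen, tail)
        if (is.null(best) || key_less(key, best_key)) {
          best <- cand
          best_key <- key
        }
      }
  if (is.null(best))
    trna_error(sprintf(
      "no cloverleaf with all four stems at minimum size (best partial score %d)",
      best_partial), "trnaclover_fold_error", best_partial = best_partial)
  new_cloverleaf(best$layout, best$seg, best$stems, L, score = best$score)
}

key_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0L && d[nz[1]] < 0
}

#' Parse a dot-bracket string into a cloverleaf structure
#'
#' Accepts the plain parenthesis dialect. The bracket tree must be a
#' cloverleaf: one outer helix (the acceptor stem, in which a single 1x1
#' internal mismatch is tolerated) enclosing exactly three inner hairpin
#' helices in D / anticodon / T order, with an optional fourth helix between
#' the anticodon and T arms (a long variable arm, flagged). Loop and connector
#' sizes are validated against the cloverleaf template (connector 8-9 of 2 nt,
#' anticodon loop of exactly 7 nt).
#'
#' @param sequence RNA string.
#' @param db Dot-bracket string of the same length.
#' @return A \code{cloverleaf} object.
#' @export
parse_dotbracket <- function(sequence, db) {
  ch <- seq_chars(sequence)
  L <- length(ch)
  bk <- seq_chars(db)
  if (length(bk) != L)
    trna_error("sequence and dot-bracket differ in length",
               "trnaclover_topology_error")
  if (!all(bk %in% c("(", ")", ".")))
    trna_error("dot-bracket must use only '(', ')' and '.'",
               "trnaclover_topology_error")
  partner <- integer(L)
  stack <- integer(0)
  for (i in seq_len(L)) {
    if (bk[i] == "(") stack <- c(stack, i)
    else if (bk[i] == ")") {
      if (!length(stack))
        trna_error(sprintf("unbalanced ')' at position %d", i),
                   "trnaclover_topology_error")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i; partner[i] <- j
    }
  }
  if (length(stack))
    trna_error(sprintf("unbalanced '(' at position %d", stack[1]),
               "trnaclover_topology_error")
  opens <- which(bk == "(")
  if (!length(opens))
    trna_error("no base pairs: not a cloverleaf", "trnaclover_topology_error")
  # group pairs into helices (contiguous stacks), then merge across 1x1
  # internal mismatches so a stem with one mismatched position stays one stem
  helices <- list()
  cur <- NULL
  for (i in opens) {
    j <- partner[i]
    if (!is.null(cur)) {
      gap5 <- i - cur$e5 - 1L
      gap3 <- cur$s3 - j - 1L
      stacked <- gap5 == 0L && gap3 == 0L
      mism <- gap5 == 1L && gap3 == 1L
      if ((stacked || mism) && j < cur$s3) {
        cur$e5 <- i; cur$s3 <- j
        cur$pairs <- rbind(cur$pairs, c(i, j))
        next
      }
      helices[[length(helices) + 1L]] <- cur
    }
    cur <- list(s5 = i, e5 = i, s3 = j, e3 = j, pairs = cbind(i, j))
  }
  helices[[length(helices) + 1L]] <- cur
  for (k in seq_along(helices)) helices[[k]]$e3 <- helices[[k]]$pairs[1, 2]
  # outermost helix = acceptor; inner helices must nest directly under it
  outer <- helices[[1]]
  if (outer$s5 != min(opens) || outer$e3 != max(partner[opens]))
    trna_error("outermost pairs do not form a single acceptor helix",
               "trnaclover_topology_error")
  inner <- helices[-1]
  contains <- vapply(inner, function(h) h$s5 > outer$e5 && h$e3 < outer$s3,
                     TRUE)
  if (!all(contains))
    trna_error("helices outside the acceptor stem: not a cloverleaf",
               "trnaclover_topology_error")
  # inner helices must be side by side (a multiloop), not nested
  if (length(inner) > 1L)
    for (k in 2:length(inner))
      if (inner[[k]]$s5 < inner[[k - 1L]]$e3)
        trna_error("nested inner helices: not a cloverleaf",
                   "trnaclover_topology_error")
  long_arm <- length(inner) == 4L
  if (length(inner) != 3L && !long_arm)
    trna_error(sprintf("%d inner helices (cloverleaf needs 3, or 4 with a long variable arm)",
                       length(inner)), "trnaclover_topology_error")
  hD <- inner[[1]]; hAC <- inner[[2]]
  hT <- inner[[length(inner)]]
  aspan <- outer$e5 - outer$s5 + 1L
  if (outer$s5 != 1L)
    trna_error("acceptor stem must start at position 1",
               "trnaclover_topology_error")
  conn <- hD$s5 - outer$e5 - 1L
  if (conn != 2L)
    trna_error(sprintf("connector 8-9 must be 2 nt, found %d", conn),
               "trnaclover_topology_error")
  dspan <- hD$e5 - hD$s5 + 1L
  dloop <- hD$s3 - hD$e5 - 1L
  n26 <- hAC$s5 - hD$e3 - 1L
  if (n26 != 1L)
    trna_error(sprintf("expected single residue 26 between D and AC arms, found %d",
                       n26), "trnaclover_topology_error")
  acspan <- hAC$e5 - hAC$s5 + 1L
  acloop <- hAC$s3 - hAC$e5 - 1L
  if (acloop != 7L)
    trna_error(sprintf("anticodon loop must be 7 nt, found %d", acloop),
               "trnaclover_topology_error")
  vlen <- hT$s5 - hAC$e3 - 1L
  tspan <- hT$e5 - hT$s5 + 1L
  tloop <- hT$s3 - hT$e5 - 1L
  if (tloop != 7L)
    trna_error(sprintf("T loop must be 7 nt, found %d", tloop),
               "trnaclover_topology_error")
  if (hT$e3 + 1L != outer$s3)
    trna_error("unpaired residues between T arm and acceptor 3' strand",
               "trnaclover_topology_error")
  tail <- L - outer$e3
  if (!(tail %in% c(1L, 4L)))
    trna_error(sprintf("expected discriminator (+ optional CCA) after the acceptor stem, found %d nt",
                       tail), "trnaclover_topology_error")
  if (!(aspan %in% 6:7) || !(dspan %in% 3:4) || !(acspan %in% 4:5) ||
      !(tspan %in% 4:5))
    trna_error(sprintf(
      "stem sizes (acceptor %d, D %d, AC %d, T %d) outside the cloverleaf template",
      aspan, dspan, acspan, tspan), "trnaclover_topology_error")
  layout <- vapply(list(aspan, dspan, acspan, tspan, dloop, vlen, tail),
                   function(x) as.integer(x[[1]]), 0L)
  names(layout) <- c("aspan", "dspan", "acspan", "tspan", "dloop", "vlen",
                     "tail")
  seg <- layout_segments(layout)
  spans <- stem_spans(seg)
  stems <- lapply(spans, function(sp) {
    k <- pair_kind(ch[sp[, 1]], ch[sp[, 2]])
    sp[k > 0L, , drop = FALSE]
  })
  new_cloverleaf(layout, seg, stems, L, long_arm = long_arm)
}

# D-loop label vector for a loop of the given bases
d_loop_labels <- function(loop_ch) {
  n <- length(loop_ch)
  if (n < 7L || n > 11L)
    trna_error(sprintf("D-loop of %d nt cannot be numbered (supported 7-11)", n),
               "trnaclover_numbering_error")
  sp <- d_loop_split(loop_ch)
  pre <- c("14", "15", "16", "17", "17a")[seq_len(sp$pre)]
  post <- switch(sp$post - 1L,
                 c("20", "21"),
                 c("20", "20a", "21"),
                 c("20", "20a", "20b", "21"))
  c(pre, "18", "19", post)
}

# variable-region labels: 48 always present, 47 kept from length 4 up,
# surplus e-labels inserted between 45 and 46
var_labels <- function(vlen) {
  if (vlen == 3L) return(c("44", "45", "48"))
  if (vlen == 4L) return(c("44", "45", "47", "48"))
  if (vlen == 5L) return(c("44", "45", "46", "47", "48"))
  ne <- vlen - 5L
  if (ne > 19L)
    trna_error(sprintf("variable region of %d nt exceeds the e-label range", vlen),
               "trnaclover_numbering_error")
  c("44", "45", paste0("e", seq_len(ne)), "46", "47", "48")
}

#' Assign canonical tRNA position labels to a folded sequence
#'
#' Maps each sequence index to its canonical label (the yeast tRNA-Phe
#' numbering 1-76, with insertion labels 17a, 20a, 20b in the D-loop and
#' e1-e19 in the variable region). G18/G19 are located by GG match inside the
#' D-loop before surplus labels are distributed on either side; an absent
#' position 17 marks tRNAs without the extra D-loop residue. Genes without a
#' 3' CCA simply lack labels 74-76, the discriminator 73 being the last
#' residue.
#'
#' @param structure A \code{cloverleaf} object.
#' @param sequence The same sequence the structure was derived from.
#' @return A \code{canonical_map}: list with \code{labels} (character vector,
#'   one label per sequence index) and \code{reverse} (named integer vector,
#'   label to index).
#' @export
assign_numbering <- function(structure, sequence) {
  stopifnot(inherits(structure, "cloverleaf"))
  ch <- seq_chars(sequence)
  if (length(ch) != structure$length)
    trna_error("sequence length does not match the structure",
               "trnaclover_numbering_error")
  lay <- structure$layout
  seg <- structure$segments
  if (length(seg$acloop) != 7L)
    trna_error("anticodon loop is not 7 nt: anticodon undefined",
               "trnaclover_numbering_error")
  lab <- character(structure$length)
  lab[seg$acc5] <- as.character(seq_len(lay[["aspan"]]))
  lab[seg$conn] <- c("8", "9")
  lab[seg$d5] <- if (lay[["dspan"]] == 4L) c("10", "11", "12", "13")
                 else c("10", "11", "12")
  lab[seg$dloop] <- d_loop_labels(ch[seg$dloop])
  lab[seg$d3] <- if (lay[["dspan"]] == 4L) as.character(22:25)
                 else as.character(23:25)
  lab[seg$n26] <- "26"
  lab[seg$ac5] <- if (lay[["acspan"]] == 5L) as.character(27:31)
                  else as.character(28:31)
  lab[seg$acloop] <- as.character(32:38)
  lab[seg$ac3] <- if (lay[["acspan"]] == 5L) as.character(39:43)
                  else as.character(39:42)
  lab[seg$var] <- var_labels(lay[["vlen"]])
  lab[seg$t5] <- if (lay[["tspan"]] == 5L) as.character(49:53)
                 else as.character(50:53)
  lab[seg$tloop] <- as.character(54:60)
  lab[seg$t3] <- if (lay[["tspan"]] == 5L) as.character(61:65)
                 else as.character(61:64)
  lab[seg$acc3] <- as.character(seq(73L - lay[["aspan"]], 72L))
  lab[seg$disc] <- "73"
  if (length(seg$cca)) lab[seg$cca] <- c("74", "75", "76")
  if (anyDuplicated(lab))
    trna_error("internal error: duplicated canonical labels",
               "trnaclover_numbering_error")
  reverse <- seq_along(lab)
  names(reverse) <- lab
  map <- list(labels = lab, reverse = reverse)
  class(map) <- "canonical_map"
  map
}

#' @export
print.canonical_map <- function(x, ...) {
  cat(sprintf("canonical map over %d residues (labels %s..%s)\n",
              length(x$labels), x$labels[1], x$labels[length(x$labels)]))
  ins <- x$labels[!grepl("^[0-9]+$", x$labels)]
  if (length(ins)) cat("  insertion labels:", paste(ins, collapse = " "), "\n")
  miss <- setdiff(as.character(1:76), x$labels)
  if (length(miss)) cat("  absent core labels:", paste(miss, collapse = " "), "\n")
  invisible(x)
}

#' Remove introns from gene records
#'
#' Splices each record's \code{raw_sequence} by removing the 1-based inclusive
#' intron span, storing the result in \code{sequence}. Records without introns
#' pass through unchanged (the operation is idempotent).
#'
#' @param genes \code{trna_genes} data.frame.
#' @return The spliced \code{trna_genes}.
#' @export
splice_intron <- function(genes) {
  for (i in seq_len(nrow(genes))) {
    s <- genes$intron_start[i]; e <- genes$intron_end[i]
    if (is.na(s)) {
      if (is.na(genes$sequence[i]) && !is.na(genes$raw_sequence[i]))
        genes$sequence[i] <- normalize_gene_sequence(genes$raw_sequence[i])
      next
    }
    raw <- genes$raw_sequence[i]
    n <- nchar(raw)
    if (is.na(e) || s < 1L || e < s || e > n)
      trna_error(sprintf("record '%s': intron [%s,%s] outside sequence of length %d",
                         genes$id[i], s, e, n), "trnaclover_intron_error")
    if (s == 1L && e == n)
      trna_error(sprintf("record '%s': intron covers the whole sequence",
                         genes$id[i]), "trnaclover_intron_error")
    spliced <- paste0(substr(raw, 1L, s - 1L), substr(raw, e + 1L, n))
    genes$sequence[i] <- normalize_gene_sequence(spliced)
  }
  genes
}

normalize_gene_sequence <- function(x) {
  normalize_modomics(chartr("T", "U", toupper(x)))$sequence
}
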