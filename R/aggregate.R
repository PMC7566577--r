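# Score filtering, feature cross-tabulation by (taxon, isotype, anticodon
# class), and co-occurrence of the two purine-purine pairs.

#' Filter records by tRNAscan-SE score
#'
#' Partition records into those at or above the analysis threshold (the
#' comparison is inclusive), those below it, and -- among the dropped -- those
#' whose score falls under the pseudogene threshold (a score below 55.0 may
#' indicate a pseudogene). Records without a score are dropped with the
#' reason \code{"no score"}. Input order is preserved in every output.
#'
#' @param records \code{trna_genes} or \code{trna_profiles} data.frame with a
#'   \code{score} column.
#' @param threshold Analysis threshold (default 60.0).
#' @param pseudogene_threshold Pseudogene threshold (default 55.0).
#' @return List with \code{kept}, \code{dropped} (with an added
#'   \code{reason} column) and \code{pseudo_flagged} (subset of dropped).
#' @export
filter_by_score <- function(records, threshold = 60.0,
                            pseudogene_threshold = 55.0) {
  sc <- records$score
  keep <- !is.na(sc) & sc >= threshold
  kept <- records[keep, , drop = FALSE]
  dropped <- records[!keep, , drop = FALSE]
  dropped$reason <- ifelse(is.na(dropped$score), "no score",
                           sprintf("score below %s", format(threshold)))
  pseudo <- dropped[!is.na(dropped$score) &
                      dropped$score < pseudogene_threshold, , drop = FALSE]
  list(kept = kept, dropped = dropped, pseudo_flagged = pseudo)
}

#' Cross-tabulate unusual-feature flags
#'
#' Counts and frequencies of each flag grouped by any subset of taxon,
#' isotype and anticodon class. By default a record with n gene copies
#' contributes n to every count (GtRNAdb alignments list copy numbers next to
#' the scores); set \code{weight_by_gene_copies = FALSE} to count records.
#' Rows are ordered lexicographically on the grouping keys, so the output is
#' permutation-invariant in its input.
#'
#' @param profiles \code{trna_profiles} data.frame.
#' @param group_by Character subset of
#'   \code{c("taxon", "isotype", "anticodon_class")}.
#' @param weight_by_gene_copies Weight counts by the \code{gene_copies}
#'   column.
#' @param flags Flag columns to tabulate.
#' @return A \code{trna_feature_table} data.frame: grouping keys,
#'   \code{n_genes}, and per flag \code{n_<flag>} and \code{freq_<flag>}.
#' @export
crosstab <- function(profiles,
                     group_by = c("taxon", "isotype", "anticodon_class"),
                     weight_by_gene_copies = TRUE, flags = FLAG_NAMES) {
  group_by <- match.arg(group_by, c("taxon", "isotype", "anticodon_class"),
                        several.ok = TRUE)
  flags <- intersect(flags, names(profiles))
  w <- if (weight_by_gene_copies) profiles$gene_copies else
    rep(1L, nrow(profiles))
  empty <- data.frame(matrix(nrow = 0, ncol = 0))
  for (k in group_by) empty[[k]] <- character(0)
  empty$n_genes <- numeric(0)
  for (fl in flags) {
    empty[[paste0("n_", fl)]] <- numeric(0)
    empty[[paste0("freq_", fl)]] <- numeric(0)
  }
  if (!nrow(profiles)) {
    class(empty) <- c("trna_feature_table", "data.frame")
    attr(empty, "group_by") <- group_by
    attr(empty, "flags") <- flags
    return(empty)
  }
  key <- interaction(profiles[, group_by, drop = FALSE], drop = TRUE,
                     sep = "\r", lex.order = TRUE)
  groups <- sort(levels(key))
  rows <- lapply(groups, function(gk) {
    sel <- key == gk
    parts <- strsplit(gk, "\r", fixed = TRUE)[[1]]
    row <- as.data.frame(as.list(parts), stringsAsFactors = FALSE)
    names(row) <- group_by
    row$n_genes <- sum(w[sel])
    for (fl in flags) {
      n <- sum(w[sel & profiles[[fl]]])
      row[[paste0("n_", fl)]] <- n
      row[[paste0("freq_", fl)]] <- n / row$n_genes
    }
    row
  })
  out <- do.call(rbind, rows)
  ord <- do.call(order, unname(as.list(out[, group_by, drop = FALSE])))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trna_feature_table", "data.frame")
  attr(out, "group_by") <- group_by
  attr(out, "flags") <- flags
  out
}

#' @export
print.trna_feature_table <- function(x, digits = 3, ...) {
  cat("Feature table grouped by",
      paste(attr(x, "group_by"), collapse = ", "), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Co-occurrence of two feature flags
#'
#' 2x2 contingency of two flags over a profile set (one count per record; the
#' four counts sum to the number of profiles) with the phi coefficient as the
#' linkage measure. Phi is NA when any margin is zero (including the perfect
#' co-occurrence case where neither flag ever appears alone together with a
#' constant flag).
#'
#' @param profiles \code{trna_profiles} data.frame.
#' @param flag_a,flag_b Names of the two flag columns; defaults are the two
#'   purine-purine pairs whose joint occurrence is the headline observation.
#' @return A \code{trna_cooccurrence} list: counts \code{both},
#'   \code{a_only}, \code{b_only}, \code{neither} and \code{phi}.
#' @export
cooccurrence <- function(profiles, flag_a = "F_15_48_RR",
                         flag_b = "F_54_58_AA") {
  a <- profiles[[flag_a]]
  b <- profiles[[flag_b]]
  stopifnot(is.logical(a), is.logical(b))
  res <- list(
    flag_a = flag_a, flag_b = flag_b,
    both = sum(a & b), a_only = sum(a & !b),
    b_only = sum(!a & b), neither = sum(!a & !b)
  )
  m <- c(res$both + res$a_only, res$b_only + res$neither,
         res$both + res$b_only, res$a_only + res$neither)
  res$phi <- if (any(m == 0)) NA_real_ else
    (res$both * res$neither - res$a_only * res$b_only) / sqrt(prod(m))
  class(res) <- "trna_cooccurrence"
  res
}

#' @export
print.trna_cooccurrence <- function(x, ...) {
  n <- x$both + x$a_only + x$b_only + x$neither
  cat(sprintf("Co-occurrence of %s and %s over %d profiles\n",
              x$flag_a, x$flag_b, n))
  cat(sprintf("  both %d | %s only %d | %s only %d | neither %d\n",
              x$both, x$flag_a, x$a_only, x$flag_b, x$b_only, x$neither))
  cat(sprintf("  phi: %s\n",
              if (is.na(x$phi)) "undefined (zero margin)"
              else format(round(x$phi, 4))))
  invisible(x)
}
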