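# Shared constants and small helpers.

RNA_BASES <- c("A", "C", "G", "U")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "U")

# Watson-Crick complement
WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

FLAG_NAMES <- c("F_3o70", "F_30o40", "F_15_48_RR", "F_54_58_AA",
                "F_extraU17", "F_R60")

#' Canonical tRNA position labels in canonical order
#'
#' Returns the full ordered universe of canonical position labels used by the
#' numbering scheme: 1-76, the D-loop insertion labels 17a, 20a, 20b, and the
#' variable-region insertion labels e1-e19 (which sort between 45 and 46).
#'
#' @return Character vector of labels in canonical 5' to 3' order.
#' @export
canonical_label_order <- function() {
  c(as.character(1:16), "17", "17a", "18", "19", "20", "20a", "20b",
    as.character(21:45), paste0("e", 1:19), as.character(46:76))
}

# rank of a label in the canonical order (NA for unknown labels)
label_rank <- function(labels) {
  match(labels, canonical_label_order())
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# condition constructor used for structured errors
trna_error <- function(msg, class, ...) {
  stop(structure(class = c(class, "trnaclover_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
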