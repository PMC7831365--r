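# Codon alignment container: a character matrix of aligned CDS rows plus a
# column map tying alignment columns to reference CDS coordinates.

ALLOWED_CHARS <- c("A", "C", "G", "T", "-", "N", "?")
MISSING_CHARS <- c("N", "?")

#' Construct a codon alignment
#'
#' @param seqs named character vector of aligned sequences (strings of equal
#'   length over A,C,G,T,'-' and the missing symbols 'N'/'?'), or a character
#'   matrix with one row per taxon.
#' @param reference name of the intact reference taxon; its ungapped sequence
#'   defines the CDS coordinate system.
#' @param check_orf if `TRUE` (default) warn when the reference ungapped
#'   sequence does not begin with ATG or end with a stop codon; if `"error"`,
#'   fail instead.
#' @return object of class `codon_alignment` with components `mat` (character
#'   matrix taxa x columns), `reference`, and `column_map` (integer vector:
#'   reference CDS position of each column, `NA` for insertion columns).
#' @export
codon_alignment <- function(seqs, reference, check_orf = TRUE) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequences have unequal lengths")
    mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
    rownames(mat) <- names(seqs)
  }
  if (nrow(mat) < 2L) stop("alignment needs at least 2 sequences")
  if (anyDuplicated(rownames(mat))) stop("duplicate taxon names")
  bad <- setdiff(unique(as.vector(mat)), ALLOWED_CHARS)
  if (length(bad))
    stop("non-IUPAC characters in alignment: ", paste(bad, collapse = ", "))
  if (!reference %in% rownames(mat))
    stop("reference taxon '", reference, "' absent from alignment")

  ref_row <- mat[reference, ]
  nongap <- ref_row != "-"
  column_map <- rep(NA_integer_, ncol(mat))
  column_map[nongap] <- seq_len(sum(nongap))

  cds_len <- sum(nongap)
  if (cds_len %% 3L != 0L)
    stop("reference ungapped length (", cds_len, ") not divisible by 3")
  ref_cds <- paste(ref_row[nongap], collapse = "")
  orf_msg <- character(0)
  if (substr(ref_cds, 1, 3) != "ATG")
    orf_msg <- c(orf_msg, "reference CDS does not begin with ATG")
  if (!substr(ref_cds, cds_len - 2, cds_len) %in% STOP_CODONS)
    orf_msg <- c(orf_msg, "reference CDS does not end with a stop codon")
  if (length(orf_msg)) {
    if (identical(check_orf, "error")) stop(paste(orf_msg, collapse = "; "))
    if (isTRUE(check_orf)) warning(paste(orf_msg, collapse = "; "))
  }

  structure(
    list(mat = mat, reference = reference, column_map = column_map),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", nrow(x$mat), "taxa x", ncol(x$mat), "columns\n")
  cat("Reference:", x$reference, "(CDS length", cds_length(x), "nt,",
      cds_length(x) / 3, "codons)\n")
  n_ins <- sum(is.na(x$column_map))
  if (n_ins) cat("Insertion columns (relative to reference):", n_ins, "\n")
  invisible(x)
}

#' Taxa of a codon alignment
#' @param aln a `codon_alignment`
#' @export
taxa <- function(aln) rownames(aln$mat)

#' Reference CDS length in nucleotides
#' @param aln a `codon_alignment`
#' @export
cds_length <- function(aln) sum(!is.na(aln$column_map))

#' Drop taxa from an alignment (reference cannot be dropped)
#' @param aln a `codon_alignment`
#' @param drop taxa to remove
#' @export
drop_taxa <- function(aln, drop) {
  if (aln$reference %in% drop) stop("cannot drop the reference taxon")
  keep <- setdiff(taxa(aln), drop)
  aln$mat <- aln$mat[keep, , drop = FALSE]
  aln
}

# Column indices of reference codon k: a 3 x ncodon matrix
ref_codon_columns <- function(aln) {
  cols <- which(!is.na(aln$column_map))
  matrix(cols[order(aln$column_map[cols])], nrow = 3)
}

#' Extract reference-frame codons for every taxon
#'
#' Insertion columns (gaps in the reference) are ignored; each cell is the
#' 3-mer a taxon carries at that reference codon.
#' @param aln a `codon_alignment`
#' @return character matrix, taxa x codons
#' @export
codon_matrix <- function(aln) {
  cc <- ref_codon_columns(aln)
  ncod <- ncol(cc)
  out <- matrix(NA_character_, nrow(aln$mat), ncod,
                dimnames = list(rownames(aln$mat), NULL))
  for (k in seq_len(ncod)) {
    out[, k] <- paste0(aln$mat[, cc[1, k]], aln$mat[, cc[2, k]], aln$mat[, cc[3, k]])
  }
  out
}

#' Recode premature stop codons as missing data
#'
#' Every fully resolved in-frame stop codon (reference frame) that is not the
#' reference's terminal stop is replaced by `???`; the terminal stop codon
#' columns are removed for all taxa. This is the standard preparation before a
#' codon-model fit, where stops are not part of the state space.
#' @param aln a `codon_alignment`
#' @return recoded `codon_alignment` (terminal stop columns removed)
#' @export
recode_premature_stops <- function(aln) {
  cc <- ref_codon_columns(aln)
  ncod <- ncol(cc)
  for (k in seq_len(ncod - 1L)) {
    cods <- paste0(aln$mat[, cc[1, k]], aln$mat[, cc[2, k]], aln$mat[, cc[3, k]])
    hit <- cods %in% STOP_CODONS
    if (any(hit)) {
      aln$mat[hit, cc[, k]] <- "?"
    }
  }
  drop_cols <- cc[, ncod]
  aln$mat <- aln$mat[, -drop_cols, drop = FALSE]
  aln$column_map <- aln$column_map[-drop_cols]
  aln
}

# Integer codon states for the likelihood: taxa x codons, 1..61 or NA for
# anything unresolved (gap, missing, or a stop that survived recoding).
codon_states <- function(aln) {
  cm <- codon_matrix(aln)
  idx <- codon_index(cm)
  matrix(idx, nrow(cm), ncol(cm), dimnames = dimnames(cm))
}
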