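# Standard nuclear genetic code machinery shared by the scanner, the
# likelihood engine and the simulator. Everything is built once at load
# into an internal environment.

.codon_env <- new.env(parent = emptyenv())

NUC <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' All 64 codons in lexicographic (A,C,G,T) order
#' @noRd
all_codons <- function() {
  g <- expand.grid(p3 = NUC, p2 = NUC, p1 = NUC, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' The 61 sense codons of the standard nuclear code
#' @return character vector of length 61, fixed order
#' @export
sense_codons <- function() {
  if (is.null(.codon_env$sense)) {
    .codon_env$sense <- setdiff(all_codons(), STOP_CODONS)
  }
  .codon_env$sense
}

#' Translate codons to amino acids (standard code)
#' @param codons character vector of 3-mers over ACGT
#' @return character vector of one-letter amino acids ("*" for stop)
#' @export
translate_codons <- function(codons) {
  tab <- codon_aa_table()
  unname(tab[toupper(codons)])
}

codon_aa_table <- function() {
  if (is.null(.codon_env$aa)) {
    cods <- all_codons()
    aa <- vapply(cods, function(cd) {
      toupper(seqinr::translate(strsplit(cd, "")[[1]]))
    }, character(1))
    .codon_env$aa <- aa
  }
  .codon_env$aa
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Pairwise substitution classification over the 61 sense codons
#'
#' Codes: 0 = not a single-nucleotide change; 1 = synonymous transversion;
#' 2 = synonymous transition; 3 = nonsynonymous transversion;
#' 4 = nonsynonymous transition. Symmetric by construction.
#' @return 61 x 61 integer matrix
#' @export
codon_pair_types <- function() {
  if (!is.null(.codon_env$pair_types)) return(.codon_env$pair_types)
  sc <- sense_codons()
  n <- length(sc)
  mat <- matrix(0L, n, n, dimnames = list(sc, sc))
  aa <- translate_codons(sc)
  split_mat <- do.call(rbind, strsplit(sc, ""))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diff <- which(split_mat[i, ] != split_mat[j, ])
      if (length(diff) != 1L) next
      ts <- is_transition(split_mat[i, diff], split_mat[j, diff])
      syn <- aa[i] == aa[j]
      code <- if (syn && !ts) 1L else if (syn && ts) 2L else if (!syn && !ts) 3L else 4L
      mat[i, j] <- code
      mat[j, i] <- code
    }
  }
  .codon_env$pair_types <- mat
  mat
}

#' Map codon strings to 1-based indices into sense_codons(); NA for
#' anything that is not a fully resolved sense codon.
#' @noRd
codon_index <- function(codons) {
  match(toupper(codons), sense_codons())
}
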