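# Scanner for gene-inactivating (ORF-disrupting) mutations in a query row of
# a codon-aware alignment, relative to an intact reference: initiation-codon
# loss, frameshift indels, premature stop codons, splice-site (GT/AG)
# mutations, whole-exon deletions. Codons containing any missing symbol are
# never called (conservative: low-coverage data must not create lesions).

#' The seven recognised classes of inactivating mutation
#'
#' Character vector of the lesion types the scanner can call and the
#' simulator can plant.
#' @export
LESION_TYPES <- c("initiation_codon_mutation", "frameshift_insertion",
                  "frameshift_deletion", "premature_stop_codon",
                  "splice_donor_mutation", "splice_acceptor_mutation",
                  "exon_deletion")

lesion_record <- function(taxon, type, cds_position, length = NA_integer_,
                          detail = "", exon_index = NA_integer_) {
  data.frame(taxon = taxon, type = type, exon_index = exon_index,
             cds_position = as.integer(cds_position),
             length = as.integer(length), detail = detail,
             stringsAsFactors = FALSE)
}

empty_lesions <- function() {
  data.frame(taxon = character(0), type = character(0),
             exon_index = integer(0), cds_position = integer(0),
             length = integer(0), detail = character(0),
             stringsAsFactors = FALSE)
}

# query characters projected onto reference CDS coordinates (length = CDS nt)
query_on_ref <- function(aln, query) {
  cols <- which(!is.na(aln$column_map))
  q <- aln$mat[query, cols]
  q[order(aln$column_map[cols])]
}

#' Detect loss of the initiation codon
#'
#' Reports a lesion iff the query's codon aligned to reference positions 1-3
#' is fully resolved (no gap or missing symbol) and differs from ATG.
#' @param aln a `codon_alignment`
#' @param query taxon to scan
#' @return a lesion data.frame with 0 or 1 rows
#' @export
detect_start_loss <- function(aln, query) {
  q <- query_on_ref(aln, query)
  cod <- paste(q[1:3], collapse = "")
  if (!grepl("^[ACGT]{3}$", cod) || cod == "ATG") return(empty_lesions())
  lesion_record(query, "initiation_codon_mutation", 1L, 3L,
                paste0("ATG→", cod))
}

#' Detect frameshift insertions and deletions
#'
#' Deletions are maximal runs of query gaps over reference-mapped columns;
#' insertions are maximal runs of insertion columns (reference gaps) where the
#' query has bases. A run is reported iff its length mod 3 != 0. Whole-exon
#' deletions are reported as `exon_deletion` (one record per fully deleted
#' exon) rather than frameshifts; residual deleted positions of a run outside
#' fully deleted exons still count toward a frameshift call.
#' @param aln a `codon_alignment`
#' @param query taxon to scan
#' @param gs optional `gene_structure` for exon annotation / exon-deletion calls
#' @return lesion data.frame
#' @export
detect_frameshift_indels <- function(aln, query, gs = NULL) {
  out <- list()
  q <- query_on_ref(aln, query)

  # deletions: runs of '-' in reference coordinates
  r <- rle(q == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    run_start <- starts[i]; run_len <- r$lengths[i]
    run_end <- ends[i]
    resid_len <- run_len
    if (!is.null(gs)) {
      ex <- gs$exons
      full <- which(ex$cds_start >= run_start & ex$cds_end <= run_end)
      for (e in full) {
        out[[length(out) + 1L]] <- lesion_record(
          query, "exon_deletion", ex$cds_start[e],
          ex$cds_end[e] - ex$cds_start[e] + 1L,
          paste0("exon ", e, " deleted"), e)
        resid_len <- resid_len - (ex$cds_end[e] - ex$cds_start[e] + 1L)
      }
    }
    if (resid_len > 0L && resid_len %% 3L != 0L) {
      out[[length(out) + 1L]] <- lesion_record(
        query, "frameshift_deletion", run_start, run_len,
        paste0("-", run_len, " del"))
    }
  }

  # insertions: runs of insertion columns with query bases
  ins_cols <- which(is.na(aln$column_map))
  if (length(ins_cols)) {
    breaks <- c(0L, which(diff(ins_cols) > 1L), length(ins_cols))
    for (b in seq_len(length(breaks) - 1L)) {
      run <- ins_cols[(breaks[b] + 1L):breaks[b + 1L]]
      ins_len <- sum(aln$mat[query, run] != "-")
      if (ins_len > 0L && ins_len %% 3L != 0L) {
        prev_mapped <- which(!is.na(aln$column_map[seq_len(min(run) - 1L)]))
        pos <- if (length(prev_mapped)) {
          aln$column_map[max(prev_mapped)]
        } else 1L
        out[[length(out) + 1L]] <- lesion_record(
          query, "frameshift_insertion", pos, ins_len,
          paste0("+", ins_len, " ins"))
      }
    }
  }
  finalize_lesions(out, gs)
}

#' Detect premature stop codons in the query's local reading frame
#'
#' The query's ungapped sequence is translated from its first base: the frame
#' starts in the reference frame and shifts with every indel, which is the
#' biologically meaningful frame downstream of a frameshift. Fully resolved
#' TAA/TAG/TGA codons lying strictly before the reference's terminal stop are
#' reported; codons containing gaps or missing symbols are skipped.
#' @param aln a `codon_alignment`
#' @param query taxon to scan
#' @param gs optional `gene_structure` for exon annotation
#' @return lesion data.frame
#' @export
detect_premature_stops <- function(aln, query, gs = NULL) {
  row <- aln$mat[query, ]
  keep <- row != "-"
  bases <- row[keep]
  # reference coordinate of each query base (insertion bases inherit the
  # coordinate of the nearest mapped column to their left)
  refpos <- aln$column_map[keep]
  if (length(refpos)) {
    for (i in seq_along(refpos)) {
      if (is.na(refpos[i])) refpos[i] <- if (i > 1L) refpos[i - 1L] else 1L
    }
  }
  L <- cds_length(aln)
  term_start <- L - 2L
  out <- list()
  ncod <- length(bases) %/% 3L
  for (k in seq_len(ncod)) {
    idx <- (3L * (k - 1L) + 1L):(3L * k)
    cod <- paste(bases[idx], collapse = "")
    if (!grepl("^[ACGT]{3}$", cod) || !(cod %in% STOP_CODONS)) next
    pos <- refpos[idx[1]]
    if (pos >= term_start) next
    out[[length(out) + 1L]] <- lesion_record(
      query, "premature_stop_codon", pos, 3L,
      paste0(cod, " at codon ", k))
  }
  finalize_lesions(out, gs)
}

#' Detect splice-site (GT/AG) mutations from the gene-structure table
#'
#' Canonical introns start GT (donor) and end AG (acceptor). A resolved
#' dinucleotide differing from the canon is a lesion; a missing or
#' partially missing dinucleotide produces no call.
#' @param gs a `gene_structure` with splice dinucleotides
#' @param query taxon to scan
#' @return lesion data.frame
#' @export
detect_splice_lesions <- function(gs, query) {
  sp <- gs$splice[gs$splice$taxon == query, , drop = FALSE]
  if (!nrow(sp)) {
    message("no splice dinucleotides for '", query, "'; splice scan skipped")
    return(empty_lesions())
  }
  out <- list()
  resolved <- function(x) !is.na(x) & grepl("^[ACGT]{2}$", x)
  for (i in seq_len(nrow(sp))) {
    intr <- sp$intron_index[i]
    if (resolved(sp$donor[i]) && sp$donor[i] != "GT") {
      out[[length(out) + 1L]] <- lesion_record(
        query, "splice_donor_mutation",
        gs$exons$cds_end[intr], 2L,
        paste0("GT→", sp$donor[i], " after exon ", intr), intr)
    }
    if (resolved(sp$acceptor[i]) && sp$acceptor[i] != "AG") {
      out[[length(out) + 1L]] <- lesion_record(
        query, "splice_acceptor_mutation",
        gs$exons$cds_start[intr + 1L], 2L,
        paste0("AG→", sp$acceptor[i], " before exon ", intr + 1L),
        intr + 1L)
    }
  }
  finalize_lesions(out, gs)
}

finalize_lesions <- function(out, gs = NULL) {
  if (!length(out)) return(empty_lesions())
  df <- do.call(rbind, out)
  if (!is.null(gs)) {
    fill <- is.na(df$exon_index)
    df$exon_index[fill] <- exon_of(gs, df$cds_position[fill])
  }
  df <- df[order(df$cds_position, df$type), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Scan one taxon for all classes of inactivating mutation
#'
#' Union of the start-loss, frameshift-indel, premature-stop and splice-site
#' detectors, sorted by CDS position. Missing data never produces a call.
#' @param aln a `codon_alignment`
#' @param gs a `gene_structure` matching the reference CDS (its coverage may
#'   include or exclude the terminal stop codon)
#' @param query taxon to scan (errors if absent)
#' @return data.frame of class `lesion_set`
#' @export
detect_lesions <- function(aln, gs, query) {
  if (!query %in% taxa(aln)) stop("query '", query, "' absent from alignment")
  glen <- max(gs$exons$cds_end)
  if (!glen %in% c(cds_length(aln), cds_length(aln) - 3L))
    stop("gene structure covers 1..", glen, " but reference CDS length is ",
         cds_length(aln))
  df <- rbind(
    detect_start_loss(aln, query),
    detect_frameshift_indels(aln, query, gs),
    detect_premature_stops(aln, query, gs),
    suppressMessages(detect_splice_lesions(gs, query))
  )
  df <- finalize_lesions(split(df, seq_len(nrow(df))), gs)
  class(df) <- c("lesion_set", class(df))
  df
}

#' Scan every non-reference taxon
#' @inheritParams detect_lesions
#' @param queries taxa to scan; defaults to all but the reference
#' @return combined `lesion_set`
#' @export
scan_alignment <- function(aln, gs, queries = setdiff(taxa(aln), aln$reference)) {
  df <- do.call(rbind, lapply(queries, function(q) detect_lesions(aln, gs, q)))
  if (is.null(df)) df <- empty_lesions()
  rownames(df) <- NULL
  class(df) <- c("lesion_set", class(df))
  df
}

#' @export
print.lesion_set <- function(x, ...) {
  cat("Inactivating-mutation records:", nrow(x), "in",
      length(unique(x$taxon)), "taxa\n")
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Place shared lesions on the species tree (Dollo parsimony)
#'
#' Lesions with identical key (type, cds_position, length, detail) carried by
#' exactly the leaf set of some clade are assigned to that clade's stem
#' branch (single origin). A lesion in one taxon maps to its terminal branch.
#' Identical lesions whose carriers are not a clade are flagged homoplastic.
#' @param records a `lesion_set` covering >= 1 taxa
#' @param tree a `phylo`; every carrier must be a tip
#' @return data.frame with key columns, `carriers`, `branch_node` (node id at
#'   the lower end of the assigned branch, NA when homoplastic) and `status`
#'   ("clade", "terminal" or "homoplastic")
#' @export
map_shared_lesions <- function(records, tree) {
  if (!nrow(records)) {
    return(data.frame(type = character(0), cds_position = integer(0),
                      length = integer(0), detail = character(0),
                      carriers = character(0), branch_node = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  missing_tips <- setdiff(unique(records$taxon), tree$tip.label)
  if (length(missing_tips))
    stop("taxa with lesions absent from tree: ",
         paste(missing_tips, collapse = ", "))
  key <- paste(records$type, records$cds_position, records$length,
               records$detail, sep = "\r")
  ntip <- length(tree$tip.label)
  groups <- split(records$taxon, key)
  out <- lapply(names(groups), function(k) {
    carriers <- sort(unique(groups[[k]]))
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    node <- NA_integer_; status <- "homoplastic"
    if (length(carriers) == 1L) {
      node <- match(carriers, tree$tip.label)
      status <- "terminal"
    } else {
      mrca <- ape::getMRCA(tree, carriers)
      below <- sort(clade_tips(tree, mrca))
      if (identical(below, carriers)) {
        node <- mrca
        status <- "clade"
      }
    }
    data.frame(type = parts[1], cds_position = as.integer(parts[2]),
               length = as.integer(parts[3]), detail = parts[4],
               carriers = paste(carriers, collapse = ","),
               branch_node = node, status = status, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$cds_position, res$type), , drop = FALSE]
  rownames(res) <- NULL
  res
}
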