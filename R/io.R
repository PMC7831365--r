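# Readers and writers for the external formats: FASTA alignment, Newick tree
# with PAML-style branch labels, TSV gene structure, YAML/JSON configs.

#' Read a codon-aware alignment from FASTA
#'
#' @param path FASTA file with >= 2 aligned records of equal length
#' @param reference_taxon name of the intact reference record
#' @param check_orf see [codon_alignment()]
#' @return a `codon_alignment`
#' @export
read_codon_alignment <- function(path, reference_taxon, check_orf = TRUE) {
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) < 2L) stop("FASTA must contain at least 2 records")
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  names(seqs) <- names(recs)
  codon_alignment(seqs, reference_taxon, check_orf = check_orf)
}

#' Write a codon alignment to FASTA
#' @param aln a `codon_alignment`
#' @param path output file
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = rownames(aln$mat),
                      file.out = path, nbchar = 60)
  invisible(path)
}

# --- trees ------------------------------------------------------------------

#' Read a species tree with PAML-style branch labels
#'
#' Branch categories are encoded as `#tag` suffixes on tip or internal node
#' labels (e.g. `((A,B)#1,C);` tags the branch above the (A,B) clade).
#' Untagged branches get category `"background"`. The result is an
#' [ape::read.tree()] `phylo` object with an extra `edge_category` character
#' vector aligned with `tree$edge` rows.
#'
#' @param path Newick file
#' @return a `phylo` with attribute-like element `edge_category`
#' @export
read_branch_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_branch_tree(txt)
}

#' Parse a Newick string with branch labels (see [read_branch_tree()])
#' @param txt Newick text
#' @export
parse_branch_tree <- function(txt) {
  # normalize "name #1" and "):0.1 #1" forms to label-attached tags
  txt <- gsub("[ \t]*#", "#", txt)
  txt <- gsub(":([0-9.eE+-]+)#([A-Za-z0-9_.]+)", "#\\2:\\1", txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("unparseable Newick")
  strip <- function(labs) {
    tag <- rep(NA_character_, length(labs))
    has <- grepl("#", labs)
    tag[has] <- sub("^.*#", "", labs[has])
    list(label = sub("#.*$", "", labs), tag = tag)
  }
  tips <- strip(tree$tip.label)
  tree$tip.label <- tips$label
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in tree")
  node_tag <- rep(NA_character_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    nl <- strip(tree$node.label)
    tree$node.label <- nl$label
    node_tag <- nl$tag
  }
  ntip <- length(tree$tip.label)
  cat_of_node <- c(tips$tag, node_tag)  # indexed by node id
  edge_category <- cat_of_node[tree$edge[, 2]]
  edge_category[is.na(edge_category)] <- "background"
  tree$edge_category <- edge_category
  tree
}

#' Serialize a labelled tree back to Newick with `#tag` labels
#' @param tree a `phylo` with `edge_category`
#' @param path optional output file; if `NULL` the Newick string is returned
#' @export
write_branch_tree <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  tr <- tree
  cat_of_node <- rep(NA_character_, ntip + tr$Nnode)
  cat_of_node[tr$edge[, 2]] <- tr$edge_category
  tagged <- !is.na(cat_of_node) & cat_of_node != "background"
  tip_ids <- seq_len(ntip)
  tr$tip.label <- ifelse(tagged[tip_ids],
                         paste0(tr$tip.label, "#", cat_of_node[tip_ids]),
                         tr$tip.label)
  node_ids <- ntip + seq_len(tr$Nnode)
  node_lab <- if (is.null(tr$node.label)) rep("", tr$Nnode) else tr$node.label
  node_lab[is.na(node_lab)] <- ""
  node_lab <- ifelse(tagged[node_ids],
                     paste0(node_lab, "#", cat_of_node[node_ids]), node_lab)
  tr$node.label <- node_lab
  tr$edge_category <- NULL
  txt <- ape::write.tree(tr)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Set branch categories on a tree by clade or tip
#'
#' Tags the terminal branch of each taxon in `tips`, and/or the stem branch of
#' the most recent common ancestor of each character vector in `clades`.
#' @param tree a `phylo` (with or without `edge_category`)
#' @param tag category label to assign
#' @param tips taxa whose terminal branches get the tag
#' @param clades list of character vectors; each clade's stem branch gets the
#'   tag; a clade entry of length >= 2 whose MRCA subtends exactly those tips
#'   may also tag all internal branches with `include_descendants = TRUE`
#' @param include_descendants also tag every branch inside each clade
#' @export
tag_branches <- function(tree, tag, tips = character(0), clades = list(),
                         include_descendants = FALSE) {
  if (is.null(tree$edge_category))
    tree$edge_category <- rep("background", nrow(tree$edge))
  ntip <- length(tree$tip.label)
  for (tp in tips) {
    id <- match(tp, tree$tip.label)
    if (is.na(id)) stop("tip '", tp, "' not in tree")
    tree$edge_category[tree$edge[, 2] == id] <- tag
  }
  for (cl in clades) {
    ids <- match(cl, tree$tip.label)
    if (anyNA(ids)) stop("clade tips missing from tree")
    mrca <- if (length(ids) == 1L) ids else ape::getMRCA(tree, ids)
    tree$edge_category[tree$edge[, 2] == mrca] <- tag
    if (include_descendants && length(ids) > 1L) {
      desc <- descendant_nodes(tree, mrca)
      tree$edge_category[tree$edge[, 2] %in% desc] <- tag
    }
  }
  tree
}

# all node ids strictly below `node`
descendant_nodes <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- tree$edge[tree$edge[, 1] %in% stack, 2]
  }
  out
}

# leaf labels under a node
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ids <- descendant_nodes(tree, node)
  tree$tip.label[ids[ids <= ntip]]
}

# --- gene structure ---------------------------------------------------------

#' Construct a gene structure (exon table + splice dinucleotides)
#'
#' @param exons data.frame with `exon_index`, `cds_start`, `cds_end`
#'   (1-based inclusive reference CDS coordinates)
#' @param splice data.frame with `taxon`, `intron_index`, `donor`, `acceptor`
#'   (2-mers, or NA when unknown); intron i separates exons i and i+1
#' @param cds_length optional expected CDS length to validate coverage against
#' @return object of class `gene_structure`
#' @export
gene_structure <- function(exons, splice = NULL, cds_length = NULL) {
  exons <- exons[order(exons$exon_index), , drop = FALSE]
  if (!all(exons$exon_index == seq_len(nrow(exons))))
    stop("exon_index must be 1..n_exons")
  if (any(exons$cds_end < exons$cds_start)) stop("exon with cds_end < cds_start")
  if (exons$cds_start[1] != 1L) stop("non-contiguous exons: first exon must start at 1")
  if (nrow(exons) > 1L) {
    gaps <- exons$cds_start[-1] - exons$cds_end[-nrow(exons)]
    if (any(gaps != 1L)) stop("non-contiguous exons")
  }
  if (!is.null(cds_length) && exons$cds_end[nrow(exons)] != cds_length)
    stop("exons cover 1..", exons$cds_end[nrow(exons)],
         " but CDS length is ", cds_length)
  if (is.null(splice)) {
    splice <- data.frame(taxon = character(0), intron_index = integer(0),
                         donor = character(0), acceptor = character(0),
                         stringsAsFactors = FALSE)
  } else {
    n_intron <- nrow(exons) - 1L
    if (any(splice$intron_index < 1L | splice$intron_index > n_intron))
      stop("intron_index out of range (intron count = exon count - 1)")
  }
  structure(list(exons = exons, splice = splice), class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat("Gene structure:", nrow(x$exons), "exons covering 1..",
      max(x$exons$cds_end), "nt;", length(unique(x$splice$taxon)),
      "taxa with splice dinucleotides\n")
  invisible(x)
}

#' Read a gene-structure TSV
#'
#' Expected columns: `taxon`, `exon_index`, `cds_start`, `cds_end`, `donor`,
#' `acceptor`. `donor` is the first two intronic bases following the exon
#' (NA/empty for the last exon); `acceptor` the last two intronic bases
#' preceding it (NA/empty for exon 1). Exon coordinates must agree across
#' taxa (they are reference CDS coordinates).
#' @param path TSV file
#' @param cds_length optional expected CDS length
#' @return a `gene_structure`
#' @export
read_gene_structure <- function(path, cds_length = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "exon_index", "cds_start", "cds_end", "donor", "acceptor")
  if (!all(need %in% names(df)))
    stop("gene structure TSV needs columns: ", paste(need, collapse = ", "))
  ex <- unique(df[, c("exon_index", "cds_start", "cds_end")])
  if (anyDuplicated(ex$exon_index))
    stop("exon coordinates differ across taxa")
  # donor of exon i -> intron i; acceptor of exon i+1 -> intron i
  clean <- function(x) {
    x <- toupper(trimws(as.character(x)))
    x[x %in% c("", "NA", ".")] <- NA_character_
    x
  }
  df$donor <- clean(df$donor); df$acceptor <- clean(df$acceptor)
  sp_list <- lapply(split(df, df$taxon), function(d) {
    d <- d[order(d$exon_index), ]
    n <- nrow(d)
    if (n < 2L) return(NULL)
    data.frame(taxon = d$taxon[1], intron_index = seq_len(n - 1L),
               donor = d$donor[-n], acceptor = d$acceptor[-1],
               stringsAsFactors = FALSE)
  })
  splice <- do.call(rbind, sp_list)
  rownames(splice) <- NULL
  gene_structure(ex, splice, cds_length = cds_length)
}

#' Write a gene structure to TSV (inverse of [read_gene_structure()])
#' @param gs a `gene_structure`
#' @param path output file
#' @param taxa taxa to emit rows for; defaults to those in the splice table
#' @export
write_gene_structure <- function(gs, path, taxa = NULL) {
  if (is.null(taxa)) taxa <- unique(gs$splice$taxon)
  if (!length(taxa)) taxa <- "reference"
  rows <- lapply(taxa, function(tx) {
    sp <- gs$splice[gs$splice$taxon == tx, ]
    n <- nrow(gs$exons)
    donor <- acceptor <- rep(NA_character_, n)
    if (nrow(sp)) {
      donor[sp$intron_index] <- sp$donor
      acceptor[sp$intron_index + 1L] <- sp$acceptor
    }
    data.frame(taxon = tx, gs$exons, donor = donor, acceptor = acceptor,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exon containing each CDS position
#' @param gs a `gene_structure`
#' @param pos integer vector of 1-based CDS positions
#' @return integer vector of exon indices (NA outside the CDS)
#' @export
exon_of <- function(gs, pos) {
  idx <- findInterval(pos, gs$exons$cds_start)
  idx[pos < 1L | pos > max(gs$exons$cds_end)] <- NA_integer_
  idx
}

#' Read a run/simulation config from YAML or JSON
#' @param path file ending in .yaml/.yml or .json
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be YAML or JSON")
}
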