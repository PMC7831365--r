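# Synthetic-data generator: codon alignments evolved along a time-calibrated
# tree under branch-specific omega, with known switch times from purifying
# selection to neutrality and planted ORF-disrupting lesions. Ground truth is
# carried alongside so the scanner, the model fits and the dating equations
# can all be validated end to end.

#' Simulation configuration
#'
#' @param tree ultrametric `phylo` with branch lengths in Ma
#' @param n_codons number of codons to simulate (including a forced ATG first
#'   codon and a forced terminal stop codon)
#' @param clock_rate expected substitutions per codon per Ma of the *neutral*
#'   (omega = 1) process; a segment under selection strength omega runs
#'   slower by the factor (B + omega*A)/(B + A) (synonymous flux B,
#'   nonsynonymous flux A), i.e. the synonymous clock is constant in time
#' @param kappa transition/transversion ratio
#' @param omega_background dN/dS while the gene is functional
#' @param pi `"uniform"` or a 61-vector of codon frequencies
#' @param switches list of switches to neutrality; each is
#'   `list(taxa = <tips>, age = <Ma>, omega = 1)`: the gene becomes neutral at
#'   `age` on the stem branch of `taxa`'s MRCA (or the terminal branch for one
#'   tip) and stays neutral in all descendants
#' @param lesions list of lesion specs for [inject_lesions()]
#' @param reference intact reference taxon (default: first tip); must not
#'   carry switches or lesions
#' @param n_exons exon count for the default gene structure
#' @param seed mandatory integer seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(tree, n_codons = 427, clock_rate = 0.005, kappa = 2,
                       omega_background = 0.116, pi = "uniform",
                       switches = list(), lesions = list(),
                       reference = tree$tip.label[1], n_exons = 11,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_codons < 10) stop("n_codons must be >= 10")
  if (is.character(pi) && pi == "uniform")
    pi <- stats::setNames(rep(1 / 61, 61), sense_codons())
  stopifnot(length(pi) == 61)
  structure(list(tree = tree, n_codons = n_codons, clock_rate = clock_rate,
                 kappa = kappa, omega_background = omega_background, pi = pi,
                 switches = switches, lesions = lesions,
                 reference = reference, n_exons = n_exons, seed = seed),
            class = "sim_config")
}

# Relative total substitution rate of the omega-process when the clock is
# calibrated to the neutral (omega = 1) rate. With synonymous flux B and
# nonsynonymous flux A (at omega = 1), a gene under selection strength omega
# substitutes at (B + omega*A)/(B + A) of the neutral rate: the synonymous
# clock ticks at constant speed while the nonsynonymous rate scales with
# omega. This is what makes the branch-average dN/dS a time-linear mixture
# of the segment omegas, as the dating equations assume.
rate_factor <- function(omega, kappa, pi) {
  pt <- codon_pair_types()
  pp <- as.numeric(pi) %o% as.numeric(pi)
  syn <- sum(pp[pt == 1L]) + kappa * sum(pp[pt == 2L])
  nonsyn <- sum(pp[pt == 3L]) + kappa * sum(pp[pt == 4L])
  (syn + omega * nonsyn) / (syn + nonsyn)
}

# node ages (Ma before present) assuming an ultrametric tree
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

# draw child states from parent states through P, grouped by parent state
sample_through <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(nrow(P), length(idx), replace = TRUE,
                           prob = P[s, ])
  }
  out
}

#' Simulate codon states along a tree with branch lengths in subs/codon
#'
#' Root codons are drawn from `pi`; each branch applies `exp(Q_omega * t)`
#' where omega follows the branch's `edge_category` (looked up in `omegas`).
#' Used for parametric bootstraps of a fit; the time-calibrated generator
#' with switches is [simulate_alignment()].
#' @param tree `phylo` with `edge.length` (subs/codon) and optionally
#'   `edge_category`
#' @param kappa,pi model parameters
#' @param omegas named vector, omega per category
#' @param n_codons alignment length in codons
#' @return `codon_alignment` (reference = first tip, no ORF enforcement)
#' @export
simulate_codon_tree <- function(tree, kappa, omegas, pi, n_codons) {
  cat_lab <- tree$edge_category
  if (is.null(cat_lab)) cat_lab <- rep("background", nrow(tree$edge))
  segs <- lapply(seq_len(nrow(tree$edge)), function(e)
    list(list(omega = unname(omegas[cat_lab[e]]), t = tree$edge.length[e])))
  states <- sim_states(tree, segs, kappa, pi, n_codons)
  mat <- states_to_char(states, tree)
  codon_alignment(mat, reference = tree$tip.label[1], check_orf = FALSE)
}

# simulate tip states given per-edge segment lists (each segment: omega, t)
sim_states <- function(tree, edge_segments, kappa, pi, n_codons) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- matrix(NA_integer_, nnode, n_codons)
  states[root, ] <- sample.int(61, n_codons, replace = TRUE,
                               prob = as.numeric(pi))
  pair_type <- codon_pair_types()
  pcache <- new.env(parent = emptyenv())
  getP <- function(omega, t) {
    key <- paste(signif(omega, 12), signif(t, 12))
    P <- pcache[[key]]
    if (is.null(P)) {
      P <- codon_pmat_cpp(kappa, omega, as.numeric(pi), pair_type, t)
      # guard row sums for sampling
      P <- P / rowSums(P)
      pcache[[key]] <- P
    }
    P
  }
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  for (e in ord) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    st <- states[parent, ]
    for (seg in edge_segments[[e]]) {
      if (seg$t > 0) st <- sample_through(st, getP(seg$omega, seg$t))
    }
    states[child, ] <- st
  }
  states
}

states_to_char <- function(states, tree) {
  ntip <- length(tree$tip.label)
  sc <- sense_codons()
  mat <- matrix("", ntip, ncol(states) * 3L)
  for (i in seq_len(ntip)) {
    mat[i, ] <- unlist(strsplit(sc[states[i, ]], ""), use.names = FALSE)
  }
  rownames(mat) <- tree$tip.label
  mat
}

#' Simulate a codon alignment with a known inactivation history
#'
#' Evolution proceeds in Ma along the config's time tree with a constant
#' *neutral* clock of `clock_rate` substitutions/codon/Ma: a segment under
#' selection strength omega substitutes at the reduced total rate
#' `clock_rate * (B + omega*A)/(B + A)`, so the synonymous rate is the same
#' on functional and neutral segments and a mixed branch's average dN/dS is
#' the time-linear mixture of its segment omegas. On switched lineages the
#' process changes to the post-switch omega at the stated age and stays
#' there in all descendants. The first codon is set to ATG and a
#' terminal TAA stop is enforced on every row so the reference has an intact
#' ORF. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()]
#' @return list with `alignment` (a `codon_alignment`), `gene_structure`,
#'   and `truth` (class `sim_truth`: per-edge omega segment history, switch
#'   truth incl. true Ts/Tn on the switched branch, lesion truth — empty
#'   until [inject_lesions()] — and the fit-ready tree in subs/codon)
#' @export
simulate_alignment <- function(cfg) {
  set.seed(cfg$seed)
  tree <- cfg$tree
  ntip <- length(tree$tip.label)
  ages <- node_ages(tree)
  nedge <- nrow(tree$edge)

  # which edges are (partly) post-switch, per switch
  seg_list <- vector("list", nedge)
  omega_edge_info <- vector("list", nedge)
  switch_truth <- list()
  affected <- rep(FALSE, nedge)
  switch_of_edge <- rep(NA_integer_, nedge)
  for (si in seq_along(cfg$switches)) {
    sw <- cfg$switches[[si]]
    ids <- match(sw$taxa, tree$tip.label)
    if (anyNA(ids)) stop("switch taxa missing from tree")
    node <- if (length(ids) == 1L) ids else ape::getMRCA(tree, ids)
    stem_edge <- which(tree$edge[, 2] == node)
    if (!length(stem_edge)) stop("switch clade has no stem branch (root)")
    p_age <- ages[tree$edge[stem_edge, 1]]
    c_age <- ages[node]
    if (sw$age > p_age || sw$age < 0)
      stop("switch age ", sw$age, " outside branch interval [", c_age, ", ",
           p_age, "]")
    sub <- c(stem_edge, which(tree$edge[, 2] %in% descendant_nodes(tree, node)))
    if (any(affected[sub] )) stop("overlapping switches")
    affected[sub] <- TRUE
    switch_of_edge[sub] <- si
    switch_truth[[si]] <- list(
      taxa = sw$taxa, node = node, age = sw$age,
      omega_post = sw$omega %||% 1,
      T_branch = p_age - c_age,
      Ts = max(0, p_age - max(sw$age, c_age)),
      Tn = max(0, min(sw$age, p_age) - c_age),
      split_age = p_age, branch_end_age = c_age)
  }

  for (e in seq_len(nedge)) {
    p_age <- ages[tree$edge[e, 1]]; c_age <- ages[tree$edge[e, 2]]
    if (!affected[e]) {
      segs <- list(list(omega = cfg$omega_background, t = p_age - c_age))
    } else {
      sw <- cfg$switches[[switch_of_edge[e]]]
      om_post <- sw$omega %||% 1
      if (sw$age >= p_age) {          # fully post-switch
        segs <- list(list(omega = om_post, t = p_age - c_age))
      } else if (sw$age <= c_age) {   # fully pre-switch (older part of clade)
        segs <- list(list(omega = cfg$omega_background, t = p_age - c_age))
      } else {
        segs <- list(list(omega = cfg$omega_background, t = p_age - sw$age),
                     list(omega = om_post, t = sw$age - c_age))
      }
    }
    # durations -> expected substitutions/codon; the clock is neutral, so a
    # functional segment runs slower by rate_factor(omega)
    seg_list[[e]] <- lapply(segs, function(s)
      list(omega = s$omega,
           t = s$t * cfg$clock_rate * rate_factor(s$omega, cfg$kappa, cfg$pi)))
    omega_edge_info[[e]] <- data.frame(
      edge = e, parent_age = p_age, child_age = c_age,
      omega = vapply(segs, `[[`, numeric(1), "omega"),
      duration_Ma = vapply(segs, `[[`, numeric(1), "t"))
  }

  states <- sim_states(tree, seg_list, cfg$kappa, cfg$pi, cfg$n_codons)
  mat <- states_to_char(states, tree)
  # enforce an intact ORF frame: ATG start, TAA terminal stop
  mat[, 1:3] <- matrix(rep(c("A", "T", "G"), each = ntip), ntip)
  mat[, (cfg$n_codons * 3 - 2):(cfg$n_codons * 3)] <-
    matrix(rep(c("T", "A", "A"), each = ntip), ntip)

  aln <- codon_alignment(mat, reference = cfg$reference, check_orf = FALSE)
  gs <- default_gene_structure(cfg$n_codons * 3L, cfg$n_exons,
                               taxa = tree$tip.label)

  # realized codon differences per edge (observable substitution proxy)
  ord <- seq_len(nedge)
  diffs <- vapply(ord, function(e)
    sum(states[tree$edge[e, 1], ] != states[tree$edge[e, 2], ]), integer(1))

  fit_tree <- tree
  # per-edge expected substitutions/codon (sum over the edge's omega segments)
  fit_tree$edge.length <- vapply(seg_list, function(ss)
    sum(vapply(ss, `[[`, numeric(1), "t")), numeric(1))
  fit_tree$edge_category <- rep("background", nedge)

  truth <- structure(list(
    omega_history = do.call(rbind, omega_edge_info),
    switches = switch_truth,
    lesions = empty_lesions(),
    realized_codon_diffs = diffs,
    tree_subs = fit_tree,
    config = cfg
  ), class = "sim_truth")

  out <- list(alignment = aln, gene_structure = gs, truth = truth)
  if (length(cfg$lesions)) out <- inject_lesions(out, cfg$lesions)
  out
}

#' Evenly split gene structure with canonical GT/AG splice sites
#' @param cds_len CDS length in nt
#' @param n_exons number of exons
#' @param taxa taxa to populate the splice table for
#' @export
default_gene_structure <- function(cds_len, n_exons = 11, taxa = character(0)) {
  cuts <- round(seq(0, cds_len, length.out = n_exons + 1))
  exons <- data.frame(exon_index = seq_len(n_exons),
                      cds_start = cuts[-(n_exons + 1)] + 1L,
                      cds_end = cuts[-1])
  splice <- NULL
  if (length(taxa) && n_exons > 1) {
    splice <- expand.grid(taxon = taxa, intron_index = seq_len(n_exons - 1L),
                          stringsAsFactors = FALSE)
    splice$donor <- "GT"; splice$acceptor <- "AG"
    splice <- splice[order(splice$taxon, splice$intron_index), ]
  }
  gene_structure(exons, splice, cds_length = cds_len)
}

# independent local-frame stop walk used for truth bookkeeping at injection
# time (fully resolved stops strictly before the reference terminal stop)
local_stops <- function(aln, taxon) {
  row <- aln$mat[taxon, ]
  keep <- row != "-"
  bases <- row[keep]
  refpos <- aln$column_map[keep]
  for (i in seq_along(refpos))
    if (is.na(refpos[i])) refpos[i] <- if (i > 1L) refpos[i - 1L] else 1L
  term_start <- cds_length(aln) - 2L
  out <- list()
  for (k in seq_len(length(bases) %/% 3L)) {
    idx <- (3L * (k - 1L) + 1L):(3L * k)
    cod <- paste(bases[idx], collapse = "")
    if (cod %in% STOP_CODONS && grepl("^[ACGT]{3}$", cod) &&
        refpos[idx[1]] < term_start) {
      out[[length(out) + 1L]] <- data.frame(
        codon_index = k, cds_position = refpos[idx[1]], codon = cod,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Plant ORF-disrupting lesions into a simulated bundle
#'
#' Each spec is a list with `type` (a [LESION_TYPES] value), `taxa`
#' (one taxon for a private lesion; several for a shared one, applied
#' identically so Dollo mapping can recover the clade), and type-specific
#' fields: `cds_position` + `length` for indels, `codon` for premature stops
#' (index in the reference frame), `intron_index` + optional `to` for splice
#' edits, `exon_index` for exon deletions, optional `to` for the start-loss
#' replacement codon (default GTG).
#'
#' All premature stops present in a taxon's final local reading frame are
#' recorded in the truth — including stops induced downstream of a planted
#' frameshift, flagged `induced = TRUE` — because they are genuine lesions of
#' the emitted sequence.
#' @param bundle output of [simulate_alignment()] (list with `alignment`,
#'   `gene_structure`, `truth`)
#' @param specs list of lesion specs
#' @return bundle with edited alignment/gene structure and updated truth
#' @export
inject_lesions <- function(bundle, specs) {
  aln <- bundle$alignment
  gs <- bundle$gene_structure
  truth_rows <- list()
  psc_taxa <- character(0)

  ref_cols <- function() {
    cols <- which(!is.na(aln$column_map))
    cols[order(aln$column_map[cols])]
  }

  for (sp in specs) {
    type <- sp$type
    taxa_t <- sp$taxa
    if (aln$reference %in% taxa_t) stop("cannot plant lesions on the reference")
    if (!all(taxa_t %in% taxa(aln))) stop("lesion target taxa not in alignment")
    for (tx in taxa_t) {
      rec <- switch(type,
        initiation_codon_mutation = {
          to <- toupper(sp$to %||% "GTG")
          cols <- ref_cols()[1:3]
          aln$mat[tx, cols] <- strsplit(to, "")[[1]]
          lesion_record(tx, type, 1L, 3L, paste0("ATG→", to))
        },
        frameshift_deletion = {
          p <- sp$cds_position; l <- sp$length
          if (l %% 3L == 0L) stop("frameshift deletion length must not be a multiple of 3")
          cols <- ref_cols()[p:(p + l - 1L)]
          aln$mat[tx, cols] <- "-"
          lesion_record(tx, type, p, l, paste0("-", l, " del"))
        },
        exon_deletion = {
          e <- sp$exon_index
          ex <- gs$exons[gs$exons$exon_index == e, ]
          cols <- ref_cols()[ex$cds_start:ex$cds_end]
          aln$mat[tx, cols] <- "-"
          lesion_record(tx, type, ex$cds_start,
                        ex$cds_end - ex$cds_start + 1L,
                        paste0("exon ", e, " deleted"), e)
        },
        frameshift_insertion = {
          p <- sp$cds_position; l <- sp$length
          if (l %% 3L == 0L) stop("frameshift insertion length must not be a multiple of 3")
          ins <- sp$bases %||% paste(rep("A", l), collapse = "")
          after_col <- ref_cols()[p]
          newmat <- matrix("-", nrow(aln$mat), l)
          rownames(newmat) <- rownames(aln$mat)
          newmat[tx, ] <- strsplit(ins, "")[[1]]
          aln$mat <- cbind(aln$mat[, 1:after_col, drop = FALSE], newmat,
                           aln$mat[, -(1:after_col), drop = FALSE])
          aln$column_map <- c(aln$column_map[1:after_col], rep(NA_integer_, l),
                              aln$column_map[-(1:after_col)])
          lesion_record(tx, type, p, l, paste0("+", l, " ins"))
        },
        premature_stop_codon = {
          k <- sp$codon
          to <- toupper(sp$to %||% "TGA")
          if (!to %in% STOP_CODONS) stop("'to' must be a stop codon")
          p <- 3L * (k - 1L) + 1L
          if (p >= cds_length(aln) - 2L) stop("stop codon must be premature")
          cols <- ref_cols()[p:(p + 2L)]
          aln$mat[tx, cols] <- strsplit(to, "")[[1]]
          psc_taxa <- c(psc_taxa, tx)
          NULL  # truth from the final local-frame walk below
        },
        splice_donor_mutation = {
          i <- sp$intron_index
          to <- toupper(sp$to %||% "AT")
          hit <- gs$splice$taxon == tx & gs$splice$intron_index == i
          if (!any(hit)) stop("no splice entry for ", tx, " intron ", i)
          gs$splice$donor[hit] <- to
          lesion_record(tx, type, gs$exons$cds_end[i], 2L,
                        paste0("GT→", to, " after exon ", i), i)
        },
        splice_acceptor_mutation = {
          i <- sp$intron_index
          to <- toupper(sp$to %||% "AC")
          hit <- gs$splice$taxon == tx & gs$splice$intron_index == i
          if (!any(hit)) stop("no splice entry for ", tx, " intron ", i)
          gs$splice$acceptor[hit] <- to
          lesion_record(tx, type, gs$exons$cds_start[i + 1L], 2L,
                        paste0("AG→", to, " before exon ", i + 1L), i + 1L)
        },
        stop("unknown lesion type '", type, "'"))
      if (!is.null(rec)) truth_rows[[length(truth_rows) + 1L]] <- rec
    }
  }

  # final-state premature-stop truth (planted and frameshift-induced)
  planted_ps <- unique(psc_taxa)
  edited <- unique(unlist(lapply(specs, `[[`, "taxa")))
  for (tx in edited) {
    st <- local_stops(aln, tx)
    if (is.null(st)) next
    for (r in seq_len(nrow(st))) {
      rec <- lesion_record(tx, "premature_stop_codon", st$cds_position[r], 3L,
                           paste0(st$codon[r], " at codon ", st$codon_index[r]))
      rec$induced <- !(tx %in% planted_ps &&
                         st$codon[r] %in% STOP_CODONS &&
                         any(vapply(specs, function(sp)
                           identical(sp$type, "premature_stop_codon") &&
                             tx %in% sp$taxa &&
                             3L * (sp$codon - 1L) + 1L == st$cds_position[r],
                           logical(1))))
      truth_rows[[length(truth_rows) + 1L]] <- rec
    }
  }

  df <- if (length(truth_rows)) {
    rows <- lapply(truth_rows, function(r) {
      if (is.null(r$induced)) r$induced <- FALSE
      r
    })
    do.call(rbind, rows)
  } else {
    cbind(empty_lesions(), induced = logical(0))
  }
  if (nrow(df)) {
    df$exon_index <- exon_of(gs, df$cds_position)
    df <- df[order(df$taxon, df$cds_position, df$type), ]
    rownames(df) <- NULL
  }

  bundle$alignment <- aln
  bundle$gene_structure <- gs
  bundle$truth$lesions <- df
  bundle
}

#' Write paired (inputs, truth) fixture bundles
#'
#' Emits a small bundle (the 14-taxon whale-like tree, 150 codons) and a
#' paper-scale bundle (116 taxa, 427 codons), each with FASTA alignment,
#' tagged Newick tree, gene-structure TSV, truth JSON and a manifest.
#' Byte-identical across runs for a given seed.
#' @param seed integer seed
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest list
#' @export
make_fixture_suite <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, bundles = list())

  write_bundle <- function(name, bundle) {
    bd <- file.path(dir, name)
    dir.create(bd, showWarnings = FALSE)
    write_codon_alignment(bundle$alignment, file.path(bd, "alignment.fasta"))
    write_branch_tree(bundle$truth$tree_subs, file.path(bd, "tree.nwk"))
    write_gene_structure(bundle$gene_structure, file.path(bd, "gene_structure.tsv"),
                         taxa = taxa(bundle$alignment))
    truth <- bundle$truth
    jsonlite::write_json(list(
      lesions = truth$lesions,
      switches = lapply(truth$switches, function(s)
        s[c("taxa", "age", "omega_post", "T_branch", "Ts", "Tn",
            "split_age", "branch_end_age")]),
      omega_history = truth$omega_history
    ), file.path(bd, "truth.json"), auto_unbox = TRUE, digits = NA)
    list(name = name, taxa = length(taxa(bundle$alignment)),
         codons = cds_length(bundle$alignment) / 3,
         lesion_count = nrow(truth$lesions),
         lesion_types = as.list(table(truth$lesions$type)))
  }

  small <- simulate_alignment(sim_config(
    tree = whale_like_tree(), n_codons = 150, seed = seed,
    reference = "Outgroup1",
    switches = list(list(taxa = paste0("Mysticete", 1:9), age = 30, omega = 1)),
    lesions = list(
      list(type = "initiation_codon_mutation", taxa = "Mysticete2"),
      list(type = "frameshift_deletion", taxa = paste0("Mysticete", 1:9),
           cds_position = 140, length = 1),
      list(type = "premature_stop_codon", taxa = "Mysticete5", codon = 20),
      list(type = "splice_donor_mutation", taxa = "Mysticete7",
           intron_index = 3))))
  manifest$bundles$small <- write_bundle("small", small)

  big <- simulate_alignment(sim_config(
    tree = random_ultrametric_tree(116, depth = 100, seed = seed + 1L),
    n_codons = 427, seed = seed + 2L))
  manifest$bundles$paper_scale <- write_bundle("paper_scale", big)

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' 14-taxon whale-like time tree (Ma): a 9-tip baleen-whale-like crown clade
#' (26 Ma), two toothed-whale-like tips, three outgroups; root at 55 Ma
#' @export
whale_like_tree <- function() {
  txt <- paste0(
    "((((((Mysticete1:8,Mysticete2:8):6,Mysticete3:14):6,",
    "((Mysticete4:10,Mysticete5:10):6,Mysticete6:16):4):6,",
    "(Mysticete7:18,(Mysticete8:12,Mysticete9:12):6):8):8,",
    "(Odontocete1:25,Odontocete2:25):9):21,",
    "(Outgroup1:40,(Outgroup2:30,Outgroup3:30):10):15);")
  ape::read.tree(text = txt)
}

#' 9-taxon crown clade of the whale-like tree (26 Ma deep), for calibration
#' harnesses
#' @export
mysticete_like_tree <- function() {
  txt <- paste0(
    "((((Mysticete1:8,Mysticete2:8):6,Mysticete3:14):6,",
    "((Mysticete4:10,Mysticete5:10):6,Mysticete6:16):4):6,",
    "(Mysticete7:18,(Mysticete8:12,Mysticete9:12):6):8);")
  ape::read.tree(text = txt)
}

#' Random ultrametric tree via a coalescent-style draw, rescaled to `depth` Ma
#' @param n number of tips
#' @param depth root age in Ma
#' @param seed integer seed
#' @export
random_ultrametric_tree <- function(n, depth = 100, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n, tip.label = sprintf("Taxon%03d", seq_len(n)))
  tr$edge.length <- tr$edge.length * depth / max(ape::node.depth.edgelength(tr))
  tr
}
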