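# hand-built alignments with known lesions; expected calls written out
# manually before running the scanner

toy_gs <- function(len, n_exons = 3, taxa = c("Q")) {
  default_gene_structure(len, n_exons, taxa = taxa)
}

test_that("an identical query yields no lesion calls", {
  ref <- paste0("ATG", strrep("AAA", 28), "TAA")   # 30 codons, 90 nt
  aln <- codon_alignment(c(Ref = ref, Q = ref), "Ref")
  out <- detect_lesions(aln, toy_gs(90), "Q")
  expect_equal(nrow(out), 0)
})

test_that("initiation-codon loss requires a resolved non-ATG codon", {
  ref <- paste0("ATG", strrep("AAA", 28), "TAA")
  gtg <- sub("^ATG", "GTG", ref)
  aln <- codon_alignment(c(Ref = ref, Q = gtg), "Ref")
  out <- detect_start_loss(aln, "Q")
  expect_equal(nrow(out), 1)
  expect_identical(out$type, "initiation_codon_mutation")
  expect_identical(out$cds_position, 1L)
  expect_identical(out$detail, "ATG→GTG")

  for (broken in c("NTG", "?TG", "-TG")) {
    q <- sub("^ATG", broken, ref)
    a <- codon_alignment(c(Ref = ref, Q = q), "Ref", check_orf = FALSE)
    expect_equal(nrow(detect_start_loss(a, "Q")), 0)
  }
})

test_that("frameshift deletions are called iff run length mod 3 != 0", {
  ref <- paste0("ATG", strrep("AAA", 28), "TAA")
  del <- function(from, len) {
    q <- strsplit(ref, "")[[1]]
    q[from:(from + len - 1)] <- "-"
    paste(q, collapse = "")
  }
  gs <- toy_gs(90)

  # in-frame 3-nt deletion: no frameshift
  a3 <- codon_alignment(c(Ref = ref, Q = del(10, 3)), "Ref", check_orf = FALSE)
  expect_equal(nrow(detect_frameshift_indels(a3, "Q", gs)), 0)

  # 1-nt deletion at CDS position 40
  a1 <- codon_alignment(c(Ref = ref, Q = del(40, 1)), "Ref", check_orf = FALSE)
  out <- detect_frameshift_indels(a1, "Q", gs)
  expect_equal(nrow(out), 1)
  expect_identical(out$type, "frameshift_deletion")
  expect_identical(out$cds_position, 40L)
  expect_identical(out$length, 1L)
  expect_identical(out$detail, "-1 del")

  # two separate runs stay two records
  q <- strsplit(ref, "")[[1]]; q[10] <- "-"; q[40:41] <- "-"
  a2 <- codon_alignment(c(Ref = ref, Q = paste(q, collapse = "")), "Ref",
                        check_orf = FALSE)
  out2 <- detect_frameshift_indels(a2, "Q", gs)
  expect_equal(nrow(out2), 2)
  expect_identical(out2$cds_position, c(10L, 40L))
  expect_identical(out2$length, c(1L, 2L))
})

test_that("frameshift insertions are read off insertion columns", {
  refc <- strsplit(paste0("ATG", strrep("CCA", 28), "TAA"), "")[[1]]
  # insert 2 bases after reference position 30
  ref_row <- c(refc[1:30], "-", "-", refc[31:90])
  q_row <- c(refc[1:30], "T", "T", refc[31:90])
  aln <- codon_alignment(c(Ref = paste(ref_row, collapse = ""),
                           Q = paste(q_row, collapse = "")), "Ref",
                         check_orf = FALSE)
  out <- detect_frameshift_indels(aln, "Q", toy_gs(90))
  expect_equal(nrow(out), 1)
  expect_identical(out$type, "frameshift_insertion")
  expect_identical(out$cds_position, 30L)
  expect_identical(out$length, 2L)
  expect_identical(out$detail, "+2 ins")

  # a 3-nt insertion is in-frame: no call
  ref_row3 <- c(refc[1:30], "-", "-", "-", refc[31:90])
  q_row3 <- c(refc[1:30], "T", "T", "T", refc[31:90])
  a3 <- codon_alignment(c(Ref = paste(ref_row3, collapse = ""),
                          Q = paste(q_row3, collapse = "")), "Ref",
                        check_orf = FALSE)
  expect_equal(nrow(detect_frameshift_indels(a3, "Q", toy_gs(90))), 0)
})

test_that("whole-exon deletions are classed as exon_deletion, not frameshift", {
  gs <- toy_gs(90)   # 3 exons: 1-30, 31-60, 61-90
  ref <- paste0("ATG", strrep("AAA", 28), "TAA")
  q <- strsplit(ref, "")[[1]]; q[31:60] <- "-"
  aln <- codon_alignment(c(Ref = ref, Q = paste(q, collapse = "")), "Ref",
                         check_orf = FALSE)
  out <- detect_frameshift_indels(aln, "Q", gs)
  expect_equal(nrow(out), 1)
  expect_identical(out$type, "exon_deletion")
  expect_identical(out$exon_index, 2L)
  expect_identical(out$cds_position, 31L)
  expect_identical(out$length, 30L)

  # exon deletion plus one extra deleted base: exon_deletion + frameshift
  q2 <- strsplit(ref, "")[[1]]; q2[31:61] <- "-"
  a2 <- codon_alignment(c(Ref = ref, Q = paste(q2, collapse = "")), "Ref",
                        check_orf = FALSE)
  out2 <- detect_frameshift_indels(a2, "Q", gs)
  expect_setequal(out2$type, c("exon_deletion", "frameshift_deletion"))
})

test_that("premature stops are read in the query's local frame", {
  ref <- paste0("ATG", strrep("CCA", 28), "TAA")
  aln0 <- codon_alignment(c(Ref = ref, Q = ref), "Ref")
  expect_equal(nrow(detect_premature_stops(aln0, "Q")), 0)

  # substitution stop in the reference frame: codon 10 CCA -> TGA
  q <- strsplit(ref, "")[[1]]; q[28:30] <- c("T", "G", "A")
  a1 <- codon_alignment(c(Ref = ref, Q = paste(q, collapse = "")), "Ref",
                        check_orf = FALSE)
  out <- detect_premature_stops(a1, "Q")
  expect_equal(nrow(out), 1)
  expect_identical(out$cds_position, 28L)
  expect_identical(out$detail, "TGA at codon 10")

  # frame shift creates a downstream stop invisible in the reference frame:
  # after deleting base 4, codon k reads bases (3k-2..3k)+1; CCA CCA...
  # becomes CAC CAC ... with a TAG planted to appear only post-shift.
  # Hand-derivation: query bases = ATG | CAC CAC ... ; plant T,A,G at
  # original positions 11:13 -> shifted codon 4 = positions 11..13 = TAG.
  q2 <- strsplit(ref, "")[[1]]
  q2[11:13] <- c("T", "A", "G")
  q2[4] <- "-"
  a2 <- codon_alignment(c(Ref = ref, Q = paste(q2, collapse = "")), "Ref",
                        check_orf = FALSE)
  out2 <- detect_premature_stops(a2, "Q")
  expect_true(any(out2$detail == "TAG at codon 4"))
  expect_true(11L %in% out2$cds_position)
  # the same codon triple is NOT a stop in the unshifted reference frame
  a3 <- codon_alignment(c(Ref = ref,
                          Q = paste(replace(strsplit(ref, "")[[1]], 11:13,
                                            c("T", "A", "G")), collapse = "")),
                        "Ref", check_orf = FALSE)
  expect_equal(nrow(detect_premature_stops(a3, "Q")), 0)

  # codons containing missing symbols are never called
  q4 <- strsplit(ref, "")[[1]]; q4[28:30] <- c("T", "G", "N")
  a4 <- codon_alignment(c(Ref = ref, Q = paste(q4, collapse = "")), "Ref",
                        check_orf = FALSE)
  expect_equal(nrow(detect_premature_stops(a4, "Q")), 0)
})

test_that("splice lesions come from non-canonical resolved dinucleotides", {
  ex <- data.frame(exon_index = 1:3, cds_start = c(1L, 31L, 61L),
                   cds_end = c(30L, 60L, 90L))
  sp <- data.frame(taxon = "Q", intron_index = 1:2,
                   donor = c("GT", "AT"), acceptor = c("AG", NA))
  gs <- gene_structure(ex, sp)
  out <- detect_splice_lesions(gs, "Q")
  expect_equal(nrow(out), 1)
  expect_identical(out$type, "splice_donor_mutation")
  expect_identical(out$cds_position, 60L)   # end of exon 2
  expect_identical(out$detail, "GT→AT after exon 2")

  sp2 <- sp; sp2$donor <- "GT"; sp2$acceptor <- c("CG", "AG")
  out2 <- detect_splice_lesions(gene_structure(ex, sp2), "Q")
  expect_identical(out2$type, "splice_acceptor_mutation")
  expect_identical(out2$cds_position, 31L)  # start of exon 2

  # all canonical -> clean
  sp3 <- sp; sp3$donor <- "GT"; sp3$acceptor <- "AG"
  expect_equal(nrow(detect_splice_lesions(gene_structure(ex, sp3), "Q")), 0)
})

test_that("a lesion-free simulated alignment scans clean (specificity)", {
  bundle <- simulate_alignment(sim_config(whale_like_tree(), n_codons = 60,
                                          seed = 31))
  out <- scan_alignment(bundle$alignment, bundle$gene_structure)
  expect_equal(nrow(out), 0)
})

test_that("exon annotation on scan output is consistent with exon_of", {
  bundle <- simulate_alignment(sim_config(
    whale_like_tree(), n_codons = 60, seed = 32, reference = "Outgroup1",
    lesions = list(
      list(type = "premature_stop_codon", taxa = "Mysticete1", codon = 12),
      list(type = "frameshift_deletion", taxa = "Odontocete1",
           cds_position = 100, length = 2))))
  out <- scan_alignment(bundle$alignment, bundle$gene_structure)
  expect_gt(nrow(out), 0)
  expect_identical(out$exon_index, exon_of(bundle$gene_structure,
                                           out$cds_position))
})

test_that("Dollo mapping separates clade, terminal and homoplastic lesions", {
  tree <- whale_like_tree()
  mys <- paste0("Mysticete", 1:9)
  rec <- data.frame(
    taxon = c(mys, "Odontocete1", "Mysticete1", "Outgroup3"),
    type = c(rep("frameshift_deletion", 9), rep("premature_stop_codon", 3)),
    exon_index = NA_integer_,
    cds_position = c(rep(140L, 9), 55L, 91L, 91L),
    length = c(rep(1L, 9), 3L, 3L, 3L),
    detail = c(rep("-1 del", 9), "TGA at codon 19",
               "TAA at codon 31", "TAA at codon 31"),
    stringsAsFactors = FALSE)
  mapped <- map_shared_lesions(rec, tree)
  expect_equal(nrow(mapped), 3)

  shared <- mapped[mapped$type == "frameshift_deletion", ]
  expect_identical(shared$status, "clade")
  expect_identical(shared$branch_node, ape::getMRCA(tree, mys))

  term <- mapped[mapped$cds_position == 55, ]
  expect_identical(term$status, "terminal")
  expect_identical(term$branch_node, match("Odontocete1", tree$tip.label))

  homo <- mapped[mapped$cds_position == 91, ]
  expect_identical(homo$status, "homoplastic")
  expect_true(is.na(homo$branch_node))

  bad <- rec[1, ]; bad$taxon <- "NotThere"
  expect_error(map_shared_lesions(bad, tree), regexp = "absent")
})

test_that("calls for a taxon do not depend on unrelated taxa being present", {
  bundle <- simulate_alignment(sim_config(
    whale_like_tree(), n_codons = 60, seed = 33,
    lesions = list(list(type = "frameshift_deletion", taxa = "Mysticete4",
                        cds_position = 70, length = 1))))
  full <- detect_lesions(bundle$alignment, bundle$gene_structure, "Mysticete4")
  slim <- drop_taxa(bundle$alignment,
                    setdiff(taxa(bundle$alignment),
                            c(bundle$alignment$reference, "Mysticete4")))
  sub <- detect_lesions(slim, bundle$gene_structure, "Mysticete4")
  expect_equal(as.data.frame(full), as.data.frame(sub))
})
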