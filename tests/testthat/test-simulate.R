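test_that("simulation is deterministic given the seed", {
  cfg <- function(seed) sim_config(whale_like_tree(), n_codons = 40,
                                   seed = seed)
  a <- simulate_alignment(cfg(5))
  b <- simulate_alignment(cfg(5))
  c <- simulate_alignment(cfg(6))
  expect_identical(a$alignment$mat, b$alignment$mat)
  expect_false(identical(a$alignment$mat, c$alignment$mat))
  expect_error(sim_config(whale_like_tree(), n_codons = 40), regexp = "seed")
})

test_that("a zero-rate clock copies the root sequence to every tip", {
  bundle <- simulate_alignment(sim_config(whale_like_tree(), n_codons = 30,
                                          clock_rate = 0, seed = 7))
  m <- bundle$alignment$mat
  for (i in 2:nrow(m)) expect_identical(unname(m[i, ]), unname(m[1, ]))
})

test_that("simulated alignments carry the enforced ORF frame", {
  bundle <- simulate_alignment(sim_config(whale_like_tree(), n_codons = 30,
                                          seed = 8))
  m <- bundle$alignment$mat
  expect_true(all(apply(m[, 1:3], 1, paste, collapse = "") == "ATG"))
  expect_true(all(apply(m[, 88:90], 1, paste, collapse = "") == "TAA"))
  gs <- bundle$gene_structure
  expect_equal(max(gs$exons$cds_end), 90)
  expect_true(all(gs$splice$donor == "GT"))
})

test_that("switch truth records the branch split into Ts and Tn", {
  mys <- paste0("Mysticete", 1:9)
  bundle <- simulate_alignment(sim_config(
    whale_like_tree(), n_codons = 30, seed = 9, reference = "Outgroup1",
    switches = list(list(taxa = mys, age = 30, omega = 1))))
  sw <- bundle$truth$switches[[1]]
  # stem branch of the 9-tip clade runs 34 -> 26 Ma; switch at 30 Ma
  expect_equal(sw$split_age, 34)
  expect_equal(sw$branch_end_age, 26)
  expect_equal(sw$T_branch, 8)
  expect_equal(sw$Ts, 4)
  expect_equal(sw$Tn, 4)
  # omega history: switched edges carry a neutral segment, background
  # edges never do
  oh <- bundle$truth$omega_history
  expect_true(any(oh$omega == 1))
  expect_true(all(oh$omega %in% c(0.116, 1)))
  # total duration bookkeeping matches the tree
  tot <- tapply(oh$duration_Ma, oh$edge, sum)
  expect_equal(as.numeric(tot),
               whale_like_tree()$edge.length[as.integer(names(tot))],
               tolerance = 1e-9)

  # a switch age outside the stem branch is rejected
  expect_error(simulate_alignment(sim_config(
    whale_like_tree(), n_codons = 30, seed = 9,
    switches = list(list(taxa = mys, age = 50, omega = 1)))),
    regexp = "outside")
})

test_that("realized dN/dS on a long two-taxon branch tracks omega (oracle)", {
  # kappa = 1, uniform frequencies: the Nei-Gojobori counter is unbiased.
  # 4000 codons keeps ~200 substitutions behind the ratio even at omega =
  # 0.2, where purifying selection slows the gene to ~0.4x the neutral clock
  tree <- ape::read.tree(text = "(A:15,B:15);")
  for (om in c(0.2, 1)) {
    bundle <- simulate_alignment(sim_config(
      tree, n_codons = 4000, clock_rate = 0.004, kappa = 1,
      omega_background = om, seed = 100 + round(om * 10)))
    r <- ng_dnds(row_string(bundle$alignment, "A"),
                 row_string(bundle$alignment, "B"))
    expect_gt(r, om * 0.75)
    expect_lt(r, om * 1.35)
  }
})

test_that("higher omega means more amino-acid change", {
  tree <- ape::read.tree(text = "(A:20,B:20);")
  sim <- function(om) simulate_alignment(sim_config(
    tree, n_codons = 800, clock_rate = 0.004, omega_background = om,
    seed = 55))
  low <- sim(0.116); high <- sim(1)
  aa_diff <- function(b) {
    cm <- codon_matrix(b$alignment)
    mean(translate_codons(cm["A", ]) != translate_codons(cm["B", ]))
  }
  expect_gt(aa_diff(high), aa_diff(low) * 2)
})

test_that("planted lesions appear in the truth and nowhere else", {
  mys <- paste0("Mysticete", 1:9)
  specs <- list(
    list(type = "initiation_codon_mutation", taxa = "Mysticete2"),
    list(type = "frameshift_deletion", taxa = "Odontocete1",
         cds_position = 50, length = 2),
    list(type = "frameshift_insertion", taxa = "Mysticete6",
         cds_position = 64, length = 1, bases = "G"),
    list(type = "premature_stop_codon", taxa = "Mysticete5", codon = 15),
    list(type = "splice_donor_mutation", taxa = "Mysticete7", intron_index = 2),
    list(type = "splice_acceptor_mutation", taxa = "Outgroup2",
         intron_index = 1),
    list(type = "exon_deletion", taxa = mys, exon_index = 3))
  bundle <- simulate_alignment(sim_config(
    whale_like_tree(), n_codons = 60, seed = 13, n_exons = 5,
    reference = "Outgroup1", lesions = specs))
  tr <- bundle$truth$lesions
  expect_setequal(unique(tr$type[!tr$induced]), LESION_TYPES)
  # the exon deletion is present in every clade member, identically
  ed <- tr[tr$type == "exon_deletion", ]
  expect_setequal(ed$taxon, mys)
  expect_equal(length(unique(ed$cds_position)), 1)

  # untouched taxa are untouched: columns outside planted windows match a
  # lesion-free run of the same seed
  clean <- simulate_alignment(sim_config(whale_like_tree(), n_codons = 60,
                                         seed = 13, n_exons = 5,
                                         reference = "Outgroup1"))
  expect_identical(bundle$alignment$mat["Outgroup1", !is.na(bundle$alignment$column_map)],
                   clean$alignment$mat["Outgroup1", ])
})

test_that("the scanner closes the loop on planted lesions (recall/precision)", {
  bundle <- simulate_alignment(sim_config(
    whale_like_tree(), n_codons = 80, seed = 14, reference = "Outgroup1",
    lesions = list(
      list(type = "frameshift_deletion", taxa = "Mysticete1",
           cds_position = 100, length = 1),
      list(type = "premature_stop_codon", taxa = "Odontocete2", codon = 30))))
  found <- scan_alignment(bundle$alignment, bundle$gene_structure)
  truth <- bundle$truth$lesions
  key <- function(d) paste(d$taxon, d$type, d$cds_position, d$length, d$detail)
  expect_setequal(key(found), key(truth))
})

test_that("fixture suites are reproducible and match their manifest", {
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- make_fixture_suite(3, d1)
  m2 <- make_fixture_suite(3, d2)
  for (f in c("small/alignment.fasta", "small/tree.nwk",
              "small/gene_structure.tsv", "small/truth.json",
              "paper_scale/alignment.fasta", "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # manifest counts agree with an independent re-scan of the emitted files
  aln <- read_codon_alignment(file.path(d1, "small/alignment.fasta"),
                              "Outgroup1", check_orf = FALSE)
  gs <- read_gene_structure(file.path(d1, "small/gene_structure.tsv"))
  truth <- jsonlite::read_json(file.path(d1, "small/truth.json"),
                               simplifyVector = TRUE)
  expect_equal(m1$bundles$small$lesion_count, nrow(truth$lesions))
  found <- scan_alignment(aln, gs)
  key <- function(d) paste(d$taxon, d$type, d$cds_position, d$length, d$detail)
  expect_setequal(key(found), key(truth$lesions))
  unlink(c(d1, d2), recursive = TRUE)
})
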