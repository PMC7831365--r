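test_that("the rate matrix has the GY94 structure and scaling", {
  pi <- uniform_pi()
  m <- build_rate_matrix(kappa = 2.5, omega = 0.3, pi = pi)
  Q <- m$Q
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  # scaled to one expected substitution per codon per unit time
  expect_equal(sum(pi * -diag(Q)), 1, tolerance = 1e-12)
  # detailed balance (reversibility): pi_i q_ij = pi_j q_ji
  F <- diag(pi) %*% Q
  expect_equal(max(abs(F - t(F))), 0, tolerance = 1e-14)
  # multi-nucleotide changes are forbidden
  expect_equal(Q["AAA", "ACC"], 0)
  expect_equal(Q["AAA", "CCC"], 0)
  # matches the independently built oracle generator
  expect_equal(max(abs(Q - oracle_Q(2.5, 0.3, pi))), 0, tolerance = 1e-12)

  # rate ratios before scaling: syn ts / syn tv = kappa,
  # nonsyn/syn (same change class) = omega
  expect_equal(Q["TTT", "TTC"] / Q["TTT", "TTA"],   # F->F (ts) vs F->L (tv)
               2.5 / 0.3, tolerance = 1e-12)
})

test_that("transition matrices are stochastic and P(0) is the identity", {
  pi <- codon_frequencies(matrix(c("ATG", "GCA", "CCC", "TTT"), 2), "F3x4")
  m <- build_rate_matrix(2, 0.5, pi)
  expect_equal(transition_matrix(m, 0), diag(61), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (t in c(0.1, 1, 10)) {
    P <- transition_matrix(m, t)
    expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-12)
    expect_true(all(P >= 0))
    # pi is stationary at every t
    expect_equal(as.numeric(pi %*% P), as.numeric(pi), tolerance = 1e-12)
  }
})

test_that("codon frequency schemes match hand computations", {
  cm <- matrix(c("ATG", "ATG", "GCA", "TTT"), nrow = 2)
  for (s in c("F1x4", "F3x4", "F61")) {
    pi <- codon_frequencies(cm, s)
    expect_length(pi, 61)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_true(all(pi > 0))
  }

  # F61 by hand: ATG seen twice, GCA and TTT once, all others floored at 0.5
  f61 <- codon_frequencies(cm, "F61")
  denom <- 2 + 1 + 1 + 58 * 0.5
  expect_equal(unname(f61["ATG"]), 2 / denom, tolerance = 1e-12)
  expect_equal(unname(f61["GCA"]), 1 / denom, tolerance = 1e-12)
  expect_equal(unname(f61["AAA"]), 0.5 / denom, tolerance = 1e-12)

  # F3x4 by hand: position-specific nucleotide tables of ATG,ATG,GCA,TTT
  # pos1 A,A,G,T -> A 2/4, G 1/4, T 1/4, C floored 0.5 -> /4.5
  # pos2 T,T,C,T -> T 3/4.5.. etc; product renormalised over sense codons
  p1 <- c(A = 2, C = 0.5, G = 1, T = 1); p1 <- p1 / sum(p1)
  p2 <- c(A = 0.5, C = 1, G = 0.5, T = 3); p2 <- p2 / sum(p2)
  p3 <- c(A = 1, C = 0.5, G = 2, T = 1); p3 <- p3 / sum(p3)
  sc <- sense_codons()
  raw <- p1[substr(sc, 1, 1)] * p2[substr(sc, 2, 2)] * p3[substr(sc, 3, 3)]
  expect_equal(as.numeric(codon_frequencies(cm, "F3x4")),
               as.numeric(raw / sum(raw)), tolerance = 1e-12)
})

test_that("two identical tips on zero-length branches give lnL = n log(1/61)", {
  tree <- ape::read.tree(text = "(A:0,B:0);")
  tree$edge_category <- rep("background", 2)
  seq <- "ATGAAACCCGGGTTTTGCCAT"   # 7 codons
  aln <- codon_alignment(c(A = seq, B = seq), "A", check_orf = FALSE)
  ll <- codon_loglik(aln, tree, kappa = 2, omegas = c(background = 0.5),
                     pi = uniform_pi())
  expect_equal(ll, 7 * log(1 / 61), tolerance = 1e-10)
})

test_that("pruning agrees with brute-force enumeration (spot check)", {
  set.seed(71)
  tree <- ape::read.tree(text = "((A:0.2,B:0.05):0.1,(C:0.3,D:0.15):0.02);")
  tree$edge_category <- rep("background", nrow(tree$edge))
  sc <- sense_codons()
  mk <- function() paste(sc[sample.int(61, 3, replace = TRUE)], collapse = "")
  aln <- codon_alignment(c(A = mk(), B = mk(), C = mk(), D = mk()), "A",
                         check_orf = FALSE)
  pi <- uniform_pi()
  ll_fast <- codon_loglik(aln, tree, 2.3, c(background = 0.4), pi)
  ll_slow <- oracle_loglik(aln, tree, 2.3, 0.4, pi)
  expect_equal(ll_fast, ll_slow, tolerance = 1e-9)

  # missing data handled identically
  aln2 <- aln
  aln2$mat["B", 4:6] <- "N"
  ll_fast2 <- codon_loglik(aln2, tree, 2.3, c(background = 0.4), pi)
  ll_slow2 <- oracle_loglik(aln2, tree, 2.3, 0.4, pi)
  expect_equal(ll_fast2, ll_slow2, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(ll_fast, ll_fast2)))
})

test_that("the likelihood is invariant to the root position (reversibility)", {
  set.seed(72)
  t1 <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.1);")
  t2 <- ape::root(t1, outgroup = "A", resolve.root = TRUE)
  for (tr in list(t1, t2)) tr$edge_category <- NULL
  sc <- sense_codons()
  mk <- function() paste(sc[sample.int(61, 5, replace = TRUE)], collapse = "")
  aln <- codon_alignment(c(A = mk(), B = mk(), C = mk(), D = mk()), "A",
                         check_orf = FALSE)
  pi <- uniform_pi()
  t1$edge_category <- rep("background", nrow(t1$edge))
  t2$edge_category <- rep("background", nrow(t2$edge))
  ll1 <- codon_loglik(aln, t1, 2, c(background = 0.3), pi)
  ll2 <- codon_loglik(aln, t2, 2, c(background = 0.3), pi)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

ladder_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      bundle <- simulate_alignment(sim_config(
        mysticete_like_tree(), n_codons = 300, seed = 41,
        switches = list(list(taxa = "Mysticete3", age = 14, omega = 1))))
      tr <- tag_branches(bundle$truth$tree_subs, "fg", tips = "Mysticete3")
      aln <- recode_premature_stops(bundle$alignment)
      memo <<- list(ladder = fit_model_ladder(aln, tr, freq = "F3x4"),
                    aln = aln, tree = tr)
    }
    memo
  }
})

test_that("fits report coherent parameter counts, AIC and methods", {
  fx <- ladder_fixture()
  f <- fx$ladder$fits
  nedge <- nrow(fx$tree$edge)
  # k = branch lengths + kappa + free omegas + frequency parameters (F3x4: 9)
  expect_equal(f$B$k, nedge + 1 + 0 + 9)
  expect_equal(f$A$k, f$B$k + 1)
  expect_equal(f$C$k, f$A$k + 1)
  expect_equal(f$D$k, f$A$k)
  for (m in names(f)) {
    expect_equal(f[[m]]$AIC, 2 * f[[m]]$k - 2 * f[[m]]$lnL)
    expect_equal(f[[m]]$convergence, 0)
  }
  expect_equal(unname(f$B$omegas["omega"]), 1)
  expect_equal(unname(f$D$omegas["omega2"]), 1)

  expect_equal(logLik(f$A)[1], f$A$lnL, ignore_attr = TRUE)
  expect_true(all(c("kappa", "omega") %in% names(coef(f$A))))
  expect_output(print(f$C), "omega")
  expect_output(print(summary(fx$ladder)), "relax")
})

test_that("nested models order their likelihoods; LRTs are valid", {
  fx <- ladder_fixture()
  f <- fx$ladder$fits
  expect_true(f$A$lnL >= f$B$lnL)
  expect_true(f$C$lnL >= f$A$lnL)
  expect_true(f$C$lnL >= f$D$lnL)
  for (lr in fx$ladder$lrt) {
    expect_gte(lr$statistic, 0)
    expect_equal(lr$df, 1)
    expect_true(lr$p.value >= 0 && lr$p.value <= 1)
  }
  expect_error(likelihood_ratio_test(f$A, f$B), regexp = "nested")
  expect_error(likelihood_ratio_test(f$C, f$D), regexp = "nested")
})

test_that("the ladder recovers a planted neutral foreground", {
  fx <- ladder_fixture()
  f <- fx$ladder$fits
  # strong overall selection signal on 300 codons of omega ~ 0.116
  expect_lt(fx$ladder$lrt$A_vs_B$p.value, 1e-6)
  expect_lt(unname(f$A$omegas["omega"]), 0.5)
  # foreground omega well above background (whole branch neutral since 14 Ma
  # on a 14 My terminal branch)
  expect_gt(unname(f$C$omegas["omega2"]), unname(f$C$omegas["omega1"]))
})

test_that("frequency-scheme selection is a valid AIC argmin", {
  fx <- ladder_fixture()
  sel <- select_frequency_scheme(fx$aln, fx$tree)
  expect_true(sel$scheme %in% c("F1x4", "F3x4", "F61"))
  expect_length(sel$AIC, 3)
  expect_equal(unname(sel$AIC[sel$scheme]), min(sel$AIC))
  # the generator uses uniform codon frequencies: richer schemes cannot beat
  # the 3-parameter one by more than their AIC penalty here
  expect_identical(sel$scheme, "F1x4")
})
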