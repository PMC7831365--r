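# Maximum-likelihood GY94 codon model with branch-category omega.
# Models of the four-model ladder:
#   A: one free omega on all branches (M0)
#   B: omega fixed at 1 on all branches
#   C: background omega_1 free, foreground omega_2 free (two-ratio)
#   D: background omega_1 free, foreground omega fixed at 1
# Likelihood-ratio tests: A vs B (any selection signal), C vs A (foreground
# differs from background), C vs D (foreground differs from neutral;
# non-significant = "complete relaxation" when C vs A is significant).

FREQ_SCHEMES <- c("F1x4", "F3x4", "F61")
FREQ_PARAMS <- c(F1x4 = 3L, F3x4 = 9L, F61 = 60L)

#' Equilibrium codon frequencies from an alignment
#'
#' `F1x4` uses pooled nucleotide frequencies, `F3x4` codon-position-specific
#' nucleotide frequencies, `F61` observed codon counts. Stop codons are
#' excluded and frequencies renormalised over the 61 sense codons; zero
#' counts are floored at a pseudocount of 0.5 before normalisation.
#' @param aln a `codon_alignment` (or a codon character matrix)
#' @param scheme one of `"F1x4"`, `"F3x4"`, `"F61"`
#' @return named numeric vector over [sense_codons()], summing to 1
#' @export
codon_frequencies <- function(aln, scheme = c("F3x4", "F1x4", "F61")) {
  scheme <- match.arg(scheme)
  cm <- if (inherits(aln, "codon_alignment")) codon_matrix(aln) else aln
  ok <- grepl("^[ACGT]{3}$", cm)
  if (!any(ok)) stop("empty alignment: no resolved codons")
  cods <- cm[ok]
  sc <- sense_codons()
  floor0 <- function(x) { x[x == 0] <- 0.5; x }
  if (scheme == "F61") {
    cnt <- table(factor(cods[cods %in% sc], levels = sc))
    pi <- floor0(as.numeric(cnt))
  } else {
    chars <- do.call(rbind, strsplit(cods, ""))
    sc_chars <- do.call(rbind, strsplit(sc, ""))
    if (scheme == "F1x4") {
      f <- floor0(as.numeric(table(factor(chars, levels = NUC))))
      f <- f / sum(f)
      pi <- f[match(sc_chars[, 1], NUC)] * f[match(sc_chars[, 2], NUC)] *
        f[match(sc_chars[, 3], NUC)]
    } else {
      fp <- sapply(1:3, function(p) {
        f <- floor0(as.numeric(table(factor(chars[, p], levels = NUC))))
        f / sum(f)
      })
      pi <- fp[match(sc_chars[, 1], NUC), 1] *
        fp[match(sc_chars[, 2], NUC), 2] * fp[match(sc_chars[, 3], NUC), 3]
    }
  }
  pi <- pi / sum(pi)
  names(pi) <- sc
  pi
}

#' Build a GY94 codon rate model
#'
#' Off-diagonal rates are `pi_j` times 1 (synonymous transversion), `kappa`
#' (synonymous transition), `omega` (nonsynonymous transversion) or
#' `omega * kappa` (nonsynonymous transition); zero for multi-nucleotide
#' changes. The generator is scaled to one expected substitution per codon
#' per unit time.
#' @param kappa transition/transversion rate ratio (> 0)
#' @param omega dN/dS ratio (> 0)
#' @param pi equilibrium frequencies over the 61 sense codons
#' @return object of class `codon_rate_model` with elements `Q`, `kappa`,
#'   `omega`, `pi`
#' @export
build_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega > 0, length(pi) == 61,
            all(pi > 0), abs(sum(pi) - 1) < 1e-8)
  Q <- codon_Q_cpp(kappa, omega, as.numeric(pi), codon_pair_types())
  dimnames(Q) <- list(sense_codons(), sense_codons())
  structure(list(Q = Q, kappa = kappa, omega = omega, pi = pi),
            class = "codon_rate_model")
}

#' Transition probability matrix exp(Q t) of a codon rate model
#' @param model a `codon_rate_model`
#' @param t branch length (expected substitutions per codon, >= 0)
#' @export
transition_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- codon_pmat_cpp(model$kappa, model$omega, as.numeric(model$pi),
                      codon_pair_types(), t)
  dimnames(P) <- dimnames(model$Q)
  P
}

# --- likelihood plumbing ----------------------------------------------------

# postorder edge data for a phylo (categories follow the reorder)
tree_postorder <- function(tree) {
  idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  list(edges = tree$edge[idx, , drop = FALSE],
       lengths = if (is.null(tree$edge.length)) rep(0.1, nrow(tree$edge))
                 else tree$edge.length[idx],
       category = if (is.null(tree$edge_category))
                    rep("background", nrow(tree$edge))
                  else tree$edge_category[idx],
       idx = idx)
}

# compress tip states (taxa x codons, NA = missing) into unique patterns
compress_patterns <- function(states) {
  st <- states
  st[is.na(st)] <- 0L
  key <- apply(st, 2, paste, collapse = ",")
  f <- factor(key, levels = unique(key))
  list(states = st[, !duplicated(key), drop = FALSE],
       weights = as.numeric(table(f)))
}

#' Log-likelihood of a codon alignment under branch-category omegas
#'
#' Felsenstein pruning over compressed site patterns; gap/missing codons
#' contribute all-ones partial vectors.
#' @param aln a `codon_alignment` (ideally stop-recoded)
#' @param tree a `phylo` with `edge_category` and branch lengths
#' @param kappa,pi model parameters
#' @param omegas named vector: omega per category label appearing on the tree
#' @return log-likelihood (scalar)
#' @export
codon_loglik <- function(aln, tree, kappa, omegas, pi) {
  dat <- likelihood_data(aln, tree)
  cats <- sort(unique(dat$post$category))
  if (!all(cats %in% names(omegas)))
    stop("omegas missing for categories: ",
         paste(setdiff(cats, names(omegas)), collapse = ", "))
  edge_cat <- match(dat$post$category, cats)
  codon_loglik_cpp(dat$pat$states, dat$pat$weights, dat$post$edges,
                   dat$post$lengths, edge_cat, kappa,
                   as.numeric(omegas[cats]), as.numeric(pi),
                   codon_pair_types())
}

likelihood_data <- function(aln, tree) {
  drop <- setdiff(tree$tip.label, taxa(aln))
  if (length(drop))
    stop("tree tips absent from alignment: ", paste(drop, collapse = ", "))
  states <- codon_states(aln)[tree$tip.label, , drop = FALSE]
  list(post = tree_postorder(tree), pat = compress_patterns(states))
}

# --- fitting ----------------------------------------------------------------

model_spec <- function(model, categories) {
  fg <- setdiff(categories, "background")
  switch(model,
    A = list(free = "omega", fixed = NULL,
             map = stats::setNames(rep("omega", length(categories)), categories)),
    B = list(free = character(0), fixed = c(omega = 1),
             map = stats::setNames(rep("omega", length(categories)), categories)),
    C = {
      if (!length(fg)) stop("model C needs at least one foreground category")
      list(free = c("omega1", "omega2"), fixed = NULL,
           map = stats::setNames(ifelse(categories == "background",
                                        "omega1", "omega2"), categories))
    },
    D = {
      if (!length(fg)) stop("model D needs at least one foreground category")
      list(free = "omega1", fixed = c(omega2 = 1),
           map = stats::setNames(ifelse(categories == "background",
                                        "omega1", "omega2"), categories))
    },
    stop("unknown model '", model, "'"))
}

#' Fit a branch-model codon substitution model by maximum likelihood
#'
#' Optimises kappa, the model's free omegas and (by default) all branch
#' lengths with bounded quasi-Newton (L-BFGS-B) on log-transformed rate
#' parameters, multi-starting the free omegas over `starts`.
#'
#' @param aln a `codon_alignment`; premature stops should be recoded first
#'   (see [recode_premature_stops()]); any remaining stop codon is treated
#'   as missing data
#' @param tree a `phylo` with `edge_category` (see [read_branch_tree()],
#'   [tag_branches()]); every non-"background" category is foreground
#' @param model one of `"A"`, `"B"`, `"C"`, `"D"` (see Details)
#' @param freq frequency scheme (`"F1x4"`, `"F3x4"`, `"F61"`), or a numeric
#'   61-vector of codon frequencies
#' @param starts initial values for each free omega (multi-start)
#' @param init optional warm start: a `codon_fit` or
#'   `list(kappa=, branch_lengths=, omegas=)`
#' @param fix_branch_lengths keep branch lengths at their initial values
#'   (fast mode; off by default — branch lengths are re-estimated in every fit)
#' @param control list: `factr` L-BFGS-B tolerance (default targets ~1e-8
#'   on the log-likelihood), `maxit`
#' @return object of class `codon_fit`
#' @details Model A estimates a single omega for every branch; model B fixes
#'   omega at 1; model C gives foreground branches their own omega_2 and
#'   background branches omega_1; model D fixes the foreground omega_2 at 1
#'   with omega_1 free. A is nested in C, B in A, and D in C.
#' @export
fit_codon_model <- function(aln, tree, model = c("A", "B", "C", "D"),
                            freq = "F3x4", starts = c(0.1, 1, 2),
                            init = NULL, fix_branch_lengths = FALSE,
                            control = list()) {
  model <- match.arg(model)
  factr <- control$factr %||% 5e7   # ~1e-8 absolute on lnL
  maxit <- control$maxit %||% 500L

  if (is.numeric(freq)) {
    pi <- freq; freq_scheme <- "custom"; freq_k <- 60L
  } else {
    freq_scheme <- match.arg(freq, FREQ_SCHEMES)
    pi <- codon_frequencies(aln, freq_scheme)
    freq_k <- FREQ_PARAMS[[freq_scheme]]
  }

  dat <- likelihood_data(aln, tree)
  categories <- sort(unique(dat$post$category))
  spec <- model_spec(model, categories)
  edge_cat_lab <- spec$map[dat$post$category]
  omega_labels <- unique(unname(spec$map[categories]))
  edge_cat <- match(edge_cat_lab, omega_labels)
  nedge <- nrow(dat$post$edges)
  pair_type <- codon_pair_types()

  bl0 <- pmin(pmax(dat$post$lengths, 1e-4), 20)
  kappa0 <- 2
  if (!is.null(init)) {
    if (inherits(init, "codon_fit")) {
      kappa0 <- init$kappa
      bl_init <- init$tree$edge.length
      if (!is.null(bl_init)) bl0 <- pmin(pmax(bl_init[dat$post$idx], 1e-6), 20)
    } else {
      if (!is.null(init$kappa)) kappa0 <- init$kappa
      if (!is.null(init$branch_lengths))
        bl0 <- pmin(pmax(init$branch_lengths[dat$post$idx], 1e-6), 20)
    }
  }

  nfree <- length(spec$free)
  omega_full <- function(free_vals) {
    vals <- stats::setNames(numeric(length(omega_labels)), omega_labels)
    if (nfree) vals[spec$free] <- free_vals
    if (!is.null(spec$fixed)) vals[names(spec$fixed)] <- spec$fixed
    vals
  }

  raw_ll <- function(kappa, free_vals, bl) {
    om <- omega_full(free_vals)
    codon_loglik_cpp(dat$pat$states, dat$pat$weights, dat$post$edges,
                     bl, edge_cat, kappa, as.numeric(om[omega_labels]),
                     as.numeric(pi), pair_type)
  }
  unpack <- function(par) list(
    kappa = exp(par[1]),
    free_vals = if (nfree) exp(par[2:(1 + nfree)]) else numeric(0),
    bl = if (fix_branch_lengths) bl0 else par[(2 + nfree):length(par)])
  negll <- function(par) {
    p <- unpack(par)
    ll <- raw_ll(p$kappa, p$free_vals, p$bl)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # analytic gradient (edge lengths, kappa, omegas), chain-ruled onto the
  # log scale used for the rate parameters
  negll_grad <- function(par) {
    p <- unpack(par)
    om <- omega_full(p$free_vals)
    gr <- codon_loglik_grad_cpp(dat$pat$states, dat$pat$weights,
                                dat$post$edges, p$bl, edge_cat, p$kappa,
                                as.numeric(om[omega_labels]), as.numeric(pi),
                                pair_type)
    gk <- p$kappa * gr$grad_kappa
    gw <- if (nfree) {
      vapply(spec$free, function(nm)
        om[[nm]] * gr$grad_omegas[match(nm, omega_labels)], numeric(1))
    } else numeric(0)
    g <- -c(gk, gw, if (!fix_branch_lengths) as.numeric(gr$grad_edge))
    g[!is.finite(g)] <- 0
    g
  }

  lower <- c(log(0.01), rep(log(1e-4), nfree),
             if (!fix_branch_lengths) rep(0, nedge))
  upper <- c(log(100), rep(log(50), nfree),
             if (!fix_branch_lengths) rep(20, nedge))

  omega_starts <- if (nfree) as.list(starts) else list(NA)
  if (nfree && !is.null(init) && !is.null(init$omegas)) {
    # warm start: seed every free omega from the previous fit's estimates
    winit <- init$omegas
    pick <- function(nm) {
      if (nm %in% names(winit)) winit[[nm]]
      else if ("omega" %in% names(winit)) winit[["omega"]]
      else winit[[1]]
    }
    ws <- stats::setNames(vapply(spec$free, pick, numeric(1)), spec$free)
    omega_starts <- c(list(ws), omega_starts)
  }

  best <- NULL
  for (st in omega_starts) {
    om0 <- if (nfree) {
      if (length(st) == nfree && !is.null(names(st))) st[spec$free]
      else rep(st[[1]], nfree)
    } else numeric(0)
    par0 <- c(log(kappa0), if (nfree) log(pmin(pmax(om0, 1e-4), 50)),
              if (!fix_branch_lengths) bl0)
    opt <- stats::optim(par0, negll, gr = negll_grad, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = factr, maxit = maxit))
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  kappa_hat <- exp(best$par[1])
  free_hat <- if (nfree) exp(best$par[2:(1 + nfree)]) else numeric(0)
  om_hat <- omega_full(free_hat)
  bl_hat <- if (fix_branch_lengths) bl0 else best$par[(2 + nfree):length(best$par)]

  fitted_tree <- tree
  el <- numeric(nedge)
  el[dat$post$idx] <- bl_hat
  fitted_tree$edge.length <- el

  lnL <- -best$value
  k <- (if (fix_branch_lengths) 0L else nedge) + 1L + nfree + freq_k
  structure(list(
    model = model, lnL = lnL, kappa = kappa_hat, omegas = om_hat,
    category_omegas = stats::setNames(om_hat[spec$map[categories]], categories),
    tree = fitted_tree, k = k, AIC = 2 * k - 2 * lnL,
    freq_scheme = freq_scheme, pi = pi, npatterns = length(dat$pat$weights),
    n_codons = sum(dat$pat$weights), convergence = best$convergence,
    fix_branch_lengths = fix_branch_lengths,
    foreground = setdiff(categories, "background")
  ), class = "codon_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Likelihood-ratio test between two nested codon-model fits
#'
#' @param null,alt `codon_fit` objects; the null must be nested in the
#'   alternative (B in A, B in C, A in C, or D in C) and share the frequency
#'   scheme
#' @return object of class `codon_lrt` with `statistic` (2 delta lnL, clamped
#'   at 0), `df` and `p.value` from the chi-squared reference distribution
#' @export
likelihood_ratio_test <- function(null, alt) {
  allowed <- list(c("B", "A"), c("B", "C"), c("A", "C"), c("D", "C"))
  ok <- any(vapply(allowed, function(p)
    identical(p, c(null$model, alt$model)), logical(1)))
  if (!ok) stop("model ", null$model, " is not nested in model ", alt$model)
  if (!identical(null$freq_scheme, alt$freq_scheme))
    stop("fits use different frequency schemes")
  df <- alt$k - null$k
  stat <- max(0, 2 * (alt$lnL - null$lnL))
  structure(list(null = null$model, alt = alt$model, statistic = stat,
                 df = df, p.value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "codon_lrt")
}

#' @export
print.codon_lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2*deltaLnL = %.4f, df = %d, p = %.4g\n",
              x$alt, x$null, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Select a codon frequency scheme by AIC
#'
#' Fits model A under F1x4, F3x4 and F61 and returns the scheme with the
#' lowest AIC; ties go to the scheme with fewer parameters.
#' @inheritParams fit_codon_model
#' @return list with `scheme` and the per-scheme `fits`
#' @export
select_frequency_scheme <- function(aln, tree, starts = c(0.1, 1, 2), ...) {
  fits <- lapply(FREQ_SCHEMES, function(s)
    fit_codon_model(aln, tree, model = "A", freq = s, starts = starts, ...))
  names(fits) <- FREQ_SCHEMES
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  # schemes are ordered by parameter count, so which.min's first-match
  # tie-break prefers fewer parameters
  scheme <- FREQ_SCHEMES[which.min(aic)]
  list(scheme = scheme, AIC = aic, fits = fits)
}

#' Fit the four-model ladder and its likelihood-ratio tests
#'
#' Fits models B, A, C, D (warm-starting each from the previous optimum, so
#' the nesting inequalities hold by construction) and assembles the
#' A-vs-B, C-vs-A and C-vs-D tests. The "complete relaxation" verdict is
#' C-vs-A significant together with C-vs-D non-significant at `alpha`:
#' the foreground omega differs from background but not from 1.
#'
#' @inheritParams fit_codon_model
#' @param models subset of the ladder to fit
#' @param alpha significance level for the relaxation verdict
#' @return object of class `codon_fit_ladder`: list of fits, LRT table,
#'   verdict
#' @export
fit_model_ladder <- function(aln, tree, models = c("A", "B", "C", "D"),
                             freq = "F3x4", starts = c(0.1, 1, 2),
                             alpha = 0.05, control = list(), ...) {
  fits <- list()
  fits$B <- if ("B" %in% models)
    fit_codon_model(aln, tree, "B", freq = freq, control = control, ...)
  fits$A <- if ("A" %in% models)
    fit_codon_model(aln, tree, "A", freq = freq, starts = starts,
                    init = fits$B, control = control, ...)
  fits$C <- if ("C" %in% models)
    fit_codon_model(aln, tree, "C", freq = freq, starts = starts,
                    init = fits$A, control = control, ...)
  fits$D <- if ("D" %in% models)
    fit_codon_model(aln, tree, "D", freq = freq, starts = starts,
                    init = fits$A, control = control, ...)
  fits <- Filter(Negate(is.null), fits)

  lrt <- list()
  if (all(c("A", "B") %in% names(fits)))
    lrt$A_vs_B <- likelihood_ratio_test(fits$B, fits$A)
  if (all(c("C", "A") %in% names(fits)))
    lrt$C_vs_A <- likelihood_ratio_test(fits$A, fits$C)
  if (all(c("C", "D") %in% names(fits)))
    lrt$C_vs_D <- likelihood_ratio_test(fits$D, fits$C)

  verdict <- NA
  if (all(c("C_vs_A", "C_vs_D") %in% names(lrt)))
    verdict <- lrt$C_vs_A$p.value < alpha && lrt$C_vs_D$p.value >= alpha

  structure(list(fits = fits, lrt = lrt, alpha = alpha,
                 completely_relaxed = verdict),
            class = "codon_fit_ladder")
}
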