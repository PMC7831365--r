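# S3 methods for the fitted-model and ladder objects.

#' @export
print.codon_fit <- function(x, ...) {
  cat("GY94 branch-model fit (model ", x$model, ", ", x$freq_scheme, ")\n",
      sep = "")
  cat(sprintf("  lnL = %.4f  k = %d  AIC = %.2f\n", x$lnL, x$k, x$AIC))
  cat(sprintf("  kappa = %.4f\n", x$kappa))
  for (nm in names(x$omegas))
    cat(sprintf("  %s = %.4f\n", nm, x$omegas[[nm]]))
  if (length(x$foreground))
    cat("  foreground categories:", paste(x$foreground, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, nobs = object$n_codons,
            class = "logLik")
}

#' @export
coef.codon_fit <- function(object, ...) {
  c(kappa = object$kappa, object$omegas)
}

#' @export
summary.codon_fit <- function(object, ...) {
  tl <- sum(object$tree$edge.length)
  structure(list(fit = object, tree_length = tl), class = "summary.codon_fit")
}

#' @export
print.summary.codon_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  tree length = %.4f subs/codon over %d branches; %d codons (%d patterns)\n",
              x$tree_length, nrow(x$fit$tree$edge), x$fit$n_codons,
              x$fit$npatterns))
  cat("  per-category omega:\n")
  print(round(x$fit$category_omegas, 4))
  invisible(x)
}

#' Simulate an alignment from a fitted codon model
#'
#' Draws `nsim` codon alignments under the fitted kappa, per-category omegas,
#' frequencies and branch lengths — a parametric bootstrap of the fit.
#' @param object a `codon_fit`
#' @param nsim number of alignments
#' @param seed integer seed (mandatory for reproducibility)
#' @param n_codons alignment length; defaults to the fitted data's length
#' @param ... unused
#' @return list of `codon_alignment` objects (length `nsim`)
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = NULL,
                               n_codons = object$n_codons, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    simulate_codon_tree(object$tree, kappa = object$kappa,
                        omegas = object$category_omegas, pi = object$pi,
                        n_codons = n_codons)
  })
}

#' @export
print.codon_fit_ladder <- function(x, ...) {
  cat("Codon model ladder:\n")
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    om <- paste(sprintf("%s=%.3f", names(f$omegas), f$omegas), collapse = " ")
    cat(sprintf("  %s: lnL = %.4f  k = %d  AIC = %.2f  %s\n",
                m, f$lnL, f$k, f$AIC, om))
  }
  for (t in x$lrt) print(t)
  if (!is.na(x$completely_relaxed))
    cat("Complete relaxation verdict (alpha =", x$alpha, "):",
        if (x$completely_relaxed) "RELAXED" else "not relaxed", "\n")
  invisible(x)
}

#' @export
summary.codon_fit_ladder <- function(object, ...) {
  lrt_df <- do.call(rbind, lapply(object$lrt, function(t)
    data.frame(null = t$null, alt = t$alt, statistic = t$statistic,
               df = t$df, p.value = t$p.value)))
  fit_df <- do.call(rbind, lapply(object$fits, function(f) {
    getom <- function(nm) if (nm %in% names(f$omegas)) f$omegas[[nm]] else NA_real_
    om1 <- getom("omega1"); if (is.na(om1)) om1 <- getom("omega")
    data.frame(model = f$model, lnL = f$lnL, k = f$k, AIC = f$AIC,
               omega1 = om1, omega2 = getom("omega2"))
  }))
  rownames(fit_df) <- rownames(lrt_df) <- NULL
  list(fits = fit_df, lrt = lrt_df,
       completely_relaxed = object$completely_relaxed)
}
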