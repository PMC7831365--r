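# Dating gene inactivation from a mixed branch's dN/dS.
#
# A branch of duration T along which the gene was functional for Ts and then
# evolved neutrally for Tn = T - Ts has an average dN/dS of
#   K = Ks * Ts/T + Kn * Tn/T,       Kn = 1
# where Ks is the dN/dS while the gene was under selection (taken from the
# background omega_1 of the same two-ratio fit). Inverting for Tn:
#   Tn = T * (K - Ks) / (1 - Ks)
# applied to the lower and upper bounds of the divergence-time confidence
# interval gives an interval of neutral-evolution time, hence an
# inactivation-date interval (branch end age + Tn, in Ma before present).

#' Estimate the neutral-evolution time of a pseudogene branch
#'
#' @param K mixed-branch dN/dS (the branch's fitted foreground omega_2)
#' @param Ks dN/dS of the functional period (background omega_1); must be in
#'   (0, 1)
#' @param T_lower,T_upper bounds (Ma) on the time since the split from the
#'   last common ancestor
#' @param branch_end_age age (Ma) of the branch's young end: 0 for terminal
#'   branches, the clade's crown age for a stem branch
#' @param Kn neutral dN/dS, 1 by definition
#' @return object of class `inactivation_dating` with fields `Tn_lower`,
#'   `Tn_upper`, `Ts_lower`, `Ts_upper`, `date_lower`, `date_upper` (Ma before
#'   present) and `clamped`. `Tn` is clamped to `[0, T]` (with the flag set)
#'   when `K < Ks` or `K > 1`, where the mixture model's domain ends.
#' @export
neutral_time <- function(K, Ks, T_lower, T_upper, branch_end_age = 0, Kn = 1) {
  stopifnot(length(K) == 1, length(Ks) == 1)
  if (Ks >= 1) stop("Ks must be < 1: the mixture equation degenerates at Ks = 1")
  if (Ks <= 0) stop("Ks must be > 0")
  if (K < 0) stop("K must be >= 0")
  if (Kn != 1) stop("Kn is 1 by definition of neutral evolution")
  if (!(T_lower > 0 && T_lower <= T_upper))
    stop("need 0 < T_lower <= T_upper")
  if (branch_end_age < 0) stop("branch_end_age must be >= 0")

  tn_raw <- function(T) T * (K - Ks) / (1 - Ks)
  clamped <- K < Ks || K > 1
  tn <- function(T) min(max(tn_raw(T), 0), T)

  Tn_l <- tn(T_lower); Tn_u <- tn(T_upper)
  structure(list(
    K = K, Ks = Ks, T_lower = T_lower, T_upper = T_upper,
    branch_end_age = branch_end_age,
    Tn_lower = Tn_l, Tn_upper = Tn_u,
    Ts_lower = T_lower - Tn_l, Ts_upper = T_upper - Tn_u,
    date_lower = branch_end_age + Tn_l, date_upper = branch_end_age + Tn_u,
    clamped = clamped
  ), class = "inactivation_dating")
}

#' @export
print.inactivation_dating <- function(x, ...) {
  cat(sprintf("Inactivation dating: K = %.3f, Ks = %.3f, T = [%.2f, %.2f] Ma\n",
              x$K, x$Ks, x$T_lower, x$T_upper))
  cat(sprintf("  neutral time Tn = [%.2f, %.2f] Ma%s\n", x$Tn_lower,
              x$Tn_upper, if (x$clamped) " (clamped)" else ""))
  cat(sprintf("  selected time Ts = [%.2f, %.2f] Ma\n", x$Ts_lower, x$Ts_upper))
  cat(sprintf("  inactivation date = [%.2f, %.2f] Ma before present\n",
              x$date_lower, x$date_upper))
  invisible(x)
}

#' Compare an inactivation-date interval with a fossil age
#'
#' Pure interval arithmetic: does the inactivation interval lie entirely
#' before (older than), entirely after (younger than), or overlap the oldest
#' fossil age of the phenotype? Predating the fossil is compatible with gene
#' loss causing the phenotype; postdating it with gene loss as a consequence.
#' @param estimate an `inactivation_dating`
#' @param fossil_age age of the oldest relevant fossil, Ma (> 0)
#' @return list with `relation` ("predates fossil", "postdates fossil",
#'   "overlaps") and the compared interval
#' @export
consistency_check <- function(estimate, fossil_age) {
  stopifnot(fossil_age > 0)
  lo <- estimate$date_lower; hi <- estimate$date_upper
  relation <- if (lo > fossil_age) "predates fossil"
  else if (hi < fossil_age) "postdates fossil"
  else "overlaps"
  list(relation = relation, interval = c(lo, hi), fossil_age = fossil_age)
}
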