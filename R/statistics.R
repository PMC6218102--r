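#' Per-clone summary statistics and the disappearance statistic Y_z
#'
#' For each clone retained after sample exclusion, computes the mean
#' relative abundance `y_i`, the temporal standard deviation `sigma_i`
#' (population form, divisor J), and the absence count
#' `z_i = #\{j : f_i(t_j) = 0\}`.  Clones absent from every retained
#' sample are dropped, so `z_i` ranges over 0..J-1, and the conditional
#' means `Y_z` (mean of `y_i` over clones with exactly `z` absences) are
#' attached.  Absence means a sampled count of exactly zero -- abundances
#' are ratios of integer counts, so no tolerance is involved.
#'
#' @param ab An `abundance_matrix`.
#' @param exclude Samples to drop before computing statistics: `"auto"`
#'   (default) drops the first sample when it was taken before month 6
#'   (early samples reflect short-term repopulating clones), an integer
#'   vector drops those column indices, `NULL` keeps all samples.
#' @return An object of class `clone_summaries`: vectors `y`, `sigma`,
#'   `z` (named by retained clone), `Y` (length J, bins z = 0..J-1),
#'   `bin_counts`, the retained sample index `kept_samples`, and `J`.
#' @export
clone_summaries <- function(ab, exclude = "auto") {
  stopifnot(inherits(ab, "abundance_matrix"))
  keep_j <- resolve_exclusion(ab, exclude)
  if (length(keep_j) < 2) stop("need at least 2 retained samples")
  f <- ab$fractions[, keep_j, drop = FALSE]
  detected <- rowSums(f) > 0
  if (!any(detected)) stop("no clone detected in any retained sample")
  f <- f[detected, , drop = FALSE]
  J <- ncol(f)
  y <- rowMeans(f)
  sigma <- sqrt(rowMeans((f - y)^2))
  z <- rowSums(f == 0)
  Yz <- conditional_mean_Yz(y, z, J)
  structure(list(y = y, sigma = sigma, z = z,
                 Y = Yz$Y, bin_counts = Yz$bin_counts,
                 kept_samples = keep_j, J = J,
                 n_dropped = sum(!detected)),
            class = "clone_summaries")
}

resolve_exclusion <- function(ab, exclude) {
  J0 <- ncol(ab$fractions)
  if (is.null(exclude)) return(seq_len(J0))
  if (identical(exclude, "auto")) {
    t1 <- ab$design$t_months[1]
    return(if (t1 < 6) seq_len(J0)[-1] else seq_len(J0))
  }
  stopifnot(is.numeric(exclude), all(exclude >= 1), all(exclude <= J0))
  seq_len(J0)[-exclude]
}

#' @export
print.clone_summaries <- function(x, ...) {
  cat("<clone_summaries> ", length(x$y), " retained clones over J = ",
      x$J, " samples (", x$n_dropped, " never detected)\n", sep = "")
  cat("  Y_z:", format(x$Y, digits = 3), "\n")
  cat("  clones per z bin:", x$bin_counts, "\n")
  invisible(x)
}

#' Conditional mean abundance by number of absences
#'
#' `Y_z` is the mean of per-clone mean abundances `y_i` over clones with
#' exactly `z` absences; empty bins are set to 0 by convention.
#'
#' @param y Per-clone mean abundances.
#' @param z Per-clone absence counts (integers in 0..J-1).
#' @param J Number of retained samples (bins run z = 0..J-1).
#' @return List with `Y` (length J, named `z0`..`z(J-1)`) and
#'   `bin_counts`.
#' @export
conditional_mean_Yz <- function(y, z, J) {
  stopifnot(length(y) == length(z), all(z >= 0), all(z < J))
  Y <- numeric(J)
  counts <- integer(J)
  for (zz in 0:(J - 1)) {
    sel <- z == zz
    counts[zz + 1] <- sum(sel)
    if (any(sel)) Y[zz + 1] <- mean(y[sel])
  }
  names(Y) <- names(counts) <- paste0("z", 0:(J - 1))
  list(Y = Y, bin_counts = counts)
}

#' Squared-error objective between two Y_z vectors
#'
#' Sums the squared differences over bins z = 1..J-1.  The z = 0 bin
#' (clones never absent) is excluded: the abundances of always-detected
#' clones are set by the clone-size configuration rather than by
#' burstiness, so it carries no information about the burst parameters.
#'
#' @param Y_model Simulated `Y_z` vector, length J (bins 0..J-1).
#' @param Y_hat Observed `Y_z` vector, same length.
#' @return The mean squared error objective (a single number).
#' @export
mse_objective <- function(Y_model, Y_hat) {
  if (length(Y_model) != length(Y_hat)) {
    stop("Y vectors must have the same length")
  }
  sum((Y_model[-1] - Y_hat[-1])^2)
}

#' One-sample t-tests of observed Y_z against simulated ensembles
#'
#' For each absence bin, tests whether the ensemble of simulated `Y_z`
#' values is consistent with the observed `Y_hat_z` (the null mean),
#' two-sided.  By the central limit theorem the conditional means are
#' approximately normal across replicates, so the t-test applies even
#' though the underlying `y_i` distribution is unknown.
#'
#' @param Y_hat Observed `Y_z`, length J.
#' @param Y_sim Matrix of simulated `Y_z`, replicates x J bins.
#' @param bins Bins to test (default 1..J-1; z = 0 is uninformative).
#' @return A data.frame with `z`, `p_value` (NA for degenerate
#'   zero-variance ensembles, flagged in `degenerate`), simulated mean
#'   and the observed value.
#' @export
ttest_Yz <- function(Y_hat, Y_sim, bins = seq_len(length(Y_hat) - 1)) {
  stopifnot(is.matrix(Y_sim), ncol(Y_sim) == length(Y_hat),
            nrow(Y_sim) >= 2)
  res <- lapply(bins, function(z) {
    v <- Y_sim[, z + 1]
    degenerate <- stats::sd(v) == 0
    p <- if (degenerate) NA_real_ else {
      stats::t.test(v, mu = Y_hat[z + 1])$p.value
    }
    data.frame(z = z, p_value = p, sim_mean = mean(v),
               observed = Y_hat[z + 1], degenerate = degenerate)
  })
  do.call(rbind, res)
}

#' Per-clone scatter table for variability diagnostics
#'
#' Tidy table of `ln y_i`, `sigma_i` and `z_i` per retained clone, the
#' coordinates of the standard abundance-vs-absence and
#' dispersion-vs-abundance diagnostic scatterplots.
#'
#' @inheritParams clone_summaries
#' @return A data.frame with columns `clone_id`, `ln_y`, `sigma`, `z`.
#' @export
scatter_stats <- function(ab, exclude = "auto") {
  s <- clone_summaries(ab, exclude)
  data.frame(clone_id = names(s$y), ln_y = log(s$y),
             sigma = s$sigma, z = s$z, row.names = NULL)
}
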