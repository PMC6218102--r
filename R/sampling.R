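#' Draw sequenced clone counts from peripheral pools
#'
#' Models the small blood sample: each clone's sampled count is an
#' independent binomial draw
#' `s_i(t_j) ~ Binomial(S_plus(t_j), m_i(t_j) / M_ss_plus)`, and its
#' relative abundance is `f_i = s_i / S_plus(t_j)` (normalized by the
#' design total, not the realized tagged total).  At sampling fractions
#' of order 1e-5 to 1e-4 the binomial approximation to hypergeometric
#' draws is exact for practical purposes.
#'
#' @param trajs A `clone_trajectories` object (or a bare clones x samples
#'   matrix of peripheral pool sizes).
#' @param design An [experiment_design()]; defaults to the design carried
#'   by `trajs`.
#' @param seed Integer RNG seed.
#' @return An object of class `abundance_matrix`: list with integer
#'   matrix `counts`, numeric matrix `fractions`, and the `design`.
#' @export
sample_blood <- function(trajs, design = NULL, seed) {
  if (inherits(trajs, "clone_trajectories")) {
    if (is.null(design)) design <- trajs$design
    m <- trajs$m
  } else {
    m <- as.matrix(trajs)
    if (is.null(design)) stop("design required when trajs is a matrix")
  }
  stopifnot(inherits(design, "experiment_design"),
            ncol(m) == length(design$t_months), all(m >= 0))
  p <- m / design$M_ss_plus
  if (any(p > 1)) {
    warning(sum(p > 1), " clone pools exceed M_ss_plus; probability ",
            "clipped to 1 (model inconsistency diagnostic)")
    p <- pmin(p, 1)
  }
  set.seed(as.integer(seed))
  counts <- matrix(
    stats::rbinom(length(p), rep(design$S_plus, each = nrow(p)), p),
    nrow(p), ncol(p), dimnames = dimnames(m))
  fractions <- sweep(counts, 2, design$S_plus, "/")
  new_abundance_matrix(counts, fractions, design)
}

new_abundance_matrix <- function(counts, fractions, design) {
  stopifnot(all(fractions >= 0), all(fractions <= 1),
            all(counts >= 0), all(counts == round(counts)),
            identical(dim(counts), dim(fractions)))
  if (is.null(rownames(counts))) {
    rownames(counts) <- rownames(fractions) <-
      paste0("clone", seq_len(nrow(counts)))
  }
  structure(list(counts = counts, fractions = fractions, design = design),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix> ", nrow(x$counts), " clones x ",
      ncol(x$counts), " samples; ",
      sum(rowSums(x$counts) > 0), " detected at least once\n", sep = "")
  invisible(x)
}

#' Probability that a clone is absent from a blood sample
#'
#' For a clone with `m_i` peripheral cells among a tagged pool of
#' `M_ss_plus`, a sample of `S_plus` tagged cells misses the clone with
#' probability approximately `exp(-m_i * S_plus / M_ss_plus)`.  Clones
#' below the inverse sampling fraction `M_ss_plus / S_plus` are therefore
#' likely to be missed even while alive -- the origin of apparent
#' extinction--resurrection events.
#'
#' @param m_i Peripheral cells of the clone (cells).
#' @param S_plus Tagged sample size (cells).
#' @param M_ss_plus Tagged peripheral pool (cells).
#' @return Probability of observing zero cells of the clone.
#' @export
detection_probability <- function(m_i, S_plus, M_ss_plus) {
  stopifnot(all(m_i >= 0), all(S_plus >= 0), all(M_ss_plus > 0))
  exp(-m_i * S_plus / M_ss_plus)
}

#' Sampling-only null model of clone variability
#'
#' Holds each clone's peripheral population fixed at
#' `m_i = y_hat_i * M_ss_plus` and redraws the blood samples alone,
#' quantifying how much sample-to-sample variability pure binomial
#' subsampling can generate.  Comparing the resulting per-clone standard
#' deviations with observed ones tests the null hypothesis that clone
#' fluctuations arise from sampling noise only.
#'
#' @param y_hat Mean relative abundances (sum at most 1).
#' @param design An [experiment_design()].
#' @param n_replicates Number of independent resampling replicates.
#' @param seed Integer RNG seed.
#' @return A data.frame with one row per clone and replicate: `clone`,
#'   `replicate`, mean abundance `y` and temporal standard deviation
#'   `sigma` (population form, divisor J).
#' @export
sampling_only_null <- function(y_hat, design, n_replicates = 1, seed) {
  # realized tagged totals of independent binomials can exceed the
  # nominal sample size, so data-derived y_hat may sum slightly above 1
  stopifnot(inherits(design, "experiment_design"),
            all(y_hat >= 0), all(y_hat <= 1), sum(y_hat) <= 1.1,
            n_replicates >= 1)
  m <- outer(y_hat * design$M_ss_plus, rep(1, length(design$t_months)))
  J <- length(design$t_months)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ab <- sample_blood(m, design, seed = substream_seed(seed, r))
    f <- ab$fractions
    y <- rowMeans(f)
    sigma <- sqrt(rowMeans((f - y)^2))
    out[[r]] <- data.frame(clone = seq_along(y_hat), replicate = r,
                           y = y, sigma = sigma, row.names = NULL)
  }
  do.call(rbind, out)
}
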