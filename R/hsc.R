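#' Stem-cell birth--death rate parameters
#'
#' Parameters of the logistic self-renewal model for the tagged
#' hematopoietic stem cell (HSC) pool: each HSC divides symmetrically at a
#' population-regulated rate `p_h * (1 - H/K_h)` and dies at constant rate
#' `mu_h`.  All rates are per day.
#'
#' @param p_h Maximal self-renewal rate (1/day).
#' @param K_h Carrying capacity of the HSC pool (cells).
#' @param mu_h HSC death rate (1/day).
#' @param H0 Initial number of transplanted tagged HSCs (each carrying a
#'   distinct tag, so every clone starts at size 1).
#' @return An object of class `hsc_rates`.
#' @export
hsc_rates <- function(p_h, K_h, mu_h, H0 = 1) {
  stopifnot(is.numeric(p_h), is.numeric(K_h), is.numeric(mu_h))
  if (p_h < 0 || mu_h < 0) stop("rates must be non-negative")
  if (K_h <= 0) stop("K_h must be positive")
  if (H0 < 1) stop("H0 must be at least 1")
  structure(list(p_h = p_h, K_h = K_h, mu_h = mu_h, H0 = H0),
            class = "hsc_rates")
}

#' Geometric clone-size law for surviving HSC clones
#'
#' After a period of stochastic self-renewal the size distribution of a
#' surviving HSC clone is geometric on \{1, 2, ...\} with success
#' probability `1 - lam`: `P(h) = (1 - lam) * lam^(h - 1)`.  The shape
#' factor `lam` in \[0, 1) controls the breadth of clone-size
#' heterogeneity (`lam = 0`: all clones size 1; `lam -> 1`: extremely
#' broad).
#'
#' @param lam Geometric shape factor, `0 <= lam < 1`.
#' @param C_h Number of surviving tagged HSC clones.
#' @return An object of class `hsc_clone_law`.
#' @export
hsc_clone_law <- function(lam, C_h) {
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) ||
      lam < 0 || lam >= 1) {
    stop("lam must be a single number in [0, 1)")
  }
  if (C_h < 1 || C_h != round(C_h)) stop("C_h must be a positive integer")
  structure(list(lam = lam, C_h = as.integer(C_h)),
            class = "hsc_clone_law")
}

#' Probability mass of the surviving-clone size law
#'
#' @param law An [hsc_clone_law()].
#' @param h Clone size(s), positive integers.
#' @return `P(h) = (1 - lam) * lam^(h - 1)`.
#' @export
hsc_clone_pmf <- function(law, h) {
  stopifnot(inherits(law, "hsc_clone_law"))
  if (any(h < 1) || any(h != round(h))) stop("h must be a positive integer")
  (1 - law$lam) * law$lam^(h - 1)
}

#' Draw a configuration of tagged HSC clone sizes
#'
#' Draws `C_h` i.i.d. clone sizes from the geometric law conditioned on
#' survival (size at least 1).
#'
#' @param law An [hsc_clone_law()].
#' @param seed Integer RNG seed; the same seed reproduces the same
#'   configuration.
#' @return An object of class `hsc_config`: list with integer vector `h`
#'   (length `C_h`, all entries >= 1) and `H_plus = sum(h)`.
#' @export
draw_hsc_config <- function(law, seed) {
  stopifnot(inherits(law, "hsc_clone_law"))
  set.seed(as.integer(seed))
  h <- stats::rgeom(law$C_h, prob = 1 - law$lam) + 1L
  new_hsc_config(h)
}

new_hsc_config <- function(h) {
  stopifnot(all(h >= 1), all(h == round(h)))
  structure(list(h = as.numeric(h), H_plus = sum(h)), class = "hsc_config")
}

#' Build a clone-size configuration proportional to observed abundances
#'
#' Sets `h_i` proportional to mean observed abundances `y_hat_i`, scaled
#' so the tagged pool totals approximately `H_plus`, rounded half-up with
#' a floor of one cell per clone.  This is the alternative to drawing from
#' the geometric law when per-clone abundance estimates exist.
#'
#' @param y_hat Mean relative abundances (any non-negative weights).
#' @param H_plus Target total tagged HSC pool size (cells).
#' @return An `hsc_config`.
#' @export
config_from_abundance <- function(y_hat, H_plus) {
  if (any(y_hat < 0)) stop("y_hat must be non-negative")
  if (sum(y_hat) <= 0) stop("y_hat must have positive total")
  h <- floor(y_hat / sum(y_hat) * H_plus + 0.5)
  new_hsc_config(pmax(h, 1))
}

#' @export
print.hsc_config <- function(x, ...) {
  cat("<hsc_config> ", length(x$h), " clones, H+ = ", x$H_plus,
      ", max h = ", max(x$h), "\n", sep = "")
  invisible(x)
}

#' Write / read a clone-size configuration as two-column TSV
#'
#' @param config An `hsc_config`.
#' @param path File path.
#' @return `write_hsc_config` returns `path` invisibly;
#'   `read_hsc_config` returns an `hsc_config`.
#' @export
write_hsc_config <- function(config, path) {
  stopifnot(inherits(config, "hsc_config"))
  utils::write.table(
    data.frame(clone_id = seq_along(config$h), h = config$h),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hsc_config
#' @export
read_hsc_config <- function(path) {
  d <- utils::read.delim(path)
  new_hsc_config(d$h)
}

#' Mean extinction time of an HSC clone
#'
#' Under near-critical homeostasis (self-renewal rate balancing death rate
#' `mu_h`), the mean time for a clone of initial size `h` in a pool of
#' steady-state size `H_ss` to hit the absorbing state 0 is approximately
#' `(h / mu_h) * (1 + log(H_ss / h))` days.  This slow coarsening
#' timescale justifies holding the clone configuration static over an
#' experiment lasting a few years.
#'
#' @param h Initial clone size, `1 <= h <= H_ss`.
#' @param mu_h HSC death rate (1/day), positive.
#' @param H_ss Steady-state HSC pool size.
#' @return Mean extinction time in days.
#' @export
mean_extinction_time <- function(h, mu_h, H_ss) {
  if (any(mu_h <= 0)) stop("mu_h must be positive")
  if (any(h < 1) || any(h > H_ss)) stop("h must lie in [1, H_ss]")
  (h / mu_h) * (1 + log(H_ss / h))
}

#' Exact stochastic simulation of HSC clone birth--death trajectories
#'
#' Event-driven simulation of independent linear birth--death clones with
#' a shared time-dependent per-cell birth rate
#' `r_h(t) = p_h * (1 - H(t) / K_h)` where `H(t)` follows the
#' deterministic logistic solution of the lumped pool equation, and
#' constant death rate `mu_h`.  Each clone starts at size 1 (one founder
#' cell per tag) and 0 is absorbing.  Used as a validation oracle for the
#' geometric clone-size law, not in the inference path.
#'
#' @param rates An [hsc_rates()].
#' @param n_clones Number of independent clones.
#' @param t_end End time (days).
#' @param seed Master seed; each clone gets an independent sub-stream.
#' @param record_times Times (days) at which sizes are recorded; defaults
#'   to `t_end` only.
#' @return Integer matrix of clone sizes, `n_clones` rows by
#'   `length(record_times)` columns.
#' @export
simulate_hsc_birth_death <- function(rates, n_clones, t_end, seed,
                                     record_times = t_end) {
  stopifnot(inherits(rates, "hsc_rates"), t_end > 0)
  record_times <- sort(record_times)
  stopifnot(max(record_times) <= t_end)
  H_t <- logistic_pool(rates)
  birth <- function(t) max(0, rates$p_h * (1 - H_t(t) / rates$K_h))
  r_max <- rates$p_h  # bound for thinning
  out <- matrix(0L, n_clones, length(record_times))
  for (i in seq_len(n_clones)) {
    set.seed(substream_seed(seed, i))
    h <- 1L
    t <- 0
    rec <- 1L
    repeat {
      if (h == 0L) break
      total_max <- h * (r_max + rates$mu_h)
      if (total_max <= 0) break
      t <- t + stats::rexp(1, total_max)
      if (t > t_end) break
      while (rec <= length(record_times) && record_times[rec] < t) {
        out[i, rec] <- h
        rec <- rec + 1L
      }
      # thinning: accept a proposed event with prob (actual rate / bound)
      b <- birth(t)
      u <- stats::runif(1) * (r_max + rates$mu_h)
      if (u < b) h <- h + 1L
      else if (u < b + rates$mu_h) h <- h - 1L
    }
    if (rec <= length(record_times)) out[i, rec:length(record_times)] <- h
  }
  colnames(out) <- paste0("t", record_times)
  out
}

# Deterministic logistic solution of the lumped HSC pool:
# dH/dt = (p_h (1 - H/K_h) - mu_h) H.  Net logistic with growth
# rho = p_h - mu_h and capacity K_h (1 - mu_h/p_h) when p_h > mu_h.
logistic_pool <- function(rates) {
  p <- rates$p_h; K <- rates$K_h; mu <- rates$mu_h; H0 <- rates$H0
  rho <- p - mu
  if (p <= 0) return(function(t) H0 * exp(-mu * t))
  if (abs(rho) < 1e-12) {
    # critical: dH/dt = -p H^2 / K
    return(function(t) H0 / (1 + p * H0 * t / K))
  }
  Keff <- K * rho / p
  function(t) Keff / (1 + (Keff / H0 - 1) * exp(-rho * t))
}

# Deterministic per-clone sub-stream seeds: a 32-bit mix of the master
# seed and the stream index, so adding clones never perturbs the draws of
# existing ones.
substream_seed <- function(seed, i) {
  x <- (as.double(seed) * 69069 + as.double(i) * 1234567) %% 2147483647
  as.integer(x)
}
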