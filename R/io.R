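#' Write an abundance matrix and its sample metadata as TSV
#'
#' The matrix file has a `clone_id` first column and one column per
#' sampling month (numeric headers); the sidecar metadata table has one
#' row per sample with `t_months`, `S_plus`, `M_ss_plus` and optionally
#' `egfp_fraction`.  Zero entries are written as literal 0 (absence is
#' exact-zero semantics).  Counts are written; fractions are recovered
#' as `counts / S_plus` on read, so the round trip is lossless.
#'
#' @param ab An `abundance_matrix`.
#' @param path Matrix TSV path.
#' @param meta_path Metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(ab, path, meta_path) {
  stopifnot(inherits(ab, "abundance_matrix"))
  d <- data.frame(clone_id = rownames(ab$counts), ab$counts,
                  check.names = FALSE)
  colnames(d) <- c("clone_id", ab$design$t_months)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(t_months = ab$design$t_months,
                     S_plus = ab$design$S_plus,
                     M_ss_plus = ab$design$M_ss_plus)
  if (!is.null(ab$design$egfp_fraction)) {
    meta$egfp_fraction <- ab$design$egfp_fraction
  }
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix with sample metadata
#'
#' Accepts either integer counts or fractions in the value cells; when
#' fractions are supplied, counts are reconstructed as
#' `round(f * S_plus)` and the reconstruction is flagged with a message.
#'
#' @param path Matrix TSV: `clone_id` first column, numeric month
#'   headers.
#' @param meta_path Metadata TSV keyed by `t_months`.
#' @return An `abundance_matrix`.
#' @export
read_abundance <- function(path, meta_path) {
  if (!file.exists(path)) stop("abundance file not found: ", path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  d <- utils::read.delim(path, check.names = FALSE)
  if (colnames(d)[1] != "clone_id") {
    stop("first column of ", path, " must be 'clone_id'")
  }
  ids <- as.character(d$clone_id)
  if (anyDuplicated(ids)) {
    stop("duplicate clone id: ", ids[duplicated(ids)][1])
  }
  months <- suppressWarnings(as.numeric(colnames(d)[-1]))
  if (any(is.na(months))) stop("column headers must be numeric months")
  if (any(diff(months) <= 0)) stop("months must be strictly increasing")
  vals <- as.matrix(d[, -1, drop = FALSE])
  if (any(is.na(vals))) stop("missing or non-numeric values in ", path)
  if (any(vals < 0)) stop("negative abundance values in ", path)

  meta <- utils::read.delim(meta_path)
  need <- c("t_months", "S_plus", "M_ss_plus")
  if (!all(need %in% colnames(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (!isTRUE(all.equal(sort(meta$t_months), months))) {
    stop("months in matrix and metadata do not match")
  }
  meta <- meta[order(meta$t_months), ]
  design <- experiment_design(
    meta$t_months, meta$S_plus, meta$M_ss_plus[1],
    if ("egfp_fraction" %in% colnames(meta)) meta$egfp_fraction[1])

  if (all(vals == round(vals)) && any(vals > 1)) {
    counts <- vals
  } else {
    if (any(vals > 1)) stop("fraction values above 1 in ", path)
    counts <- round(sweep(vals, 2, design$S_plus, "*"))
    message("values read as fractions; counts reconstructed as ",
            "round(f * S_plus)")
  }
  rownames(counts) <- ids
  new_abundance_matrix(counts, sweep(counts, 2, design$S_plus, "/"),
                       design)
}

#' Export summary statistics tables as TSV
#'
#' @param stats A `clone_summaries` object.
#' @param path Per-clone table path (clone, y, sigma, z).
#' @param yz_path Optional `Y_z`-by-bin table path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(stats, path, yz_path = NULL) {
  stopifnot(inherits(stats, "clone_summaries"))
  utils::write.table(
    data.frame(clone_id = names(stats$y), y = stats$y,
               sigma = stats$sigma, z = stats$z),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(yz_path)) {
    utils::write.table(
      data.frame(z = seq_along(stats$Y) - 1, Y = stats$Y,
                 n_clones = stats$bin_counts),
      yz_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
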