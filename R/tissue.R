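#' Intron-by-sample count matrix with a tissue map
#'
#' Container for the tissue-specificity tests: a read-count matrix (rows =
#' introns, columns = samples), a sample-to-tissue assignment, and the three
#' test thresholds.
#'
#' @param counts numeric matrix, rownames = intron ids, colnames = samples.
#' @param sample_tissue named character vector mapping every sample (name)
#'   to exactly one tissue (value).
#' @param presence_read_min reads for a sample to count as expressing the
#'   intron (default 10).
#' @param presence_sample_frac fraction of a tissue's samples that must
#'   express the intron for tissue-level presence (default 0.15).
#' @param absence_expected_frac expected absent fraction per tissue under
#'   the null of the absence test (default 0.85).
#' @return list of class \code{"tissue_count_matrix"}.
#' @export
tissue_count_matrix <- function(counts, sample_tissue,
                                presence_read_min = 10,
                                presence_sample_frac = 0.15,
                                absence_expected_frac = 0.85) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)),
            !is.null(rownames(counts)))
  if (!all(colnames(counts) %in% names(sample_tissue)))
    stop("every sample must map to exactly one tissue")
  if (presence_sample_frac <= 0 || presence_sample_frac > 1 ||
      absence_expected_frac <= 0 || absence_expected_frac > 1)
    stop("fraction thresholds must lie in (0, 1]")
  if (presence_read_min < 1) stop("presence_read_min must be >= 1")
  structure(list(counts = counts,
                 sample_tissue = sample_tissue[colnames(counts)],
                 presence_read_min = presence_read_min,
                 presence_sample_frac = presence_sample_frac,
                 absence_expected_frac = absence_expected_frac),
            class = "tissue_count_matrix")
}

#' Tissue-level presence test for an intron
#'
#' The intron is present in a tissue iff at least
#' \code{presence_sample_frac} of that tissue's samples have
#' \code{>= presence_read_min} reads (boundary inclusive: 15\% exactly
#' passes).
#'
#' @param m a [tissue_count_matrix()].
#' @param intron intron id (rowname).
#' @param tissue tissue name.
#' @return logical.
#' @export
presence_test <- function(m, intron, tissue) {
  sel <- m$sample_tissue == tissue
  if (!any(sel)) stop("unknown tissue: ", tissue)
  x <- m$counts[intron, sel]
  mean(x >= m$presence_read_min) >= m$presence_sample_frac
}

#' Chi-square absence test for an intron
#'
#' For each tissue t with N_t samples, the expected number of samples from
#' which the intron is absent is \code{E_t = absence_expected_frac * N_t}
#' (kept fractional) and the observed number O_t counts samples with fewer
#' than \code{presence_read_min} reads. Columns with \code{O_t < E_t} —
#' tissues absent only at the margin of error — are dropped, and the
#' goodness-of-fit statistic \code{sum((O-E)^2 / E)} over the retained
#' columns is referred to a chi-square with \code{k - 1} degrees of freedom.
#' Fewer than 2 retained columns cannot reject and return p = 1 (with
#' attribute \code{degenerate = TRUE} when none are retained).
#'
#' @param m a [tissue_count_matrix()] with at least 2 tissues.
#' @param intron intron id.
#' @param variant \code{"gof"} (default) or \code{"independence"}, the
#'   2-by-k contingency reading of the same table.
#' @return p-value in [0, 1].
#' @export
absence_test <- function(m, intron, variant = c("gof", "independence")) {
  variant <- match.arg(variant)
  tissues <- unique(m$sample_tissue)
  if (length(tissues) < 2L) stop("absence test needs >= 2 tissues")
  x <- m$counts[intron, ]
  n_t <- vapply(tissues, function(t) sum(m$sample_tissue == t), 0)
  o_t <- vapply(tissues, function(t)
    sum(x[m$sample_tissue == t] < m$presence_read_min), 0)
  e_t <- m$absence_expected_frac * n_t
  keep <- o_t >= e_t
  if (sum(keep) == 0L) {
    return(structure(1, degenerate = TRUE))
  }
  if (sum(keep) < 2L) return(1)
  o <- o_t[keep]; e <- e_t[keep]
  if (variant == "gof") {
    stat <- sum((o - e)^2 / e)
    stats::pchisq(stat, df = sum(keep) - 1L, lower.tail = FALSE)
  } else {
    suppressWarnings(stats::chisq.test(rbind(e, o))$p.value)
  }
}

#' Call an intron tissue-specific
#'
#' True iff the intron passes the presence test in the target tissue and in
#' no other tissue, and the absence test rejects at \code{p <= alpha}.
#'
#' @param m a [tissue_count_matrix()].
#' @param intron intron id.
#' @param target_tissue the tissue of interest (e.g. "brain").
#' @param alpha significance cutoff, compared inclusively (default 0.001).
#' @return logical.
#' @export
call_tissue_specific <- function(m, intron, target_tissue, alpha = 0.001) {
  tissues <- unique(m$sample_tissue)
  pres <- vapply(tissues, function(t) presence_test(m, intron, t),
                 logical(1L))
  if (!(pres[[target_tissue]] && sum(pres) == 1L)) return(FALSE)
  as.numeric(absence_test(m, intron)) <= alpha
}
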