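#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around \code{\link[stats]{ks.test}} returning the supremum
#' absolute difference D of the two empirical CDFs and the two-sided
#' p-value. Per-CDS codon percentages are heavily tied (counts are small
#' integers), and the asymptotic p-value is then severely conservative —
#' its type-I rate collapses to well under 0.01 at the nominal 0.05 — so
#' by default the exact method is used whenever the product of the two
#' sample sizes is at most \code{exact_limit} (the exact two-sample
#' distribution is permutation-exact in the presence of ties). D itself is
#' always the exact ECDF supremum. If all values of both samples are
#' identical (e.g. a codon absent from every CDS) the test is degenerate
#' and (D = 0, p = 1) is returned rather than an error.
#'
#' @param sample_a,sample_b Numeric vectors (per-CDS codon percentages).
#' @param exact \code{NULL} (default) chooses the exact method when
#'   \code{length(sample_a) * length(sample_b) <= exact_limit}; TRUE/FALSE
#'   force it.
#' @param exact_limit Size-product cutoff for the automatic exact method
#'   (default 40000, i.e. up to 200 vs 200).
#' @return List with elements \code{D} and \code{p_value}.
#' @export
#' @examples
#' ks_two_sample(c(1, 2, 3, 4), c(3, 4, 5, 6))$D   # 0.5
ks_two_sample <- function(sample_a, sample_b, exact = NULL,
                          exact_limit = 40000) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pooled <- c(sample_a, sample_b)
  if (all(pooled == pooled[1])) {
    return(list(D = 0, p_value = 1))
  }
  if (is.null(exact)) {
    exact <- length(sample_a) * length(sample_b) <= exact_limit
  }
  res <- suppressWarnings(
    stats::ks.test(sample_a, sample_b, exact = exact)
  )
  list(D = unname(res$statistic), p_value = unname(res$p.value))
}

#' Enumerate statistically significant codons
#'
#' Runs the two-sample KS test per codon, comparing the N extremophile
#' percentage values against the N counterpart values, and flags codons
#' with p-value below \code{alpha} (the study threshold is 0.05). The
#' samples enter the test unpaired even though the data arrive as
#' homologous pairs (KS is a two-sample test), which makes the filter
#' conservative on paired designs. No multiple-testing correction is
#' applied by default, matching the raw per-codon threshold; a
#' Benjamini-Hochberg adjustment can be switched on via
#' \code{p_adjust = "BH"}, in which case significance is judged on the
#' adjusted values.
#'
#' @param paired A \code{paired_dataset}.
#' @param alpha Significance level (default 0.05).
#' @param exact Exact-method control, see \code{\link{ks_two_sample}}
#'   (default NULL = automatic).
#' @param p_adjust Multiple-testing correction method, \code{"none"}
#'   (default) or any method accepted by \code{\link[stats]{p.adjust}}.
#' @return Object of class \code{sig_codon_set}: data.frame with one row
#'   per codon (canonical order) and columns \code{codon}, \code{D},
#'   \code{p_value}, \code{significant}; attributes \code{dataset_label},
#'   \code{alpha}, \code{n_significant}.
#' @export
filter_significant <- function(paired, alpha = 0.05, exact = NULL,
                               p_adjust = "none") {
  stopifnot(inherits(paired, "paired_dataset"))
  if (paired$n_pairs < 2) {
    stop("at least 2 pairs are required for the KS test", call. = FALSE)
  }
  res <- lapply(seq_len(64), function(j) {
    ks_two_sample(paired$matrix_e[, j], paired$matrix_ne[, j], exact = exact)
  })
  df <- data.frame(
    codon = .codons(),
    D = vapply(res, `[[`, numeric(1), "D"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  p_for_call <- df$p_value
  if (!identical(p_adjust, "none")) {
    df$p_adjusted <- stats::p.adjust(df$p_value, method = p_adjust)
    p_for_call <- df$p_adjusted
  }
  df$significant <- p_for_call < alpha
  structure(df,
            dataset_label = paired$dataset_label,
            alpha = alpha,
            n_significant = sum(df$significant),
            class = c("sig_codon_set", "data.frame"))
}

#' Significant codons of a filter result
#'
#' @param sigset A \code{sig_codon_set}.
#' @return Character vector of significant codons in canonical order.
#' @export
significant_codons <- function(sigset) {
  stopifnot(inherits(sigset, "sig_codon_set"))
  sigset$codon[sigset$significant]
}

#' @export
print.sig_codon_set <- function(x, ...) {
  cat(sprintf("<sig_codon_set> %s: %d of 64 codons significant at alpha = %g\n",
              attr(x, "dataset_label"), attr(x, "n_significant"),
              attr(x, "alpha")))
  sig <- significant_codons(x)
  if (length(sig) > 0) cat(" ", paste(sig, collapse = " "), "\n")
  invisible(x)
}
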