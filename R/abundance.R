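#' Relative abundance of significant codons
#'
#' For each statistically significant codon j the class means over the N
#' homologous pairs are formed,
#' \deqn{\bar\alpha_e = \frac{1}{N}\sum_i (\alpha_e)_i, \qquad
#'       \bar\alpha_{ne} = \frac{1}{N}\sum_i (\alpha_{ne})_i,}
#' their difference \eqn{\alpha_j = \bar\alpha_e - \bar\alpha_{ne}} is taken
#' and normalised by the maximum difference over the significant set,
#' \deqn{\beta_{rel} = \alpha_j / \alpha_{max}.}
#' By default \eqn{\alpha_{max}} is the maximum \emph{absolute} difference,
#' which bounds \eqn{\beta_{rel}} in [-1, 1] and preserves its sign; with
#' \code{alpha_max = "signed"} the literal signed maximum is used instead,
#' which leaves \eqn{\beta_{rel}} unbounded below when differences of both
#' signs occur. Codons with \eqn{\beta_{rel} > 0} are positive contributors
#' to the extremophile class.
#'
#' @param paired A \code{paired_dataset}.
#' @param sigset A \code{sig_codon_set} (or character vector of codons).
#' @param alpha_max \code{"absolute"} (default) or \code{"signed"}.
#' @return Object of class \code{abundance_result}: data.frame with
#'   columns \code{codon}, \code{mean_e}, \code{mean_ne}, \code{diff},
#'   \code{beta_rel}; attributes \code{alpha_max}, \code{dataset_label}.
#' @export
relative_abundance <- function(paired, sigset,
                               alpha_max = c("absolute", "signed")) {
  alpha_max <- match.arg(alpha_max)
  stopifnot(inherits(paired, "paired_dataset"))
  codons <- if (inherits(sigset, "sig_codon_set")) {
    significant_codons(sigset)
  } else {
    as.character(sigset)
  }
  if (length(codons) == 0) {
    stop("significant codon set is empty; nothing to rank", call. = FALSE)
  }
  bad <- setdiff(codons, .codons())
  if (length(bad) > 0) {
    stop(sprintf("invalid codon(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  mean_e <- colMeans(paired$matrix_e[, codons, drop = FALSE])
  mean_ne <- colMeans(paired$matrix_ne[, codons, drop = FALSE])
  diff <- mean_e - mean_ne
  amax <- if (alpha_max == "absolute") max(abs(diff)) else max(diff)
  if (amax == 0) {
    warning("all weighted-average differences are zero; beta_rel set to 0",
            call. = FALSE)
    beta <- rep(0, length(diff))
  } else {
    beta <- diff / amax
  }
  structure(
    data.frame(codon = codons, mean_e = unname(mean_e),
               mean_ne = unname(mean_ne), diff = unname(diff),
               beta_rel = unname(beta), stringsAsFactors = FALSE),
    alpha_max = amax,
    alpha_max_convention = alpha_max,
    dataset_label = paired$dataset_label,
    class = c("abundance_result", "data.frame")
  )
}

#' Positive contributors of an abundance result
#'
#' Codons whose relative abundance is strictly positive, i.e. preferred by
#' the extremophile side of the comparison.
#'
#' @param abundance An \code{abundance_result}.
#' @return Character vector of codons.
#' @export
positive_contributors <- function(abundance) {
  stopifnot(inherits(abundance, "abundance_result"))
  abundance$codon[abundance$beta_rel > 0]
}

#' @export
print.abundance_result <- function(x, ...) {
  cat(sprintf("<abundance_result> %s: %d significant codons, %d positive contributors (alpha_max = %.4g)\n",
              attr(x, "dataset_label"), nrow(x),
              sum(x$beta_rel > 0), attr(x, "alpha_max")))
  invisible(x)
}

# Eq-5 style min-max interval scaling of ratio weights onto [1, 9].
# Integer ranks use round-half-up so the scale endpoints stay at 1 and 9.
.scale_1_9 <- function(xi) {
  a <- min(xi)
  b <- max(xi)
  if (b == a) {
    warning("all ratio weights equal; every codon assigned mid-scale rank 5",
            call. = FALSE)
    W <- rep(5, length(xi))
  } else {
    W <- (xi - a) / (b - a) * 8 + 1
  }
  list(W = W, rank = as.integer(floor(W + 0.5)), alpha_min = a, beta_max = b)
}

#' Rank significant codons on the 1-9 preference scale
#'
#' The ratio weight of codon i is \eqn{\xi_i = \bar\alpha_e /
#' \bar\alpha_{ne}} (extremophile over counterpart mean percentage). Ratio
#' weights are mapped onto the 1-9 interval scale by min-max scaling,
#' \deqn{W_i = \frac{\xi_i - \alpha}{\beta - \alpha} \times 8 + 1,}
#' with \eqn{\alpha = \min_i \xi_i} and \eqn{\beta = \max_i \xi_i}, so the
#' most extremophile-preferred codon scores 9 and the least scores 1.
#' Integer ranks are \code{W} rounded half-up. A zero counterpart mean
#' would make the ratio undefined; such codons receive a pseudocount of
#' half the smallest non-zero class mean in the table, and the fallback is
#' reported via a warning and the \code{pseudocount} column.
#'
#' @param x An \code{abundance_result}, or a named numeric vector of ratio
#'   weights (names are codons).
#' @param ... Unused.
#' @return Object of class \code{rank_table}: data.frame with columns
#'   \code{codon}, \code{xi}, \code{W}, \code{rank} (and
#'   \code{pseudocount} when triggered); attributes \code{alpha_min},
#'   \code{beta_max}.
#' @export
#' @examples
#' rank_codons(c(CAA = 0.5, ACC = 1.0, AGG = 1.5))$rank   # 1 5 9
rank_codons <- function(x, ...) UseMethod("rank_codons")

#' @rdname rank_codons
#' @export
rank_codons.abundance_result <- function(x, ...) {
  mean_ne <- x$mean_ne
  mean_e <- x$mean_e
  pseudo <- rep(FALSE, nrow(x))
  if (any(mean_ne == 0)) {
    nz <- c(mean_e, mean_ne)
    nz <- nz[nz > 0]
    if (length(nz) == 0) {
      stop("all class means are zero; ratio weights undefined", call. = FALSE)
    }
    pc <- min(nz) / 2
    pseudo <- mean_ne == 0
    warning(sprintf("%d codon(s) with zero counterpart mean given pseudocount %.4g",
                    sum(pseudo), pc), call. = FALSE)
    mean_ne[pseudo] <- pc
    mean_e[pseudo & x$mean_e == 0] <- pc
  }
  xi <- mean_e / mean_ne
  names(xi) <- x$codon
  out <- rank_codons.numeric(xi)
  if (any(pseudo)) out$pseudocount <- pseudo
  attr(out, "dataset_label") <- attr(x, "dataset_label")
  out
}

#' @rdname rank_codons
#' @export
rank_codons.numeric <- function(x, ...) {
  if (length(x) == 0) stop("no ratio weights supplied", call. = FALSE)
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("feature_", seq_along(x))
  sc <- .scale_1_9(x)
  structure(
    data.frame(codon = nm, xi = unname(x), W = sc$W, rank = sc$rank,
               stringsAsFactors = FALSE),
    alpha_min = sc$alpha_min,
    beta_max = sc$beta_max,
    class = c("rank_table", "data.frame")
  )
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("<rank_table> %d codons; xi in [%.4g, %.4g]\n", nrow(x),
              attr(x, "alpha_min"), attr(x, "beta_max")))
  ex <- extreme_codons(x)
  cat(sprintf("  highest (rank %d): %s   lowest (rank %d): %s\n",
              max(x$rank), ex$highest, min(x$rank), ex$lowest))
  invisible(x)
}

#' Highest- and lowest-ranked codons
#'
#' Returns the codons with the maximal and minimal continuous scale value
#' W. Exact ties are broken lexicographically on the codon string.
#'
#' @param ranks A \code{rank_table}.
#' @return List with elements \code{highest} and \code{lowest}.
#' @export
extreme_codons <- function(ranks) {
  stopifnot(inherits(ranks, "rank_table"), nrow(ranks) > 0)
  hi <- ranks$codon[ranks$W == max(ranks$W)]
  lo <- ranks$codon[ranks$W == min(ranks$W)]
  list(highest = sort(hi)[1], lowest = sort(lo)[1])
}

#' Normalised per-pair data-point series for one codon
#'
#' Extracts the raw per-CDS percentage of a codon for both classes and
#' divides by the global maximum over the union, giving scores in [0, 1]
#' with the maximal data-point at exactly 1. If every raw value is zero the
#' series is returned as-is with a warning (no division).
#'
#' @param paired A \code{paired_dataset}.
#' @param codon A single codon.
#' @return Object of class \code{datapoint_series}: data.frame with
#'   columns \code{pair_id}, \code{value_e}, \code{value_ne}; attribute
#'   \code{codon}.
#' @export
datapoint_series <- function(paired, codon) {
  stopifnot(inherits(paired, "paired_dataset"))
  if (!(codon %in% .codons())) {
    stop(sprintf("invalid codon: %s", codon), call. = FALSE)
  }
  ve <- paired$matrix_e[, codon]
  vn <- paired$matrix_ne[, codon]
  m <- max(ve, vn)
  if (m == 0) {
    warning(sprintf("codon %s absent from every CDS; series left at zero", codon),
            call. = FALSE)
  } else {
    ve <- ve / m
    vn <- vn / m
  }
  structure(
    data.frame(pair_id = paired$pair_ids, value_e = unname(ve),
               value_ne = unname(vn), stringsAsFactors = FALSE),
    codon = codon,
    dataset_label = paired$dataset_label,
    class = c("datapoint_series", "data.frame")
  )
}
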