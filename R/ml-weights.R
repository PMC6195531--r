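#' Build a pooled feature table for classification
#'
#' Stacks the extremophile and counterpart rows of a paired dataset into
#' one table (2N rows), keeping the percentage columns of the requested
#' codons (typically the statistically significant ones) plus a class
#' label factor.
#'
#' @param paired A \code{paired_dataset}.
#' @param codons A \code{sig_codon_set}, a character vector of codons, or
#'   NULL for all 64.
#' @return Object of class \code{feature_table}: data.frame whose feature
#'   columns are codon strings and whose last column \code{label} is a
#'   two-level factor.
#' @export
feature_table <- function(paired, codons = NULL) {
  stopifnot(inherits(paired, "paired_dataset"))
  if (is.null(codons)) {
    codons <- .codons()
  } else if (inherits(codons, "sig_codon_set")) {
    codons <- significant_codons(codons)
  }
  if (length(codons) == 0) {
    stop("no feature codons supplied (empty significant set?)", call. = FALSE)
  }
  .check_codons(codons)
  x <- rbind(paired$matrix_e[, codons, drop = FALSE],
             paired$matrix_ne[, codons, drop = FALSE])
  df <- as.data.frame(x, check.names = FALSE)
  df$label <- factor(rep(c(paired$label_e, paired$label_ne),
                         each = paired$n_pairs),
                     levels = c(paired$label_e, paired$label_ne))
  rownames(df) <- NULL
  structure(df, dataset_label = paired$dataset_label,
            class = c("feature_table", "data.frame"))
}

.entropy2 <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -(p * log2(p) + (1 - p) * log2(1 - p)))
}

.entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

.gini_counts <- function(counts) {
  p <- counts / sum(counts)
  1 - sum(p^2)
}

# equal-frequency discretisation into at most `bins` bins
.ef_bins <- function(x, bins = 5) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7)
  brk <- unique(qs)
  if (length(brk) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = brk, include.lowest = TRUE))
}

# raw (unnormalised) weight of one feature under one algorithm
.raw_weight <- function(alg, x, y01, bins) {
  b <- .ef_bins(x, bins)
  tab <- table(b, y01)
  n <- length(y01)
  Hy <- .entropy_counts(table(y01))
  cond <- function(fun) {
    sum(vapply(rownames(tab), function(r) {
      sum(tab[r, ]) / n * fun(tab[r, ])
    }, numeric(1)))
  }
  switch(alg,
    chisq = {
      if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
      e <- outer(rowSums(tab), colSums(tab)) / n
      sum((tab - e)^2 / e)
    },
    infogain = Hy - cond(.entropy_counts),
    gainratio = {
      Hb <- .entropy_counts(table(b))
      if (Hb == 0) 0 else (Hy - cond(.entropy_counts)) / Hb
    },
    gini = .gini_counts(table(y01)) - cond(.gini_counts),
    correlation = {
      if (stats::sd(x) == 0) 0 else abs(stats::cor(x, y01))
    },
    uncertainty = {
      Hb <- .entropy_counts(table(b))
      if (Hy + Hb == 0) 0 else 2 * (Hy - cond(.entropy_counts)) / (Hy + Hb)
    },
    stop(sprintf("unknown weighting algorithm: %s", alg), call. = FALSE)
  )
}

# Relief with one nearest hit/miss per instance, all instances used;
# features range-normalised, neighbours found in the full feature space.
# Negative relevances are clipped to zero (at-or-below-chance features).
.relief_weights <- function(x, y01) {
  rng <- apply(x, 2, function(v) diff(range(v)))
  keep <- rng > 0
  xs <- x
  xs[, keep] <- sweep(sweep(x[, keep, drop = FALSE], 2,
                            apply(x[, keep, drop = FALSE], 2, min)),
                      2, rng[keep], "/")
  xs[, !keep] <- 0
  n <- nrow(xs)
  d <- as.matrix(stats::dist(xs))
  diag(d) <- Inf
  w <- numeric(ncol(xs))
  for (i in seq_len(n)) {
    same <- y01 == y01[i]
    same[i] <- FALSE
    hit <- which(same)[which.min(d[i, same])]
    miss <- which(!same)[which.min(d[i, !same])]
    w <- w - abs(xs[i, ] - xs[hit, ]) / n + abs(xs[i, ] - xs[miss, ]) / n
  }
  pmax(as.numeric(w), 0)
}

#' Attribute weighting of codon features
#'
#' Weights every feature codon by its discriminative value for the binary
#' class label, independently under several feature-weighting algorithms:
#' chi-squared statistic (on equal-frequency bins), information gain, gain
#' ratio, Gini-impurity reduction, absolute Pearson correlation, symmetric
#' uncertainty and Relief. Each algorithm's weights are min-max normalised
#' across codons into [0, 1], so every algorithm's most discriminative
#' codon scores 1 and its least scores 0. Additional weighters can be
#' plugged in as functions \code{f(x_matrix, y01)} returning one raw
#' weight per column.
#'
#' @param table A \code{feature_table}.
#' @param algorithms Subset of the built-in algorithm names.
#' @param bins Number of equal-frequency bins for the discretising
#'   algorithms (default 5).
#' @param custom Optional named list of plug-in weighting functions.
#' @return Object of class \code{weight_matrix}: numeric matrix codon x
#'   algorithm with all entries in [0, 1].
#' @export
attribute_weights <- function(table,
                              algorithms = c("chisq", "infogain",
                                             "gainratio", "gini",
                                             "correlation", "uncertainty",
                                             "relief"),
                              bins = 5, custom = NULL) {
  stopifnot(inherits(table, "feature_table"))
  feats <- setdiff(names(table), "label")
  y <- table$label
  if (nlevels(droplevels(y)) < 2) {
    stop("feature table must contain both classes", call. = FALSE)
  }
  if (min(table(y)) < 2) {
    stop("at least 2 rows per class are required", call. = FALSE)
  }
  y01 <- as.integer(y == levels(y)[2])
  x <- as.matrix(table[, feats, drop = FALSE])
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  raw <- sapply(algorithms, function(alg) {
    if (alg == "relief") {
      .relief_weights(x, y01)
    } else {
      vapply(feats, function(f) .raw_weight(alg, x[, f], y01, bins),
             numeric(1))
    }
  })
  if (!is.null(custom)) {
    for (nm in names(custom)) {
      raw <- cbind(raw, as.numeric(custom[[nm]](x, y01)))
      colnames(raw)[ncol(raw)] <- nm
    }
  }
  rownames(raw) <- feats
  norm <- apply(raw, 2, function(w) {
    r <- range(w)
    if (r[2] == r[1]) rep(0, length(w)) else (w - r[1]) / (r[2] - r[1])
  })
  norm <- matrix(norm, nrow = length(feats),
                 dimnames = list(feats, colnames(raw)))
  structure(norm, class = c("weight_matrix", class(norm)))
}

#' Count supporting algorithms per codon
#'
#' For each codon, the number of weighting algorithms that assigned it a
#' normalised weight at or above the threshold (default 0.5).
#'
#' @param wm A \code{weight_matrix}.
#' @param threshold Weight threshold (default 0.5).
#' @return Data frame with columns \code{codon} and \code{n_algorithms},
#'   sorted by decreasing support.
#' @export
support_counts <- function(wm, threshold = 0.5) {
  stopifnot(inherits(wm, "weight_matrix"))
  cnt <- rowSums(unclass(wm) >= threshold)
  df <- data.frame(codon = rownames(wm), n_algorithms = as.integer(cnt),
                   stringsAsFactors = FALSE)
  df[order(-df$n_algorithms, df$codon), , drop = FALSE]
}
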