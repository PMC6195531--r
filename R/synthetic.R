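#' Class-specific synonymous-codon profile
#'
#' Per amino-acid family probability vectors over that family's codons,
#' used by the synthetic generator to choose which synonymous codon encodes
#' each residue for a given class. The default background is uniform within
#' every family (including the stop family \code{"*"}); individual family
#' vectors can be overridden.
#'
#' @param overrides Optional named list: amino-acid symbol -> named
#'   probability vector over that family's codons (must sum to 1).
#' @return Object of class \code{class_codon_profile}: named list of
#'   probability vectors, one per family.
#' @export
#' @examples
#' p <- class_codon_profile()
#' p[["Q"]]   # Gln family: CAA, CAG, each 0.5
class_codon_profile <- function(overrides = NULL) {
  fams <- codon_families()
  prof <- lapply(fams, function(cs) {
    stats::setNames(rep(1 / length(cs), length(cs)), cs)
  })
  if (!is.null(overrides)) {
    for (aa in names(overrides)) {
      if (!aa %in% names(prof)) {
        stop(sprintf("unknown amino-acid symbol: %s", aa), call. = FALSE)
      }
      v <- overrides[[aa]]
      if (!setequal(names(v), names(prof[[aa]]))) {
        stop(sprintf("override for %s must name codons %s", aa,
                     paste(names(prof[[aa]]), collapse = ", ")),
             call. = FALSE)
      }
      if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
        stop(sprintf("override for %s is not a probability vector", aa),
             call. = FALSE)
      }
      prof[[aa]] <- v[names(prof[[aa]])]
    }
  }
  structure(prof, class = "class_codon_profile")
}

#' Within-family codon bias specification
#'
#' Describes a known injected bias: \code{delta} of within-family
#' probability mass is moved toward (positive) or away from (negative) the
#' target codon, the remainder being renormalised proportionally among the
#' other codons of the same family.
#'
#' @param codon Target codon.
#' @param delta Probability mass shifted (signed).
#' @return Object of class \code{bias_spec}.
#' @export
bias_spec <- function(codon, delta) {
  .check_codons(codon)
  stopifnot(is.numeric(delta), length(delta) == 1, is.finite(delta))
  structure(list(codon = codon, delta = delta), class = "bias_spec")
}

#' Apply bias specifications to a codon profile
#'
#' Adds each bias's \code{delta} to the target codon's within-family
#' probability and rescales the remaining codons of the family
#' proportionally so the family still sums to 1. Any bias that would push a
#' probability outside [0, 1] is an error, never silently clipped.
#'
#' @param background A \code{class_codon_profile}.
#' @param biases List of \code{\link{bias_spec}} objects.
#' @return A new \code{class_codon_profile}.
#' @export
#' @examples
#' p <- make_profiles(class_codon_profile(), list(bias_spec("CAG", 0.3)))
#' p[["Q"]]   # CAA 0.2, CAG 0.8
make_profiles <- function(background, biases = list()) {
  stopifnot(inherits(background, "class_codon_profile"))
  prof <- unclass(background)
  gc <- genetic_code()
  for (b in biases) {
    stopifnot(inherits(b, "bias_spec"))
    aa <- unname(gc[b$codon])
    fam <- prof[[aa]]
    p0 <- fam[b$codon]
    p1 <- p0 + b$delta
    if (p1 < 0 || p1 > 1) {
      stop(sprintf("bias %+g on %s pushes its probability to %.3f, outside [0, 1]",
                   b$delta, b$codon, p1), call. = FALSE)
    }
    others <- setdiff(names(fam), b$codon)
    rest0 <- sum(fam[others])
    rest1 <- 1 - p1
    if (length(others) > 0) {
      if (rest0 == 0 && rest1 > 0) {
        stop(sprintf("bias %+g on %s requires mass for zero-probability family members",
                     b$delta, b$codon), call. = FALSE)
      }
      if (rest1 < -1e-12) {
        stop(sprintf("bias %+g on %s would make other family codons negative",
                     b$delta, b$codon), call. = FALSE)
      }
      if (rest0 > 0) fam[others] <- fam[others] * (rest1 / rest0)
    } else if (abs(p1 - 1) > 1e-12) {
      stop(sprintf("%s is the only codon of its family; bias must be 0", b$codon),
           call. = FALSE)
    }
    fam[b$codon] <- p1
    prof[[aa]] <- fam
  }
  structure(prof, class = "class_codon_profile")
}

#' Synthetic dataset configuration
#'
#' Bundles everything the generator needs: number of homologous pairs,
#' gene length in codons, the amino-acid composition shared by each pair,
#' the two class codon profiles, whether to append a stop codon, and the
#' seed that fully determines the output.
#'
#' @param n_pairs Number of homologous pairs (>= 1).
#' @param gene_length Gene length in sense codons (>= 10).
#' @param aa_profile Named probability vector over the 20 amino acids
#'   (default uniform).
#' @param profile_e,profile_ne Codon profiles of the extremophile class and
#'   its counterpart (default uniform background).
#' @param include_stop Append one stop codon per CDS (default TRUE,
#'   mirroring full-length CDS).
#' @param seed Integer seed.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(n_pairs, gene_length = 300, aa_profile = NULL,
                         profile_e = class_codon_profile(),
                         profile_ne = class_codon_profile(),
                         include_stop = TRUE, seed = 1L) {
  problems <- character(0)
  if (!is.numeric(n_pairs) || n_pairs < 1) {
    problems <- c(problems, "n_pairs must be >= 1")
  }
  if (!is.numeric(gene_length) || gene_length < 10) {
    problems <- c(problems, "gene_length must be >= 10 codons")
  }
  aas <- setdiff(names(codon_families()), "*")
  if (is.null(aa_profile)) {
    aa_profile <- stats::setNames(rep(1 / 20, 20), aas)
  } else {
    if (!setequal(names(aa_profile), aas) || any(aa_profile < 0) ||
        abs(sum(aa_profile) - 1) > 1e-9) {
      problems <- c(problems,
                    "aa_profile must be a probability vector over the 20 amino acids")
    } else {
      aa_profile <- aa_profile[aas]
    }
  }
  if (!inherits(profile_e, "class_codon_profile")) {
    problems <- c(problems, "profile_e must be a class_codon_profile")
  }
  if (!inherits(profile_ne, "class_codon_profile")) {
    problems <- c(problems, "profile_ne must be a class_codon_profile")
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    problems <- c(problems, "seed must be a finite number")
  }
  if (length(problems) > 0) {
    stop(paste0("invalid synth_config:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  structure(
    list(n_pairs = as.integer(n_pairs), gene_length = as.integer(gene_length),
         aa_profile = aa_profile, profile_e = profile_e,
         profile_ne = profile_ne, include_stop = isTRUE(include_stop),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Vectorised encoding of an amino-acid matrix (positions x genes) into a
# codon matrix under one class profile; uses the current RNG stream.
.encode_codons <- function(aa_mat, profile) {
  cod <- matrix(NA_character_, nrow = nrow(aa_mat), ncol = ncol(aa_mat))
  for (aa in unique(as.vector(aa_mat))) {
    pos <- which(aa_mat == aa)
    fam <- profile[[aa]]
    if (length(fam) == 1) {
      cod[pos] <- names(fam)
    } else {
      cod[pos] <- sample(names(fam), length(pos), replace = TRUE, prob = fam)
    }
  }
  cod
}

#' Generate one homologous CDS pair
#'
#' Encodes the same amino-acid sequence twice, sampling each position's
#' synonymous codon independently from the respective class profile, so
#' the two CDS translate identically but differ in codon choice. Uses the
#' current RNG state.
#'
#' @param aa_sequence Character vector of amino-acid symbols (may include
#'   \code{"*"}).
#' @param profile_e,profile_ne Class codon profiles.
#' @return List with codon vectors \code{codons_e} and \code{codons_ne}.
#' @export
generate_pair <- function(aa_sequence, profile_e, profile_ne) {
  stopifnot(inherits(profile_e, "class_codon_profile"),
            inherits(profile_ne, "class_codon_profile"))
  aa_mat <- matrix(aa_sequence, ncol = 1)
  list(codons_e = as.vector(.encode_codons(aa_mat, profile_e)),
       codons_ne = as.vector(.encode_codons(aa_mat, profile_ne)))
}

#' Generate a synthetic paired dataset
#'
#' Draws \code{n_pairs} amino-acid sequences from the amino-acid profile,
#' encodes each into an extremophile CDS and a counterpart CDS under the
#' two class profiles (optionally appending one stop codon sampled from the
#' stop family), and returns records, manifest and ground truth together.
#' The same seed always yields byte-identical output.
#'
#' @param config A \code{\link{synth_config}}.
#' @param dataset_label Label for the resulting comparison (default
#'   \code{"synthetic"}).
#' @param label_e,label_ne Class labels attached to the records.
#' @return Object of class \code{synthetic_dataset}: list with
#'   \code{records} (named list of \code{cds_record}s for both classes),
#'   \code{manifest} (a \code{pair_manifest}) and \code{ground_truth}
#'   (expected per-codon percentages per class under the config).
#' @export
generate_dataset <- function(config, dataset_label = "synthetic",
                             label_e = "extremophile",
                             label_ne = "non-extremophile") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  L <- config$gene_length
  aas <- names(config$aa_profile)
  aa_mat <- matrix(sample(aas, L * n, replace = TRUE,
                          prob = config$aa_profile),
                   nrow = L, ncol = n)
  if (config$include_stop) {
    aa_mat <- rbind(aa_mat, rep("*", n))
  }
  cod_e <- .encode_codons(aa_mat, config$profile_e)
  cod_ne <- .encode_codons(aa_mat, config$profile_ne)
  wid <- nchar(as.character(n))
  pair_ids <- sprintf("pair_%0*d", wid, seq_len(n))
  ids_e <- sprintf("E_%0*d", wid, seq_len(n))
  ids_ne <- sprintf("C_%0*d", wid, seq_len(n))
  mk <- function(id, codons, lab) {
    structure(list(id = id, raw_sequence = paste(codons, collapse = ""),
                   codons = codons, class_label = lab,
                   organism = NA_character_),
              class = "cds_record")
  }
  recs <- c(
    lapply(seq_len(n), function(i) mk(ids_e[i], cod_e[, i], label_e)),
    lapply(seq_len(n), function(i) mk(ids_ne[i], cod_ne[, i], label_ne))
  )
  names(recs) <- c(ids_e, ids_ne)
  manifest <- structure(
    data.frame(pair_id = pair_ids, ext_id = ids_e, ctl_id = ids_ne,
               stringsAsFactors = FALSE),
    dataset_label = dataset_label,
    class = c("pair_manifest", "data.frame")
  )
  structure(
    list(records = recs, manifest = manifest,
         ground_truth = .ground_truth(config),
         config = config, dataset_label = dataset_label,
         label_e = label_e, label_ne = label_ne),
    class = "synthetic_dataset"
  )
}

# Closed-form expected percentage of every codon under a config: for sense
# codon c, 100 * L * p_aa(aa(c)) * p(c | family) / L_total; for stops,
# 100 * include_stop * p(c | stop family) / L_total.
.ground_truth <- function(config) {
  gc <- genetic_code()
  L <- config$gene_length
  Lt <- L + as.integer(config$include_stop)
  expected <- function(profile) {
    vapply(.codons(), function(cod) {
      aa <- unname(gc[cod])
      p_fam <- profile[[aa]][cod]
      if (aa == "*") {
        100 * as.integer(config$include_stop) * unname(p_fam) / Lt
      } else {
        100 * L * unname(config$aa_profile[aa]) * unname(p_fam) / Lt
      }
    }, numeric(1))
  }
  e <- expected(config$profile_e)
  ne <- expected(config$profile_ne)
  list(expected_pct_e = e, expected_pct_ne = ne,
       expected_displacement = e - ne,
       total_codons = Lt)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %s: %d pairs, %d codons per CDS (seed %d)\n",
              x$dataset_label, x$config$n_pairs,
              x$ground_truth$total_codons, x$config$seed))
  invisible(x)
}

#' Convert a synthetic dataset to a paired frequency dataset
#'
#' @param ds A \code{synthetic_dataset}.
#' @return A \code{paired_dataset}, as from
#'   \code{\link{build_paired_dataset}}.
#' @export
as_paired_dataset <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  build_paired_dataset(ds$manifest, ds$records,
                       dataset_label = ds$dataset_label,
                       label_e = ds$label_e, label_ne = ds$label_ne)
}

#' Write a synthetic dataset to disk
#'
#' Writes one FASTA per class, the pair manifest TSV and the ground-truth
#' JSON into a directory, in the exact formats the I/O layer reads back.
#'
#' @param ds A \code{synthetic_dataset}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, named vector of the four file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_e <- ds$manifest$ext_id
  paths <- c(
    fasta_e = file.path(dir, "extremophile.fasta"),
    fasta_ne = file.path(dir, "counterpart.fasta"),
    manifest = file.path(dir, "manifest.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_cds_fasta(ds$records[is_e], paths["fasta_e"])
  write_cds_fasta(ds$records[ds$manifest$ctl_id], paths["fasta_ne"])
  write_tsv(as.data.frame(ds$manifest), paths["manifest"])
  gt <- ds$ground_truth
  gt$biases_note <- "expected_displacement = expected_pct_e - expected_pct_ne"
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
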