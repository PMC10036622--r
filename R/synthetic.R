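#' Specification of a synthetic omics cohort
#'
#' Describes a seeded multi-condition cohort with a planted pairwise
#' dependence structure, used to validate every downstream stage against a
#' known ground truth. Conditions are arbitrary names (e.g.
#' \code{"WT_0"}, \code{"WT_4"}); condition differences are encoded purely as
#' differences between the planted edge sets.
#'
#' @param n_molecules number of molecules \eqn{m}.
#' @param n_samples named integer vector or single integer: samples per
#'   condition (default 12; real cohorts of this design have 11-12).
#' @param conditions character vector of condition names (ignored if
#'   \code{n_samples} is named).
#' @param node_type_labels ordered character vector of node-type labels
#'   (default: the 11 KEGG metabolism classes).
#' @param label_probs probabilities over the number of labels per molecule
#'   (first element = P(1 label), ...). Default \code{c(0.8, 0.2)}: 80%
#'   single-label, 20% double-label, exercising the fractional ET weighting.
#' @param planted data frame with columns \code{condition}, \code{i},
#'   \code{j} (molecule indices, \code{i != j}), \code{kind} (one of
#'   \code{"linear"}, \code{"quadratic"}, \code{"xor"}), \code{strength}
#'   (dependence strength in (0, 1]). \code{NULL} for no planted structure.
#' @param noise_sd standard deviation of additive measurement noise.
#' @param seed integer root seed.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_molecules, n_samples = 12L,
                        conditions = c("cond0", "cond4"),
                        node_type_labels = kegg_metabolism_classes(),
                        label_probs = c(0.8, 0.2),
                        planted = NULL, noise_sd = 0.1, seed = 1L) {
  if (!is.null(names(n_samples))) {
    conditions <- names(n_samples)
  } else if (length(n_samples) == 1L) {
    n_samples <- setNames(rep(as.integer(n_samples), length(conditions)),
                          conditions)
  } else {
    n_samples <- setNames(as.integer(n_samples), conditions)
  }
  if (any(label_probs < 0) || sum(label_probs) <= 0)
    stop("label_probs must be nonnegative with positive sum")
  if (length(label_probs) > length(node_type_labels))
    stop("more labels per molecule than labels in the scheme")
  label_probs <- label_probs / sum(label_probs)
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("condition", "i", "j", "kind", "strength") %in%
                    names(planted)))
    if (any(planted$i == planted$j)) stop("planted pairs must be distinct")
    if (any(planted$i < 1 | planted$j < 1 |
            planted$i > n_molecules | planted$j > n_molecules))
      stop("planted indices out of range")
    if (!all(planted$condition %in% conditions))
      stop("planted condition not in conditions")
    if (!all(planted$kind %in% c("linear", "quadratic", "xor")))
      stop("unknown dependence kind")
    if (any(planted$strength <= 0 | planted$strength > 1))
      stop("strength must be in (0, 1]")
    for (cc in unique(planted$condition)) {
      tgt <- planted$j[planted$condition == cc]
      if (anyDuplicated(tgt))
        stop("each molecule may be the target (j) of at most one planted ",
             "pair per condition")
    }
    key <- pair_key(pmin(planted$i, planted$j), pmax(planted$i, planted$j))
    if (anyDuplicated(paste(planted$condition, key)))
      stop("duplicate planted pair within a condition")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 n_samples = n_samples,
                 conditions = conditions,
                 node_type_labels = node_type_labels,
                 label_probs = label_probs,
                 planted = planted,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with planted dependencies
#'
#' For each condition, molecules are drawn as independent standard normals
#' across samples; each planted pair \eqn{(i, j)} then overwrites molecule
#' \eqn{j} with a function of molecule \eqn{i} plus independent noise:
#' \describe{
#'   \item{linear}{\eqn{x_j = \rho x_i + \sqrt{1-\rho^2}\,\epsilon}, Pearson
#'     correlation \eqn{\rho} = strength.}
#'   \item{quadratic}{\eqn{x_j = a (x_i^2 - 1)/\sqrt{2} +
#'     \sqrt{1-a^2}\,\epsilon}: strong dependence with (population) zero
#'     linear correlation.}
#'   \item{xor}{\eqn{x_j = s\,(a x_i + \sqrt{1-a^2}\,\epsilon)} with a random
#'     sign \eqn{s = \pm 1} per sample: dependent yet linearly uncorrelated.}
#' }
#' Finally i.i.d. \eqn{N(0, \mathrm{noise\_sd}^2)} measurement noise is added
#' everywhere. Multi-label node-type annotations are drawn once for the whole
#' cohort. Fully deterministic given the spec's seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list with \code{matrices} (named list of molecule x sample
#'   matrices, one per condition), \code{annotations} (named list: molecule
#'   ID -> character vector of labels), \code{truth} (named list: condition
#'   -> data frame of planted pairs with molecule IDs), and \code{spec}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- spec$n_molecules
  ids <- sprintf("mol%03d", seq_len(m))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  n_labels <- sample.int(length(spec$label_probs), m, replace = TRUE,
                         prob = spec$label_probs)
  annotations <- lapply(n_labels, function(k)
    sample(spec$node_type_labels, k, replace = FALSE))
  names(annotations) <- ids

  matrices <- list()
  truth <- list()
  for (cc in spec$conditions) {
    n <- spec$n_samples[[cc]]
    x <- matrix(rnorm(m * n), nrow = m, ncol = n,
                dimnames = list(ids, sprintf("%s_s%02d", cc, seq_len(n))))
    pl <- spec$planted
    pl <- if (is.null(pl)) NULL else pl[pl$condition == cc, , drop = FALSE]
    if (!is.null(pl) && nrow(pl) > 0L) {
      for (r in seq_len(nrow(pl))) {
        i <- pl$i[r]; j <- pl$j[r]; a <- pl$strength[r]
        base <- x[i, ]
        eps <- rnorm(n)
        x[j, ] <- switch(pl$kind[r],
          linear    = a * base + sqrt(1 - a^2) * eps,
          quadratic = a * (base^2 - 1) / sqrt(2) + sqrt(1 - a^2) * eps,
          xor       = sample(c(-1, 1), n, replace = TRUE) *
                        (a * base + sqrt(1 - a^2) * eps))
      }
    }
    x <- x + matrix(rnorm(m * n, sd = spec$noise_sd), nrow = m)
    matrices[[cc]] <- x
    truth[[cc]] <- if (is.null(pl) || nrow(pl) == 0L) {
      data.frame(mol_a = character(), mol_b = character(),
                 kind = character(), strength = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(mol_a = ids[pmin(pl$i, pl$j)],
                 mol_b = ids[pmax(pl$i, pl$j)],
                 kind = pl$kind, strength = pl$strength,
                 stringsAsFactors = FALSE)
    }
  }
  list(matrices = matrices, annotations = annotations, truth = truth,
       spec = spec)
}

#' Default planted design for a two-genotype, two-timepoint study
#'
#' Builds a planted-edge table over disjoint molecule pairs that mirrors the
#' four edge fates: per genotype, some pairs are dependent at both
#' timepoints (P to P), some only before (P to A), some only after (A to P);
#' the remainder stay independent (A to A). Dependence kinds cycle through
#' linear, quadratic and xor so the nonlinear path is always exercised.
#'
#' @param n_molecules number of molecules (must be at least twice the number
#'   of planted pairs).
#' @param n_ptop,n_ptoa,n_atop pairs per fate class and genotype.
#' @param strength dependence strength used for every planted pair.
#' @param genotypes two genotype names; conditions are named
#'   \code{<genotype>_0} and \code{<genotype>_4}.
#' @return data frame suitable for \code{\link{cohort_spec}}'s
#'   \code{planted} argument, covering the four conditions.
#' @export
planted_study_design <- function(n_molecules, n_ptop = 3L, n_ptoa = 3L,
                                 n_atop = 3L, strength = 0.95,
                                 genotypes = c("WT", "ob")) {
  per_geno <- n_ptop + n_ptoa + n_atop
  if (2L * per_geno > n_molecules)
    stop("not enough molecules for disjoint planted pairs")
  kinds <- c("linear", "quadratic", "xor")
  out <- list()
  pool <- matrix(seq_len(2L * per_geno), ncol = 2L, byrow = TRUE)
  for (g in genotypes) {
    fates <- rep(c("PtoP", "PtoA", "AtoP"), times = c(n_ptop, n_ptoa, n_atop))
    for (r in seq_len(per_geno)) {
      kind <- kinds[(r - 1L) %% 3L + 1L]
      conds <- switch(fates[r],
                      PtoP = paste0(g, c("_0", "_4")),
                      PtoA = paste0(g, "_0"),
                      AtoP = paste0(g, "_4"))
      out[[length(out) + 1L]] <- data.frame(
        condition = conds, i = pool[r, 1L], j = pool[r, 2L],
        kind = kind, strength = strength, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a generated cohort to plain-text files
#'
#' Matrices go to \code{<dir>/<condition>.tsv} (first column
#' \code{molecule_id}, then one column per sample), annotations to
#' \code{annotations.tsv} (molecule ID, pipe-separated labels), and the
#' ground-truth planted edges to \code{truth.json}.
#'
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cc in names(cohort$matrices)) {
    write_matrix_tsv(cohort$matrices[[cc]],
                     file.path(dir, paste0(cc, ".tsv")))
  }
  write_annotations_tsv(cohort$annotations,
                        file.path(dir, "annotations.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
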