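#' Configuration for a full study run
#'
#' A study is one or more omics layers, each measured under two genotypes
#' x two timepoints. Condition names must be \code{<genotype>_0} and
#' \code{<genotype>_4} for each genotype.
#'
#' @param layers named list: layer name -> named list of condition matrices
#'   (molecule x sample) or TSV paths readable by
#'   \code{\link{read_matrix_tsv}}.
#' @param annotations named list (molecule ID -> labels) or a TSV path.
#' @param scheme node-type scheme (ordered label vector).
#' @param genotypes the two genotype prefixes.
#' @param mi an \code{\link{mi_config}}.
#' @param p0 edge threshold.
#' @param thresholds threshold grid for the robustness scan (must contain
#'   \code{p0}).
#' @param et_subset labels defining the ET subset used for distance
#'   matrices and MDS (default: all scheme labels).
#' @param out_dir output directory, or \code{NULL} for no files.
#' @return an object of class \code{study_config}.
#' @export
study_config <- function(layers, annotations, scheme = kegg_metabolism_classes(),
                         genotypes = c("WT", "ob"), mi = mi_config(),
                         p0 = 0.05, thresholds = c(0.03, 0.04, 0.05, 0.06, 0.07),
                         et_subset = NULL, out_dir = NULL) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (!any(abs(thresholds - p0) < 1e-12)) stop("thresholds must contain p0")
  conds <- as.vector(outer(genotypes, c("_0", "_4"), paste0))
  layers <- lapply(layers, function(lay) {
    lay <- lapply(lay, function(x) if (is.character(x)) read_matrix_tsv(x)
                                   else as.matrix(x))
    if (!all(conds %in% names(lay)))
      stop("each layer needs conditions: ", paste(conds, collapse = ", "))
    lay[conds]
  })
  if (is.character(annotations)) annotations <- read_annotations_tsv(annotations)
  structure(list(layers = layers, annotations = annotations, scheme = scheme,
                 genotypes = genotypes, conditions = conds, mi = mi, p0 = p0,
                 thresholds = thresholds,
                 et_subset = et_subset %||% scheme, out_dir = out_dir),
            class = "study_config")
}

#' Run the full edge-type study workflow
#'
#' Per layer: infers the four condition networks, builds the two genotype
#' response networks, and computes density reports, per-ET response
#' distributions with net-change rankings, genotype-vs-genotype chi-squared
#' distances per ET, ET-by-ET distance matrices with their 2-D Torgerson MDS
#' embeddings, the 6-pair Cramér-von Mises comparison table of condition ET
#' distributions (Bonferroni x6), MI-difference counts among PtoP edges, and
#' the threshold-robustness and cross-condition scans. With two or more
#' layers, layer-vs-layer chi-squared distances per ET are added. All stages
#' are seeded through the MI config; a rerun with the same config is
#' identical.
#'
#' @param cfg a \code{\link{study_config}}.
#' @return a named report bundle (list); written as TSV/JSON under
#'   \code{cfg$out_dir} when set.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  catalog <- build_catalog(cfg$scheme)
  sub_cat <- subset_catalog(catalog, cfg$et_subset)
  out <- list(catalog = catalog)
  for (layer in names(cfg$layers)) {
    mats <- cfg$layers[[layer]]
    nets <- lapply(mats, infer_network, cfg = cfg$mi, p0 = cfg$p0)
    resp <- list()
    for (g in cfg$genotypes) {
      resp[[g]] <- response_network(nets[[paste0(g, "_0")]],
                                    nets[[paste0(g, "_4")]])
    }
    density <- do.call(rbind, lapply(names(nets), function(cc) {
      e <- nrow(network_edges(nets[[cc]]))
      n <- length(nets[[cc]]$nodes)
      data.frame(condition = cc, N = n, E = e,
                 density_pct = 100 * graph_density(e, n),
                 stringsAsFactors = FALSE)
    }))
    resp_dists <- lapply(resp, response_distribution_per_et,
                         annotations = cfg$annotations, catalog = catalog)
    rankings <- lapply(resp_dists, function(rd)
      net_change_ranking(rd[sub_cat$et, , drop = FALSE]))
    # genotype-vs-genotype chi-squared distance of fate histograms per ET
    g1 <- cfg$genotypes[1]; g2 <- cfg$genotypes[2]
    geno_chi2 <- vapply(sub_cat$et, function(et) {
      h1 <- resp_dists[[g1]][et, ]; h2 <- resp_dists[[g2]][et, ]
      if (sum(h1) == 0 || sum(h2) == 0) return(NA_real_)
      chi2_histogram_distance(h1, h2)
    }, numeric(1))
    dist_mats <- lapply(resp_dists, function(rd) {
      keep <- sub_cat$et[rowSums(rd[sub_cat$et, , drop = FALSE]) > 0]
      et_distance_matrix(rd, ets = keep)
    })
    mds <- lapply(dist_mats, function(D)
      if (nrow(D) >= 2) suppressWarnings(torgerson_mds(D, 2L)) else NULL)
    et_dists <- lapply(nets, et_distribution, annotations = cfg$annotations,
                       catalog = catalog)
    cvm <- cvm_condition_table(et_dists)
    mi_diff <- lapply(setNames(cfg$genotypes, cfg$genotypes), function(g)
      ptop_mi_difference(resp[[g]], mats[[paste0(g, "_0")]],
                         mats[[paste0(g, "_4")]], cfg$mi))
    robustness <- lapply(nets, robustness_scan, thresholds = cfg$thresholds,
                         annotations = cfg$annotations, catalog = catalog,
                         reference = cfg$p0)
    conditions_vs_ref <- condition_scan(nets, cfg$conditions[1],
                                        cfg$annotations, catalog)
    out[[layer]] <- list(networks = nets, response = resp, density = density,
                         response_distributions = resp_dists,
                         rankings = rankings, genotype_chi2 = geno_chi2,
                         distance_matrices = dist_mats, mds = mds,
                         et_distributions = et_dists, cvm = cvm,
                         ptop_mi_difference = mi_diff,
                         robustness = robustness,
                         condition_scan = conditions_vs_ref)
  }
  if (length(cfg$layers) >= 2L) {
    ln <- names(cfg$layers)
    cross <- list()
    for (i in seq_along(ln)[-1]) for (j in seq_len(i - 1L)) {
      for (g in cfg$genotypes) {
        d1 <- out[[ln[j]]]$response_distributions[[g]]
        d2 <- out[[ln[i]]]$response_distributions[[g]]
        cross[[paste(ln[j], ln[i], g, sep = ".")]] <-
          vapply(sub_cat$et, function(et) {
            if (sum(d1[et, ]) == 0 || sum(d2[et, ]) == 0) return(NA_real_)
            chi2_histogram_distance(d1[et, ], d2[et, ])
          }, numeric(1))
      }
    }
    out$layer_chi2 <- cross
  }
  if (!is.null(cfg$out_dir)) write_study(out, cfg)
  invisible(out)
}

# Cramér-von Mises comparisons of the ET distributions of all condition
# pairs (6 for four conditions), Bonferroni-corrected by the family size.
cvm_condition_table <- function(et_dists) {
  cn <- names(et_dists)
  pairs <- utils::combn(cn, 2L)
  fam <- ncol(pairs)
  do.call(rbind, lapply(seq_len(fam), function(k) {
    r <- compare_et_distributions(et_dists[[pairs[1, k]]],
                                  et_dists[[pairs[2, k]]],
                                  bonferroni = fam)
    data.frame(cond_a = pairs[1, k], cond_b = pairs[2, k],
               statistic = r$statistic, p_value = r$p_value,
               stringsAsFactors = FALSE)
  }))
}

# Count PtoP edges whose MI differs significantly between the two
# timepoints (permutation test per edge, seeded per pair).
ptop_mi_difference <- function(resp, mat0, mat4, cfg, p0 = 0.05) {
  ptop <- resp$pairs[resp$pairs$fate == "PtoP", , drop = FALSE]
  z0 <- standardize(mat0); z4 <- standardize(mat4)
  sig <- 0L
  pvals <- numeric(nrow(ptop))
  for (r in seq_len(nrow(ptop))) {
    a <- ptop$a[r]; b <- ptop$b[r]
    res <- permutation_test_mi_difference(
      z0[a, ], z0[b, ], z4[a, ], z4[b, ], cfg,
      seed = pair_seed(cfg$seed + 1L, a, b))
    pvals[r] <- res$p_value
    if (res$p_value < p0) sig <- sig + 1L
  }
  list(n_ptop = nrow(ptop), n_significant = sig,
       pairs = cbind(ptop[, c("a", "b")], p_value = pvals))
}

write_study <- function(out, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- out$catalog
  for (layer in names(cfg$layers)) {
    res <- out[[layer]]
    ld <- file.path(cfg$out_dir, layer)
    dir.create(ld, showWarnings = FALSE)
    for (cc in names(res$networks)) {
      export_network(res$networks[[cc]],
                     file.path(ld, paste0("network_", cc, ".tsv")))
      export_network(res$networks[[cc]],
                     file.path(ld, paste0("network_", cc, ".graphml")),
                     format = "graphml", annotations = cfg$annotations)
      write_et_distribution(res$et_distributions[[cc]], catalog,
                            file.path(ld, paste0("et_distribution_", cc,
                                                 ".tsv")))
    }
    for (g in names(res$response)) {
      write.table(res$response[[g]]$pairs,
                  file.path(ld, paste0("response_", g, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$rankings[[g]],
                  file.path(ld, paste0("ranking_", g, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(res$mds[[g]]))
        write.table(data.frame(et = rownames(res$mds[[g]]),
                               res$mds[[g]], check.names = FALSE),
                    file.path(ld, paste0("mds_", g, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(res$density, file.path(ld, "density.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$cvm, file.path(ld, "cvm.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(genotype_chi2 = as.list(res$genotype_chi2),
           ptop_mi_difference = lapply(res$ptop_mi_difference, function(x)
             x[c("n_ptop", "n_significant")])),
      file.path(ld, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(cfg$out_dir)
}
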