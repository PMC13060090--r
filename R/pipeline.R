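#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run with its default: anchor FDR
#' level 0.1, path bound k = 4, 1000 co-membership iterations, anchor
#' dendrogram cut 0.8, minimum 2 anchors per valid module, 100 permutation
#' shuffles, and the 1 - p labelling mode. The configuration is serialized
#' verbatim into the output directory's manifest.
#'
#' @param network path to the edge-list TSV.
#' @param ec_scores path to the EC score TSV (or \code{NULL}).
#' @param met_scores path to the metabolite score TSV (or \code{NULL}).
#' @param outdir output directory.
#' @param pathways optional path to a pathway membership TSV.
#' @param fdr_level anchor FDR level.
#' @param k path-length bound.
#' @param n_iter co-membership iterations.
#' @param cut anchor clustering cut (dendrogram height on 1 - M).
#' @param cut_is_distance see \code{\link{cluster_anchors}}.
#' @param min_anchors minimum anchors per valid module.
#' @param B permutation shuffles.
#' @param n_iter_shuffle iterations per shuffled rerun (default: n_iter).
#' @param mode labelling mode, see \code{\link{da_probability}}.
#' @param currency_max_degree optional currency-metabolite degree cutoff.
#' @param currency_list optional character vector of currency metabolite ids
#'   to remove (default: none).
#' @param seed master seed.
#' @param dump_co_membership also write the anchor co-membership matrix.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(network, ec_scores = NULL, met_scores = NULL,
                       outdir = "metabodule_out", pathways = NULL,
                       fdr_level = 0.1, k = 4, n_iter = 1000, cut = 0.8,
                       cut_is_distance = TRUE,
                       min_anchors = 2, B = 100, n_iter_shuffle = NULL,
                       mode = c("one_minus_p", "bum_posterior"),
                       currency_max_degree = NULL, currency_list = NULL,
                       seed = 1L, dump_co_membership = FALSE) {
  structure(
    list(network = network, ec_scores = ec_scores, met_scores = met_scores,
         outdir = outdir, pathways = pathways, fdr_level = fdr_level,
         k = as.integer(k), n_iter = as.integer(n_iter), cut = cut,
         cut_is_distance = isTRUE(cut_is_distance),
         min_anchors = as.integer(min_anchors), B = as.integer(B),
         n_iter_shuffle = n_iter_shuffle, mode = match.arg(mode),
         currency_max_degree = currency_max_degree,
         currency_list = currency_list, seed = as.integer(seed),
         dump_co_membership = isTRUE(dump_co_membership)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Every field of \code{\link{run_config}} may appear in the YAML file;
#' \code{overrides} (a named list, e.g. from command-line flags) take
#' precedence.
#'
#' @param path YAML file path.
#' @param overrides named list of overriding values.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  vals <- vals[intersect(names(vals), names(formals(run_config)))]
  do.call(run_config, vals)
}

#' Run the full module-discovery pipeline
#'
#' Reads the network and score tables, optionally removes currency
#' metabolites, projects scores, fits the per-omic beta-uniform mixtures,
#' discovers modules, assesses their significance by the topology-aware
#' permutation test, and (when pathways are supplied) computes the
#' over-representation baselines. All results and a machine-readable
#' manifest (configuration, seed, package version) are written under
#' \code{cfg$outdir}; rerunning with the same configuration reproduces the
#' outputs exactly.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return the tested \code{module_set}, invisibly. Output files:
#'   \code{manifest.yaml}, \code{bum_fit.txt}, \code{anchors.tsv},
#'   \code{module_nodes.tsv}, \code{module_summary.tsv}, and with pathways
#'   \code{ora_ec.tsv}, \code{ora_metabolite.tsv},
#'   \code{module_pathway_overlap.tsv}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  net <- read_edge_list(cfg$network)
  if (!is.null(cfg$currency_max_degree)) {
    net <- filter_currency_metabolites(net,
                                       max_degree = cfg$currency_max_degree)
  } else if (length(cfg$currency_list) > 0) {
    net <- filter_currency_metabolites(net, explicit_list = cfg$currency_list)
  }
  ec <- if (!is.null(cfg$ec_scores)) read_score_table(cfg$ec_scores)
  met <- if (!is.null(cfg$met_scores)) read_score_table(cfg$met_scores)
  an <- project_scores(net, ec, met)
  fits <- fit_bum_per_type(an, fdr_level = cfg$fdr_level)
  write_fit_report(an, fits, file.path(cfg$outdir, "bum_fit.txt"))

  scfg <- sampling_config(n_iter = cfg$n_iter, k = cfg$k, mode = cfg$mode,
                          seed = cfg$seed)
  disc <- discover_modules(an, fits, scfg, cut = cfg$cut,
                           cut_is_distance = cfg$cut_is_distance,
                           min_anchors = cfg$min_anchors)
  types <- node_types(net)
  utils::write.table(
    data.frame(node_id = disc$anchors, node_type = types[disc$anchors],
               p_value = an$p[disc$anchors], stringsAsFactors = FALSE),
    file.path(cfg$outdir, "anchors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (cfg$dump_co_membership && !is.null(disc$M)) {
    write_co_membership(disc$M, file.path(cfg$outdir, "co_membership.tsv"))
  }

  tested <- disc$modules
  if (cfg$B > 0 && length(tested$modules) > 0) {
    tested <- permutation_test(an, fits, scfg, tested, B = cfg$B,
                               cut = cfg$cut,
                               cut_is_distance = cfg$cut_is_distance,
                               seed = cfg$seed + 1L,
                               n_iter_shuffle = cfg$n_iter_shuffle)
  }
  write_module_tables(tested, an, types, cfg$outdir)

  if (!is.null(cfg$pathways)) {
    db <- read_pathway_table(cfg$pathways)
    for (ty in c("EC", "METABOLITE")) {
      fit <- fits[[ty]]
      if (is.null(fit) || fit$tau <= 0) next
      obs <- an$observed[types[an$observed] == ty]
      sig <- obs[an$p[obs] < fit$tau]
      tab <- ora(sig, obs, db)
      utils::write.table(tab, file.path(cfg$outdir,
                                        sprintf("ora_%s.tsv", tolower(ty))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    universe <- intersect(net$nodes$node_id, db$universe)
    rows <- list()
    for (m in tested$modules) {
      if (!isTRUE(m$valid)) next
      tab <- module_pathway_overlap(m, db, universe = universe)
      tab <- cbind(module_id = m$module_id, tab)
      rows[[length(rows) + 1]] <- tab
    }
    if (length(rows) > 0) {
      utils::write.table(do.call(rbind, rows),
                         file.path(cfg$outdir, "module_pathway_overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- unclass(cfg)
  manifest$package_version <- as.character(utils::packageVersion("metabodule"))
  manifest$r_version <- as.character(getRversion())
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  invisible(tested)
}

write_fit_report <- function(an, fits, path) {
  lines <- c("Per-omic beta-uniform mixture fits", "")
  for (ty in c("EC", "METABOLITE")) {
    f <- fits[[ty]]
    lines <- c(lines, sprintf("[%s] coverage = %.4f", ty, an$coverage[ty]))
    if (is.null(f)) {
      lines <- c(lines, "  no observed nodes; not fitted", "")
      next
    }
    lines <- c(lines,
               sprintf("  a = %.6f  lambda = %.6f  (n = %d, logLik = %.4f)",
                       f$a, f$lam, f$n, f$loglik),
               sprintf("  tau = %.6g at FDR = %g%s", f$tau, f$fdr_level,
                       if (f$tau == 0) "  [sentinel: no anchors]" else ""),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

write_module_tables <- function(tested, an, types, outdir) {
  nodes_rows <- list()
  for (m in tested$modules) {
    nodes_rows[[length(nodes_rows) + 1]] <- data.frame(
      module_id = m$module_id, node_id = m$nodes,
      node_type = unname(types[m$nodes]),
      is_anchor = m$nodes %in% m$anchors,
      p_value = ifelse(m$nodes %in% names(an$p), an$p[m$nodes], NA_real_),
      stringsAsFactors = FALSE
    )
  }
  nodes_tab <- if (length(nodes_rows) > 0) do.call(rbind, nodes_rows) else
    data.frame(module_id = integer(0), node_id = character(0),
               node_type = character(0), is_anchor = logical(0),
               p_value = numeric(0))
  utils::write.table(nodes_tab, file.path(outdir, "module_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- as.data.frame(tested)
  summ$significant <- !is.na(summ$q) & summ$q < 0.1
  utils::write.table(summ, file.path(outdir, "module_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
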