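#' Construct a per-omic score table
#'
#' A score table holds one association p-value per feature (node id) of a
#' single omic. Exact zeros are clamped to \code{p_floor} (the Beta(a,1)
#' signal density diverges at 0) and reported.
#'
#' @param node_id character vector of feature ids.
#' @param node_type \code{"EC"} or \code{"METABOLITE"} (recycled if length 1).
#' @param p_value numeric vector of p-values in [0, 1].
#' @param p_floor clamp applied to exact zeros (default 1e-10).
#' @return an object of class \code{score_table}: data frame with columns
#'   \code{node_id}, \code{node_type}, \code{p_value}.
#' @export
score_table <- function(node_id, node_type, p_value, p_floor = 1e-10) {
  node_id <- trimws(as.character(node_id))
  node_type <- rep_len(as.character(node_type), length(node_id))
  p_value <- as.numeric(p_value)
  if (!all(node_type %in% c("EC", "METABOLITE"))) {
    stop("node_type must be 'EC' or 'METABOLITE'")
  }
  if (anyNA(p_value) || any(p_value < 0) || any(p_value > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  nz <- sum(p_value == 0)
  if (nz > 0) {
    message(nz, " zero p-value(s) clamped to ", p_floor)
    p_value[p_value == 0] <- p_floor
  }
  if (anyDuplicated(node_id)) {
    stop("duplicate node id(s) in score table: ",
         paste(utils::head(unique(node_id[duplicated(node_id)]), 5),
               collapse = ", "))
  }
  structure(
    data.frame(node_id = node_id, node_type = node_type, p_value = p_value,
               stringsAsFactors = FALSE),
    class = c("score_table", "data.frame")
  )
}

#' Read a score table from TSV
#'
#' Expects a tab-separated file with header columns \code{node_id},
#' \code{node_type}, \code{p_value}.
#'
#' @param path path to the TSV file.
#' @param p_floor clamp applied to exact zeros.
#' @return a \code{\link{score_table}}.
#' @export
read_score_table <- function(path, p_floor = 1e-10) {
  if (!file.exists(path)) stop("score table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "node_type", "p_value")
  if (!all(need %in% names(df))) {
    stop("score table must have columns node_id, node_type, p_value: ", path)
  }
  score_table(df$node_id, df$node_type, df$p_value, p_floor = p_floor)
}

#' Write a score table to TSV
#'
#' @param scores a \code{\link{score_table}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Project per-omic p-values onto the metabolic network
#'
#' Network nodes with an available p-value become "observed"; the rest are
#' "unobserved" (to be imputed from the fitted mixture during sampling).
#' Score-table ids absent from the network are dropped and counted, never
#' silently merged.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param ec_scores a \code{\link{score_table}} of EC p-values (may be
#'   \code{NULL}).
#' @param met_scores a \code{\link{score_table}} of metabolite p-values (may
#'   be \code{NULL}).
#' @return an object of class \code{annotated_network}: list with
#'   \code{network}, \code{p} (named numeric over observed nodes),
#'   \code{observed} (character), \code{coverage} (named numeric: fraction
#'   of EC / metabolite nodes observed), \code{dropped} (named integer
#'   counts of score ids not in the network).
#' @export
project_scores <- function(net, ec_scores = NULL, met_scores = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  types <- node_types(net)
  shared <- intersect(ec_scores$node_id %||% character(),
                      met_scores$node_id %||% character())
  if (length(shared) > 0) {
    stop("id(s) present in both score tables: ",
         paste(utils::head(shared, 5), collapse = ", "))
  }
  p <- numeric(0)
  dropped <- c(EC = 0L, METABOLITE = 0L)
  for (tab in list(ec_scores, met_scores)) {
    if (is.null(tab)) next
    in_net <- tab$node_id %in% names(types)
    hit <- tab[in_net, , drop = FALSE]
    mismatch <- hit$node_id[types[hit$node_id] != hit$node_type]
    if (length(mismatch) > 0) {
      stop("node_type in score table conflicts with network for: ",
           paste(utils::head(mismatch, 5), collapse = ", "))
    }
    dropped[tab$node_type[1]] <- dropped[tab$node_type[1]] + sum(!in_net)
    p <- c(p, stats::setNames(hit$p_value, hit$node_id))
  }
  if (anyDuplicated(names(p))) stop("duplicate node id across score tables")
  cov <- vapply(c(EC = "EC", METABOLITE = "METABOLITE"), function(ty) {
    tot <- sum(types == ty)
    if (tot == 0) return(0)
    sum(types[names(p)] == ty) / tot
  }, 1)
  structure(
    list(network = net, p = p, observed = names(p), coverage = cov,
         dropped = dropped),
    class = "annotated_network"
  )
}

#' @export
print.annotated_network <- function(x, ...) {
  cat("Annotated metabolic network\n")
  print(x$network)
  cat(sprintf("  observed: %d nodes (EC coverage %.1f%%, metabolite coverage %.1f%%)\n",
              length(x$observed), 100 * x$coverage["EC"],
              100 * x$coverage["METABOLITE"]))
  if (sum(x$dropped) > 0) {
    cat(sprintf("  dropped score ids not in network: %d EC, %d metabolite\n",
                x$dropped["EC"], x$dropped["METABOLITE"]))
  }
  invisible(x)
}

#' Fit the beta-uniform mixture per omic
#'
#' Fits one \code{\link{fit_bum}} model per node type on the observed
#' p-values of an annotated network. The two omics are fitted independently.
#'
#' A node type with fewer than \code{min_n} observed p-values cannot support
#' a stable mixture fit; it falls back (with a warning) to a pure-noise fit
#' (\code{lam} at the upper boundary, sentinel \code{tau = 0}), so that its
#' unobserved nodes are imputed from Uniform(0,1) and it contributes no
#' anchors.
#'
#' @param an an \code{\link{project_scores}} annotated network.
#' @param fdr_level anchor FDR level passed to \code{\link{fit_bum}}.
#' @param min_n minimum p-values per type.
#' @return named list with elements \code{EC} and \code{METABOLITE}
#'   (\code{bum_fit} objects, or \code{NULL} for a type with no observed
#'   nodes).
#' @export
fit_bum_per_type <- function(an, fdr_level = 0.1, min_n = 20) {
  stopifnot(inherits(an, "annotated_network"))
  types <- node_types(an$network)
  out <- list(EC = NULL, METABOLITE = NULL)
  for (ty in names(out)) {
    pv <- an$p[types[an$observed] == ty]
    if (length(pv) == 0) next
    if (length(pv) < min_n) {
      warning("only ", length(pv), " observed ", ty, " p-values (< ", min_n,
              "); falling back to a pure-noise fit (no ", ty, " anchors)")
      out[[ty]] <- uniform_bum_fit(length(pv), fdr_level)
    } else {
      out[[ty]] <- fit_bum(pv, fdr_level = fdr_level, min_n = min_n)
    }
  }
  out
}

# Pure-noise fallback fit: all mass in the uniform component, no anchors.
uniform_bum_fit <- function(n, fdr_level = 0.1) {
  structure(
    list(a = 0.5, lam = 1 - 1e-6, pi_ub = 1 - 5e-7, tau = 0, loglik = 0,
         n = n, fdr_level = fdr_level, boundary = TRUE, degenerate = TRUE),
    class = "bum_fit"
  )
}
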