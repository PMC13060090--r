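#' Construct a pathway database
#'
#' @param pathways named list mapping pathway id to a character vector of
#'   member node ids, or a two-column data frame (\code{pathway_id},
#'   \code{node_id}).
#' @param universe optional universe of node ids; defaults to the union of
#'   all pathway members.
#' @return an object of class \code{pathway_db}.
#' @export
pathway_db <- function(pathways, universe = NULL) {
  if (is.data.frame(pathways)) {
    stopifnot(all(c("pathway_id", "node_id") %in% names(pathways)))
    pathways <- split(trimws(pathways$node_id), trimws(pathways$pathway_id))
  }
  pathways <- lapply(pathways, function(x) sort(unique(trimws(x))))
  universe <- sort(unique(universe %||% unlist(pathways)))
  bad <- !vapply(pathways, function(s) all(s %in% universe), TRUE)
  if (any(bad)) {
    stop("pathway member(s) outside universe in: ",
         paste(utils::head(names(pathways)[bad], 5), collapse = ", "))
  }
  structure(list(pathways = pathways, universe = universe),
            class = "pathway_db")
}

#' Read pathway memberships from TSV
#'
#' One membership per row, header columns \code{pathway_id}, \code{node_id}.
#'
#' @param path TSV path.
#' @param universe optional universe of node ids.
#' @return a \code{\link{pathway_db}}.
#' @export
read_pathway_table <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "node_id") %in% names(df))) {
    stop("pathway table must have columns pathway_id, node_id: ", path)
  }
  pathway_db(df, universe = universe)
}

# One-sided (over-representation) hypergeometric upper-tail p-value for a
# 2x2 table: x successes in a draw of n from a population of size N with K
# successes. P(X >= x).
hyper_upper <- function(x, K, n, N) {
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of significant features
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) per pathway on
#' the 2x2 table pathway-membership x significance, restricted to
#' \code{background} intersected with the database universe. Mirrors the
#' standard pathway-level baseline against which custom modules are
#' compared: the per-omic "significant" feature set is typically those with
#' p below the mixture threshold tau of that omic.
#'
#' @param significant character vector of significant node ids (subset of
#'   \code{background}).
#' @param background character vector of tested node ids.
#' @param db a \code{\link{pathway_db}}.
#' @return data frame with columns \code{pathway_id}, \code{n_sig_in}
#'   (significant in pathway), \code{n_in} (background in pathway),
#'   \code{n_sig}, \code{n_bg}, \code{p}, \code{q} (BH), sorted by p.
#' @export
ora <- function(significant, background, db) {
  stopifnot(inherits(db, "pathway_db"))
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  if (!all(significant %in% background)) {
    stop("significant set must be a subset of background")
  }
  bg <- intersect(background, db$universe)
  sig <- intersect(unique(significant), bg)
  rows <- lapply(names(db$pathways), function(pw) {
    inset <- intersect(db$pathways[[pw]], bg)
    x <- length(intersect(inset, sig))
    data.frame(pathway_id = pw, n_sig_in = x, n_in = length(inset),
               n_sig = length(sig), n_bg = length(bg),
               p = hyper_upper(x, length(inset), length(sig), length(bg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_correct(out$p)
  out[order(out$p, out$pathway_id), , drop = FALSE]
}

#' Module-versus-pathway overlap
#'
#' For each pathway, a one-sided Fisher's exact test of module membership
#' against pathway membership over the given universe, plus the containment
#' fraction |module ∩ pathway| / |module|. A module is "mostly contained"
#' in a pathway when containment exceeds 0.8; significant overlap is
#' reported at q < 0.05.
#'
#' @param module a \code{metabolic_module} (or character vector of node ids).
#' @param db a \code{\link{pathway_db}}.
#' @param universe character vector of node ids over which the 2x2 table is
#'   formed; commonly all network nodes annotated to at least one pathway.
#'   Module nodes outside the universe are dropped (count reported via
#'   attribute \code{"dropped"}).
#' @return data frame with columns \code{pathway_id}, \code{n_overlap},
#'   \code{p}, \code{q}, \code{containment}, \code{mostly_contained},
#'   \code{significant} (q < 0.05), sorted by p.
#' @export
module_pathway_overlap <- function(module, db, universe = NULL) {
  stopifnot(inherits(db, "pathway_db"))
  nodes <- if (inherits(module, "metabolic_module")) module$nodes else module
  nodes <- unique(nodes)
  if (length(nodes) == 0) stop("empty module")
  universe <- unique(universe %||% db$universe)
  inside <- intersect(nodes, universe)
  dropped <- length(nodes) - length(inside)
  if (length(inside) == 0) stop("no module node lies in the universe")
  rows <- lapply(names(db$pathways), function(pw) {
    pwset <- intersect(db$pathways[[pw]], universe)
    x <- length(intersect(inside, pwset))
    cont <- length(intersect(nodes, db$pathways[[pw]])) / length(nodes)
    data.frame(pathway_id = pw, n_overlap = x,
               p = hyper_upper(x, length(pwset), length(inside),
                               length(universe)),
               containment = cont, mostly_contained = cont > 0.8,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_correct(out$p)
  out$significant <- out$q < 0.05
  out <- out[order(out$p, out$pathway_id),
             c("pathway_id", "n_overlap", "p", "q", "containment",
               "mostly_contained", "significant")]
  attr(out, "dropped") <- dropped
  out
}
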