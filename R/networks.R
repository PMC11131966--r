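#' Taxonomic relative-abundance profile
#'
#' Constructs the relative-abundance vector \eqn{p = (p_1, \dots, p_N)} over a
#' set of taxa. Abundances must be non-negative and are required to sum to 1
#' (within `tol`) unless `renormalize = TRUE`, in which case they are rescaled.
#'
#' @param p numeric vector of relative abundances. If unnamed, `taxon_ids`
#'   must be supplied.
#' @param taxon_ids character vector of unique taxon identifiers, recycled
#'   from `names(p)` when missing.
#' @param renormalize logical; rescale `p` to sum to 1 instead of erroring.
#' @param tol tolerance on `sum(p) - 1`.
#' @return A named numeric vector of class `"taxonomic_profile"`.
#' @examples
#' taxonomic_profile(c(T1 = 0.5, T2 = 0.5))
#' @export
taxonomic_profile <- function(p, taxon_ids = names(p), renormalize = FALSE,
                              tol = 1e-9) {
  if (is.null(taxon_ids)) stop("taxon identifiers are required")
  taxon_ids <- as.character(taxon_ids)
  if (length(taxon_ids) != length(p)) stop("'p' and 'taxon_ids' lengths differ")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon identifiers")
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0)) stop("abundances must be finite and >= 0")
  s <- sum(p)
  if (abs(s - 1) > tol) {
    if (!renormalize)
      stop(sprintf("abundances sum to %.6g, not 1; use renormalize = TRUE", s))
    if (s <= 0) stop("cannot renormalize a zero-sum profile")
    p <- p / s
  }
  structure(p, names = taxon_ids, class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("Taxonomic profile:", length(x), "taxa\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Bipartite taxon-by-function content network
#'
#' A content network records which taxa own (gene level, GCN) or express
#' (protein level, PCN) each function, as a binary incidence matrix with taxa
#' in rows and functions in columns.
#'
#' @param incidence binary matrix (taxa x functions); dimnames are used as
#'   identifiers when `taxon_ids`/`function_ids` are not given.
#' @param level `"gene"` for a GCN or `"protein"` for a PCN.
#' @param taxon_ids,function_ids optional identifier vectors overriding
#'   dimnames.
#' @return An object of class `"content_network"`: a list with elements
#'   `incidence` (binary matrix with dimnames) and `level`.
#' @examples
#' m <- rbind(T1 = c(red = 1, blue = 1), T2 = c(red = 1, blue = 0))
#' content_network(m, "gene")
#' @export
content_network <- function(incidence, level = c("gene", "protein"),
                            taxon_ids = rownames(incidence),
                            function_ids = colnames(incidence)) {
  level <- match.arg(level)
  incidence <- as.matrix(incidence)
  if (nrow(incidence) < 1L || ncol(incidence) < 1L)
    stop("a content network needs at least one taxon and one function")
  if (is.null(taxon_ids) || is.null(function_ids))
    stop("taxon and function identifiers are required")
  taxon_ids <- as.character(taxon_ids)
  function_ids <- as.character(function_ids)
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon identifiers")
  if (anyDuplicated(function_ids)) stop("duplicate function identifiers")
  storage.mode(incidence) <- "double"
  if (any(!incidence %in% c(0, 1)))
    stop("incidence entries must be 0 or 1")
  dimnames(incidence) <- list(taxon_ids, function_ids)
  structure(list(incidence = incidence, level = level),
            class = "content_network")
}

#' @export
print.content_network <- function(x, ...) {
  cat(sprintf("%s content network: %d taxa x %d functions, %d edges\n",
              if (x$level == "gene") "Gene (GCN)" else "Protein (PCN)",
              nrow(x$incidence), ncol(x$incidence), sum(x$incidence)))
  invisible(x)
}

#' Align a GCN/PCN pair onto shared functions and taxa
#'
#' Restricts both networks to the intersection of their function sets and the
#' union of their taxon sets (taxa missing from one network get all-zero rows:
#' they own or express nothing there). Profile abundances for taxa absent from
#' the profile are set to 0 and the profile is renormalized over the retained
#' taxa, so that it remains a proper composition. Row and column orders are
#' lexicographic, making outputs byte-stable.
#'
#' @param gcn gene-level [content_network()].
#' @param pcn protein-level [content_network()].
#' @param profile [taxonomic_profile()] covering at least one network taxon.
#' @return An object of class `"paired_networks"`: list with `gcn`, `pcn`
#'   (aligned content networks) and `profile` (renormalized).
#' @examples
#' fx <- two_species_example()
#' paired_networks(fx$gcn, fx$pcn, fx$profile)
#' @export
paired_networks <- function(gcn, pcn, profile) {
  stopifnot(inherits(gcn, "content_network"), inherits(pcn, "content_network"),
            inherits(profile, "taxonomic_profile"))
  if (gcn$level != "gene" || pcn$level != "protein")
    stop("'gcn' must be gene level and 'pcn' protein level")
  funs <- sort(intersect(colnames(gcn$incidence), colnames(pcn$incidence)))
  if (length(funs) == 0L)
    stop("the two networks share no functions")
  taxa <- sort(union(rownames(gcn$incidence), rownames(pcn$incidence)))
  if (!any(names(profile) %in% taxa))
    stop("profile taxa are disjoint from network taxa")
  expand <- function(net) {
    m <- matrix(0, length(taxa), length(funs), dimnames = list(taxa, funs))
    common <- intersect(rownames(net$incidence), taxa)
    m[common, ] <- net$incidence[common, funs, drop = FALSE]
    m
  }
  p <- setNames(numeric(length(taxa)), taxa)
  common <- intersect(names(profile), taxa)
  p[common] <- profile[common]
  if (sum(p) <= 0) stop("no profile mass on network taxa")
  p <- p / sum(p)
  structure(list(gcn = content_network(expand(gcn), "gene"),
                 pcn = content_network(expand(pcn), "protein"),
                 profile = taxonomic_profile(p)),
            class = "paired_networks")
}

#' @export
print.paired_networks <- function(x, ...) {
  cat(sprintf("Paired GCN/PCN: %d taxa, %d shared functions\n",
              nrow(x$gcn$incidence), ncol(x$gcn$incidence)))
  invisible(x)
}

#' Binary pair distance for one function
#'
#' Distance between two taxa with respect to a single function: 0 if and only
#' if both taxa carry (GCN) or express (PCN) the function, 1 otherwise.
#'
#' @param net a [content_network()].
#' @param function_id,taxon_i,taxon_j identifiers present in `net`.
#' @return 0 or 1.
#' @export
pair_distance <- function(net, function_id, taxon_i, taxon_j) {
  stopifnot(inherits(net, "content_network"))
  inc <- net$incidence
  for (id in c(taxon_i, taxon_j))
    if (!id %in% rownames(inc)) stop(sprintf("unknown taxon '%s'", id))
  if (!function_id %in% colnames(inc))
    stop(sprintf("unknown function '%s'", function_id))
  if (inc[taxon_i, function_id] == 1 && inc[taxon_j, function_id] == 1) 0 else 1
}

#' Per-function functional redundancy
#'
#' The abundance-weighted probability that two individuals drawn from
#' different taxa both carry (gene level) or express (protein level) the
#' function:
#' \deqn{FR = \sum_{i} \sum_{j \ne i} (1 - d_{ij}) p_i p_j,}
#' with the binary pair distance of [pair_distance()]. Because \eqn{1-d_{ij}}
#' is 1 exactly when both taxa own the function, this equals
#' \eqn{(\sum_{i \in O} p_i)^2 - \sum_{i \in O} p_i^2} over the owner set
#' \eqn{O}, which is how it is computed.
#'
#' @param net a [content_network()].
#' @param profile [taxonomic_profile()] aligned to the taxa of `net`.
#' @param function_id a single function identifier, or `NULL` for all
#'   functions at once (named vector).
#' @return Functional redundancy value(s) in `[0, 1 - sum(p^2)]`.
#' @examples
#' fx <- two_species_example()
#' functional_redundancy(fx$pcn, fx$profile, "red")  # expressed by one taxon: 0
#' @export
functional_redundancy <- function(net, profile, function_id = NULL) {
  stopifnot(inherits(net, "content_network"),
            inherits(profile, "taxonomic_profile"))
  inc <- net$incidence
  if (!setequal(names(profile), rownames(inc)))
    stop("profile taxa must match network taxa")
  p <- unclass(profile)[rownames(inc)]
  if (!is.null(function_id)) {
    if (!all(function_id %in% colnames(inc)))
      stop(sprintf("unknown function '%s'",
                   paste(setdiff(function_id, colnames(inc)), collapse = ", ")))
    inc <- inc[, function_id, drop = FALSE]
  }
  s1 <- as.vector(crossprod(inc, p))
  s2 <- as.vector(crossprod(inc, p^2))
  fr <- s1^2 - s2
  fr[fr < 0] <- 0  # guard round-off on single-owner functions
  setNames(fr, colnames(inc))
}

#' Taxonomic diversity (Simpson-type)
#'
#' \eqn{TD = 1 - \sum_i p_i^2}, the upper bound of functional redundancy for
#' any fully shared function under profile `p`.
#'
#' @param profile a [taxonomic_profile()].
#' @return A number in `[0, 1)`.
#' @export
taxonomic_diversity <- function(profile) {
  stopifnot(inherits(profile, "taxonomic_profile"))
  1 - sum(unclass(profile)^2)
}

#' Normalized functional redundancy
#'
#' `nFR = FR / TD`, mapping redundancy onto `[0, 1]` so that profiles with
#' different evenness become comparable. A single-taxon community has
#' `TD = 0`; its normalized redundancy is defined as 0.
#'
#' @param fr functional redundancy value(s).
#' @param td taxonomic diversity of the same profile.
#' @return `fr / td`, or 0 where `td == 0`.
#' @export
normalized_redundancy <- function(fr, td) {
  if (length(td) != 1L) stop("'td' must be a single value")
  if (td < 0 || td >= 1) stop("'td' must lie in [0, 1)")
  if (any(fr < -1e-12)) stop("'fr' must be non-negative")
  if (any(fr > td + 1e-12))
    stop("fr exceeds td: redundancy cannot exceed the taxonomic diversity of its own profile")
  if (td == 0) return(rep(0, length(fr)))
  pmin(pmax(fr / td, 0), 1)
}

#' Network degree of a function
#'
#' Number of taxa owning (GCN) or expressing (PCN) the function: the column
#' sum of the incidence matrix.
#'
#' @inheritParams functional_redundancy
#' @return Integer count(s) of taxa.
#' @export
network_degree <- function(net, function_id = NULL) {
  stopifnot(inherits(net, "content_network"))
  inc <- net$incidence
  if (!is.null(function_id)) {
    if (!all(function_id %in% colnames(inc)))
      stop(sprintf("unknown function '%s'",
                   paste(setdiff(function_id, colnames(inc)), collapse = ", ")))
    inc <- inc[, function_id, drop = FALSE]
  }
  k <- colSums(inc)
  storage.mode(k) <- "integer"
  k
}

#' Connectance of a content network
#'
#' Realized edges divided by the maximal possible number of edges
#' (taxa x functions).
#'
#' @param net a [content_network()].
#' @return A number in `[0, 1]`.
#' @export
connectance <- function(net) {
  stopifnot(inherits(net, "content_network"))
  sum(net$incidence) / length(net$incidence)
}

#' NODF nestedness of a binary matrix
#'
#' Nestedness metric based on Overlap and Decreasing Fill: for every ordered
#' pair of rows (and of columns) whose marginal totals strictly decrease, the
#' paired overlap is the fraction of the poorer line's presences also present
#' in the richer line; pairs with equal marginal totals contribute 0. The
#' statistic averages paired overlap across all row pairs and column pairs and
#' is reported here on the `[0, 1]` scale (the conventional 0-100 value is
#' this times 100).
#'
#' @param net a [content_network()] or a binary matrix.
#' @return NODF in `[0, 1]`.
#' @export
nodf <- function(net) {
  m <- if (inherits(net, "content_network")) net$incidence else as.matrix(net)
  if (any(!m %in% c(0, 1))) stop("matrix must be binary")
  if (nrow(m) < 2L && ncol(m) < 2L)
    stop("NODF needs at least two rows or two columns")
  axis_sum <- function(x) {
    mt <- rowSums(x)
    n <- nrow(x)
    if (n < 2L) return(c(0, 0))
    ov <- tcrossprod(x)                    # shared presences per line pair
    dec <- outer(mt, mt, ">") & rep(mt > 0, each = n)  # [hi, lo] with mt_hi > mt_lo > 0
    po <- ov / rep(pmax(mt, 1), each = n)  # ov[hi, lo] / mt[lo], columnwise
    c(sum(po[dec]), n * (n - 1) / 2)
  }
  r <- axis_sum(m)
  cl <- axis_sum(t(m))
  (r[1] + cl[1]) / (r[2] + cl[2])
}

#' Per-function metrics table for a paired GCN/PCN
#'
#' Computes, for every shared function: degrees `k_gcn`, `k_pcn`, functional
#' redundancies `fr_g`, `fr_p`, their normalized versions `nfr_g`, `nfr_p`,
#' and a flag marking functions whose protein-level redundancy exceeds the
#' gene-level one (a detection-depth artifact on real data: such records are
#' reported, never clamped).
#'
#' @param paired a [paired_networks()] object.
#' @return A data.frame with one row per function, in lexicographic function
#'   order, of class `c("function_metrics", "data.frame")`.
#' @examples
#' function_metrics(two_species_example()$paired)
#' @export
function_metrics <- function(paired) {
  stopifnot(inherits(paired, "paired_networks"))
  td <- taxonomic_diversity(paired$profile)
  fr_g <- functional_redundancy(paired$gcn, paired$profile)
  fr_p <- functional_redundancy(paired$pcn, paired$profile)
  out <- data.frame(
    function_id = colnames(paired$gcn$incidence),
    k_gcn = network_degree(paired$gcn),
    k_pcn = network_degree(paired$pcn),
    fr_g = unname(fr_g),
    fr_p = unname(fr_p),
    nfr_g = unname(normalized_redundancy(fr_g, td)),
    nfr_p = unname(normalized_redundancy(fr_p, td)),
    flag_frp_gt_frg = unname(fr_p > fr_g + 1e-12),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("function_metrics", "data.frame")
  attr(out, "td") <- td
  out
}
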