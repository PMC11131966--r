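#' Two-species, three-protein worked example
#'
#' The canonical didactic fixture: two taxa (T1, T2) and three proteins. Both
#' taxa encode the red protein but only T2 expresses it (niche function: the
#' degree drops from k_GCN = 2 to k_PCN = 1 and FR_p = 0); both encode and
#' express the green protein (essential function: no degree reduction,
#' FR_g = FR_p); only T1 encodes and expresses the blue protein (specialist:
#' FR_g = FR_p = 0).
#'
#' @param p relative abundances of (T1, T2); the default is the equal-
#'   abundance case, `c(0.9, 0.1)` gives the uneven variant.
#' @return List with `gcn`, `pcn`, `profile`, the aligned `paired` networks
#'   and `expected` -- the metrics table implied by the construction.
#' @examples
#' fx <- two_species_example()
#' function_metrics(fx$paired)
#' @export
two_species_example <- function(p = c(0.5, 0.5)) {
  stopifnot(length(p) == 2L)
  gcn <- content_network(
    matrix(c(1, 1,   # red: encoded by both
             1, 1,   # green: encoded by both
             1, 0),  # blue: encoded by T1 only
           nrow = 2, ncol = 3,
           dimnames = list(c("T1", "T2"), c("red", "green", "blue"))),
    level = "gene")
  pcn <- content_network(
    matrix(c(0, 1,   # red: expressed by T2 only
             1, 1,   # green: expressed by both
             1, 0),  # blue: expressed by T1 only
           nrow = 2, ncol = 3,
           dimnames = list(c("T1", "T2"), c("red", "green", "blue"))),
    level = "protein")
  profile <- taxonomic_profile(p, c("T1", "T2"))
  paired <- paired_networks(gcn, pcn, profile)
  td <- 1 - sum(p^2)
  shared <- 2 * p[1] * p[2]
  expected <- data.frame(
    function_id = c("blue", "green", "red"),
    k_gcn = c(1L, 2L, 2L),
    k_pcn = c(1L, 2L, 1L),
    fr_g = c(0, shared, shared),
    fr_p = c(0, shared, 0),
    nfr_g = c(0, shared / td, shared / td),
    nfr_p = c(0, shared / td, 0),
    stringsAsFactors = FALSE)
  list(gcn = gcn, pcn = pcn, profile = profile, paired = paired,
       expected = expected)
}

#' Planted paired networks with known function types
#'
#' A fast classifier fixture that bypasses community dynamics: ownership is
#' Bernoulli per type, and expression follows the idealized type semantics --
#' essential functions are expressed wherever owned, each niche function is
#' expressed by exactly one owning taxon (selective expression), and
#' specialist functions (low ownership) are expressed wherever owned.
#'
#' @param n_taxa number of taxa.
#' @param n_per_type functions per type.
#' @param p_own ownership probability for niche and essential functions.
#' @param p_spec ownership probability for specialist functions.
#' @param profile optional abundance vector (default uniform).
#' @param seed RNG seed.
#' @return List with `paired` ([paired_networks()]) and `labels`.
#' @export
planted_networks <- function(n_taxa = 40L, n_per_type = 20L, p_own = 0.7,
                             p_spec = 0.2, profile = NULL, seed = 1L) {
  set.seed(seed)
  labels <- setNames(
    rep(c("niche", "specialist", "essential"), each = n_per_type),
    c(sprintf("niche_%02d", seq_len(n_per_type)),
      sprintf("specialist_%02d", seq_len(n_per_type)),
      sprintf("essential_%02d", seq_len(n_per_type))))
  prob <- c(niche = p_own, specialist = p_spec, essential = p_own)[labels]
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  gcn_m <- matrix(rbinom(n_taxa * length(labels), 1L, rep(prob, each = n_taxa)),
                  n_taxa, length(labels), dimnames = list(taxa, names(labels)))
  ## guarantee every function has at least one owner so niche expression is
  ## well defined
  empty <- colSums(gcn_m) == 0
  if (any(empty)) gcn_m[sample.int(n_taxa, sum(empty), TRUE) +
                          (which(empty) - 1L) * n_taxa] <- 1L
  pcn_m <- gcn_m
  for (j in which(labels == "niche")) {
    owners <- which(gcn_m[, j] == 1)
    expresser <- if (length(owners) == 1L) owners else sample(owners, 1L)
    pcn_m[, j] <- 0L
    pcn_m[expresser, j] <- 1L
  }
  if (is.null(profile)) profile <- rep(1 / n_taxa, n_taxa)
  prof <- taxonomic_profile(profile, taxa, renormalize = TRUE)
  paired <- paired_networks(content_network(gcn_m, "gene"),
                            content_network(pcn_m, "protein"), prof)
  list(paired = paired, labels = labels[colnames(paired$gcn$incidence)])
}
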