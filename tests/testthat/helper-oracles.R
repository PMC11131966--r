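## Independent oracles and small generators shared across test files.

## Literal double-loop pair-sum for functional redundancy (the defining
## formula, not the closed form used by the package).
fr_oracle <- function(incidence, p) {
  vapply(seq_len(ncol(incidence)), function(f) {
    tot <- 0
    for (i in seq_along(p)) for (j in seq_along(p)) {
      if (i == j) next
      d <- if (incidence[i, f] == 1 && incidence[j, f] == 1) 0 else 1
      tot <- tot + (1 - d) * p[i] * p[j]
    }
    tot
  }, numeric(1))
}

## Random paired networks with PCN a subset of GCN.
random_paired <- function(n_taxa, n_fun, seed, p_own = 0.6, p_expr = 0.5) {
  set.seed(seed)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  funs <- sprintf("f%02d", seq_len(n_fun))
  g <- matrix(rbinom(n_taxa * n_fun, 1, p_own), n_taxa, n_fun,
              dimnames = list(taxa, funs))
  e <- g * matrix(rbinom(n_taxa * n_fun, 1, p_expr), n_taxa, n_fun)
  p <- as.vector(stats::runif(n_taxa)); p <- p / sum(p)
  paired_networks(content_network(g, "gene"),
                  content_network(e, "protein"),
                  taxonomic_profile(p, taxa))
}

## Three well-separated feature blobs laid out in the canonical type geometry
## (specialist near the origin, niche high gene-level / low protein-level,
## essential high on both axes).
blob_features <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  centers <- list(specialist = c(0.04, 0.02),
                  niche = c(0.50, 0.03),
                  essential = c(0.50, 0.42))
  f <- do.call(rbind, lapply(centers, function(ctr)
    cbind(rnorm(n_per, ctr[1], 0.015), rnorm(n_per, ctr[2], 0.015))))
  list(features = f, labels = rep(names(centers), each = n_per))
}

## Small, fast consumer-resource configuration for dynamics tests.
small_params <- function(seed = 1, ...) {
  crm_params(n_species = 400L, n_niche = 5L, n_specialist = 5L,
             n_essential = 5L, t_max = 2e5, seed = seed, ...)
}
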