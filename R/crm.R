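#' Consumer-resource model parameters
#'
#' Configuration for the community-assembly simulator. Each niche and each
#' specialist function is the ability to consume one unique, externally
#' supplied resource; essential functions do not consume anything but each
#' *missing* (unexpressed) essential function multiplies a species' uptake by
#' `1 - essential_penalty`. Species allocate a fixed catabolic proteome budget
#' evenly across their expressed consumption functions and pay a per-expressed
#' consumption-protein burden `expr_cost`, so parsimonious expressers are
#' favoured during assembly -- the mechanism behind selective expression of
#' niche functions.
#'
#' @param n_species size of the initial species pool.
#' @param n_niche,n_specialist,n_essential functions per type.
#' @param p_n,p_s,p_e genome-assignment probabilities per type.
#' @param p_expr probability that an encoded function is expressed.
#' @param essential_penalty growth multiplier decrement per missing
#'   (unexpressed) essential function.
#' @param expr_cost maintenance burden per expressed consumption protein
#'   (same units as `maintenance`).
#' @param maint_cv coefficient of variation of the lognormal per-species
#'   maintenance rate (breaks exact fitness ties between species with
#'   identical expressed repertoires).
#' @param resource_supply constant inflow rate per resource.
#' @param dilution abiotic resource loss rate.
#' @param maintenance per-capita death rate (median across species).
#' @param extinction_threshold abundance below which a species is removed.
#' @param steady_state_tol convergence tolerance on per-capita growth rates.
#' @param t_max maximum integration time.
#' @param h_max maximum integration step.
#' @param seed master seed; substreams are derived for genomes (`seed`),
#'   expression (`seed + 1`), random controls (`seed + 2`) and maintenance
#'   variation (`seed + 3`).
#' @return A list of class `"crm_params"`.
#' @export
crm_params <- function(n_species = 10000L, n_niche = 20L, n_specialist = 20L,
                       n_essential = 20L, p_n = 0.7, p_s = 0.2, p_e = 0.7,
                       p_expr = 0.35, essential_penalty = 0.05,
                       expr_cost = 0.1, maint_cv = 0.05,
                       resource_supply = 1, dilution = 0.1, maintenance = 0.1,
                       extinction_threshold = 1e-6, steady_state_tol = 1e-8,
                       t_max = 6e4, h_max = 0.5, seed = 1L) {
  pr <- c(p_n = p_n, p_s = p_s, p_e = p_e, p_expr = p_expr)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  if (essential_penalty < 0 || essential_penalty >= 1)
    stop("'essential_penalty' must lie in [0, 1)")
  cnt <- c(n_species, n_niche, n_specialist, n_essential)
  if (any(cnt < 1)) stop("counts must be positive")
  structure(list(n_species = as.integer(n_species),
                 n_niche = as.integer(n_niche),
                 n_specialist = as.integer(n_specialist),
                 n_essential = as.integer(n_essential),
                 p_n = p_n, p_s = p_s, p_e = p_e, p_expr = p_expr,
                 essential_penalty = essential_penalty,
                 expr_cost = expr_cost, maint_cv = maint_cv,
                 resource_supply = resource_supply, dilution = dilution,
                 maintenance = maintenance,
                 extinction_threshold = extinction_threshold,
                 steady_state_tol = steady_state_tol,
                 t_max = t_max, h_max = h_max, seed = as.integer(seed)),
            class = "crm_params")
}

.crm_function_ids <- function(params) {
  c(sprintf("niche_%02d", seq_len(params$n_niche)),
    sprintf("specialist_%02d", seq_len(params$n_specialist)),
    sprintf("essential_%02d", seq_len(params$n_essential)))
}

.crm_labels <- function(params) {
  setNames(rep(c("niche", "specialist", "essential"),
               c(params$n_niche, params$n_specialist, params$n_essential)),
           .crm_function_ids(params))
}

#' Draw a genome pool
#'
#' Every (species, function) cell is an independent Bernoulli draw whose
#' probability depends only on the function's type (`p_n`, `p_s`, `p_e`).
#'
#' @param params a [crm_params()] object.
#' @return A list of class `"genome_pool"` with `genome` (binary species x
#'   function matrix) and `function_labels` (named type vector).
#' @export
generate_genomes <- function(params) {
  stopifnot(inherits(params, "crm_params"))
  labels <- .crm_labels(params)
  prob <- c(niche = params$p_n, specialist = params$p_s,
            essential = params$p_e)[labels]
  set.seed(params$seed)
  genome <- matrix(rbinom(params$n_species * length(labels), 1L,
                          rep(prob, each = params$n_species)),
                   nrow = params$n_species, ncol = length(labels),
                   dimnames = list(sprintf("sp%05d", seq_len(params$n_species)),
                                   names(labels)))
  structure(list(genome = genome, function_labels = labels),
            class = "genome_pool")
}

#' Sub-sample expressed functions from a genome pool
#'
#' Each encoded function is retained (expressed) independently with
#' probability `p_expr`, so the expression matrix is always an elementwise
#' subset of the genome.
#'
#' @param pool a [generate_genomes()] result.
#' @param p_expr retention probability.
#' @param seed RNG seed for the expression substream.
#' @return Binary species x function matrix of expressed functions.
#' @export
subsample_expression <- function(pool, p_expr, seed) {
  stopifnot(inherits(pool, "genome_pool"))
  if (p_expr < 0 || p_expr > 1) stop("'p_expr' must lie in [0, 1]")
  set.seed(seed)
  keep <- matrix(rbinom(length(pool$genome), 1L, p_expr),
                 nrow = nrow(pool$genome))
  expressed <- pool$genome * keep
  dimnames(expressed) <- dimnames(pool$genome)
  expressed
}

#' Per-capita growth rate
#'
#' \deqn{g_i = (1 - \pi)^{m_i} \frac{1}{b_i} \sum_{a \in E_i} R_a
#'       - (\mu_i + c\, b_i)}
#' where \eqn{E_i} is the set of consumption (niche or specialist) functions
#' species *i* expresses, \eqn{b_i = |E_i|} its catabolic breadth (the fixed
#' uptake budget is split evenly), \eqn{m_i} the number of essential functions
#' it does *not* express, \eqn{\pi} the `essential_penalty`, \eqn{\mu_i} the
#' maintenance rate and \eqn{c} the `expr_cost` burden. A species expressing
#' no consumption function has zero uptake and a strictly negative growth
#' rate.
#'
#' @param expressed binary expression vector for one species (or a matrix,
#'   one row per species), with one entry per function.
#' @param resources named or ordered vector of resource concentrations, one
#'   per consumption (niche + specialist) function, in function order.
#' @param function_labels type vector ("niche"/"specialist"/"essential")
#'   aligned with the columns of `expressed`.
#' @param params a [crm_params()] object.
#' @param maintenance optional per-species maintenance rate(s); defaults to
#'   `params$maintenance` for every species.
#' @return Numeric growth rate(s), one per species.
#' @export
growth_rate <- function(expressed, resources, function_labels, params,
                        maintenance = params$maintenance) {
  stopifnot(inherits(params, "crm_params"))
  if (is.null(dim(expressed))) expressed <- matrix(expressed, nrow = 1L)
  cons <- function_labels != "essential"
  if (sum(cons) != length(resources))
    stop("'resources' must have one entry per consumption function")
  if (any(resources < 0)) stop("resources must be non-negative")
  E <- expressed[, cons, drop = FALSE]
  b <- rowSums(E)
  alloc <- E / pmax(b, 1)
  m_miss <- sum(!cons) - rowSums(expressed[, !cons, drop = FALSE])
  eps <- (1 - params$essential_penalty)^m_miss
  as.vector(eps * (alloc %*% resources)) - (maintenance + params$expr_cost * b)
}

#' Assemble a community to steady state
#'
#' Integrates the consumer-resource dynamics
#' \deqn{dN_i/dt = N_i g_i, \qquad
#'       dR_a/dt = s - \delta R_a - R_a \sum_i N_i c_{ia}}
#' with the growth rates of [growth_rate()] and allocation
#' \eqn{c_{ia} = e_{ia}/b_i}, from \eqn{N_i = 1/n} and \eqn{R_a = 1}. Because
#' resources are linear given abundances and abundances grow exponentially
#' given resources, the integrator is a Lie-splitting exponential scheme:
#' resources are updated exactly under frozen abundances and abundances by a
#' trapezoidal exponential step, with the step size adapted so that no species
#' changes by more than ~20% per step (capped at `h_max`). Fixed points of the
#' dynamics are fixed points of the scheme.
#'
#' Species falling below `extinction_threshold` are removed at every step. The
#' run is declared steady when every established species (abundance above
#' 1/1000 of the current maximum) has `|g| < steady_state_tol` while all
#' remaining stragglers are strictly declining; such stragglers carry
#' negligible biomass and are deterministically extinct, and are removed from
#' the survivor set. If `t_max` is reached first the result is flagged
#' non-steady rather than raising an error.
#'
#' @param params a [crm_params()] object.
#' @param pool optional pre-built [generate_genomes()] pool.
#' @param expression optional pre-built expression matrix (defaults to
#'   [subsample_expression()] with the expression substream seed).
#' @return An object of class `"crm_assembly"` with survivor identifiers,
#'   relative abundances (summing to 1), steady-state resources, survivor
#'   genome/expression sub-matrices, function labels, a trajectory summary
#'   (time, surviving species, total biomass) and the convergence flag.
#' @export
assemble_community <- function(params, pool = NULL, expression = NULL) {
  stopifnot(inherits(params, "crm_params"))
  if (is.null(pool)) pool <- generate_genomes(params)
  if (is.null(expression))
    expression <- subsample_expression(pool, params$p_expr, params$seed + 1L)
  if (any(expression > pool$genome))
    stop("expression must be a subset of the genome")
  labels <- pool$function_labels
  cons <- labels != "essential"
  set.seed(params$seed + 3L)
  m_i <- params$maintenance * exp(rnorm(nrow(pool$genome), 0, params$maint_cv))

  E <- expression[, cons, drop = FALSE]
  b <- rowSums(E)
  alloc_all <- E / pmax(b, 1)
  m_miss <- sum(!cons) - rowSums(expression[, !cons, drop = FALSE])
  eps_all <- (1 - params$essential_penalty)^m_miss
  mtot_all <- m_i + params$expr_cost * b

  alive <- seq_len(nrow(pool$genome))
  C <- alloc_all
  eps <- eps_all
  mtot <- mtot_all
  N <- rep(1 / params$n_species, nrow(pool$genome))
  R <- rep(1, sum(cons))

  t_cur <- 0; converged <- FALSE; nstep <- 0L
  traj <- list()
  tol <- params$steady_state_tol
  while (t_cur < params$t_max) {
    g <- eps * as.vector(C %*% R) - mtot
    established <- N > 1e-3 * max(N)
    if (max(abs(g[established])) < tol && all(g[!established] < 0)) {
      converged <- TRUE
      break
    }
    A <- params$dilution + as.vector(crossprod(C, N))
    Rstar <- params$resource_supply / A
    h <- min(0.2 / max(abs(g)), params$h_max, params$t_max - t_cur)
    decay <- exp(-A * h)
    R <- Rstar + (R - Rstar) * decay
    g2 <- eps * as.vector(C %*% R) - mtot
    N <- N * exp(0.5 * (g + g2) * h)
    t_cur <- t_cur + h
    nstep <- nstep + 1L
    keep <- N >= params$extinction_threshold
    if (!all(keep)) {
      N <- N[keep]; C <- C[keep, , drop = FALSE]
      eps <- eps[keep]; mtot <- mtot[keep]; alive <- alive[keep]
    }
    if (nstep %% 200L == 0L)
      traj[[length(traj) + 1L]] <- c(t_cur, length(alive), sum(N))
  }
  if (length(alive) == 0L)
    stop("all species went extinct; check parameters")
  ## drop stragglers: negligible biomass and still strictly declining
  g <- eps * as.vector(C %*% R) - mtot
  straggler <- g < 0 & N <= 1e-3 * max(N)
  alive <- alive[!straggler]
  N <- N[!straggler]
  traj <- do.call(rbind, traj)
  trajectory <- if (is.null(traj)) {
    data.frame(time = numeric(), n_species = integer(), biomass = numeric())
  } else {
    data.frame(time = traj[, 1], n_species = as.integer(traj[, 2]),
               biomass = traj[, 3])
  }
  ids <- rownames(pool$genome)[alive]
  structure(list(
    survivor_ids = ids,
    abundance = setNames(N / sum(N), ids),
    resources = setNames(R, names(labels)[cons]),
    genome = pool$genome[alive, , drop = FALSE],
    expressed = expression[alive, , drop = FALSE],
    function_labels = labels,
    converged = converged,
    t_final = t_cur,
    trajectory = trajectory,
    params = params
  ), class = "crm_assembly")
}

#' @export
print.crm_assembly <- function(x, ...) {
  cat(sprintf(
    "Consumer-resource assembly: %d survivors of %d species (%s at t = %.0f)\n",
    length(x$survivor_ids), x$params$n_species,
    if (x$converged) "steady" else "NOT steady", x$t_final))
  invisible(x)
}

#' @export
summary.crm_assembly <- function(object, ...) {
  k <- tapply(colSums(object$expressed), object$function_labels, mean)
  cat(sprintf("Survivors: %d | converged: %s | t = %.0f\n",
              length(object$survivor_ids), object$converged, object$t_final))
  cat("Mean expressed degree by function type:\n")
  print(round(k, 2))
  cat(sprintf("Abundance evenness (1 - sum p^2): %.3f\n",
              1 - sum(object$abundance^2)))
  invisible(object)
}

#' @export
plot.crm_assembly <- function(x, ...) {
  if (nrow(x$trajectory) == 0) {
    warning("no trajectory recorded")
    return(invisible(x))
  }
  graphics::plot(x$trajectory$time, x$trajectory$n_species, log = "xy",
                 type = "l", xlab = "time", ylab = "surviving species", ...)
  invisible(x)
}

#' Build paired networks from an assembled community
#'
#' The survivors' genome rows become the GCN, their expression rows the PCN,
#' and the steady-state relative abundances the taxonomic profile; ground
#' truth function labels are carried through.
#'
#' @param assembly a [assemble_community()] result with at least 2 survivors.
#' @return List with `paired` ([paired_networks()]) and `labels` (named type
#'   vector over the shared functions, in the paired network's column order).
#' @export
crm_networks <- function(assembly) {
  stopifnot(inherits(assembly, "crm_assembly"))
  if (length(assembly$survivor_ids) < 2L)
    stop("need at least two survivors to build networks")
  gcn <- content_network(assembly$genome, "gene")
  pcn <- content_network(assembly$expressed, "protein")
  profile <- taxonomic_profile(assembly$abundance)
  paired <- paired_networks(gcn, pcn, profile)
  labels <- assembly$function_labels[colnames(paired$gcn$incidence)]
  list(paired = paired, labels = labels)
}

#' Random control networks without assembly
#'
#' Picks `n_pick` species uniformly at random from the initial pool -- no
#' community dynamics -- and builds the GCN/PCN from their genome and
#' expression rows, with either equal abundances or a user-supplied abundance
#' vector (e.g. the surviving community's abundances).
#'
#' @param pool a [generate_genomes()] pool.
#' @param expression expression matrix for the pool (see
#'   [subsample_expression()]).
#' @param n_pick number of species to sample.
#' @param abundances optional abundance vector of length `n_pick`; default is
#'   equal abundances `1/n_pick`.
#' @param seed RNG seed for the control substream.
#' @return List with `paired` and `labels`, as in [crm_networks()].
#' @export
random_control_networks <- function(pool, expression, n_pick,
                                    abundances = NULL, seed) {
  stopifnot(inherits(pool, "genome_pool"))
  if (n_pick > nrow(pool$genome)) stop("'n_pick' exceeds the pool size")
  set.seed(seed)
  pick <- sample.int(nrow(pool$genome), n_pick)
  if (is.null(abundances)) abundances <- rep(1 / n_pick, n_pick)
  if (length(abundances) != n_pick)
    stop("'abundances' must have length 'n_pick'")
  ids <- rownames(pool$genome)[pick]
  gcn <- content_network(pool$genome[pick, , drop = FALSE], "gene")
  pcn <- content_network(expression[pick, , drop = FALSE], "protein")
  profile <- taxonomic_profile(abundances, ids, renormalize = TRUE)
  paired <- paired_networks(gcn, pcn, profile)
  labels <- pool$function_labels[colnames(paired$gcn$incidence)]
  list(paired = paired, labels = labels)
}
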