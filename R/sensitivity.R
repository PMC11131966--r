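#' Apply an abundance percentile threshold to a content network
#'
#' Emulates detection depth: keeps only the edges whose abundance ranks in the
#' top `keep_percent` percent of all nonzero abundance entries (global ranking
#' across the whole matrix), zeroing the rest. Ties at the cutoff are all
#' retained, which makes the operation deterministic and order-independent.
#' `keep_percent = 100` returns the network unchanged.
#'
#' @param net a [content_network()].
#' @param abund non-negative taxon x function abundance/intensity matrix,
#'   aligned with `net` and zero wherever the incidence is zero.
#' @param keep_percent percentage (0-100) of most abundant entries kept.
#' @return A filtered [content_network()] of the same level.
#' @export
apply_percentile_threshold <- function(net, abund, keep_percent) {
  stopifnot(inherits(net, "content_network"))
  abund <- as.matrix(abund)
  if (!identical(dim(abund), dim(net$incidence)))
    stop("abundance matrix shape does not match the network")
  if (any(abund < 0)) stop("abundances must be non-negative")
  if (any(abund[net$incidence == 0] != 0))
    stop("abundance must be zero where the network has no edge")
  if (keep_percent < 0 || keep_percent > 100)
    stop("'keep_percent' must lie in [0, 100]")
  if (keep_percent == 100) return(net)
  inc <- net$incidence
  vals <- abund[inc == 1 & abund > 0]
  n_keep <- floor(keep_percent / 100 * length(vals) + 1e-9)
  keep <- matrix(FALSE, nrow(inc), ncol(inc))
  if (n_keep > 0) {
    cutoff <- sort(vals, decreasing = TRUE)[n_keep]
    keep <- abund >= cutoff & inc == 1
  }
  out <- inc
  out[!keep] <- 0
  content_network(out, net$level)
}

#' Redundancy as a function of detection depth (PAPT/GAPT sweep)
#'
#' Recomputes per-function FR_g and FR_p while varying the gene abundance
#' percentile threshold (GAPT, applied to the GCN) and the protein abundance
#' percentile threshold (PAPT, applied to the PCN). FR_g depends only on the
#' GCN and FR_p only on the PCN, so both filters are swept over the same grid
#' in one pass. For each GAPT level the sweep also counts the functions whose
#' unfiltered FR_p exceeds the filtered FR_g -- the detection-depth artifact
#' that produces FR_p > FR_g records on real data.
#'
#' @param paired a [paired_networks()] object.
#' @param abund_g,abund_p abundance matrices aligned with the GCN and PCN.
#' @param grid numeric vector of keep-percent levels.
#' @return An object of class `"fr_sweep"`: list with `sweep` (long
#'   data.frame: `threshold_level`, `function_id`, `fr_g`, `fr_p`) and
#'   `frp_exceeds` (data.frame: `threshold_level`, `n_frp_gt_frg`).
#' @export
threshold_sweep <- function(paired, abund_g, abund_p,
                            grid = c(100, 80, 60, 40, 20)) {
  stopifnot(inherits(paired, "paired_networks"))
  fr_p_full <- functional_redundancy(paired$pcn, paired$profile)
  rows <- list(); excess <- list()
  for (th in grid) {
    gcn_f <- apply_percentile_threshold(paired$gcn, abund_g, th)
    pcn_f <- apply_percentile_threshold(paired$pcn, abund_p, th)
    fr_g <- functional_redundancy(gcn_f, paired$profile)
    fr_p <- functional_redundancy(pcn_f, paired$profile)
    rows[[length(rows) + 1L]] <- data.frame(
      threshold_level = th,
      function_id = names(fr_g),
      fr_g = unname(fr_g),
      fr_p = unname(fr_p),
      stringsAsFactors = FALSE)
    excess[[length(excess) + 1L]] <- data.frame(
      threshold_level = th,
      n_frp_gt_frg = sum(fr_p_full > fr_g + 1e-12))
  }
  structure(list(sweep = do.call(rbind, rows),
                 frp_exceeds = do.call(rbind, excess)),
            class = "fr_sweep")
}

#' @export
print.fr_sweep <- function(x, ...) {
  cat("PAPT/GAPT sweep over", length(unique(x$sweep$threshold_level)),
      "levels x", length(unique(x$sweep$function_id)), "functions\n")
  print(x$frp_exceeds)
  invisible(x)
}
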