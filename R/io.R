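#' Read a taxon x function incidence table
#'
#' Tab-separated, UTF-8: first column taxon identifiers, header row of
#' function identifiers, cells 0/1. Non-binary cells, duplicated identifiers
#' and ragged rows raise errors that name the offending coordinates.
#'
#' @param path file path.
#' @param level `"gene"` or `"protein"`.
#' @return A [content_network()].
#' @export
read_incidence <- function(path, level = c("gene", "protein")) {
  level <- match.arg(level)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("incidence file needs a header and >= 1 row")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  n_col <- length(header)
  fun_ids <- header[-1L]
  if (anyDuplicated(fun_ids))
    stop("duplicate function identifiers in header")
  rows <- parts[-1L]
  bad <- which(lengths(rows) != n_col)
  if (length(bad))
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 bad[1L] + 1L, n_col, length(rows[[bad[1L]]])))
  taxa <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(taxa)) stop("duplicate taxon identifiers")
  m <- matrix(0, length(rows), length(fun_ids),
              dimnames = list(taxa, fun_ids))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    off <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(off))
      stop(sprintf("non-binary cell at row %d ('%s'), column %d ('%s')",
                   i + 1L, taxa[i], off[1L] + 1L, fun_ids[off[1L]]))
    m[i, ] <- v
  }
  content_network(m, level)
}

#' Write a content network as a TSV incidence table
#'
#' Inverse of [read_incidence()]: `read_incidence(write_incidence(x))` is
#' bit-identical to `x`.
#'
#' @param net a [content_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(net, path) {
  stopifnot(inherits(net, "content_network"))
  inc <- net$incidence
  lines <- c(paste(c("taxon_id", colnames(inc)), collapse = "\t"),
             vapply(seq_len(nrow(inc)), function(i)
               paste(c(rownames(inc)[i], format(inc[i, ], trim = TRUE)),
                     collapse = "\t"), ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a taxonomic profile from a two-column TSV
#'
#' Columns: `taxon_id`, `relative_abundance`. Negative abundances always
#' error; a sum far from 1 errors unless `renormalize = TRUE`.
#'
#' @param path file path.
#' @param renormalize rescale to sum to 1.
#' @param tol tolerance on the sum before renormalization is required.
#' @return A [taxonomic_profile()].
#' @export
read_profile <- function(path, renormalize = FALSE, tol = 1e-6) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("profile file needs two columns")
  p <- as.numeric(df[[2L]])
  if (any(is.na(p))) stop("non-numeric abundance values")
  taxonomic_profile(p, df[[1L]], renormalize = renormalize, tol = tol)
}

#' Write a taxonomic profile
#' @param profile a [taxonomic_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "taxonomic_profile"))
  utils::write.table(
    data.frame(taxon_id = names(profile),
               relative_abundance = as.numeric(profile)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a function annotation table
#'
#' TSV with columns `function_id`, `family` and optionally `category`;
#' function identifiers must be unique.
#'
#' @param path file path.
#' @return data.frame with `function_id`, `family` and, when present,
#'   `category`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation file needs at least two columns")
  names(df)[1:2] <- c("function_id", "family")
  if (ncol(df) >= 3L) names(df)[3] <- "category"
  if (anyDuplicated(df$function_id))
    stop("duplicate function_id in annotation")
  df
}

#' Write a per-function metrics table
#' @param metrics a [function_metrics()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_function_metrics <- function(metrics, path) {
  utils::write.table(as.data.frame(metrics), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
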