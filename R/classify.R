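#' Extract a 2-column feature matrix from metrics or raw input
#'
#' @param x a [function_metrics()] table or a 2-column numeric matrix /
#'   data.frame (rows = functions).
#' @param feature_space `"redundancy"` for (fr_g, fr_p), `"degree"` for
#'   (k_gcn, k_pcn) divided by the taxon count so that synthetic and real
#'   scales are comparable.
#' @param n_taxa taxon count used to scale degrees; taken from the metrics
#'   table attribute when available.
#' @return Numeric matrix with one row per function; rownames are function
#'   identifiers when available.
#' @keywords internal
.fr_features <- function(x, feature_space, n_taxa = NULL) {
  if (inherits(x, "function_metrics") ||
      (is.data.frame(x) && all(c("fr_g", "fr_p") %in% names(x)))) {
    if (feature_space == "redundancy") {
      f <- cbind(x$fr_g, x$fr_p)
    } else {
      if (is.null(n_taxa)) n_taxa <- attr(x, "n_taxa")
      if (is.null(n_taxa))
        stop("'n_taxa' is required for the degree feature space")
      f <- cbind(x$k_gcn, x$k_pcn) / n_taxa
    }
    rownames(f) <- x$function_id
  } else {
    f <- as.matrix(x)
    if (ncol(f) != 2L) stop("features must have exactly two columns")
  }
  storage.mode(f) <- "double"
  if (any(!is.finite(f))) stop("features must be finite")
  colnames(f) <- if (feature_space == "redundancy") c("fr_g", "fr_p")
                 else c("k_gcn_scaled", "k_pcn_scaled")
  f
}

## Full-covariance Gaussian-mixture EM. Restarts are k-means seeded; when true
## labels are supplied a label-derived initialization joins the pool.
## Solutions in which one component absorbs more than `max_prop` of the points
## are discarded as degenerate (the synthetic reference design is balanced),
## unless nothing else converged.
.fit_gmm <- function(x, G = 3L, restarts = 10L, tol = 1e-6, max_iter = 1000L,
                     reg = 1e-6, seed = 1L, labels = NULL, max_prop = 0.5) {
  n <- nrow(x); d <- ncol(x)
  if (nrow(unique(x)) < G)
    stop("need at least ", G, " distinct feature points")
  ridge <- diag(rep(reg, d), d)
  set.seed(seed)
  inits <- replicate(restarts,
                     suppressWarnings(stats::kmeans(x, G, nstart = 1))$cluster,
                     simplify = FALSE)
  if (!is.null(labels)) {
    lab <- as.integer(factor(labels))
    if (length(unique(lab)) == G) inits <- c(inits, list(lab))
  }
  run_em <- function(cl0) {
    mu <- do.call(rbind, lapply(seq_len(G), function(g)
      colMeans(x[cl0 == g, , drop = FALSE])))
    pro <- pmax(tabulate(cl0, G), 1) / n
    sig <- lapply(seq_len(G), function(g) {
      xs <- x[cl0 == g, , drop = FALSE]
      S <- if (nrow(xs) > 1) stats::cov(xs) else matrix(0, d, d)
      S + ridge
    })
    ll_old <- -Inf; ll <- -Inf; z <- NULL
    for (it in seq_len(max_iter)) {
      logdens <- vapply(seq_len(G), function(g) {
        xc <- x - matrix(mu[g, ], n, d, byrow = TRUE)
        Si <- solve(sig[[g]])
        -0.5 * (rowSums((xc %*% Si) * xc) +
                  determinant(sig[[g]])$modulus[1] + d * log(2 * pi)) +
          log(pro[g])
      }, numeric(n))
      mx <- apply(logdens, 1, max)
      lse <- mx + log(rowSums(exp(logdens - mx)))
      ll <- sum(lse)
      z <- exp(logdens - lse)
      nk <- pmax(colSums(z), 1e-12)
      pro <- nk / n
      for (g in seq_len(G)) {
        mu[g, ] <- colSums(z[, g] * x) / nk[g]
        xc <- x - matrix(mu[g, ], n, d, byrow = TRUE)
        sig[[g]] <- crossprod(xc * z[, g], xc) / nk[g] + ridge
      }
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(loglik = ll, mean = mu, sigma = sig, pro = pro, z = z)
  }
  fits <- lapply(inits, run_em)
  ok <- vapply(fits, function(f) is.finite(f$loglik) && max(f$pro) <= max_prop,
               logical(1))
  pool <- if (any(ok)) fits[ok] else fits
  pool[[which.max(vapply(pool, `[[`, 0, "loglik"))]]
}

.gmm_posterior <- function(model, x) {
  n <- nrow(x); d <- ncol(x); G <- nrow(model$mean)
  logdens <- vapply(seq_len(G), function(g) {
    xc <- x - matrix(model$mean[g, ], n, d, byrow = TRUE)
    Si <- solve(model$sigma[[g]])
    -0.5 * (rowSums((xc %*% Si) * xc) +
              determinant(model$sigma[[g]])$modulus[1] + d * log(2 * pi)) +
      log(model$pro[g])
  }, numeric(n))
  if (n == 1L) logdens <- matrix(logdens, nrow = 1L)
  mx <- apply(logdens, 1, max)
  z <- exp(logdens - (mx + log(rowSums(exp(logdens - mx)))))
  z
}

#' Map mixture components to function types by centroid geometry
#'
#' In either feature plane the three types occupy canonical regions:
#' specialist functions sit lowest on the gene-level axis; of the remaining
#' two components the one higher on the protein-level axis is essential and
#' the other is niche (widely encoded, selectively expressed).
#'
#' @param centroids numeric matrix with 3 rows (components) and 2 columns
#'   (gene-level feature, protein-level feature).
#' @return Character vector of length 3: the type of each component.
#' @examples
#' map_components_to_types(rbind(c(0.02, 0.01), c(0.3, 0.02), c(0.25, 0.22)))
#' @export
map_components_to_types <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != 3L || ncol(centroids) != 2L)
    stop("'centroids' must be a 3 x 2 matrix")
  if (anyDuplicated(round(centroids, 12)))
    stop("coincident centroids cannot be mapped to types")
  out <- character(3)
  spec <- which.min(centroids[, 1])
  out[spec] <- "specialist"
  rest <- setdiff(1:3, spec)
  ess <- rest[which.max(centroids[rest, 2])]
  out[ess] <- "essential"
  out[setdiff(rest, ess)] <- "niche"
  out
}

## Majority-label component mapping: the bijection maximizing agreement with
## the true labels; ties are broken in favour of the geometric mapping.
.map_by_labels <- function(cluster, labels, centroids) {
  types <- c("specialist", "niche", "essential")
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  geo <- tryCatch(map_components_to_types(centroids),
                  error = function(e) NULL)
  best <- -1L; best_map <- NULL
  for (pm in perms) {
    mp <- types[pm]
    a <- sum(mp[cluster] == labels)
    if (a > best || (a == best && !is.null(geo) && identical(mp, geo))) {
      best <- a; best_map <- mp
    }
  }
  best_map
}

#' Fit a specialist/niche/essential function-type classifier
#'
#' The central model of the package: given per-function feature pairs --
#' (FR_g, FR_p) redundancies or taxon-scaled (k_GCN, k_PCN) degrees -- fits a
#' reference model with three components and a bijective component-to-type
#' mapping. Methods:
#'
#' * `"gmm"` (default): full-covariance 3-component Gaussian mixture fitted by
#'   EM with k-means-seeded restarts (see Details);
#' * `"kmeans"`: K-means with K = 3 and multiple restarts, hard assignments;
#' * `"qda"`: supervised quadratic discriminant analysis, requiring `labels`
#'   for all three types.
#'
#' Components are mapped to types by majority true label when `labels` are
#' given (ties broken by centroid geometry), otherwise purely by geometry via
#' [map_components_to_types()].
#'
#' @details For the mixture, restart solutions in which a single component
#' absorbs more than half the functions are discarded as degenerate: on
#' synthetic reference data the design is balanced and such solutions merge
#' the two near-zero-variance clusters into one slab. When labels are
#' supplied, a label-derived initialization is added to the restart pool.
#' Singular class covariances in QDA are handled by refitting with a small
#' diagonal ridge rather than failing.
#'
#' @param x a [function_metrics()] table or 2-column feature matrix.
#' @param labels optional true type per row (`"specialist"`, `"niche"`,
#'   `"essential"`); required for `method = "qda"`.
#' @param method classifier kind.
#' @param feature_space `"redundancy"` or `"degree"` (see [.fr_features]).
#' @param seed RNG seed controlling all restarts.
#' @param restarts number of random restarts (gmm / kmeans).
#' @param rescale logical; store per-axis min-max rescaling fitted on the
#'   training features and apply it when predicting (off by default: raw
#'   redundancy transfers from synthetic to real data unchanged).
#' @param reg covariance ridge for the mixture (and the QDA fallback).
#' @param n_taxa taxon count for the degree feature space when `x` does not
#'   carry it.
#' @return An object of class `"fr_classifier"` with elements `method`,
#'   `feature_space`, `mapping` (component type vector), `model` (fitted
#'   parameters), `features` (training matrix), `assignments` (training
#'   [predict.fr_classifier()] output) and `seed`.
#' @seealso [predict.fr_classifier()], [evaluate_accuracy()]
#' @examples
#' set.seed(1)
#' f <- rbind(matrix(rnorm(40, c(0.05, 0.02), 0.01), ncol = 2, byrow = TRUE),
#'            matrix(rnorm(40, c(0.50, 0.02), 0.02), ncol = 2, byrow = TRUE),
#'            matrix(rnorm(40, c(0.50, 0.40), 0.02), ncol = 2, byrow = TRUE))
#' fit <- fr_classify(f, seed = 1)
#' table(predict(fit, f)$assigned_type)
#' @export
fr_classify <- function(x, labels = NULL,
                        method = c("gmm", "kmeans", "qda"),
                        feature_space = c("redundancy", "degree"),
                        seed = 1L, restarts = 10L, rescale = FALSE,
                        reg = 1e-6, n_taxa = NULL) {
  method <- match.arg(method)
  feature_space <- match.arg(feature_space)
  feats <- .fr_features(x, feature_space, n_taxa)
  if (nrow(unique(feats)) < 2L)
    stop("degenerate features: all points identical")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(feats))
      stop("'labels' must have one entry per row of 'x'")
    bad <- setdiff(unique(labels), c("specialist", "niche", "essential"))
    if (length(bad))
      stop("unknown labels: ", paste(bad, collapse = ", "))
  }
  scaling <- NULL
  train <- feats
  if (rescale) {
    lo <- apply(feats, 2, min); hi <- apply(feats, 2, max)
    hi <- ifelse(hi > lo, hi, lo + 1)
    scaling <- list(lo = lo, hi = hi)
    train <- sweep(sweep(feats, 2, lo), 2, hi - lo, "/")
  }
  model <- switch(method,
    gmm = {
      fit <- .fit_gmm(train, restarts = restarts, reg = reg, seed = seed,
                      labels = labels)
      cl <- apply(fit$z, 1, which.max)
      mapping <- if (is.null(labels)) map_components_to_types(fit$mean)
                 else .map_by_labels(cl, labels, fit$mean)
      list(fit = fit, mapping = mapping, centroids = fit$mean)
    },
    kmeans = {
      if (nrow(unique(train)) < 3L)
        stop("k-means needs at least 3 distinct points")
      set.seed(seed)
      km <- suppressWarnings(stats::kmeans(train, 3L, nstart = restarts))
      mapping <- if (is.null(labels)) map_components_to_types(km$centers)
                 else .map_by_labels(km$cluster, labels, km$centers)
      list(fit = km, mapping = mapping, centroids = km$centers)
    },
    qda = {
      if (is.null(labels))
        stop("QDA is supervised: training 'labels' are required")
      if (length(unique(labels)) < 3L)
        stop("QDA training needs all three types present")
      fit <- tryCatch(
        MASS::qda(train, grouping = factor(labels)),
        error = function(e) NULL)
      if (is.null(fit)) {
        ## ridge-regularized Gaussian discriminants (documented fallback)
        grp <- split(seq_len(nrow(train)), labels)
        fit <- list(ridge = lapply(grp, function(ix) {
          xs <- train[ix, , drop = FALSE]
          S <- if (nrow(xs) > 1) stats::cov(xs) else matrix(0, 2, 2)
          list(mean = colMeans(xs), sigma = S + diag(2) * max(reg, 1e-6),
               prior = length(ix) / nrow(train))
        }))
      }
      centroids_types <- c("specialist", "niche", "essential")
      list(fit = fit, mapping = centroids_types, centroids = NULL)
    })
  obj <- structure(list(method = method, feature_space = feature_space,
                        mapping = model$mapping, model = model$fit,
                        centroids = model$centroids, scaling = scaling,
                        features = feats, labels = labels, seed = seed,
                        call = match.call()),
                   class = "fr_classifier")
  obj$assignments <- predict(obj, feats)
  obj
}

#' Predict function types
#'
#' @param object a fitted [fr_classify()] model.
#' @param newdata a [function_metrics()] table or 2-column feature matrix; an
#'   empty input yields an empty assignment table.
#' @param n_taxa taxon count for the degree feature space.
#' @param ... unused.
#' @return A data.frame with columns `function_id`, `assigned_type` and the
#'   per-type posterior probabilities `p_specialist`, `p_niche`,
#'   `p_essential` (hard 0/1 for k-means). Posteriors sum to 1 per row and the
#'   assigned type is the posterior argmax.
#' @export
predict.fr_classifier <- function(object, newdata, n_taxa = NULL, ...) {
  empty <- data.frame(function_id = character(), assigned_type = character(),
                      p_specialist = numeric(), p_niche = numeric(),
                      p_essential = numeric(), stringsAsFactors = FALSE)
  if (is.null(newdata) || NROW(newdata) == 0L) return(empty)
  feats <- .fr_features(newdata, object$feature_space, n_taxa)
  if (!is.null(object$scaling))
    feats <- sweep(sweep(feats, 2, object$scaling$lo), 2,
                   object$scaling$hi - object$scaling$lo, "/")
  types <- c("specialist", "niche", "essential")
  post_by_type <- matrix(0, nrow(feats), 3, dimnames = list(NULL, types))
  if (object$method == "gmm") {
    z <- .gmm_posterior(object$model, feats)
    for (g in seq_len(ncol(z)))
      post_by_type[, object$mapping[g]] <-
        post_by_type[, object$mapping[g]] + z[, g]
  } else if (object$method == "kmeans") {
    d2 <- vapply(seq_len(nrow(object$model$centers)), function(g)
      rowSums(sweep(feats, 2, object$model$centers[g, ])^2), numeric(nrow(feats)))
    if (nrow(feats) == 1L) d2 <- matrix(d2, nrow = 1L)
    hard <- apply(d2, 1, which.min)
    for (i in seq_along(hard))
      post_by_type[i, object$mapping[hard[i]]] <- 1
  } else {
    if (!is.null(object$model$ridge)) {
      ld <- vapply(object$model$ridge, function(cls) {
        xc <- sweep(feats, 2, cls$mean)
        Si <- solve(cls$sigma)
        -0.5 * (rowSums((xc %*% Si) * xc) +
                  determinant(cls$sigma)$modulus[1]) + log(cls$prior)
      }, numeric(nrow(feats)))
      if (nrow(feats) == 1L) ld <- matrix(ld, nrow = 1L,
                                          dimnames = list(NULL, names(object$model$ridge)))
      mx <- apply(ld, 1, max)
      z <- exp(ld - (mx + log(rowSums(exp(ld - mx)))))
      post_by_type[, colnames(z)] <- z
    } else {
      pr <- stats::predict(object$model, feats)
      post_by_type[, colnames(pr$posterior)] <- pr$posterior
    }
  }
  ids <- rownames(feats)
  if (is.null(ids)) ids <- sprintf("f%04d", seq_len(nrow(feats)))
  data.frame(function_id = ids,
             assigned_type = types[max.col(post_by_type, ties.method = "first")],
             p_specialist = post_by_type[, "specialist"],
             p_niche = post_by_type[, "niche"],
             p_essential = post_by_type[, "essential"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.fr_classifier <- function(x, ...) {
  cat(sprintf("Function-type classifier (%s, %s features)\n",
              toupper(x$method), x$feature_space))
  if (!is.null(x$centroids)) {
    cm <- cbind(as.data.frame(round(x$centroids, 4)), type = x$mapping)
    print(cm)
  }
  invisible(x)
}

#' @export
summary.fr_classifier <- function(object, ...) {
  print(object)
  cat("\nTraining assignments:\n")
  print(table(object$assignments$assigned_type))
  invisible(object)
}

#' @export
plot.fr_classifier <- function(x, ...) {
  cols <- c(specialist = "#377eb8", niche = "#e41a1c", essential = "#4daf4a")
  graphics::plot(x$features, col = cols[x$assignments$assigned_type],
                 pch = 19, ...)
  if (!is.null(x$centroids))
    graphics::points(x$centroids, pch = 3, cex = 2,
                     col = cols[x$mapping], lwd = 2)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}

#' Assumed ground-truth mapping of protein families to function types
#'
#' ABC-type transporters are taken as niche functions (resource-uptake
#' machinery under ecological selection), ribosomal proteins as essential
#' functions (indispensable for growth), and PTS (phosphotransferase system)
#' proteins as specialist functions.
#'
#' @return Named character vector: family -> type.
#' @export
ground_truth_map <- function() {
  c("ABC-type transporter" = "niche",
    "ribosomal protein" = "essential",
    "PTS" = "specialist")
}

#' Score assignments against assumed ground-truth families
#'
#' Joins type assignments with a family annotation, maps families to assumed
#' types via `truth`, and reports per-family and overall accuracy. Functions
#' whose family is not in `truth` (e.g. unknown-function families) are
#' classified but excluded from scoring.
#'
#' @param assignments output of [predict.fr_classifier()] (or any data.frame
#'   with `function_id` and `assigned_type`).
#' @param annotation data.frame with columns `function_id` and `family`.
#' @param truth named character vector family -> type; defaults to
#'   [ground_truth_map()].
#' @return An object of class `"fr_accuracy"`: list with `per_family`
#'   (family, n_correct, n_total, accuracy), `n_correct`, `n_total`,
#'   `accuracy`.
#' @export
evaluate_accuracy <- function(assignments, annotation,
                              truth = ground_truth_map()) {
  stopifnot(all(c("function_id", "assigned_type") %in% names(assignments)),
            all(c("function_id", "family") %in% names(annotation)))
  m <- merge(assignments, annotation, by = "function_id")
  m <- m[m$family %in% names(truth), , drop = FALSE]
  if (nrow(m) == 0L)
    stop("no annotated functions from the evaluated families")
  m$true_type <- truth[m$family]
  per <- do.call(rbind, lapply(split(m, m$family), function(d)
    data.frame(family = d$family[1],
               n_correct = sum(d$assigned_type == d$true_type),
               n_total = nrow(d),
               accuracy = mean(d$assigned_type == d$true_type),
               stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  structure(list(per_family = per,
                 n_correct = sum(per$n_correct),
                 n_total = sum(per$n_total),
                 accuracy = sum(per$n_correct) / sum(per$n_total)),
            class = "fr_accuracy")
}

#' @export
print.fr_accuracy <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.1f%% (%d/%d)\n", 100 * x$accuracy,
              x$n_correct, x$n_total))
  print(x$per_family)
  invisible(x)
}
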