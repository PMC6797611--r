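#' Affinity propagation hyperparameters
#'
#' @param damping Update damping factor in `[0.5, 1)`; higher is more
#'   stable, slower.
#' @param preference Self-similarity controlling how readily points
#'   become exemplars: a number, or `"median"` for the median
#'   off-diagonal similarity (a moderate cluster count without fixing
#'   K in advance).
#' @param max_iterations Iteration cap.
#' @param convergence_window Number of consecutive iterations the
#'   exemplar set must stay unchanged to declare convergence.
#' @return A list of class `ap_parameters`.
#' @export
ap_parameters <- function(damping = 0.9, preference = "median",
                          max_iterations = 1000L, convergence_window = 50L) {
  if (!is.numeric(damping) || damping < 0.5 || damping >= 1) {
    stop("`damping` must lie in [0.5, 1).", call. = FALSE)
  }
  if (!(identical(preference, "median") || (is.numeric(preference) && is.finite(preference)))) {
    stop("`preference` must be a finite number or \"median\".", call. = FALSE)
  }
  if (max_iterations < 1L || convergence_window < 1L) {
    stop("`max_iterations` and `convergence_window` must be positive.", call. = FALSE)
  }
  structure(list(damping = damping, preference = preference,
                 max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window)),
            class = "ap_parameters")
}

#' Threshold a region matrix to binary
#'
#' Entries strictly above `threshold` become 1, the rest 0; missing
#' entries stay missing. This reproduces the binary-matrix variant of
#' subject clustering once a threshold is chosen (e.g. 0 for signed
#' z-maps, or a matrix quantile).
#'
#' @param S A [region_matrix].
#' @param threshold Finite scalar.
#' @return A [region_matrix] with entries in `{0, 1}` (and `NA`).
#' @export
binarize_matrix <- function(S, threshold) {
  stopifnot(inherits(S, "region_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop("`threshold` must be a single finite number.", call. = FALSE)
  }
  B <- ifelse(unclass(S) > threshold, 1, 0)
  new_region_matrix(B, attr(S, "region_labels"), attr(S, "region_names"),
                    attr(S, "subject_ids"), paste0(attr(S, "statistic"), ">",
                                                   format(threshold)))
}

# Core affinity propagation (Frey & Dueck message passing) on a
# similarity matrix. Vectorized responsibility/availability updates
# with damping; exemplars are the points k with r(k,k) + a(k,k) > 0.
ap_message_passing <- function(sim, params) {
  N <- nrow(sim)
  pref <- if (identical(params$preference, "median")) {
    stats::median(sim[row(sim) != col(sim)])
  } else {
    params$preference
  }
  S <- sim
  diag(S) <- pref
  # tiny zero-mean deterministic jitter breaks exact ties that otherwise
  # oscillate; index-derived, so no RNG state is touched, and scaled to
  # the last representable digit so robust outcomes are unaffected
  jit <- outer(seq_len(N), seq_len(N),
               function(i, j) ((i * 173 + j * 331) %% 997) / 997 - 0.5)
  S <- S + abs(S) * .Machine$double.eps * jit
  R <- matrix(0, N, N)
  A <- matrix(0, N, N)
  lam <- params$damping
  stable <- 0L
  prev_ex <- integer(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iterations)) {
    iters <- it
    # responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    AS <- A + S
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(N), max1_idx)]
    AS2 <- AS
    AS2[cbind(seq_len(N), max1_idx)] <- -Inf
    max2 <- AS2[cbind(seq_len(N), max.col(AS2, ties.method = "first"))]
    Rnew <- S - max1
    Rnew[cbind(seq_len(N), max1_idx)] <- S[cbind(seq_len(N), max1_idx)] - max2
    R <- lam * R + (1 - lam) * Rnew
    # availabilities: a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsums <- colSums(Rp)
    Anew <- matrix(colsums, N, N, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- lam * A + (1 - lam) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, prev_ex) && length(ex) > 0L) {
      stable <- stable + 1L
      if (stable >= params$convergence_window) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
      prev_ex <- ex
    }
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0L) {
    ex <- which.max(diag(R) + diag(A))
  }
  assign_ex <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_ex[ex] <- ex  # exemplars belong to themselves
  # refine: re-pick each cluster's exemplar to maximize within-cluster similarity
  for (e in unique(assign_ex)) {
    members <- which(assign_ex == e)
    if (length(members) > 1L) {
      best <- members[which.max(colSums(S[members, members, drop = FALSE]))]
      assign_ex[members] <- best
    }
  }
  list(exemplar_of = assign_ex, converged = converged, iterations = iters,
       preference = pref)
}

#' Cluster subjects with affinity propagation
#'
#' Partitions the N subjects of a region matrix into exemplar-based
#' subgroups. Each subject's column is a point; similarity between
#' two subjects is the negative squared Euclidean distance between
#' their region vectors. Message passing exchanges responsibilities
#' and availabilities until the exemplar set is stable; the number of
#' clusters is not fixed in advance, and every cluster is represented
#' by one of the actual subjects (its exemplar), not an average.
#'
#' @param S A [region_matrix] with N >= 2 subjects and no missing
#'   entries (impute or drop affected regions first; missing data is
#'   refused, never silently filled).
#' @param params An [ap_parameters()] object.
#' @param binarize Optional threshold: when given, clustering runs on
#'   [binarize_matrix()] output instead of the raw values.
#' @return A list of class `brainglance_clusters`: `assignments`
#'   (integer cluster id per subject, named by subject id),
#'   `exemplars` (subject index per cluster), `sizes`, `order`
#'   (display order: descending size, ties by exemplar index),
#'   `converged`, `iterations`, `parameters`.
#' @export
cluster_subjects <- function(S, params = ap_parameters(), binarize = NULL) {
  stopifnot(inherits(S, "region_matrix"), inherits(params, "ap_parameters"))
  X <- unclass(S)
  if (!is.null(binarize)) X <- unclass(binarize_matrix(S, binarize))
  if (ncol(X) < 2L) stop("Clustering needs at least 2 subjects.", call. = FALSE)
  if (anyNA(X)) {
    stop("Region matrix has missing entries; exclude the affected regions ",
         "or impute before clustering.", call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(t(X)))^2
  if (max(d2) == 0) {
    # all subjects identical: message passing carries no information,
    # the only sensible partition is one cluster around subject 1
    res <- list(exemplar_of = rep(1L, ncol(X)), converged = TRUE,
                iterations = 0L, preference = 0)
  } else {
    res <- ap_message_passing(-d2, params)
  }
  if (!res$converged) {
    warning("Affinity propagation did not converge within ",
            params$max_iterations, " iterations; returning current state.",
            call. = FALSE)
  }
  ex_subjects <- sort(unique(res$exemplar_of))
  sizes <- vapply(ex_subjects, function(e) sum(res$exemplar_of == e), integer(1))
  ord <- order(-sizes, ex_subjects)
  cluster_id <- match(res$exemplar_of, ex_subjects[ord])
  structure(
    list(assignments = stats::setNames(cluster_id, attr(S, "subject_ids")),
         exemplars = ex_subjects[ord],
         sizes = sizes[ord],
         order = seq_along(ord),
         subject_ids = attr(S, "subject_ids"),
         converged = res$converged, iterations = res$iterations,
         preference = res$preference, parameters = params),
    class = "brainglance_clusters"
  )
}

#' @export
print.brainglance_clusters <- function(x, ...) {
  cat("<brainglance_clusters> ", length(x$sizes), " cluster(s) over ",
      length(x$assignments), " subjects",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("  sizes: ", paste(x$sizes, collapse = ", "), "\n", sep = "")
  cat("  exemplars: ", paste(x$subject_ids[x$exemplars], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-subject view of a clustering
#'
#' @param x A `brainglance_clusters` object.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `cluster`, `exemplar_id`,
#'   `is_exemplar`.
#' @method tidy brainglance_clusters
#' @export
tidy.brainglance_clusters <- function(x, ...) {
  tibble::tibble(
    subject_id = names(x$assignments),
    cluster = unname(x$assignments),
    exemplar_id = x$subject_ids[x$exemplars[x$assignments]],
    is_exemplar = names(x$assignments) == x$subject_ids[x$exemplars[x$assignments]]
  )
}

#' One-row summary of a clustering
#'
#' @param x A `brainglance_clusters` object.
#' @param ... Unused.
#' @method glance brainglance_clusters
#' @export
glance.brainglance_clusters <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$assignments), n_clusters = length(x$sizes),
    largest = max(x$sizes), smallest = min(x$sizes),
    converged = x$converged, iterations = x$iterations,
    preference = x$preference
  )
}

#' Serialize a clustering to JSON
#'
#' @param x A `brainglance_clusters` object.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @export
clusters_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "brainglance_clusters"))
  js <- jsonlite::toJSON(
    list(assignments = as.list(x$assignments),
         exemplars = x$subject_ids[x$exemplars],
         sizes = x$sizes, converged = x$converged,
         iterations = x$iterations, preference = x$preference,
         parameters = list(damping = x$parameters$damping,
                           preference = x$parameters$preference,
                           max_iterations = x$parameters$max_iterations,
                           convergence_window = x$parameters$convergence_window)),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Collapse a region matrix to cluster-level columns
#'
#' One column per cluster, in display order: either the member-wise
#' mean of the (un-binarized) values or the exemplar subject's own
#' column. Cluster sizes are carried along so the renderer can scale
#' row heights.
#'
#' @param S The subject-level [region_matrix].
#' @param clusters A `brainglance_clusters` from [cluster_subjects()].
#' @param statistic `"mean"` or `"exemplar"`.
#' @return A [region_matrix] over clusters with a `sizes` attribute.
#' @export
summarize_clusters <- function(S, clusters, statistic = "mean") {
  stopifnot(inherits(S, "region_matrix"), inherits(clusters, "brainglance_clusters"))
  if (!identical(attr(S, "subject_ids"), clusters$subject_ids)) {
    stop("Clustering and region matrix refer to different subjects.", call. = FALSE)
  }
  if (!statistic %in% c("mean", "exemplar")) {
    stop("Unknown cluster statistic '", statistic,
         "'; use \"mean\" or \"exemplar\".", call. = FALSE)
  }
  X <- unclass(S)
  cols <- purrr::map(clusters$order, function(cid) {
    members <- which(clusters$assignments == cid)
    if (statistic == "mean") {
      rowMeans(X[, members, drop = FALSE], na.rm = TRUE)
    } else {
      X[, clusters$exemplars[cid]]
    }
  })
  M <- do.call(cbind, cols)
  M[is.nan(M)] <- NA_real_
  ids <- paste0("cluster-", clusters$order, " (",
                clusters$subject_ids[clusters$exemplars],
                ", n=", clusters$sizes, ")")
  new_region_matrix(M, attr(S, "region_labels"), attr(S, "region_names"),
                    ids, attr(S, "statistic"), sizes = clusters$sizes)
}

#' Voxel-wise mean map per cluster
#'
#' Averages the subjects' 3D maps within each cluster, e.g. to show a
#' representative activation map per subgroup.
#'
#' @param maps List of [scalar_volume()]s, one per subject, on one grid.
#' @param clusters A `brainglance_clusters`; its subject order must
#'   match `maps`.
#' @return List of [scalar_volume()]s, one per cluster in display order.
#' @export
cluster_mean_volumes <- function(maps, clusters) {
  stopifnot(inherits(clusters, "brainglance_clusters"),
            length(maps) == length(clusters$assignments))
  ref <- dim(maps[[1L]]$grid)
  for (m in maps) {
    if (!identical(dim(m$grid), ref)) {
      stop("All maps must share one grid; got ", paste(dim(m$grid), collapse = "x"),
           " vs ", paste(ref, collapse = "x"), ".", call. = FALSE)
    }
  }
  purrr::map(clusters$order, function(cid) {
    members <- which(clusters$assignments == cid)
    acc <- Reduce(`+`, purrr::map(maps[members], "grid")) / length(members)
    scalar_volume(acc, voxel_size = maps[[members[1L]]]$voxel_size,
                  space_tag = paste0("cluster-", cid))
  })
}
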