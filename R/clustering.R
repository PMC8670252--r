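#' Row-standardize expression profiles for soft clustering
#'
#' Each profile is scaled to mean 0 and standard deviation 1 so that
#' clustering groups temporal shapes, not amplitudes. Rows with missing
#' values are excluded (counted in a message); zero-variance (flat) rows are
#' excluded with a warning since a shape cannot be defined for them.
#' Standardization is idempotent.
#'
#' @param table expression_table (log2fc or signal) or a numeric matrix
#' @return numeric N x D matrix of standardized profiles
#' @export
standardize_profiles <- function(table) {
  x <- if (inherits(table, "expression_table")) table$values else as.matrix(table)
  if (ncol(x) < 2) stop("standardize_profiles: need >= 2 columns")
  complete <- !apply(x, 1, anyNA)
  if (any(!complete)) {
    message(sprintf("standardize_profiles: %d incomplete rows excluded", sum(!complete)))
    x <- x[complete, , drop = FALSE]
  }
  sds <- apply(x, 1, stats::sd)
  if (all(sds == 0)) stop("standardize_profiles: all rows have zero variance")
  if (any(sds == 0)) {
    warning(sprintf("standardize_profiles: %d zero-variance rows excluded", sum(sds == 0)),
            call. = FALSE)
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (x - rowMeans(x)) / sds
}

#' Build the clustering input from a fold-change table
#'
#' Prepends the implicit reference column (log2fc = 0 at the reference time
#' point) so that profiles span all sampling times, then standardizes. With
#' the default four-time-point design this yields the D = 4 profiles the
#' fuzzifier estimate is calibrated on.
#'
#' @param fc_table replicate-mean log2fc expression_table
#' @return standardized N x D matrix
#' @export
cluster_input <- function(fc_table) {
  stopifnot(inherits(fc_table, "expression_table"))
  if (fc_table$value_kind != "log2fc") stop("cluster_input: need a log2fc table")
  x <- cbind(t0 = 0, fc_table$values)
  standardize_profiles(x)
}

#' Closed-form fuzzifier estimate
#'
#' The fuzzy c-means fuzzifier m controls how soft memberships are; this
#' returns the Schwaemmle-Jensen estimate as a function of the number of
#' profiles N and their dimension D:
#' \deqn{m = 1 + (1418/N + 22.05) D^{-2} +
#'           (12.33/N + 0.243) D^{-0.0406 \ln N - 0.1134}}
#' It decreases in D and stays above 1 (m -> 1 recovers hard k-means).
#'
#' @param N number of profiles (>= 2)
#' @param D profile dimension (number of time points, >= 1)
#' @return fuzzifier m > 1
#' @export
estimate_fuzzifier <- function(N, D) {
  if (!is.finite(N) || !is.finite(D) || N < 2 || D < 1) {
    stop("estimate_fuzzifier: need N >= 2 and D >= 1")
  }
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means clustering
#'
#' Alternating minimization of the objective
#' \deqn{J = \sum_i \sum_k u_{ik}^m \|x_i - v_k\|^2}
#' with the standard update rules: centroids
#' \eqn{v_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m} and memberships
#' \eqn{u_{ik} = 1 / \sum_j (\|x_i - v_k\| / \|x_i - v_j\|)^{2/(m-1)}}.
#' A point coinciding with a centroid gets membership 1 there and 0
#' elsewhere (the singularity rule). Initialization samples `c` distinct
#' rows as centroids; `nstart` restarts are run and the fit with the lowest
#' objective is kept, which stabilizes the method's sensitivity to
#' initialization. Convergence is declared when the largest membership
#' change drops below `tol`.
#'
#' @param X numeric N x D matrix (typically standardized profiles)
#' @param c number of clusters, 2 <= c < N
#' @param m fuzzifier > 1
#' @param seed integer seed for reproducible initialization
#' @param tol convergence tolerance on max |delta u| (default 1e-9)
#' @param max_iter iteration cap per restart (default 1000)
#' @param nstart random restarts (default 10)
#' @return object of class `cluster_model`: list with `c`, `m`, `centroids`
#'   (c x D), `memberships` (N x c, rows sum to 1), `objective`,
#'   `objective_trace`, `converged`, `direction` (per-cluster
#'   "induced"/"repressed"), `assignments` (NULL until
#'   [assign_clusters()] is applied)
#' @export
fuzzy_cmeans <- function(X, c, m, seed = 1, tol = 1e-9, max_iter = 1000,
                         nstart = 10) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (c < 2 || c >= N) stop("fuzzy_cmeans: need 2 <= c < N")
  if (m <= 1) stop("fuzzy_cmeans: fuzzifier m must exceed 1")
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(nstart)) {
    init <- X[sample.int(N, c), , drop = FALSE]
    fit <- fcm_single(X, init, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  centroids <- best$centroids
  rownames(centroids) <- paste0("cluster", seq_len(c))
  memberships <- best$memberships
  dimnames(memberships) <- list(rownames(X), rownames(centroids))
  structure(list(
    c = c, m = m,
    centroids = centroids,
    memberships = memberships,
    objective = best$objective,
    objective_trace = best$trace,
    converged = best$converged,
    direction = centroid_directions(centroids),
    assignments = NULL
  ), class = "cluster_model")
}

# One FCM run from a fixed initial centroid matrix.
fcm_single <- function(X, centroids, m, tol, max_iter) {
  N <- nrow(X)
  c <- nrow(centroids)
  u <- fcm_memberships(X, centroids, m)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- u^m
    centroids <- (t(w) %*% X) / colSums(w)
    u_new <- fcm_memberships(X, centroids, m)
    trace <- c(trace, fcm_objective(X, centroids, u_new, m))
    if (max(abs(u_new - u)) < tol) {
      u <- u_new
      converged <- TRUE
      break
    }
    u <- u_new
  }
  list(centroids = centroids, memberships = u,
       objective = fcm_objective(X, centroids, u, m),
       trace = trace, converged = converged)
}

# Squared Euclidean distances of every row of X to every centroid.
fcm_dist2 <- function(X, centroids) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centroids))) -
    2 * X %*% t(centroids) +
    outer(rep(1, nrow(X)), rowSums(centroids^2))
  pmax(d2, 0)
}

fcm_memberships <- function(X, centroids, m) {
  d2 <- fcm_dist2(X, centroids)
  p <- 1 / (m - 1)
  inv <- (1 / pmax(d2, .Machine$double.xmin))^p
  u <- inv / rowSums(inv)
  zero <- d2 < 1e-300
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ][zero[hit, , drop = FALSE]] <- 1 / rowSums(zero)[hit]
  }
  u
}

fcm_objective <- function(X, centroids, u, m) {
  sum(u^m * fcm_dist2(X, centroids))
}

# induced iff the centroid entry of maximal absolute value is positive
centroid_directions <- function(centroids) {
  apply(centroids, 1, function(v) {
    if (v[which.max(abs(v))] > 0) "induced" else "repressed"
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: c = %d, m = %.3f, J = %.4f (%s)\n",
              x$c, x$m, x$objective,
              if (x$converged) "converged" else "NOT converged"))
  cat("directions:", paste(x$direction, collapse = ", "), "\n")
  if (!is.null(x$assignments)) {
    cat(sprintf("assignments: %d of %d profiles assigned\n",
                sum(!is.na(x$assignments)), length(x$assignments)))
  }
  invisible(x)
}

#' Select the cluster count by the elbow of the minimum centroid distance
#'
#' For each candidate c the model is fitted and the minimum pairwise
#' centroid distance recorded. This curve collapses once c exceeds the
#' number of genuine profile shapes (extra centroids split a real cluster
#' and land close together), so the elbow is the last candidate before the
#' collapse. Deterministic detection rule: compute second differences of
#' the curve over the interior candidates; a flat-then-drop kink at c makes
#' the second difference there strongly negative. The elbow is the most
#' negative second difference among those within half the maximum
#' magnitude (ties to the smaller c), accepted when the curve actually
#' halves across it (d(c) >= 2 d(c+1)). If no interior kink qualifies but
#' the curve halves right after the smallest candidate, the kink sits at
#' the range boundary and the smallest candidate is returned. Otherwise
#' the data show no elbow (e.g. a single featureless blob) and the
#' smallest candidate is returned with a low-confidence warning.
#'
#' @param X standardized N x D matrix
#' @param m fuzzifier
#' @param c_range candidate cluster counts (default 2:12); at least 3
#' @param seed seed for each fit
#' @param nstart restarts per candidate (default 5; the final model is
#'   typically refitted with more)
#' @return list: `c` (chosen count), `curve` (data.frame c, min_centroid_dist)
#' @export
select_cluster_count <- function(X, m, c_range = 2:12, seed = 1, nstart = 5) {
  c_range <- sort(unique(as.integer(c_range)))
  if (length(c_range) < 3) stop("select_cluster_count: need >= 3 candidates (elbow undefined)")
  if (max(c_range) >= nrow(X)) stop("select_cluster_count: c_range must stay below N")
  dmin <- vapply(c_range, function(cc) {
    fit <- fuzzy_cmeans(X, cc, m, seed = seed, nstart = nstart)
    min(stats::dist(fit$centroids))
  }, numeric(1))
  curve <- data.frame(c = c_range, min_centroid_dist = dmin)
  # Second difference d[i-1] - 2 d[i] + d[i+1]: strongly negative at the
  # last candidate before a flat-then-drop kink.
  nd <- length(dmin)
  d2 <- dmin[seq_len(nd - 2)] - 2 * dmin[seq(2, nd - 1)] + dmin[seq(3, nd)]
  interior <- c_range[seq(2, length(c_range) - 1)]
  halves_after <- function(i) dmin[i] >= 2 * dmin[i + 1]
  qualifying <- which(d2 < 0 & abs(d2) >= 0.5 * max(abs(d2)))
  if (length(qualifying) > 0) {
    cand <- qualifying[which.min(d2[qualifying])]
    if (halves_after(cand + 1)) {           # cand + 1: index of interior c in dmin
      return(list(c = interior[cand], curve = curve))
    }
  }
  if (halves_after(1)) {
    # the kink sits at the lower range boundary
    return(list(c = c_range[1], curve = curve))
  }
  warning("select_cluster_count: no elbow detected (low confidence); returning the smallest candidate",
          call. = FALSE)
  list(c = c_range[1], curve = curve)
}

#' Apply the membership filters and assign profiles to clusters
#'
#' A profile is assigned to its maximum-membership cluster when that
#' membership reaches `membership_min`. Profiles below that gate are
#' rescued when their summed membership over the two same-direction
#' clusters (the induced pair, or the repressed pair) exceeds
#' `combined_min`; they are then assigned to the larger of the two.
#' Everything else stays unassigned (`NA`).
#'
#' @param model cluster_model
#' @param membership_min minimum single membership (default 0.5)
#' @param combined_min minimum combined same-direction membership,
#'   strict > (default 0.6)
#' @return the model with `assignments` filled in (named integer vector,
#'   NA = unassigned)
#' @export
assign_clusters <- function(model, membership_min = 0.5, combined_min = 0.6) {
  stopifnot(inherits(model, "cluster_model"))
  u <- model$memberships
  top <- max.col(u, ties.method = "first")
  topval <- u[cbind(seq_len(nrow(u)), top)]
  assign <- ifelse(topval >= membership_min, top, NA_integer_)
  dir <- model$direction
  for (d in unique(dir)) {
    idx <- which(dir == d)
    if (length(idx) < 2) next
    combined <- rowSums(u[, idx, drop = FALSE])
    rescue <- is.na(assign) & combined > combined_min
    if (any(rescue)) {
      within <- idx[max.col(u[rescue, idx, drop = FALSE], ties.method = "first")]
      assign[rescue] <- within
    }
  }
  names(assign) <- rownames(u)
  model$assignments <- assign
  model
}

#' Cluster assignment table
#'
#' @param model cluster_model with assignments
#' @return data.frame: feature_id, cluster (NA = unassigned), direction,
#'   max_membership
#' @export
assignment_table <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(model$assignments)) stop("assignment_table: run assign_clusters() first")
  u <- model$memberships
  data.frame(
    feature_id = rownames(u),
    cluster = unname(model$assignments),
    direction = ifelse(is.na(model$assignments), NA_character_,
                       model$direction[model$assignments]),
    max_membership = unname(apply(u, 1, max)),
    stringsAsFactors = FALSE
  )
}
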