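#' K-medoids (PAM) clustering of trajectory rows
#'
#' Partitions the rows of a series matrix around k medoids with Euclidean
#' distance, using the PAM build + swap algorithm (swaps are applied until no
#' exchange of a medoid with a non-medoid lowers the total within-cluster
#' distance-to-medoid). PAM's deterministic BUILD initialisation makes the
#' result reproducible without randomness; the \code{seed} argument is kept in
#' the interface for callers that treat clustering as a seeded stage.
#'
#' On very small instances the deterministic BUILD start can leave the swap
#' phase in a visible local optimum, so a few seeded random restarts are added
#' there; for cohort-sized inputs BUILD + swap alone is used.
#'
#' @param x numeric matrix, one series per row.
#' @param k number of clusters, \code{2 <= k <= nrow(x)} (k = n is allowed and
#'   yields singleton clusters).
#' @param seed integer governing the random-restart initialisations (only
#'   consulted on small instances); the calling R session's RNG state is
#'   preserved.
#' @param restarts number of extra random medoid initialisations; default
#'   (NULL) uses 10 when \code{nrow(x) <= 30} and 0 otherwise.
#' @return object of class \code{cluster_solution}: list with \code{k},
#'   \code{labels} (integer vector), \code{medoid_indices} (row indices),
#'   \code{objective} (total distance to medoids), \code{db_index} (NA until
#'   filled by \code{\link{select_k}}) and \code{per_k_db} (NULL here).
#' @export
kmedoids <- function(x, k, seed = NULL, restarts = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("input error: k must not exceed the number of series", call. = FALSE)
  if (k < 1) stop("input error: k must be at least 1", call. = FALSE)
  if (is.null(restarts)) restarts <- if (n <= 30) 10L else 0L
  if (k == n) {
    # every point its own medoid; pam itself requires k < n
    return(structure(list(k = as.integer(k), labels = seq_len(n),
                          medoid_indices = seq_len(n), objective = 0,
                          db_index = NA_real_, per_k_db = NULL),
                     class = "cluster_solution"))
  }
  fit <- cluster::pam(x, k, metric = "euclidean", keep.diss = FALSE,
                      keep.data = FALSE)
  labels <- as.integer(fit$clustering)
  med <- as.integer(fit$id.med)
  obj <- pam_cost(x, med)
  if (restarts > 0 && k < n) {
    rs <- restart_medoid_sets(n, k, restarts, seed)
    for (start in rs) {
      f2 <- tryCatch(cluster::pam(x, k, medoids = start, metric = "euclidean",
                                  keep.diss = FALSE, keep.data = FALSE),
                     error = function(e) NULL)
      if (is.null(f2)) next
      o2 <- pam_cost(x, as.integer(f2$id.med))
      if (o2 < obj - 1e-12) {
        obj <- o2
        med <- as.integer(f2$id.med)
        labels <- as.integer(f2$clustering)
      }
    }
  }
  structure(list(k = as.integer(k), labels = labels, medoid_indices = med,
                 objective = obj, db_index = NA_real_, per_k_db = NULL),
            class = "cluster_solution")
}

# deterministic restart sets; leaves the caller's RNG stream untouched
restart_medoid_sets <- function(n, k, restarts, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(if (is.null(seed)) 20240101L else as.integer(seed))
  replicate(restarts, sample.int(n, k), simplify = FALSE)
}

# total distance of each row to its nearest medoid
pam_cost <- function(x, medoid_idx) {
  d <- vapply(medoid_idx, function(m)
    sqrt(rowSums(sweep(x, 2, x[m, ])^2)), numeric(nrow(x)))
  sum(apply(as.matrix(d), 1, min))
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("K-medoids solution: k = %d, objective = %.3f", x$k, x$objective))
  if (!is.na(x$db_index)) cat(sprintf(", Davies-Bouldin = %.3f", x$db_index))
  cat("\n  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  if (!is.null(x$per_k_db)) {
    cat("  DB by k:\n")
    print(round(x$per_k_db, 4))
  }
  invisible(x)
}

#' Davies-Bouldin cluster validity index
#'
#' Classical (centroid-based) definition: with \eqn{S_i} the mean Euclidean
#' distance of cluster-i members to the cluster-i centre and \eqn{M_{ij}} the
#' distance between centres,
#' \deqn{DB = \frac{1}{k}\sum_i \max_{j \ne i} \frac{S_i + S_j}{M_{ij}}.}
#' Lower is better. Setting \code{center = "medoid"} replaces centroids by the
#' supplied medoids, matching the medoid-based partition geometry.
#'
#' @param x numeric matrix of series.
#' @param labels cluster assignment per row (at least 2 non-empty clusters).
#' @param center \code{"centroid"} (default, classical) or \code{"medoid"}.
#' @param medoid_indices row indices of medoids, required for
#'   \code{center = "medoid"}.
#' @return non-negative scalar.
#' @export
davies_bouldin <- function(x, labels, center = c("centroid", "medoid"),
                           medoid_indices = NULL) {
  center <- match.arg(center)
  x <- as.matrix(x)
  ks <- sort(unique(labels))
  if (length(ks) < 2)
    stop("input error: Davies-Bouldin needs at least 2 clusters", call. = FALSE)
  if (any(tabulate(match(labels, ks)) == 0))
    stop("input error: empty cluster", call. = FALSE)
  centres <- if (center == "centroid") {
    t(vapply(ks, function(g) colMeans(x[labels == g, , drop = FALSE]),
             numeric(ncol(x))))
  } else {
    if (is.null(medoid_indices) || length(medoid_indices) != length(ks))
      stop("input error: medoid_indices required for center = 'medoid'",
           call. = FALSE)
    x[medoid_indices, , drop = FALSE]
  }
  S <- vapply(seq_along(ks), function(i) {
    rows <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, centres[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(dist(centres))
  k <- length(ks)
  ratios <- vapply(seq_len(k), function(i) {
    others <- setdiff(seq_len(k), i)
    if (any(M[i, others] == 0))
      stop("input error: identical cluster centres make the index undefined",
           call. = FALSE)
    max((S[i] + S[others]) / M[i, others])
  }, numeric(1))
  mean(ratios)
}

#' Select the number of clusters by the Davies-Bouldin index
#'
#' Runs \code{\link{kmedoids}} for every k in \code{k_range}, scores each
#' partition with \code{\link{davies_bouldin}}, and returns the solution with
#' the minimal index (ties broken toward smaller k, favouring parsimony).
#'
#' @param x numeric matrix of (normalized) series; \code{nrow(x)} must exceed
#'   \code{max(k_range)}.
#' @param k_range candidate cluster counts, default 2:7.
#' @param seed forwarded to \code{\link{kmedoids}} (deterministic; kept for
#'   interface stability).
#' @param center dispersion definition for the index, see
#'   \code{\link{davies_bouldin}}.
#' @return \code{cluster_solution} for the winning k, with \code{db_index}
#'   set and \code{per_k_db} a named numeric vector over \code{k_range}.
#' @export
select_k <- function(x, k_range = 2:7, seed = NULL,
                     center = c("centroid", "medoid")) {
  center <- match.arg(center)
  x <- as.matrix(x)
  if (nrow(x) <= max(k_range))
    stop("input error: need more series than max(k_range)", call. = FALSE)
  sols <- lapply(k_range, function(k) kmedoids(x, k, seed))
  db <- vapply(seq_along(k_range), function(i)
    davies_bouldin(x, sols[[i]]$labels, center = center,
                   medoid_indices = sols[[i]]$medoid_indices), numeric(1))
  names(db) <- as.character(k_range)
  best <- which.min(db)  # which.min takes the first (smallest k) on ties
  sol <- sols[[best]]
  sol$db_index <- db[[best]]
  sol$per_k_db <- db
  sol
}

#' Relabel clusters by descending size with Roman numerals
#'
#' Cohort reports label clusters I, II, ... from largest to smallest.
#'
#' @param labels integer cluster assignments.
#' @return factor of Roman numeral labels, levels ordered by descending
#'   cluster size (ties by original label order).
#' @export
relabel_by_size <- function(labels) {
  sizes <- table(labels)
  ord <- names(sizes)[order(-as.numeric(sizes), names(sizes))]
  roman <- as.character(utils::as.roman(seq_along(ord)))
  factor(roman[match(as.character(labels), ord)], levels = roman)
}
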